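# Contrast transfer function and tomography weighting.

#' CTF parameter set
#'
#' @param defocus_u,defocus_v defocus along the major/minor astigmatism axes,
#'   in Angstrom (positive = underfocus).
#' @param astigmatism_angle angle of the major axis, degrees.
#' @param voltage acceleration voltage, kV.
#' @param cs spherical aberration, mm.
#' @param amplitude_contrast amplitude contrast fraction in `[0, 1]`.
#' @param phase_shift additional phase shift (phase plate), degrees.
#' @param b_factor optional envelope B-factor, Angstrom^2.
#' @return object of class `ctf_params`.
#' @export
ctf_params <- function(defocus_u = 10000, defocus_v = 10000,
                       astigmatism_angle = 0, voltage = 300, cs = 2.7,
                       amplitude_contrast = 0.1, phase_shift = 0,
                       b_factor = 0) {
  if (defocus_u <= 0 || defocus_v <= 0) stop("defocus must be positive")
  if (voltage <= 0) stop("voltage must be positive")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("amplitude_contrast must lie in [0, 1]")
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 astigmatism_angle = astigmatism_angle, voltage = voltage,
                 cs = cs, amplitude_contrast = amplitude_contrast,
                 phase_shift = phase_shift, b_factor = b_factor),
            class = "ctf_params")
}

#' Relativistic electron wavelength
#' @param voltage_kv acceleration voltage in kV.
#' @return wavelength in Angstrom.
#' @keywords internal
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1000
  12.2643247 / sqrt(v * (1 + v * 0.978466e-6))
}

#' Evaluate the CTF on a frequency lattice
#'
#' CTFFIND-style convention:
#' `C(k) = -(sqrt(1 - w^2) sin(gamma) + w cos(gamma))` with phase
#' `gamma = pi lambda dz(a) |k|^2 - (pi/2) Cs lambda^3 |k|^4 + phase_shift`
#' and astigmatic defocus
#' `dz(a) = (zu + zv)/2 + (zu - zv)/2 cos(2 (a - a_ast))`.
#' At `k = 0` the value is `-w` (amplitude contrast only). An optional
#' B-factor applies the envelope `exp(-B |k|^2 / 4)`.
#'
#' @param ctf a [ctf_params()] object.
#' @param kx,ky frequency coordinates in cycles per image length (vectors of
#'   equal length), or `kx` a two-column matrix.
#' @param D image size (pixels).
#' @param pixel_size pixel size in Angstrom.
#' @return numeric vector of CTF values (within `[-1, 1]` before B-factor).
#' @export
eval_ctf <- function(ctf, kx, ky = NULL, D, pixel_size) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (is.matrix(kx) && is.null(ky)) { ky <- kx[, 2]; kx <- kx[, 1] }
  # convert cycles/image-length -> 1/Angstrom
  sx <- kx / (D * pixel_size)
  sy <- ky / (D * pixel_size)
  s2 <- sx^2 + sy^2
  ang <- atan2(sy, sx)
  lam <- electron_wavelength(ctf$voltage)
  zu <- ctf$defocus_u; zv <- ctf$defocus_v
  dz <- (zu + zv) / 2 +
    (zu - zv) / 2 * cos(2 * (ang - ctf$astigmatism_angle * pi / 180))
  gamma <- pi * lam * dz * s2 - (pi / 2) * (ctf$cs * 1e7) * lam^3 * s2^2 +
    ctf$phase_shift * pi / 180
  w <- ctf$amplitude_contrast
  out <- -(sqrt(1 - w^2) * sin(gamma) + w * cos(gamma))
  if (ctf$b_factor != 0) out <- out * exp(-ctf$b_factor * s2 / 4)
  out
}

#' Dose-dependent frequency weighting
#'
#' Exposure attenuation `exp(-d / (2 Ne(k)))` with the empirical critical
#' exposure `Ne(k) = 0.245 k^-1.665 + 2.81` (k in 1/Angstrom), as used in
#' standard dose-compensation schemes for tilt series.
#'
#' @param k_abs spatial frequency magnitude, 1/Angstrom.
#' @param dose cumulative dose, electrons/Angstrom^2.
#' @return weights in `(0, 1]`.
#' @export
dose_weight <- function(k_abs, dose) {
  ne <- 0.245 * pmax(k_abs, 1e-12)^(-1.665) + 2.81
  exp(-dose / (2 * ne))
}

#' Tilt metadata record
#' @param tilt_angle stage tilt, degrees.
#' @param cumulative_dose accumulated exposure at acquisition time, e/A^2.
#' @param tilt_order acquisition index (0-based).
#' @return object of class `tilt_meta`.
#' @export
tilt_meta <- function(tilt_angle, cumulative_dose = 0, tilt_order = 0L) {
  if (cumulative_dose < 0) stop("cumulative_dose must be >= 0")
  structure(list(tilt_angle = tilt_angle, cumulative_dose = cumulative_dose,
                 tilt_order = as.integer(tilt_order)), class = "tilt_meta")
}

#' Combined CTF, tilt and dose weights for a subtilt image
#'
#' Multiplies the CTF by `cos(tilt_angle)` (thickness attenuation at high
#' tilt) and by the dose-exposure weight at each frequency.
#'
#' @param ctf a [ctf_params()] object.
#' @param tilt a [tilt_meta()] object.
#' @inheritParams eval_ctf
#' @return numeric vector of weights.
#' @export
tilt_weights <- function(ctf, tilt, kx, ky = NULL, D, pixel_size) {
  if (abs(tilt$tilt_angle) >= 90) stop("|tilt_angle| must be < 90 degrees")
  if (is.matrix(kx) && is.null(ky)) { ky <- kx[, 2]; kx <- kx[, 1] }
  base <- eval_ctf(ctf, kx, ky, D = D, pixel_size = pixel_size)
  k_abs <- sqrt(kx^2 + ky^2) / (D * pixel_size)
  base * cos(tilt$tilt_angle * pi / 180) *
    dose_weight(k_abs, tilt$cumulative_dose)
}
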