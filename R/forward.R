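# Forward model: central-slice extraction, real-space projection oracle,
# and full image simulation (slice -> translate -> CTF -> noise).

#' Sample a gridded Hartley volume at arbitrary frequency coordinates
#'
#' Trilinear interpolation on the periodically extended lattice; points
#' outside `[-0.5, 0.5]^3` evaluate to 0 (band limit), never an error.
#'
#' @param vhat_ext extended Hartley volume, `(D+1)^3` array (see
#'   [ht_extend()]).
#' @param coords M x 3 matrix of frequencies in cycles per image length.
#' @param D underlying (even) grid size.
#' @return numeric vector of length M.
#' @export
sample_hartley_volume <- function(vhat_ext, coords, D) {
  L <- D + 1L
  stopifnot(all(dim(vhat_ext) == L))
  g <- coords * D + D / 2  # [0, D] on the extended grid
  g[coords < -0.5 - 1e-12 | coords > 0.5 + 1e-12] <- -1  # force fill
  .trilinear_cpp(as.numeric(vhat_ext), L, g, 0)
}

#' Central slice of a Hartley volume
#'
#' Implements the Fourier slice theorem in Hartley space: the slice at
#' rotation R samples `V_hat(R (kx, ky, 0)^T)` over the 2D frequency
#' lattice. Gridded volumes are interpolated trilinearly; a neural volume
#' field is evaluated directly at the rotated coordinates.
#'
#' With unitary transforms on a D-grid, the discrete Hartley transform of a
#' projection equals `sqrt(D)` times the sampled central slice of the 3D
#' transform (the z-sum collapses one 1/sqrt(D) factor); the returned slice
#' includes that factor, so `slice_volume(dht(V), R)` is directly comparable
#' to `dht(project_real(V, R))`.
#'
#' @param vhat a D^3 Hartley volume (compact lattice), a prepared slicer
#'   from [prep_slicer()], or a `volume_field`.
#' @param R 3 x 3 rotation matrix (acts on frequency coordinates as
#'   `k -> R k`).
#' @param D image size; required for fields, inferred for arrays.
#' @param z latent embedding (fields only).
#' @param oversample integer zero-padding factor for gridded volumes:
#'   the volume is padded to `oversample * D` before transforming, which
#'   shrinks the trilinear interpolation error of the narrow Hartley-domain
#'   features (default 1 = interpolate the native grid).
#' @return D x D Hartley image on the centered lattice.
#' @export
slice_volume <- function(vhat, R, D = NULL, z = NULL, oversample = 1L) {
  check_rotation(R)
  if (inherits(vhat, "volume_field")) {
    if (is.null(D)) stop("D is required when slicing a volume field")
    mi <- freq_index(D)
    k2 <- as.matrix(expand.grid(kx = mi / D, ky = mi / D))
    k3 <- cbind(k2, 0) %*% t(R)
    vals <- eval_field(vhat, z, k3)
    return(matrix(vals, D, D) * sqrt(D))
  }
  if (!inherits(vhat, "hartley_slicer")) {
    vhat <- prep_slicer(vhat, oversample = oversample)
  }
  D <- vhat$D
  mi <- freq_index(D)
  k2 <- as.matrix(expand.grid(kx = mi / D, ky = mi / D))
  k3 <- cbind(k2, 0) %*% t(R)
  matrix(sample_hartley_volume(vhat$vext, k3, vhat$D_big) * vhat$scale, D, D)
}

#' Prepare a gridded Hartley volume for repeated slicing
#'
#' Optionally zero-pads the volume (reducing interpolation error) and
#' precomputes the periodically extended transform so that many slices can
#' be drawn cheaply from the same volume.
#'
#' @param vhat D^3 Hartley volume (compact centered lattice).
#' @param oversample integer padding factor (1 = native grid).
#' @return object of class `hartley_slicer`.
#' @export
prep_slicer <- function(vhat, oversample = 1L) {
  dd <- dim(vhat)
  if (length(dd) != 3L || length(unique(dd)) != 1L)
    stop("prep_slicer expects a cubic Hartley volume")
  D <- dd[1]
  oversample <- as.integer(oversample)
  if (oversample <= 1L) {
    vext <- ht_extend(vhat)
    D_big <- D
    scale <- sqrt(D)
  } else {
    D_big <- oversample * D
    off <- (D_big - D) %/% 2L
    vol <- idht(vhat)
    big <- array(0, dim = rep(D_big, 3))
    big[off + 1:D, off + 1:D, off + 1:D] <- vol
    vext <- ht_extend(dht(big))
    # unitary coefficients shrink by oversample^(3/2) under zero padding
    scale <- sqrt(D) * oversample^1.5
  }
  structure(list(vext = vext, D = D, D_big = D_big, scale = scale),
            class = "hartley_slicer")
}

#' Real-space projection oracle
#'
#' Rotates a real-space volume by resampling at `R x` (so that the Fourier
#' transform of the projection equals the central slice at `R k`), sums along
#' the z axis, then applies the in-plane translation `t` in Hartley space.
#' This is the direct discretization of the orthographic projection model and
#' serves as the independent oracle for the Hartley slicing pipeline.
#'
#' @param vol D^3 real volume.
#' @param R 3 x 3 rotation matrix.
#' @param t length-2 translation in pixels (default none).
#' @return D x D projected image.
#' @export
project_real <- function(vol, R, t = c(0, 0)) {
  check_rotation(R)
  d <- dim(vol)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("project_real expects a cubic volume")
  D <- d[1]
  # centered coordinates matching the DHT convention: voxel i has
  # coordinate i - 1 - D/2, so the rotation center is voxel D/2 + 1
  mi <- freq_index(D)
  g <- as.matrix(expand.grid(x = mi, y = mi, z = mi))
  rc <- g %*% t(R) + D / 2  # 0-based grid coords for the sampler
  vals <- .trilinear_cpp(as.numeric(vol), D, rc, 0)
  rot <- array(vals, dim = d)
  img <- apply(rot, c(1, 2), sum)
  if (any(t != 0)) img <- idht(translate_hartley(dht(img), t))
  img
}

#' Simulate one observed image
#'
#' Full generative model: central slice of the (gridded or neural) Hartley
#' volume at rotation R, Hartley-space translation by t, element-wise CTF
#' (or tilt/dose weights), inverse Hartley transform, additive white
#' Gaussian noise. Noise uses the current RNG stream.
#'
#' @param vhat Hartley volume (compact or extended) or `volume_field`.
#' @param pose list with elements `R` (3 x 3) and `t` (length 2, pixels).
#' @param ctf [ctf_params()] or `NULL` for an all-ones (identity) CTF.
#' @param D image size; required for fields.
#' @param pixel_size pixel size in Angstrom (needed when `ctf` given).
#' @param tilt optional [tilt_meta()]; switches to [tilt_weights()].
#' @param noise_std standard deviation of the additive noise (>= 0).
#' @param z latent embedding (fields only).
#' @param oversample slicing oversampling factor, see [slice_volume()].
#' @return list with `image` (noisy) and `clean` (noiseless) D x D images.
#' @export
simulate_observation <- function(vhat, pose, ctf = NULL, D = NULL,
                                 pixel_size = 1, tilt = NULL,
                                 noise_std = 0, z = NULL, oversample = 1L) {
  if (noise_std < 0) stop("noise_std must be >= 0")
  sl <- slice_volume(vhat, pose$R, D = D, z = z, oversample = oversample)
  D <- nrow(sl)
  if (any(pose$t != 0)) sl <- translate_hartley(sl, pose$t)
  if (!is.null(ctf)) {
    mi <- freq_index(D)
    kk <- as.matrix(expand.grid(kx = mi, ky = mi))
    w <- if (is.null(tilt)) {
      eval_ctf(ctf, kk, D = D, pixel_size = pixel_size)
    } else {
      tilt_weights(ctf, tilt, kk, D = D, pixel_size = pixel_size)
    }
    sl <- sl * matrix(w, D, D)
  }
  clean <- idht(sl)
  img <- clean
  if (noise_std > 0) img <- img + matrix(stats::rnorm(D * D, sd = noise_std), D, D)
  list(image = img, clean = clean)
}
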