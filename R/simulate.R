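# Synthetic-data generator: Gaussian-mixture phantoms and simulated
# single-particle, 1D-motion and tilt-series datasets. The generator's
# defaults are the study conditions used throughout the test suite: uniform
# SO(3) rotations, centered images (no translations unless requested),
# log-normal defocus, white Gaussian noise of standard deviation 0.5.

#' Gaussian-mixture phantom specification
#'
#' @param centers list of length-3 blob centers (pixels, centered
#'   coordinates).
#' @param sigmas per-blob isotropic standard deviation in pixels, or a list
#'   of 3 x 3 covariance matrices.
#' @param amps per-blob amplitudes (>= 0).
#' @param mobile optional integer vector: indices of blobs forming a mobile
#'   sub-component for heterogeneity.
#' @param axis,pivot rotation axis (unit 3-vector) and pivot point (pixels)
#'   of the mobile component.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(centers, sigmas, amps, mobile = NULL,
                         axis = c(0, 0, 1), pivot = c(0, 0, 0)) {
  n <- length(centers)
  if (length(sigmas) == 1L) sigmas <- rep(sigmas, n)
  if (length(amps) == 1L) amps <- rep(amps, n)
  stopifnot(length(sigmas) == n, length(amps) == n, all(amps >= 0))
  structure(list(centers = centers, sigmas = sigmas, amps = amps,
                 mobile = mobile, axis = axis / sqrt(sum(axis^2)),
                 pivot = pivot), class = "phantom_spec")
}

#' Default two-domain phantom
#'
#' A deliberately asymmetric arrangement of Gaussian blobs with a mobile
#' arm, standing in for a macromolecular density in the simulated
#' datasets. No blob pair is close to centrosymmetric: a nearly even
#' density makes views from opposite directions nearly indistinguishable,
#' which is a property of the object rather than of any estimator. Blob
#' scale keeps both the map and its Hartley transform adequately sampled
#' at the default box sizes.
#'
#' @param D box size the phantom is intended for (scales blob geometry).
#' @return a [phantom_spec()].
#' @export
default_phantom <- function(D = 32) {
  s <- D / 32
  phantom_spec(
    centers = list(c(3, 1, 2) * s, c(-1, 4, -1) * s, c(1, -3, -3) * s,
                   c(-4, -1, 2) * s, c(0, 1, -1) * s),
    sigmas = c(2.5, 2, 2, 1.8, 3) * s,
    amps = c(1, 0.8, 0.9, 0.7, 0.5),
    mobile = c(4L, 5L), axis = c(0, 0, 1), pivot = c(0, 0, 0)
  )
}

#' Rotate a phantom's mobile sub-component
#' @param spec a [phantom_spec()] with a `mobile` subset.
#' @param angle rotation angle in radians about `spec$axis` through
#'   `spec$pivot`.
#' @return new `phantom_spec` with moved blob centers.
#' @export
rotate_mobile <- function(spec, angle) {
  if (is.null(spec$mobile)) stop("phantom has no mobile component")
  a <- spec$axis
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  out <- spec
  for (i in spec$mobile) {
    out$centers[[i]] <- as.numeric(R %*% (spec$centers[[i]] - spec$pivot)) +
      spec$pivot
  }
  out
}

#' Sample a phantom on the voxel grid
#'
#' @param spec a [phantom_spec()].
#' @param D even box size.
#' @return D^3 real array (sum of the Gaussian blobs).
#' @export
make_phantom <- function(spec, D) {
  .check_even(D)
  mi <- freq_index(D)
  g <- as.matrix(expand.grid(x = mi, y = mi, z = mi))
  v <- numeric(nrow(g))
  for (i in seq_along(spec$amps)) {
    if (is.matrix(spec$sigmas[[1]])) {
      S <- solve(spec$sigmas[[i]])
      dd <- sweep(g, 2, spec$centers[[i]])
      q <- rowSums((dd %*% S) * dd)
    } else {
      q <- rowSums(sweep(g, 2, spec$centers[[i]])^2) / spec$sigmas[i]^2
    }
    v <- v + spec$amps[i] * exp(-q / 2)
  }
  array(v, dim = rep(D, 3))
}

#' Analytic Hartley transform of a phantom
#'
#' Closed form: the transform of an isotropic Gaussian blob of width sigma,
#' amplitude a and center c, sampled on the unitary centered D-lattice, is
#' `a (2 pi)^(3/2) sigma^3 / D^(3/2) * exp(-2 pi^2 sigma^2 |f|^2) *
#' (cos(2 pi f.c) + sin(2 pi f.c))` with `f` in cycles per pixel. Used as
#' the independent oracle for the numeric transform.
#'
#' @param spec a [phantom_spec()] with scalar sigmas.
#' @param D box size.
#' @return D^3 array of Hartley coefficients.
#' @export
phantom_hartley_analytic <- function(spec, D) {
  mi <- freq_index(D)
  f <- as.matrix(expand.grid(x = mi, y = mi, z = mi)) / D
  v <- numeric(nrow(f))
  for (i in seq_along(spec$amps)) {
    s <- spec$sigmas[i]
    ph <- 2 * pi * (f %*% spec$centers[[i]])
    v <- v + spec$amps[i] * (2 * pi)^1.5 * s^3 / D^1.5 *
      exp(-2 * pi^2 * s^2 * rowSums(f^2)) * (cos(ph) + sin(ph))
  }
  array(v, dim = rep(D, 3))
}

#' Log-normal defocus sampler
#' @param n number of draws.
#' @param median_um median defocus in micrometers.
#' @param sigma_log log-scale standard deviation.
#' @return defocus values in Angstrom.
#' @export
sample_defocus <- function(n, median_um = 1.0, sigma_log = 0.3) {
  stats::rlnorm(n, meanlog = log(median_um * 1e4), sdlog = sigma_log)
}

#' Simulate a single-particle dataset
#'
#' Per image: a uniform SO(3) rotation, translation 0 (or uniform in
#' `+/- translation_px`), a log-normal defocus CTF, the Hartley-space
#' projection pipeline, and white Gaussian noise of `noise_std`.
#'
#' @param phantoms a [phantom_spec()], a single D^3 volume, or a list of
#'   either (one entry per discrete state).
#' @param n number of images.
#' @param D even image size.
#' @param noise_std additive noise standard deviation (paper-style default
#'   0.5 for normalized-intensity phantoms).
#' @param pixel_size Angstrom per pixel.
#' @param translation_px if > 0, translations are sampled uniformly in
#'   `[-translation_px, translation_px]` per axis; default 0 (centered).
#' @param defocus_median_um,defocus_sigma_log log-normal defocus parameters.
#' @param states optional integer vector of per-image state labels (indices
#'   into `phantoms`); default cycles uniformly at random.
#' @param seed RNG seed for the whole dataset.
#' @param oversample slicing oversampling factor.
#' @return object of class `simulated_dataset`: a list with `images`
#'   (D x D x n), `clean` (noiseless renders), `poses` (list of R, t),
#'   `ctf` (list of [ctf_params()]), `states`, `maps` (per-state ground
#'   truth volumes), `noise_std`, `pixel_size`, `D`.
#' @export
simulate_spa <- function(phantoms, n, D = 64, noise_std = 0.5,
                         pixel_size = 3.0, translation_px = 0,
                         defocus_median_um = 1.0, defocus_sigma_log = 0.3,
                         states = NULL, seed = 0, oversample = 2L) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  if (inherits(phantoms, "phantom_spec") || is.array(phantoms))
    phantoms <- list(phantoms)
  maps <- lapply(phantoms, function(p) {
    if (inherits(p, "phantom_spec")) make_phantom(p, D) else p
  })
  slicers <- lapply(maps, function(m) prep_slicer(dht(m), oversample))
  if (is.null(states)) {
    states <- if (length(maps) == 1L) rep(1L, n)
              else sample.int(length(maps), n, replace = TRUE)
  }
  rots <- random_rotations(n)
  trans <- if (translation_px > 0) {
    matrix(stats::runif(2 * n, -translation_px, translation_px), n, 2)
  } else matrix(0, n, 2)
  defocus <- sample_defocus(n, defocus_median_um, defocus_sigma_log)
  ast <- stats::runif(n, 0, 180)
  images <- array(0, dim = c(D, D, n))
  clean <- array(0, dim = c(D, D, n))
  ctfs <- vector("list", n)
  for (i in seq_len(n)) {
    ctfs[[i]] <- ctf_params(defocus_u = defocus[i] * 1.02,
                            defocus_v = defocus[i] * 0.98,
                            astigmatism_angle = ast[i])
    ob <- simulate_observation(slicers[[states[i]]],
                               pose = list(R = rots[[i]], t = trans[i, ]),
                               ctf = ctfs[[i]], pixel_size = pixel_size,
                               noise_std = noise_std)
    images[, , i] <- ob$image
    clean[, , i] <- ob$clean
  }
  structure(list(images = images, clean = clean,
                 poses = list(R = rots, t = trans), ctf = ctfs,
                 states = states, maps = maps, noise_std = noise_std,
                 pixel_size = pixel_size, D = D, seed = seed),
            class = "simulated_dataset")
}

#' Simulate a continuous 1D-motion dataset
#'
#' Generates `n_states` ground-truth maps along a 1D reaction coordinate by
#' rotating the phantom's mobile sub-component in fixed increments
#' (defaults: 50 states, 0.03 rad), then projects each state
#' `images_per_state` times with random poses.
#'
#' @param base_spec a [phantom_spec()] with a mobile component.
#' @param n_states number of states along the coordinate (>= 2).
#' @param increment_rad rotation increment between adjacent states.
#' @param images_per_state projections per state.
#' @param translation_px translation range (the reference setting uses
#'   +/- 10 pixels at D = 128; scale accordingly).
#' @inheritParams simulate_spa
#' @return a `simulated_dataset`; `states` holds the 1-based state index.
#' @export
simulate_1d_motion <- function(base_spec, n_states = 50L,
                               increment_rad = 0.03,
                               images_per_state = 10L, D = 32,
                               noise_std = 0.5, pixel_size = 3.0,
                               translation_px = 0, seed = 0,
                               oversample = 2L) {
  if (n_states < 2) stop("n_states must be >= 2")
  specs <- lapply(seq_len(n_states) - 1L,
                  function(s) rotate_mobile(base_spec, s * increment_rad))
  states <- rep(seq_len(n_states), each = images_per_state)
  simulate_spa(specs, n = length(states), D = D, noise_std = noise_std,
               pixel_size = pixel_size, translation_px = translation_px,
               states = states, seed = seed, oversample = oversample)
}

#' Dose-symmetric tilt sequence
#' @param J number of tilts.
#' @param increment_deg angular increment between consecutive tilts.
#' @return numeric vector of tilt angles in acquisition order
#'   (0, +d, -d, +2d, -2d, ...).
#' @export
dose_symmetric_tilts <- function(J, increment_deg = 3) {
  k <- seq_len(J) - 1L
  ang <- ceiling(k / 2) * increment_deg
  sign <- ifelse(k == 0, 0, ifelse(k %% 2 == 1, 1, -1))
  sign * ang
}

#' Simulate a subtilt (tilt-series) dataset
#'
#' One orientation per particle; subtilt j composes the particle pose with
#' the stage tilt (`R_ij = Ry(tilt_j) R_i`), and the per-subtilt weights
#' apply the CTF, the cosine of the tilt angle and the cumulative-dose
#' attenuation (`dose = tilt_order * dose_per_tilt`).
#'
#' @param phantom a [phantom_spec()] or D^3 volume.
#' @param n_particles number of particles.
#' @param J tilts per particle.
#' @param tilt_increment_deg degrees between consecutive tilts (default 3).
#' @param dose_per_tilt electrons/Angstrom^2 accumulated per tilt image.
#' @inheritParams simulate_spa
#' @return a `simulated_dataset` with additional fields `particle_index`
#'   (one per image), `tilts` (list of [tilt_meta()] per image) and
#'   `particle_poses` (per-particle ground truth).
#' @export
simulate_tilt_series <- function(phantom, n_particles, J = 11L,
                                 tilt_increment_deg = 3,
                                 dose_per_tilt = 3, D = 32,
                                 noise_std = 0.5, pixel_size = 3.0,
                                 seed = 0, oversample = 2L) {
  if (J < 1) stop("J must be >= 1")
  set.seed(seed)
  vol <- if (inherits(phantom, "phantom_spec")) make_phantom(phantom, D)
         else phantom
  slicer <- prep_slicer(dht(vol), oversample)
  angles <- dose_symmetric_tilts(J, tilt_increment_deg)
  prots <- random_rotations(n_particles)
  defocus <- sample_defocus(n_particles)
  n <- n_particles * J
  images <- array(0, dim = c(D, D, n))
  clean <- array(0, dim = c(D, D, n))
  ctfs <- vector("list", n); tilts <- vector("list", n)
  rots <- vector("list", n)
  particle_index <- integer(n)
  idx <- 0L
  for (i in seq_len(n_particles)) {
    ctf_i <- ctf_params(defocus_u = defocus[i], defocus_v = defocus[i])
    for (j in seq_len(J)) {
      idx <- idx + 1L
      tl <- tilt_meta(angles[j], cumulative_dose = (j - 1L) * dose_per_tilt,
                      tilt_order = j - 1L)
      Rij <- rot_y(angles[j] * pi / 180) %*% prots[[i]]
      ob <- simulate_observation(slicer, pose = list(R = Rij, t = c(0, 0)),
                                 ctf = ctf_i, pixel_size = pixel_size,
                                 tilt = tl, noise_std = noise_std)
      images[, , idx] <- ob$image
      clean[, , idx] <- ob$clean
      ctfs[[idx]] <- ctf_i; tilts[[idx]] <- tl; rots[[idx]] <- Rij
      particle_index[idx] <- i
    }
  }
  structure(list(images = images, clean = clean,
                 poses = list(R = rots, t = matrix(0, n, 2)), ctf = ctfs,
                 tilts = tilts, particle_index = particle_index,
                 particle_poses = prots, states = rep(1L, n),
                 maps = list(vol), noise_std = noise_std,
                 pixel_size = pixel_size, D = D, J = J, seed = seed),
            class = "simulated_dataset")
}
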