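# ParticleStack: images plus per-image CTF/tilt metadata.

#' Construct a particle stack
#'
#' @param images D x D x N array of real images (D even, >= 16).
#' @param pixel_size Angstrom per pixel (> 0).
#' @param ctf list of [ctf_params()] (length N) or NULL.
#' @param tilt list of [tilt_meta()] (length N) or NULL.
#' @param particle_index integer per image grouping subtilts of one
#'   particle (defaults to 1..N, one particle per image).
#' @return object of class `particle_stack`.
#' @export
particle_stack <- function(images, pixel_size, ctf = NULL, tilt = NULL,
                           particle_index = NULL) {
  d <- dim(images)
  if (length(d) == 2L) { images <- array(images, dim = c(d, 1L)); d <- dim(images) }
  if (d[1] != d[2]) stop("images must be square, got ", d[1], " x ", d[2])
  if (d[1] %% 2L != 0L || d[1] < 16L)
    stop("image size must be even and >= 16, got ", d[1])
  if (any(!is.finite(images))) stop("images contain non-finite values")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  N <- d[3]
  if (!is.null(ctf) && length(ctf) != N)
    stop("ctf list length (", length(ctf), ") != image count (", N, ")")
  if (is.null(particle_index)) particle_index <- seq_len(N)
  if (!is.null(tilt)) {
    if (length(tilt) != N) stop("tilt list must have one entry per image")
    Js <- table(particle_index)
    if (length(unique(Js)) != 1L)
      stop("every particle must have the same number of subtilts")
    # dose must be non-decreasing in acquisition order within a particle
    for (p in unique(particle_index)) {
      rows <- which(particle_index == p)
      ord <- order(vapply(tilt[rows], `[[`, integer(1), "tilt_order"))
      doses <- vapply(tilt[rows][ord], `[[`, numeric(1), "cumulative_dose")
      if (any(diff(doses) < 0))
        stop("cumulative dose must be non-decreasing within particle ", p)
    }
  }
  structure(list(images = images, D = d[1], n = N,
                 pixel_size = pixel_size, ctf = ctf, tilt = tilt,
                 particle_index = as.integer(particle_index)),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  cat("particle_stack:", x$n, "images of", x$D, "x", x$D, "px at",
      x$pixel_size, "A/px;",
      if (is.null(x$tilt)) "no tilt metadata" else
        paste0(length(unique(x$particle_index)), " particles with tilts"),
      "\n")
  invisible(x)
}

#' Normalize images in place
#'
#' Subtracts the per-image mean and divides by the per-image standard
#' deviation (the pixel-space normalization applied to every input
#' dataset); raw values are preserved when `normalize = FALSE` at load.
#'
#' @param stack a `particle_stack`.
#' @return normalized stack.
#' @export
normalize_stack <- function(stack) {
  for (i in seq_len(stack$n)) {
    im <- stack$images[, , i]
    s <- stats::sd(im)
    stack$images[, , i] <- (im - mean(im)) / if (s > 0) s else 1
  }
  stack
}

#' Read a particle stack from MRCS + STAR
#'
#' The STAR rows must align 1:1 with the stack images (by order). CTF
#' parameters are taken from the standard RELION tags; tilt metadata (when
#' present) from the tomography tags, with the cumulative dose either read
#' from a dose tag or computed as `tilt_order * dose_per_tilt`.
#'
#' @param mrcs_path MRCS image stack.
#' @param star_path STAR metadata file.
#' @param normalize per-image mean/sd normalization (default TRUE).
#' @param dose_per_tilt fallback dose increment for tilt series.
#' @return a [particle_stack()].
#' @export
read_particle_stack <- function(mrcs_path, star_path = NULL,
                                normalize = TRUE, dose_per_tilt = NULL) {
  mrc <- read_mrc(mrcs_path)
  imgs <- mrc$data
  if (dim(imgs)[1] != dim(imgs)[2])
    stop("non-square images (", dim(imgs)[1], " x ", dim(imgs)[2],
         ") are not supported")
  N <- dim(imgs)[3]
  ctf <- NULL; tilt <- NULL; pidx <- NULL
  px <- mrc$pixel_size
  if (!is.null(star_path)) {
    df <- star_particles(read_star(star_path))
    if (nrow(df) != N)
      stop("STAR has ", nrow(df), " rows but MRCS holds ", N, " images")
    ctf <- star_ctf(df)
    star_px <- .star_first(df, c("rlnImagePixelSize", "rlnPixelSize"))
    if (!is.null(star_px)) px <- star_px[1]
    tilt_ang <- .star_first(df, c("rlnTomoTiltAngle", "rlnAngleTilt",
                                  "rlnTiltAngle"))
    if (!is.null(tilt_ang)) {
      tg <- tilt_groups(df, dose_per_tilt = dose_per_tilt)
      pidx <- integer(N)
      for (g in seq_along(tg$groups)) pidx[tg$groups[[g]]] <- g
      ordv <- unlist(lapply(tg$groups, function(g) seq_along(g) - 1L))
      ord <- integer(N); ord[unlist(tg$groups)] <- ordv
      tilt <- lapply(seq_len(N), function(i) {
        tilt_meta(tilt_ang[i],
                  cumulative_dose = if (is.na(tg$dose[i])) 0 else tg$dose[i],
                  tilt_order = ord[i])
      })
    }
  }
  st <- particle_stack(imgs, pixel_size = px, ctf = ctf, tilt = tilt,
                       particle_index = pidx)
  if (normalize) st <- normalize_stack(st) else st
}

#' Write a particle stack to MRCS + STAR
#'
#' @param stack a `particle_stack`.
#' @param mrcs_path,star_path output files.
#' @return invisibly, the two paths.
#' @export
write_particle_stack <- function(stack, mrcs_path, star_path = NULL) {
  write_mrc(stack$images, stack$pixel_size, mrcs_path, is_stack = TRUE)
  if (!is.null(star_path)) {
    n <- stack$n
    df <- data.frame(
      rlnImageName = sprintf("%06d@%s", seq_len(n), basename(mrcs_path)))
    if (!is.null(stack$ctf)) {
      g <- function(f) vapply(stack$ctf, `[[`, numeric(1), f)
      df$rlnDefocusU <- g("defocus_u")
      df$rlnDefocusV <- g("defocus_v")
      df$rlnDefocusAngle <- g("astigmatism_angle")
      df$rlnVoltage <- g("voltage")
      df$rlnSphericalAberration <- g("cs")
      df$rlnAmplitudeContrast <- g("amplitude_contrast")
      df$rlnPhaseShift <- g("phase_shift")
    }
    if (!is.null(stack$tilt)) {
      df$rlnTomoParticleId <- stack$particle_index
      df$rlnTomoTiltAngle <- vapply(stack$tilt, `[[`, numeric(1),
                                    "tilt_angle")
      df$rlnCumulativeDose <- vapply(stack$tilt, `[[`, numeric(1),
                                     "cumulative_dose")
      df$rlnTomoTiltOrder <- vapply(stack$tilt, `[[`, integer(1),
                                    "tilt_order")
    }
    df$rlnImagePixelSize <- stack$pixel_size
    write_star(list(particles = df), star_path)
  }
  invisible(c(mrcs_path, star_path))
}

#' Poses as a STAR-compatible table
#' @param poses list with `R` (list) and `t` (N x 2, pixels).
#' @return data frame with ZYZ Euler angles (degrees) and origin shifts.
#' @export
poses_to_star_table <- function(poses) {
  ang <- t(vapply(poses$R, euler_zyz, numeric(3))) * 180 / pi
  data.frame(rlnAngleRot = ang[, 1], rlnAngleTilt = ang[, 2],
             rlnAnglePsi = ang[, 3],
             rlnOriginX = poses$t[, 1], rlnOriginY = poses$t[, 2])
}
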