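# Minimal HEALPix (nested scheme) pixel centers.
#
# Only the pieces the pose-search grid needs: pixel-center directions for a
# power-of-two nside in the NESTED numbering (so the 4 children of pixel p at
# the next resolution are 4p .. 4p+3). Implements the standard equal-area
# pixelization geometry: 12 base faces, polar caps and equatorial belt.

# de-interleave the even bits of x (compressed), for x < 2^30
.compress_bits <- function(x) {
  out <- integer(length(x))
  bit <- 0L
  while (any(x > 0L)) {
    out <- bitwOr(out, bitwShiftL(bitwAnd(x, 1L), bit))
    x <- bitwShiftR(x, 2L)
    bit <- bit + 1L
  }
  out
}

#' HEALPix nested pixel centers
#'
#' Returns the spherical coordinates of pixel centers for the nested
#' numbering scheme.
#'
#' @param nside resolution parameter (power of two); the sphere has
#'   `12 * nside^2` equal-area pixels.
#' @param ipix integer pixel indices in `0 .. 12 nside^2 - 1` (default all).
#' @return matrix with columns `theta` (colatitude, radians) and `phi`
#'   (longitude, radians).
#' @export
healpix_pix2ang <- function(nside, ipix = seq_len(12 * nside^2) - 1L) {
  if (bitwAnd(nside, nside - 1L) != 0L) stop("nside must be a power of two")
  npface <- nside * nside
  if (any(ipix < 0L | ipix >= 12L * npface)) stop("pixel index out of range")
  jrll <- c(2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L)
  jpll <- c(1L, 3L, 5L, 7L, 0L, 2L, 4L, 6L, 1L, 3L, 5L, 7L)
  face <- ipix %/% npface
  p <- ipix %% npface
  ix <- .compress_bits(p)
  iy <- .compress_bits(p %/% 2L)
  jr <- jrll[face + 1L] * nside - ix - iy - 1L
  z <- numeric(length(ipix)); nr <- integer(length(ipix))
  kshift <- integer(length(ipix))
  north <- jr < nside
  south <- jr > 3L * nside
  equa <- !north & !south
  nr[north] <- jr[north]
  z[north] <- 1 - nr[north]^2 / (3 * nside^2)
  nr[south] <- 4L * nside - jr[south]
  z[south] <- -1 + nr[south]^2 / (3 * nside^2)
  nr[equa] <- nside
  z[equa] <- (2L * nside - jr[equa]) * 2 / (3 * nside)
  kshift[equa] <- bitwAnd(jr[equa] - nside, 1L)
  jp <- (jpll[face + 1L] * nr + ix - iy + 1L + kshift) %/% 2L
  jp <- ifelse(jp > 4L * nr, jp - 4L * nr, ifelse(jp < 1L, jp + 4L * nr, jp))
  phi <- (jp - (kshift + 1) * 0.5) * (pi / (2 * nr))
  cbind(theta = acos(z), phi = phi)
}

#' Nested children of a HEALPix pixel
#' @param ipix pixel index at the current resolution.
#' @return the four child indices at nside doubled.
#' @keywords internal
healpix_children <- function(ipix) 4L * ipix + 0:3

#' Unit vectors of pixel centers
#' @param ang matrix from [healpix_pix2ang()].
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
ang_to_vec <- function(ang) {
  st <- sin(ang[, 1])
  cbind(st * cos(ang[, 2]), st * sin(ang[, 2]), cos(ang[, 1]))
}
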