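#' @useDynLib cryofield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Centered, unitary discrete Hartley transforms.
#
# All transforms act on grids whose spatial and frequency axes are centered:
# index i in 1..D maps to coordinate m = i - 1 - D/2 in [-D/2, D/2 - 1]
# (D even). Frequencies are expressed in cycles per image length, k = m / D,
# so k lies in [-0.5, 0.5). Unitary normalization (1/sqrt(D) per axis) makes
# the transform an involution: dht(dht(x)) == x.

#' Shift the zero index to/from the array center
#'
#' For even-sized axes the forward and inverse shifts coincide, so a single
#' function serves both directions.
#'
#' @param x numeric or complex array (vector, matrix or 3D array).
#' @return array of the same shape with halves swapped along every axis.
#' @keywords internal
fft_shift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    h <- n %/% 2L
    c((h + 1L):n, seq_len(h))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Centered frequency indices of a D-sample axis
#' @param D even axis length.
#' @return integer vector -D/2 .. D/2-1.
#' @keywords internal
freq_index <- function(D) seq.int(-D %/% 2L, D %/% 2L - 1L)

.check_even <- function(D) {
  if (D %% 2L != 0L) stop("grid size must be even, got ", D)
}

#' Discrete Hartley transform (centered, unitary)
#'
#' Computes `H(x) = Re(F(x)) - Im(F(x))` on centered spatial and frequency
#' grids with unitary normalization, so `dht(dht(x)) == x`. Works on
#' matrices (images) and 3D arrays (volumes).
#'
#' @param x real matrix or cubic array with even side length.
#' @return real array of the same shape: the Hartley coefficients on the
#'   centered frequency lattice (index i corresponds to frequency
#'   (i - 1 - D/2)/D cycles per image length).
#' @export
#' @examples
#' x <- matrix(rnorm(64), 8, 8)
#' max(abs(dht(dht(x)) - x)) < 1e-12
dht <- function(x) {
  if (is.complex(x)) stop("dht expects real input")
  d <- dim(x)
  if (is.null(d)) stop("dht expects a matrix or 3D array")
  for (n in d) .check_even(n)
  f <- fft_shift(stats::fft(fft_shift(x)))
  (Re(f) - Im(f)) / sqrt(prod(d))
}

#' @rdname dht
#' @export
idht <- function(x) dht(x)

#' Complex centered unitary DFT (helper for FSC and oracles)
#' @param x real array.
#' @return complex array, centered frequency lattice.
#' @keywords internal
cfft <- function(x) {
  d <- dim(x)
  fft_shift(stats::fft(fft_shift(x))) / sqrt(prod(d))
}

#' Periodically extend a Hartley array to the closed lattice from -D/2 to D/2
#'
#' The compact centered lattice misses the +D/2 row/column, which equals the
#' -D/2 one by periodicity. The extended (D+1)-per-axis array makes the -k
#' partner of every lattice point exact, which the Hartley translation
#' identity and trilinear slicing rely on.
#'
#' @param h real matrix (D x D) or array (D^3) of Hartley coefficients.
#' @return array with each axis extended to D+1 samples.
#' @export
ht_extend <- function(h) {
  d <- dim(h)
  if (length(d) == 2L) {
    out <- rbind(h, h[1L, , drop = FALSE])
    cbind(out, out[, 1L, drop = FALSE])
  } else if (length(d) == 3L) {
    D <- d[1L]
    out <- array(0, dim = d + 1L)
    out[1:D, 1:D, 1:D] <- h
    out[D + 1L, , ] <- out[1L, , ]
    out[, D + 1L, ] <- out[, 1L, ]
    out[, , D + 1L] <- out[, , 1L]
    out
  } else stop("ht_extend expects a 2D or 3D array")
}

#' In-band frequency lattice of a D x D image
#'
#' Enumerates the centered lattice points with |m| <= cutoff (grid units,
#' cycles per image length) together with the position of each point's -k
#' partner. The full band is radius D/2 - 1: the Nyquist ring is excluded so
#' that every retained point has an exact partner on the compact lattice.
#'
#' @param D even image size.
#' @param cutoff radial band limit in grid units; `NULL` means full band
#'   (D/2 - 1).
#' @return list with `m`,`n` (integer grid coords), `k` (M x 2 matrix in
#'   cycles/image length), `idx` (linear index into the D x D matrix),
#'   `neg` (row index of the -k partner within this set), `cutoff`, `D`.
#' @export
inband_lattice <- function(D, cutoff = NULL) {
  .check_even(D)
  full <- D %/% 2L - 1L
  if (is.null(cutoff)) cutoff <- full
  if (cutoff > full) cutoff <- full
  mi <- freq_index(D)
  g <- expand.grid(m = mi, n = mi)
  keep <- g$m^2 + g$n^2 <= cutoff^2
  m <- g$m[keep]; n <- g$n[keep]
  idx <- (m + D %/% 2L + 1L) + (n + D %/% 2L) * D
  key <- paste(m, n)
  neg <- match(paste(-m, -n), key)
  stopifnot(!anyNA(neg))
  list(m = m, n = n, k = cbind(m, n) / D, idx = idx, neg = neg,
       cutoff = cutoff, D = D)
}

#' Translate an image in Hartley space
#'
#' Applies the Hartley-domain shift identity
#' `T_t H(k) = cos(2 pi t.k) H(k) + sin(2 pi t.k) H(-k)`,
#' the real-valued analogue of the Fourier shift theorem. The -k lookup uses
#' the periodic extension of the compact centered lattice, so the identity is
#' exact for every lattice point including the Nyquist row.
#'
#' @param h D x D Hartley image (centered lattice).
#' @param t length-2 translation in pixels (applied as a shift of the
#'   underlying real image by +t).
#' @return translated Hartley image, same shape.
#' @export
translate_hartley <- function(h, t) {
  D <- nrow(h)
  if (ncol(h) != D) stop("translate_hartley expects a square image")
  .check_even(D)
  if (all(t == 0)) return(h)
  mi <- freq_index(D)
  kx <- matrix(mi / D, D, D)
  ky <- matrix(mi / D, D, D, byrow = TRUE)
  ph <- 2 * pi * (t[1] * kx + t[2] * ky)
  # -k partner on the compact lattice: negation with the -D/2 index fixed
  # (its partner +D/2 aliases back onto itself by periodicity)
  flip <- c(1L, D:2L)
  hneg <- h[flip, flip]
  cos(ph) * h + sin(ph) * hneg
}

#' Band-limit an image stack by Fourier cropping
#'
#' Keeps the central `D_new` x `D_new` block of the centered Fourier
#' transform and returns to real space, rescaling so that the image mean and
#' all in-band sinusoid amplitudes are preserved. This is the standard
#' downsampling step applied to particle stacks before reconstruction.
#'
#' @param x a D x D image, a D x D x N image stack, or a `particle_stack`.
#' @param D_new target (even) size, `D_new <= D`.
#' @return object of the same kind at size `D_new`; for a `particle_stack`
#'   the pixel size is scaled by `D / D_new`.
#' @export
fourier_crop <- function(x, D_new) {
  if (inherits(x, "particle_stack")) {
    imgs <- fourier_crop(x$images, D_new)
    out <- x
    out$images <- imgs
    out$D <- D_new
    out$pixel_size <- x$pixel_size * dim(x$images)[1] / D_new
    return(out)
  }
  d <- dim(x)
  D <- d[1]
  .check_even(D); .check_even(D_new)
  if (D_new > D) stop("D_new (", D_new, ") exceeds current size (", D, ")")
  if (D_new == D) return(x)
  crop1 <- function(img) {
    f <- fft_shift(stats::fft(fft_shift(img)))
    lo <- D %/% 2L - D_new %/% 2L + 1L
    hi <- lo + D_new - 1L
    fc <- f[lo:hi, lo:hi] * (D_new / D)^2
    Re(fft_shift(stats::fft(fft_shift(fc), inverse = TRUE))) / D_new^2
  }
  if (length(d) == 2L) return(crop1(x))
  out <- array(0, dim = c(D_new, D_new, d[3]))
  for (i in seq_len(d[3])) out[, , i] <- crop1(x[, , i])
  out
}
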