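# Conditional implicit neural representation of Hartley volumes.
#
# The field maps (latent z in R^d, frequency k in [-0.5, 0.5]^3) to a single
# Hartley coefficient. Architecture: 64 Gaussian random Fourier base
# frequencies (sd 0.5, fixed after initialization) expand k into a
# 128-vector [sin(2 pi B k); cos(2 pi B k)]; the concatenation with z passes
# through a linear layer to the hidden width, 3 residual hidden layers
# (y = relu(x + W_b relu(W_a x + b_a) + b_b)) with ReLU, and a final linear
# layer to one output. Forward, backward (wrt weights, z and k) and Adam are
# implemented explicitly in matrix algebra; gradients are validated against
# finite differences in the test suite.

#' Initialize a conditional volume field
#'
#' @param d latent dimension (>= 1).
#' @param seed integer seed; the same seed reproduces parameters bitwise.
#' @param width hidden width (default 256).
#' @param depth number of residual hidden layers (default 3).
#' @param n_freqs number of Gaussian base frequencies (default 64; the
#'   positional encoding has length `2 * n_freqs`).
#' @param freq_sd standard deviation of the base-frequency Gaussian
#'   (default 0.5).
#' @return object of class `volume_field`: list with the base-frequency
#'   matrix `B` (excluded from optimization), the parameter list `params`,
#'   and architecture metadata.
#' @export
init_field <- function(d, seed = 0, width = 256L, depth = 3L,
                       n_freqs = 64L, freq_sd = 0.5) {
  if (d < 1) stop("latent dimension d must be >= 1")
  set.seed(seed)
  B <- matrix(stats::rnorm(n_freqs * 3, sd = freq_sd), n_freqs, 3)
  n_in <- 2L * n_freqs + as.integer(d)
  lin_init <- function(fan_in, fan_out) {
    bound <- 1 / sqrt(fan_in)
    list(W = matrix(stats::runif(fan_in * fan_out, -bound, bound),
                    fan_in, fan_out),
         b = stats::runif(fan_out, -bound, bound))
  }
  params <- list()
  l1 <- lin_init(n_in, width)
  params$W1 <- l1$W; params$b1 <- l1$b
  for (i in seq_len(depth)) {
    la <- lin_init(width, width); lb <- lin_init(width, width)
    params[[paste0("Wa", i)]] <- la$W; params[[paste0("ba", i)]] <- la$b
    params[[paste0("Wb", i)]] <- lb$W; params[[paste0("bb", i)]] <- lb$b
  }
  lo <- lin_init(width, 1L)
  params$Wo <- lo$W; params$bo <- lo$b
  structure(list(B = B, params = params, d = as.integer(d),
                 width = as.integer(width), depth = as.integer(depth),
                 n_freqs = as.integer(n_freqs), seed = seed),
            class = "volume_field")
}

#' Number of trainable parameters of a field
#' @param field a `volume_field`.
#' @return integer parameter count (a pure function of the architecture).
#' @export
field_param_count <- function(field) {
  sum(vapply(field$params, length, integer(1)))
}

#' Fourier-feature positional encoding
#'
#' @param field a `volume_field` (supplies the fixed base frequencies B).
#' @param coords M x 3 matrix of frequencies in `[-0.5, 0.5]^3`.
#' @return M x (2 n_freqs) matrix `[sin(2 pi K B^T), cos(2 pi K B^T)]`,
#'   entries bounded in `[-1, 1]`.
#' @export
fourier_features <- function(field, coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  S <- 2 * pi * coords %*% t(field$B)
  cbind(sin(S), cos(S))
}

# Forward pass with cached intermediates (for backward).
.field_forward <- function(field, Z, coords) {
  p <- field$params
  S <- 2 * pi * coords %*% t(field$B)
  F1 <- cbind(sin(S), cos(S))
  X0 <- cbind(F1, Z)
  A1 <- sweep(X0 %*% p$W1, 2, p$b1, `+`)
  X <- pmax(A1, 0)
  cache <- list(S = S, X0 = X0, A1 = A1, blocks = vector("list", field$depth))
  Xs <- vector("list", field$depth + 1L); Xs[[1L]] <- X
  for (i in seq_len(field$depth)) {
    Au <- sweep(X %*% p[[paste0("Wa", i)]], 2, p[[paste0("ba", i)]], `+`)
    U <- pmax(Au, 0)
    V <- sweep(U %*% p[[paste0("Wb", i)]], 2, p[[paste0("bb", i)]], `+`)
    Anew <- X + V
    X <- pmax(Anew, 0)
    cache$blocks[[i]] <- list(Au = Au, U = U, Anew = Anew)
    Xs[[i + 1L]] <- X
  }
  out <- drop(X %*% p$Wo) + p$bo
  cache$Xs <- Xs
  list(out = out, cache = cache)
}

# Backward pass. dout: length-M vector dL/dout. Returns list(grads = named
# list matching params, dZ = M x d, dK = M x 3).
.field_backward <- function(field, Z, coords, cache, dout) {
  p <- field$params
  depth <- field$depth
  g <- list()
  Xlast <- cache$Xs[[depth + 1L]]
  dX <- matrix(dout, ncol = 1) %*% t(p$Wo)
  g$Wo <- t(Xlast) %*% matrix(dout, ncol = 1)
  g$bo <- sum(dout)
  for (i in rev(seq_len(depth))) {
    blk <- cache$blocks[[i]]
    Wa <- p[[paste0("Wa", i)]]; Wb <- p[[paste0("Wb", i)]]
    dAnew <- dX * (blk$Anew > 0)
    dV <- dAnew
    g[[paste0("Wb", i)]] <- t(blk$U) %*% dV
    g[[paste0("bb", i)]] <- colSums(dV)
    dU <- dV %*% t(Wb)
    dAu <- dU * (blk$Au > 0)
    Xin <- cache$Xs[[i]]
    g[[paste0("Wa", i)]] <- t(Xin) %*% dAu
    g[[paste0("ba", i)]] <- colSums(dAu)
    dX <- dAnew + dAu %*% t(Wa)
  }
  dA1 <- dX * (cache$A1 > 0)
  g$W1 <- t(cache$X0) %*% dA1
  g$b1 <- colSums(dA1)
  dX0 <- dA1 %*% t(p$W1)
  nf2 <- 2L * field$n_freqs
  dF1 <- dX0[, seq_len(nf2), drop = FALSE]
  dZ <- dX0[, nf2 + seq_len(field$d), drop = FALSE]
  nf <- field$n_freqs
  dS <- dF1[, seq_len(nf), drop = FALSE] * cos(cache$S) -
    dF1[, nf + seq_len(nf), drop = FALSE] * sin(cache$S)
  dK <- 2 * pi * dS %*% field$B
  list(grads = g, dZ = dZ, dK = dK)
}

#' Evaluate the field
#'
#' Deterministic given (parameters, z, coords). Coordinates outside
#' `[-0.5, 0.5]^3` evaluate to 0 (band limit) without error.
#'
#' @param field a `volume_field`.
#' @param z latent vector of length `d`, or an M x d matrix (one row per
#'   coordinate).
#' @param coords M x 3 matrix of frequency coordinates.
#' @return numeric vector of length M of Hartley coefficients.
#' @export
eval_field <- function(field, z, coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  M <- nrow(coords)
  if (is.null(z)) z <- numeric(field$d)
  Z <- if (is.null(dim(z))) matrix(z, M, field$d, byrow = TRUE) else z
  inside <- rowSums(abs(coords) > 0.5 + 1e-12) == 0L
  out <- numeric(M)
  if (any(inside)) {
    fw <- .field_forward(field, Z[inside, , drop = FALSE],
                         coords[inside, , drop = FALSE])
    out[inside] <- fw$out
  }
  out
}

#' Render a real-space map from the field
#'
#' Evaluates the field on the full 3D frequency lattice and applies the
#' inverse Hartley transform.
#'
#' @param field a `volume_field`.
#' @param z latent vector of length `d`.
#' @param D even map size.
#' @param gain optional global intensity scale applied to the coefficients.
#' @return D x D x D real array.
#' @export
render_map <- function(field, z, D, gain = 1) {
  vhat <- render_hartley(field, z, D) * gain
  idht(vhat)
}

#' Evaluate the field on the full compact frequency lattice
#' @inheritParams render_map
#' @return D^3 array of Hartley coefficients.
#' @export
render_hartley <- function(field, z, D) {
  mi <- freq_index(D)
  g <- as.matrix(expand.grid(x = mi / D, y = mi / D, z = mi / D))
  array(eval_field(field, z, g), dim = c(D, D, D))
}

#' Gridded band-limited cache of the field
#'
#' Evaluates the field at the lattice points within a radial band and
#' returns the extended `(D+1)^3` array used by the trilinear pose-search
#' slicer. Points outside the band are zero.
#'
#' @param field a `volume_field`.
#' @param z latent vector.
#' @param D grid size.
#' @param cutoff band radius in grid units; the cache covers
#'   `|m| <= cutoff + 2` so interpolation near the band edge is exact.
#' @return `(D+1)^3` array.
#' @export
field_grid_cache <- function(field, z, D, cutoff) {
  half <- D %/% 2L
  r <- min(cutoff + 2L, half)
  mi <- seq.int(-r, r)
  g <- as.matrix(expand.grid(x = mi, y = mi, z = mi))
  keep <- rowSums(g^2) <= (r + 1)^2
  vals <- numeric(nrow(g))
  vals[keep] <- eval_field(field, z, g[keep, , drop = FALSE] / D)
  vext <- array(0, dim = rep(D + 1L, 3))
  # indices of mi within the extended lattice (coordinate m -> m + D/2 + 1)
  sel <- mi + half + 1L
  vext[sel, sel, sel] <- array(vals, dim = rep(length(mi), 3))
  # mirror the band edge onto the aliased +D/2 faces if the band reaches it
  if (r == half) {
    vext[D + 1L, , ] <- vext[1L, , ]
    vext[, D + 1L, ] <- vext[, 1L, ]
    vext[, , D + 1L] <- vext[, , 1L]
  }
  vext
}

# ---- Adam optimizer on named parameter lists -------------------------------

#' Create an Adam optimizer state
#' @param params named list of numeric arrays.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return optimizer state (list).
#' @keywords internal
adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0))
}

#' One Adam update
#' @param params named list of parameters.
#' @param grads matching named list of gradients.
#' @param st optimizer state from [adam_init()].
#' @param lr optional learning-rate override for this step.
#' @return list(params, st) updated.
#' @keywords internal
adam_step <- function(params, grads, st, lr = NULL) {
  if (is.null(lr)) lr <- st$lr
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * gr
    st$v[[nm]] <- st$beta2 * st$v[[nm]] + (1 - st$beta2) * gr^2
    mh <- st$m[[nm]] / bc1
    vh <- st$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + st$eps)
  }
  list(params = params, st = st)
}
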