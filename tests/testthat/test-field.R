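# Conditional neural field: initialization, encoding, evaluation,
# gradients, rendering.

test_that("initialization is seed-deterministic with Gaussian frequencies", {
  f1 <- init_field(4, seed = 11, width = 32, n_freqs = 64)
  f2 <- init_field(4, seed = 11, width = 32, n_freqs = 64)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$B, f2$B)
  # B ~ N(0, 0.5^2): sample sd over 192 entries within a 3-sigma band
  expect_gt(sd(f1$B), 0.35)
  expect_lt(sd(f1$B), 0.65)
  expect_error(init_field(0), "d")
})

test_that("fourier features have the contracted form and bounds", {
  f <- init_field(2, seed = 1, width = 16, n_freqs = 64)
  ft0 <- fourier_features(f, matrix(0, 1, 3))
  expect_equal(length(ft0), 128L)            # 2 x 64 base frequencies
  expect_equal(as.numeric(ft0[1, 1:64]), rep(0, 64))     # sin block
  expect_equal(as.numeric(ft0[1, 65:128]), rep(1, 64))   # cos block
  set.seed(12)
  ft <- fourier_features(f, matrix(runif(30, -0.5, 0.5), 10, 3))
  expect_true(all(abs(ft) <= 1))
})

test_that("field evaluation is deterministic, z-sensitive, band-limited", {
  f <- init_field(3, seed = 2, width = 24, n_freqs = 16)
  set.seed(13)
  K <- matrix(runif(60, -0.45, 0.45), 20, 3)
  z1 <- rnorm(3, sd = 0.5); z2 <- rnorm(3, sd = 0.5)
  expect_identical(eval_field(f, z1, K), eval_field(f, z1, K))
  expect_false(isTRUE(all.equal(eval_field(f, z1, K),
                                eval_field(f, z2, K))))
  # out-of-band coordinates evaluate to zero, no error
  Kout <- rbind(c(0.7, 0, 0), c(0, -0.6, 0.2))
  expect_equal(eval_field(f, z1, Kout), c(0, 0))
  expect_true(all(is.finite(eval_field(f, z1,
    matrix(runif(3000, -0.5, 0.5), 1000, 3)))))
})

test_that("parameter count is a pure function of the architecture", {
  f <- init_field(8, seed = 3)
  n_in <- 128 + 8
  expected <- (n_in * 256 + 256) + 3 * 2 * (256 * 256 + 256) + (256 + 1)
  expect_equal(field_param_count(f), expected)
  expect_equal(field_param_count(init_field(8, seed = 99)), expected)
})

test_that("analytic gradients match finite differences", {
  set.seed(14)
  f <- init_field(3, seed = 5, width = 16, depth = 2, n_freqs = 8)
  M <- 5
  K <- matrix(runif(M * 3, -0.4, 0.4), M, 3)
  Z <- matrix(rnorm(M * 3, sd = 0.3), M, 3)
  tgt <- rnorm(M)
  lossfun <- function(fld, Zm, Km) {
    sum((cryofield:::.field_forward(fld, Zm, Km)$out - tgt)^2)
  }
  fw <- cryofield:::.field_forward(f, Z, K)
  bk <- cryofield:::.field_backward(f, Z, K, fw$cache, 2 * (fw$out - tgt))
  eps <- 1e-6
  for (nm in c("W1", "Wa2", "bb1", "Wo")) {
    p <- f$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      fp <- f; fp$params[[nm]][i] <- p[i] + eps
      fm <- f; fm$params[[nm]][i] <- p[i] - eps
      gn <- (lossfun(fp, Z, K) - lossfun(fm, Z, K)) / (2 * eps)
      expect_lt(abs(gn - bk$grads[[nm]][i]), 1e-6)
    }
  }
  gz <- sapply(1:3, function(j) {
    Zp <- Z; Zp[2, j] <- Z[2, j] + eps
    Zm <- Z; Zm[2, j] <- Z[2, j] - eps
    (lossfun(f, Zp, K) - lossfun(f, Zm, K)) / (2 * eps)
  })
  expect_lt(max(abs(gz - bk$dZ[2, ])), 1e-6)
  gk <- sapply(1:3, function(j) {
    Kp <- K; Kp[3, j] <- K[3, j] + eps
    Km <- K; Km[3, j] <- K[3, j] - eps
    (lossfun(f, Z, Kp) - lossfun(f, Z, Km)) / (2 * eps)
  })
  expect_lt(max(abs(gk - bk$dK[3, ])), 1e-6)
})

test_that("the field can overfit a small Hartley volume", {
  D <- 16
  vol <- make_phantom(phantom_spec(list(c(2, -1.5, 1)), 3, 1), D)
  vhat <- dht(vol)
  mi <- cryofield:::freq_index(D)
  coords <- as.matrix(expand.grid(x = mi, y = mi, z = mi)) / D
  target <- as.numeric(vhat)
  f <- init_field(2, seed = 3, width = 64, n_freqs = 64)
  Zm <- matrix(0, nrow(coords), 2)
  opt <- cryofield:::adam_init(f$params, 1e-3)
  mse0 <- mean((cryofield:::.field_forward(f, Zm, coords)$out - target)^2)
  for (it in 1:300) {
    fw <- cryofield:::.field_forward(f, Zm, coords)
    r <- fw$out - target
    bk <- cryofield:::.field_backward(f, Zm, coords, fw$cache,
                                      2 * r / length(r))
    up <- cryofield:::adam_step(f$params, bk$grads, opt)
    f$params <- up$params; opt <- up$st
  }
  mse1 <- mean((cryofield:::.field_forward(f, Zm, coords)$out - target)^2)
  expect_gt(mse0 / mse1, 100)
  # rendering: map correlates with the target volume
  m <- render_map(f, c(0, 0), D)
  expect_gt(cor(as.numeric(m), as.numeric(vol)), 0.95)
  # render -> dht reproduces the lattice evaluations (lossless loop)
  h <- dht(render_map(f, c(0, 0), D))
  ev <- matrix(eval_field(f, c(0, 0), coords), D^2)
  expect_lt(max(abs(as.numeric(h) - as.numeric(ev))), 1e-5)
  # two renders with the same inputs are identical; z as a table row or a
  # plain vector gives the same map
  expect_identical(render_map(f, c(0, 0), D), render_map(f, c(0, 0), D))
})
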