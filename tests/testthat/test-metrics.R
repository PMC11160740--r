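# Metrics: FSC, rotation alignment and decomposition, optimal shift,
# quaternion loss.

test_that("fsc is 1 for identical, -1 for negated, ~0 for noise, and
          symmetric", {
  set.seed(41)
  D <- 32
  x <- array(rnorm(D^3), dim = rep(D, 3))
  fx <- fsc(x, x)
  expect_true(all(abs(fx$fsc - 1) < 1e-10))
  fneg <- fsc(x, -x)
  expect_true(all(abs(fneg$fsc + 1) < 1e-10))
  y <- array(rnorm(D^3), dim = rep(D, 3))
  fn <- fsc(x, y)
  expect_lt(mean(abs(fn$fsc[-1])), 0.1)    # independent white noise
  expect_equal(fsc(x, y)$fsc, fsc(y, x)$fsc)
  expect_error(fsc(x, array(0, rep(16, 3))), "identical dimensions")
  # crossings are reported for a decaying pair
  v <- make_phantom(asym_phantom(D), D)
  fv <- fsc(v, v + 0.08 * sd(v) * array(rnorm(D^3) *
            as.numeric(dht(array(rnorm(D^3), rep(D, 3)))), rep(D, 3)))
  expect_true(is.numeric(attr(fv, "crossing_0.5")))
})

test_that("rotation alignment undoes a planted global rotation", {
  set.seed(42)
  ref <- random_rotations(40)
  # est = ref: identity alignment, zero errors
  al0 <- align_rotations(ref, ref)
  expect_lt(max(abs(al0$R_align - diag(3))), 1e-10)
  expect_lt(max(al0$errors), 1e-6)
  # est = ref composed with a fixed global rotation
  R0 <- random_rotations(1)[[1]]
  est <- lapply(ref, function(R) R %*% R0)
  al <- align_rotations(est, ref)
  expect_lt(max(al$errors), 1e-6)
})

test_that("error decomposition separates viewing direction from spin", {
  set.seed(43)
  ref <- random_rotations(20)
  d0 <- decompose_errors(ref, ref)
  expect_lt(max(d0$out_of_plane), 1e-4)
  expect_lt(max(d0$in_plane), 1e-6)
  # pure in-plane spin by 10 degrees: (0, 10)
  est <- lapply(ref, function(R) R %*% cryofield:::rot_z(10 * pi / 180))
  d1 <- decompose_errors(est, ref)
  expect_lt(max(d1$out_of_plane), 1e-4)
  expect_equal(d1$in_plane, rep(10, 20), tolerance = 1e-8)
  # out-of-plane error never exceeds the total geodesic angle
  est2 <- random_rotations(20)
  d2 <- decompose_errors(est2, ref)
  geo <- sapply(1:20, function(i) rot_geodesic(est2[[i]], ref[[i]])) *
    180 / pi
  expect_true(all(d2$out_of_plane <= geo + 1e-8))
})

test_that("optimal shift recovers a planted 3D origin offset", {
  set.seed(44)
  N <- 50
  Rl <- random_rotations(N)
  Tm <- matrix(runif(2 * N, -3, 3), N, 2)
  P <- rbind(c(1, 0, 0), c(0, 1, 0))
  # t = T: zero shift
  s0 <- optimal_shift(Tm, Tm, Rl)
  expect_lt(max(abs(s0$u)), 1e-8)
  # planted u0: t_i = T_i - P r_i u0
  u0 <- c(2, -1, 3)
  tm <- Tm - t(vapply(Rl, function(R) as.numeric(P %*% R %*% u0),
                      numeric(2)))
  s1 <- optimal_shift(tm, Tm, Rl)
  expect_lt(max(abs(s1$u - u0)), 1e-6)
  expect_lt(s1$mse_after, 1e-12)
  # least-squares property: correction never increases the MSE
  for (trial in 1:5) {
    tr <- matrix(runif(2 * N, -2, 2), N, 2)
    s <- optimal_shift(tr, Tm, Rl)
    expect_lte(s$mse_after, s$mse_before + 1e-12)
  }
})

test_that("quaternion loss respects the double cover", {
  set.seed(45)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  expect_equal(quaternion_loss(q, q), 0, tolerance = 1e-12)
  expect_equal(quaternion_loss(q, -q), 0, tolerance = 1e-12)
  # orthogonal quaternions give 1
  qp <- c(-q[2], q[1], -q[4], q[3])
  expect_equal(quaternion_loss(q, qp), 1, tolerance = 1e-12)
  expect_warning(quaternion_loss(2 * q, q), "normalized")
})
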