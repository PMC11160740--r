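# Synthetic-data generator: phantoms, analytic transforms, dataset
# simulators, reproducibility.

test_that("phantom sampling: symmetry, analytic transform, empty spec", {
  D <- 32
  # single centered isotropic blob is radially symmetric
  sp <- phantom_spec(list(c(0, 0, 0)), 4, 1)
  v <- make_phantom(sp, D)
  expect_lt(max(abs(v - aperm(v, c(2, 1, 3)))), 1e-12)
  # value is a function of the radius alone
  mi <- cryofield:::freq_index(D)
  g <- as.matrix(expand.grid(x = mi, y = mi, z = mi))
  spread <- tapply(as.numeric(v), rowSums(g^2),
                   function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)
  # analytic Hartley transform matches the numeric one
  sp2 <- phantom_spec(list(c(2, -1, 1), c(-2, 1.5, -0.5)), c(3, 2.5),
                      c(1, 0.6))
  num <- dht(make_phantom(sp2, D))
  ana <- phantom_hartley_analytic(sp2, D)
  expect_lt(sqrt(sum((num - ana)^2) / sum(num^2)), 0.01)
  # zero-amplitude spec gives the zero map
  expect_equal(max(abs(make_phantom(
    phantom_spec(list(c(0, 0, 0)), 3, 0), 16))), 0)
})

test_that("single-particle simulation follows its contracts", {
  sim <- simulate_spa(asym_phantom(32), n = 60, D = 32, noise_std = 0,
                      pixel_size = 3, seed = 4)
  # zero noise: image equals its CTF-filtered projection exactly
  expect_identical(sim$images, sim$clean)
  # bitwise reproducibility under the same seed
  sim2 <- simulate_spa(asym_phantom(32), n = 60, D = 32, noise_std = 0,
                       pixel_size = 3, seed = 4)
  expect_identical(sim$images, sim2$images)
  # rotations are uniform: mean viewing axis near zero
  n <- 400
  set.seed(5)
  axes <- t(vapply(random_rotations(n), function(R) R[, 3], numeric(3)))
  expect_lt(sqrt(sum(colMeans(axes)^2)), 4 / sqrt(n))
  # requested noise level is realized (SNR control)
  simn <- simulate_spa(asym_phantom(32), n = 100, D = 32, noise_std = 0.5,
                       pixel_size = 3, seed = 6)
  expect_lt(abs(sd(simn$images - simn$clean) - 0.5) / 0.5, 0.1)
})

test_that("1D-motion datasets span a monotone reaction coordinate", {
  sp <- asym_phantom(32)
  sim <- simulate_1d_motion(sp, n_states = 8, increment_rad = 0.15,
                            images_per_state = 2, D = 32, noise_std = 0,
                            seed = 7)
  # defaults follow the reference settings
  expect_equal(formals(simulate_1d_motion)$n_states, 50L)
  expect_equal(formals(simulate_1d_motion)$increment_rad, 0.03)
  # state 1 is the base phantom
  expect_lt(max(abs(sim$maps[[1]] - make_phantom(sp, 32))), 1e-12)
  # correlation to state 1 decays monotonically along the coordinate
  cors <- sapply(2:8, function(s) cor(as.numeric(sim$maps[[1]]),
                                      as.numeric(sim$maps[[s]])))
  expect_true(all(diff(cors) < 0))
  expect_error(simulate_1d_motion(sp, n_states = 1), "n_states")
})

test_that("tilt-series simulation composes the dose-symmetric scheme", {
  expect_equal(dose_symmetric_tilts(11, 3),
               c(0, 3, -3, 6, -6, 9, -9, 12, -12, 15, -15))
  expect_equal(sort(unique(abs(dose_symmetric_tilts(11, 3)))),
               c(0, 3, 6, 9, 12, 15))      # +/- 15 degrees total coverage
  sim <- simulate_tilt_series(asym_phantom(32), n_particles = 3, J = 5,
                              dose_per_tilt = 3, D = 32, noise_std = 0,
                              pixel_size = 3, seed = 8)
  expect_equal(dim(sim$images)[3], 15L)
  expect_equal(sim$particle_index, rep(1:3, each = 5))
  # subtilt 0 equals the untilted image of the same particle
  i0 <- which(sim$particle_index == 2)[1]
  ob <- simulate_observation(prep_slicer(dht(sim$maps[[1]]), 2L),
                             pose = list(R = sim$particle_poses[[2]],
                                         t = c(0, 0)),
                             ctf = sim$ctf[[i0]], pixel_size = 3,
                             tilt = sim$tilts[[i0]], noise_std = 0)
  expect_lt(max(abs(sim$images[, , i0] - ob$image)), 1e-10)
  # J = 1 reduces to a plain single-particle image (no tilt weighting)
  sim1 <- simulate_tilt_series(asym_phantom(32), n_particles = 2, J = 1,
                               dose_per_tilt = 3, D = 32, noise_std = 0,
                               pixel_size = 3, seed = 9)
  expect_equal(vapply(sim1$tilts, `[[`, numeric(1), "tilt_angle"),
               c(0, 0))
  expect_equal(vapply(sim1$tilts, `[[`, numeric(1), "cumulative_dose"),
               c(0, 0))
})
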