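# Trainer: loss identities, phase behavior, schedules, determinism.

test_that("loss vanishes for a perfect model and matches reprojection
          errors", {
  D <- 32
  f <- init_field(2, seed = 71, width = 32, n_freqs = 32)
  set.seed(71)
  n <- 4
  rots <- random_rotations(n)
  ctfs <- replicate(n, test_ctf(), simplify = FALSE)
  imgs <- array(0, dim = c(D, D, n))
  for (i in 1:n) {
    imgs[, , i] <- simulate_observation(f, pose = list(R = rots[[i]],
                                                       t = c(1, -0.5)),
                                        ctf = ctfs[[i]], D = D,
                                        pixel_size = 3, noise_std = 0,
                                        z = c(0.1, -0.2))$image
  }
  data <- list(images = imgs, ctf = ctfs, pixel_size = 3)
  poses <- list(R = rots, t = matrix(c(1, -0.5), n, 2, byrow = TRUE))
  Z <- matrix(c(0.1, -0.2), n, 2, byrow = TRUE)
  l0 <- train_loss(f, poses, Z, data, 1:n)
  ref <- sum(cryofield:::.all_dht(imgs)^2)
  expect_lt(l0 / ref, 1e-8)
  # equals the sum of per-image reprojection errors at full band
  wrong <- poses; wrong$t <- wrong$t + 0.7
  l1 <- train_loss(f, wrong, Z, data, 1:n)
  e1 <- sum(sapply(1:n, function(i) {
    reprojection_error(imgs[, , i], f, z = Z[i, ],
                       pose = list(R = wrong$R[[i]], t = wrong$t[i, ]),
                       ctf = ctfs[[i]], pixel_size = 3)
  }))
  expect_equal(l1, e1, tolerance = 1e-10)
})

test_that("white noise raises the expected loss by sigma^2 x coefficient
          count", {
  D <- 32
  f <- init_field(2, seed = 72, width = 32, n_freqs = 32)
  set.seed(72)
  n <- 30
  rots <- random_rotations(n)
  imgs <- array(0, dim = c(D, D, n))
  sigma <- 0.4
  for (i in 1:n) {
    cl <- simulate_observation(f, pose = list(R = rots[[i]], t = c(0, 0)),
                               D = D, noise_std = 0, z = c(0, 0))$clean
    imgs[, , i] <- cl + matrix(rnorm(D * D, sd = sigma), D, D)
  }
  data <- list(images = imgs, ctf = NULL, pixel_size = 3)
  poses <- list(R = rots, t = matrix(0, n, 2))
  Z <- matrix(0, n, 2)
  lat <- inband_lattice(D, NULL)
  l <- train_loss(f, poses, Z, data, 1:n)
  # unitary transform: white pixel noise contributes sigma^2 per retained
  # coefficient
  expected <- n * sigma^2 * length(lat$m)
  expect_lt(abs(l - expected) / expected, 0.1)
})

test_that("phase lengths follow the max(2N, 5e5) rule", {
  expect_equal(train_config(N = 1e5)$hps_images, 5e5)
  expect_equal(train_config(N = 3e5)$hps_images, 6e5)
  expect_equal(train_config(N = 1e5, mode = "sta")$hps_images, 2e5)
  expect_equal(train_config(N = 5e4, mode = "sta")$hps_images, 1.5e5)
  # STA defaults: pose lr 1e-5, SGD batch 32, 11 tilts
  cs <- train_config(N = 100, mode = "sta")
  expect_equal(cs$lr_pose, 1e-5)
  expect_equal(cs$batch_sgd, 32L)
  expect_equal(cs$n_tilts, 11L)
  # SPA defaults mirror the reference settings
  cp <- train_config(N = 100)
  expect_equal(cp$lr_field, 1e-4)
  expect_equal(cp$lr_z, 1e-2)
  expect_equal(cp$lr_pose, 1e-3)
  expect_equal(cp$batch_pretrain, 32L)
  expect_equal(cp$batch_hps, 8L)
  expect_equal(cp$batch_sgd, 256L)
  expect_equal(cp$pretrain_images, 10000L)
})

test_that("pretraining updates only the network and reduces its loss", {
  D <- 32
  sim <- simulate_spa(asym_phantom(D), n = 32, D = D, noise_std = 0.1,
                      pixel_size = 3, seed = 73)
  cfg <- train_config(N = 32, d = 2, seed = 3, width = 32,
                      pretrain_images = 320, hps_images = 8,
                      sgd_images = 8, batch_sgd = 8,
                      t_extent = 2.5, nside = 2L, n_psi = 12L)
  # run a pretrain-only state by hand
  set.seed(cfg$seed)
  state <- list(field = init_field(cfg$d, seed = cfg$seed + 1L,
                                   width = cfg$width,
                                   n_freqs = cfg$n_freqs),
                gain = 1,
                latents = matrix(rnorm(32 * 2, sd = 0.1), 32, 2),
                poses = list(R = random_rotations(32),
                             t = matrix(0, 32, 2)),
                images_processed = 0L, phase = "pretrain",
                log = list(), config = cfg)
  state$Hmat <- cryofield:::.all_dht(sim$images)
  state$Wmat <- cryofield:::.all_weights(sim)
  state$opt_field <- cryofield:::adam_init(state$field$params,
                                           cfg$lr_field)
  poses_before <- state$poses
  data <- sim
  l_before <- train_loss(state$field, state$poses, state$latents, data,
                         1:32, gain = state$gain, cutoff = cfg$k_min)
  st2 <- cryofield:::.run_pretrain(state, data, cfg, log_every = 5L,
                                   verbose = FALSE)
  l_after <- train_loss(st2$field, st2$poses, st2$latents, data, 1:32,
                        gain = st2$gain, cutoff = cfg$k_min)
  # poses untouched by pretraining
  expect_identical(st2$poses, poses_before)
  expect_lt(l_after, l_before)
  # log records carry valid phase tags
  expect_true(all(vapply(st2$log, function(r) r$phase, "") %in%
                  c("pretrain", "hps", "sgd")))
})

test_that("a full tiny run is bitwise deterministic under its seed", {
  D <- 32
  sim <- simulate_spa(asym_phantom(D), n = 16, D = D, noise_std = 0.1,
                      pixel_size = 3, seed = 74)
  cfg <- train_config(N = 16, d = 2, seed = 5, width = 24, n_freqs = 16,
                      pretrain_images = 64, hps_images = 32,
                      sgd_images = 32, batch_sgd = 8,
                      t_extent = 2.5, nside = 2L, n_psi = 12L)
  s1 <- train_spa(sim, cfg)
  s2 <- train_spa(sim, cfg)
  expect_identical(s1$final_loss, s2$final_loss)
  expect_identical(s1$latents, s2$latents)
  expect_identical(s1$poses$t, s2$poses$t)
  # counters are monotone over the log
  counts <- vapply(s1$log, function(r) r$images_processed, numeric(1))
  if (length(counts) > 1) expect_true(all(diff(counts) >= 0))
  # diagnostics serialize to parseable JSONL
  lp <- file.path(tempdir(), "log.jsonl")
  write_train_log(s1, lp)
  lines <- readLines(lp)
  if (length(lines) > 0) {
    rec <- jsonlite::fromJSON(lines[1])
    expect_true(all(c("phase", "images_processed", "cutoff", "loss") %in%
                    names(rec)))
  }
})

test_that("interrupted training resumes bit-for-bit after save/load", {
  D <- 32
  sim <- simulate_spa(asym_phantom(D), n = 16, D = D, noise_std = 0.1,
                      pixel_size = 3, seed = 75)
  cfg <- train_config(N = 16, d = 2, seed = 6, width = 24, n_freqs = 16,
                      pretrain_images = 64, hps_images = 16,
                      sgd_images = 16, batch_sgd = 8,
                      t_extent = 2.5, nside = 2L, n_psi = 12L)
  s1 <- train_spa(sim, cfg)
  dir <- file.path(tempdir(), "resume")
  save_state(s1, dir)
  # uninterrupted next batch
  set.seed(101)
  l_direct <- train_loss(s1$field, s1$poses, s1$latents, sim,
                         sample(16, 8), gain = s1$gain)
  # reload and repeat: same RNG stream, same state, same loss
  rnorm(50)
  s2 <- load_state(dir)
  set.seed(101)
  l_resumed <- train_loss(s2$field, s2$poses, s2$latents, sim,
                          sample(16, 8), gain = s2$gain)
  expect_identical(l_direct, l_resumed)
})
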