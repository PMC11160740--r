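# Hartley transforms, translation operator, Fourier cropping.

test_that("dht is a unitary involution and matches the DFT identity", {
  set.seed(1)
  x <- matrix(rnorm(64), 8, 8)
  expect_lt(max(abs(dht(dht(x)) - x)), 1e-6)
  # H = Re(F) - Im(F) under matching centering/normalization
  f4 <- matrix(rnorm(16), 4, 4)
  Fc <- cryofield:::cfft(f4)
  expect_lt(max(abs(dht(f4) - (Re(Fc) - Im(Fc)))), 1e-12)
  # Parseval: unitary transform preserves the L2 norm
  expect_lt(abs(sum(dht(x)^2) - sum(x^2)) / sum(x^2), 1e-10)
  # constant image concentrates all energy at k = 0
  cc <- matrix(3, 8, 8)
  h <- dht(cc)
  expect_equal(h[5, 5], 3 * 8, tolerance = 1e-12)   # D * mean
  h[5, 5] <- 0
  expect_lt(max(abs(h)), 1e-12)
  expect_error(dht(matrix(complex(real = 1, imaginary = 1), 2, 2)),
               "real")
})

test_that("translate_hartley reproduces circular shifts and is orthogonal", {
  set.seed(2)
  D <- 16
  img <- matrix(rnorm(D * D), D, D)
  h <- dht(img)
  # t = 0 identity
  expect_identical(translate_hartley(h, c(0, 0)), h)
  # integer shift matches the real-space circular shift
  sh <- idht(translate_hartley(h, c(3, 0)))
  expect_lt(max(abs(sh - img[c((D - 2):D, 1:(D - 3)), ])), 1e-5)
  # group property T_a T_b = T_{a+b} and orthogonality hold exactly on
  # the in-band disk (the aliased Nyquist row is its own -k partner and is
  # excluded from every band-limited operation)
  lat <- inband_lattice(D)
  a <- c(1.3, -0.6); b <- c(-2.1, 0.9)
  tab <- translate_hartley(translate_hartley(h, a), b)
  tsum <- translate_hartley(h, a + b)
  expect_lt(max(abs(tab[lat$idx] - tsum[lat$idx])), 1e-10)
  ht <- translate_hartley(h, c(1.7, 2.2))
  expect_lt(abs(sum(ht[lat$idx]^2) - sum(h[lat$idx]^2)) /
            sum(h[lat$idx]^2), 1e-10)
})

test_that("in-band lattice points all have exact -k partners", {
  for (co in c(3, 6, NULL)) {
    lat <- inband_lattice(16, co)
    expect_true(all(lat$m[lat$neg] == -lat$m))
    expect_true(all(lat$n[lat$neg] == -lat$n))
  }
  # full band excludes the Nyquist ring
  lat <- inband_lattice(16)
  expect_lte(max(lat$m^2 + lat$n^2), 7^2)
})

test_that("fourier_crop preserves mean, in-band content, and composes", {
  # identity
  x <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(fourier_crop(x, 32L), x)
  # DC preservation
  cc <- matrix(5, 64, 64)
  expect_lt(max(abs(fourier_crop(cc, 32) - 5)), 1e-10)
  # a low-frequency sinusoid below the new Nyquist resamples exactly
  mi64 <- cryofield:::freq_index(64)
  mi32 <- cryofield:::freq_index(32)
  s64 <- outer(mi64, mi64, function(a, b) cos(2 * pi * 3 * a / 64) +
                 0.5 * sin(2 * pi * 5 * b / 64))
  s32 <- outer(mi32, mi32, function(a, b) cos(2 * pi * 3 * a / 32) +
                 0.5 * sin(2 * pi * 5 * b / 32))
  expect_lt(max(abs(fourier_crop(s64, 32) - s32)), 1e-6)
  # idempotent composition: crop twice equals single crop
  expect_lt(max(abs(fourier_crop(fourier_crop(x, 16L), 8L) -
                    fourier_crop(x, 8L))), 1e-10)
  # stacks: pixel size scales by D / D_new
  st <- particle_stack(array(rnorm(32 * 32 * 3), c(32, 32, 3)), 2.0)
  st2 <- fourier_crop(st, 16L)
  expect_equal(st2$pixel_size, 4.0)
  expect_equal(dim(st2$images), c(16L, 16L, 3L))
  expect_error(fourier_crop(x, 64L), "exceeds")
})
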