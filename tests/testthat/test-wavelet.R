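test_that("mother wavelets carry the closed-form Fourier factors", {
  expect_equal(mother_wavelet("morlet", 6)$fourier_factor,
               4 * pi / (6 + sqrt(2 + 36)))
  expect_equal(round(mother_wavelet("morlet", 6)$fourier_factor, 4), 1.0330)
  expect_equal(mother_wavelet("paul", 4)$fourier_factor, 4 * pi / 9)
  expect_equal(mother_wavelet("dog", 2)$fourier_factor, 2 * pi / sqrt(2.5))
  expect_error(mother_wavelet("morlet", 1), "inadmissible")
  expect_error(mother_wavelet("paul", 2.5), "inadmissible")
  expect_error(mother_wavelet("dog", 0), "inadmissible")
})

test_that("standardize centres and scales, is idempotent, rejects constants", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z)
  expect_error(standardize(rep(4, 10)), "constant series")
  expect_error(standardize(c(1, NA, 3)), "missing")
})

test_that("the geometric period grid doubles every `suboctaves` steps", {
  g <- build_period_grid(8, 16962, 20)
  expect_equal(g[1], 8)
  expect_equal(g[21], 16)
  expect_equal(g[41], 32)
  # closed-form size on random endpoint choices
  set.seed(5)
  for (i in 1:10) {
    mn <- runif(1, 2, 20); mx <- runif(1, 100, 5e4); so <- sample(4:24, 1)
    expect_length(build_period_grid(mn, mx, so),
                  floor(so * log2(mx / mn) + 1e-9) + 1)
  }
  expect_error(build_period_grid(10, 5), "below")
})

test_that("FFT transform agrees with the direct O(N^2) convolution oracle", {
  set.seed(42)
  x <- standardize(rnorm(200))
  periods <- build_period_grid(8, 64, 6)
  for (m in list(c("morlet", 6), c("dog", 2))) {
    got <- cwt(x, periods, mother_wavelet(m[1], as.numeric(m[2])))$power
    want <- cwt_direct_power(x, periods, m[1], as.numeric(m[2]))
    expect_lt(max(abs(got - want)) / max(want), 1e-6)
  }
})

test_that("a pure sinusoid peaks at the nearest grid period; superposition adds peaks", {
  n <- 4096
  periods <- build_period_grid(8, 256, 12)
  x24 <- standardize(sin(2 * pi * seq_len(n) / 24))
  g <- cwt(x24, periods)$global_power
  expect_equal(periods[which.max(g)],
               periods[which.min(abs(periods - 24))])

  x <- standardize(sin(2 * pi * seq_len(n) / 24) + sin(2 * pi * seq_len(n) / 96))
  g2 <- cwt(x, periods)$global_power
  local_max <- which(diff(sign(diff(g2))) == -2) + 1
  peak_periods <- periods[local_max[order(g2[local_max], decreasing = TRUE)][1:2]]
  expect_true(any(abs(peak_periods / 24 - 1) < 0.06))
  expect_true(any(abs(peak_periods / 96 - 1) < 0.06))
})

test_that("white-noise global spectra are flat at periods well below series length", {
  periods <- build_period_grid(8, 128, 8)
  g <- 0
  for (seed in 1:5) {
    set.seed(seed)
    g <- g + cwt(standardize(rnorm(1024)), periods)$global_power
  }
  g <- g / 5
  expect_lt(max(g), 3 * median(g))
})

test_that("power is quadratic in amplitude and covariant under time shifts", {
  set.seed(9)
  base <- rnorm(256)
  periods <- build_period_grid(8, 32, 6)
  p1 <- cwt(base, periods)$power
  p3 <- cwt(3 * base, periods)$power
  expect_equal(p3, 9 * p1, tolerance = 1e-10)

  shift <- 64
  x <- c(base, rnorm(shift))
  pa <- cwt(x, periods)$power
  # interior columns of the shifted series match the original's, away from edges
  expect_equal(pa[, 100:150], cwt(x[1:256], periods)$power[, 100:150],
               tolerance = 0.02)
})

test_that("too-short series and unsorted grids are rejected", {
  expect_error(cwt(rnorm(20), periods = c(8, 16)), "shorter")
  expect_error(cwt(rnorm(200), periods = c(16, 8)), "increasing")
  expect_error(cwt(c(rnorm(100), NA), periods = c(8, 16)), "gap-free")
})

test_that("Monte-Carlo significance flags a strong sinusoid and is calibrated on noise", {
  set.seed(11)
  n <- 512
  periods <- build_period_grid(8, 64, 6)
  x <- standardize(sin(2 * pi * seq_len(n) / 32) + 0.2 * rnorm(n))
  ws <- significance(cwt(x, periods), n_sim = 60, seed = 1)
  row32 <- which.min(abs(periods - 32))
  expect_true(all(ws$pvalues[row32, 100:400] <= 0.05))

  frac <- numeric(3)
  for (s in 1:3) {
    set.seed(s)
    wn <- significance(cwt(standardize(rnorm(n)), periods), n_sim = 100,
                       seed = 100 + s)
    frac[s] <- mean(wn$pvalues <= 0.05)
  }
  expect_lt(abs(mean(frac) - 0.05), 0.02)

  expect_warning(significance(cwt(standardize(rnorm(64)), periods = c(8, 12, 16)),
                              n_sim = 10, seed = 1), "resolution")
})

test_that("global and display normalisation behave as documented", {
  set.seed(3)
  ws <- cwt(standardize(rnorm(256)), build_period_grid(8, 32, 6))
  gn <- global_and_normalized(ws)
  expect_equal(gn$global_power, rowMeans(ws$power))
  expect_equal(max(gn$display_power), 1)
  expect_true(all(gn$display_power >= 0 & gn$display_power <= 1))
})
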