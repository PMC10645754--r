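mk_part <- function(twd, gro = NULL, start = "2015-01-01 00:00", species = "FASY") {
  n <- length(twd)
  partitioned_series(hourly_ts(start, n), twd, gro %||% rep(0, n),
                     cummax(twd), level = "species", species = species)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a constant series gives identical bin means, zero CIs, zero contrast", {
  n <- 24 * 120
  p <- mk_part(rep(5, n))
  lun <- lunar_series(p$timestamp)
  pm <- phase_means(p, lun)
  expect_equal(pm$bins$twd$mean, rep(5, 12))
  expect_equal(pm$bins$twd$se, rep(0, 12))
  qt <- quartile_contrast_test(pm)
  expect_equal(qt$twd$contrast, 0)
  expect_false(qt$twd$verdict)
  expect_false(qt$moon_wood_signature)
})

test_that("an injected lunar sinusoid is traced by the bin means with the sinc attenuation", {
  ts <- hourly_ts("2015-01-01 00:00", 6 * 8766)
  phase <- synodic_phase(ts)
  A <- 10
  p <- mk_part(20 + A * cos(2 * pi * phase))
  pm <- phase_means(p, lunar_series(ts))
  m <- pm$bins$twd$mean
  # within-bin averaging attenuates a cosine by sinc(pi/12) ~ 0.989 under
  # uniform phase dwell; the moon's eccentric motion makes dwell slightly
  # uneven, so allow 5%
  atten <- sin(pi / 12) / (pi / 12)
  expect_equal(max(m) - min(m), 2 * A * atten, tolerance = 0.05)
  expect_equal(which.max(m) %in% c(12, 1), TRUE)  # peak at the new-moon pair
})

test_that("a pure diel cycle leaves lunar-bin means flat", {
  ts <- hourly_ts("2015-01-01 00:00", 8 * 709)   # >= 6 synodic months
  A <- 10
  x <- 20 + A * sin(2 * pi * seq_along(ts) / 24)
  p <- mk_part(x)
  pm <- phase_means(p, lunar_series(ts))
  m <- pm$bins$twd$mean
  expect_lt(max(m) - min(m), 0.05 * A)
})

test_that("frost handling above_zero drops cold timesteps from TWD only", {
  n <- 24 * 90
  twd <- rep(c(2, 8), length.out = n)           # cold hours carry high TWD
  gro <- rep(1, n)
  temp <- rep(c(5, -5), length.out = n)
  p <- mk_part(twd, gro)
  lun <- lunar_series(p$timestamp)
  pm_all <- phase_means(p, lun, temp, "all")
  pm_warm <- phase_means(p, lun, temp, "above_zero")
  expect_equal(pm_warm$bins$twd$mean, rep(2, 12))
  expect_equal(mean(pm_all$bins$twd$mean), 5, tolerance = 0.05)
  expect_equal(pm_warm$bins$gro$mean, rep(1, 12))
  expect_error(phase_means(p, lun, NULL, "above_zero"), "temperature")
})

test_that("AR(1)-corrected intervals are wider than naive ones on autocorrelated data", {
  set.seed(21)
  n <- 24 * 200
  x <- as.numeric(stats::filter(rnorm(n), 0.95, method = "recursive")) + 50
  p <- mk_part(x - min(x) + 1)
  lun <- lunar_series(p$timestamp)
  se_ar1 <- phase_means(p, lun, ci = "ar1")$bins$twd$se
  se_naive <- phase_means(p, lun, ci = "naive")$bins$twd$se
  expect_true(all(se_ar1 > se_naive))
})

test_that("bin-occupancy-weighted bin means recover the overall mean exactly", {
  set.seed(22)
  n <- 24 * 400
  x <- abs(cumsum(rnorm(n))) + 1
  p <- mk_part(x)
  lun <- lunar_series(p$timestamp)
  pm <- phase_means(p, lun)
  b <- pm$bins$twd
  expect_equal(sum(b$mean * b$n) / sum(b$n), mean(x), tolerance = 1e-10)
})

test_that("variability decomposition matches closed forms for pure cycles", {
  n <- 2 * 365 * 24                              # whole days, two years
  ts <- hourly_ts("2015-01-01 00:00", n)
  hour <- as.POSIXlt(ts)$hour
  A <- 6

  diel <- mk_part(20 + A * sin(2 * pi * hour / 24))
  vd <- variability_decomposition(diel, lunar_series(ts))
  twd_row <- vd[vd$variable == "twd", ]
  expect_equal(twd_row$sd_hour_of_day, A / sqrt(2), tolerance = 1e-10)
  expect_lt(twd_row$sd_lunar_bin, 0.05 * A)
  expect_lt(twd_row$sd_day_of_year, 0.05 * A)

  yd <- as.POSIXlt(ts)$yday
  annual <- mk_part(20 + A * sin(2 * pi * yd / 365.25))
  vd2 <- variability_decomposition(annual, lunar_series(ts))
  twd2 <- vd2[vd2$variable == "twd", ]
  expect_equal(twd2$sd_day_of_year, A / sqrt(2), tolerance = 0.02)
  expect_lt(twd2$sd_hour_of_day, 0.05 * A)

  const <- mk_part(rep(7, n))
  vd3 <- variability_decomposition(const, lunar_series(ts))
  expect_equal(vd3$sd_day_of_year, c(0, 0))
  expect_equal(vd3$sd_hour_of_day, c(0, 0))
  expect_equal(vd3$sd_lunar_bin, c(0, 0))
})

test_that("hour-of-day SD is invariant to rotating the series by whole days", {
  set.seed(23)
  n <- 40 * 24
  x <- abs(rnorm(n)) + 1
  ts <- hourly_ts("2015-01-01 00:00", n)
  p1 <- mk_part(x)
  p2 <- mk_part(c(x[-(1:48)], x[1:48]))          # rotate by 2 days
  v1 <- variability_decomposition(p1, lunar_series(ts))
  v2 <- variability_decomposition(p2, lunar_series(ts))
  expect_equal(v1$sd_hour_of_day, v2$sd_hour_of_day, tolerance = 1e-12)
})
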