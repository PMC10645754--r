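test_that("reading a dendrometer table yields per-tree series and a read report", {
  df <- data.frame(
    timestamp = rep(c("2019-06-01 00:00:00", "2019-06-01 01:00:00",
                      "2019-06-01 02:00:00"), 2),
    tree_id = rep(c("B", "A"), each = 3),
    species = "FASY", site = "s1",
    radius_um = c(10, 11, 12, 20, 21, 22))
  # interleave rows and shuffle time order for one tree
  df <- df[c(4, 1, 5, 2, 6, 3), ]
  p <- write_dendro_csv(df)
  trees <- read_dendrometer_table(p)
  expect_named(trees, c("A", "B"))
  expect_equal(nrow(trees$A), 3)
  expect_false(is.unsorted(trees$B$timestamp, strictly = TRUE))
  expect_equal(trees$B$radius_um, c(10, 11, 12))
  expect_equal(attr(trees, "read_report")$rows_dropped, 0)
})

test_that("NA radii are kept as missing; unparseable rows are dropped and counted", {
  df <- data.frame(timestamp = c("2019-06-01 00:00", "2019-06-01 01:00",
                                 "not-a-time", "2019-06-01 03:00"),
                   tree_id = "A", species = "FASY", site = "s1",
                   radius_um = c("10", "NA", "12", "oops"))
  p <- write_dendro_csv(df)
  trees <- read_dendrometer_table(p)
  rep <- attr(trees, "read_report")
  expect_equal(nrow(trees$A), 2)           # bad timestamp + bad radius dropped
  expect_true(is.na(trees$A$radius_um[2])) # "NA" kept as missing
  expect_equal(rep$rows_dropped, 2)
  expect_equal(rep$missing_radius, 1)
})

test_that("missing mandatory columns and empty files are rejected", {
  df <- data.frame(timestamp = "2019-06-01 00:00", tree_id = "A",
                   species = "FASY", radius_um = 1)
  p <- write_dendro_csv(df[0, ])
  expect_error(read_dendrometer_table(p), "empty")
  p2 <- write_dendro_csv(df[, -2])
  expect_error(read_dendrometer_table(p2), "tree_id")
})

test_that("hourly subsampling picks the observation nearest the top of the hour", {
  # 10-min series: the :00 values must be selected verbatim
  ts <- seq(as.POSIXct("2019-06-01 00:00", tz = "UTC"), by = 600, length.out = 25)
  s <- stem_series("A", "FASY", "s1", ts, seq_along(ts))
  h <- subsample_hourly(s)
  expect_true(all(diff(as.numeric(h$timestamp)) == 3600))
  expect_equal(h$radius_um, c(1, 7, 13, 19, 25))

  # 30-min series: tie between :30 before and :30 after broken toward earlier,
  # so the :00 observation (exactly on the hour) wins everywhere
  ts2 <- seq(as.POSIXct("2019-06-01 00:00", tz = "UTC"), by = 1800, length.out = 9)
  s2 <- stem_series("A", "FASY", "s1", ts2, seq_along(ts2))
  h2 <- subsample_hourly(s2)
  expect_equal(h2$radius_um, c(1, 3, 5, 7, 9))
})

test_that("a sensor outage leaves missing hourly slots", {
  ts <- seq(as.POSIXct("2019-06-01 00:00", tz = "UTC"), by = 600, length.out = 61)
  keep <- !(ts >= as.POSIXct("2019-06-01 02:25", tz = "UTC") &
              ts <= as.POSIXct("2019-06-01 05:35", tz = "UTC"))
  s <- stem_series("A", "FASY", "s1", ts[keep], seq_along(ts)[keep])
  h <- subsample_hourly(s)
  expect_equal(sum(is.na(h$radius_um)), 3)
  expect_equal(which(is.na(h$radius_um)), 4:6)  # hours 03, 04, 05
})

test_that("hourly subsampling is idempotent on hourly series", {
  ts <- hourly_ts("2019-06-01 00:00", 48)
  s <- stem_series("A", "FASY", "s1", ts, rnorm(48, 100))
  expect_equal(subsample_hourly(s)$radius_um, s$radius_um)
})

test_that("vapour pressure deficit follows the Magnus form", {
  expect_equal(compute_vpd(20, 100), 0)
  esat20 <- 0.61365 * exp(17.502 * 20 / (240.97 + 20))  # independent evaluation
  expect_equal(compute_vpd(20, 0), esat20, tolerance = 1e-12)
  expect_equal(compute_vpd(20, 50), esat20 / 2, tolerance = 1e-12)
  expect_error(compute_vpd(20, 101), "humidity")
  expect_error(compute_vpd(20, -1), "humidity")
})

test_that("vpd is monotone: decreasing in RH, increasing in T", {
  t_grid <- seq(-10, 35, by = 5)
  rh_grid <- seq(0, 100, by = 10)
  for (tt in t_grid)
    expect_true(all(diff(compute_vpd(rep(tt, length(rh_grid)), rh_grid)) <= 0))
  for (rh in rh_grid[-length(rh_grid)])
    expect_true(all(diff(compute_vpd(t_grid, rep(rh, length(t_grid)))) > 0))
})

test_that("prepare_meteo keeps a clean window unchanged and median-fills short gaps", {
  n <- 600
  ts <- hourly_ts("2019-01-01 00:00", n)
  temp <- sin(seq_len(n) / 24) * 10 + 8
  rh <- rep(70, n)
  m <- meteo_series("s1", ts, temp, rh)
  out <- prepare_meteo(m, min_window = 500, max_gap = 6)
  expect_equal(nrow(out), n)
  expect_equal(out$temperature_c, temp)

  temp2 <- temp; temp2[100:104] <- NA    # one 5-h gap
  m2 <- meteo_series("s1", ts, temp2, rh)
  out2 <- prepare_meteo(m2, min_window = 500, max_gap = 6)
  expect_equal(nrow(out2), n)
  expect_equal(sum(attr(out2, "imputed_n")), 5)
  expect_equal(out2$temperature_c[100:104],
               rep(median(temp2, na.rm = TRUE), 5))   # hand-computed median rule
  expect_false(anyNA(out2$temperature_c))
})

test_that("prepare_meteo rejects series whose every window has a long gap", {
  n <- 600
  ts <- hourly_ts("2019-01-01 00:00", n)
  temp <- rep(10, n)
  temp[c(150:156, 450:456)] <- NA        # 7-h gaps split the series
  m <- meteo_series("s1", ts, temp, rep(70, n))
  expect_error(prepare_meteo(m, min_window = 500, max_gap = 6),
               "insufficient continuous meteorology")
})

test_that("median imputation leaves the window median unchanged", {
  set.seed(7)
  n <- 400
  temp <- rnorm(n, 10, 5)
  temp[sample(n, 20)] <- NA
  m <- meteo_series("s1", hourly_ts("2019-01-01", n), temp, rep(70, n))
  out <- prepare_meteo(m, min_window = 300, max_gap = 25)
  expect_equal(median(out$temperature_c), median(temp, na.rm = TRUE))
})
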