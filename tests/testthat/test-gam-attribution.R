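# helper: synthetic power tables with known structure; smooth positive
# curves stand in for global wavelet spectra
fake_power_table <- function(n_species = 4, n_periods = 120, seed = 1,
                             response_fun = NULL, noise = 0.05,
                             temp_noise = 0.1) {
  set.seed(seed)
  periods <- build_period_grid(8, 2000, n_periods / log2(2000 / 8))
  periods <- periods[seq_len(min(n_periods, length(periods)))]
  spectra <- list()
  for (i in seq_len(n_species)) {
    sp <- sprintf("SP%02d", i)
    TEMP <- exp(sin(log(periods)) + temp_noise * rnorm(length(periods)))
    VPD <- exp(cos(log(periods)) + 0.1 * rnorm(length(periods)))
    LUN <- exp(-((log(periods) - log(709))^2) / 0.5) + 0.01
    y <- if (is.null(response_fun)) abs(rnorm(length(periods)))
         else response_fun(TEMP, VPD, LUN, i) + noise * rnorm(length(periods))
    spectra[[sp]] <- list(GRO = y, TWD = y, TEMP = TEMP, VPD = VPD, LUN = LUN)
  }
  assemble_power_table(spectra, periods)
}

test_that("power-table assembly has one row per species x period and validates inputs", {
  periods <- c(8, 16, 32)
  sp <- list(A = list(GRO = 1:3, TWD = 1:3, TEMP = 1:3, VPD = 1:3),
             B = list(GRO = 4:6, TWD = 4:6, TEMP = 1:3, VPD = 1:3))
  tab <- assemble_power_table(sp, periods, lun = c(1, 1, 1))
  expect_equal(nrow(tab), 6)
  expect_equal(tab$LUN, rep(1, 6))

  sp$B$VPD <- NULL
  expect_error(assemble_power_table(sp, periods, lun = c(1, 1, 1)), "B")
  sp$B$VPD <- 1:2
  expect_error(assemble_power_table(sp, periods, lun = c(1, 1, 1)), "grid")
})

test_that("a response built from TEMP plus species offsets is fit almost perfectly", {
  tab <- fake_power_table(4, 120, seed = 2,
                          response_fun = function(T, V, L, i) sin(T) + i,
                          noise = 0)
  fit <- fit_power_gam(tab, "GRO")
  expect_gte(fit$r2, 0.99)
})

test_that("an independent-noise response has near-zero R2", {
  r2 <- vapply(1:3, function(s)
    fit_power_gam(fake_power_table(5, 120, seed = s), "GRO")$r2, numeric(1))
  expect_lt(mean(r2), 0.1)
})

test_that("delta-R2 isolates the active predictor and ignores nuisance terms", {
  # TEMP carries idiosyncratic (non-smooth-in-period) variation that the
  # response depends on, so no other smooth can stand in for it
  tab <- fake_power_table(4, 120, seed = 3, temp_noise = 0.4,
                          response_fun = function(T, V, L, i) sin(2 * T) + 0.5 * i)
  a <- delta_r2_table(tab, "GRO")
  expect_lt(a$delta_r2[["TEMP"]], -0.3)
  expect_equal(names(which.min(a$delta_r2)), "TEMP")
  expect_lt(abs(a$delta_r2[["LUN"]]), 0.02)    # pure nuisance
  expect_lt(abs(a$delta_r2[["VPD"]]), 0.05)
  # reduced-model R2 never exceeds the full model beyond selection noise
  expect_true(all(a$r2_reduced <= a$r2_full + 0.01))
})

test_that("attribution is invariant to positive rescaling of a predictor", {
  tab <- fake_power_table(4, 100, seed = 4,
                          response_fun = function(T, V, L, i) sin(T) + i)
  a1 <- delta_r2_table(tab, "GRO")
  tab2 <- tab; tab2$TEMP <- tab2$TEMP * 37.5; tab2$LUN <- tab2$LUN / 1000
  a2 <- delta_r2_table(tab2, "GRO")
  expect_equal(a1$r2_full, a2$r2_full, tolerance = 1e-4)
  expect_equal(a1$delta_r2, a2$delta_r2, tolerance = 1e-3)
})

test_that("duplicated predictors share the credit: each delta-R2 collapses to ~0", {
  tab <- fake_power_table(4, 120, seed = 5,
                          response_fun = function(T, V, L, i) sin(T) + i)
  tab$VPD <- tab$TEMP                      # perfectly collinear
  a <- delta_r2_table(tab, "GRO")
  expect_lt(abs(a$delta_r2[["TEMP"]]), 0.02)
  expect_lt(abs(a$delta_r2[["VPD"]]), 0.02)
})

test_that("small tables and non-finite values are rejected", {
  tab <- fake_power_table(1, 20, seed = 6)
  expect_error(fit_power_gam(tab, "GRO"), "too small")
  tab2 <- fake_power_table(2, 60, seed = 7)
  tab2$TEMP[3] <- NA
  expect_error(fit_power_gam(tab2, "GRO"), "non-finite")
})

test_that("the mother-wavelet sweep runs all admissible combinations and skips the rest", {
  set.seed(8)
  n <- 1024
  mk <- function() {
    base <- sin(2 * pi * seq_len(n) / 24) + 0.3 * rnorm(n)
    list(GRO = base + 0.1 * rnorm(n), TWD = base + 0.1 * rnorm(n),
         TEMP = base + 0.1 * rnorm(n), VPD = base + 0.1 * rnorm(n))
  }
  series <- list(A = mk(), B = mk(), C = mk())
  lun <- sin(2 * pi * seq_len(n) / 709) + 0.05 * rnorm(n)
  res <- mother_wavelet_sensitivity(series, lun,
                                    periods = build_period_grid(8, 256, 6),
                                    families = c("morlet", "paul", "dog"),
                                    params = c(1, 6))
  # morlet(1) inadmissible -> 5 combos x 2 responses
  expect_equal(nrow(res), 10)
  expect_match(attr(res, "skipped"), "morlet\\(1\\)")
  expect_true(all(res$r2_full >= 0 & res$r2_full <= 1))
})
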