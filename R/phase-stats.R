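# Lunar-bin summary statistics: per-bin means with autocorrelation-corrected
# confidence intervals, the last-quartile contrast, and the three-way
# variability decomposition (day-of-year / hour-of-day / lunar bin).

bin_summary <- function(x, bins, rho, n_bins = 12) {
  out <- data.frame(bin = seq_len(n_bins), n = NA_integer_, mean = NA_real_,
                    se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
  for (b in seq_len(n_bins)) {
    v <- x[bins == b]
    v <- v[!is.na(v)]
    if (length(v) == 0) stopf("empty lunar bin %d: mean undefined", b)
    neff <- ess_ar1(length(v), rho)
    m <- mean(v); se <- stats::sd(v) / sqrt(neff)
    if (!is.finite(se)) se <- 0
    out[b, c("n", "mean", "se", "ci_lo", "ci_hi")] <-
      c(length(v), m, se, m - 1.96 * se, m + 1.96 * se)
  }
  out
}

group_contrast <- function(x, in_window, rho) {
  a <- x[in_window & !is.na(x)]; b <- x[!in_window & !is.na(x)]
  se <- sqrt(stats::sd(a)^2 / ess_ar1(length(a), rho) +
               stats::sd(b)^2 / ess_ar1(length(b), rho))
  if (!is.finite(se)) se <- 0
  d <- mean(a) - mean(b)
  c(contrast = d, ci_lo = d - 1.96 * se, ci_hi = d + 1.96 * se)
}

#' Lunar-bin means of TWD and GRO with confidence intervals
#'
#' Averages a species' TWD and GRO over the 12 equal synodic-phase
#' intervals and attaches 95% confidence intervals. Because hourly TWD is
#' strongly autocorrelated, the default standard error uses an effective
#' sample size from an AR(1) correction (`n_eff = n (1-rho)/(1+rho)` with
#' `rho` the series' lag-1 autocorrelation); `ci = "naive"` uses the plain
#' `sd/sqrt(n)`. The last-quartile contrast (mean over phase in
#' \[0.75, 1) minus mean over the rest) is computed per variable.
#' With `frost_handling = "above_zero"`, timesteps with air temperature not
#' above 0 degC are dropped from the TWD statistics (GRO is unaffected),
#' removing freezing-shrinkage artefacts.
#'
#' @param series a species-level [partitioned_series].
#' @param lunar a [lunar_series] covering the same timestamps.
#' @param temperature optional aligned temperature (numeric or
#'   [meteo_series]); required for `frost_handling = "above_zero"`.
#' @param frost_handling `"all"` or `"above_zero"`.
#' @param ci `"ar1"` (default) or `"naive"`.
#' @return Object of class `phase_summary`: list with per-variable bin
#'   tables, quartile contrasts, and metadata.
#' @export
phase_means <- function(series, lunar, temperature = NULL,
                        frost_handling = c("all", "above_zero"),
                        ci = c("ar1", "naive")) {
  frost_handling <- match.arg(frost_handling)
  ci <- match.arg(ci)
  stopifnot(inherits(series, "partitioned_series"), inherits(lunar, "lunar_series"))
  idx <- match(as.numeric(series$timestamp), as.numeric(lunar$timestamp))
  if (anyNA(idx)) stopf("lunar series does not cover the partitioned series")
  bins <- lunar$bin[idx]
  frac <- lunar$phase_fraction[idx]
  temp <- NULL
  if (!is.null(temperature)) {
    temp <- if (inherits(temperature, "meteo_series")) {
      ti <- match(as.numeric(series$timestamp), as.numeric(temperature$timestamp))
      temperature$temperature_c[ti]
    } else as.numeric(temperature)
  }
  if (frost_handling == "above_zero" && is.null(temp))
    stopf("frost_handling = 'above_zero' requires a temperature series")
  vars <- list(twd = series$twd_um, gro = series$gro_um_h)
  summaries <- list(); contrasts <- list()
  for (v in names(vars)) {
    x <- vars[[v]]
    keep <- !is.na(x)
    if (v == "twd" && frost_handling == "above_zero")
      keep <- keep & !is.na(temp) & temp > 0
    rho <- if (ci == "ar1") ar1_coef(x[keep]) else 0
    summaries[[v]] <- bin_summary(x[keep], bins[keep], rho)
    contrasts[[v]] <- group_contrast(x[keep], frac[keep] >= 0.75, rho)
  }
  structure(list(species = attr(series, "species"),
                 frost_handling = frost_handling, ci = ci,
                 bins = summaries, quartile_contrast = contrasts),
            class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf("<phase_summary> %s (frost: %s, ci: %s)\n",
              x$species, x$frost_handling, x$ci))
  for (v in names(x$bins)) {
    qc <- x$quartile_contrast[[v]]
    cat(sprintf("  %s: bin means %.3f..%.3f; last-quartile contrast %+.4f [%.4f, %.4f]\n",
                v, min(x$bins[[v]]$mean), max(x$bins[[v]]$mean),
                qc["contrast"], qc["ci_lo"], qc["ci_hi"]))
  }
  invisible(x)
}

#' Test the moon-wood last-quartile signature
#'
#' The moon wood theory predicts that stems shrink during the last quartile
#' of the synodic cycle (third quarter to new moon): TWD should be higher,
#' and growth lower, than over the rest of the cycle. The verdict is `TRUE`
#' for a variable when the 95% CI of the last-quartile contrast excludes 0
#' in the shrinkage direction (positive for TWD, negative for GRO).
#'
#' @param summary a [phase_means()] result.
#' @return List with per-variable `contrast`, `ci` and logical `verdict`,
#'   plus an overall `moon_wood_signature` (TRUE if either variable shows
#'   the predicted effect).
#' @export
quartile_contrast_test <- function(summary) {
  stopifnot(inherits(summary, "phase_summary"))
  res <- list()
  for (v in names(summary$quartile_contrast)) {
    qc <- summary$quartile_contrast[[v]]
    verdict <- if (v == "twd") qc["ci_lo"] > 0 else qc["ci_hi"] < 0
    res[[v]] <- list(contrast = unname(qc["contrast"]),
                     ci = unname(qc[c("ci_lo", "ci_hi")]),
                     verdict = unname(verdict))
  }
  res$moon_wood_signature <- any(vapply(res[c("twd", "gro")],
                                        function(r) isTRUE(r$verdict), TRUE))
  res
}

#' Decompose variability across calendar and lunar groupings
#'
#' Computes group means of TWD and GRO by day of year (Feb 29 its own
#' group), hour of day (24 groups) and lunar bin (12 groups), and reports
#' the (population) standard deviation across group means for each
#' grouping -- a scale-free comparison of annual, diel and lunar
#' variability -- both in the variable's units and as a percentage of its
#' long-term mean.
#'
#' @param series a species-level [partitioned_series] spanning >= 1 year.
#' @param lunar a [lunar_series] covering the same timestamps.
#' @param excluded optional logical vector of timesteps to drop (e.g. the
#'   frost flag from [equalize_frozen_twd()] subsample mode; applied to TWD
#'   only).
#' @return Object of class `variability_decomposition`: data frame with one
#'   row per variable and columns `sd_day_of_year`, `sd_hour_of_day`,
#'   `sd_lunar_bin`, `mean`, and the three SDs as `pct_*` of the mean.
#' @export
variability_decomposition <- function(series, lunar, excluded = NULL) {
  stopifnot(inherits(series, "partitioned_series"), inherits(lunar, "lunar_series"))
  idx <- match(as.numeric(series$timestamp), as.numeric(lunar$timestamp))
  if (anyNA(idx)) stopf("lunar series does not cover the partitioned series")
  bins <- lunar$bin[idx]
  doy <- format(series$timestamp, "%m-%d")
  hod <- format(series$timestamp, "%H")
  sd_pop <- function(m) {
    m <- m[is.finite(m)]
    sqrt(mean((m - mean(m))^2))
  }
  rows <- lapply(c(twd = "twd_um", gro = "gro_um_h"), function(col) {
    x <- series[[col]]
    if (col == "twd_um" && !is.null(excluded)) x[excluded] <- NA
    gmean <- function(g) tapply(x, g, mean, na.rm = TRUE)
    m <- mean(x, na.rm = TRUE)
    sds <- c(sd_day_of_year = sd_pop(gmean(doy)),
             sd_hour_of_day = sd_pop(gmean(hod)),
             sd_lunar_bin = sd_pop(gmean(bins)))
    data.frame(t(sds), mean = m,
               pct_day_of_year = 100 * sds[1] / m,
               pct_hour_of_day = 100 * sds[2] / m,
               pct_lunar_bin = 100 * sds[3] / m)
  })
  out <- do.call(rbind, rows)
  out <- cbind(variable = names(rows), out)
  rownames(out) <- NULL
  structure(out, class = c("variability_decomposition", "data.frame"),
            species = attr(series, "species"))
}
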