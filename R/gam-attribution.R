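# Attribution of per-period mean wavelet power of GRO and TWD to the
# corresponding powers of temperature, VPD and lunar phase, via additive
# smooth models with species-specific intercepts.

#' Assemble the per-species, per-period power table
#'
#' Takes, for each species, the global (time-mean) wavelet power spectra of
#' its GRO, TWD, temperature and VPD series plus the shared lunar-phase
#' spectrum, and stacks them into a long table with one row per species x
#' period.
#'
#' @param spectra named list (per species) of named lists with numeric
#'   global-power vectors `GRO`, `TWD`, `TEMP`, `VPD` (and optionally
#'   `LUN`); all on the same period grid.
#' @param periods the common period grid (hours).
#' @param lun the lunar-phase global power (used for every species unless a
#'   species supplies its own).
#' @return Object of class `power_table`: data frame with columns `species`,
#'   `period`, `GRO`, `TWD`, `TEMP`, `VPD`, `LUN`.
#' @export
assemble_power_table <- function(spectra, periods, lun = NULL) {
  rows <- lapply(names(spectra), function(sp) {
    s <- spectra[[sp]]
    for (v in c("GRO", "TWD", "TEMP", "VPD")) {
      if (is.null(s[[v]]))
        stopf("missing %s spectrum for species %s", v, sp)
      if (length(s[[v]]) != length(periods))
        stopf("spectrum %s of species %s not on the common period grid", v, sp)
    }
    lv <- s$LUN %||% lun
    if (is.null(lv)) stopf("missing LUN spectrum for species %s", sp)
    if (length(lv) != length(periods))
      stopf("LUN spectrum not on the common period grid")
    data.frame(species = sp, period = periods, GRO = s$GRO, TWD = s$TWD,
               TEMP = s$TEMP, VPD = s$VPD, LUN = lv)
  })
  structure(do.call(rbind, rows), class = c("power_table", "data.frame"))
}

r2_unadjusted <- function(fit, y) {
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Fit the additive power-attribution model
#'
#' Fits `response_f = a0_species + s(TEMP_f) + s(VPD_f) + s(LUN_f)` with
#' thin-plate regression splines (basis dimension `k`), smoothing selected
#' by generalized cross-validation, where each variable is the mean wavelet
#' power at period `f`. R-squared is reported unadjusted,
#' `1 - RSS/TSS`.
#'
#' @param table a [assemble_power_table()] result (>= 30 rows).
#' @param response `"GRO"` or `"TWD"`.
#' @param exclude character vector of predictors (`"TEMP"`, `"VPD"`,
#'   `"LUN"`) to omit from the model.
#' @param k basis dimension per smooth term.
#' @return List with the `mgcv::gam` fit, `r2`, `response`, `predictors`.
#' @export
fit_power_gam <- function(table, response = c("GRO", "TWD"), exclude = NULL,
                          k = 10) {
  response <- match.arg(response)
  stopifnot(inherits(table, "data.frame"))
  if (nrow(table) < 30) stopf("power table too small (%d rows; need >= 30)", nrow(table))
  preds <- setdiff(c("TEMP", "VPD", "LUN"), exclude)
  if (!all(stats::complete.cases(table[c(response, preds)])))
    stopf("non-finite values in power table")
  df <- table
  df$species <- factor(df$species)
  terms <- sprintf("s(%s, bs = 'tp', k = %d)", preds, k)
  rhs <- paste(c(if (nlevels(df$species) > 1) "species" else "1", terms),
               collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- mgcv::gam(fml, data = df, method = "GCV.Cp")
  list(fit = fit, r2 = r2_unadjusted(fit, df[[response]]),
       response = response, predictors = preds)
}

#' Full and leave-one-predictor-out attribution
#'
#' Refits the model excluding each smooth term in turn (with fresh
#' smoothing selection) and reports `delta_r2 = R2_reduced - R2_full` per
#' predictor -- a negative value whose magnitude measures the predictor's
#' unique contribution.
#'
#' @inheritParams fit_power_gam
#' @return Object of class `attribution_result`: list with `response`,
#'   `r2_full`, `delta_r2` (named numeric), `r2_reduced` (named numeric),
#'   and the full fit.
#' @export
delta_r2_table <- function(table, response = c("GRO", "TWD"), k = 10) {
  response <- match.arg(response)
  full <- fit_power_gam(table, response, k = k)
  preds <- full$predictors
  r2_red <- vapply(preds, function(p)
    fit_power_gam(table, response, exclude = p, k = k)$r2, numeric(1))
  structure(list(response = response, r2_full = full$r2,
                 r2_reduced = r2_red, delta_r2 = r2_red - full$r2,
                 fit = full$fit),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> %s ~ species + s(TEMP) + s(VPD) + s(LUN)\n",
              x$response))
  cat(sprintf("  full model R2 = %.3f\n", x$r2_full))
  for (p in names(x$delta_r2))
    cat(sprintf("  excluding %-4s R2 = %.3f (dR2 = %+.3f)\n",
                p, x$r2_reduced[p], x$delta_r2[p]))
  invisible(x)
}

#' Sensitivity of attribution to the mother-wavelet choice
#'
#' Recomputes the wavelet spectra, power table and attribution models for
#' every requested mother family and non-dimensional parameter, holding
#' everything else fixed. Inadmissible combinations (e.g. Morlet with
#' k0 < 4) are skipped and logged in the `skipped` attribute.
#'
#' @param species_series named list (per species) of named lists with the
#'   standardized-ready numeric series `GRO`, `TWD`, `TEMP`, `VPD` (gap
#'   free, common hourly axis per species).
#' @param lun numeric lunar-phase series on the same axis length.
#' @param periods period grid (hours).
#' @param families mother families to sweep.
#' @param params non-dimensional parameters to sweep.
#' @param k GAM basis dimension.
#' @return Data frame with one row per admissible (family, param, response):
#'   `family`, `param`, `response`, `r2_full`, `dr2_temp`, `dr2_vpd`,
#'   `dr2_lun`.
#' @export
mother_wavelet_sensitivity <- function(species_series, lun, periods,
                                       families = c("morlet", "paul", "dog"),
                                       params = 1:10, k = 10) {
  rows <- list(); skipped <- character()
  for (fam in families) for (p in params) {
    mother <- tryCatch(mother_wavelet(fam, p), error = function(e) e)
    if (inherits(mother, "error")) {
      skipped <- c(skipped, sprintf("%s(%g): %s", fam, p, conditionMessage(mother)))
      next
    }
    gl <- function(x) cwt(standardize(x), periods = periods, mother = mother)$global_power
    spectra <- lapply(species_series, function(s)
      list(GRO = gl(s$GRO), TWD = gl(s$TWD), TEMP = gl(s$TEMP), VPD = gl(s$VPD)))
    tab <- assemble_power_table(spectra, periods, lun = gl(lun))
    for (resp in c("GRO", "TWD")) {
      a <- delta_r2_table(tab, resp, k = k)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, param = p, response = resp, r2_full = a$r2_full,
        dr2_temp = a$delta_r2[["TEMP"]], dr2_vpd = a$delta_r2[["VPD"]],
        dr2_lun = a$delta_r2[["LUN"]])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
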