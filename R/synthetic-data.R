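# Synthetic hourly meteorology and stem-radius series with known ground
# truth: annual/semiannual/daily temperature cycles, VPD-driven reversible
# shrink-swell, warm-season irreversible growth, sporadic freezing
# shrinkage, observation noise, sensor gaps, and an injectable
# lunar-period component of configurable amplitude.

site_defaults <- function() {
  list(
    baltic = list(temp_mean = 9, temp_annual_amp = 9, temp_semiannual_amp = 1.5,
                  temp_daily_amp = 4, temp_ar = 0.97, temp_noise_sd = 2,
                  rh_base = 82, rh_daily_slope = 3.5, rh_noise_sd = 7),
    alpine = list(temp_mean = 4, temp_annual_amp = 8, temp_semiannual_amp = 1.2,
                  temp_daily_amp = 5, temp_ar = 0.97, temp_noise_sd = 2.2,
                  rh_base = 78, rh_daily_slope = 3.0, rh_noise_sd = 8))
}

species_defaults <- function(lunar_amplitude = 0) {
  mk <- function(site, growth_peak, water_gain, freeze_shrink)
    list(site = site, n_trees = 5, growth_peak = growth_peak,
         water_gain = water_gain, freeze_shrink = freeze_shrink,
         lunar_amplitude = lunar_amplitude, noise_sd = 2,
         gap_rate = 2, gap_mean_h = 24)
  list(FASY = mk("baltic", 1.3, 160, 60),
       QURO = mk("baltic", 1.1, 180, 80),
       ACPS = mk("baltic", 1.2, 150, 60),
       CABE = mk("baltic", 1.0, 140, 70),
       PCAB = mk("alpine", 1.2, 120, 30),
       PISY = mk("alpine", 1.0, 110, 30))
}

#' Configuration for the synthetic dendrometer world
#'
#' The `paper_scale` profile emulates the study conditions the pipeline is
#' designed for: six years (2015--2020) of hourly records for six species
#' (four temperate broadleaves at a Baltic-lowland-like site, two conifers
#' at an Alpine-like site) with at least five trees per species. The
#' `tiny` profile (two species, three trees, one year) is for fast
#' round-trip checks. `lunar_amplitude` (um) injects a synodic-period
#' component into the reversible water term of every tree, peaking in the
#' last-quartile window; 0 gives the lunar-null world.
#'
#' @param profile `"tiny"` or `"paper_scale"`.
#' @param lunar_amplitude amplitude (um) of the injected lunar component.
#' @param n_years,start override the monitoring span.
#' @param species optional named list overriding per-species settings
#'   (fields `site`, `n_trees`, `growth_peak` um/h, `water_gain` um/kPa,
#'   `freeze_shrink` um, `lunar_amplitude` um, `noise_sd` um, `gap_rate`
#'   outages/year, `gap_mean_h`).
#' @param sites optional named list overriding per-site meteorology params.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(profile = c("paper_scale", "tiny"),
                         lunar_amplitude = 0, n_years = NULL, start = NULL,
                         species = NULL, sites = NULL) {
  profile <- match.arg(profile)
  spdef <- species_defaults(lunar_amplitude)
  if (profile == "tiny") {
    spdef <- spdef[c("FASY", "PCAB")]
    for (i in seq_along(spdef)) spdef[[i]]$n_trees <- 3
    n_years <- n_years %||% 1
  } else {
    n_years <- n_years %||% 6
  }
  if (!is.null(species)) {
    for (sp in names(species)) {
      base <- spdef[[sp]] %||% species[[sp]]
      base[names(species[[sp]])] <- species[[sp]]
      spdef[[sp]] <- base
    }
    spdef <- spdef[intersect(names(spdef), names(species))]
  }
  stdef <- site_defaults()
  if (!is.null(sites)) {
    for (s in names(sites)) stdef[[s]][names(sites[[s]])] <- sites[[s]]
  }
  start <- as_utc(start %||% "2015-01-01 00:00:00")
  end <- start + (round(n_years * 365.25 * 24) - 1) * 3600
  structure(list(profile = profile, start = start, end = end,
                 n_years = n_years, sites = stdef, species = spdef),
            class = "synth_config")
}

ar1_noise <- function(n, phi, sd_marginal) {
  as.numeric(stats::filter(stats::rnorm(n, 0, sd_marginal * sqrt(1 - phi^2)),
                           phi, method = "recursive"))
}

#' Generate synthetic hourly meteorology
#'
#' Temperature is the sum of annual, semiannual and daily sinusoids (peaks
#' around mid-July, winter/summer shoulders and mid-afternoon) plus
#' persistent AR(1) noise; relative humidity is anticorrelated with the
#' diel temperature cycle, clamped to \[15, 100\] percent; VPD follows via
#' [compute_vpd()]. The global wavelet spectrum of such a temperature
#' series peaks at 24 h, half a year and one year.
#'
#' @param config a [synth_config()].
#' @param seed integer root seed (substream `"meteo-<site>"`).
#' @return Named list of gap-free [meteo_series], one per site in use.
#' @export
generate_meteo <- function(config, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  ts <- seq(config$start, config$end, by = 3600)
  lt <- as.POSIXlt(ts)
  yd <- lt$yday + lt$hour / 24
  hour <- lt$hour
  used_sites <- unique(vapply(config$species, `[[`, "", "site"))
  out <- list()
  for (s in used_sites) {
    p <- config$sites[[s]]
    set.seed(derive_seed(seed, paste0("meteo-", s)))
    ann <- p$temp_annual_amp * cos(2 * pi * (yd - 200) / 365.25)
    semi <- p$temp_semiannual_amp * cos(4 * pi * (yd - 15) / 365.25)
    daily <- p$temp_daily_amp * cos(2 * pi * (hour - 15) / 24)
    noise <- ar1_noise(length(ts), p$temp_ar, p$temp_noise_sd)
    temp <- p$temp_mean + ann + semi + daily + noise
    rh <- p$rh_base - p$rh_daily_slope * daily - 1.2 * noise +
      ar1_noise(length(ts), 0.9, p$rh_noise_sd)
    rh <- pmin(pmax(rh, 15), 100)
    out[[s]] <- meteo_series(s, ts, temp, rh)
  }
  out
}

#' Generate synthetic stem-radius series with ground truth
#'
#' Each tree's radius is built as
#' `r(t) = r0 + G(t) - W(t) - L(t) - F(t) + eps(t)` where `G` is
#' non-decreasing cumulative growth (rate positive only while a 14-day
#' smoothed temperature gate is open, modulated by concurrent temperature
#' and a nocturnal diel weight), `W = water_gain *` exponentially smoothed
#' VPD (reversible shrinkage), `L = lunar_amplitude * (1 - cos(2 pi
#' (phase - 0.875))) / 2` (a synodic-period shrinkage peaking mid
#' last-quartile), `F` a freezing-shrinkage response tracking sub-zero
#' episodes with recovery, and `eps` white observation noise. Per-tree
#' lognormal multipliers perturb growth and water gains; sensor outages are
#' injected as a Poisson process of gaps. All randomness derives from the
#' root seed via named substreams.
#'
#' @param config a [synth_config()].
#' @param meteo output of [generate_meteo()] (same config and seed).
#' @param seed integer root seed.
#' @return List with `series` (named list of [stem_series]) and `truth`
#'   (per tree: `G`, `W`, `L`, `F` component series, `r0`, multipliers;
#'   plus site-level `freeze_events` instants).
#' @export
generate_stem_series <- function(config, meteo, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  series <- list(); truth <- list(trees = list(), freeze_events = list())
  ts <- seq(config$start, config$end, by = 3600)
  n <- length(ts)
  hour <- as.POSIXlt(ts)$hour
  phase <- synodic_phase(ts)
  lun_shape <- (1 - cos(2 * pi * (phase - 0.875))) / 2
  site_cache <- list()
  for (s in unique(vapply(config$species, `[[`, "", "site"))) {
    met <- meteo[[s]]
    if (is.null(met)) stopf("no meteo series for site %s", s)
    if (nrow(met) != n) stopf("meteo for site %s does not cover the span", s)
    temp <- met$temperature_c
    fnorm <- numeric(n); f <- 0
    frozen <- !is.na(temp) & temp < 0
    for (i in seq_len(n)) {
      f <- f + 0.25 * ((if (frozen[i]) 1 else 0) - f)
      fnorm[i] <- f
    }
    season <- stats::plogis((moving_average(temp, 14 * 24) - 5) / 1.5)
    site_cache[[s]] <- list(
      temp = temp, fnorm = fnorm, season = season,
      tempresp = stats::plogis((temp - 8) / 3),
      wet = ema(met$vpd_kpa, 0.9),  # one-sided smoothed VPD, unit steady-state gain
      diel = 0.5 + 0.5 * cos(2 * pi * (hour - 3) / 24))
    truth$freeze_events[[s]] <- ts[which(diff(c(FALSE, frozen)) == 1)]
  }
  for (sp in names(config$species)) {
    cs <- config$species[[sp]]
    sc <- site_cache[[cs$site]]
    for (i in seq_len(cs$n_trees)) {
      id <- sprintf("%s_%02d", sp, i)
      set.seed(derive_seed(seed, paste0("tree-", id)))
      rate_mult <- exp(stats::rnorm(1, 0, 0.15))
      water_mult <- exp(stats::rnorm(1, 0, 0.15))
      r0 <- 1000 + stats::runif(1, 0, 500)
      g <- cs$growth_peak * rate_mult * sc$season * sc$tempresp * sc$diel
      g[1] <- 0
      G <- cumsum(g)
      W <- cs$water_gain * water_mult * sc$wet
      L <- cs$lunar_amplitude * lun_shape
      F_ <- cs$freeze_shrink * sc$fnorm
      eps <- if (cs$noise_sd > 0) stats::rnorm(n, 0, cs$noise_sd) else numeric(n)
      radius <- r0 + G - W - L - F_ + eps
      set.seed(derive_seed(seed, paste0("gaps-", id)))
      n_gaps <- stats::rpois(1, cs$gap_rate * config$n_years)
      if (n_gaps > 0) {
        starts <- sample.int(n, n_gaps)
        lens <- stats::rgeom(n_gaps, 1 / cs$gap_mean_h) + 1
        for (k in seq_len(n_gaps))
          radius[starts[k]:min(n, starts[k] + lens[k] - 1)] <- NA
      }
      series[[id]] <- stem_series(id, sp, cs$site, ts, radius)
      truth$trees[[id]] <- list(tree_id = id, species = sp, r0 = r0,
                                rate_mult = rate_mult, water_mult = water_mult,
                                G = G, W = W, L = L, F = F_)
    }
  }
  list(series = series, truth = truth)
}

#' Write a synthetic fixture dataset to disk
#'
#' Produces `dendro.csv` and `meteo.csv` in the [read_dendrometer_table()] /
#' [read_meteo_table()] schema, a ground-truth sidecar (`truth.csv`: full
#' component series for the tiny profile, per-tree cumulative growth for
#' paper scale) and a `manifest.json` recording profile, seed and species.
#'
#' @param dir output directory (created if needed).
#' @param profile `"tiny"` or `"paper_scale"`.
#' @param seed integer root seed.
#' @param config optional [synth_config()] overriding the profile default.
#' @return The directory path, invisibly; file paths in attribute `files`.
#' @export
make_fixture_dataset <- function(dir, profile = c("tiny", "paper_scale"),
                                 seed = 1, config = NULL) {
  profile <- match.arg(profile)
  config <- config %||% synth_config(profile)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  met <- generate_meteo(config, seed)
  gen <- generate_stem_series(config, met, seed)
  fmt <- function(t) format(t, "%Y-%m-%d %H:%M:%S")
  dendro <- do.call(rbind, lapply(gen$series, function(s)
    data.frame(timestamp = fmt(s$timestamp), tree_id = attr(s, "tree_id"),
               species = attr(s, "species"), site = attr(s, "site"),
               radius_um = s$radius_um)))
  utils::write.csv(dendro, file.path(dir, "dendro.csv"), row.names = FALSE)
  meteo_tab <- do.call(rbind, lapply(met, function(m)
    data.frame(timestamp = fmt(m$timestamp), site = attr(m, "site"),
               temperature_c = m$temperature_c, rh_pct = m$rh_pct)))
  utils::write.csv(meteo_tab, file.path(dir, "meteo.csv"), row.names = FALSE)
  if (config$profile == "tiny") {
    truth <- do.call(rbind, lapply(gen$truth$trees, function(tr)
      data.frame(timestamp = fmt(gen$series[[tr$tree_id]]$timestamp),
                 tree_id = tr$tree_id, G = tr$G, W = tr$W, L = tr$L, F = tr$F)))
  } else {
    truth <- do.call(rbind, lapply(gen$truth$trees, function(tr)
      data.frame(tree_id = tr$tree_id, species = tr$species, r0 = tr$r0,
                 cumulative_growth_um = tr$G[length(tr$G)])))
  }
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  manifest <- list(profile = config$profile, seed = seed,
                   start = fmt(config$start), end = fmt(config$end),
                   species = lapply(config$species, function(s)
                     s[c("site", "n_trees", "lunar_amplitude")]))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- file.path(dir, c("dendro.csv", "meteo.csv", "truth.csv", "manifest.json"))
  invisible(structure(dir, files = files))
}
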