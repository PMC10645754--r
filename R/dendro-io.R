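# Reading, validation and preparation of dendrometer and meteorological tables.

#' Construct a stem-radius series for one tree
#'
#' A `stem_series` holds one tree's (sub-)hourly record of stem radius in
#' micrometres together with species and site metadata. Timestamps must be
#' strictly increasing; radius values may be missing but must be finite and
#' non-negative where present.
#'
#' @param tree_id character scalar identifying the tree.
#' @param species character species code (e.g. `"FASY"`, `"PCAB"`).
#' @param site character site identifier.
#' @param timestamps POSIXct (UTC) instants, strictly increasing.
#' @param radius numeric stem radius in micrometres; `NA` allowed.
#' @return An object of class `stem_series` (a data frame with columns
#'   `timestamp` and `radius_um` plus metadata attributes).
#' @export
stem_series <- function(tree_id, species, site, timestamps, radius) {
  timestamps <- as_utc(timestamps)
  if (length(timestamps) != length(radius))
    stopf("timestamps and radius differ in length (%d vs %d)",
          length(timestamps), length(radius))
  if (anyNA(timestamps)) stopf("unparseable timestamps in stem_series")
  if (is.unsorted(timestamps, strictly = TRUE))
    stopf("timestamps must be strictly increasing (tree %s)", tree_id)
  radius <- as.numeric(radius)
  bad <- !is.na(radius) & (!is.finite(radius) | radius < 0)
  if (any(bad)) stopf("radius must be finite and non-negative where present")
  out <- data.frame(timestamp = timestamps, radius_um = radius)
  structure(out, class = c("stem_series", "data.frame"),
            tree_id = as.character(tree_id), species = as.character(species),
            site = as.character(site))
}

#' @export
print.stem_series <- function(x, ...) {
  cat(sprintf("<stem_series> tree %s (%s, site %s): %d obs, %s .. %s, %d missing\n",
              attr(x, "tree_id"), attr(x, "species"), attr(x, "site"),
              nrow(x), format(x$timestamp[1]), format(x$timestamp[nrow(x)]),
              sum(is.na(x$radius_um))))
  invisible(x)
}

#' Read a dendrometer table into per-tree stem series
#'
#' Reads a delimited text file with one row per observation and splits it
#' into one [stem_series] per tree, sorted by time. Rows whose timestamp or
#' radius cannot be parsed are dropped and counted in the read report
#' attached as attribute `"read_report"`.
#'
#' @param path path to a CSV/TSV file.
#' @param schema named list mapping the roles `timestamp`, `tree_id`,
#'   `species`, `radius` (and optionally `site`) to column names in the file.
#' @param tz time zone of the file's clock times; converted to UTC.
#' @param sep field separator.
#' @return Named list of [stem_series] (names are tree ids), with a
#'   `read_report` attribute (rows read / dropped / missing radius).
#' @export
read_dendrometer_table <- function(path,
                                   schema = list(timestamp = "timestamp",
                                                 tree_id = "tree_id",
                                                 species = "species",
                                                 site = "site",
                                                 radius = "radius_um"),
                                   tz = "UTC", sep = ",") {
  if (!file.exists(path)) stopf("input error: file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (nrow(tab) == 0) stopf("input error: empty file: %s", path)
  need <- c("timestamp", "tree_id", "species", "radius")
  for (role in need) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(tab))
      stopf("configuration error: mandatory column for role '%s' (%s) not in %s",
            role, col %||% "<unset>", path)
  }
  has_site <- !is.null(schema$site) && schema$site %in% names(tab)
  ts <- suppressWarnings(as_utc(as.character(tab[[schema$timestamp]]), tz = tz))
  rad <- suppressWarnings(as.numeric(as.character(tab[[schema$radius]])))
  rad_raw <- as.character(tab[[schema$radius]])
  bad_ts <- is.na(ts)
  # a radius that was present in the file but did not parse is a bad row;
  # an empty/NA field is a legitimate missing value
  bad_rad <- is.na(rad) & !is.na(rad_raw) & !(toupper(trimws(rad_raw)) %in% "NA")
  keep <- !bad_ts & !bad_rad
  tab <- tab[keep, , drop = FALSE]; ts <- ts[keep]; rad <- rad[keep]
  report <- list(path = path, rows_read = length(keep),
                 rows_dropped = sum(!keep),
                 dropped_bad_timestamp = sum(bad_ts),
                 dropped_bad_radius = sum(bad_rad & !bad_ts),
                 missing_radius = sum(is.na(rad)))
  ids <- as.character(tab[[schema$tree_id]])
  out <- lapply(split(seq_len(nrow(tab)), ids), function(i) {
    o <- i[order(ts[i])]
    stem_series(tree_id = ids[o[1]],
                species = as.character(tab[[schema$species]])[o[1]],
                site = if (has_site) as.character(tab[[schema$site]])[o[1]] else "site1",
                timestamps = ts[o], radius = rad[o])
  })
  structure(out, read_report = report)
}

#' Subsample a stem series to an exact hourly grid
#'
#' For every clock hour between the first and last observation the value
#' observed at, or nearest to, the top of the hour is selected (ties broken
#' toward the earlier instant). Hours with no observation within 30 minutes
#' are left missing. Values are selected, never averaged: radius, TWD and
#' GRO are state variables.
#'
#' @param series a [stem_series] at 10--60 min resolution.
#' @return A [stem_series] on a strict 3600-s grid.
#' @export
subsample_hourly <- function(series) {
  stopifnot(inherits(series, "stem_series"))
  if (nrow(series) == 0) return(series)
  ts <- series$timestamp
  grid <- hourly_axis(ts[1], ts[length(ts)])
  tnum <- as.numeric(ts)
  hour_of <- round(tnum / 3600) * 3600          # nearest top-of-hour
  dist <- abs(tnum - hour_of)
  ok <- dist <= 1800
  # order by (hour, distance, time): first row per hour is nearest, tie earlier
  o <- order(hour_of, dist, tnum)
  o <- o[ok[o]]
  first <- o[!duplicated(hour_of[o])]
  sel_hour <- hour_of[first]
  val <- rep(NA_real_, length(grid))
  idx <- match(sel_hour, as.numeric(grid))
  keep <- !is.na(idx)
  val[idx[keep]] <- series$radius_um[first][keep]
  stem_series(attr(series, "tree_id"), attr(series, "species"),
              attr(series, "site"), grid, val)
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' Uses a Magnus-type saturation vapour pressure
#' `esat(T) = a * exp(b * T / (c + T))` in kPa with the constants of the
#' common ecophysiological implementation (a = 0.61365 kPa, b = 17.502,
#' c = 240.97 degC), then `vpd = esat(T) * (1 - RH/100)`.
#'
#' @param temperature air temperature, degrees Celsius.
#' @param relative_humidity relative humidity, percent, in \[0, 100\].
#' @param a,b,c Magnus constants; defaults as above.
#' @return VPD in kPa, elementwise; zero wherever RH = 100.
#' @export
compute_vpd <- function(temperature, relative_humidity,
                        a = 0.61365, b = 17.502, c = 240.97) {
  rh <- relative_humidity
  bad <- !is.na(rh) & (rh < 0 | rh > 100)
  if (any(bad))
    stopf("validation error: relative humidity outside [0, 100] (%d values)",
          sum(bad))
  esat <- a * exp(b * temperature / (c + temperature))
  pmax(esat * (1 - rh / 100), 0)
}

#' Construct an hourly meteorological series for one site
#'
#' @param site character site identifier.
#' @param timestamps hourly POSIXct (UTC).
#' @param temperature air temperature, degC.
#' @param relative_humidity relative humidity, percent.
#' @return Object of class `meteo_series`: data frame with `timestamp`,
#'   `temperature_c`, `rh_pct` and derived `vpd_kpa`.
#' @export
meteo_series <- function(site, timestamps, temperature, relative_humidity) {
  timestamps <- as_utc(timestamps)
  n <- length(timestamps)
  stopifnot(length(temperature) == n, length(relative_humidity) == n)
  if (is.unsorted(timestamps, strictly = TRUE))
    stopf("meteo timestamps must be strictly increasing")
  vpd <- rep(NA_real_, n)
  okv <- !is.na(temperature) & !is.na(relative_humidity)
  vpd[okv] <- compute_vpd(temperature[okv], relative_humidity[okv])
  out <- data.frame(timestamp = timestamps, temperature_c = as.numeric(temperature),
                    rh_pct = as.numeric(relative_humidity), vpd_kpa = vpd)
  structure(out, class = c("meteo_series", "data.frame"), site = as.character(site))
}

#' @export
print.meteo_series <- function(x, ...) {
  cat(sprintf("<meteo_series> site %s: %d hourly obs, %s .. %s, %d missing\n",
              attr(x, "site"), nrow(x), format(x$timestamp[1]),
              format(x$timestamp[nrow(x)]),
              sum(is.na(x$temperature_c) | is.na(x$rh_pct))))
  invisible(x)
}

#' Read a meteorological table
#'
#' @inheritParams read_dendrometer_table
#' @param schema named list mapping roles `timestamp`, `temperature`,
#'   `relative_humidity` (and optionally `site`) to column names.
#' @return Named list of [meteo_series], one per site.
#' @export
read_meteo_table <- function(path,
                             schema = list(timestamp = "timestamp",
                                           site = "site",
                                           temperature = "temperature_c",
                                           relative_humidity = "rh_pct"),
                             tz = "UTC", sep = ",") {
  if (!file.exists(path)) stopf("input error: file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (nrow(tab) == 0) stopf("input error: empty file: %s", path)
  for (role in c("timestamp", "temperature", "relative_humidity")) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(tab))
      stopf("configuration error: mandatory column for role '%s' missing", role)
  }
  has_site <- !is.null(schema$site) && schema$site %in% names(tab)
  sites <- if (has_site) as.character(tab[[schema$site]]) else rep("site1", nrow(tab))
  ts <- as_utc(as.character(tab[[schema$timestamp]]), tz = tz)
  lapply(split(seq_len(nrow(tab)), sites), function(i) {
    o <- i[order(ts[i])]
    meteo_series(site = sites[o[1]], timestamps = ts[o],
                 temperature = as.numeric(tab[[schema$temperature]])[o],
                 relative_humidity = as.numeric(tab[[schema$relative_humidity]])[o])
  })
}

#' Select and gap-fill a continuous meteorological analysis window
#'
#' Finds the longest contiguous stretch of at least `min_window` hours in
#' which no run of missing observations exceeds `max_gap` hours, then
#' replaces the remaining (short) gaps with the variable's long-term median
#' over that window. The returned series has no missing values, as required
#' by the wavelet transform.
#'
#' @param series a [meteo_series].
#' @param min_window minimum acceptable window length in hours
#'   (default two years).
#' @param max_gap longest tolerated missing segment, hours (default 6).
#' @return A gap-free [meteo_series] restricted to the selected window, with
#'   attribute `imputed_n` (values filled per variable).
#' @export
prepare_meteo <- function(series, min_window = 2 * 365 * 24, max_gap = 6) {
  stopifnot(inherits(series, "meteo_series"))
  if (!is_hourly(series$timestamp)) stopf("prepare_meteo expects an hourly series")
  miss <- is.na(series$temperature_c) | is.na(series$rh_pct)
  n <- nrow(series)
  r <- rle(miss)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  # break the series at missing runs longer than max_gap
  long_gap <- r$values & r$lengths > max_gap
  seg_start <- c(1, ends[long_gap] + 1)
  seg_end <- c(starts[long_gap] - 1, n)
  seg_len <- seg_end - seg_start + 1
  valid <- seg_len > 0
  seg_start <- seg_start[valid]; seg_end <- seg_end[valid]; seg_len <- seg_len[valid]
  if (length(seg_len) == 0 || max(seg_len) < min_window) {
    longest <- if (length(seg_len)) max(seg_len) else 0
    stopf(paste0("insufficient continuous meteorology: longest window with no ",
                 "gap > %d h is %d h (< %d h required)"),
          max_gap, longest, min_window)
  }
  i <- which.max(seg_len)
  w <- seg_start[i]:seg_end[i]
  out <- series[w, , drop = FALSE]
  imputed <- c(temperature_c = 0, rh_pct = 0)
  for (v in c("temperature_c", "rh_pct")) {
    na <- is.na(out[[v]])
    if (any(na)) {
      out[[v]][na] <- stats::median(out[[v]], na.rm = TRUE)
      imputed[v] <- sum(na)
    }
  }
  res <- meteo_series(attr(series, "site"), out$timestamp,
                      out$temperature_c, out$rh_pct)
  attr(res, "imputed_n") <- imputed
  res
}
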