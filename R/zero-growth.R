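# Zero-growth partitioning of stem-radius series into TWD and GRO.

#' Construct a partitioned (TWD/GRO) series
#'
#' Container for the result of zero-growth partitioning: aligned hourly
#' series of tree water deficit (`twd_um`, micrometres, >= 0), growth rate
#' (`gro_um_h`, micrometres per hour, >= 0) and the running maximum radius.
#' At every timestep at most one of TWD and GRO is nonzero.
#'
#' @param timestamps hourly POSIXct (UTC).
#' @param twd tree water deficit, um.
#' @param gro growth rate, um/h.
#' @param running_max running maximum radius, um.
#' @param level `"tree"` or `"species"`.
#' @param species species code.
#' @param tree_id tree id (tree level only).
#' @return Object of class `partitioned_series` (data frame).
#' @export
partitioned_series <- function(timestamps, twd, gro, running_max,
                               level = c("tree", "species"),
                               species, tree_id = NA_character_) {
  level <- match.arg(level)
  n <- length(timestamps)
  stopifnot(length(twd) == n, length(gro) == n, length(running_max) == n)
  if (any(twd < -1e-9, na.rm = TRUE)) stopf("negative TWD")
  if (any(gro < -1e-9, na.rm = TRUE)) stopf("negative GRO")
  out <- data.frame(timestamp = as_utc(timestamps), twd_um = as.numeric(twd),
                    gro_um_h = as.numeric(gro), running_max_um = as.numeric(running_max))
  structure(out, class = c("partitioned_series", "data.frame"),
            level = level, species = as.character(species),
            tree_id = as.character(tree_id))
}

#' @export
print.partitioned_series <- function(x, ...) {
  cat(sprintf("<partitioned_series> %s level (%s%s): %d hourly steps, mean TWD %.2f um, mean GRO %.3f um/h\n",
              attr(x, "level"), attr(x, "species"),
              if (attr(x, "level") == "tree") paste0(", tree ", attr(x, "tree_id")) else "",
              nrow(x), mean(x$twd_um, na.rm = TRUE), mean(x$gro_um_h, na.rm = TRUE)))
  invisible(x)
}

#' Partition a stem-radius series under the zero-growth assumption
#'
#' The zero-growth concept assumes that a stem only grows while its radius
#' exceeds the previous historical maximum; all variation below that maximum
#' is reversible, water-related shrinking and swelling. Accordingly
#' `running_max[t]` is the maximum radius observed up to `t`,
#' `twd[t] = running_max[t] - radius[t]` (tree water deficit, um) and
#' `gro[t] = max(0, radius[t] - running_max[t-1]) / 1 h` (growth rate,
#' um/h). At most one of the two is nonzero at any timestep. Missing radius
#' values propagate as missing TWD/GRO; the running maximum is carried
#' across gaps (the previous maximum is a physical state of the stem). The
#' first observed timestep has `gro = 0` and `twd = 0` by definition.
#'
#' @param series a [stem_series] on an hourly grid.
#' @return A tree-level [partitioned_series].
#' @export
partition_zero_growth <- function(series) {
  stopifnot(inherits(series, "stem_series"))
  r <- series$radius_um
  n <- length(r)
  if (n == 0 || all(is.na(r))) {
    warnf("all-missing radius series (tree %s): empty partition",
          attr(series, "tree_id"))
    return(partitioned_series(series$timestamp, rep(NA_real_, n),
                              rep(NA_real_, n), rep(NA_real_, n),
                              level = "tree", species = attr(series, "species"),
                              tree_id = attr(series, "tree_id")))
  }
  v <- ifelse(is.na(r), -Inf, r)
  rmax <- cummax(v)
  rmax[!is.finite(rmax)] <- NA_real_   # before the first observation
  prev_max <- c(NA_real_, rmax[-n])
  gro <- pmax(0, r - prev_max)         # NA where r or prev_max missing
  gro[!is.na(r) & is.na(prev_max)] <- 0  # first observed step: no previous maximum
  twd <- rmax - r
  twd[is.na(r)] <- NA_real_
  gro[is.na(r)] <- NA_real_
  partitioned_series(series$timestamp, twd, gro, rmax, level = "tree",
                     species = attr(series, "species"),
                     tree_id = attr(series, "tree_id"))
}

#' Replace unrealistic growth-rate spikes with zero
#'
#' Tree-level GRO values strictly exceeding `threshold` (default
#' 100 um/h) are attributed to dendrometer manipulation or sensor faults
#' and replaced with 0 um/h. The number of replacements is recorded in the
#' `replaced_n` attribute.
#'
#' @param series a tree-level [partitioned_series].
#' @param threshold replacement threshold in um/h; values exactly at the
#'   threshold are kept ("exceeding" is strict).
#' @return The cleaned [partitioned_series].
#' @export
clean_growth_outliers <- function(series, threshold = 100) {
  stopifnot(inherits(series, "partitioned_series"))
  if (attr(series, "level") != "tree")
    stopf("outlier cleaning is defined at the tree level")
  bad <- !is.na(series$gro_um_h) & series$gro_um_h > threshold
  series$gro_um_h[bad] <- 0
  attr(series, "replaced_n") <- sum(bad)
  series
}

#' Average tree-level partitions into a species-mean series
#'
#' TWD and GRO are averaged arithmetically over all trees reporting at each
#' timestep. Timesteps at which no tree reports are imputed with the
#' species' long-term median of the variable (computed over the whole
#' window), so the species series is gap-free. Counts of imputed timesteps
#' are recorded in the `imputed_n` attribute.
#'
#' @param series_set list of tree-level [partitioned_series] of one species.
#' @param species species code; defaults to the first tree's.
#' @return A species-level [partitioned_series].
#' @export
aggregate_species <- function(series_set, species = NULL) {
  if (length(series_set) == 0) stopf("aggregate_species: empty input")
  stopifnot(all(vapply(series_set, inherits, TRUE, "partitioned_series")))
  species <- species %||% attr(series_set[[1]], "species")
  t0 <- min(do.call(c, lapply(series_set, function(s) s$timestamp[1])))
  t1 <- max(do.call(c, lapply(series_set, function(s) s$timestamp[nrow(s)])))
  grid <- hourly_axis(t0, t1)
  key <- as.numeric(grid)
  acc <- function(var) {
    sum_v <- numeric(length(grid)); n_v <- integer(length(grid))
    for (s in series_set) {
      idx <- match(as.numeric(s$timestamp), key)
      ok <- !is.na(idx) & !is.na(s[[var]])
      sum_v[idx[ok]] <- sum_v[idx[ok]] + s[[var]][ok]
      n_v[idx[ok]] <- n_v[idx[ok]] + 1L
    }
    m <- ifelse(n_v > 0, sum_v / n_v, NA_real_)
    miss <- is.na(m)
    m[miss] <- stats::median(m, na.rm = TRUE)
    list(mean = m, imputed = sum(miss))
  }
  twd <- acc("twd_um"); gro <- acc("gro_um_h"); rmx <- acc("running_max_um")
  out <- partitioned_series(grid, twd$mean, gro$mean, rmx$mean,
                            level = "species", species = species)
  attr(out, "imputed_n") <- c(twd = twd$imputed, gro = gro$imputed)
  out
}

#' Equalize tree water deficit during freezing periods
#'
#' Sporadic freezing of intercellular water causes severe stem shrinkage
#' that can imprint spurious multi-day cycles on TWD. Two treatments are
#' offered: `mode = "replace"` substitutes the series' long-term median of
#' TWD at every timestep with air temperature below 0 degC (used before the
#' wavelet transform); `mode = "subsample"` leaves values untouched but
#' flags timesteps with temperature not above 0 degC as excluded for
#' downstream averaging (used for lunar-bin means).
#'
#' @param series a species-level [partitioned_series].
#' @param temperature a [meteo_series] or numeric temperature vector aligned
#'   with `series`.
#' @param mode `"replace"` or `"subsample"`.
#' @return The treated [partitioned_series]; in subsample mode with a
#'   logical column `excluded`.
#' @export
equalize_frozen_twd <- function(series, temperature,
                                mode = c("replace", "subsample")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "partitioned_series"))
  if (inherits(temperature, "meteo_series")) {
    idx <- match(as.numeric(series$timestamp), as.numeric(temperature$timestamp))
    if (anyNA(idx)) stopf("temperature series does not cover the partitioned series")
    temp <- temperature$temperature_c[idx]
  } else {
    if (length(temperature) != nrow(series))
      stopf("misaligned time axes: temperature length %d, series length %d",
            length(temperature), nrow(series))
    temp <- as.numeric(temperature)
  }
  if (mode == "replace") {
    frozen <- !is.na(temp) & temp < 0
    med <- stats::median(series$twd_um, na.rm = TRUE)
    series$twd_um[frozen] <- med
    attr(series, "frozen_replaced_n") <- sum(frozen)
  } else {
    series$excluded <- !(!is.na(temp) & temp > 0)
  }
  series
}

#' Write a partitioned series as tidy CSV
#'
#' @param series a [partitioned_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partitioned_csv <- function(series, path) {
  df <- data.frame(timestamp = format(series$timestamp, "%Y-%m-%d %H:%M:%S"),
                   species = attr(series, "species"),
                   level = attr(series, "level"),
                   twd_um = series$twd_um, gro_um_per_h = series$gro_um_h)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
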