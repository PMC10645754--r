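# Low-precision analytic lunar ephemeris: synodic phase, new-moon epochs,
# and the 12-interval phase binning used for lunar-cycle contrasts.

DEG <- pi / 180

julian_day <- function(t) as.numeric(t) / 86400 + 2440587.5

# Apparent-ish ecliptic longitude of the sun (degrees, unnormalized);
# truncated equation-of-center series, adequate to a few arcminutes.
sun_longitude <- function(T) {
  L0 <- 280.46646 + 36000.76983 * T + 0.0003032 * T^2
  M <- (357.52911 + 35999.05029 * T - 0.0001537 * T^2) * DEG
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * sin(M) +
    (0.019993 - 0.000101 * T) * sin(2 * M) + 0.000289 * sin(3 * M)
  L0 + C
}

# Ecliptic longitude of the moon (degrees); the 20 largest periodic terms
# of the standard lunar-theory series. Worst-case error is a few
# arcminutes -- well under the 0.01-cycle (3.6 degree) tolerance needed for
# 1/12-cycle phase binning.
moon_longitude <- function(T) {
  Lp <- 218.3164477 + 481267.88123421 * T - 0.0015786 * T^2
  D <- (297.8501921 + 445267.1114034 * T - 0.0018819 * T^2) * DEG
  M <- (357.5291092 + 35999.0502909 * T - 0.0001536 * T^2) * DEG
  Mp <- (134.9633964 + 477198.8675055 * T + 0.0087414 * T^2) * DEG
  F <- (93.2720950 + 483202.0175233 * T - 0.0036539 * T^2) * DEG
  Lp +
    6.288774 * sin(Mp) + 1.274027 * sin(2 * D - Mp) + 0.658314 * sin(2 * D) +
    0.213618 * sin(2 * Mp) - 0.185116 * sin(M) - 0.114332 * sin(2 * F) +
    0.058793 * sin(2 * D - 2 * Mp) + 0.057066 * sin(2 * D - M - Mp) +
    0.053322 * sin(2 * D + Mp) + 0.045758 * sin(2 * D - M) -
    0.040923 * sin(M - Mp) - 0.034720 * sin(D) - 0.030383 * sin(M + Mp) +
    0.015327 * sin(2 * D - 2 * F) - 0.012528 * sin(Mp + 2 * F) -
    0.010980 * sin(Mp - 2 * F) + 0.010675 * sin(4 * D - Mp) +
    0.010034 * sin(3 * Mp) + 0.008548 * sin(4 * D - 2 * Mp) -
    0.007888 * sin(2 * D + M - Mp)
}

check_ephemeris_range <- function(t) {
  y <- as.integer(format(t, "%Y"))
  if (any(y < 1900 | y > 2100, na.rm = TRUE))
    stopf("ephemeris valid for 1900-2100 only")
}

#' Synodic phase of the moon
#'
#' Fraction of the synodic cycle elapsed since the preceding new moon, in
#' \[0, 1): 0 = new moon, 0.25 = first quarter, 0.5 = full moon, 0.75 =
#' third quarter. Computed as the geocentric elongation (moon minus sun
#' ecliptic longitude, from truncated analytic series) divided by 360
#' degrees; accurate to well under 0.01 cycle against almanac new-moon
#' instants.
#'
#' @param timestamps POSIXct instants (UTC), years 1900--2100.
#' @return Numeric vector of phase fractions in \[0, 1).
#' @export
synodic_phase <- function(timestamps) {
  t <- as_utc(timestamps)
  check_ephemeris_range(t)
  T <- (julian_day(t) - 2451545) / 36525
  ((moon_longitude(T) - sun_longitude(T)) %% 360) / 360
}

# Signed elongation near zero (degrees in (-180, 180]); root = new moon.
elongation_signed <- function(t) {
  T <- (julian_day(t) - 2451545) / 36525
  d <- (moon_longitude(T) - sun_longitude(T)) %% 360
  ifelse(d > 180, d - 360, d)
}

#' New-moon epochs within a time window
#'
#' Scans an hourly grid for upward zero-crossings of the signed elongation
#' and refines each bracket by bisection to better than one minute.
#'
#' @param start,end POSIXct (UTC) window bounds, `start < end`.
#' @return POSIXct vector of new-moon instants inside \[start, end\].
#' @export
new_moon_epochs <- function(start, end) {
  start <- as_utc(start); end <- as_utc(end)
  if (!(start < end)) stopf("new_moon_epochs: start must precede end")
  check_ephemeris_range(c(start, end))
  grid <- seq(start, end, by = 3600)
  if (grid[length(grid)] < end) grid <- c(grid, end)
  e <- elongation_signed(grid)
  cross <- which(e[-length(e)] < 0 & e[-1] >= 0)
  refine <- function(lo, hi) {
    for (i in 1:16) {   # 3600 s / 2^16 < 0.1 s
      mid <- lo + (hi - lo) / 2
      if (elongation_signed(mid) < 0) lo <- mid else hi <- mid
    }
    lo + (hi - lo) / 2
  }
  out <- vapply(cross, function(i) as.numeric(refine(grid[i], grid[i + 1])),
                numeric(1))
  as.POSIXct(out, origin = "1970-01-01", tz = "UTC")
}

#' Count the lunar cycles sampled by a monitoring window
#'
#' Returns the number of new-moon epochs inside the window, i.e. the number
#' of consecutive synodic cycles commencing during monitoring. (The number
#' of *complete* new-moon-to-new-moon intervals is one less; the epochs
#' themselves are available from [new_moon_epochs()].)
#'
#' @inheritParams new_moon_epochs
#' @return Integer count of cycles.
#' @export
count_lunar_cycles <- function(start, end) {
  length(new_moon_epochs(start, end))
}

#' Map synodic phase fractions to 12 equal intervals
#'
#' Bin `k` covers fractions in `[(k-1)/12, k/12)`, so the consecutive bin
#' pairs 12--1, 3--4, 6--7 and 9--10 are centered on the new moon, first
#' quarter, full moon and third quarter, and are labelled `NM`, `1Q`, `FM`,
#' `3Q` (other bins: `none`). The "last quartile" window of the moon wood
#' theory (third quarter to new moon) is phase in \[0.75, 1.0), i.e. bins
#' 10--12.
#'
#' @param phase_fraction numeric in \[0, 1).
#' @param n_bins number of equal intervals (12 for the principal-phase
#'   labelling).
#' @return Data frame with columns `bin` (integer) and `label` (character).
#' @export
phase_bins <- function(phase_fraction, n_bins = 12) {
  if (any(phase_fraction < 0 | phase_fraction >= 1, na.rm = TRUE))
    stopf("phase fractions must lie in [0, 1)")
  bin <- pmin(floor(phase_fraction * n_bins) + 1L, n_bins)
  label <- rep("none", length(bin))
  if (n_bins == 12) {
    label[bin %in% c(12L, 1L)] <- "NM"
    label[bin %in% c(3L, 4L)] <- "1Q"
    label[bin %in% c(6L, 7L)] <- "FM"
    label[bin %in% c(9L, 10L)] <- "3Q"
  }
  data.frame(bin = bin, label = label)
}

#' Hourly lunar series: phase fraction, bin and principal-phase label
#'
#' @param timestamps hourly POSIXct (UTC).
#' @return Object of class `lunar_series`: data frame with `timestamp`,
#'   `phase_fraction`, `bin`, `label`.
#' @export
lunar_series <- function(timestamps) {
  t <- as_utc(timestamps)
  frac <- synodic_phase(t)
  b <- phase_bins(frac)
  structure(data.frame(timestamp = t, phase_fraction = frac,
                       bin = b$bin, label = b$label),
            class = c("lunar_series", "data.frame"))
}

#' @export
print.lunar_series <- function(x, ...) {
  cat(sprintf("<lunar_series> %d hourly steps, %s .. %s\n", nrow(x),
              format(x$timestamp[1]), format(x$timestamp[nrow(x)])))
  invisible(x)
}
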