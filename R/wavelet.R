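# Continuous wavelet transform (Torrence & Compo formulation) with Morlet,
# Paul and derivative-of-Gaussian mothers, geometric period grids, global
# spectra and Monte-Carlo white-noise significance.

#' Define a mother wavelet
#'
#' Supported families and non-dimensional parameters:
#' * `morlet` -- plane wave modulated by a Gaussian; `param` is the
#'   wavenumber `k0` (default 6). Values below 4 violate the zero-mean
#'   (admissibility) approximation and are rejected.
#' * `paul` -- order `m` (positive integer).
#' * `dog` -- `m`-th derivative of a Gaussian (positive integer; `m = 2` is
#'   the Mexican hat).
#'
#' The Fourier factor converts scale to equivalent Fourier period:
#' `4*pi/(k0 + sqrt(2 + k0^2))` (Morlet), `4*pi/(2m + 1)` (Paul),
#' `2*pi/sqrt(m + 1/2)` (DOG).
#'
#' @param family `"morlet"`, `"paul"` or `"dog"`.
#' @param param non-dimensional parameter (see above).
#' @return Object of class `mother_wavelet` with fields `family`, `param`,
#'   `fourier_factor` and the cone-of-influence e-folding coefficient.
#' @export
mother_wavelet <- function(family = c("morlet", "paul", "dog"), param = NULL) {
  family <- match.arg(tolower(family[1]), c("morlet", "paul", "dog"))
  param <- param %||% switch(family, morlet = 6, paul = 4, dog = 2)
  if (family == "morlet") {
    if (param < 4)
      stopf("inadmissible mother wavelet: Morlet k0 = %g < 4", param)
    ff <- 4 * pi / (param + sqrt(2 + param^2))
    efold <- sqrt(2)
  } else if (family == "paul") {
    if (param < 1 || param != round(param))
      stopf("inadmissible mother wavelet: Paul order must be a positive integer")
    ff <- 4 * pi / (2 * param + 1)
    efold <- 1 / sqrt(2)
  } else {
    if (param < 1 || param != round(param))
      stopf("inadmissible mother wavelet: DOG order must be a positive integer")
    ff <- 2 * pi / sqrt(param + 0.5)
    efold <- sqrt(2)
  }
  structure(list(family = family, param = param, fourier_factor = ff,
                 efold = efold),
            class = "mother_wavelet")
}

#' @export
print.mother_wavelet <- function(x, ...) {
  cat(sprintf("<mother_wavelet> %s, param %g, fourier factor %.4f\n",
              x$family, x$param, x$fourier_factor))
  invisible(x)
}

# Fourier transform of the (unit-energy, unscaled) mother at s*omega.
psi_hat <- function(mother, w) {
  if (mother$family == "morlet") {
    out <- pi^(-1/4) * exp(-(w - mother$param)^2 / 2)
    out[w <= 0] <- 0
    as.complex(out)
  } else if (mother$family == "paul") {
    m <- mother$param
    out <- 2^m / sqrt(m * factorial(2 * m - 1)) * w^m * exp(-w)
    out[w <= 0] <- 0
    as.complex(out)
  } else {
    m <- mother$param
    -(1i^m) / sqrt(gamma(m + 0.5)) * as.complex(w)^m * exp(-w^2 / 2)
  }
}

#' Standardize a series to zero mean and unit variance
#'
#' Wavelet powers of different variables are only comparable after each
#' series is centred and scaled.
#'
#' @param x numeric series with positive variance (no missing values).
#' @return `(x - mean(x)) / sd(x)`.
#' @export
standardize <- function(x) {
  if (anyNA(x)) stopf("standardize: series contains missing values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stopf("constant series: wavelet power undefined for zero variance")
  (x - mean(x)) / s
}

#' Geometric period grid for the wavelet transform
#'
#' Periods `p_j = min_period * 2^(j / suboctaves)` for `j = 0, 1, ...`,
#' keeping `p_j <= max_period`. The defaults (8 h to 1.9 years = 16,962 h
#' at 20 sub-octaves) give a 222-period grid spanning sub-daily through
#' supra-annual oscillations; pass an explicit vector to [cwt()] to use any
#' other grid.
#'
#' @param min_period smallest period, hours.
#' @param max_period largest period, hours.
#' @param suboctaves grid points per octave (period doubling).
#' @return Strictly increasing numeric vector of periods (hours).
#' @export
build_period_grid <- function(min_period = 8, max_period = 16962,
                              suboctaves = 20) {
  if (!(min_period < max_period)) stopf("min_period must be below max_period")
  J <- floor(suboctaves * log2(max_period / min_period) + 1e-9)
  min_period * 2^((0:J) / suboctaves)
}

#' Continuous wavelet transform of a standardized series
#'
#' FFT-based convolution of the series with scaled, translated mother
#' wavelets, one scale per requested period (`scale = period /
#' fourier_factor`), with the usual unit-energy normalisation so that power
#' is comparable across scales. The series is zero-padded to the next power
#' of two before transforming; the padding is removed from the output.
#' Power is the squared modulus of the coefficients. The cone of influence
#' (largest trustworthy period per timestep, from the wavelet's e-folding
#' time) is returned but not applied as a mask.
#'
#' @param x numeric series (gap-free; typically already [standardize()]d).
#' @param periods period grid in hours (see [build_period_grid()]).
#' @param mother a [mother_wavelet()].
#' @param dt sampling step in hours (1 for hourly data).
#' @param timestamps optional POSIXct axis stored alongside.
#' @return Object of class `wavelet_spectrum`: list with `periods`, `times`,
#'   `power` (periods x time), `global_power`, `coi`, `mother`.
#' @export
cwt <- function(x, periods = build_period_grid(), mother = mother_wavelet("morlet", 6),
                dt = 1, timestamps = NULL) {
  if (anyNA(x)) stopf("cwt requires a gap-free series")
  n <- length(x)
  if (n * dt < 3 * min(periods))
    stopf("series (%g h) shorter than 3x the smallest period (%g h)",
          n * dt, min(periods))
  if (is.unsorted(periods, strictly = TRUE))
    stopf("periods must be strictly increasing")
  npad <- 2^ceiling(log2(n))
  xpad <- c(x, rep(0, npad - n))
  xhat <- stats::fft(xpad)
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, k, k - npad) * (2 * pi / (npad * dt))
  scales <- periods / mother$fourier_factor
  power <- matrix(NA_real_, nrow = length(periods), ncol = n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    daughter <- Conj(psi_hat(mother, s * omega)) * sqrt(2 * pi * s / dt)
    w <- stats::fft(xhat * daughter, inverse = TRUE) / npad
    power[j, ] <- Mod(w[seq_len(n)])^2
  }
  d <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  coi <- mother$fourier_factor * d / mother$efold
  structure(list(periods = periods,
                 times = timestamps %||% seq_len(n),
                 power = power,
                 global_power = rowMeans(power),
                 coi = coi,
                 mother = mother, dt = dt),
            class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> %d periods (%.3g..%.3g h) x %d timesteps, %s(%g)%s\n",
              length(x$periods), min(x$periods), max(x$periods),
              ncol(x$power), x$mother$family, x$mother$param,
              if (!is.null(x$pvalues)) ", with p-values" else ""))
  invisible(x)
}

#' Monte-Carlo significance of wavelet power against a white-noise null
#'
#' Pointwise p-values: the fraction of `n_sim` standardized Gaussian
#' white-noise surrogates of the same length whose power at a given
#' period/time cell exceeds the observed power. Cells with `p <= 0.05`
#' carry significant power at the 5% level.
#'
#' @param spectrum a [cwt()] result.
#' @param n_sim number of surrogate series (default 100; below 20 the
#'   p-value resolution is coarser than 0.05 and a warning is emitted).
#' @param seed optional integer seed for the surrogate stream.
#' @return The spectrum with added `pvalues` matrix and logical
#'   `significant` matrix (`p <= 0.05`).
#' @export
significance <- function(spectrum, n_sim = 100, seed = NULL) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  if (n_sim < 20)
    warnf("n_sim = %d gives p-value resolution coarser than 0.05", n_sim)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(spectrum$power)
  exceed <- matrix(0L, nrow = nrow(spectrum$power), ncol = n)
  for (i in seq_len(n_sim)) {
    surr <- standardize(stats::rnorm(n))
    ps <- cwt(surr, periods = spectrum$periods, mother = spectrum$mother,
              dt = spectrum$dt)
    exceed <- exceed + (ps$power >= spectrum$power)
  }
  spectrum$pvalues <- exceed / n_sim
  spectrum$significant <- spectrum$pvalues <= 0.05
  spectrum
}

#' Global and display-normalized wavelet power
#'
#' The global spectrum is the time-average of power at each period; the
#' display power is the full matrix divided by its maximum, giving the 0--1
#' scale used for heatmap comparison across species and variables.
#'
#' @param spectrum a [cwt()] result.
#' @return List with `global_power` (per period) and `display_power`
#'   (matrix in \[0, 1\], maximum exactly 1).
#' @export
global_and_normalized <- function(spectrum) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  list(global_power = rowMeans(spectrum$power),
       display_power = spectrum$power / max(spectrum$power))
}
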