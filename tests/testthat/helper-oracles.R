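# Independent oracles used across the suite.

# --- Meeus lunation-number polynomial for new/full moon instants ----------
# A different algorithmic route than the package's elongation-based
# ephemeris: mean phase time by lunation number k plus periodic corrections.
meeus_phase_jde <- function(k, phase = c("new", "full")) {
  phase <- match.arg(phase)
  if (phase == "full") k <- k + 0.5
  T <- k / 1236.85
  d2r <- pi / 180
  JDE <- 2451550.09766 + 29.530588861 * k + 0.00015437 * T^2 -
    0.000000150 * T^3 + 0.00000000073 * T^4
  E <- 1 - 0.002516 * T - 0.0000074 * T^2
  M <- (2.5534 + 29.10535670 * k - 0.0000014 * T^2 - 0.00000011 * T^3) * d2r
  Mp <- (201.5643 + 385.81693528 * k + 0.0107582 * T^2 + 0.00001238 * T^3 -
           0.000000058 * T^4) * d2r
  F <- (160.7108 + 390.67050284 * k - 0.0016118 * T^2 - 0.00000227 * T^3 +
          0.000000011 * T^4) * d2r
  Om <- (124.7746 - 1.56375588 * k + 0.0020672 * T^2 + 0.00000215 * T^3) * d2r
  if (phase == "new") {
    corr <- -0.40720 * sin(Mp) + 0.17241 * E * sin(M) + 0.01608 * sin(2 * Mp) +
      0.01039 * sin(2 * F) + 0.00739 * E * sin(Mp - M) -
      0.00514 * E * sin(Mp + M) + 0.00208 * E^2 * sin(2 * M) -
      0.00111 * sin(Mp - 2 * F) - 0.00057 * sin(Mp + 2 * F) +
      0.00056 * E * sin(2 * Mp + M) - 0.00042 * sin(3 * Mp) +
      0.00042 * E * sin(M + 2 * F) + 0.00038 * E * sin(M - 2 * F) -
      0.00024 * E * sin(2 * Mp - M) - 0.00017 * sin(Om) -
      0.00007 * sin(Mp + 2 * M)
  } else {
    corr <- -0.40614 * sin(Mp) + 0.17302 * E * sin(M) + 0.01614 * sin(2 * Mp) +
      0.01043 * sin(2 * F) + 0.00734 * E * sin(Mp - M) -
      0.00515 * E * sin(Mp + M) + 0.00209 * E^2 * sin(2 * M) -
      0.00111 * sin(Mp - 2 * F) - 0.00057 * sin(Mp + 2 * F) +
      0.00056 * E * sin(2 * Mp + M) - 0.00042 * sin(3 * Mp) +
      0.00042 * E * sin(M + 2 * F) + 0.00038 * E * sin(M - 2 * F) -
      0.00024 * E * sin(2 * Mp - M) - 0.00017 * sin(Om) -
      0.00007 * sin(Mp + 2 * M)
  }
  JDE + corr
}

meeus_phase_time <- function(k, phase = "new") {
  as.POSIXct((meeus_phase_jde(k, phase) - 2440587.5) * 86400,
             origin = "1970-01-01", tz = "UTC")
}

# lunation numbers whose new moons fall in 2015-2020
K_WINDOW <- 186:259

# --- brute-force zero-growth partition ------------------------------------
partition_brute <- function(radius) {
  n <- length(radius)
  rmax <- twd <- gro <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    past <- radius[seq_len(t)]
    if (all(is.na(past))) next
    rmax[t] <- max(past, na.rm = TRUE)
    if (!is.na(radius[t])) {
      twd[t] <- rmax[t] - radius[t]
      prev <- if (t > 1 && any(!is.na(radius[seq_len(t - 1)])))
        max(radius[seq_len(t - 1)], na.rm = TRUE) else NA
      gro[t] <- if (is.na(prev)) 0 else max(0, radius[t] - prev)
    }
  }
  list(rmax = rmax, twd = twd, gro = gro)
}

# --- direct O(N^2) time-domain wavelet convolution ------------------------
# Convolves the zero-padded series with the periodized time-domain mother
# (the FFT route is circular over the padded array), entirely without FFTs.
cwt_direct_power <- function(x, periods, family = "morlet", param = 6, dt = 1) {
  mother <- dendrocycles::mother_wavelet(family, param)
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x, rep(0, npad - n))
  m <- seq_len(npad)
  psi0 <- function(eta) {
    if (family == "morlet") {
      pi^(-1 / 4) * exp(1i * param * eta) * exp(-eta^2 / 2)
    } else if (family == "dog" && param == 2) {
      (1 - eta^2) * exp(-eta^2 / 2) / sqrt(gamma(2.5)) + 0i
    } else stop("oracle supports morlet and dog(2) only")
  }
  out <- matrix(0, length(periods), n)
  for (j in seq_along(periods)) {
    s <- periods[j] / mother$fourier_factor
    for (t in seq_len(n)) {
      d <- ((m - t + npad / 2) %% npad) - npad / 2
      w <- 0 + 0i
      for (k in -2:2)
        w <- w + sum(xp * sqrt(dt / s) * Conj(psi0((d + k * npad) * dt / s)))
      out[j, t] <- Mod(w)^2
    }
  }
  out
}
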