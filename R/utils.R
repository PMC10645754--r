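#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce timestamps to hourly UTC POSIXct
#'
#' @param x character, Date or POSIXct timestamps.
#' @param tz time zone the input clock times are expressed in; output is
#'   always UTC.
#' @return POSIXct vector in UTC.
#' @keywords internal
as_utc <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  out <- rep(as.POSIXct(NA), length(x))
  fmts <- c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M", "%Y-%m-%d %H", "%Y-%m-%d")
  todo <- !is.na(x)
  for (f in fmts) {
    if (!any(todo)) break
    parsed <- as.POSIXct(x[todo], tz = tz, format = f)
    ok <- !is.na(parsed)
    out[which(todo)[ok]] <- parsed[ok]
    todo[todo] <- !ok
  }
  attr(out, "tzone") <- "UTC"
  out
}

#' Regular hourly time axis spanning two instants
#' @keywords internal
hourly_axis <- function(start, end) {
  start <- as_utc(start); end <- as_utc(end)
  seq(from = floor_hour(start), to = floor_hour(end), by = 3600)
}

floor_hour <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 3600) * 3600,
             origin = "1970-01-01", tz = "UTC")
}

is_hourly <- function(t, tol = 1e-6) {
  if (length(t) < 2) return(TRUE)
  d <- diff(as.numeric(t))
  all(abs(d - 3600) < tol)
}

#' Centered moving average with NA-tolerant edges
#' @keywords internal
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  n <- length(x)
  cs <- cumsum(ifelse(is.na(x), 0, x))
  cn <- cumsum(!is.na(x))
  half <- floor(width / 2)
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  s <- cs[hi] - ifelse(lo > 1, cs[lo - 1], 0)
  k <- cn[hi] - ifelse(lo > 1, cn[lo - 1], 0)
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Exponential moving average (one-sided, recursive)
#' @keywords internal
ema <- function(x, alpha) {
  x0 <- ifelse(is.na(x), 0, x)
  as.numeric(stats::filter((1 - alpha) * x0, alpha, method = "recursive"))
}

#' Lag-1 autocorrelation of a series, NA-tolerant
#' @keywords internal
ar1_coef <- function(x) {
  x1 <- x[-length(x)]; x2 <- x[-1]
  ok <- !is.na(x1) & !is.na(x2)
  if (sum(ok) < 3) return(0)
  r <- suppressWarnings(stats::cor(x1[ok], x2[ok]))
  if (!is.finite(r)) 0 else max(min(r, 0.999), -0.999)
}

#' Effective sample size under an AR(1) dependence model
#'
#' n_eff = n (1 - rho) / (1 + rho); rho is clipped to \[0, 0.999\] because a
#' negative lag-1 autocorrelation should not inflate the sample size.
#' @keywords internal
ess_ar1 <- function(n, rho) {
  rho <- max(min(rho, 0.999), 0)
  max(n * (1 - rho) / (1 + rho), 2)
}

#' Derive a reproducible substream seed from a root seed and a label
#'
#' Keeps every derived seed inside the 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) %% 2^20) * 1009 + h * 7919) %% 2147483647L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
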