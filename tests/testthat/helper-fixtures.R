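# Shared fixtures: small in-code CSV builders and a memoized cache for the
# expensive scaled synthetic runs used by the acceptance checks.

write_dendro_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

hourly_ts <- function(start, n) {
  seq(as.POSIXct(start, tz = "UTC"), by = 3600, length.out = n)
}

# one cache per test session; acceptance blocks share the heavy runs
.acc_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .acc_cache)) assign(key, expr, envir = .acc_cache)
  get(key, envir = .acc_cache)
}

# a scaled-down lunar-null world used for calibration: six species, three
# years, 1-y-topped period grid at 12 suboctaves
null_world_run <- function(seed) {
  cfg <- dendrocycles::run_config(
    synthetic = list(profile = "paper_scale", n_years = 3),
    min_period = 8, max_period = 8766, suboctaves = 12, seed = seed)
  dendrocycles::run_pipeline(cfg)
}
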