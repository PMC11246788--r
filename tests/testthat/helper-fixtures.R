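# fixtures built in code: hourly temperature series and daily GCC curves

# hourly series where every hour of day i carries daily_means[i]
make_hourly_series <- function(daily_means, year = 2020, start_doy = 100,
                               plot_id = "plot") {
  doys <- start_doy + seq_along(daily_means) - 1
  grid <- expand.grid(hour = 0:23, doy = doys)
  ts <- ISOdatetime(year, 1, 1, grid$hour, 0, 0, tz = "UTC") +
    (grid$doy - 1) * 86400
  tibble::tibble(plot_id = plot_id, timestamp = ts,
                 temp_c = rep(daily_means, each = 24))
}

# random hourly series over n_days (for oracle comparisons)
make_random_hourly_series <- function(n_days = 10, year = 2020,
                                      start_doy = 150, seed = 1) {
  set.seed(seed)
  doys <- start_doy + 0:(n_days - 1)
  grid <- expand.grid(hour = 0:23, doy = doys)
  ts <- ISOdatetime(year, 1, 1, grid$hour, 0, 0, tz = "UTC") +
    (grid$doy - 1) * 86400
  tibble::tibble(plot_id = "rand", timestamp = ts,
                 temp_c = rnorm(nrow(grid), 5, 4))
}

# symmetric triangular daily GCC curve
make_triangle_gcc <- function(peak_doy = 200, half_width = 30,
                              baseline = 1 / 3, peak = 0.44) {
  doy <- (peak_doy - half_width - 5):(peak_doy + half_width + 5)
  frac <- pmax(1 - abs(doy - peak_doy) / half_width, 0)
  tibble::tibble(doy = doy, gcc = baseline + frac * (peak - baseline))
}

# per-image GCC records, n_per_day images per day at hours 10..(10+n-1)
make_gcc_records <- function(daily_gcc, n_per_day = 1, year = 2020,
                             start_doy = 180, jitter_sd = 0, seed = 1) {
  set.seed(seed)
  doys <- start_doy + seq_along(daily_gcc) - 1
  grid <- expand.grid(hour = 10 + 0:(n_per_day - 1), doy = doys)
  ts <- ISOdatetime(year, 1, 1, grid$hour, 0, 0, tz = "UTC") +
    (grid$doy - 1) * 86400
  tibble::tibble(timestamp = ts,
                 gcc = rep(daily_gcc, each = n_per_day) +
                   rnorm(nrow(grid), 0, jitter_sd))
}

# hand-rolled linearly interpolated percentile (independent of quantile())
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# clean image-record batch passing every QC rule
make_clean_records <- function(n = 20, gcc = 0.4, year = 2020,
                               start_doy = 180) {
  doys <- start_doy + (seq_len(n) - 1) %/% 8
  hours <- 10 + (seq_len(n) - 1) %% 8
  ts <- ISOdatetime(year, 1, 1, hours, 0, 0, tz = "UTC") + (doys - 1) * 86400
  total <- 0.9
  tibble::tibble(
    filename = sprintf("img_%03d.png", seq_len(n)),
    timestamp = ts,
    exposure_time_s = 10,
    exposure_ratio = 5,
    r = (1 - gcc) * total / 2,
    g = gcc * total,
    b = (1 - gcc) * total / 2
  )
}
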