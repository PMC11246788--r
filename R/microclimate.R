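#' Read an hourly soil-temperature log
#'
#' Reads a CSV with columns `timestamp` (ISO-8601) and `temp_c` and returns
#' a temperature series tibble with columns `plot_id`, `timestamp`, `temp_c`.
#' Timestamps must be strictly increasing.
#'
#' @param path Path to the CSV file.
#' @param plot_id Identifier attached to every row; defaults to the file
#'   name without the extension.
#' @param tz Time zone used to parse timestamps (default `"UTC"`; field
#'   loggers record local clock time, treated as a fixed offset).
#' @return A tibble with columns `plot_id`, `timestamp` (POSIXct), `temp_c`.
#' @seealso [detect_snowmelt_day()], [compute_gdd()]
#' @export
read_soil_temperature <- function(path, plot_id = NULL, tz = "UTC") {
  plot_id <- plot_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_character(),
    temp_c = readr::col_double()
  ))
  out <- tibble::tibble(
    plot_id = plot_id,
    timestamp = as.POSIXct(raw$timestamp, tz = tz,
                           tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                          "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")),
    temp_c = raw$temp_c
  )
  validate_temperature_series(out)
  out
}

validate_temperature_series <- function(series) {
  stopifnot(all(c("plot_id", "timestamp", "temp_c") %in% names(series)))
  if (nrow(series) == 0) stop("temperature series is empty", call. = FALSE)
  dt <- diff(as.numeric(series$timestamp))
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  invisible(series)
}

#' Daily mean soil temperature with gap interpolation
#'
#' Collapses an hourly series to daily means. Days with fewer than
#' `min_frac_hours` of the expected 24 hourly records are treated as gaps
#' and their means are linearly interpolated from the nearest complete
#' days; interpolated days are flagged.
#'
#' @param series A temperature series tibble (see [read_soil_temperature()]).
#' @param min_frac_hours Minimum fraction of the 24 hourly records a day
#'   needs before its own mean is trusted (default 0.75).
#' @return A tibble with columns `date`, `doy`, `mean_temp_c`, `n_hours`,
#'   `interpolated`.
#' @export
daily_mean_temperature <- function(series, min_frac_hours = 0.75) {
  validate_temperature_series(series)
  df <- tibble::tibble(
    date = as.Date(series$timestamp, tz = attr(series$timestamp, "tzone") %||% "UTC"),
    temp_c = series$temp_c
  )
  daily <- df |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(mean_temp_c = mean(.data$temp_c), n_hours = dplyr::n(),
                     .groups = "drop")
  daily$doy <- as.integer(strftime(daily$date, "%j"))
  daily$interpolated <- daily$n_hours < min_frac_hours * 24
  if (any(daily$interpolated)) {
    ok <- !daily$interpolated
    if (sum(ok) < 2) stop("too few complete days to interpolate gaps", call. = FALSE)
    t_num <- as.numeric(daily$date)
    daily$mean_temp_c[daily$interpolated] <-
      approx(t_num[ok], daily$mean_temp_c[ok], xout = t_num[daily$interpolated],
             rule = 2)$y
  }
  daily[, c("date", "doy", "mean_temp_c", "n_hours", "interpolated")]
}

#' Detect the day of snowmelt (DOSM) from soil temperature
#'
#' Under an insulating snowpack, soil temperature hovers near 0 degrees C;
#' once snow melts the soil warms rapidly. The plot is considered snow-free
#' on the first day whose daily mean temperature exceeds `threshold_c` and
#' stays above it for `persistence_days` consecutive days. The persistence
#' requirement (default one full day) guards against isolated warm spikes
#' recorded under a thinning snowpack.
#'
#' @param series A temperature series tibble.
#' @param threshold_c Snow-free temperature threshold in degrees C (default 2).
#' @param persistence_days Number of consecutive qualifying days required
#'   (default 1).
#' @return The day of year (integer) of snowmelt, or `NA_integer_` if no
#'   day qualifies (no-snowmelt signal).
#' @examples
#' s <- simulate_soil_temperature(
#'   site_spec("demo", melt_doy_by_year = c("2020" = 150)), 2020, seed = 1)
#' detect_snowmelt_day(s)
#' @export
detect_snowmelt_day <- function(series, threshold_c = 2, persistence_days = 1L) {
  stopifnot(persistence_days >= 1)
  daily <- daily_mean_temperature(series)
  above <- daily$mean_temp_c > threshold_c
  if (!any(above)) return(NA_integer_)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= persistence_days)
  if (length(hit) == 0) return(NA_integer_)
  daily$doy[starts[hit[1]]]
}

#' Cumulative growing degree days (GDD)
#'
#' Thermal sum of daily mean soil temperature above a base temperature,
#' accumulated from `start_doy` (normally the day of snowmelt). Daily means
#' are computed from the hourly record; negative excursions below the base
#' do not subtract (the daily contribution is `max(mean - base, 0)`).
#'
#' @param series A temperature series tibble.
#' @param start_doy First day of year included in the sum; typically the
#'   DOSM from [detect_snowmelt_day()].
#' @param base_c Base temperature in degrees C (default 0, which retains
#'   the growth responses of snowbed species at low temperature).
#' @param include_pre_melt Also emit rows for logged days before
#'   `start_doy`, with negative `dfsm` and `gdd = 0` (default `FALSE`);
#'   useful for flagging observations dated before snowmelt.
#' @return A climate-alignment tibble with columns `date`, `doy`,
#'   `dfsm` (days from `start_doy`), `gdd` (nondecreasing).
#' @export
compute_gdd <- function(series, start_doy, base_c = 0,
                        include_pre_melt = FALSE) {
  daily <- daily_mean_temperature(series)
  if (start_doy < min(daily$doy) || start_doy > max(daily$doy)) {
    stop("start_doy ", start_doy, " outside the span of the series (",
         min(daily$doy), "-", max(daily$doy), ")", call. = FALSE)
  }
  if (include_pre_melt) {
    pre <- daily[daily$doy < start_doy, ]
    pre_tbl <- tibble::tibble(
      date = pre$date, doy = pre$doy,
      dfsm = pre$doy - as.integer(start_doy), gdd = 0)
  }
  post <- daily[daily$doy >= start_doy, ]
  out <- tibble::tibble(
    date = post$date,
    doy = post$doy,
    dfsm = post$doy - as.integer(start_doy),
    gdd = cumsum(pmax(post$mean_temp_c - base_c, 0))
  )
  if (include_pre_melt) out <- dplyr::bind_rows(pre_tbl, out)
  out
}

#' Summarize day of snowmelt across sites and years
#'
#' Produces the per-site mean DOSM (rounded to the nearest day), its
#' min-max range across years, the yearly values, and the mean of yearly
#' signed differences (late minus early site) when two sites are present.
#'
#' @param seasons A tibble with columns `site`, `year`, `dosm`.
#' @param late,early Site names identifying the late- and early-snowmelt
#'   sites for the between-site difference. If omitted and exactly two
#'   sites are present, the site with the larger mean DOSM is taken as late.
#' @return A list with elements `by_site` (site, mean_dosm, min_dosm,
#'   max_dosm, n_years), `yearly` (the input, site-ordered), and
#'   `mean_difference_days` (rounded mean of yearly late - early
#'   differences; `NA` when not two sites).
#' @export
summarize_dosm <- function(seasons, late = NULL, early = NULL) {
  stopifnot(all(c("site", "year", "dosm") %in% names(seasons)))
  if (nrow(seasons) == 0) stop("no snow seasons supplied", call. = FALSE)
  if (any(is.na(seasons$dosm))) stop("dosm contains missing values", call. = FALSE)
  by_site <- seasons |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      mean_dosm = round(mean(.data$dosm)),
      min_dosm = min(.data$dosm),
      max_dosm = max(.data$dosm),
      n_years = dplyr::n(),
      .groups = "drop"
    )
  sites <- unique(seasons$site)
  mean_diff <- NA_real_
  if (length(sites) == 2) {
    if (is.null(late) || is.null(early)) {
      ord <- by_site$site[order(by_site$mean_dosm, decreasing = TRUE)]
      late <- late %||% ord[1]
      early <- early %||% ord[2]
    }
    wide <- seasons |>
      dplyr::select("site", "year", "dosm") |>
      tidyr::pivot_wider(names_from = "site", values_from = "dosm")
    if (!all(c(late, early) %in% names(wide))) {
      stop("late/early site names not found in `seasons`", call. = FALSE)
    }
    diffs <- wide[[late]] - wide[[early]]
    diffs <- diffs[!is.na(diffs)]
    if (length(diffs) > 0) mean_diff <- round(mean(diffs))
  }
  list(by_site = by_site,
       yearly = dplyr::arrange(seasons, .data$site, .data$year),
       mean_difference_days = mean_diff)
}

#' Mean soil temperature over a window
#'
#' Arithmetic mean of the hourly values whose timestamps fall inside
#' `window`, reported to 0.1 degrees C (the resolution used for site
#' summaries).
#'
#' @param series A temperature series tibble.
#' @param window Length-2 vector (Date or POSIXct) giving the inclusive
#'   window; `NULL` averages the whole series.
#' @return Mean temperature in degrees C, rounded to one decimal.
#' @export
mean_soil_temperature <- function(series, window = NULL) {
  validate_temperature_series(series)
  x <- series$temp_c
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    lo <- as.POSIXct(window[1], tz = attr(series$timestamp, "tzone") %||% "UTC")
    hi <- as.POSIXct(window[2], tz = attr(series$timestamp, "tzone") %||% "UTC")
    keep <- series$timestamp >= lo & series$timestamp <= hi
    if (!any(keep)) stop("window contains no observations", call. = FALSE)
    x <- x[keep]
  }
  round(mean(x), 1)
}

#' Build a snow-season summary for one plot-year
#'
#' Convenience wrapper combining snowmelt detection, snow-cover duration
#' (days logged before the DOSM) and the snow-free mean soil temperature.
#'
#' @inheritParams detect_snowmelt_day
#' @param year Calendar year of the series (recorded in the output).
#' @return A one-row tibble: `plot_id`, `year`, `dosm`, `snow_cover_days`,
#'   `mean_soil_temp` (snow-free period).
#' @export
snow_season <- function(series, year, threshold_c = 2, persistence_days = 1L) {
  dosm <- detect_snowmelt_day(series, threshold_c, persistence_days)
  daily <- daily_mean_temperature(series)
  if (is.na(dosm)) {
    snow_days <- nrow(daily)
    mst <- NA_real_
  } else {
    snow_days <- sum(daily$doy < dosm)
    post <- series[as.integer(strftime(series$timestamp, "%j")) >= dosm, ]
    mst <- round(mean(post$temp_c), 1)
  }
  tibble::tibble(plot_id = series$plot_id[1], year = year, dosm = dosm,
                 snow_cover_days = snow_days, mean_soil_temp = mst)
}
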