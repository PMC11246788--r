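#' Green chromatic coordinate
#'
#' `GCC = G / (R + G + B)` of ROI-mean channel values: the fraction of
#' total brightness carried by the green band, a standard canopy greenness
#' index. Grey pixels (R = G = B) give exactly 1/3, and the index is
#' invariant to uniform brightness scaling.
#'
#' @param r,g,b Nonnegative channel means (vectors recycled to a common
#'   length).
#' @return Numeric vector of GCC values in (0, 1) for positive channels.
#' @examples
#' compute_gcc(30, 60, 10) # 0.6
#' @export
compute_gcc <- function(r, g, b) {
  if (any(r < 0 | g < 0 | b < 0)) {
    stop("negative channel values", call. = FALSE)
  }
  total <- r + g + b
  if (any(total == 0)) {
    stop("undefined GCC: R + G + B = 0 for ", sum(total == 0), " record(s)",
         call. = FALSE)
  }
  g / total
}

#' Channel means over a region of interest
#'
#' @param pixels An `H x W x 3` numeric array (RGB, any common scale).
#' @param mask Logical `H x W` matrix; `TRUE` marks pixels inside the ROI.
#'   `NULL` uses the full frame.
#' @return Named numeric vector `c(r =, g =, b =)` of channel-wise
#'   arithmetic means over ROI pixels.
#' @export
extract_roi_mean <- function(pixels, mask = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (is.null(mask)) {
    mask <- matrix(TRUE, dim(pixels)[1], dim(pixels)[2])
  }
  if (!all(dim(mask) == dim(pixels)[1:2])) {
    stop("ROI mask dimensions ", paste(dim(mask), collapse = "x"),
         " do not match image ", paste(dim(pixels)[1:2], collapse = "x"),
         call. = FALSE)
  }
  if (!any(mask)) stop("ROI mask selects no pixels", call. = FALSE)
  c(r = mean(pixels[, , 1][mask]),
    g = mean(pixels[, , 2][mask]),
    b = mean(pixels[, , 3][mask]))
}

#' Quality-control rules for phenocam images
#'
#' Thresholds for the image filters: long exposures (over-exposed or
#' night-time frames), low exposure ratios, acquisition outside the
#' 10:00-17:00 window, brightness outliers, and the snow/fog cluster.
#' The time-of-day rule has a lenient variant in which outside-window
#' frames are kept when their exposure time is short.
#'
#' @param max_exposure_s Maximum exposure time in seconds (default 50).
#' @param min_exposure_ratio Minimum camera-reported exposure ratio
#'   (default 2).
#' @param tod_start,tod_end Retained local acquisition window in hours
#'   (defaults 10 and 17, inclusive).
#' @param lenient_tod If `TRUE`, outside-window frames are kept when
#'   `exposure_time_s <= max_exposure_s` (default `FALSE`: hard window).
#' @param brightness_quantiles Length-2 band; images whose mean luminance
#'   falls outside these sample quantiles of the whole batch are dropped
#'   (default `c(0.025, 0.975)`; `NULL` disables).
#' @param cluster_filter Drop the non-vegetation (snow/fog: brighter,
#'   less green) group of a 2-means clustering of (luminance, GCC)
#'   (default `TRUE`).
#' @param cluster_luminance_margin Minimum relative luminance separation
#'   between the two clusters before the bright cluster is treated as
#'   snow/fog and dropped (fraction of median luminance, default 0.1).
#' @return A `qc_rules` list.
#' @export
qc_rules <- function(max_exposure_s = 50, min_exposure_ratio = 2,
                     tod_start = 10, tod_end = 17, lenient_tod = FALSE,
                     brightness_quantiles = c(0.025, 0.975),
                     cluster_filter = TRUE, cluster_luminance_margin = 0.1) {
  structure(list(max_exposure_s = max_exposure_s,
                 min_exposure_ratio = min_exposure_ratio,
                 tod_start = tod_start, tod_end = tod_end,
                 lenient_tod = lenient_tod,
                 brightness_quantiles = brightness_quantiles,
                 cluster_filter = cluster_filter,
                 cluster_luminance_margin = cluster_luminance_margin),
            class = "qc_rules")
}

#' Filter phenocam image records
#'
#' Applies the quality-control rules to a batch of image records. Each
#' rule is evaluated as an independent predicate per record (brightness
#' quantiles and the 2-means snow/fog clustering are computed once on the
#' whole input batch), so relaxing any single rule can only grow the
#' retained set. Every rejection is logged with the name of the rule that
#' fired first.
#'
#' @param records A tibble with columns `timestamp` (POSIXct), `r`, `g`,
#'   `b` (ROI channel means), `exposure_time_s`, `exposure_ratio`, and
#'   optionally `filename`.
#' @param rules A [qc_rules()] object.
#' @return A list with `retained` (records plus a `gcc` column),
#'   `rejections` (timestamp, filename, rule) and `n_input`. An empty
#'   retained set is allowed and signalled with a warning.
#' @export
qc_filter <- function(records, rules = qc_rules()) {
  needed <- c("timestamp", "r", "g", "b", "exposure_time_s", "exposure_ratio")
  stopifnot(all(needed %in% names(records)))
  n <- nrow(records)
  if (!("filename" %in% names(records))) records$filename <- NA_character_
  gcc <- compute_gcc(records$r, records$g, records$b)
  luminance <- (records$r + records$g + records$b) / 3
  hour <- as.numeric(format(records$timestamp, "%H")) +
    as.numeric(format(records$timestamp, "%M")) / 60

  fail <- rep(NA_character_, n)
  mark <- function(fail, bad, rule) {
    ifelse(is.na(fail) & bad, rule, fail)
  }
  fail <- mark(fail, records$exposure_time_s > rules$max_exposure_s, "exposure_time")
  fail <- mark(fail, records$exposure_ratio < rules$min_exposure_ratio, "exposure_ratio")
  outside <- hour < rules$tod_start | hour > rules$tod_end
  if (rules$lenient_tod) {
    outside <- outside & records$exposure_time_s > rules$max_exposure_s
  }
  fail <- mark(fail, outside, "time_of_day")
  if (!is.null(rules$brightness_quantiles)) {
    band <- quantile(luminance, rules$brightness_quantiles, names = FALSE)
    fail <- mark(fail, luminance < band[1] | luminance > band[2], "brightness")
  }
  if (isTRUE(rules$cluster_filter) && n >= 4 &&
      sd(luminance) > 0 && sd(gcc) > 0) {
    feats <- scale(cbind(luminance, gcc))
    init <- feats[c(which.min(luminance), which.max(luminance)), , drop = FALSE]
    if (sum(!duplicated(init)) == 2) {
      km <- kmeans(feats, centers = init)
      lum_by_cl <- tapply(luminance, km$cluster, mean)
      gcc_by_cl <- tapply(gcc, km$cluster, mean)
      bright <- which.max(lum_by_cl)
      sep <- diff(range(lum_by_cl)) > rules$cluster_luminance_margin * median(luminance)
      if (sep && gcc_by_cl[bright] < gcc_by_cl[-bright]) {
        fail <- mark(fail, km$cluster == bright, "cluster")
      }
    }
  }

  retained <- records[is.na(fail), , drop = FALSE]
  retained$gcc <- gcc[is.na(fail)]
  rejections <- tibble::tibble(
    timestamp = records$timestamp[!is.na(fail)],
    filename = records$filename[!is.na(fail)],
    rule = fail[!is.na(fail)]
  )
  if (nrow(retained) == 0) {
    warning("qc_filter retained no images", call. = FALSE)
  }
  list(retained = retained, rejections = rejections, n_input = n)
}

#' Moving-window percentile smoothing of a GCC series
#'
#' For each calendar day, takes the given percentile (default the 90th)
#' of all retained per-image GCC values whose timestamps fall in a
#' `window_days`-day window. The default anchoring is trailing (the
#' window ends on the day being smoothed), giving a causal filter;
#' centred anchoring is available. Percentiles use the linear
#' interpolation between order statistics (R's default quantile type 7).
#' With `window_days = 1` and `percentile = 100` the result is the daily
#' maximum series.
#'
#' @param records A tibble with columns `timestamp` and `gcc` (typically
#'   `qc_filter()$retained`).
#' @param window_days Width of the moving window in days (default 4).
#' @param percentile Percentile in (0, 100] (default 90).
#' @param anchor `"trailing"` (default) or `"centered"`.
#' @return A tibble with one row per day from the first to the last
#'   retained image: `date`, `doy`, `gcc_smoothed` (`NA` when the window
#'   holds no images), `n_images`.
#' @export
percentile_smooth <- function(records, window_days = 4L, percentile = 90,
                              anchor = c("trailing", "centered")) {
  stopifnot(all(c("timestamp", "gcc") %in% names(records)))
  stopifnot(window_days >= 1, percentile > 0, percentile <= 100)
  anchor <- match.arg(anchor)
  if (nrow(records) == 0) {
    return(tibble::tibble(date = as.Date(character()), doy = integer(),
                          gcc_smoothed = numeric(), n_images = integer()))
  }
  day <- as.Date(records$timestamp,
                 tz = attr(records$timestamp, "tzone") %||% "UTC")
  days <- seq(min(day), max(day), by = "day")
  offsets <- if (anchor == "trailing") {
    c(-(window_days - 1L), 0L)
  } else {
    h <- (window_days - 1L) / 2
    c(-floor(h), ceiling(h))
  }
  out <- lapply(days, function(d) {
    in_win <- day >= d + offsets[1] & day <= d + offsets[2]
    vals <- records$gcc[in_win]
    tibble::tibble(
      date = d,
      doy = as.integer(strftime(d, "%j")),
      gcc_smoothed = if (length(vals) == 0) NA_real_ else
        quantile(vals, percentile / 100, names = FALSE, type = 7),
      n_images = length(vals)
    )
  })
  dplyr::bind_rows(out)
}

#' Read phenocam image metadata and ROI masks
#'
#' `read_image_meta()` reads `image_meta.csv` (filename, timestamp,
#' exposure_time_s, exposure_ratio). `read_roi_mask()` reads a PNG mask
#' where any nonzero pixel is inside the ROI. `extract_roi_means()` runs
#' [extract_roi_mean()] over a directory of PNG images listed in the
#' metadata and returns the per-image record table ready for
#' [qc_filter()].
#'
#' @param path CSV or PNG path.
#' @param tz Time zone for parsing timestamps.
#' @return `read_image_meta()`: a tibble; `read_roi_mask()`: a logical
#'   matrix.
#' @export
read_image_meta <- function(path, tz = "UTC") {
  raw <- readr::read_csv(path, col_types = readr::cols(
    filename = readr::col_character(),
    timestamp = readr::col_character(),
    exposure_time_s = readr::col_double(),
    exposure_ratio = readr::col_double()
  ))
  raw$timestamp <- as.POSIXct(raw$timestamp, tz = tz,
                              tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                             "%Y-%m-%d %H:%M:%S",
                                             "%Y-%m-%dT%H:%M",
                                             "%Y-%m-%d %H:%M"))
  raw
}

#' @rdname read_image_meta
#' @export
read_roi_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' @rdname read_image_meta
#' @param image_dir Directory holding the PNG images named in the metadata.
#' @param meta Metadata tibble from [read_image_meta()].
#' @param mask Logical ROI mask (or `NULL` for full frame).
#' @export
extract_roi_means <- function(image_dir, meta, mask = NULL) {
  means <- lapply(meta$filename, function(f) {
    px <- png::readPNG(file.path(image_dir, f))
    if (length(dim(px)) == 3 && dim(px)[3] > 3) px <- px[, , 1:3]
    extract_roi_mean(px, mask)
  })
  m <- do.call(rbind, means)
  dplyr::bind_cols(meta, tibble::tibble(r = m[, "r"], g = m[, "g"], b = m[, "b"]))
}
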