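#' Partition a seasonal GCC series into phenological events
#'
#' Derives the five primary events of the greenness season from a smoothed
#' daily GCC series:
#'
#' * **POS** (peak of season): the day attaining the seasonal maximum
#'   GCC (earliest day on ties).
#' * **SPS / EPS** (start / end of the peak): first and last day on which
#'   the GCC lies within 95% of the seasonal maximum
#'   (`gcc >= 0.95 * gcc_max`).
#' * **SOS / EOS** (start / end of season): first and last day on which
#'   the GCC exceeds the pre-season baseline by `baseline_frac` of the
#'   seasonal amplitude, where the baseline is the median GCC of the
#'   first `n_baseline_days` days of the series (the snow-free soil
#'   floor, close to 1/3).
#'
#' A series that never falls back to the threshold after its maximum
#' (e.g. truncated before browning) yields `eos = NA` and is flagged
#' incomplete.
#'
#' @param daily A tibble with columns `doy` and a GCC column
#'   (`gcc_smoothed` or `gcc`); rows ordered by day, `NA` days allowed.
#' @param baseline_frac Fraction of the amplitude above baseline that
#'   defines SOS/EOS (default 0.1).
#' @param peak_frac Fraction of the maximum defining the SPS-EPS plateau
#'   (default 0.95).
#' @param n_baseline_days Days at the start of the series used for the
#'   baseline (default 5).
#' @return A one-row `season_metrics` tibble: `sos`, `sps`, `pos`, `eps`,
#'   `eos` (day-of-year integers), `gcc_max`, `baseline`,
#'   `season_length_days` (`eos - sos`), `complete`,
#'   `plateau_fragmented` (`TRUE` when the GCC dips below the 95% line
#'   between SPS and EPS).
#' @export
extract_season_metrics <- function(daily, baseline_frac = 0.1,
                                   peak_frac = 0.95, n_baseline_days = 5L) {
  gcc_col <- intersect(c("gcc_smoothed", "gcc"), names(daily))[1]
  if (is.na(gcc_col)) stop("no `gcc_smoothed` or `gcc` column", call. = FALSE)
  stopifnot("doy" %in% names(daily))
  df <- daily[!is.na(daily[[gcc_col]]), ]
  if (nrow(df) < n_baseline_days + 2) {
    stop("series too short to extract season metrics", call. = FALSE)
  }
  gcc <- df[[gcc_col]]
  doy <- df$doy
  gcc_max <- max(gcc)
  pos <- doy[which.max(gcc)] # which.max returns the earliest tie
  baseline <- median(head(gcc, n_baseline_days))
  thr_peak <- peak_frac * gcc_max
  thr_season <- baseline + baseline_frac * (gcc_max - baseline)

  in_peak <- gcc >= thr_peak
  sps <- doy[which(in_peak)[1]]
  eps <- doy[tail(which(in_peak), 1)]
  fragmented <- any(!in_peak[which(in_peak)[1]:tail(which(in_peak), 1)])

  in_season <- gcc >= thr_season
  sos <- doy[which(in_season)[1]]
  eos_idx <- tail(which(in_season), 1)
  # incomplete season: the series is still above threshold on its last day
  complete <- eos_idx < length(gcc)
  eos <- if (complete) doy[eos_idx] else NA_integer_

  tibble::tibble(
    sos = sos, sps = sps, pos = pos, eps = eps, eos = eos,
    gcc_max = gcc_max, baseline = baseline,
    season_length_days = if (complete) eos - sos else NA_integer_,
    complete = complete, plateau_fragmented = fragmented
  )
}

#' Within-site and between-site phenological intervals
#'
#' Computes the event intervals of one season-metrics record (green-up
#' length SOS to POS, plateau length SPS to EPS, season length SOS to
#' EOS) and, given a second record, the per-event day offsets
#' (`other` minus `metrics`).
#'
#' @param metrics A season-metrics row (see [extract_season_metrics()]),
#'   or any list with elements `sos`, `sps`, `pos`, `eps`, `eos`.
#' @param other Optional second record for between-site offsets.
#' @return A list with `within` (tibble: interval, days; `NA` for
#'   intervals involving missing events) and, when `other` is supplied,
#'   `between` (tibble: event, offset_days).
#' @examples
#' early <- list(sos = 176, sps = 190, pos = 197, eps = 220, eos = 265)
#' late <- list(sos = 197, sps = 208, pos = 215, eps = 235, eos = 268)
#' season_intervals(early, late)
#' @export
season_intervals <- function(metrics, other = NULL) {
  ev <- function(m, name) {
    v <- m[[name]]
    if (is.null(v) || length(v) == 0) NA_integer_ else as.integer(v)
  }
  events <- c("sos", "sps", "pos", "eps", "eos")
  m <- setNames(lapply(events, ev, m = metrics), events)
  within <- tibble::tibble(
    interval = c("sos_to_pos", "sps_to_eps", "sos_to_eos"),
    days = c(m$pos - m$sos, m$eps - m$sps, m$eos - m$sos)
  )
  out <- list(within = within)
  if (!is.null(other)) {
    o <- setNames(lapply(events, ev, m = other), events)
    out$between <- tibble::tibble(
      event = events,
      offset_days = unname(vapply(events, function(e) o[[e]] - m[[e]],
                                  integer(1)))
    )
  }
  out
}
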