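#' Phenological development rate (PDR)
#'
#' The PDR of one species in one plot and year is the slope of the
#' regression line of median phenophase on accumulated thermal time,
#' computed over the development window: from the first observation with
#' phenophase >= 9 (emergence) to the last observation with phenophase
#' < 59 (before completion of the cycle), endpoints inclusive. The
#' primary axis is GDD (BBCH units per degree-day); calendar days are
#' available as an alternative axis. By default the slope is the
#' ordinary least-squares fit over all in-window observations; a
#' two-point chord between the window endpoints is available and agrees
#' with OLS on two-point windows.
#'
#' @param series A tibble for one plot/species/year with columns
#'   `median_phase` and `gdd` (and `doy` when `axis = "day"`), ordered by
#'   date.
#' @param axis `"gdd"` (default) or `"day"`.
#' @param mode `"ols"` (default) or `"two_point"`.
#' @return A one-row tibble: `slope` (BBCH units per GDD or per day),
#'   `n_obs_in_window`, `window_start`, `window_end` (axis values of the
#'   window endpoints). `slope` is `NA` with a warning when fewer than
#'   two in-window observations exist or the axis is constant.
#' @examples
#' compute_pdr(tibble::tibble(gdd = c(0, 500), median_phase = c(9, 49)))
#' @export
compute_pdr <- function(series, axis = c("gdd", "day"),
                        mode = c("ols", "two_point")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  stopifnot("median_phase" %in% names(series))
  xcol <- if (axis == "gdd") "gdd" else "doy"
  stopifnot(xcol %in% names(series))
  phase <- series$median_phase
  i1 <- which(phase >= 9)[1]
  i2 <- tail(which(phase < 59), 1)
  undefined <- tibble::tibble(slope = NA_real_, n_obs_in_window = 0L,
                              window_start = NA_real_, window_end = NA_real_)
  if (is.na(i1) || length(i2) == 0 || i2 < i1) {
    warning("PDR undefined: no development window", call. = FALSE)
    return(undefined)
  }
  win <- series[i1:i2, ]
  win <- win[win$median_phase < 59, ] # completed records inside the window
  x <- win[[xcol]]
  y <- win$median_phase
  if (length(x) < 2 || var(x) == 0) {
    warning("PDR undefined: fewer than two distinct in-window observations",
            call. = FALSE)
    return(undefined)
  }
  slope <- if (mode == "two_point") {
    (y[length(y)] - y[1]) / (x[length(x)] - x[1])
  } else {
    cov(x, y) / var(x)
  }
  tibble::tibble(slope = slope, n_obs_in_window = length(x),
                 window_start = x[1], window_end = x[length(x)])
}

#' Aggregate PDR estimates to species/site means
#'
#' Mean (M) and sample standard deviation (SD) of plot-year PDR
#' estimates, one summary per species and site (every plot and all
#' monitored years weighted equally at the plot-year level).
#'
#' @param estimates A tibble with columns `species`, `site`, `slope`
#'   (typically one row per plot-year from [compute_pdr()]).
#' @return A tibble: `species`, `site`, `m`, `sd` (`NA` for singleton
#'   groups), `n`.
#' @export
aggregate_pdr <- function(estimates) {
  stopifnot(all(c("species", "site", "slope") %in% names(estimates)))
  est <- estimates[!is.na(estimates$slope), ]
  if (nrow(est) == 0) stop("no defined PDR estimates to aggregate", call. = FALSE)
  est |>
    dplyr::group_by(.data$species, .data$site) |>
    dplyr::summarise(m = mean(.data$slope),
                     sd = if (dplyr::n() >= 2) sd(.data$slope) else NA_real_,
                     n = dplyr::n(), .groups = "drop")
}

#' Compare PDR between sites
#'
#' Two-sided test of a site difference in PDR for each species. The
#' default is Welch's two-sample t-test on the plot-year estimates,
#' which tolerates the unequal plot numbers and variances of a
#' two-site design; a year-paired t-test on yearly site means is
#' offered as an alternative unit of replication.
#'
#' @param estimates A tibble with columns `species`, `site`, `slope` and,
#'   for the paired method, `year`.
#' @param method `"welch"` (default) or `"year_paired"`.
#' @return A tibble per species: per-site `m_<site>`, `sd_<site>`, `p`
#'   (two-sided), `stars` (at the .05/.01/.001 levels). Two groups with
#'   zero variance get `p = 1` when their means are equal and `p = 0`
#'   otherwise, by convention.
#' @export
compare_pdr_sites <- function(estimates, method = c("welch", "year_paired")) {
  method <- match.arg(method)
  stopifnot(all(c("species", "site", "slope") %in% names(estimates)))
  sites <- sort(unique(estimates$site))
  if (length(sites) != 2) stop("exactly two sites required", call. = FALSE)
  if (method == "year_paired" && !("year" %in% names(estimates))) {
    stop("year column required for the year-paired test", call. = FALSE)
  }
  est <- estimates[!is.na(estimates$slope), ]
  res <- lapply(split(est, est$species), function(d) {
    g1 <- d$slope[d$site == sites[1]]
    g2 <- d$slope[d$site == sites[2]]
    if (length(g1) < 2 || length(g2) < 2) {
      stop("need at least two estimates per site for species ",
           d$species[1], call. = FALSE)
    }
    p <- if (method == "welch") {
      if (sd(g1) == 0 && sd(g2) == 0) {
        if (isTRUE(all.equal(mean(g1), mean(g2)))) 1 else 0
      } else {
        t.test(g1, g2, var.equal = FALSE)$p.value
      }
    } else {
      ym <- d |>
        dplyr::group_by(.data$year, .data$site) |>
        dplyr::summarise(m = mean(.data$slope), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "site", values_from = "m")
      dd <- ym[[sites[1]]] - ym[[sites[2]]]
      dd <- dd[!is.na(dd)]
      if (length(dd) < 2) stop("too few paired years", call. = FALSE)
      if (sd(dd) == 0) {
        if (isTRUE(all.equal(mean(dd), 0))) 1 else 0
      } else {
        t.test(dd)$p.value
      }
    }
    tibble::tibble(
      species = d$species[1],
      m_1 = mean(g1), sd_1 = sd(g1), n_1 = length(g1),
      m_2 = mean(g2), sd_2 = sd(g2), n_2 = length(g2),
      p = p,
      stars = if (p < 0.001) "***" else if (p < 0.01) "**"
              else if (p < 0.05) "*" else ""
    )
  })
  out <- dplyr::bind_rows(res)
  names(out) <- sub("_1$", paste0("_", sites[1]), names(out))
  names(out) <- sub("_2$", paste0("_", sites[2]), names(out))
  out
}
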