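#' The snowbed-adapted BBCH phenophase scale
#'
#' Returns the ordinal BBCH scale adapted to snowbed plant communities:
#' six principal growth stages (germination/bud development, leaf
#' development, inflorescence emergence, flowering, fruit development,
#' dissemination) coded from 0 (plants not visible) to 59 (completely
#' senescent), with stage descriptions specific to annual (A), perennial
#' (P) and graminoid (G) morphotypes. Code 47 exists only for graminoids.
#'
#' @return A tibble with columns `code` (integer), `morphotype`
#'   (`"A"`, `"P"` or `"G"`) and `description`.
#' @examples
#' scale <- bbch_scale()
#' bbch_codes(scale)
#' @export
bbch_scale <- function() {
  path <- system.file("extdata", "bbch_scale.csv", package = "nivophen",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    code = readr::col_integer(),
    morphotype = readr::col_character(),
    description = readr::col_character()
  ))
}

#' Valid BBCH codes, optionally restricted to a morphotype
#'
#' @param scale The scale tibble from [bbch_scale()].
#' @param morphotype Optional morphotype (`"A"`, `"P"`, `"G"`); when given,
#'   only codes defined for that morphotype are returned.
#' @return Sorted integer vector of valid codes.
#' @export
bbch_codes <- function(scale = bbch_scale(), morphotype = NULL) {
  if (!is.null(morphotype)) {
    stopifnot(morphotype %in% c("A", "P", "G"))
    scale <- scale[scale$morphotype == morphotype, ]
  }
  sort(unique(scale$code))
}

#' Default species-to-morphotype mapping
#'
#' The five monitored snowbed species: *Euphrasia minima* is the only
#' annual (A), *Poa alpina* the only graminoid (G); *Salix herbacea*,
#' *Gnaphalium supinum* and *Veronica alpina* are perennials (P).
#'
#' @return Named character vector mapping species name to morphotype.
#' @export
species_morphotypes <- function() {
  c("Euphrasia minima" = "A",
    "Salix herbacea" = "P",
    "Gnaphalium supinum" = "P",
    "Veronica alpina" = "P",
    "Poa alpina" = "G")
}

#' Snap a continuous phase value to the nearest valid BBCH code
#'
#' Used by the synthetic generator and available for cleaning digitized
#' records. Distance is plain integer difference on the quasi-continuous
#' scale; ties go to the lower code.
#'
#' @param phase Numeric vector of phase values.
#' @param morphotype Morphotype restricting the admissible code set.
#' @param scale The scale tibble from [bbch_scale()].
#' @return Integer vector of valid codes.
#' @export
snap_to_bbch <- function(phase, morphotype = "P", scale = bbch_scale()) {
  codes <- bbch_codes(scale, morphotype)
  vapply(phase, function(p) {
    d <- abs(codes - p)
    codes[which.min(d)] # which.min takes the first (lower) code on ties
  }, integer(1))
}

#' Validate phenophase observations against the BBCH scale
#'
#' Checks that every recorded code is a member of the adapted scale and is
#' defined for the observed species' morphotype (e.g. code 47, "late
#' milk", exists only for graminoids).
#'
#' @param obs A tibble with at least columns `species` and `bbch`.
#' @param scale The scale tibble from [bbch_scale()].
#' @param morphotypes Named vector mapping species to morphotype
#'   (default [species_morphotypes()]).
#' @return The input tibble with a logical `valid` column and, for invalid
#'   rows, a `nearest_valid` column suggesting the closest admissible codes.
#' @export
validate_observations <- function(obs, scale = bbch_scale(),
                                  morphotypes = species_morphotypes()) {
  stopifnot(all(c("species", "bbch") %in% names(obs)))
  unknown <- setdiff(unique(obs$species), names(morphotypes))
  if (length(unknown) > 0) {
    stop("no morphotype mapping for species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mt <- unname(morphotypes[obs$species])
  valid <- mapply(function(code, m) code %in% bbch_codes(scale, m),
                  obs$bbch, mt)
  out <- obs
  out$valid <- as.logical(valid)
  out$nearest_valid <- NA_integer_
  if (any(!out$valid)) {
    bad <- which(!out$valid)
    out$nearest_valid[bad] <- mapply(function(code, m) {
      snap_to_bbch(code, m, scale)
    }, obs$bbch[bad], mt[bad])
  }
  out
}

#' Median phenophase across subplots
#'
#' The plot-level phenophase for one species and date is the sample median
#' of the subplot codes (in each subplot only the most advanced individual
#' is recorded). With an even number of subplots the median is the mean of
#' the two central codes and may fall between valid codes; it is kept as a
#' real number because downstream models treat the scale as
#' quasi-continuous.
#'
#' @param codes Numeric vector of subplot BBCH codes (one plot, species,
#'   date).
#' @return The median phase (numeric scalar).
#' @examples
#' median_phenophase(c(10, 11, 13, 19)) # 12
#' @export
median_phenophase <- function(codes) {
  if (length(codes) == 0) stop("no observations supplied", call. = FALSE)
  median(codes)
}

#' Aggregate subplot observations to plot-level median series
#'
#' @param obs A tibble with columns `site`, `plot`, `subplot`, `species`,
#'   `date`, `bbch`.
#' @return A tibble with one row per site/plot/species/date carrying
#'   `median_phase` and `n_subplots`.
#' @export
plot_median_series <- function(obs) {
  stopifnot(all(c("site", "plot", "species", "date", "bbch") %in% names(obs)))
  obs |>
    dplyr::group_by(.data$site, .data$plot, .data$species, .data$date) |>
    dplyr::summarise(median_phase = median_phenophase(.data$bbch),
                     n_subplots = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$site, .data$plot, .data$species, .data$date)
}

#' Align a plot-level phenophase series with climate covariates
#'
#' Joins each observation with the day-of-year (DOY), days-from-snowmelt
#' (DFSM) and growing-degree-day (GDD) values of its date and plot.
#' Observations dated before the plot's snowmelt get a negative DFSM and
#' are flagged `pre_melt`.
#'
#' @param series Plot-level median series (see [plot_median_series()]),
#'   needing columns `plot` and `date`.
#' @param climate A climate-alignment table as produced by [compute_gdd()],
#'   with an added `plot` column when several plots are stacked.
#' @return `series` with columns `doy`, `dfsm`, `gdd`, `pre_melt` appended.
#' @export
align_observations <- function(series, climate) {
  stopifnot(all(c("plot", "date") %in% names(series)))
  stopifnot(all(c("date", "doy", "dfsm", "gdd") %in% names(climate)))
  by <- if ("plot" %in% names(climate)) c("plot", "date") else "date"
  out <- dplyr::left_join(series, climate[, unique(c(by, "doy", "dfsm", "gdd"))],
                          by = by)
  miss <- is.na(out$gdd)
  if (any(miss)) {
    pre <- out[miss, ]
    stop("no climate coverage for ", sum(miss), " observation(s), e.g. plot ",
         pre$plot[1], " on ", pre$date[1], call. = FALSE)
  }
  out$pre_melt <- out$dfsm < 0
  out
}

#' Read / write phenophase observation tables
#'
#' `read_pheno_obs()` reads a CSV with columns `site`, `plot`, `subplot`,
#' `species`, `date`, `bbch`; `write_pheno_obs()` writes one.
#'
#' @param path CSV path.
#' @return `read_pheno_obs()`: a tibble of observations.
#' @export
read_pheno_obs <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    site = readr::col_character(),
    plot = readr::col_character(),
    subplot = readr::col_character(),
    species = readr::col_character(),
    date = readr::col_date(),
    bbch = readr::col_integer()
  ))
}

#' @rdname read_pheno_obs
#' @param obs Observation tibble to write.
#' @export
write_pheno_obs <- function(obs, path) {
  readr::write_csv(obs, path)
  invisible(path)
}
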