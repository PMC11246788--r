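#' Screen climate predictors for collinearity
#'
#' Pairwise Pearson correlations among the candidate predictors
#' day-of-year (DOY), days-from-snowmelt (DFSM) and growing degree days
#' (GDD). These are all time-dependent and typically highly collinear;
#' pairs with `|r|` above the threshold are flagged so that downstream
#' models are fitted with a single predictor at a time.
#'
#' @param alignment A tibble with columns `doy`, `dfsm`, `gdd`.
#' @param threshold Absolute correlation above which a pair is flagged
#'   (default 0.90).
#' @return A list: `correlations` (3x3 matrix, `NA` where a predictor is
#'   constant), `flagged` (tibble of flagged pairs), `constant`
#'   (character vector of degenerate predictors), `degenerate_n`
#'   (`TRUE` when fewer than 3 rows make every correlation trivially
#'   +/-1).
#' @export
screen_predictors <- function(alignment, threshold = 0.90) {
  vars <- c("doy", "dfsm", "gdd")
  stopifnot(all(vars %in% names(alignment)))
  x <- as.matrix(alignment[, vars])
  constant <- vars[apply(x, 2, function(v) var(v) == 0 || is.na(var(v)))]
  cm <- suppressWarnings(cor(x))
  cm[constant, ] <- NA_real_
  cm[, constant] <- NA_real_
  pairs <- utils::combn(vars, 2)
  flagged <- tibble::tibble(
    var1 = pairs[1, ], var2 = pairs[2, ],
    r = cm[cbind(pairs[1, ], pairs[2, ])]
  )
  flagged <- flagged[!is.na(flagged$r) & abs(flagged$r) > threshold, ]
  list(correlations = cm, flagged = flagged, constant = constant,
       degenerate_n = nrow(alignment) < 3)
}

#' Fit a penalized-spline phenophase model with random effects
#'
#' Models plot-level median phenophase as a smooth function of a single
#' climate predictor (GDD, DFSM or DOY), pooling years, with plot and
#' year random intercepts. The smooth is a penalized cubic regression
#' spline; random effects enter as penalized (ridge-equivalent) group
#' intercepts, and all smoothing/variance parameters are selected
#' jointly by restricted maximum likelihood. The BBCH response is
#' treated as quasi-continuous (Gaussian family).
#'
#' @param data A tibble with columns `median_phase`, the chosen predictor
#'   (`gdd`, `dfsm` or `doy`) and, for random effects, `plot` and/or
#'   `year`.
#' @param predictor One of `"gdd"`, `"dfsm"`, `"doy"`.
#' @param random_effects Subset of `c("plot", "year")`; terms whose
#'   column has a single level are dropped with a warning.
#' @param basis_dim Spline basis dimension `k` (default 8, matching the
#'   10-15 observation dates available per season).
#' @param method Smoothness selection criterion passed to [mgcv::gam()]
#'   (default `"REML"`).
#' @param ... Further arguments to [mgcv::gam()] (e.g. `sp` to fix the
#'   smoothing parameter).
#' @return A `pheno_smooth_fit` object: list with the fitted `gam`, the
#'   `predictor`, `random_effects` used, adjusted `r2`, conditional
#'   `aic` (on effective degrees of freedom), `edf` of the predictor
#'   smooth, the training predictor `range`, and a data `fingerprint`
#'   for comparison safety.
#' @export
fit_phenophase_smooth <- function(data, predictor = c("gdd", "dfsm", "doy"),
                                  random_effects = c("plot", "year"),
                                  basis_dim = 8, method = "REML", ...) {
  predictor <- match.arg(predictor)
  stopifnot("median_phase" %in% names(data), predictor %in% names(data))
  if (nrow(data) < basis_dim + 2) {
    stop("need at least basis_dim + 2 = ", basis_dim + 2, " observations",
         call. = FALSE)
  }
  if (var(data[[predictor]]) == 0) {
    stop("predictor `", predictor, "` is constant", call. = FALSE)
  }
  df <- as.data.frame(data)
  re_terms <- character(0)
  for (re in intersect(random_effects, c("plot", "year"))) {
    if (!(re %in% names(df))) next
    df[[re]] <- factor(df[[re]])
    if (nlevels(df[[re]]) < 2) {
      warning("random effect `", re, "` has a single level; dropped",
              call. = FALSE)
    } else {
      re_terms <- c(re_terms, sprintf("s(%s, bs = \"re\")", re))
    }
  }
  rhs <- c(sprintf("s(%s, bs = \"cr\", k = %d)", predictor, basis_dim), re_terms)
  fml <- stats::as.formula(paste("median_phase ~", paste(rhs, collapse = " + ")))
  fit <- mgcv::gam(fml, data = df, method = method, ...)
  sm <- summary(fit)
  structure(list(
    gam = fit,
    predictor = predictor,
    random_effects = sub("s\\((\\w+).*", "\\1", re_terms),
    r2 = sm$r.sq,
    aic = AIC(fit),
    edf = unname(sm$edf[1]),
    range = range(df[[predictor]]),
    n = nrow(df),
    fingerprint = c(n = nrow(df), response_sum = sum(df$median_phase))
  ), class = "pheno_smooth_fit")
}

#' @export
print.pheno_smooth_fit <- function(x, ...) {
  cat("Phenophase smooth fit\n")
  cat("  predictor:      ", x$predictor, " (edf ", round(x$edf, 2), ")\n", sep = "")
  cat("  random effects: ",
      if (length(x$random_effects)) paste(x$random_effects, collapse = ", ")
      else "none", "\n", sep = "")
  cat("  n = ", x$n, ", adj. R2 = ", round(x$r2, 3),
      ", AIC = ", round(x$aic, 2), "\n", sep = "")
  invisible(x)
}

#' Compare single-predictor phenophase models by AIC
#'
#' Tabulates adjusted R-squared and AIC for a set of fits of the same
#' response data and names the winning predictor (lowest AIC; ties broken
#' by the priority GDD over DFSM over DOY, the order of mechanistic
#' preference for thermal-sum drivers).
#'
#' @param fits A list of `pheno_smooth_fit` objects sharing the same
#'   response data (checked via the stored data fingerprint).
#' @return A list: `table` (tibble predictor, r2, aic, edf) and `winner`.
#' @export
compare_predictors <- function(fits) {
  stopifnot(length(fits) >= 2)
  lapply(fits, function(f) stopifnot(inherits(f, "pheno_smooth_fit")))
  fps <- lapply(fits, `[[`, "fingerprint")
  for (fp in fps[-1]) {
    if (!isTRUE(all.equal(fps[[1]], fp))) {
      stop("fits were not trained on the same response data", call. = FALSE)
    }
  }
  tab <- tibble::tibble(
    predictor = vapply(fits, `[[`, character(1), "predictor"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    edf = vapply(fits, `[[`, numeric(1), "edf")
  )
  priority <- c(gdd = 1, dfsm = 2, doy = 3)
  ord <- order(tab$aic, priority[tab$predictor])
  list(table = tab, winner = tab$predictor[ord[1]])
}

#' Model ecosystem greenness from species phenophases
#'
#' Fits the daily GCC as an additive combination of per-species smooths
#' of median phenophase, quantifying how much each species contributes
#' to ecosystem-level greenness.
#'
#' @param gcc_daily A tibble with columns `date` and `gcc_smoothed` (or
#'   `gcc`).
#' @param species_phases A tibble with columns `date`, `species`,
#'   `median_phase` (site-level, e.g. medians across plots).
#' @param k Basis dimension per species smooth (default 4; with the
#'   few matched dates of a single season, little more is identifiable).
#' @param min_dates Minimum number of matched dates (default 10).
#' @return A `gcc_species_fit` object: the `gam`, `terms` tibble
#'   (species, edf, ref_df, f, p_value), `intercept`, adjusted `r2`,
#'   `deviance_explained`, `n`.
#' @export
fit_gcc_species_model <- function(gcc_daily, species_phases, k = 4,
                                  min_dates = 10) {
  gcc_col <- intersect(c("gcc_smoothed", "gcc"), names(gcc_daily))[1]
  if (is.na(gcc_col)) stop("no `gcc_smoothed` or `gcc` column", call. = FALSE)
  stopifnot(all(c("date", "species", "median_phase") %in% names(species_phases)))
  wide <- species_phases |>
    dplyr::select("date", "species", "median_phase") |>
    tidyr::pivot_wider(names_from = "species", values_from = "median_phase")
  species <- setdiff(names(wide), "date")
  safe <- make.names(species)
  names(wide) <- c("date", safe)
  df <- dplyr::inner_join(
    tibble::tibble(date = gcc_daily$date, gcc = gcc_daily[[gcc_col]]),
    wide, by = "date")
  df <- df[complete.cases(df), ]
  n_coef <- 1 + length(species) * (k - 1)
  if (nrow(df) < max(min_dates, n_coef)) {
    stop("only ", nrow(df), " matched dates; need at least ",
         max(min_dates, n_coef), " for ", length(species),
         " species smooths with k = ", k, call. = FALSE)
  }
  rhs <- paste(sprintf("s(%s, bs = \"cr\", k = %d)", safe, k), collapse = " + ")
  fit <- mgcv::gam(stats::as.formula(paste("gcc ~", rhs)),
                   data = as.data.frame(df), method = "REML")
  sm <- summary(fit)
  structure(list(
    gam = fit,
    terms = tibble::tibble(
      species = species,
      edf = unname(sm$s.table[, "edf"]),
      ref_df = unname(sm$s.table[, "Ref.df"]),
      f = unname(sm$s.table[, "F"]),
      p_value = unname(sm$s.table[, "p-value"])
    ),
    intercept = unname(coef(fit)[1]),
    r2 = sm$r.sq,
    deviance_explained = sm$dev.expl,
    n = nrow(df)
  ), class = "gcc_species_fit")
}

#' @export
print.gcc_species_fit <- function(x, ...) {
  cat("GCC ~ species-phenophase smooths (n = ", x$n, ")\n", sep = "")
  cat("  adj. R2 = ", round(x$r2, 3), ", deviance explained = ",
      round(100 * x$deviance_explained, 1), "%\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' Predict phenology across sites from a fitted smooth
#'
#' Space-for-time prediction: a smooth fitted at one site (typically the
#' late-snowmelt site, representing current conditions) predicts the
#' phenophase at another site from that site's climate alignment. Random
#' effects are excluded (population-level curve). Predictions are
#' clamped to the BBCH range [0, 59]; pre-clamp values are retained, and
#' target predictor values beyond the training range are flagged as
#' extrapolation.
#'
#' @param fit A `pheno_smooth_fit`.
#' @param newdata A tibble holding the fit's predictor column (e.g. the
#'   early site's `gdd` per observation date).
#' @return `newdata` with columns `predicted` (clamped), `predicted_raw`,
#'   `extrapolated` appended.
#' @export
predict_cross_site <- function(fit, newdata) {
  stopifnot(inherits(fit, "pheno_smooth_fit"))
  if (!(fit$predictor %in% names(newdata))) {
    stop("newdata lacks the fit's predictor `", fit$predictor, "`",
         call. = FALSE)
  }
  out <- tibble::as_tibble(newdata)
  if (nrow(out) == 0) {
    out$predicted <- numeric(0)
    out$predicted_raw <- numeric(0)
    out$extrapolated <- logical(0)
    return(out)
  }
  nd <- as.data.frame(out)
  exclude <- character(0)
  for (re in fit$random_effects) {
    lev <- levels(fit$gam$model[[re]])
    nd[[re]] <- factor(lev[1], levels = lev) # placeholder, term excluded
    exclude <- c(exclude, sprintf("s(%s)", re))
  }
  raw <- as.numeric(predict(fit$gam, newdata = nd, exclude = exclude,
                            newdata.guaranteed = TRUE))
  out$predicted_raw <- raw
  out$predicted <- pmin(pmax(raw, 0), 59)
  out$extrapolated <- out[[fit$predictor]] < fit$range[1] |
    out[[fit$predictor]] > fit$range[2]
  out
}

#' Assess cross-site predictions against observations
#'
#' @param predicted,observed Paired numeric vectors of predicted and
#'   observed phenophases (BBCH units).
#' @param stage_breaks Principal-stage bin edges for the residual
#'   breakdown (default the six principal BBCH stages).
#' @return A list: `pearson_r`, `mean_abs_error` (BBCH units),
#'   `residuals` (tibble: observed, predicted, residual, stage).
#' @export
assess_predictions <- function(predicted, observed,
                               stage_breaks = c(0, 9, 20, 30, 40, 50, 59)) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed differ in length", call. = FALSE)
  }
  if (length(predicted) == 0) stop("empty prediction set", call. = FALSE)
  res <- predicted - observed
  list(
    pearson_r = cor(predicted, observed),
    mean_abs_error = mean(abs(res)),
    residuals = tibble::tibble(
      observed = observed,
      predicted = predicted,
      residual = res,
      stage = cut(observed, breaks = unique(c(-Inf, stage_breaks, Inf)),
                  right = FALSE)
    )
  )
}
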