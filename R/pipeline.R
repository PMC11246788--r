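#' Assemble a pipeline configuration
#'
#' Collects every tunable of the analysis chain with its default. A
#' configuration can also be read from a YAML file with
#' [read_pipeline_config()]; fields missing from the file keep the
#' defaults listed here.
#'
#' @param output_dir Directory receiving all output CSVs and the run
#'   manifest.
#' @param seed Integer seed controlling the synthetic scenario and every
#'   stochastic stage.
#' @param scenario A [nivophen_scenario()] to simulate, or `NULL` to
#'   build the default scenario from `seed`.
#' @param threshold_c,persistence_days Snowmelt detection parameters.
#' @param base_c GDD base temperature.
#' @param qc A [qc_rules()] object.
#' @param window_days,percentile GCC smoothing parameters.
#' @param baseline_frac Season-event threshold fraction.
#' @param predictors Predictors compared in the model stage.
#' @param random_effects Random-effect terms for the smooth models.
#' @param train_site,target_site Sites used for cross-site prediction
#'   (defaults: fit on `"late"`, predict `"early"`).
#' @param pdr_axis,pdr_mode PDR regression axis and mode.
#' @param write_raw Also write the simulated hourly temperature logs and
#'   raw observation table (default `FALSE`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir = tempfile("nivophen_run_"),
                            seed = 1L, scenario = NULL,
                            threshold_c = 2, persistence_days = 1L,
                            base_c = 0, qc = qc_rules(),
                            window_days = 4L, percentile = 90,
                            baseline_frac = 0.1,
                            predictors = c("gdd", "dfsm", "doy"),
                            random_effects = c("plot", "year"),
                            train_site = "late", target_site = "early",
                            pdr_axis = "gdd", pdr_mode = "ols",
                            write_raw = FALSE) {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 scenario = scenario, threshold_c = threshold_c,
                 persistence_days = persistence_days, base_c = base_c,
                 qc = qc, window_days = window_days, percentile = percentile,
                 baseline_frac = baseline_frac, predictors = predictors,
                 random_effects = random_effects, train_site = train_site,
                 target_site = target_site, pdr_axis = pdr_axis,
                 pdr_mode = pdr_mode, write_raw = write_raw),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the fields above.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full snowbed-phenology pipeline
#'
#' Executes simulate -> climate -> observations -> gcc -> season metrics
#' -> model fitting and cross-site prediction -> PDR on a synthetic
#' scenario, writing one CSV per stage plus a `manifest.json` with the
#' configuration hash and per-stage record counts. Outputs are
#' byte-identical across reruns with the same configuration.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file).
#' @return Invisibly, a run report list: `outputs` (paths), `counts`,
#'   `manifest_path`, and the in-memory stage results (`results`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(config$output_dir, f)
  counts <- list()
  outputs <- character(0)

  scenario <- config$scenario %||% nivophen_scenario(seed = config$seed)
  sim <- run_stage("simulate", simulate_scenario(scenario))
  counts$simulate <- c(plots = length(sim$temperature),
                       observations = nrow(sim$observations))
  if (isTRUE(config$write_raw)) {
    for (nm in names(sim$temperature)) {
      ts <- sim$temperature[[nm]]
      readr::write_csv(
        tibble::tibble(timestamp = format(ts$timestamp, "%Y-%m-%dT%H:%M:%S"),
                       temp_c = ts$temp_c),
        out_path(paste0("soil_temp_", nm, ".csv")))
    }
    write_pheno_obs(sim$observations, out_path("pheno_obs.csv"))
  }

  climate <- run_stage("climate", {
    seasons <- list()
    aligns <- list()
    for (nm in names(sim$temperature)) {
      ts <- sim$temperature[[nm]]
      year <- as.integer(sub(".*_(\\d{4})$", "\\1", nm))
      ss <- snow_season(ts, year, config$threshold_c, config$persistence_days)
      ss$site <- sub("_P\\d+.*", "", nm)
      seasons[[nm]] <- ss
      al <- compute_gdd(ts, ss$dosm, config$base_c)
      al$plot <- ts$plot_id[1]
      al$year <- year
      aligns[[nm]] <- al
    }
    list(seasons = dplyr::bind_rows(seasons),
         alignment = dplyr::bind_rows(aligns))
  })
  readr::write_csv(climate$seasons, out_path("snow_seasons.csv"))
  readr::write_csv(climate$alignment, out_path("climate_alignment.csv"))
  outputs <- c(outputs, out_path("snow_seasons.csv"),
               out_path("climate_alignment.csv"))
  counts$climate <- c(seasons = nrow(climate$seasons),
                      alignment = nrow(climate$alignment))

  phases <- run_stage("observations", {
    med <- plot_median_series(sim$observations)
    aligned <- align_observations(med, climate$alignment)
    aligned$year <- as.integer(format(aligned$date, "%Y"))
    aligned
  })
  readr::write_csv(phases, out_path("plot_phenophases.csv"))
  outputs <- c(outputs, out_path("plot_phenophases.csv"))
  counts$observations <- c(plot_series = nrow(phases))

  gcc <- run_stage("gcc", {
    daily <- list()
    rejections <- list()
    for (nm in names(sim$images)) {
      qc <- qc_filter(sim$images[[nm]], config$qc)
      sm <- percentile_smooth(qc$retained, config$window_days,
                              config$percentile)
      mx <- percentile_smooth(qc$retained, 1L, 100)
      sm$gcc_daily_max <- mx$gcc_smoothed[match(sm$date, mx$date)]
      sm$site <- sub("_\\d{4}$", "", nm)
      sm$year <- as.integer(sub(".*_(\\d{4})$", "\\1", nm))
      daily[[nm]] <- sm
      rj <- qc$rejections
      if (nrow(rj) > 0) rj$site_year <- nm
      rejections[[nm]] <- rj
    }
    list(daily = dplyr::bind_rows(daily),
         rejections = dplyr::bind_rows(rejections))
  })
  names(gcc$daily)[names(gcc$daily) == "gcc_smoothed"] <- "gcc_p90"
  readr::write_csv(gcc$daily, out_path("gcc_daily.csv"))
  outputs <- c(outputs, out_path("gcc_daily.csv"))
  counts$gcc <- c(days = nrow(gcc$daily), rejected = nrow(gcc$rejections))

  metrics <- run_stage("metrics", {
    res <- list()
    for (nm in names(sim$images)) {
      d <- gcc$daily[paste(gcc$daily$site, gcc$daily$year, sep = "_") == nm, ]
      # events are read off the daily-maximum series
      mm <- extract_season_metrics(
        tibble::tibble(doy = d$doy, gcc = d$gcc_daily_max),
        baseline_frac = config$baseline_frac)
      mm$site <- d$site[1]
      mm$year <- d$year[1]
      res[[nm]] <- mm
    }
    dplyr::bind_rows(res)
  })
  readr::write_csv(metrics, out_path("season_metrics.csv"))
  outputs <- c(outputs, out_path("season_metrics.csv"))
  counts$metrics <- c(site_years = nrow(metrics))

  models <- run_stage("fit", {
    train <- phases[phases$site == config$train_site, ]
    comp <- list()
    fits_by_species <- list()
    for (sp in unique(train$species)) {
      d <- train[train$species == sp, ]
      fits <- lapply(config$predictors, function(p) {
        fit_phenophase_smooth(d, predictor = p,
                              random_effects = config$random_effects)
      })
      cmp <- compare_predictors(fits)
      tab <- cmp$table
      tab$species <- sp
      tab$site <- config$train_site
      tab$winner <- tab$predictor == cmp$winner
      comp[[sp]] <- tab
      fits_by_species[[sp]] <- fits[[which(config$predictors == "gdd")]]
    }
    list(comparison = dplyr::bind_rows(comp), fits = fits_by_species)
  })
  readr::write_csv(models$comparison, out_path("model_comparison.csv"))
  outputs <- c(outputs, out_path("model_comparison.csv"))
  counts$fit <- c(models = nrow(models$comparison))

  predictions <- run_stage("predict", {
    target <- phases[phases$site == config$target_site, ]
    preds <- list()
    assess <- list()
    for (sp in names(models$fits)) {
      d <- target[target$species == sp, ]
      if (nrow(d) == 0) next
      pr <- predict_cross_site(models$fits[[sp]], d)
      preds[[sp]] <- pr
      a <- assess_predictions(pr$predicted, pr$median_phase)
      assess[[sp]] <- tibble::tibble(species = sp, pearson_r = a$pearson_r,
                                     mean_abs_error = a$mean_abs_error,
                                     n = nrow(pr))
    }
    list(predictions = dplyr::bind_rows(preds),
         assessment = dplyr::bind_rows(assess))
  })
  readr::write_csv(predictions$predictions, out_path("predictions.csv"))
  readr::write_csv(predictions$assessment, out_path("prediction_assessment.csv"))
  outputs <- c(outputs, out_path("predictions.csv"),
               out_path("prediction_assessment.csv"))
  counts$predict <- c(predictions = nrow(predictions$predictions))

  pdr <- run_stage("pdr", {
    est <- phases |>
      dplyr::group_by(.data$site, .data$plot, .data$species, .data$year) |>
      dplyr::group_modify(function(d, key) {
        # species that never emerge in a plot-year yield NA with a warning;
        # they are dropped at aggregation
        suppressWarnings(
          compute_pdr(d, axis = config$pdr_axis, mode = config$pdr_mode))
      }) |>
      dplyr::ungroup()
    agg <- aggregate_pdr(est)
    cmp <- compare_pdr_sites(est)
    list(estimates = est, aggregate = agg, comparison = cmp)
  })
  readr::write_csv(pdr$estimates, out_path("pdr_estimates.csv"))
  readr::write_csv(pdr$comparison, out_path("pdr_comparison.csv"))
  outputs <- c(outputs, out_path("pdr_estimates.csv"),
               out_path("pdr_comparison.csv"))
  counts$pdr <- c(estimates = nrow(pdr$estimates))

  manifest <- list(
    package_version = as.character(utils::packageVersion("nivophen")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    counts = lapply(counts, as.list),
    outputs = basename(outputs)
  )
  manifest_path <- out_path("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(outputs = outputs, counts = counts,
                 manifest_path = manifest_path,
                 results = list(sim = sim, climate = climate, phases = phases,
                                gcc = gcc, metrics = metrics, models = models,
                                predictions = predictions, pdr = pdr)))
}
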