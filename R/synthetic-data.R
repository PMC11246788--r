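#' Specification of a monitoring site for the scenario generator
#'
#' @param name Site name (e.g. `"late"`, `"early"`).
#' @param n_plots Number of permanent plots.
#' @param melt_doy_by_year Named numeric vector mapping year to the
#'   site-level day of snowmelt (day of year, 1-366).
#' @param subplots_per_plot Subplots per plot (default 16; one plot may
#'   be reduced to 14 via `reduced_plot`).
#' @param reduced_plot Optional index of a plot with only 14 subplots.
#' @param summer_mean_temp Mean snow-free soil temperature in degrees C.
#' @param diurnal_amplitude Amplitude of the post-melt diurnal
#'   temperature cycle in degrees C.
#' @param gcc_plateau Seasonal maximum GCC of the site's phenocam view.
#' @param pos_lag_days Days from start of greenness season to its peak.
#' @return A `site_spec` list.
#' @export
site_spec <- function(name, n_plots = 8, melt_doy_by_year,
                      subplots_per_plot = 16, reduced_plot = NULL,
                      summer_mean_temp = 10, diurnal_amplitude = 4,
                      gcc_plateau = 0.44, pos_lag_days = 21) {
  melt <- unlist(melt_doy_by_year)
  stopifnot(all(melt >= 1 & melt <= 366),
            subplots_per_plot %in% c(14, 16),
            n_plots >= 1)
  structure(list(name = name, n_plots = n_plots,
                 melt_doy_by_year = melt,
                 subplots_per_plot = subplots_per_plot,
                 reduced_plot = reduced_plot,
                 summer_mean_temp = summer_mean_temp,
                 diurnal_amplitude = diurnal_amplitude,
                 gcc_plateau = gcc_plateau,
                 pos_lag_days = pos_lag_days),
            class = "site_spec")
}

#' Developmental program of a simulated species
#'
#' A species develops along a linear ramp in thermal time: after an
#' onset lag of `onset_lag_gdd` degree-days past snowmelt, its
#' (continuous) phase grows at `rate_phase_per_gdd` BBCH units per
#' degree-day until senescence, and observed codes are the nearest valid
#' codes of the snowbed BBCH scale. The ramp is nondecreasing in GDD
#' before observation noise.
#'
#' @param species Species name.
#' @param morphotype `"A"` (annual), `"P"` (perennial) or `"G"`
#'   (graminoid); controls the admissible code set.
#' @param onset_lag_gdd Thermal lag before emergence (degree-days >= 0).
#' @param rate_phase_per_gdd Development rate (BBCH units per
#'   degree-day, > 0); this is the quantity the PDR estimator targets.
#' @param senescence_phase Code at which development stops (default 59).
#' @return A `species_program` list.
#' @export
species_program <- function(species, morphotype = c("P", "A", "G"),
                            onset_lag_gdd = 0, rate_phase_per_gdd = 0.08,
                            senescence_phase = 59) {
  morphotype <- match.arg(morphotype)
  stopifnot(onset_lag_gdd >= 0, rate_phase_per_gdd > 0)
  structure(list(species = species, morphotype = morphotype,
                 onset_lag_gdd = onset_lag_gdd,
                 rate_phase_per_gdd = rate_phase_per_gdd,
                 senescence_phase = senescence_phase),
            class = "species_program")
}

#' The five default species programs
#'
#' Onset lags and rates chosen to reproduce the qualitative ordering of
#' the monitored snowbed community: *Salix herbacea* with the earliest
#' transitions and fastest rate, the annual *Euphrasia minima* delayed by
#' 250 degree-days, and intermediate perennials/graminoids; rates lie in
#' the realistic 0.06-0.09 BBCH-per-degree-day band.
#'
#' @return Named list of [species_program()] objects.
#' @export
default_species_programs <- function() {
  progs <- list(
    species_program("Salix herbacea", "P", onset_lag_gdd = 0,
                    rate_phase_per_gdd = 0.089),
    species_program("Poa alpina", "G", onset_lag_gdd = 60,
                    rate_phase_per_gdd = 0.080),
    species_program("Veronica alpina", "P", onset_lag_gdd = 100,
                    rate_phase_per_gdd = 0.068),
    species_program("Gnaphalium supinum", "P", onset_lag_gdd = 40,
                    rate_phase_per_gdd = 0.060),
    species_program("Euphrasia minima", "A", onset_lag_gdd = 250,
                    rate_phase_per_gdd = 0.071)
  )
  setNames(progs, vapply(progs, `[[`, character(1), "species"))
}

#' Phenocam properties for the scenario generator
#'
#' @param image_size Side length in pixels of the (square) simulated
#'   frames (default 64).
#' @param baseline_gcc GCC of snow-free bare ground (grey soil gives
#'   exactly 1/3).
#' @param plateau_gcc Seasonal maximum GCC; must exceed the baseline.
#' @param artifact_rates Named probabilities for the three artifact
#'   classes `overexposed` (long exposure, brightened), `fog` (bright,
#'   grey) and `out_of_window` (timestamp outside 10:00-17:00).
#' @param noise_sd_gcc Per-image GCC noise standard deviation.
#' @return A `camera_spec` list.
#' @export
camera_spec <- function(image_size = 64, baseline_gcc = 1 / 3,
                        plateau_gcc = 0.44,
                        artifact_rates = c(overexposed = 0.02, fog = 0.03,
                                           out_of_window = 0.02),
                        noise_sd_gcc = 0.005) {
  stopifnot(plateau_gcc > baseline_gcc,
            all(artifact_rates >= 0 & artifact_rates <= 1),
            noise_sd_gcc >= 0)
  structure(list(image_size = image_size, baseline_gcc = baseline_gcc,
                 plateau_gcc = plateau_gcc,
                 artifact_rates = artifact_rates,
                 noise_sd_gcc = noise_sd_gcc),
            class = "camera_spec")
}

#' Assemble a synthetic monitoring scenario
#'
#' The default scenario mirrors the structure of a two-site, three-year
#' snowbed monitoring design: a late-snowmelt site with eight plots and
#' an early-snowmelt site with four (one reduced to 14 subplots), 16
#' subplots per plot, five species on thermal-ramp programs, fortnightly
#' observations and an hourly phenocam.
#'
#' @param sites List of [site_spec()] objects.
#' @param years Integer vector of monitored years.
#' @param species List of [species_program()] objects.
#' @param camera A [camera_spec()].
#' @param seed Integer RNG seed; a fixed seed makes the whole scenario
#'   byte-identical across runs.
#' @param obs_interval_days Phenophase observation cadence in days
#'   (default 14, approximately fortnightly).
#' @param noise_sd_phase Subplot phenophase noise (BBCH units; default
#'   1.5, a free scenario parameter for within-plot heterogeneity).
#' @param season_start_doy,season_end_doy Logged span of each year's
#'   soil-temperature record (defaults 120 and 280: mid-spring under
#'   snow to post-browning).
#' @param temp_noise_sd Hourly temperature sensor/microsite noise
#'   (degrees C).
#' @param weather_sd Day-to-day standard deviation of post-melt daily
#'   mean temperature (degrees C).
#' @return A `nivophen_scenario` list.
#' @export
nivophen_scenario <- function(sites = NULL, years = 2018:2020,
                              species = default_species_programs(),
                              camera = camera_spec(), seed = 1L,
                              obs_interval_days = 14,
                              noise_sd_phase = 1.5,
                              season_start_doy = 120, season_end_doy = 280,
                              temp_noise_sd = 0.5, weather_sd = 2) {
  if (is.null(sites)) {
    sites <- list(
      site_spec("late", n_plots = 8,
                melt_doy_by_year = c("2018" = 194, "2019" = 182, "2020" = 191),
                summer_mean_temp = 9.8, gcc_plateau = 0.46,
                pos_lag_days = 18),
      site_spec("early", n_plots = 4, reduced_plot = 1,
                melt_doy_by_year = c("2018" = 164, "2019" = 193, "2020" = 175),
                summer_mean_temp = 10.4, gcc_plateau = 0.44,
                pos_lag_days = 21)
    )
  }
  stopifnot(obs_interval_days > 0, noise_sd_phase >= 0)
  structure(list(sites = sites, years = as.integer(years), species = species,
                 camera = camera, seed = as.integer(seed),
                 obs_interval_days = obs_interval_days,
                 noise_sd_phase = noise_sd_phase,
                 season_start_doy = season_start_doy,
                 season_end_doy = season_end_doy,
                 temp_noise_sd = temp_noise_sd, weather_sd = weather_sd),
            class = "nivophen_scenario")
}

# deterministic substream seed from a base seed and up to three indices
substream_seed <- function(seed, i = 0L, j = 0L, k = 0L) {
  as.integer((as.numeric(seed) + 97 * i + 8191 * j + 524287 * k) %% 2147483629)
}

#' Simulate an hourly soil-temperature series
#'
#' Before the melt day the soil sits on the snow-insulated plateau
#' (uniform in -0.5 to 1.5 degrees C, strictly below the 2-degree
#' snow-free threshold); from the melt day onward the daily mean is the
#' site's summer mean plus day-to-day weather noise (floored at 2.5
#' degrees C so that the first threshold crossing falls exactly on the
#' constructed melt day), overlaid with a sinusoidal diurnal cycle
#' peaking mid-afternoon and hourly sensor noise.
#'
#' @param site A [site_spec()].
#' @param year Monitored year; must be a name of `melt_doy_by_year`.
#' @param seed Integer seed.
#' @param plot_id Identifier stored in the series (default site name).
#' @param melt_doy Override of the site melt day (e.g. with a per-plot
#'   offset); default the site value for `year`.
#' @param season_start_doy,season_end_doy Span of the record.
#' @param noise_sd Hourly sensor noise standard deviation (degrees C).
#' @param weather_sd Day-to-day weather noise standard deviation.
#' @return A temperature series tibble (`plot_id`, `timestamp`, `temp_c`).
#' @export
simulate_soil_temperature <- function(site, year, seed, plot_id = site$name,
                                      melt_doy = NULL,
                                      season_start_doy = 120,
                                      season_end_doy = 280,
                                      noise_sd = 0.5, weather_sd = 2) {
  key <- as.character(year)
  if (is.null(melt_doy)) {
    if (!(key %in% names(site$melt_doy_by_year))) {
      stop("no melt day configured for year ", year, " at site ", site$name,
           call. = FALSE)
    }
    melt_doy <- site$melt_doy_by_year[[key]]
  }
  stopifnot(melt_doy > season_start_doy, melt_doy <= season_end_doy)
  set.seed(seed)
  doys <- season_start_doy:season_end_doy
  n_days <- length(doys)
  hours <- 0:23
  # day-level means
  pre <- doys < melt_doy
  day_mean <- numeric(n_days)
  day_mean[!pre] <- pmax(
    rnorm(sum(!pre), site$summer_mean_temp, weather_sd), 2.5)
  grid <- expand.grid(hour = hours, doy = doys)
  mean_h <- rep(day_mean, each = 24)
  diurnal <- ifelse(rep(pre, each = 24), 0,
                    site$diurnal_amplitude * sin(2 * pi * (grid$hour - 9) / 24))
  temp <- mean_h + diurnal + rnorm(nrow(grid), 0, noise_sd)
  # snow plateau: uniform, strictly below the detection threshold
  temp[rep(pre, each = 24)] <- runif(sum(pre) * 24, -0.5, 1.5)
  ts <- ISOdatetime(year, 1, 1, grid$hour, 0, 0, tz = "UTC") +
    (grid$doy - 1) * 86400
  tibble::tibble(plot_id = plot_id, timestamp = ts, temp_c = temp)
}

#' Simulate subplot phenophase observations for one plot
#'
#' Observation dates run from snowmelt to the end of the record on the
#' configured cadence. For each subplot and date the recorded code is
#' the nearest valid BBCH code (for the species' morphotype) to the
#' onset-lag-shifted linear GDD ramp plus subplot noise, clamped to
#' [0, 59]; before emergence the ramp sits at 0.
#'
#' @param program A [species_program()].
#' @param temps A temperature series for the plot (see
#'   [simulate_soil_temperature()]).
#' @param seed Integer seed.
#' @param obs_interval_days Observation cadence (days).
#' @param noise_sd_phase Subplot noise (BBCH units).
#' @param n_subplots Number of subplots (14 or 16).
#' @param site,plot Labels stored in the output.
#' @param scale BBCH scale tibble (passing it avoids re-reading the
#'   packaged CSV in tight loops).
#' @return An observation tibble: `site`, `plot`, `subplot`, `species`,
#'   `date`, `doy`, `bbch`.
#' @export
simulate_phenophases <- function(program, temps, seed,
                                 obs_interval_days = 14,
                                 noise_sd_phase = 1.5, n_subplots = 16,
                                 site = NA_character_, plot = NA_character_,
                                 scale = bbch_scale()) {
  melt <- detect_snowmelt_day(temps)
  if (is.na(melt)) stop("temperature series has no snowmelt", call. = FALSE)
  align <- compute_gdd(temps, melt)
  obs_doys <- seq(melt, max(align$doy), by = obs_interval_days)
  idx <- match(obs_doys, align$doy)
  gdd_obs <- align$gdd[idx]
  dates <- align$date[idx]
  set.seed(seed)
  ramp <- pmax(program$rate_phase_per_gdd * (gdd_obs - program$onset_lag_gdd), 0)
  ramp <- pmin(ramp, program$senescence_phase)
  out <- lapply(seq_len(n_subplots), function(sp) {
    noisy <- ramp + rnorm(length(ramp), 0, noise_sd_phase)
    noisy <- pmin(pmax(noisy, 0), 59)
    tibble::tibble(
      site = site, plot = plot, subplot = sprintf("S%02d", sp),
      species = program$species, date = dates, doy = obs_doys,
      bbch = snap_to_bbch(noisy, program$morphotype, scale)
    )
  })
  dplyr::bind_rows(out)
}

#' Seasonal GCC curve through the five phenological events
#'
#' Piecewise-linear greenness curve anchored so that threshold-based
#' extraction recovers the constructed events exactly: the curve crosses
#' the 10%-of-amplitude line on SOS and EOS, the 95%-of-maximum line on
#' SPS and EPS, and attains its unique maximum on POS. A tiny positive
#' offset at the crossing anchors keeps the recovery robust to
#' floating-point comparison.
#'
#' @param doy Integer vector of days at which to evaluate the curve.
#' @param metrics A list with `sos`, `sps`, `pos`, `eps`, `eos`.
#' @param baseline,plateau Baseline and maximum GCC.
#' @param baseline_frac,peak_frac The extraction thresholds being
#'   encoded (defaults 0.1 and 0.95, matching
#'   [extract_season_metrics()]).
#' @param shoulder_days Days over which the curve leaves/returns to
#'   baseline outside the season.
#' @return Numeric vector of GCC values.
#' @export
gcc_season_curve <- function(doy, metrics, baseline = 1 / 3, plateau = 0.44,
                             baseline_frac = 0.1, peak_frac = 0.95,
                             shoulder_days = 10) {
  m <- metrics
  stopifnot(m$sos <= m$sps, m$sps <= m$pos, m$pos <= m$eps, m$eps <= m$eos)
  eps_num <- 1e-6
  thr_season <- baseline + baseline_frac * (plateau - baseline) + eps_num
  thr_peak <- peak_frac * plateau + eps_num
  xs <- c(m$sos - shoulder_days, m$sos, m$sps, m$pos, m$eps, m$eos,
          m$eos + shoulder_days)
  ys <- c(baseline, thr_season, thr_peak, plateau, thr_peak, thr_season,
          baseline)
  keep <- !duplicated(xs)
  approx(xs[keep], ys[keep], xout = doy, rule = 2)$y
}

#' Simulate phenocam image records for one site-year
#'
#' Produces hourly image records (eight per day, 10:00-17:00) whose
#' ROI-mean GCC follows the seasonal curve of [gcc_season_curve()]
#' through the supplied true events, with per-image noise and camera
#' artifacts injected at the configured rates: over-exposed frames get
#' exposure times beyond 50 s (and brighter channels), fog frames turn
#' bright and grey, and out-of-window frames are re-stamped outside the
#' 10:00-17:00 acquisition window. The injected artifact class is kept
#' in the `artifact` column as ground truth.
#'
#' @param camera A [camera_spec()].
#' @param metrics_true A list/row with the true `sos`, `sps`, `pos`,
#'   `eps`, `eos` (must be ordered).
#' @param year Calendar year for the timestamps.
#' @param seed Integer seed.
#' @param site Site label used in filenames.
#' @param start_doy,end_doy Imaging span; defaults bracket the season
#'   from just before SOS to just after EOS.
#' @param plateau_gcc Optional override of the camera plateau (e.g. a
#'   site-specific maximum).
#' @return An image-record tibble: `filename`, `timestamp`,
#'   `exposure_time_s`, `exposure_ratio`, `r`, `g`, `b`, `artifact`,
#'   `gcc_true`.
#' @export
simulate_phenocam <- function(camera, metrics_true, year, seed,
                              site = "site", start_doy = NULL, end_doy = NULL,
                              plateau_gcc = NULL) {
  m <- metrics_true
  if (!(m$sos <= m$sps && m$sps <= m$pos && m$pos <= m$eps && m$eps <= m$eos)) {
    stop("metrics_true must be ordered sos <= sps <= pos <= eps <= eos",
         call. = FALSE)
  }
  plateau <- plateau_gcc %||% camera$plateau_gcc
  start_doy <- start_doy %||% (m$sos - 12)
  end_doy <- end_doy %||% (m$eos + 12)
  set.seed(seed)
  grid <- expand.grid(hour = 10:17, doy = start_doy:end_doy)
  n <- nrow(grid)
  gcc_curve <- gcc_season_curve(grid$doy, m, baseline = camera$baseline_gcc,
                                plateau = plateau)
  gcc <- gcc_curve + rnorm(n, 0, camera$noise_sd_gcc)
  gcc <- pmin(pmax(gcc, 0.01), 0.99)
  total <- rep(0.9, n) # channel sum of a typical mid-day frame
  exposure_time <- pmin(pmax(rnorm(n, 10, 2), 1), 30)
  exposure_ratio <- pmax(rnorm(n, 5, 1), 2.2)
  artifact <- rep("none", n)
  u <- runif(n)
  rates <- camera$artifact_rates
  cuts <- cumsum(c(overexposed = unname(rates["overexposed"]),
                   fog = unname(rates["fog"]),
                   out_of_window = unname(rates["out_of_window"])))
  artifact[u < cuts[1]] <- "overexposed"
  artifact[u >= cuts[1] & u < cuts[2]] <- "fog"
  artifact[u >= cuts[2] & u < cuts[3]] <- "out_of_window"

  over <- artifact == "overexposed"
  exposure_time[over] <- 51 + runif(sum(over), 0, 40)
  total[over] <- total[over] * 1.5
  fog <- artifact == "fog"
  gcc[fog] <- 1 / 3 + rnorm(sum(fog), 0, 0.003)
  total[fog] <- total[fog] * 1.8

  hour <- grid$hour
  oow <- artifact == "out_of_window"
  hour[oow] <- sample(c(7L, 8L, 9L, 18L, 19L), sum(oow), replace = TRUE)

  ts <- ISOdatetime(year, 1, 1, hour, 0, 0, tz = "UTC") + (grid$doy - 1) * 86400
  tibble::tibble(
    filename = paste0(site, "_", format(ts, "%Y%m%d_%H%M"), ".png"),
    timestamp = ts,
    exposure_time_s = exposure_time,
    exposure_ratio = exposure_ratio,
    r = (1 - gcc) * total / 2,
    g = gcc * total,
    b = (1 - gcc) * total / 2,
    artifact = artifact,
    gcc_true = gcc_curve
  )
}

#' Render simulated image records as PNG files
#'
#' Writes one small RGB PNG per record (pixel values are the record's
#' ROI-mean channels plus balanced pixel noise) together with a
#' full-frame ROI mask and an `image_meta.csv`, so the pixel-level
#' extraction path can be exercised end to end.
#'
#' @param records Image records from [simulate_phenocam()].
#' @param dir Output directory (created if missing).
#' @param camera A [camera_spec()] (controls image size).
#' @param seed Integer seed for the pixel noise.
#' @param pixel_noise_sd Per-pixel channel noise (default 0.02).
#' @return Invisibly, the directory path.
#' @export
write_phenocam_images <- function(records, dir, camera = camera_spec(),
                                  seed = 1L, pixel_noise_sd = 0.02) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  sz <- camera$image_size
  for (i in seq_len(nrow(records))) {
    px <- array(0, dim = c(sz, sz, 3))
    ch <- c(records$r[i], records$g[i], records$b[i])
    # channel sum <= 2.7 here, so per-channel values stay in [0, 1]
    for (kk in 1:3) {
      noise <- rnorm(sz * sz, 0, pixel_noise_sd)
      noise <- noise - mean(noise) # preserve the ROI mean exactly
      px[, , kk] <- pmin(pmax(ch[kk] + noise, 0), 1)
    }
    png::writePNG(px, file.path(dir, records$filename[i]))
  }
  mask <- matrix(1, sz, sz)
  png::writePNG(mask, file.path(dir, "roi_mask.png"))
  readr::write_csv(
    tibble::tibble(filename = records$filename,
                   timestamp = format(records$timestamp, "%Y-%m-%dT%H:%M:%S"),
                   exposure_time_s = records$exposure_time_s,
                   exposure_ratio = records$exposure_ratio),
    file.path(dir, "image_meta.csv"))
  invisible(dir)
}

#' True season metrics implied by a site's melt day
#'
#' The generator places the greenness season relative to snowmelt: SOS
#' two days after melt, POS after the site's green-up lag, a plateau
#' from seven days before to twenty days after the peak, and browning
#' completed in late September (day 268).
#'
#' @param site A [site_spec()].
#' @param year Year (to look up the melt day).
#' @param eos_doy Day of season end (default 268).
#' @return A list with `sos`, `sps`, `pos`, `eps`, `eos`.
#' @export
true_season_metrics <- function(site, year, eos_doy = 268) {
  melt <- site$melt_doy_by_year[[as.character(year)]]
  if (is.null(melt)) stop("no melt day for year ", year, call. = FALSE)
  sos <- melt + 2
  pos <- sos + site$pos_lag_days
  list(sos = sos, sps = pos - 7, pos = pos, eps = pos + 20,
       eos = max(eos_doy, pos + 21))
}

#' Run the full scenario generator
#'
#' Simulates every plot's hourly soil temperature, every species'
#' subplot phenophase observations and each site-year's phenocam record
#' stream, and returns them together with the generating truth (per-plot
#' melt days, per-species rates, per-site-year season events) so that
#' downstream estimators can be validated by round trip.
#'
#' Per-plot melt days are the site melt day plus a small integer offset
#' (-2 to 2 days) representing microtopographic variation.
#'
#' @param scenario A [nivophen_scenario()].
#' @return A list: `temperature` (named list of series), `observations`
#'   (one tibble), `images` (named list of record tibbles per
#'   site-year), `truth` (list of `melt`, `rates`, `metrics` tibbles),
#'   `scenario`.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "nivophen_scenario"))
  scale <- bbch_scale()
  temperature <- list()
  obs <- list()
  images <- list()
  melt_truth <- list()
  metrics_truth <- list()
  for (si in seq_along(scenario$sites)) {
    site <- scenario$sites[[si]]
    set.seed(substream_seed(scenario$seed, si))
    plot_offsets <- sample(-2:2, site$n_plots, replace = TRUE)
    for (yi in seq_along(scenario$years)) {
      year <- scenario$years[yi]
      site_melt <- site$melt_doy_by_year[[as.character(year)]]
      if (is.null(site_melt)) {
        stop("site ", site$name, " has no melt day for ", year, call. = FALSE)
      }
      for (pi in seq_len(site$n_plots)) {
        plot_id <- sprintf("%s_P%02d", site$name, pi)
        melt_p <- site_melt + plot_offsets[pi]
        ts <- simulate_soil_temperature(
          site, year, seed = substream_seed(scenario$seed, si, yi, pi),
          plot_id = plot_id, melt_doy = melt_p,
          season_start_doy = scenario$season_start_doy,
          season_end_doy = scenario$season_end_doy,
          noise_sd = scenario$temp_noise_sd, weather_sd = scenario$weather_sd)
        temperature[[paste(plot_id, year, sep = "_")]] <- ts
        melt_truth[[length(melt_truth) + 1]] <- tibble::tibble(
          site = site$name, plot = plot_id, year = year, melt_doy = melt_p)
        n_sub <- if (!is.null(site$reduced_plot) && pi == site$reduced_plot) {
          14L
        } else {
          site$subplots_per_plot
        }
        for (ki in seq_along(scenario$species)) {
          prog <- scenario$species[[ki]]
          obs[[length(obs) + 1]] <- dplyr::mutate(
            simulate_phenophases(
              prog, ts,
              seed = substream_seed(scenario$seed, si, yi, pi * 100 + ki),
              obs_interval_days = scenario$obs_interval_days,
              noise_sd_phase = scenario$noise_sd_phase,
              n_subplots = n_sub, site = site$name, plot = plot_id,
              scale = scale),
            year = year)
        }
      }
      mt <- true_season_metrics(site, year)
      images[[paste(site$name, year, sep = "_")]] <- simulate_phenocam(
        scenario$camera, mt, year,
        seed = substream_seed(scenario$seed, si, yi, 9999),
        site = site$name, plateau_gcc = site$gcc_plateau)
      metrics_truth[[length(metrics_truth) + 1]] <- tibble::tibble(
        site = site$name, year = year, sos = mt$sos, sps = mt$sps,
        pos = mt$pos, eps = mt$eps, eos = mt$eos)
    }
  }
  rates <- tibble::tibble(
    species = vapply(scenario$species, `[[`, character(1), "species"),
    morphotype = vapply(scenario$species, `[[`, character(1), "morphotype"),
    onset_lag_gdd = vapply(scenario$species, `[[`, numeric(1), "onset_lag_gdd"),
    rate_phase_per_gdd = vapply(scenario$species, `[[`, numeric(1),
                                "rate_phase_per_gdd")
  )
  list(temperature = temperature,
       observations = dplyr::bind_rows(obs),
       images = images,
       truth = list(melt = dplyr::bind_rows(melt_truth),
                    rates = rates,
                    metrics = dplyr::bind_rows(metrics_truth)),
       scenario = scenario)
}
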