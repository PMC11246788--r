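test_that("soil-temperature generator encodes the melt day exactly", {
  site <- site_spec("x", melt_doy_by_year = c("2020" = 175),
                    summer_mean_temp = 10)
  ts <- simulate_soil_temperature(site, 2020, seed = 3)
  expect_equal(detect_snowmelt_day(ts), 175)
  # pre-melt plateau strictly below the 2 degC threshold
  doy <- as.integer(strftime(ts$timestamp, "%j"))
  expect_true(all(ts$temp_c[doy < 175] < 2))

  expect_error(simulate_soil_temperature(site, 2021, seed = 1),
               "no melt day")
})

test_that("a degenerate noise-free generator is flat at the summer mean", {
  site <- site_spec("x", melt_doy_by_year = c("2020" = 175),
                    summer_mean_temp = 10, diurnal_amplitude = 0)
  ts <- simulate_soil_temperature(site, 2020, seed = 1, noise_sd = 0,
                                  weather_sd = 0)
  doy <- as.integer(strftime(ts$timestamp, "%j"))
  expect_true(all(ts$temp_c[doy >= 175] == 10))
})

test_that("generators are deterministic under a fixed seed", {
  site <- site_spec("x", melt_doy_by_year = c("2020" = 170))
  a <- simulate_soil_temperature(site, 2020, seed = 7)
  b <- simulate_soil_temperature(site, 2020, seed = 7)
  expect_identical(a, b)

  prog <- species_program("sp", "P", rate_phase_per_gdd = 0.08)
  oa <- simulate_phenophases(prog, a, seed = 5)
  ob <- simulate_phenophases(prog, b, seed = 5)
  expect_identical(oa, ob)

  cam <- camera_spec()
  mt <- list(sos = 176, sps = 190, pos = 197, eps = 217, eos = 260)
  expect_identical(simulate_phenocam(cam, mt, 2020, seed = 2),
                   simulate_phenocam(cam, mt, 2020, seed = 2))
})

test_that("the phase ramp snaps noise-free GDD to the expected code", {
  site <- site_spec("x", melt_doy_by_year = c("2020" = 170),
                    summer_mean_temp = 10, diurnal_amplitude = 0)
  ts <- simulate_soil_temperature(site, 2020, seed = 1, noise_sd = 0,
                                  weather_sd = 0)
  # GDD accrues exactly 10 per day (melt day included): the observation
  # 14 days after melt sits at GDD 150, and a 0.1 ramp lands on code 15
  prog <- species_program("sp", "P", onset_lag_gdd = 0,
                          rate_phase_per_gdd = 0.1)
  obs <- simulate_phenophases(prog, ts, seed = 1, noise_sd_phase = 0,
                              n_subplots = 1)
  expect_equal(obs$bbch[obs$doy == 170], 0)  # GDD 10 -> phase 1 -> code 0
  expect_equal(obs$bbch[obs$doy == 184], 15) # 150 GDD x 0.1
})

test_that("a 250-GDD onset lag keeps early observations at code 0 or 09", {
  site <- site_spec("x", melt_doy_by_year = c("2020" = 170))
  ts <- simulate_soil_temperature(site, 2020, seed = 2)
  al <- compute_gdd(ts, detect_snowmelt_day(ts))
  prog <- species_program("late sp", "A", onset_lag_gdd = 250,
                          rate_phase_per_gdd = 0.08)
  obs <- simulate_phenophases(prog, ts, seed = 3, noise_sd_phase = 1.5,
                              n_subplots = 16)
  obs$gdd <- al$gdd[match(obs$doy, al$doy)]
  expect_true(all(obs$bbch[obs$gdd < 250] %in% c(0L, 9L)))
})

test_that("generated codes are always members of the adapted scale", {
  site <- site_spec("x", melt_doy_by_year = c("2020" = 170))
  ts <- simulate_soil_temperature(site, 2020, seed = 4)
  for (mt in c("A", "P", "G")) {
    prog <- species_program("sp", mt, onset_lag_gdd = 30,
                            rate_phase_per_gdd = 0.09)
    obs <- simulate_phenophases(prog, ts, seed = 5, noise_sd_phase = 3,
                                n_subplots = 8)
    expect_true(all(obs$bbch %in% bbch_codes(morphotype = mt)))
  }
  # non-graminoids never receive the graminoid-only code 47
  progP <- species_program("sp", "P", rate_phase_per_gdd = 0.09)
  obsP <- simulate_phenophases(progP, ts, seed = 6, noise_sd_phase = 3)
  expect_false(47 %in% obsP$bbch)
})

test_that("over-exposed artifacts carry exposure times the QC must reject", {
  cam <- camera_spec(artifact_rates = c(overexposed = 0.2, fog = 0,
                                        out_of_window = 0))
  mt <- list(sos = 176, sps = 190, pos = 197, eps = 217, eos = 260)
  rec <- simulate_phenocam(cam, mt, 2020, seed = 8)
  over <- rec[rec$artifact == "overexposed", ]
  expect_gt(nrow(over), 0)
  expect_true(all(over$exposure_time_s > 50))
  kept <- qc_filter(rec)$retained$filename
  expect_true(all(!(over$filename %in% kept)))
})

test_that("pre-season frames show the grey-soil baseline GCC of 1/3", {
  cam <- camera_spec(artifact_rates = c(overexposed = 0, fog = 0,
                                        out_of_window = 0), noise_sd_gcc = 0)
  mt <- list(sos = 200, sps = 214, pos = 221, eps = 241, eos = 268)
  rec <- simulate_phenocam(cam, mt, 2020, seed = 1)
  doy <- as.integer(strftime(rec$timestamp, "%j"))
  pre <- compute_gcc(rec$r, rec$g, rec$b)[doy < 190]
  expect_equal(pre, rep(1 / 3, length(pre)), tolerance = 1e-9)

  expect_error(simulate_phenocam(cam, list(sos = 210, sps = 205, pos = 221,
                                           eps = 241, eos = 268), 2020, 1),
               "ordered")
})

test_that("the scenario reproduces the two-site plot/subplot design", {
  scn <- nivophen_scenario(seed = 11, years = 2018:2019)
  sim <- simulate_scenario(scn)
  obs <- sim$observations
  late_plots <- unique(obs$plot[obs$site == "late"])
  early_plots <- unique(obs$plot[obs$site == "early"])
  expect_length(late_plots, 8)
  expect_length(early_plots, 4)
  counts <- obs |>
    dplyr::filter(.data$site == "early") |>
    dplyr::distinct(.data$plot, .data$subplot) |>
    dplyr::count(.data$plot)
  expect_equal(sort(counts$n), c(14, 16, 16, 16))
  expect_setequal(unique(obs$species), names(default_species_programs()))

  # whole-scenario determinism
  sim2 <- simulate_scenario(nivophen_scenario(seed = 11, years = 2018:2019))
  expect_identical(sim$observations, sim2$observations)
  expect_identical(sim$truth, sim2$truth)
})
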