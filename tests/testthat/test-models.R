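# shared small synthetic data set for the model tests
make_model_data <- function(noise = 0, seed = 1, n_plots = 4, years = 3) {
  set.seed(seed)
  out <- list()
  for (p in seq_len(n_plots)) for (y in seq_len(years)) {
    gdd <- seq(0, 700, by = 70)
    phase <- pmin(pmax(0.08 * (gdd - 30), 0), 59)
    out[[length(out) + 1]] <- tibble::tibble(
      plot = sprintf("P%02d", p), year = 2017 + y,
      doy = 180 + seq_along(gdd) * 7 + (y - 2) * 10,
      dfsm = seq_along(gdd) * 7,
      gdd = gdd,
      median_phase = phase + rnorm(length(gdd), 0, noise)
    )
  }
  dplyr::bind_rows(out)
}

test_that("collinear predictors are flagged by the correlation screen", {
  # constant-temperature season: gdd is an exact multiple of dfsm
  al <- tibble::tibble(doy = 150:200, dfsm = 0:50, gdd = 9.8 * (0:50))
  sc <- screen_predictors(al)
  expect_equal(sc$correlations["dfsm", "gdd"], 1)
  expect_true(all(c("doy", "dfsm", "gdd") %in%
                    c(sc$flagged$var1, sc$flagged$var2)))

  # independent noise stays below the flag threshold
  set.seed(4)
  ind <- tibble::tibble(doy = rnorm(200), dfsm = rnorm(200), gdd = rnorm(200))
  expect_equal(nrow(screen_predictors(ind)$flagged), 0)

  # degenerate cases: constant predictor and 2-point data
  cst <- tibble::tibble(doy = rep(1, 10), dfsm = 1:10, gdd = 1:10)
  scc <- screen_predictors(cst)
  expect_true("doy" %in% scc$constant)
  expect_true(is.na(scc$correlations["doy", "gdd"]))
  expect_true(screen_predictors(al[1:2, ])$degenerate_n)
})

test_that("a noise-free smooth response is fitted almost perfectly", {
  d <- make_model_data(noise = 0)
  fit <- fit_phenophase_smooth(d, "gdd")
  expect_gte(fit$r2, 0.999)
  null_aic <- AIC(mgcv::gam(median_phase ~ 1, data = as.data.frame(d)))
  expect_lt(fit$aic, null_aic)

  # shuffled response: no structure left
  set.seed(2)
  d2 <- d
  d2$median_phase <- sample(d2$median_phase)
  fit2 <- fit_phenophase_smooth(d2, "gdd")
  expect_lt(fit2$r2, 0.1)
  expect_gt(fit2$aic, fit$aic)
})

test_that("single-level random effects are dropped with a warning", {
  d <- make_model_data(noise = 0.5, years = 1)
  expect_warning(fit <- fit_phenophase_smooth(d, "gdd"), "single level")
  expect_equal(fit$random_effects, "plot")
  expect_error(fit_phenophase_smooth(d[1:5, ], "gdd"), "at least")
  dd <- d
  dd$gdd <- 1
  expect_error(fit_phenophase_smooth(dd, "gdd"), "constant")
})

test_that("an infinite smoothing penalty reduces to the least-squares line", {
  d <- make_model_data(noise = 1, seed = 9)
  d$median_phase <- 5 + 0.07 * d$gdd + rnorm(nrow(d), 0, 1)
  fit <- suppressWarnings(
    fit_phenophase_smooth(d, "gdd", random_effects = character(0),
                          sp = 1e9))
  ols <- lm(median_phase ~ gdd, data = d)
  expect_equal(unname(fit$gam$fitted.values), unname(ols$fitted.values),
               tolerance = 1e-4)
})

test_that("predictor comparison picks the lowest AIC with a fixed tie rule", {
  d <- make_model_data(noise = 1, seed = 3)
  fits <- lapply(c("gdd", "dfsm", "doy"), function(p)
    fit_phenophase_smooth(d, p))
  cmp <- compare_predictors(fits)
  expect_equal(cmp$winner, cmp$table$predictor[which.min(cmp$table$aic)])

  # tie: identical fits under different labels resolve by gdd > dfsm > doy
  f1 <- fits[[1]]
  f2 <- f1
  f2$predictor <- "doy"
  expect_equal(compare_predictors(list(f2, f1))$winner, "gdd")

  # refusing fits on different data
  other <- fit_phenophase_smooth(make_model_data(noise = 1, seed = 4), "gdd")
  expect_error(compare_predictors(list(fits[[1]], other)), "same response")
})

test_that("the GCC-by-species model attributes signal to the driving species", {
  set.seed(21)
  n_rep <- 15
  p_driver <- numeric(n_rep)
  p_others <- matrix(0, n_rep, 2)
  driver_lowest <- logical(n_rep)
  for (rep in seq_len(n_rep)) {
    n <- 24
    phases <- lapply(1:3, function(i) cumsum(runif(n, 0, 4)))
    gcc <- 0.35 + 0.002 * phases[[1]] + rnorm(n, 0, 0.004)
    sp_names <- c("Salix herbacea", "Gnaphalium supinum", "Euphrasia minima")
    long <- dplyr::bind_rows(lapply(1:3, function(i)
      tibble::tibble(date = as.Date("2020-06-01") + seq_len(n),
                     species = sp_names[i], median_phase = phases[[i]])))
    daily <- tibble::tibble(date = as.Date("2020-06-01") + seq_len(n),
                            gcc = gcc)
    fit <- fit_gcc_species_model(daily, long)
    p_driver[rep] <- fit$terms$p_value[1]
    p_others[rep, ] <- fit$terms$p_value[2:3]
    driver_lowest[rep] <- which.min(fit$terms$p_value) == 1
  }
  # monotone phase trajectories are mutually concurve, so perfect
  # significance attribution is not attainable: require the driving
  # species to rank first nearly always and to be significant in the
  # clear majority, with idle species near their nominal rate
  expect_gte(mean(driver_lowest), 0.9)
  expect_gte(mean(p_driver < 0.05), 0.7)
  expect_lte(mean(p_others < 0.05), 0.3)
})

test_that("the GCC-by-species model handles null signal and refuses tiny n", {
  set.seed(5)
  n <- 30
  long <- dplyr::bind_rows(lapply(c("Salix herbacea", "Poa alpina"),
                                  function(s)
    tibble::tibble(date = as.Date("2020-06-01") + seq_len(n), species = s,
                   median_phase = cumsum(runif(n, 0, 3)))))
  daily <- tibble::tibble(date = as.Date("2020-06-01") + seq_len(n),
                          gcc = rnorm(n, 0.4, 0.01))
  fit <- fit_gcc_species_model(daily, long)
  expect_lt(fit$deviance_explained, 0.4)
  # mean-centred identity: intercept is the mean response
  expect_equal(fit$intercept, mean(daily$gcc), tolerance = 1e-6)
  expect_error(fit_gcc_species_model(daily[1:5, ], long), "matched dates")
})

test_that("cross-site prediction clamps, flags extrapolation and validates", {
  d <- make_model_data(noise = 0.5, seed = 6)
  fit <- fit_phenophase_smooth(d, "gdd")
  nd <- tibble::tibble(gdd = c(100, 400, 900)) # 900 beyond training range
  pr <- predict_cross_site(fit, nd)
  expect_true(all(pr$predicted >= 0 & pr$predicted <= 59))
  expect_equal(pr$extrapolated, c(FALSE, FALSE, TRUE))

  empty <- predict_cross_site(fit, tibble::tibble(gdd = numeric(0)))
  expect_equal(nrow(empty), 0)

  expect_error(predict_cross_site(fit, tibble::tibble(doy = 1:3)),
               "predictor")
})

test_that("prediction assessment separates correlation from bias", {
  obs <- c(5, 10, 20, 33, 45)
  a <- assess_predictions(obs, obs)
  expect_equal(a$pearson_r, 1)
  expect_equal(a$mean_abs_error, 0)

  b <- assess_predictions(obs + 3, obs)
  expect_equal(b$pearson_r, 1)
  expect_equal(b$mean_abs_error, 3)

  set.seed(10)
  p <- runif(20, 0, 59)
  o <- runif(20, 0, 59)
  expect_equal(assess_predictions(p, o)$mean_abs_error, mean(abs(p - o)))
  expect_error(assess_predictions(1:3, 1:4), "length")
})
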