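test_that("GCC arithmetic: grey identity, pure green, direct ratio", {
  expect_equal(compute_gcc(5, 5, 5), 1 / 3)
  expect_equal(compute_gcc(0, 0.7, 0), 1)
  expect_equal(compute_gcc(30, 60, 10), 0.6)
  expect_error(compute_gcc(0, 0, 0), "R \\+ G \\+ B = 0")
  expect_error(compute_gcc(-1, 2, 3), "negative")
})

test_that("GCC is scale-invariant and bounded in (0,1)", {
  set.seed(1)
  for (i in 1:50) {
    ch <- runif(3, 0.01, 1)
    k <- runif(1, 0.1, 10)
    g1 <- compute_gcc(ch[1], ch[2], ch[3])
    g2 <- compute_gcc(k * ch[1], k * ch[2], k * ch[3])
    expect_equal(g1, g2)
    expect_true(g1 > 0 && g1 < 1)
  }
})

test_that("ROI means match a per-channel loop oracle", {
  px <- array(rep(c(10, 20, 30), each = 4), dim = c(2, 2, 3))
  expect_equal(extract_roi_mean(px), c(r = 10, g = 20, b = 30))

  # masking: excluded zero pixel does not dilute the mean
  px2 <- array(0, dim = c(1, 2, 3))
  px2[1, 2, ] <- 9
  mask <- matrix(c(FALSE, TRUE), 1, 2)
  expect_equal(extract_roi_mean(px2, mask), c(r = 9, g = 9, b = 9))

  set.seed(8)
  px3 <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  m <- matrix(runif(64) > 0.4, 8, 8)
  got <- extract_roi_mean(px3, m)
  oracle <- c(0, 0, 0)
  n <- 0
  for (i in 1:8) for (j in 1:8) if (m[i, j]) {
    oracle <- oracle + px3[i, j, ]
    n <- n + 1
  }
  expect_equal(unname(got), oracle / n)

  expect_error(extract_roi_mean(px3, matrix(TRUE, 4, 4)), "dimensions")
  expect_error(extract_roi_mean(px3, matrix(FALSE, 8, 8)), "no pixels")
})

test_that("QC rejects long exposures, low ratios and out-of-window frames", {
  rec <- make_clean_records(4)
  rec$exposure_time_s[2] <- 60
  rec$exposure_ratio[3] <- 1.5
  rec$timestamp[4] <- as.POSIXct("2020-06-28 09:00:00", tz = "UTC")
  out <- qc_filter(rec, qc_rules(cluster_filter = FALSE,
                                 brightness_quantiles = NULL))
  expect_equal(nrow(out$retained), 1)
  expect_setequal(out$rejections$rule,
                  c("exposure_time", "exposure_ratio", "time_of_day"))

  # lenient mode keeps short-exposure frames outside the window
  lenient <- qc_filter(rec, qc_rules(cluster_filter = FALSE,
                                     brightness_quantiles = NULL,
                                     lenient_tod = TRUE))
  expect_equal(nrow(lenient$retained), 2)
})

test_that("relaxing any single QC rule never shrinks the retained set", {
  cam <- camera_spec(artifact_rates = c(overexposed = 0.1, fog = 0.1,
                                        out_of_window = 0.1))
  mt <- list(sos = 176, sps = 190, pos = 197, eps = 217, eos = 260)
  rec <- simulate_phenocam(cam, mt, 2020, seed = 5)
  base <- qc_rules()
  relaxed <- list(
    qc_rules(max_exposure_s = Inf),
    qc_rules(min_exposure_ratio = 0),
    qc_rules(tod_start = 0, tod_end = 24),
    qc_rules(brightness_quantiles = c(0, 1)),
    qc_rules(cluster_filter = FALSE)
  )
  kept0 <- qc_filter(rec, base)$retained$filename
  for (r in relaxed) {
    kept <- qc_filter(rec, r)$retained$filename
    expect_true(all(kept0 %in% kept))
  }
})

test_that("the cluster filter drops the bright grey fog group", {
  cam <- camera_spec(artifact_rates = c(overexposed = 0, fog = 0.15,
                                        out_of_window = 0))
  mt <- list(sos = 176, sps = 190, pos = 197, eps = 217, eos = 260)
  rec <- simulate_phenocam(cam, mt, 2020, seed = 9)
  out <- qc_filter(rec, qc_rules(brightness_quantiles = NULL))
  fog <- rec$filename[rec$artifact == "fog"]
  expect_true(length(fog) > 0)
  expect_true(all(!(fog %in% out$retained$filename)))
})

test_that("percentile smoothing matches a brute-force window oracle", {
  # constant series stays constant
  const <- make_gcc_records(rep(0.40, 10))
  sm <- percentile_smooth(const)
  expect_true(all(sm$gcc_smoothed == 0.40))

  # window 1, one image per day: identity
  daily <- make_gcc_records(seq(0.34, 0.44, length.out = 11))
  expect_equal(percentile_smooth(daily, 1L, 90)$gcc_smoothed,
               daily$gcc)

  # random fixtures against an independent sort-based percentile
  for (seed in 1:10) {
    rec <- make_gcc_records(runif(12, 0.3, 0.5), n_per_day = 3,
                            jitter_sd = 0.02, seed = seed)
    sm <- percentile_smooth(rec, 4L, 90)
    day <- as.Date(rec$timestamp, tz = "UTC")
    for (k in seq_len(nrow(sm))) {
      vals <- rec$gcc[day >= sm$date[k] - 3 & day <= sm$date[k]]
      expect_equal(sm$gcc_smoothed[k], oracle_percentile(vals, 90))
    }
  }
})

test_that("window 1 at the 100th percentile is the daily maximum", {
  rec <- make_gcc_records(runif(8, 0.3, 0.5), n_per_day = 5,
                          jitter_sd = 0.03, seed = 2)
  sm <- percentile_smooth(rec, 1L, 100)
  day <- as.Date(rec$timestamp, tz = "UTC")
  expect_equal(sm$gcc_smoothed,
               as.numeric(tapply(rec$gcc, day, max)[as.character(sm$date)]))
})

test_that("pixel rendering and ROI extraction round-trip through PNG", {
  cam <- camera_spec(image_size = 16,
                     artifact_rates = c(overexposed = 0, fog = 0,
                                        out_of_window = 0))
  mt <- list(sos = 176, sps = 190, pos = 197, eps = 217, eos = 260)
  rec <- simulate_phenocam(cam, mt, 2020, seed = 3)[1:4, ]
  dir <- withr::local_tempdir()
  write_phenocam_images(rec, dir, cam, seed = 1)
  meta <- read_image_meta(file.path(dir, "image_meta.csv"))
  mask <- read_roi_mask(file.path(dir, "roi_mask.png"))
  expect_equal(dim(mask), c(16, 16))
  got <- extract_roi_means(dir, meta, mask)
  # PNG stores 8-bit channels: agreement to quantization accuracy
  expect_equal(got$r, rec$r, tolerance = 0.01)
  expect_equal(got$g, rec$g, tolerance = 0.01)
  expect_equal(compute_gcc(got$r, got$g, got$b),
               compute_gcc(rec$r, rec$g, rec$b), tolerance = 0.02)
})
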