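test_that("clean maternal and fetal traces are detected beat for beat", {
  src <- generate_source(ecg_source_spec(80, 250, 60, rr_jitter_frac = 0.03,
                                         seed = 7L))
  det <- pan_tompkins(src$signal, 250, mode = "maternal")
  expect_equal(length(det), 80, tolerance = 1)
  offs <- vapply(det, function(i) min(abs(src$r_peaks - i)), numeric(1))
  expect_lt(max(offs) / 250 * 1000, 20)   # every detection within 20 ms
  # 100 % sensitivity with +/- 50 ms matching, both modes, several rates
  for (conf in list(list(60, "maternal", 1L), list(100, "maternal", 2L),
                    list(120, "fetal", 3L), list(180, "fetal", 4L))) {
    sp <- if (conf[[2]] == "maternal") {
      ecg_source_spec(conf[[1]], 250, 30, rr_jitter_frac = 0.03, seed = conf[[3]])
    } else {
      fetal_spec(conf[[1]], duration_s = 30, seed = conf[[3]])
    }
    s <- generate_source(sp)
    d <- pan_tompkins(s$signal, 250, mode = conf[[2]])
    cnt <- match_peaks(d, s$r_peaks, tolerance_ms = 50, fs = 250)
    expect_equal(cnt$FN, 0L)
    expect_equal(cnt$FP, 0L)
  }
})

test_that("detection is polarity-blind", {
  src <- generate_source(ecg_source_spec(75, 250, 30, rr_jitter_frac = 0.02,
                                         seed = 3L))
  d_pos <- pan_tompkins(src$signal, 250, "maternal")
  d_neg <- pan_tompkins(-src$signal, 250, "maternal")
  expect_equal(d_pos, d_neg, tolerance = 2)
})

test_that("degenerate inputs are handled", {
  expect_warning(out <- pan_tompkins(rep(0, 1000), 250, "maternal"),
                 "no QRS")
  expect_length(out, 0L)
  expect_error(pan_tompkins(rnorm(100), 250), "2 s")
  expect_error(pan_tompkins(rnorm(1000), 50, "maternal"), "100 Hz")
})

test_that("heart rates are exact arithmetic on peak indices", {
  hr <- heart_rates(c(1L, 251L, 501L), 250)
  expect_equal(hr$dp, c(250L, 250L))
  expect_equal(hr$rates_bpm, c(60, 60))
  expect_equal(hr$mean_rate_bpm, 60)
  hr2 <- heart_rates(c(1L, 126L), 250)
  expect_equal(hr2$rates_bpm, 120)
  # independent re-computation loop reproduces rates bit for bit
  idx <- sort(sample.int(50000, 40))
  hr3 <- heart_rates(idx, 1000)
  manual <- numeric(length(idx) - 1)
  for (l in seq_along(manual)) manual[l] <- 60 * 1000 / (idx[l + 1] - idx[l])
  expect_identical(hr3$rates_bpm, manual)
  expect_identical(hr3$mean_rate_bpm, mean(manual))
  expect_error(heart_rates(c(5L), 250), class = "nsfecg_insufficient_data")
})

test_that("jittered fetal trains average to the nominal rate", {
  src <- generate_source(fetal_spec(140, duration_s = 60, seed = 9L))
  hr <- heart_rates(pan_tompkins(src$signal, 250, "fetal"), 250)
  expect_equal(hr$mean_rate_bpm, 140, tolerance = 2)
})

test_that("doubling the sampling frequency leaves the mean rate stable", {
  hr1 <- heart_rates(pan_tompkins(
    generate_source(ecg_source_spec(90, 250, 30, rr_jitter_frac = 0.03,
                                    seed = 12L))$signal, 250, "maternal"), 250)
  hr2 <- heart_rates(pan_tompkins(
    generate_source(ecg_source_spec(90, 500, 30, rr_jitter_frac = 0.03,
                                    seed = 12L))$signal, 500, "maternal"), 500)
  expect_equal(hr1$mean_rate_bpm, hr2$mean_rate_bpm, tolerance = 1)
})

test_that("peak-set tidiers expose beats and summary rows", {
  hr <- heart_rates(c(1L, 251L, 501L), 250)
  td <- tidy(hr)
  expect_equal(nrow(td), 3L)
  expect_equal(td$time_s, c(0, 1, 2))
  gl <- glance(hr)
  expect_equal(gl$count, 3L)
  expect_equal(gl$var_rate_bpm, 0)
})
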