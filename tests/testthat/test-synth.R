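test_that("zero-jitter source places R peaks on an exact periodic grid", {
  src <- generate_source(ecg_source_spec(60, 250, 10, rr_jitter_frac = 0))
  expect_length(src$r_peaks, 10L)
  expect_equal(unique(diff(src$r_peaks)), 250L)
  expect_equal(mean(src$signal), 0, tolerance = 1e-12)
  # R deflections are the largest-magnitude extrema
  expect_true(which.max(abs(src$signal)) %in% src$r_peaks)
})

test_that("mean inter-peak spacing follows the requested rate", {
  src <- generate_source(ecg_source_spec(140, 250, 60, rr_jitter_frac = 0))
  det <- pan_tompkins(src$signal, 250, mode = "fetal")
  expect_equal(mean(diff(det)), 60 * 250 / 140, tolerance = 0.01)
  # autocorrelation rate estimate within 2 % of the nominal rate
  est <- nsfecg:::estimate_rate(src$signal, 250)
  expect_lt(abs(est - 140) / 140, 0.02)
})

test_that("generation is bit-identical under a fixed seed", {
  sp <- ecg_source_spec(123, 500, 8, rr_jitter_frac = 0.1, seed = 42L)
  expect_identical(generate_source(sp)$signal, generate_source(sp)$signal)
  rec1 <- simulate_fecg_record(duration_s = 4, seed = 9L)
  rec2 <- simulate_fecg_record(duration_s = 4, seed = 9L)
  expect_identical(rec1$X, rec2$X)
})

test_that("invalid source specs name the offending field", {
  expect_error(ecg_source_spec(-10, 250, 10), "rate_bpm",
               class = "nsfecg_parameter_error")
  expect_error(ecg_source_spec(60, 250, 10, rr_jitter_frac = 0.5),
               "rr_jitter_frac", class = "nsfecg_parameter_error")
  expect_error(ecg_source_spec(60, 100, 10), "fs",
               class = "nsfecg_parameter_error")
})

test_that("scale_fetal imposes the requested fetal-to-maternal power ratio", {
  m <- generate_source(ecg_source_spec(80, 250, 20))$signal
  f <- generate_source(fetal_spec(duration_s = 20))$signal
  # equal powers: q = 0 leaves the signal unscaled, q = -20 scales by 0.1
  f_eq <- f * sqrt(mean(m^2) / mean(f^2))
  expect_equal(scale_fetal(f_eq, m, 0), f_eq, tolerance = 1e-12)
  expect_equal(scale_fetal(f_eq, m, -20), 0.1 * f_eq, tolerance = 1e-12)
  # arbitrary powers: measured ratio hits q
  sf <- scale_fetal(f, m, -30)
  expect_equal(10 * log10(mean(sf^2) / mean(m^2)), -30, tolerance = 1e-9)
  expect_error(scale_fetal(numeric(10), m, 0), class = "nsfecg_degenerate_signal")
})

test_that("build_mixture realises X = A S + noise with centred rows", {
  S <- rbind(sin(seq_len(500) / 7), cos(seq_len(500) / 13))
  # identity mixing, no noise: rows equal the centred sources
  rec <- build_mixture(S, mixture_spec(diag(2), noise_sigma = 0), fs = 100)
  expect_equal(rec$X, S - rowMeans(S), tolerance = 1e-12, ignore_attr = TRUE)
  # arbitrary A, no noise: X - A S is the centring offset only
  A <- matrix(c(1, 2, 0.5, -1, 3, 0.2), 3, 2)
  rec2 <- build_mixture(S, mixture_spec(A, noise_sigma = 0), fs = 100)
  resid <- rec2$X - A %*% S
  expect_equal(apply(resid, 1, sd), rep(0, 3), tolerance = 1e-10)
  expect_error(build_mixture(S, mixture_spec(cbind(c(1, 2), c(2, 4)))),
               class = "nsfecg_configuration_error")
})

test_that("injected noise has the configured standard deviation and SNR", {
  n <- 10000
  S <- rbind(sin(seq_len(n) / 5), sin(seq_len(n) / 11 + 1))
  A <- matrix(c(1, 0.4, -0.7, 0.3, 1.1, 0.8), 3, 2)
  rec <- build_mixture(S, mixture_spec(A, noise_sigma = 0.25, seed = 5L), fs = 100)
  resid <- rec$X + rowMeans(A %*% S) - A %*% S   # undo row centring
  expect_equal(apply(resid, 1, sd), rep(0.25, 3), tolerance = 0.25 * 0.05)
  # channel SNR mode: measured power ratio within 0.2 dB of the request
  rec2 <- build_mixture(S, mixture_spec(A, channel_snr_db = 9, seed = 6L), fs = 100)
  measured <- 10 * log10(mean((A %*% S)^2) / mean(rec2$truth$noise^2))
  expect_equal(measured, 9, tolerance = 0.2)
})

test_that("simulated records keep fetal rate above maternal rate", {
  rec <- simulate_fecg_record(duration_s = 20, seed = 11L)
  n_m <- length(rec$truth$r_peaks[[1]])
  n_f <- length(rec$truth$r_peaks[[2]])
  expect_gt(n_f, n_m)
  expect_equal(n_m / 20 * 60, 80, tolerance = 5)
  expect_equal(n_f / 20 * 60, 140, tolerance = 5)
  expect_true(all(dim(rec$truth$S) == c(2, ncol(rec$X))))
})
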