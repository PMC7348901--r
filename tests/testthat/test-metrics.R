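test_that("SPI closed forms hold", {
  v <- vectors_with_corr2(0.5)
  expect_equal(spi(v$y, v$s), 0, tolerance = 1e-8)
  v9 <- vectors_with_corr2(0.9)
  expect_equal(spi(v9$y, v9$s), 10 * log10(1 / 0.9 - 1), tolerance = 1e-8)
  expect_equal(spi(v9$y, v9$s), -9.54, tolerance = 0.01)
  # identical signals floor at -300 dB; orthogonal signals cap at +300 dB
  expect_equal(spi(v$s, v$s), -300)
  expect_equal(spi(2.7 * v$s, v$s), -300)
  orth <- vectors_with_corr2(0)
  expect_equal(spi(orth$y, orth$s), 300)
})

test_that("SPI is symmetric and scale invariant", {
  v <- vectors_with_corr2(0.73, seed = 5L)
  expect_equal(spi(v$y, v$s), spi(v$s, v$y))
  expect_equal(spi(3.2 * v$y, v$s), spi(v$y, 0.04 * v$s))
})

test_that("the BSS-eval decomposition is exact and orthogonal", {
  n <- 300
  S <- withr::with_seed(4, {
    s1 <- rnorm(n); s1 <- s1 / sqrt(sum(s1^2))
    s2 <- rnorm(n); s2 <- s2 - sum(s2 * s1) * s1; s2 <- s2 / sqrt(sum(s2^2))
    rbind(s1, s2)
  })
  # y = s1 + 0.1 s2 with orthonormal sources: SIR = 20 dB exactly
  y <- S[1, ] + 0.1 * S[2, ]
  dec <- bss_eval(y, S, target = 1)
  expect_equal(dec$sir_db, 20, tolerance = 1e-8)
  expect_equal(dec$s_target + dec$e_interf + dec$e_noise + dec$e_artif, y,
               tolerance = 1e-10)
  # energies add up (orthogonal parts)
  expect_equal(sum(y^2),
               sum(dec$s_target^2) + sum(dec$e_interf^2) +
               sum(dec$e_noise^2) + sum(dec$e_artif^2),
               tolerance = 1e-8)
  # perfect estimate: all three ratios at the cap
  dec0 <- bss_eval(S[1, ], S, target = 1)
  expect_equal(c(dec0$sir_db, dec0$sar_db, dec0$sdr_db), c(300, 300, 300))
})

test_that("noise and artifact terms land in their own parts", {
  n <- 300
  S <- withr::with_seed(6, {
    s1 <- rnorm(n); s1 <- s1 / sqrt(sum(s1^2))
    s2 <- rnorm(n); s2 <- s2 - sum(s2 * s1) * s1; s2 <- s2 / sqrt(sum(s2^2))
    rbind(s1, s2)
  })
  noise <- withr::with_seed(7, {
    v <- rnorm(n)
    v <- v - sum(v * S[1, ]) * S[1, ] - sum(v * S[2, ]) * S[2, ]
    v / sqrt(sum(v^2))
  })
  y <- S[1, ] + 0.2 * noise
  dec <- bss_eval(y, S, noise = noise, target = 1)
  expect_equal(sum(dec$e_noise^2), 0.04, tolerance = 1e-8)
  expect_equal(sum(dec$e_artif^2), 0, tolerance = 1e-10)
  expect_error(bss_eval(y, matrix(0, 1, n)), class = "nsfecg_degenerate_signal")
})

test_that("qSNR follows its closed forms and caps", {
  n <- 400
  s <- withr::with_seed(8, rnorm(n))
  e <- withr::with_seed(9, rnorm(n))
  e <- e - sum(e * s) / sum(s^2) * s
  s_hat <- s + e * sqrt(sum((s + 0)^2) / sum(e^2) / 10)  # placeholder scale
  # construct ||e'||^2 = ||s_hat||^2 / 10 exactly: solve for alpha
  # ||s + alpha e||^2 = s2 + alpha^2 e2 ; want alpha^2 e2 = (s2 + alpha^2 e2)/10
  s2 <- sum(s^2); e2 <- sum(e^2)
  alpha <- sqrt(s2 / (9 * e2))
  s_hat <- s + alpha * e
  expect_equal(qsnr(s, s_hat), 10, tolerance = 1e-8)
  expect_equal(qsnr(s, s), 300)
  expect_equal(qsnr(s, rep(0, n)), -300)
  # conventional form uses the true-signal energy in the numerator
  expect_equal(qsnr(s, s_hat, form = "conventional"),
               10 * log10(s2 / (alpha^2 * e2)), tolerance = 1e-8)
})

test_that("qSNR decreases monotonically with added noise", {
  s <- generate_source(ecg_source_spec(80, 250, 8))$signal
  qs <- vapply(c(0.01, 0.05, 0.1, 0.3, 1), function(sg) {
    noisy <- s + withr::with_seed(11, rnorm(length(s), sd = sg))
    qsnr(s, noisy, scale_align = TRUE)
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
})

test_that("peak matching is greedy, one-to-one and tolerance-bounded", {
  ref <- c(100L, 200L, 300L, 400L)
  cnt <- match_peaks(ref, ref, tolerance_ms = 50, fs = 1000)
  expect_equal(c(cnt$TP, cnt$FP, cnt$FN), c(4L, 0L, 0L))
  cnt2 <- match_peaks(integer(0), seq(100, 1000, by = 100), 50, fs = 1000)
  expect_equal(c(cnt2$TP, cnt2$FP, cnt2$FN), c(0L, 0L, 10L))
  # one spurious detection far from any reference peak
  cnt3 <- match_peaks(c(ref, 5000L), ref, 50, fs = 1000)
  expect_equal(c(cnt3$TP, cnt3$FP, cnt3$FN), c(4L, 1L, 0L))
  # one-to-one: two detections near one reference give one TP, one FP
  cnt4 <- match_peaks(c(195L, 205L), c(200L), 50, fs = 1000)
  expect_equal(c(cnt4$TP, cnt4$FP, cnt4$FN), c(1L, 1L, 0L))
  # tolerance boundary: 50 ms at 1 kHz is 50 samples
  expect_equal(match_peaks(c(250L), c(200L), 50, fs = 1000)$TP, 1L)
  expect_equal(match_peaks(c(251L), c(200L), 50, fs = 1000)$TP, 0L)
})

test_that("greedy matching agrees with an independent oracle on small lists", {
  # oracle: repeatedly take the globally closest unused pair within tolerance
  greedy_oracle <- function(det, ref, tol) {
    tp <- 0L
    repeat {
      if (!length(det) || !length(ref)) break
      dmat <- abs(outer(det, ref, "-"))
      if (min(dmat) > tol) break
      ij <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      det <- det[-ij[1]]
      ref <- ref[-ij[2]]
      tp <- tp + 1L
    }
    tp
  }
  withr::with_seed(13, {
    for (k in 1:15) {
      det <- sort(sample.int(2000, sample(3:10, 1)))
      ref <- sort(sample.int(2000, sample(3:10, 1)))
      cnt <- match_peaks(det, ref, tolerance_ms = 100, fs = 1000)
      expect_identical(cnt$TP, greedy_oracle(det, ref, 100))
      expect_identical(cnt$FP + cnt$TP, length(det))
      expect_identical(cnt$FN + cnt$TP, length(ref))
    }
  })
})

test_that("detection statistics implement the three ratios", {
  st <- detection_stats(tp = 1, fp = 1, fn = 1)
  expect_equal(st$se_pct, 50)
  expect_equal(st$acc_pct, 100 / 3, tolerance = 1e-10)
  expect_equal(st$ppv_pct, 50)
  expect_error(detection_stats(tp = 0, fp = 0, fn = 5),
               class = "nsfecg_undefined_statistic")
  # ACC <= min(SE, PPV) over random counts
  withr::with_seed(17, {
    for (k in 1:25) {
      tp <- sample(1:200, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
      s <- detection_stats(tp = tp, fp = fp, fn = fn)
      expect_lte(s$acc_pct, min(s$se_pct, s$ppv_pct) + 1e-12)
    }
  })
})

test_that("alignment removes permutation and sign ambiguity from the metrics", {
  rec <- small_mixture(seed = 5L, m = 4)
  src <- extract_sources(rec, method = "nsitm", L = 2)
  al1 <- align_sources(src$Y, rec$truth$S)
  scrambled <- rbind(-src$Y[2, ], src$Y[1, ])
  al2 <- align_sources(scrambled, rec$truth$S)
  expect_equal(al1$correlations, al2$correlations, tolerance = 1e-12)
  expect_equal(spi(al1$Y, rec$truth$S), spi(al2$Y, rec$truth$S),
               tolerance = 1e-10)
  d1 <- bss_eval(al1$Y[2, ], rec$truth$S, target = 2)
  d2 <- bss_eval(al2$Y[2, ], rec$truth$S, target = 2)
  expect_equal(d1$sir_db, d2$sir_db, tolerance = 1e-8)
})

test_that("separation reports assemble every metric with sane ranges", {
  rec <- small_mixture(seed = 7L, m = 5, duration_s = 10)
  src <- extract_sources(rec, method = "nsitm", L = 2)
  rep <- separation_report(src, rec)
  expect_s3_class(rep, "separation_report")
  expect_true(all(c("spi_db", "sir_db", "sar_db", "sdr_db", "qsnr_db",
                    "se_pct", "acc_pct", "ppv_pct") %in% names(rep)))
  expect_true(rep$se_pct >= 0 && rep$se_pct <= 100)
  expect_lte(rep$acc_pct, min(rep$se_pct, rep$ppv_pct) + 1e-9)
  expect_gt(rep$fetal_corr, 0.9)
  expect_error(separation_report(src, multichannel_record(rec$X, rec$fs)),
               class = "nsfecg_unavailable_metric")
})
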