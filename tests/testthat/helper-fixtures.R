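# shared fixtures, built in code at test time

fetal_spec <- function(rate_bpm = 140, fs = 250, duration_s = 10,
                       rr_jitter_frac = 0.03, seed = 1L) {
  ecg_source_spec(
    rate_bpm = rate_bpm, fs = fs, duration_s = duration_s,
    wave_amplitudes = c(P = 0.1, Q = -0.08, R = 1, S = -0.2, T = 0.25),
    wave_widths_ms = c(P = 15, Q = 6, R = 7, S = 6, T = 25),
    wave_offsets_frac = c(P = -0.18, Q = -0.045, R = 0, S = 0.045, T = 0.25),
    rr_jitter_frac = rr_jitter_frac, seed = seed
  )
}

# a small noiseless two-source mixture with known truth
small_mixture <- function(seed = 1L, m = 4, fs = 250, duration_s = 10,
                          fmsnr_db = -5, channel_snr_db = Inf) {
  simulate_fecg_record(
    duration_s = duration_s, fs = fs,
    n_abdominal = m, n_thoracic = 0,
    fmsnr_db = fmsnr_db, channel_snr_db = channel_snr_db, seed = seed
  )
}

# random full-rank zero-mean channel matrix
random_xp <- function(m, n, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(m * n), m, n)
    x - rowMeans(x)
  })
}

# vectors with an exact squared cosine similarity (zero-mean)
vectors_with_corr2 <- function(rho2, n = 400, seed = 2L) {
  withr::with_seed(seed, {
    s <- rnorm(n); s <- s - mean(s); s <- s / sqrt(sum(s^2))
    e <- rnorm(n); e <- e - mean(e)
    e <- e - sum(e * s) * s; e <- e / sqrt(sum(e^2))
    y <- sqrt(rho2) * s + sqrt(1 - rho2) * e
    list(y = y, s = s)
  })
}
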