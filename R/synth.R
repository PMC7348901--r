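#' Specification of a synthetic quasi-periodic ECG source
#'
#' Describes one ECG-like source (maternal or fetal) as a train of beats, each
#' beat a sum of Gaussian deflections for the P wave, the QRS complex
#' (Q, R, S) and the T wave. Beat-to-beat (RR) intervals are perturbed by a
#' truncated multiplicative Gaussian jitter, which reproduces the
#' quasi-periodic character of real maternal and fetal ECG without producing
#' pathological intervals.
#'
#' @param rate_bpm mean beat rate in beats per minute (> 0).
#' @param fs sampling frequency in Hz.
#' @param duration_s record duration in seconds.
#' @param wave_amplitudes named numeric vector of relative amplitudes for the
#'   `P`, `Q`, `R`, `S`, `T` deflections; the R amplitude should dominate.
#' @param wave_widths_ms named numeric vector of Gaussian standard deviations
#'   (milliseconds) for the five deflections.
#' @param wave_offsets_frac named numeric vector of deflection centres relative
#'   to the R peak, as fractions of the RR interval.
#' @param rr_jitter_frac standard deviation of the per-beat multiplicative RR
#'   jitter, as a fraction of the mean RR; must lie in [0, 0.2]. Jitter draws
#'   are truncated at +/- 3 sd.
#' @param seed integer seed; identical specs give bit-identical waveforms.
#'
#' @return an object of class `ecg_source_spec`.
#' @seealso [generate_source()]
#' @export
ecg_source_spec <- function(rate_bpm,
                            fs,
                            duration_s,
                            wave_amplitudes = c(P = 0.15, Q = -0.1, R = 1, S = -0.25, T = 0.35),
                            wave_widths_ms = c(P = 25, Q = 8, R = 10, S = 8, T = 40),
                            wave_offsets_frac = c(P = -0.2, Q = -0.035, R = 0, S = 0.035, T = 0.28),
                            rr_jitter_frac = 0,
                            seed = 1L) {
  check_scalar_number(rate_bpm, "rate_bpm", lower = 1e-6)
  check_scalar_number(fs, "fs", lower = 1e-6)
  check_scalar_number(duration_s, "duration_s", lower = 1e-6)
  check_scalar_number(rr_jitter_frac, "rr_jitter_frac", lower = 0, upper = 0.2)
  waves <- c("P", "Q", "R", "S", "T")
  for (nm in c("wave_amplitudes", "wave_widths_ms", "wave_offsets_frac")) {
    v <- get(nm)
    if (!all(waves %in% names(v))) {
      stop_input(sprintf("`%s` must name all of P, Q, R, S, T", nm),
                 class = "nsfecg_parameter_error")
    }
  }
  if (any(wave_widths_ms[waves] <= 0)) {
    stop_input("`wave_widths_ms` must be positive", class = "nsfecg_parameter_error")
  }
  if (abs(wave_amplitudes[["R"]]) < max(abs(wave_amplitudes[waves != "R"]))) {
    stop_input("`wave_amplitudes`: the R deflection must dominate",
               class = "nsfecg_parameter_error")
  }
  # the sharpest deflection (smallest sigma) sets the highest frequency
  # content; require fs comfortably above twice its characteristic band edge
  f_max <- 500 / min(wave_widths_ms[waves])
  if (fs <= 2 * f_max) {
    stop_input(sprintf(
      "`fs` = %g Hz undersamples the morphology (need > %g Hz for the narrowest wave)",
      fs, 2 * f_max), class = "nsfecg_parameter_error")
  }
  structure(
    list(
      rate_bpm = rate_bpm, fs = fs, duration_s = duration_s,
      wave_amplitudes = wave_amplitudes[waves],
      wave_widths_ms = wave_widths_ms[waves],
      wave_offsets_frac = wave_offsets_frac[waves],
      rr_jitter_frac = rr_jitter_frac,
      seed = as.integer(seed)
    ),
    class = "ecg_source_spec"
  )
}

#' Generate a synthetic single-channel ECG-like source
#'
#' Produces a zero-mean quasi-periodic waveform from an [ecg_source_spec()].
#' R peaks fall exactly on sample positions; with zero jitter the peak train
#' is exactly periodic (rate 60 bpm at 250 Hz over 10 s gives 10 R peaks
#' spaced 250 samples apart).
#'
#' @param spec an [ecg_source_spec()].
#' @return an object of class `ecg_source`: a list with `signal` (numeric,
#'   length `fs * duration_s`, zero mean), `fs`, `r_peaks` (1-based sample
#'   indices of the true R peaks) and the generating `spec`.
#' @export
generate_source <- function(spec) {
  if (!inherits(spec, "ecg_source_spec")) {
    stop_input("`spec` must be an `ecg_source_spec`", class = "nsfecg_parameter_error")
  }
  fs <- spec$fs
  n <- round(fs * spec$duration_s)
  rr_s <- 60 / spec$rate_bpm

  # beat grid: first R at half a period, then jittered RR increments
  r_times <- withr::with_seed(spec$seed, {
    t_cur <- rr_s / 2
    out <- numeric(0)
    while (t_cur < spec$duration_s + rr_s) {
      out <- c(out, t_cur)
      z <- rnorm(1)
      z <- pmin(pmax(z, -3), 3)
      t_cur <- t_cur + rr_s * (1 + spec$rr_jitter_frac * z)
    }
    out
  })
  r_idx <- round(r_times * fs) + 1L
  keep <- r_idx >= 1L & r_idx <= n
  r_idx <- r_idx[keep]

  t_axis <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  amps <- spec$wave_amplitudes
  sig_s <- spec$wave_widths_ms / 1000
  offs <- spec$wave_offsets_frac * rr_s
  for (k in seq_along(r_idx)) {
    t_r <- (r_idx[k] - 1L) / fs
    for (w in names(amps)) {
      ctr <- t_r + offs[[w]]
      # only evaluate near the bump (5 sigma support) for speed
      lo <- max(1L, floor((ctr - 5 * sig_s[[w]]) * fs) + 1L)
      hi <- min(n, ceiling((ctr + 5 * sig_s[[w]]) * fs) + 1L)
      if (lo > hi) next
      seg <- lo:hi
      x[seg] <- x[seg] + amps[[w]] * exp(-((t_axis[seg] - ctr)^2) / (2 * sig_s[[w]]^2))
    }
  }
  x <- x - mean(x)
  structure(
    list(signal = x, fs = fs, r_peaks = r_idx, spec = spec),
    class = "ecg_source"
  )
}

#' Scale a fetal waveform to a target fetal-to-maternal SNR
#'
#' Multiplies the fetal waveform by the factor p = sqrt(pm/pf) * 10^(q/20),
#' where pm and pf are the maternal and fetal signal powers, so that the
#' post-scaling fetal-to-maternal power ratio equals `q_db` decibels. This is
#' the standard way to impose a fetal-to-maternal SNR (fmSNR) before mixing.
#'
#' @param fecg fetal waveform (numeric vector, or `ecg_source`).
#' @param mecg maternal waveform (numeric vector, or `ecg_source`).
#' @param q_db target fetal-to-maternal SNR in dB (typically in [-30, 0]).
#' @return the scaled fetal waveform, same type as `fecg`.
#' @export
scale_fetal <- function(fecg, mecg, q_db) {
  check_scalar_number(q_db, "q_db")
  f <- if (inherits(fecg, "ecg_source")) fecg$signal else fecg
  m <- if (inherits(mecg, "ecg_source")) mecg$signal else mecg
  pf <- signal_power(f)
  pm <- signal_power(m)
  if (pf <= 0 || pm <= 0) {
    stop_input("degenerate signal: zero power input to `scale_fetal`",
               class = "nsfecg_degenerate_signal")
  }
  p <- sqrt(pm / pf) * 10^(q_db / 20)
  if (inherits(fecg, "ecg_source")) {
    fecg$signal <- p * fecg$signal
    fecg
  } else {
    p * fecg
  }
}

#' Specification of a linear mixing of ECG sources
#'
#' @param A mixing matrix, M channels x L sources, full column rank.
#' @param noise_sigma per-channel additive white Gaussian noise standard
#'   deviation (signal units); ignored when `channel_snr_db` is given.
#' @param channel_snr_db optional mixture signal-to-noise ratio in dB; the
#'   noise sd is then derived from the power of `A %*% S`. Use `Inf` (or
#'   `noise_sigma = 0`) for a noiseless mixture.
#' @param seed integer seed for the noise draw.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(A, noise_sigma = 0, channel_snr_db = NULL, seed = 1L) {
  A <- as.matrix(A)
  if (ncol(A) > nrow(A)) {
    stop_input("mixing matrix must have at least as many channels as sources (L <= M)",
               class = "nsfecg_configuration_error")
  }
  if (qr(A)$rank < ncol(A)) {
    stop_input("mixing matrix `A` is rank deficient",
               class = "nsfecg_configuration_error")
  }
  check_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  if (!is.null(channel_snr_db)) check_scalar_number(channel_snr_db, "channel_snr_db")
  structure(
    list(A = A, noise_sigma = noise_sigma, channel_snr_db = channel_snr_db,
         seed = as.integer(seed)),
    class = "mixture_spec"
  )
}

#' Multichannel ECG record container
#'
#' The in-memory container used throughout the package: a channels x samples
#' matrix plus sampling frequency, per-channel roles, and (for simulated
#' records) the ground truth sources.
#'
#' @param X numeric matrix, M channels x N samples (N > M).
#' @param fs sampling frequency in Hz.
#' @param channel_roles character vector of length M; one of `"abdominal"`,
#'   `"thoracic"`, `"reference"`, `"unknown"`.
#' @param truth optional list with elements `S` (L x N true source matrix),
#'   `noise` (M x N), `A`, `r_peaks` (list of true R-peak index vectors) and
#'   `labels` (source labels, e.g. `c("mecg", "fecg")`).
#' @return object of class `multichannel_record`.
#' @export
multichannel_record <- function(X, fs, channel_roles = NULL, truth = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) {
    stop_input("a multichannel record needs at least 2 channels",
               class = "nsfecg_format_error")
  }
  if (ncol(X) <= nrow(X)) {
    stop_input("record must have more samples than channels (N > M)",
               class = "nsfecg_format_error")
  }
  check_scalar_number(fs, "fs", lower = 1e-6)
  roles <- channel_roles %||% rep("unknown", nrow(X))
  if (length(roles) != nrow(X)) {
    stop_input("`channel_roles` must have one entry per channel",
               class = "nsfecg_format_error")
  }
  ok <- roles %in% c("abdominal", "thoracic", "reference", "unknown")
  if (!all(ok)) stop_input("invalid channel role(s)", class = "nsfecg_format_error")
  if (!is.null(truth) && !is.null(truth$S) && ncol(truth$S) != ncol(X)) {
    stop_input("truth source matrix must match the record length",
               class = "nsfecg_format_error")
  }
  structure(
    list(X = X, fs = fs, channel_roles = roles, truth = truth),
    class = "multichannel_record"
  )
}

#' @export
print.multichannel_record <- function(x, ...) {
  cat(sprintf("<multichannel_record> %d channels x %d samples @ %g Hz\n",
              nrow(x$X), ncol(x$X), x$fs))
  cat("roles:", paste(x$channel_roles, collapse = ", "), "\n")
  if (!is.null(x$truth)) cat("ground truth: present\n")
  invisible(x)
}

#' Mix source waveforms into a multichannel record
#'
#' Forms `X = A %*% S + noise`, then mean-centres every channel (the blind
#' source separation model assumes zero-mean mixtures). The true sources and
#' the realised noise are kept in the record's `truth` slot.
#'
#' @param sources L x N numeric matrix of source waveforms (rows), or a list
#'   of `ecg_source` objects.
#' @param spec a [mixture_spec()].
#' @param fs sampling frequency (taken from the sources if they are
#'   `ecg_source` objects).
#' @param labels optional character labels for the source rows.
#' @return a [multichannel_record()] with ground truth attached.
#' @export
build_mixture <- function(sources, spec, fs = NULL, labels = NULL) {
  if (!inherits(spec, "mixture_spec")) {
    stop_input("`spec` must be a `mixture_spec`", class = "nsfecg_configuration_error")
  }
  r_peaks <- NULL
  if (is.list(sources) && !is.matrix(sources) &&
      all(vapply(sources, inherits, logical(1), "ecg_source"))) {
    fs <- fs %||% sources[[1]]$fs
    r_peaks <- lapply(sources, `[[`, "r_peaks")
    sources <- do.call(rbind, lapply(sources, `[[`, "signal"))
  }
  S <- as.matrix(sources)
  A <- spec$A
  if (ncol(A) != nrow(S)) {
    stop_input("mixing matrix columns must match the number of sources",
               class = "nsfecg_configuration_error")
  }
  if (is.null(fs)) stop_input("`fs` is required for matrix sources",
                              class = "nsfecg_configuration_error")
  X0 <- A %*% S
  sigma <- spec$noise_sigma
  if (!is.null(spec$channel_snr_db)) {
    sigma <- if (is.infinite(spec$channel_snr_db)) 0 else {
      sqrt(signal_power(X0) * 10^(-spec$channel_snr_db / 10))
    }
  }
  noise <- if (sigma > 0) {
    withr::with_seed(spec$seed, matrix(rnorm(length(X0), sd = sigma), nrow(X0)))
  } else {
    matrix(0, nrow(X0), ncol(X0))
  }
  X <- X0 + noise
  X <- X - rowMeans(X)
  roles <- rep("abdominal", nrow(X))
  multichannel_record(
    X, fs,
    channel_roles = roles,
    truth = list(S = S, noise = noise, A = A, r_peaks = r_peaks,
                 labels = labels, noise_sigma = sigma)
  )
}

#' Simulate a full abdominal/thoracic ECG recording with ground truth
#'
#' Convenience generator emulating the standard measurement geometry for
#' non-invasive fetal ECG: abdominal electrodes see a strong maternal and a
#' weak fetal component, thoracic (reference) electrodes see essentially only
#' the maternal component. The fetal source is rescaled so its power relative
#' to the maternal source equals `fmsnr_db` decibels, and white channel noise
#' is added at `channel_snr_db`.
#'
#' @param duration_s record length in seconds.
#' @param fs sampling frequency, Hz.
#' @param n_abdominal,n_thoracic electrode counts (defaults 5 + 2).
#' @param maternal_rate_bpm,fetal_rate_bpm mean heart rates (defaults 80, 140).
#' @param fmsnr_db fetal-to-maternal SNR in dB (default -10).
#' @param channel_snr_db mixture SNR in dB; `Inf` means noiseless (default 12).
#' @param rr_jitter_frac beat-to-beat RR jitter fraction (default 0.03).
#' @param seed integer seed controlling sources, mixing gains and noise.
#' @return a [multichannel_record()] with `truth` rows `mecg`, `fecg`.
#' @export
simulate_fecg_record <- function(duration_s = 10,
                                 fs = 250,
                                 n_abdominal = 5,
                                 n_thoracic = 2,
                                 maternal_rate_bpm = 80,
                                 fetal_rate_bpm = 140,
                                 fmsnr_db = -10,
                                 channel_snr_db = 12,
                                 rr_jitter_frac = 0.03,
                                 seed = 1L) {
  seed <- as.integer(seed)
  if (fetal_rate_bpm <= maternal_rate_bpm) {
    warn("fetal rate does not exceed maternal rate; source labelling by rate may be unreliable")
  }
  m_spec <- ecg_source_spec(
    rate_bpm = maternal_rate_bpm, fs = fs, duration_s = duration_s,
    rr_jitter_frac = rr_jitter_frac, seed = seed
  )
  # fetal morphology: smaller, narrower deflections and compressed intervals
  f_spec <- ecg_source_spec(
    rate_bpm = fetal_rate_bpm, fs = fs, duration_s = duration_s,
    wave_amplitudes = c(P = 0.1, Q = -0.08, R = 1, S = -0.2, T = 0.25),
    wave_widths_ms = c(P = 15, Q = 6, R = 7, S = 6, T = 25),
    wave_offsets_frac = c(P = -0.18, Q = -0.045, R = 0, S = 0.045, T = 0.25),
    rr_jitter_frac = rr_jitter_frac, seed = seed + 1000L
  )
  mecg <- generate_source(m_spec)
  fecg <- generate_source(f_spec)
  fecg <- scale_fetal(fecg, mecg, fmsnr_db)

  m_total <- n_abdominal + n_thoracic
  A <- withr::with_seed(seed + 2000L, {
    # fetal gains carry random polarity: electrodes at different abdominal
    # sites see the fetal cardiac dipole under different projections
    abd <- cbind(runif(n_abdominal, 0.6, 1.2),
                 runif(n_abdominal, 0.4, 1.2) * sample(c(-1, 1), n_abdominal, replace = TRUE))
    if (n_thoracic > 0) {
      tho <- cbind(runif(n_thoracic, 0.9, 1.1), runif(n_thoracic, 0, 0.02))
      rbind(abd, tho)
    } else {
      abd
    }
  })
  spec <- mixture_spec(A, channel_snr_db = channel_snr_db, seed = seed + 3000L)
  rec <- build_mixture(list(mecg, fecg), spec, labels = c("mecg", "fecg"))
  rec$channel_roles <- c(rep("abdominal", n_abdominal), rep("thoracic", n_thoracic))
  rec$truth$labels <- c("mecg", "fecg")
  rec$truth$fmsnr_db <- fmsnr_db
  rec$truth$channel_snr_db <- channel_snr_db
  rec
}
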