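pt_defaults <- function(mode) {
  switch(mode,
    maternal = list(band = c(5, 15), int_win_s = 0.150, refractory_s = 0.200),
    fetal = list(band = c(10, 25), int_win_s = 0.080, refractory_s = 0.150),
    stop_input("`mode` must be 'maternal' or 'fetal'")
  )
}

#' Pan-Tompkins QRS detection
#'
#' Classic QRS detector: band-pass filtering, five-point differentiation,
#' squaring, moving-window integration, and adaptive dual-threshold peak
#' search with search-back, followed by refinement of each detection to the
#' local extremum of the band-passed trace. Works on either polarity (the
#' squaring stage is sign-blind), which matters because blind source
#' separation recovers waveforms up to sign.
#'
#' The maternal parameter set uses the classic 5-15 Hz band with a 150 ms
#' integration window and 200 ms refractory period; the fetal set shifts to
#' 10-25 Hz, 80 ms and 150 ms to suit rates up to 180+ bpm. All are
#' overridable.
#'
#' @param x numeric waveform.
#' @param fs sampling frequency, Hz (>= 100).
#' @param mode `"maternal"` or `"fetal"` parameter set.
#' @param band,int_win_s,refractory_s optional overrides of the band-pass
#'   corners (Hz), integration window (s) and refractory period (s).
#' @return sorted integer vector of R-peak sample indices (1-based). When
#'   nothing is detected an empty vector is returned with a warning.
#' @export
pan_tompkins <- function(x, fs, mode = c("maternal", "fetal"),
                         band = NULL, int_win_s = NULL, refractory_s = NULL) {
  mode <- match.arg(mode)
  if (fs < 100) stop_input("`fs` must be at least 100 Hz for QRS detection")
  n <- length(x)
  if (n < 2 * fs) stop_input("signal shorter than 2 s; too short for QRS detection")
  par <- pt_defaults(mode)
  band <- band %||% par$band
  int_win_s <- int_win_s %||% par$int_win_s
  refractory_s <- refractory_s %||% par$refractory_s

  bp <- signal::butter(3, pmin(band / (fs / 2), 0.99), type = "pass")
  xf <- as.numeric(signal::filtfilt(bp, x))
  # five-point derivative (causal, 2-sample delay)
  h <- c(1, 2, 0, -2, -1) * (fs / 8)
  xd <- as.numeric(stats::filter(c(rep(0, 4), xf), h, method = "convolution",
                                 sides = 1))[-(1:4)]
  xd[is.na(xd)] <- 0
  xs <- xd^2
  win <- max(1L, as.integer(round(int_win_s * fs)))
  xi <- moving_sum(xs, win) / win
  refr <- max(1L, as.integer(round(refractory_s * fs)))

  # candidate local maxima of the integrated signal
  dxi <- diff(xi)
  cand <- which(diff(sign(dxi)) == -2) + 1L
  # a QRS right at the record edge leaves the integrator still rising; count
  # the final sample as a candidate so the last beat is not dropped
  if (dxi[n - 1L] > 0) cand <- c(cand, n)
  if (!length(cand) || max(xi) <= 0) {
    warn("no QRS candidates found; returning an empty peak set")
    return(integer(0))
  }

  # adaptive dual thresholds (running signal/noise peak estimates)
  learn <- xi[seq_len(min(n, 2L * round(fs)))]
  spki <- max(learn)
  npki <- mean(learn)
  thr1 <- npki + 0.25 * (spki - npki)
  accepted <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    idx <- cand[i]
    v <- xi[idx]
    if (idx - last >= refr) {
      if (v > thr1) {
        if (is.finite(last)) rr_hist <- c(rr_hist, idx - last)
        if (length(rr_hist) > 8L) rr_hist <- tail(rr_hist, 8L)
        accepted <- c(accepted, idx)
        last <- idx
        spki <- 0.125 * v + 0.875 * spki
      } else {
        npki <- 0.125 * v + 0.875 * npki
        # search-back: long gap without a peak -> retry at half threshold
        rr_avg <- if (length(rr_hist)) mean(rr_hist) else NA_real_
        if (!is.na(rr_avg) && idx - last > 1.66 * rr_avg && v > 0.5 * thr1) {
          if (is.finite(last)) rr_hist <- c(rr_hist, idx - last)
          if (length(rr_hist) > 8L) rr_hist <- tail(rr_hist, 8L)
          accepted <- c(accepted, idx)
          last <- idx
          spki <- 0.25 * v + 0.75 * spki
        }
      }
      thr1 <- npki + 0.25 * (spki - npki)
    }
    i <- i + 1L
  }
  if (!length(accepted)) {
    warn("no QRS peaks passed the adaptive threshold; returning an empty peak set")
    return(integer(0))
  }

  # refine: integration + derivative delay means the true R peak sits within
  # one window before the integrator maximum; take the band-passed extremum
  refined <- vapply(accepted, function(idx) {
    lo <- max(1L, idx - win - 2L)
    hi <- min(n, idx)
    lo + which.max(abs(xf[lo:hi])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement
  keep <- rep(TRUE, length(refined))
  last <- refined[1]
  for (k in seq_along(refined)[-1]) {
    if (refined[k] - last < refr) keep[k] <- FALSE else last <- refined[k]
  }
  refined[keep]
}

#' Inter-beat intervals and heart rates from R-peak indices
#'
#' Converts detected R-peak positions into inter-peak intervals
#' `dp(l) = p(l+1) - p(l)`, per-interval heart rates `60 * fs / dp`, and the
#' mean rate over all intervals. This is exact arithmetic on the indices.
#'
#' @param indices sorted integer vector of R-peak sample indices (>= 2 of
#'   them).
#' @param fs sampling frequency, Hz.
#' @return object of class `peak_set`: `indices`, `dp` (sample intervals),
#'   `rates_bpm`, `mean_rate_bpm`, `fs`, `count`.
#' @export
heart_rates <- function(indices, fs) {
  indices <- as.integer(indices)
  if (length(indices) < 2L) {
    stop_input("need at least two peaks to compute heart rates",
               class = "nsfecg_insufficient_data")
  }
  if (is.unsorted(indices, strictly = TRUE)) {
    stop_input("peak indices must be strictly increasing")
  }
  check_scalar_number(fs, "fs", lower = 1e-6)
  dp <- diff(indices)
  rates <- 60 * fs / dp
  structure(
    list(indices = indices, dp = dp, rates_bpm = rates,
         mean_rate_bpm = mean(rates), fs = fs, count = length(indices)),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks @ %g Hz, mean rate %.1f bpm\n",
              x$count, x$fs, x$mean_rate_bpm))
  invisible(x)
}

#' Detect R peaks and compute heart rates in one call
#'
#' @param x numeric waveform.
#' @param fs sampling frequency, Hz.
#' @param mode `"maternal"` or `"fetal"`.
#' @param ... passed to [pan_tompkins()].
#' @return a `peak_set` (see [heart_rates()]); errors if fewer than two peaks
#'   are found.
#' @export
detect_peaks <- function(x, fs, mode = c("maternal", "fetal"), ...) {
  mode <- match.arg(mode)
  idx <- pan_tompkins(x, fs, mode = mode, ...)
  heart_rates(idx, fs)
}
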