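#' Control-logic configuration for maternal-beat removal
#'
#' Residual maternal beats in the raw fetal trace shorten some fetal
#' inter-peak intervals, which both inflates the per-interval fetal heart
#' rates and blows up their variance. The control logic therefore activates
#' maternal-beat removal only when both the FHR level and the FHR variance
#' exceed their bounds.
#'
#' @param max_fhr maximum plausible fetal heart rate in bpm (default 180,
#'   appropriate from about 20 weeks of gestation).
#' @param max_var maximum variance of the per-interval FHR vector; values of
#'   1-5 are appropriate (default 3).
#' @return object of class `control_config`.
#' @export
control_config <- function(max_fhr = 180, max_var = 3) {
  check_scalar_number(max_fhr, "max_fhr", lower = 1e-9)
  check_scalar_number(max_var, "max_var", lower = 1e-9)
  structure(list(max_fhr = max_fhr, max_var = max_var), class = "control_config")
}

#' Decide whether maternal-beat removal is needed
#'
#' Returns `TRUE` iff `var(fhr) > max_var` **and** the fetal heart rate
#' exceeds `max_fhr`. The rate clause uses the mean FHR by default
#' (`mode = "mean"`); `mode = "any"` triggers when any single interval rate
#' exceeds the bound.
#'
#' @param fhr_vector per-interval fetal heart rates (bpm), length >= 2.
#' @param config a [control_config()].
#' @param mode `"mean"` (default) or `"any"`.
#' @return logical scalar.
#' @export
control_decision <- function(fhr_vector, config = control_config(),
                             mode = c("mean", "any")) {
  mode <- match.arg(mode)
  if (length(fhr_vector) < 2L) {
    stop_input("need at least two FHR values for the control decision",
               class = "nsfecg_insufficient_data")
  }
  rate_high <- if (mode == "mean") mean(fhr_vector) > config$max_fhr
               else any(fhr_vector > config$max_fhr)
  var(fhr_vector) > config$max_var && rate_high
}

#' Build the adaptive comb filter
#'
#' Constructs the length-`N` gain vector `h`: inside each window of half-width
#' `U` centred on a maternal R peak, `h(p + r) = a_r` with
#' `a_r = 0.46 - 0.46 * cos(2 * pi * r / (2U + 1))`, a valley-shaped window
#' whose gain is exactly zero at the peak itself; outside all windows `h = 1`
#' so the fetal signal passes unchanged. Overlapping windows combine by
#' pointwise minimum (the deepest attenuation wins) and windows near the
#' record edges are truncated.
#'
#' The default window equals one minus a centred Hamming window, so its gain
#' is exactly zero at the peak but only 0.92 at the window edge;
#' `shape = "hann_valley"` substitutes `0.5 - 0.5 * cos(.)`, which also zeroes
#' the peak but recovers unit gain at the window edge.
#'
#' @param p1 maternal R-peak sample indices (1-based); may be empty, in which
#'   case the filter is the identity.
#' @param U window half-width in samples (window length `2U + 1`); for 1 kHz
#'   data lengths of 20-45 samples are appropriate.
#' @param N record length in samples.
#' @param shape `"raised_cosine"` (default, zero gain at each peak) or
#'   `"hann_valley"`.
#' @return object of class `comb_filter`: `h` (length N, values in [0, 1]),
#'   `centers`, `U`, `window_coeffs` (the `a_r`, r = -U..U).
#' @export
build_acf <- function(p1, U, N, shape = c("raised_cosine", "hann_valley")) {
  shape <- match.arg(shape)
  check_scalar_number(U, "U", lower = 1)
  check_scalar_number(N, "N", lower = 1)
  U <- as.integer(U)
  N <- as.integer(N)
  p1 <- as.integer(p1)
  if (length(p1) && (min(p1) < 1L || max(p1) > N)) {
    stop_input("maternal peak indices out of range")
  }
  r <- seq.int(-U, U)
  a <- switch(shape,
    raised_cosine = 0.46 - 0.46 * cos(2 * pi * r / (2 * U + 1)),
    hann_valley = 0.5 - 0.5 * cos(2 * pi * r / (2 * U + 1))
  )
  a <- pmin(pmax(a, 0), 1)
  h <- rep(1, N)
  for (p in p1) {
    lo <- max(1L, p - U)
    hi <- min(N, p + U)
    seg <- lo:hi
    h[seg] <- pmin(h[seg], a[seg - p + U + 1L])
  }
  structure(
    list(h = h, centers = p1, U = U, window_coeffs = a, shape = shape),
    class = "comb_filter"
  )
}

#' Remove maternal beats from the raw fetal trace
#'
#' Pointwise multiplication of the raw FECG by the comb-filter gain vector:
#' samples at maternal peak centres are zeroed (the window gain there is 0),
#' samples outside all windows pass unchanged, and the output energy never
#' exceeds the input energy since all gains lie in [0, 1].
#'
#' @param raw_fecg numeric waveform, same length as the comb filter.
#' @param comb a [build_acf()] result.
#' @return the cleaned fetal waveform.
#' @export
remove_mecg <- function(raw_fecg, comb) {
  if (!inherits(comb, "comb_filter")) stop_input("`comb` must be a `comb_filter`")
  if (length(raw_fecg) != length(comb$h)) {
    stop_input(sprintf("waveform length %d does not match comb filter length %d",
                       length(raw_fecg), length(comb$h)))
  }
  raw_fecg * comb$h
}
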