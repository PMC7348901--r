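#' Denoising filter-bank configuration
#'
#' Three cascaded stages applied channel-wise before separation: a Butterworth
#' low-pass at `f1` (limits the ECG band), a Butterworth high-pass at `f2`
#' (removes baseline wander), and a second-order IIR notch at `f3` (removes
#' 50 or 60 Hz power-line interference, selected by regional standard).
#'
#' @param f1 low-pass cutoff in Hz (default 100).
#' @param f2 high-pass cutoff in Hz (default 0.5).
#' @param f3 notch frequency in Hz, 50 or 60 (default 50).
#' @param lowpass_order,highpass_order Butterworth orders (default 4).
#' @param notch_q notch quality factor; bandwidth is `f3 / notch_q`
#'   (default 30).
#' @param zero_phase apply each stage forward-backward (zero phase, default)
#'   so R-peak positions are not delayed; set `FALSE` for single-pass causal
#'   filtering.
#' @return object of class `filter_bank_config`.
#' @export
filter_bank_config <- function(f1 = 100, f2 = 0.5, f3 = 50,
                               lowpass_order = 4, highpass_order = 4,
                               notch_q = 30, zero_phase = TRUE) {
  check_scalar_number(f1, "f1", lower = 1e-9)
  check_scalar_number(f2, "f2", lower = 1e-9)
  check_scalar_number(f3, "f3", lower = 1e-9)
  check_scalar_number(notch_q, "notch_q", lower = 1e-9)
  if (!(f2 < f3 && f3 < f1)) {
    stop_input("filter cutoffs must satisfy f2 < f3 < f1",
               class = "nsfecg_configuration_error")
  }
  structure(
    list(f1 = f1, f2 = f2, f3 = f3,
         lowpass_order = as.integer(lowpass_order),
         highpass_order = as.integer(highpass_order),
         notch_q = notch_q, zero_phase = isTRUE(zero_phase)),
    class = "filter_bank_config"
  )
}

# second-order IIR notch biquad (constrained pole-zero design); unity gain in
# the passband, zero at f0
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  beta <- tan(w0 / (2 * q))
  gain <- 1 / (1 + beta)
  list(b = gain * c(1, -2 * cos(w0), 1),
       a = c(1, -2 * gain * cos(w0), 2 * gain - 1))
}

apply_stage <- function(x, b, a, zero_phase) {
  if (zero_phase) {
    as.numeric(signal::filtfilt(signal::Arma(b = b, a = a), x))
  } else {
    as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
  }
}

denoise_channel <- function(x, fs, config) {
  lp <- signal::butter(config$lowpass_order, config$f1 / (fs / 2), type = "low")
  hp <- signal::butter(config$highpass_order, config$f2 / (fs / 2), type = "high")
  nt <- design_notch(config$f3, fs, config$notch_q)
  y <- apply_stage(x, lp$b, lp$a, config$zero_phase)
  y <- apply_stage(y, hp$b, hp$a, config$zero_phase)
  y <- apply_stage(y, nt$b, nt$a, config$zero_phase)
  y - mean(y)
}

#' Denoise a record with the cascaded filter bank
#'
#' Applies low-pass, high-pass and power-line notch filtering to each channel
#' in cascade, then re-centres every channel to zero mean. The operation is
#' linear and stateless: identical input gives identical output.
#'
#' @param record a [multichannel_record()], a numeric matrix (channels x
#'   samples) or a numeric vector.
#' @param config a [filter_bank_config()].
#' @param fs sampling frequency in Hz; taken from the record when available.
#' @return same type as the input, filtered.
#' @export
denoise <- function(record, config = filter_bank_config(), fs = NULL) {
  if (!inherits(config, "filter_bank_config")) {
    stop_input("`config` must be a `filter_bank_config`",
               class = "nsfecg_configuration_error")
  }
  if (inherits(record, "multichannel_record")) fs <- record$fs
  if (is.null(fs)) stop_input("`fs` is required", class = "nsfecg_configuration_error")
  if (config$f1 >= fs / 2) {
    stop_input(sprintf("low-pass cutoff f1 = %g Hz is not below Nyquist (fs = %g Hz)",
                       config$f1, fs),
               class = "nsfecg_configuration_error")
  }
  if (inherits(record, "multichannel_record")) {
    record$X <- t(apply(record$X, 1L, denoise_channel, fs = fs, config = config))
    record
  } else if (is.matrix(record)) {
    t(apply(record, 1L, denoise_channel, fs = fs, config = config))
  } else {
    denoise_channel(as.numeric(record), fs, config)
  }
}
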