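#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a peak set into one row per detected beat
#'
#' @param x a `peak_set` from [heart_rates()].
#' @param ... unused.
#' @return tibble with `peak`, `index`, `time_s`, and the interval/rate to
#'   the following beat (`rr_samples`, `rr_s`, `rate_bpm`; NA on the last
#'   beat).
#' @export
tidy.peak_set <- function(x, ...) {
  tibble::tibble(
    peak = seq_len(x$count),
    index = x$indices,
    time_s = (x$indices - 1) / x$fs,
    rr_samples = c(x$dp, NA_integer_),
    rr_s = c(x$dp / x$fs, NA_real_),
    rate_bpm = c(x$rates_bpm, NA_real_)
  )
}

#' One-row summary of a peak set
#'
#' @param x a `peak_set`.
#' @param ... unused.
#' @return tibble with `count`, `mean_rate_bpm`, `sd_rate_bpm`,
#'   `var_rate_bpm`, `fs`.
#' @export
glance.peak_set <- function(x, ...) {
  tibble::tibble(
    count = x$count,
    mean_rate_bpm = x$mean_rate_bpm,
    sd_rate_bpm = sd(x$rates_bpm),
    var_rate_bpm = var(x$rates_bpm),
    fs = x$fs
  )
}

#' Tidy a multichannel record into long form
#'
#' @param x a [multichannel_record()].
#' @param ... unused.
#' @return tibble with `channel`, `role`, `time_s`, `value`.
#' @export
tidy.multichannel_record <- function(x, ...) {
  m <- nrow(x$X)
  nm <- rownames(x$X) %||% paste0("ch", seq_len(m))
  purrr::map_dfr(seq_len(m), function(i) {
    tibble::tibble(
      channel = nm[i], role = x$channel_roles[i],
      time_s = (seq_len(ncol(x$X)) - 1) / x$fs,
      value = x$X[i, ]
    )
  })
}

#' Tidy a pipeline run into long waveforms
#'
#' @param x an `fecg_run` from [run_pipeline()].
#' @param ... unused.
#' @return tibble with `signal` (`mecg`, `raw_fecg`, `clean_fecg`), `time_s`,
#'   `value`.
#' @export
tidy.fecg_run <- function(x, ...) {
  n <- length(x$clean_fecg)
  t_s <- (seq_len(n) - 1) / x$fs
  dplyr::bind_rows(
    tibble::tibble(signal = "mecg", time_s = t_s, value = x$mecg),
    tibble::tibble(signal = "raw_fecg", time_s = t_s, value = x$raw_fecg),
    tibble::tibble(signal = "clean_fecg", time_s = t_s, value = x$clean_fecg)
  )
}

#' One-row summary of a pipeline run
#'
#' @param x an `fecg_run`.
#' @param ... unused.
#' @return tibble with the method, maternal and fetal rates, peak counts and
#'   the control-logic verdict.
#' @export
glance.fecg_run <- function(x, ...) {
  tibble::tibble(
    method = x$manifest$method,
    mhr_bpm = if (is.null(x$maternal_peaks)) NA_real_ else x$maternal_peaks$mean_rate_bpm,
    fhr_bpm = if (is.null(x$fetal_peaks)) NA_real_ else x$fetal_peaks$mean_rate_bpm,
    maternal_beats = if (is.null(x$maternal_peaks)) 0L else x$maternal_peaks$count,
    fetal_beats = if (is.null(x$fetal_peaks)) 0L else x$fetal_peaks$count,
    control_applied = x$control_applied
  )
}

#' Plot a multichannel record
#'
#' @param object a [multichannel_record()].
#' @param ... unused.
#' @return a ggplot: channels stacked as facets over time.
#' @export
autoplot.multichannel_record <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("ECG mixture (%g Hz)", object$fs)) +
    ggplot2::theme_minimal()
}

#' Plot the waveforms of a pipeline run with detected peaks
#'
#' @param object an `fecg_run`.
#' @param ... unused.
#' @return a ggplot: maternal, raw fetal and clean fetal traces with the
#'   detected R peaks marked.
#' @export
autoplot.fecg_run <- function(object, ...) {
  df <- tidy(object)
  df$signal <- factor(df$signal, levels = c("mecg", "raw_fecg", "clean_fecg"))
  pk <- dplyr::bind_rows(
    if (!is.null(object$maternal_peaks)) tibble::tibble(
      signal = "mecg", time_s = (object$maternal_peaks$indices - 1) / object$fs),
    if (!is.null(object$fetal_peaks)) tibble::tibble(
      signal = "raw_fecg", time_s = (object$fetal_peaks$indices - 1) / object$fs)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$signal), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(pk)) {
    pk$signal <- factor(pk$signal, levels = levels(df$signal))
    p <- p + ggplot2::geom_vline(data = pk,
                                 ggplot2::aes(xintercept = .data$time_s),
                                 colour = "red", linetype = "dotted",
                                 linewidth = 0.25)
  }
  p
}

#' Plot a fetal-to-maternal SNR sweep
#'
#' @param sweep the tibble returned by [fmsnr_sweep()].
#' @return a ggplot of mean qSNR against fmSNR, one line per method.
#' @export
plot_fmsnr_sweep <- function(sweep) {
  df <- sweep |>
    dplyr::group_by(.data$fmsnr_db, .data$method) |>
    dplyr::summarise(qsnr_db = mean(.data$qsnr_db), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fmsnr_db, y = .data$qsnr_db,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fetal-to-maternal SNR (dB)", y = "qSNR (dB)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
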