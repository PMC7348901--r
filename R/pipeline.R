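#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end extraction pipeline; all defaults
#' follow the package-wide conventions (see the individual constructors).
#'
#' @param method extraction method: `"nsitm"` (default), `"pca"`,
#'   `"fastica"` or `"plp"`.
#' @param l_sources number of sources to recover (default 2: maternal +
#'   fetal).
#' @param filter a [filter_bank_config()].
#' @param control a [control_config()].
#' @param acf_window_ms adaptive comb filter window length in milliseconds
#'   (default 21 ms, i.e. 21 samples at 1 kHz; scaled by the record's
#'   sampling frequency and rounded to an odd number of samples).
#' @param order_by,select null-space ordering and selection rules, see
#'   [null_space_extract()].
#' @param control_mode `"mean"` or `"any"`, see [control_decision()].
#' @param acf_shape comb window shape, see [build_acf()].
#' @param seed seed forwarded to the seeded extractors (fastica, plp).
#' @param fastica,plp optional per-method settings: `fastica` a list with
#'   `max_iter`/`tol`, `plp` a [plp_config()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(method = c("nsitm", "pca", "fastica", "plp"),
                            l_sources = 2,
                            filter = filter_bank_config(),
                            control = control_config(),
                            acf_window_ms = 21,
                            order_by = "xp_spectrum",
                            select = "dominant",
                            control_mode = "mean",
                            acf_shape = "raised_cosine",
                            seed = 1L,
                            fastica = list(max_iter = 200, tol = 1e-6),
                            plp = plp_config()) {
  structure(
    list(method = match.arg(method), l_sources = as.integer(l_sources),
         filter = filter, control = control, acf_window_ms = acf_window_ms,
         order_by = order_by, select = select, control_mode = control_mode,
         acf_shape = acf_shape, seed = as.integer(seed),
         fastica = fastica, plp = plp),
    class = "pipeline_config"
  )
}

#' Extract source waveforms from a (preprocessed) mixture
#'
#' Unified front end over the four extractors. The input is denoised with the
#' configured filter bank, sources are recovered by the chosen method, and
#' rows are labelled maternal/fetal by estimated beat rate.
#'
#' @param record a [multichannel_record()].
#' @param method `"nsitm"`, `"pca"`, `"fastica"` or `"plp"`.
#' @param L number of sources (default 2).
#' @param config a [pipeline_config()]; its `method` is overridden by the
#'   `method` argument.
#' @param denoise_first run the filter bank before extraction (default TRUE).
#' @return a labelled `extracted_sources` object with `fs` attached.
#' @export
extract_sources <- function(record, method = c("nsitm", "pca", "fastica", "plp"),
                            L = 2, config = pipeline_config(),
                            denoise_first = TRUE) {
  method <- match.arg(method)
  if (!inherits(record, "multichannel_record")) {
    stop_input("`record` must be a `multichannel_record`")
  }
  rec <- if (denoise_first) denoise(record, config$filter) else record
  Xp <- rec$X
  src <- switch(method,
    nsitm = {
      itm <- compute_itm(Xp)
      null_space_extract(itm, L, order_by = config$order_by,
                         select = config$select)
    },
    pca = pca_extract(Xp, L, select = config$select),
    fastica = fastica_extract(Xp, L, seed = config$seed,
                              max_iter = config$fastica$max_iter,
                              tol = config$fastica$tol),
    plp = plp_extract(Xp, L, config = config$plp)
  )
  src <- label_sources(src, record$fs)
  src$fs <- record$fs
  src
}

#' Run the full fetal-ECG extraction pipeline
#'
#' End-to-end procedure: denoise the mixture, build the idempotent
#' transformation matrix and its null space (or run a baseline extractor),
#' recover and label the maternal and raw fetal waveforms, detect maternal
#' and fetal R peaks, compute both heart rates, and decide via the control
#' logic whether residual maternal beats contaminate the raw fetal trace. If
#' they do, the adaptive comb filter zeroes them; otherwise the raw fetal
#' trace passes through untouched.
#'
#' @param record a [multichannel_record()] with at least 2 channels.
#' @param config a [pipeline_config()].
#' @return object of class `fecg_run`: `clean_fecg`, `raw_fecg`, `mecg`
#'   (waveforms), `maternal_peaks` and `fetal_peaks` ([heart_rates()]
#'   objects, possibly NULL when detection found < 2 peaks),
#'   `control_applied`, `comb` (the comb filter or NULL), `sources`, `fs`,
#'   and a reproducibility `manifest`.
#' @export
run_pipeline <- function(record, config = pipeline_config()) {
  if (!inherits(record, "multichannel_record")) {
    stop_input("`record` must be a `multichannel_record`")
  }
  fs <- record$fs
  src <- extract_sources(record, method = config$method,
                         L = config$l_sources, config = config)
  raw_fecg <- src$Y[match("fecg_raw", src$labels), ]
  mecg <- src$Y[match("mecg", src$labels), ]
  n <- length(raw_fecg)

  maternal_peaks <- tryCatch(
    heart_rates(pan_tompkins(mecg, fs, mode = "maternal"), fs),
    error = function(e) NULL, warning = function(w) NULL
  )
  fetal_peaks <- tryCatch(
    heart_rates(pan_tompkins(raw_fecg, fs, mode = "fetal"), fs),
    error = function(e) NULL, warning = function(w) NULL
  )

  apply_removal <- FALSE
  if (!is.null(fetal_peaks) && !is.null(maternal_peaks)) {
    apply_removal <- control_decision(fetal_peaks$rates_bpm, config$control,
                                      mode = config$control_mode)
  }
  comb <- NULL
  fetal_peaks_raw <- fetal_peaks
  if (apply_removal) {
    win <- max(3L, round(config$acf_window_ms / 1000 * fs))
    if (win %% 2L == 0L) win <- win + 1L
    U <- (win - 1L) %/% 2L
    comb <- build_acf(maternal_peaks$indices, U, n, shape = config$acf_shape)
    clean_fecg <- remove_mecg(raw_fecg, comb)
    # the reported fetal beats come from the cleaned trace: the maternal
    # residual that triggered removal also corrupts the raw detections
    fetal_peaks <- tryCatch(
      heart_rates(pan_tompkins(clean_fecg, fs, mode = "fetal"), fs),
      error = function(e) fetal_peaks_raw, warning = function(w) fetal_peaks_raw
    )
  } else {
    clean_fecg <- raw_fecg
  }

  manifest <- build_manifest(record, config, decisions = list(
    control_applied = apply_removal,
    acf_window_samples = if (is.null(comb)) NA_integer_ else 2L * comb$U + 1L,
    suppressed_peaks = if (is.null(comb)) 0L else length(comb$centers),
    basis_indices = src$basis_indices,
    labels = src$labels
  ))
  structure(
    list(clean_fecg = clean_fecg, raw_fecg = raw_fecg, mecg = mecg,
         maternal_peaks = maternal_peaks, fetal_peaks = fetal_peaks,
         fetal_peaks_raw = fetal_peaks_raw,
         control_applied = apply_removal, comb = comb, sources = src,
         fs = fs, manifest = manifest),
    class = "fecg_run"
  )
}

#' @export
print.fecg_run <- function(x, ...) {
  cat(sprintf("<fecg_run> method %s, %d samples @ %g Hz\n",
              x$manifest$method, length(x$clean_fecg), x$fs))
  mhr <- if (is.null(x$maternal_peaks)) NA_real_ else x$maternal_peaks$mean_rate_bpm
  fhr <- if (is.null(x$fetal_peaks)) NA_real_ else x$fetal_peaks$mean_rate_bpm
  cat(sprintf("MHR %.1f bpm, FHR %.1f bpm, maternal-beat removal: %s\n",
              mhr, fhr, if (x$control_applied) "applied" else "not needed"))
  invisible(x)
}
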