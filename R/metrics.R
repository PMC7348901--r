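#' Similarity performance index (SPI)
#'
#' Per matched source pair, `10 * log10(<y,y> <s,s> / <y,s>^2 - 1)` averaged
#' over the `L` sources. The argument of the log is `1/rho^2 - 1` where `rho`
#' is the cosine similarity, so identical waveforms give `-Inf` (floored at
#' -300 dB), a squared correlation of 0.5 gives exactly 0 dB, and orthogonal
#' waveforms give `+Inf` (capped at +300 dB). More negative is more similar.
#' SPI is symmetric in its arguments and invariant to positive rescaling of
#' either; rows must be aligned (permutation and sign) beforehand, e.g. with
#' [align_sources()].
#'
#' @param Y L x N estimated sources (or a numeric vector for L = 1).
#' @param S L x N true sources, same shape.
#' @param cap dB cap for degenerate cases (default 300).
#' @return SPI in dB (scalar).
#' @export
spi <- function(Y, S, cap = 300) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  if (is.vector(S)) S <- matrix(S, nrow = 1)
  if (!all(dim(Y) == dim(S))) stop_input("`Y` and `S` must have matching shapes")
  vals <- vapply(seq_len(nrow(Y)), function(i) {
    y <- Y[i, ]; s <- S[i, ]
    yy <- sum(y * y); ss <- sum(s * s); ys <- sum(y * s)
    if (yy == 0 || ss == 0) {
      stop_input("degenerate (all-zero) waveform in SPI",
                 class = "nsfecg_degenerate_signal")
    }
    if (ys == 0) return(cap)               # orthogonal: no similarity at all
    arg <- yy * ss / ys^2 - 1
    if (arg <= 0) return(-cap)             # y is exactly proportional to s
    db10(arg)
  }, numeric(1))
  mean(cap_db(vals, cap))
}

#' BSS-eval orthogonal decomposition and SIR/SAR/SDR
#'
#' Decomposes an estimated waveform `y` into
#' `y = s_target + e_interf + e_noise + e_artif` by nested orthogonal
#' projections: `s_target` is the projection of `y` onto its matched true
#' source, `e_interf` adds the remaining span of all true sources,
#' `e_noise` adds the span of the true noise, and `e_artif` is the remainder.
#' The four parts sum to `y` exactly and are mutually orthogonal, so their
#' energies add up to the energy of `y`. Requires ground truth and is
#' therefore a simulation-only metric.
#'
#' @param y estimated waveform (numeric, length N).
#' @param S L x N matrix of true sources (rows).
#' @param noise optional true noise, a vector or channels x N matrix.
#' @param target row index of the matched true source; defaults to the row
#'   with maximal absolute correlation with `y`.
#' @param cap dB cap (default 300).
#' @return a list of class `bss_decomposition`: the four parts plus
#'   `sir_db`, `sar_db`, `sdr_db` and `target`.
#' @export
bss_eval <- function(y, S, noise = NULL, target = NULL, cap = 300) {
  if (is.vector(S)) S <- matrix(S, nrow = 1)
  if (length(y) != ncol(S)) stop_input("`y` and `S` lengths differ")
  if (is.null(noise)) {
    noise_m <- NULL
  } else {
    noise_m <- if (is.vector(noise)) matrix(noise, nrow = 1) else as.matrix(noise)
    if (ncol(noise_m) != length(y)) stop_input("noise length mismatch")
  }
  if (is.null(target)) {
    target <- which.max(abs(apply(S, 1L, function(s) {
      if (sd(s) == 0 || sd(y) == 0) 0 else cor(y, s)
    })))
  }
  s <- S[target, ]
  ss <- sum(s * s)
  if (ss == 0) stop_input("matched true source has zero energy",
                          class = "nsfecg_degenerate_signal")
  s_target <- (sum(y * s) / ss) * s

  proj_span <- function(y, rows) {
    # orthogonal projection of y onto the row space of `rows`
    sv <- svd(rows, nu = 0)
    keep <- sv$d > 1e-12 * max(sv$d)
    V <- sv$v[, keep, drop = FALSE]
    as.numeric(V %*% crossprod(V, y))
  }
  p_s <- proj_span(y, S)
  e_interf <- p_s - s_target
  if (is.null(noise_m)) {
    p_sn <- p_s
  } else {
    p_sn <- proj_span(y, rbind(S, noise_m))
  }
  e_noise <- p_sn - p_s
  e_artif <- y - p_sn

  en <- function(v) sum(v^2)
  sir <- cap_db(db10(en(s_target) / en(e_interf)), cap)
  sar <- cap_db(db10(en(s_target + e_interf + e_noise) / en(e_artif)), cap)
  sdr <- cap_db(db10(en(s_target) / en(e_interf + e_noise + e_artif)), cap)
  structure(
    list(s_target = s_target, e_interf = e_interf, e_noise = e_noise,
         e_artif = e_artif, sir_db = sir, sar_db = sar, sdr_db = sdr,
         target = target),
    class = "bss_decomposition"
  )
}

#' Quality signal-to-noise ratio (qSNR) of an extracted waveform
#'
#' `qSNR = 10 * log10( sum(s_hat^2) / sum((s_true - s_hat)^2) )` - note the
#' numerator uses the *estimate* (`form = "as_printed"`, the default);
#' `form = "conventional"` uses the true signal energy instead. The estimate
#' should be amplitude-aligned to the truth first (least-squares scale);
#' `scale_align = TRUE` does this internally.
#'
#' @param s_true true waveform.
#' @param s_hat estimated waveform, same length.
#' @param scale_align least-squares rescale `s_hat` onto `s_true` before
#'   evaluating (default `FALSE`; the formula assumes aligned inputs).
#' @param form `"as_printed"` or `"conventional"`.
#' @param cap dB cap (default 300): a perfect estimate gives +cap, a zero
#'   estimate -cap.
#' @return qSNR in dB (scalar).
#' @export
qsnr <- function(s_true, s_hat, scale_align = FALSE,
                 form = c("as_printed", "conventional"), cap = 300) {
  form <- match.arg(form)
  if (length(s_true) != length(s_hat)) stop_input("waveform lengths differ")
  if (scale_align) {
    denom <- sum(s_hat^2)
    if (denom == 0) return(-cap)
    s_hat <- s_hat * sum(s_true * s_hat) / denom
  }
  num <- if (form == "as_printed") sum(s_hat^2) else sum(s_true^2)
  den <- sum((s_true - s_hat)^2)
  if (num == 0) return(-cap)
  if (den == 0) return(cap)
  cap_db(db10(num / den), cap)
}

#' Align estimated sources to true sources
#'
#' Blind source separation recovers sources only up to permutation and sign.
#' This finds the row permutation maximising the total absolute correlation
#' between estimates and truth (exhaustive assignment, L <= 8), then flips
#' signs so every matched correlation is positive.
#'
#' @param Y L x N estimated sources.
#' @param S L x N true sources.
#' @return list with `Y` (aligned estimates), `perm` (such that aligned row i
#'   estimates `S[i, ]`), `signs`, and `correlations` (post-alignment, per
#'   row).
#' @export
align_sources <- function(Y, S) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  if (is.vector(S)) S <- matrix(S, nrow = 1)
  L <- nrow(S)
  if (nrow(Y) < L) stop_input("need at least as many estimates as true sources")
  cmat <- matrix(0, L, nrow(Y))
  for (i in seq_len(L)) {
    for (j in seq_len(nrow(Y))) {
      cmat[i, j] <- if (sd(S[i, ]) == 0 || sd(Y[j, ]) == 0) 0 else cor(S[i, ], Y[j, ])
    }
  }
  best <- NULL
  best_score <- -Inf
  for (p in all_permutations(nrow(Y))) {
    sel <- p[seq_len(L)]
    score <- sum(abs(cmat[cbind(seq_len(L), sel)]))
    if (score > best_score) { best_score <- score; best <- sel }
  }
  signs <- sign(cmat[cbind(seq_len(L), best)])
  signs[signs == 0] <- 1
  Ya <- Y[best, , drop = FALSE] * signs
  list(Y = Ya, perm = best, signs = signs,
       correlations = abs(cmat[cbind(seq_len(L), best)]))
}

#' Match detected peaks against reference peaks
#'
#' Greedy one-to-one matching: candidate (detected, reference) pairs within
#' the tolerance are taken in order of increasing distance, each peak used at
#' most once. Matched pairs are true positives, unmatched detections false
#' positives, unmatched references false negatives.
#'
#' @param detected,reference sorted integer vectors of peak sample indices.
#' @param tolerance_ms matching window, milliseconds (default 50, the usual
#'   convention for fetal QRS scoring).
#' @param fs sampling frequency, Hz.
#' @return object of class `detection_counts`: `TP`, `FP`, `FN`,
#'   `tolerance_ms`, `matches` (two-column matrix of matched indices).
#' @export
match_peaks <- function(detected, reference, tolerance_ms = 50, fs) {
  check_scalar_number(fs, "fs", lower = 1e-6)
  check_scalar_number(tolerance_ms, "tolerance_ms", lower = 0)
  detected <- as.integer(detected)
  reference <- as.integer(reference)
  tol <- tolerance_ms / 1000 * fs
  if (!length(detected) || !length(reference)) {
    counts <- list(TP = 0L, FP = length(detected), FN = length(reference),
                   tolerance_ms = tolerance_ms,
                   matches = matrix(integer(0), ncol = 2))
    return(structure(counts, class = "detection_counts"))
  }
  pairs <- expand.grid(d = seq_along(detected), r = seq_along(reference))
  pairs$dist <- abs(detected[pairs$d] - reference[pairs$r])
  pairs <- pairs[pairs$dist <= tol, , drop = FALSE]
  pairs <- pairs[order(pairs$dist, pairs$d, pairs$r), , drop = FALSE]
  used_d <- logical(length(detected))
  used_r <- logical(length(reference))
  matches <- matrix(integer(0), ncol = 2)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$d[k]; j <- pairs$r[k]
    if (!used_d[i] && !used_r[j]) {
      used_d[i] <- TRUE; used_r[j] <- TRUE
      matches <- rbind(matches, c(detected[i], reference[j]))
    }
  }
  structure(
    list(TP = sum(used_d), FP = sum(!used_d), FN = sum(!used_r),
         tolerance_ms = tolerance_ms, matches = matches),
    class = "detection_counts"
  )
}

#' Sensitivity, accuracy and positive predictive value
#'
#' `SE = 100 * TP / (TP + FN)`, `ACC = 100 * TP / (TP + FN + FP)`,
#' `PPV = 100 * TP / (TP + FP)`. Accepts a [match_peaks()] result or raw
#' counts. ACC never exceeds the smaller of SE and PPV.
#'
#' @param counts a `detection_counts` object, or ignored when `tp`, `fp`,
#'   `fn` are given directly.
#' @param tp,fp,fn raw counts (alternative to `counts`).
#' @return a one-row tibble with `tp`, `fp`, `fn`, `se_pct`, `acc_pct`,
#'   `ppv_pct`.
#' @export
detection_stats <- function(counts = NULL, tp = NULL, fp = NULL, fn = NULL) {
  if (!is.null(counts)) {
    if (!inherits(counts, "detection_counts")) {
      stop_input("`counts` must be a `detection_counts` (or pass tp/fp/fn)")
    }
    tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  }
  if (any(c(tp, fp, fn) < 0)) stop_input("counts must be non-negative")
  if (tp + fn == 0 || tp + fp == 0) {
    stop_input("detection statistics undefined: zero reference or zero detections",
               class = "nsfecg_undefined_statistic")
  }
  tibble::tibble(
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    se_pct = 100 * tp / (tp + fn),
    acc_pct = 100 * tp / (tp + fn + fp),
    ppv_pct = 100 * tp / (tp + fp)
  )
}

#' Full separation-quality report for an extraction run
#'
#' Aligns the extracted sources to the simulated ground truth (optimal
#' permutation and sign), then assembles every evaluation metric the package
#' computes: SPI over the aligned pairs, SIR/SAR/SDR from the BSS-eval
#' decomposition of the fetal estimate, qSNR of the fetal estimate
#' (least-squares amplitude aligned), and SE/ACC/PPV of fetal R-peak
#' detection against the true peak positions.
#'
#' @param sources an `extracted_sources` object (or bare matrix of estimates).
#' @param record the [multichannel_record()] carrying ground truth.
#' @param fetal_row index of the true fetal source row in `record$truth$S`
#'   (defaults to the row labelled `"fecg"`).
#' @param tolerance_ms peak-matching window (default 50 ms).
#' @param detected_fetal_peaks optional detected fetal peak indices; when
#'   missing they are detected on the aligned fetal estimate.
#' @return a one-row tibble of class `separation_report`.
#' @export
separation_report <- function(sources, record, fetal_row = NULL,
                              tolerance_ms = 50, detected_fetal_peaks = NULL) {
  if (is.null(record$truth) || is.null(record$truth$S)) {
    stop_input("separation metrics need simulated ground truth",
               class = "nsfecg_unavailable_metric")
  }
  Y <- if (inherits(sources, "extracted_sources")) sources$Y else as.matrix(sources)
  S <- record$truth$S
  fs <- record$fs
  labels <- record$truth$labels %||% rep("unknown", nrow(S))
  fetal_row <- fetal_row %||% match("fecg", labels)
  if (is.na(fetal_row)) stop_input("cannot identify the true fetal source row")

  al <- align_sources(Y, S)
  spi_db <- spi(al$Y, S)
  fetal_hat <- al$Y[fetal_row, ]
  dec <- bss_eval(fetal_hat, S, noise = record$truth$noise, target = fetal_row)
  q <- qsnr(S[fetal_row, ], fetal_hat, scale_align = TRUE)

  truth_peaks <- record$truth$r_peaks[[fetal_row]]
  stats <- NULL
  if (!is.null(truth_peaks)) {
    det <- detected_fetal_peaks %||% suppressWarnings(
      pan_tompkins(fetal_hat, fs, mode = "fetal"))
    counts <- match_peaks(det, truth_peaks, tolerance_ms, fs)
    stats <- tryCatch(detection_stats(counts), error = function(e) NULL)
  }
  out <- tibble::tibble(
    method = if (inherits(sources, "extracted_sources")) sources$method else "unknown",
    spi_db = spi_db, sir_db = dec$sir_db, sar_db = dec$sar_db,
    sdr_db = dec$sdr_db, qsnr_db = q,
    fetal_corr = al$correlations[fetal_row],
    se_pct = if (is.null(stats)) NA_real_ else stats$se_pct,
    acc_pct = if (is.null(stats)) NA_real_ else stats$acc_pct,
    ppv_pct = if (is.null(stats)) NA_real_ else stats$ppv_pct
  )
  attr(out, "alignment") <- list(perm = al$perm, signs = al$signs)
  class(out) <- c("separation_report", class(out))
  out
}
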