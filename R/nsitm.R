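#' Compute the idempotent transformation matrix (ITM)
#'
#' Builds `W = (1/N) t(Xp) %*% solve(Cx) %*% Xp` with
#' `Cx = (1/N) Xp %*% t(Xp)`, i.e. the symmetric orthogonal projector onto
#' the row space of the preprocessed mixture `Xp`. The separation matrix is
#' `Q = W - I`; its null space (the eigenvalue-1 eigenspace of W) contains
#' the source waveforms, which is what [null_space_extract()] exploits.
#'
#' A small ridge `lambda = 1e-10 * trace(Cx) / M` regularises `Cx` so that
#' rank-deficient mixtures (e.g. noiseless two-source data on five channels)
#' still yield an exact projector onto the numerical row space.
#'
#' The null-space basis is obtained from the thin SVD of `Xp` itself (the
#' right singular vectors span the row space), which avoids the N x N SVD of
#' `Q`; with `full = TRUE` the complete orthonormal matrix `Vq` and all N
#' singular values of `Q` are materialised (orthonormal completion by QR),
#' which is what the projector diagnostics use at small N.
#'
#' @param Xp numeric matrix, M channels x N samples, rows zero mean, N > M.
#' @param full materialise `Q`, the complete `Vq` and all N singular values
#'   of `Q`; defaults to `TRUE` for N <= 1500. The null-space block and `W`
#'   are always available.
#' @param rank_tol relative singular-value threshold of `Xp` defining its
#'   numerical rank (default 1e-8).
#' @param max_n memory guard: refuse records longer than this many samples
#'   (W is N x N); default 20000.
#' @return object of class `itm_result` with elements `W`, `Q` (NULL unless
#'   `full`), `singular_values` (of `Q`, descending; null block only unless
#'   `full`), `Vq` (full N x N when `full`, otherwise the N x r null-space
#'   block), `nullspace_basis` (N x r, columns ordered by decreasing energy
#'   of `Xp` along them), `xp_singular_values`, `nullspace_dim`, `n`, `m`.
#' @export
compute_itm <- function(Xp, full = NULL, rank_tol = 1e-8, max_n = 20000) {
  Xp <- as.matrix(Xp)
  m <- nrow(Xp)
  n <- ncol(Xp)
  if (n <= m) stop_input("`Xp` must have more samples than channels (N > M)")
  if (n > max_n) {
    stop_input(sprintf(
      "record too long for an explicit N x N projector (N = %d > %d); process in windows",
      n, max_n), class = "nsfecg_memory_guard")
  }
  rmeans <- rowMeans(Xp)
  if (max(abs(rmeans)) > 1e-6 * max(1, max(abs(Xp)))) {
    Xp <- Xp - rmeans
  }
  full <- full %||% (n <= 1500)

  Cx <- tcrossprod(Xp) / n
  lambda <- 1e-10 * sum(diag(Cx)) / m
  Cx_reg <- Cx + diag(lambda, m)
  kappa <- tryCatch(kappa(Cx_reg, exact = FALSE), error = function(e) Inf)
  sol <- tryCatch(solve(Cx_reg, Xp), error = function(e) NULL)
  if (is.null(sol)) {
    stop_input(sprintf(
      "covariance is numerically singular beyond regularisation (condition number %.3g)",
      kappa), class = "nsfecg_numerical_rank")
  }
  W <- crossprod(Xp, sol) / n

  sx <- svd(Xp, nu = 0, nv = m)        # right singular vectors span row(Xp)
  d <- sx$d
  r <- sum(d > rank_tol * d[1])
  if (r == 0) stop_input("`Xp` has no numerical rank (zero input?)",
                         class = "nsfecg_numerical_rank")
  basis <- sx$v[, seq_len(r), drop = FALSE]   # descending Xp spectrum

  # singular values of Q on the null block, computed against the actual W
  qb <- W %*% basis - basis
  sv_null <- sqrt(colSums(qb^2))

  if (full) {
    Vfull <- qr.Q(qr(basis), complete = TRUE)
    compl <- Vfull[, setdiff(seq_len(n), seq_len(r)), drop = FALSE]
    Vq <- cbind(compl, basis)                 # null block last, as an SVD orders it
    Q <- W
    diag(Q) <- diag(Q) - 1
    qv <- Q %*% Vq
    sv <- sqrt(colSums(qv^2))
  } else {
    Vq <- basis
    Q <- NULL
    sv <- sv_null
  }

  structure(
    list(W = W, Q = Q,
         singular_values = sv,
         Vq = Vq,
         nullspace_basis = basis,
         xp_singular_values = d[seq_len(r)],
         nullspace_dim = r,
         ridge = lambda, condition_number = kappa,
         n = n, m = m, full = full),
    class = "itm_result"
  )
}

#' @export
print.itm_result <- function(x, ...) {
  cat(sprintf("<itm_result> W: %d x %d projector, rank %d (M = %d channels)\n",
              x$n, x$n, x$nullspace_dim, x$m))
  cat(sprintf("null-space singular values of Q: max %.3g\n",
              max(tail(x$singular_values, x$nullspace_dim))))
  invisible(x)
}

# apply Q = W - I to the columns of V without materialising Q
itm_apply_q <- function(itm, V) itm$W %*% V - V

#' Recover source waveforms from the null space of Q
#'
#' Selects `L` orthonormal vectors from the null space of `Q = W - I` (the
#' row space of the preprocessed mixture). The basis is ordered by the energy
#' of `Xp` along each direction, descending, so the first direction is the
#' dominant (maternal) component. By default the `L` dominant directions are
#' returned (`select = "dominant"`): under additive channel noise the row
#' space has dimension M and its minor directions carry noise rather than the
#' weak fetal source, so the fetal component is found among the leading
#' directions (typically the second). `select = "minor"` returns the trailing
#' directions instead; the two choices coincide when the mixture is noiseless
#' and the numerical null space has dimension L.
#'
#' @param itm an [compute_itm()] result.
#' @param L number of sources to recover (must not exceed the null-space
#'   dimension).
#' @param order_by `"xp_spectrum"` (default) orders the null-space basis by
#'   the singular spectrum of `Xp`; `"svd_native"` keeps the basis exactly as
#'   stored (which is the same ordering for this construction).
#' @param select `"dominant"` (default) or `"minor"`, see Details.
#' @return object of class `extracted_sources`: `Y` (L x N, unit-norm rows),
#'   `labels` (initially `"unassigned"`), `basis_indices`, `method`.
#' @export
null_space_extract <- function(itm, L,
                               order_by = c("xp_spectrum", "svd_native"),
                               select = c("dominant", "minor")) {
  if (!inherits(itm, "itm_result")) stop_input("`itm` must be an `itm_result`")
  order_by <- match.arg(order_by)
  select <- match.arg(select)
  r <- itm$nullspace_dim
  if (r >= itm$n) {
    stop_input("W is (numerically) the identity: the null space of Q is the whole space",
               class = "nsfecg_degenerate_input")
  }
  if (L > r) {
    stop_input(sprintf("requested L = %d sources but the null space has dimension %d",
                       L, r), class = "nsfecg_dimensionality_error")
  }
  basis <- itm$nullspace_basis   # already in descending Xp-spectrum order
  idx <- if (select == "dominant") seq_len(L) else seq.int(r - L + 1L, r)
  Y <- t(basis[, idx, drop = FALSE])
  resid <- frob(itm_apply_q(itm, t(Y)))
  if (resid > 1e-6) {
    stop_input(sprintf("null-space residual ||Q Y'|| = %.3g exceeds 1e-6", resid),
               class = "nsfecg_numerical_rank")
  }
  Y <- unit_rows(Y)
  structure(
    list(Y = Y, labels = rep("unassigned", L), basis_indices = idx,
         method = "nsitm", order_by = order_by, select = select,
         null_residual = resid),
    class = "extracted_sources"
  )
}

#' @export
print.extracted_sources <- function(x, ...) {
  cat(sprintf("<extracted_sources> %d x %d (%s)\n",
              nrow(x$Y), ncol(x$Y), x$method))
  cat("labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# dominant beat rate (bpm) via autocorrelation of the rectified, band-passed
# trace; NA when no periodicity is found in the physiological band
estimate_rate <- function(x, fs, rate_range = c(40, 220)) {
  n <- length(x)
  if (n < 2 * fs) return(NA_real_)
  bp <- tryCatch(
    signal::butter(3, pmin(c(5, 25) / (fs / 2), 0.99), type = "pass"),
    error = function(e) NULL
  )
  env <- if (is.null(bp)) x^2 else
    as.numeric(signal::filtfilt(bp, x))^2
  ac <- stats::acf(env, lag.max = floor(60 / rate_range[1] * fs),
                   plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lo <- max(2L, floor(60 / rate_range[2] * fs))
  hi <- length(ac) - 1L
  if (hi <= lo) return(NA_real_)
  lag_vals <- ac[(lo + 1L):(hi + 1L)]        # acf[k+1] is lag k
  lags <- lo:hi
  # first strong local maximum (morphology side-lobes stay below 70 % of the
  # beat-period peak), else the global maximum
  is_peak <- c(FALSE, diff(sign(diff(lag_vals))) == -2, FALSE)
  cand <- which(is_peak & lag_vals > pmax(0.2, 0.7 * max(lag_vals)))
  best <- if (length(cand)) cand[1] else which.max(lag_vals)
  60 * fs / lags[best]
}

#' Label extracted sources as fetal or maternal
#'
#' The fetal heart beats faster than the maternal heart, so the row with the
#' higher estimated beat rate is labelled `fecg_raw` and its counterpart
#' `mecg`. Rates are estimated by autocorrelation of the rectified band-passed
#' trace; ties are broken by the dominant spectral frequency.
#'
#' @param sources an `extracted_sources` object with at least two rows.
#' @param fs sampling frequency in Hz.
#' @return `sources` with `labels` filled in (`fecg_raw`, `mecg`; additional
#'   rows stay `unassigned`) and estimated `rates_bpm` attached.
#' @export
label_sources <- function(sources, fs) {
  if (!inherits(sources, "extracted_sources")) {
    stop_input("`sources` must be an `extracted_sources`")
  }
  Lr <- nrow(sources$Y)
  if (Lr < 2L) {
    stop_input("source labelling needs at least two rows",
               class = "nsfecg_labelling_error")
  }
  rates <- vapply(seq_len(Lr), function(i) estimate_rate(sources$Y[i, ], fs),
                  numeric(1))
  if (all(is.na(rates))) {
    sources$labels <- rep("unassigned", Lr)
    stop_input("beat-rate estimation failed on every row; cannot label sources",
               class = "nsfecg_labelling_error")
  }
  dom_freq <- vapply(seq_len(Lr), function(i) {
    sp <- Mod(fft(sources$Y[i, ]))^2
    n <- length(sp)
    freqs <- (seq_len(n) - 1) * fs / n
    keep <- freqs > 0.5 & freqs < fs / 2
    freqs[keep][which.max(sp[keep])]
  }, numeric(1))
  key <- ifelse(is.na(rates), -Inf, rates) + 1e-6 * dom_freq
  fet <- which.max(key)
  mat <- setdiff(order(key, decreasing = FALSE), fet)[1]
  labels <- rep("unassigned", Lr)
  labels[fet] <- "fecg_raw"
  labels[mat] <- "mecg"
  sources$labels <- labels
  sources$rates_bpm <- rates
  sources
}
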