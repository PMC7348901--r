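# eigenvalue whitening of a channels x samples matrix; keeps components whose
# covariance eigenvalue exceeds tol * max
whiten_rows <- function(Xp, n_keep = NULL, tol = 1e-10) {
  Xp <- as.matrix(Xp)
  Xp <- Xp - rowMeans(Xp)
  n <- ncol(Xp)
  Cx <- tcrossprod(Xp) / n
  eg <- eigen(Cx, symmetric = TRUE)
  keep <- which(eg$values > tol * max(eg$values))
  if (!is.null(n_keep)) {
    if (length(keep) < n_keep) {
      stop_input(sprintf(
        "covariance has numerical rank %d; cannot whiten to %d components",
        length(keep), n_keep), class = "nsfecg_numerical_rank")
    }
    keep <- keep[seq_len(n_keep)]
  }
  Wmat <- diag(1 / sqrt(eg$values[keep]), length(keep)) %*% t(eg$vectors[, keep, drop = FALSE])
  list(Z = Wmat %*% Xp, whitening = Wmat,
       eigenvalues = eg$values, kept = keep)
}

as_extracted <- function(Y, method, extra = list()) {
  structure(
    c(list(Y = unit_rows(as.matrix(Y)),
           labels = rep("unassigned", nrow(Y)),
           basis_indices = NULL, method = method),
      extra),
    class = "extracted_sources"
  )
}

#' PCA-whitening source extraction
#'
#' Whitens the preprocessed mixture (`Y = Cx^{-1/2} Xp`) and returns `L` of
#' the whitened components, which are mutually uncorrelated by construction.
#' By default the `L` components along the largest-variance principal
#' directions are returned (maternal first, then fetal on typical abdominal
#' mixtures); `select = "minor"` returns the smallest-variance components.
#'
#' @param Xp numeric matrix, M channels x N samples, rows zero mean.
#' @param L number of components to return.
#' @param select `"dominant"` (default) or `"minor"`.
#' @return an `extracted_sources` object (unit-norm rows).
#' @export
pca_extract <- function(Xp, L, select = c("dominant", "minor")) {
  select <- match.arg(select)
  wh <- whiten_rows(Xp)
  m <- nrow(wh$Z)
  if (L > m) {
    stop_input(sprintf("requested L = %d components but whitened rank is %d", L, m),
               class = "nsfecg_numerical_rank")
  }
  idx <- if (select == "dominant") seq_len(L) else seq.int(m - L + 1L, m)
  as_extracted(wh$Z[idx, , drop = FALSE], "pca",
               extra = list(eigenvalues = wh$eigenvalues, component_indices = idx))
}

#' Fixed-point ICA source extraction
#'
#' Symmetric fixed-point independent component analysis with the log-cosh
#' contrast: the mixture is whitened to `L` dominant components, a seeded
#' random orthonormal unmixing matrix is iterated with symmetric
#' (eigenvalue-based) orthogonalisation until the update stalls, and the
#' resulting maximally non-Gaussian components are returned. Deterministic
#' under a fixed seed. When every component looks Gaussian (near-zero excess
#' kurtosis) the decomposition is not identifiable; a warning is raised and
#' the components are returned anyway.
#'
#' @param Xp numeric matrix, M channels x N samples.
#' @param L number of components.
#' @param seed integer seed for the initial unmixing matrix.
#' @param max_iter,tol iteration cap (default 200) and convergence threshold
#'   on the rotation update (default 1e-6).
#' @return an `extracted_sources` object (unit-norm rows) with a
#'   `converged` flag.
#' @export
fastica_extract <- function(Xp, L, seed = 1L, max_iter = 200, tol = 1e-6) {
  wh <- whiten_rows(Xp, n_keep = L)
  Z <- wh$Z
  n <- ncol(Z)
  # whitened rows have unit variance; rescale so cov(Z) = I exactly in the
  # 1/N convention used below
  W <- withr::with_seed(as.integer(seed), matrix(rnorm(L * L), L, L))
  sym_orth <- function(M) {
    s <- M %*% t(M)
    eg <- eigen(s, symmetric = TRUE)
    eg$vectors %*% diag(1 / sqrt(pmax(eg$values, 1e-300)), L) %*% t(eg$vectors) %*% M
  }
  W <- sym_orth(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Y <- W %*% Z
    G <- tanh(Y)
    gprime <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / n - diag(gprime, L) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("fixed-point ICA did not converge in %d iterations; returning best iterate",
                 max_iter))
  }
  Y <- W %*% Z
  kurt <- apply(Y, 1L, function(y) mean(y^4) / mean(y^2)^2 - 3)
  if (all(abs(kurt) < 0.1)) {
    warn("all components are near-Gaussian; ICA decomposition is not identifiable")
  }
  as_extracted(Y, "fastica",
               extra = list(converged = converged, iterations = it,
                            excess_kurtosis = kurt, unmixing = W %*% wh$whitening))
}

#' Parallel-linear-predictor configuration
#'
#' @param mu_y gradient-descent learning rate (default 0.02).
#' @param max_iters iteration cap (default 2000).
#' @param tol convergence threshold on the update norm (default 1e-5).
#' @param seed integer seed for the initial extractors (random init only).
#' @param init `"pca"` (identity in the whitened coordinates, deterministic,
#'   default) or `"random"` (seeded).
#' @return object of class `plp_config`.
#' @export
plp_config <- function(mu_y = 0.02, max_iters = 2000, tol = 1e-5,
                       seed = 1L, init = c("pca", "random")) {
  check_scalar_number(mu_y, "mu_y", lower = 0)
  check_scalar_number(max_iters, "max_iters", lower = 1)
  check_scalar_number(tol, "tol", lower = 0)
  structure(
    list(mu_y = mu_y, max_iters = as.integer(max_iters), tol = tol,
         seed = as.integer(seed), init = match.arg(init)),
    class = "plp_config"
  )
}

#' Parallel-linear-predictor (PLP) source extraction
#'
#' A bank of `L` linear predictors working in parallel on the whitened
#' mixture: each extractor's output is its own one-step linear prediction
#' target, and the extractors descend the prediction-error energy by gradient
#' steps of size `mu_y`, with symmetric decorrelation keeping the bank
#' orthogonal in the whitened coordinates. Quasi-periodic sources are highly
#' predictable, so the bank converges to temporally structured components
#' (the maternal trace first, the fetal trace in the orthogonal extractor).
#' The printed signal-space update `y <- y + mu_y (R - I) E_r`, with `R` the
#' Gram operator of the whitened data, only moves `y` through the whitened
#' row space; the implementation performs the equivalent projected update
#' directly in whitening coordinates. Iteration stops when the update norm
#' falls below `tol`; a divergence error names `mu_y` when the update norm
#' grows for 10 consecutive iterations.
#'
#' @param Xp numeric matrix, M channels x N samples.
#' @param L number of sources.
#' @param config a [plp_config()].
#' @return an `extracted_sources` object (unit-norm rows) with `iterations`
#'   and `converged` fields.
#' @export
plp_extract <- function(Xp, L, config = plp_config()) {
  if (!inherits(config, "plp_config")) stop_input("`config` must be a `plp_config`")
  wh <- whiten_rows(Xp, n_keep = L)
  Z <- wh$Z
  n <- ncol(Z)
  sym_orth <- function(M) {
    s <- M %*% t(M)
    eg <- eigen(s, symmetric = TRUE)
    eg$vectors %*% diag(1 / sqrt(pmax(eg$values, 1e-300)), nrow(M)) %*% t(eg$vectors) %*% M
  }
  Wc <- if (config$init == "pca") diag(L) else {
    withr::with_seed(config$seed, matrix(rnorm(L * L), L, L))
  }
  Wc <- sym_orth(Wc)
  if (config$mu_y == 0) {
    return(as_extracted(Wc %*% Z, "plp",
                        extra = list(converged = TRUE, iterations = 0L)))
  }
  grow <- 0L
  prev_delta <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(config$max_iters)) {
    Y <- Wc %*% Z
    Grad <- matrix(0, L, L)
    for (mrow in seq_len(L)) {
      y <- Y[mrow, ]
      y_lag <- c(0, y[-n])
      a <- sum(y[-1] * y[-n]) / max(sum(y[-n]^2), 1e-300)
      e <- y - a * y_lag                 # one-step prediction error
      e_adj <- e - a * c(e[-1], 0)       # adjoint of (I - a * shift)
      Grad[mrow, ] <- 2 * (Z %*% e_adj) / n
    }
    Wnew <- sym_orth(Wc - config$mu_y * Grad)
    delta <- frob(Wnew - Wc)
    Wc <- Wnew
    # converged: update below tol, or stalled on the orthogonality ridge
    # (the constrained step size stops changing)
    if (delta < config$tol ||
        (is.finite(prev_delta) && abs(delta - prev_delta) < 1e-4 * delta)) {
      converged <- TRUE; break
    }
    if (delta > 1.2 * prev_delta) grow <- grow + 1L else grow <- 0L
    if (grow >= 10L) {
      stop_input(sprintf(
        "PLP iteration diverging (update norm grew 10 times in a row); reduce mu_y = %g",
        config$mu_y), class = "nsfecg_divergence")
    }
    prev_delta <- delta
  }
  as_extracted(Wc %*% Z, "plp",
               extra = list(converged = converged, iterations = it))
}
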