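#' @importFrom rlang abort warn %||%
#' @importFrom stats var sd cor fft rnorm runif median quantile
NULL

# signal power = mean squared amplitude
signal_power <- function(x) mean(x^2)

db10 <- function(ratio) 10 * log10(ratio)

# cap a dB value into [-cap, cap]; NaN/Inf from degenerate ratios collapse to
# the signed cap so reports stay finite and comparable
cap_db <- function(x, cap = 300) {
  x[is.nan(x)] <- -cap
  pmin(pmax(x, -cap), cap)
}

stop_input <- function(msg, class = "nsfecg_input_error") {
  abort(msg, class = c(class, "nsfecg_error"))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_input(sprintf(
      "`%s` must be a single number in [%s, %s] (got %s)",
      name, format(lower), format(upper), paste(format(x), collapse = ", ")
    ), class = "nsfecg_parameter_error")
  }
  invisible(x)
}

# all permutations of 1..n, as a list; guarded so alignment never explodes
all_permutations <- function(n) {
  if (n > 8L) stop_input("permutation alignment supports at most 8 sources")
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

frob <- function(m) sqrt(sum(m^2))

unit_rows <- function(Y) {
  nrm <- sqrt(rowSums(Y^2))
  nrm[nrm == 0] <- 1
  Y / nrm
}

# moving average with a causal window (used by the QRS detector)
moving_sum <- function(x, width) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  idx <- seq_len(n)
  lo <- pmax(idx - width, 0L)
  cs[idx + 1L] - cs[lo + 1L]
}
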