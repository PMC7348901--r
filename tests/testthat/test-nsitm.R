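test_that("the single-channel projector matches the hand-computed outer product", {
  x <- c(1, -1, 0, 0)                     # zero mean
  itm <- compute_itm(matrix(x, 1))
  W_expected <- outer(x, x) / 2           # x' x / ||x||^2, here ||x||^2 = 2
  expect_equal(itm$W, W_expected, tolerance = 1e-8)
  expect_equal(itm$W %*% itm$W, itm$W, tolerance = 1e-8)
  expect_equal(sum(diag(itm$W)), 1, tolerance = 1e-8)
})

test_that("projector trace equals the channel count and orthonormal rows cancel Cx", {
  Xp <- random_xp(3, 50, seed = 4L)
  itm <- compute_itm(Xp)
  expect_equal(sum(diag(itm$W)), 3, tolerance = 1e-8)
  # orthonormal rows: W reduces to Xp' Xp
  Q_rows <- qr.Q(qr(t(random_xp(3, 60, seed = 5L))))[, 1:3]
  Xo <- t(Q_rows)
  Xo <- Xo - rowMeans(Xo)                 # keep rows zero mean
  Xo <- t(qr.Q(qr(t(Xo)))[, 1:3])         # re-orthonormalise after centring
  itm2 <- compute_itm(Xo)
  expect_equal(itm2$W, crossprod(Xo), tolerance = 1e-6)
})

test_that("eigenvalues of W cluster at 0 and 1 and Q's singular values match", {
  Xp <- random_xp(4, 120, seed = 6L)
  itm <- compute_itm(Xp, full = TRUE)
  ev <- eigen(itm$W, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(abs(ev) < 1e-6 | abs(ev - 1) < 1e-6))
  expect_equal(sum(ev > 0.5), 4L)
  expect_true(all(abs(itm$singular_values) < 1e-6 |
                  abs(itm$singular_values - 1) < 1e-6))
  expect_equal(itm$nullspace_dim, 4L)
})

test_that("null-space extraction agrees with a brute-force eigendecomposition", {
  # oracle: eigenvectors of W with eigenvalue ~1 span the same subspace
  for (seed in 1:5) {
    m <- sample(2:5, 1)
    Xp <- random_xp(m, 150, seed = 100L + seed)
    itm <- compute_itm(Xp)
    src <- null_space_extract(itm, m)
    eg <- eigen(itm$W, symmetric = TRUE)
    oracle <- eg$vectors[, eg$values > 0.5, drop = FALSE]
    # principal angles between the two m-dimensional subspaces
    sv <- svd(crossprod(oracle, t(src$Y)))$d
    angles <- acos(pmin(pmax(sv, -1), 1))
    expect_lt(max(angles), 1e-6)
    expect_equal(src$Y %*% t(src$Y), diag(m), tolerance = 1e-8)
    expect_lt(src$null_residual, 1e-6)
  }
})

test_that("two orthogonal channels are recovered exactly (L = nullspace dim)", {
  base <- random_xp(2, 80, seed = 7L)
  Xp <- t(qr.Q(qr(t(base)))[, 1:2])       # orthonormal rows
  Xp <- Xp - rowMeans(Xp)
  itm <- compute_itm(Xp)
  src <- null_space_extract(itm, 2)
  sv <- svd(tcrossprod(src$Y, Xp))$d / sqrt(rowSums(Xp^2))
  expect_lt(max(acos(pmin(sv, 1))), 1e-4) # same plane
})

test_that("noiseless mixtures are separated with high fidelity", {
  rec <- small_mixture(seed = 3L, m = 4)
  rd <- denoise(rec)
  itm <- compute_itm(rd$X)
  src <- null_space_extract(itm, 2)
  cm <- abs(cor(t(src$Y), t(rec$truth$S)))
  expect_gte(max(cm[, 1]), 0.95)   # maternal found in one row
  expect_gte(max(cm[, 2]), 0.95)   # fetal found in another
})

test_that("degenerate and out-of-range requests fail loudly", {
  Xp <- random_xp(3, 40, seed = 8L)
  itm <- compute_itm(Xp)
  expect_error(null_space_extract(itm, 5), class = "nsfecg_dimensionality_error")
  expect_error(compute_itm(matrix(rnorm(4 * 30000), 4)),
               class = "nsfecg_memory_guard")
  expect_error(compute_itm(matrix(0, 2, 20)), class = "nsfecg_numerical_rank")
})

test_that("rate-based labelling tags the faster row as fetal", {
  mat <- generate_source(ecg_source_spec(82, 250, 20, seed = 1L))$signal
  fet <- generate_source(fetal_spec(rate_bpm = 141, duration_s = 20))$signal
  src <- nsfecg:::as_extracted(rbind(mat, fet), "test")
  out <- label_sources(src, 250)
  expect_equal(out$labels, c("mecg", "fecg_raw"))
  # swapped rows swap the labels
  out2 <- label_sources(nsfecg:::as_extracted(rbind(fet, mat), "test"), 250)
  expect_equal(out2$labels, c("fecg_raw", "mecg"))
  expect_error(label_sources(nsfecg:::as_extracted(matrix(fet, 1), "test"), 250),
               class = "nsfecg_labelling_error")
})

test_that("labels match ground truth end to end on simulated mixtures", {
  for (seed in c(2L, 5L)) {
    rec <- small_mixture(seed = seed, m = 5)
    src <- extract_sources(rec, method = "nsitm", L = 2)
    al <- align_sources(src$Y, rec$truth$S)
    # truth row 2 is fetal; the aligned fetal estimate must carry the label
    expect_equal(src$labels[al$perm[2]], "fecg_raw")
  }
})
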