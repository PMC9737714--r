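make_band_spectra <- function(k, n_bins = 16, seed = 1) {
  out <- lapply(seq_along(mcsv:::csv_band_order), function(b) {
    lapply(seq_len(k), function(s) random_spectrum(n_bins, seed = seed + 100 * b + s))
  })
  names(out) <- mcsv:::csv_band_order
  out
}

test_that("feature map has 6 rows in the alpha..full order and k columns", {
  bs <- make_band_spectra(10)
  fm <- build_feature_map(bs, fpa_config(rng_seed = 1), channel = "C3")
  expect_equal(dim(fm$values), c(6L, 10L))
  expect_identical(rownames(fm$values),
                   c("alpha", "beta", "gamma", "theta", "delta", "full"))
  expect_equal(dim(fm$validity), c(6L, 10L))

  fm0 <- build_feature_map(make_band_spectra(0), fpa_config(rng_seed = 1))
  expect_equal(ncol(fm0$values), 0L)

  bs_missing <- bs[-3]
  expect_error(build_feature_map(bs_missing, fpa_config()), "missing band")
})

test_that("sentinel cells are imputed as 0 Hz and flagged invalid", {
  bs <- make_band_spectra(2)
  flat <- structure(list(freqs = 0:9, psd = rep(1, 10), ps_avg = 1),
                    class = "band_spectrum")
  bs$gamma[[2]] <- flat
  fm <- build_feature_map(bs, fpa_config(rng_seed = 4))
  expect_equal(unname(fm$values["gamma", 2]), 0)
  expect_false(fm$validity["gamma", 2])
  expect_true(all(fm$validity["gamma", 1]))
})

test_that("an injected 130 Hz burst drives the gamma-row CSV above 120 Hz", {
  fs <- 400
  t <- (0:1599) / fs
  gamma_seg <- 2 * sin(2 * pi * 130 * t) + 0.3 * mcsv:::with_seed(8, rnorm(1600))
  sp <- compute_psd(gamma_seg, fs, band_definition("gamma", 30, 200))
  res <- compute_csv(sp, fpa_config(rng_seed = 1))
  expect_true(res$valid)
  expect_gt(res$frequency, 120)
})

test_that("channel matrix is the pairwise |CSV difference| with CSVs on the diagonal", {
  mk_map <- function(ch, v) {
    structure(list(channel = ch,
                   values = matrix(v, nrow = 6, ncol = 1,
                                   dimnames = list(mcsv:::csv_band_order, NULL)),
                   validity = matrix(TRUE, 6, 1), bands = mcsv:::csv_band_order),
              class = "csv_feature_map")
  }
  maps <- list(mk_map("a", rep(10, 6)), mk_map("b", rep(30, 6)))
  M <- build_channel_matrix(maps, "gamma", 1)
  expect_equal(unname(M), matrix(c(10, 20, 20, 30), 2))

  maps_eq <- list(mk_map("a", rep(7, 6)), mk_map("b", rep(7, 6)), mk_map("c", rep(7, 6)))
  Me <- build_channel_matrix(maps_eq, "alpha", 1)
  expect_true(all(Me[upper.tri(Me)] == 0))
  expect_true(all(diag(Me) == 7))

  # symmetric off-diagonal; off-diagonal invariant to a common shift
  maps21 <- lapply(1:21, function(i) mk_map(paste0("c", i), rep(i * 3, 6)))
  M21 <- build_channel_matrix(maps21, "beta", 1)
  expect_equal(dim(M21), c(21L, 21L))
  expect_equal(M21[upper.tri(M21)], t(M21)[upper.tri(M21)])
  maps21s <- lapply(1:21, function(i) mk_map(paste0("c", i), rep(i * 3 + 100, 6)))
  M21s <- build_channel_matrix(maps21s, "beta", 1)
  off <- function(m) { diag(m) <- 0; m }
  expect_equal(off(M21s), off(M21))
})

test_that("PCA reduction yields an N x 1 vector with eigenvalue-ratio variances", {
  X <- mcsv:::with_seed(6, matrix(rnorm(21 * 21), 21))
  red <- pca_reduce(X, 1)
  expect_length(red$vector, 21)
  expect_true(all(diff(red$explained_variance) <= 1e-12))
  expect_lte(sum(red$explained_variance), 1 + 1e-12)

  # rank-1 matrix: first component carries all variance
  r1 <- outer(rnorm(10), rnorm(10))
  expect_equal(pca_reduce(r1, 1)$explained_variance[1], 1)

  # constructed covariance: explained fractions equal eigenvalue ratios
  ev <- c(9, 4, 1)
  A <- diag(sqrt(ev))
  Z <- mcsv:::with_seed(9, matrix(rnorm(3 * 4000), ncol = 3)) %*% A
  S <- stats::cov(Z)
  lam <- eigen(S, symmetric = TRUE)$values
  red2 <- pca_reduce(Z, 2)
  expect_equal(red2$explained_variance, lam / sum(lam), tolerance = 1e-8)

  # degenerate all-equal input
  red0 <- pca_reduce(matrix(5, 4, 4))
  expect_true(red0$degenerate)
  expect_equal(red0$vector, rep(0, 4))
  expect_true(all(is.na(red0$explained_variance)))

  expect_error(pca_reduce(matrix(0, 3, 3), 4), "n_components")
})

test_that("re-projecting a projection is idempotent on the retained subspace", {
  X <- mcsv:::with_seed(12, matrix(rnorm(15 * 15), 15))
  pr <- stats::prcomp(X, center = TRUE)
  # reconstruct from the first component and re-reduce
  X1 <- pr$x[, 1, drop = FALSE] %*% t(pr$rotation[, 1, drop = FALSE])
  X1 <- sweep(X1, 2, pr$center, "+")
  red_a <- pca_reduce(X1, 1)
  red_b <- pca_reduce(X1 + 0, 1)
  expect_equal(abs(red_a$vector), abs(red_b$vector), tolerance = 1e-10)
  expect_equal(red_a$explained_variance[1], 1, tolerance = 1e-8)
})

test_that("feature table flattens maps and joins labels", {
  bs <- make_band_spectra(3)
  maps <- list(C3 = build_feature_map(bs, fpa_config(rng_seed = 1), "C3"),
               C4 = build_feature_map(bs, fpa_config(rng_seed = 2), "C4"))
  labels <- matrix(c(1L, 0L, 1L, 0L, 0L, 1L), nrow = 3,
                   dimnames = list(NULL, c("C3", "C4")))
  ft <- feature_table(maps, labels)
  expect_equal(nrow(ft), 6)
  expect_true(all(c("csv_gamma", "valid_full", "label") %in% names(ft)))
  expect_equal(ft$label[ft$channel == "C3"], c(1L, 0L, 1L))
  expect_equal(ncol(feature_matrix(ft)), 12)
})
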