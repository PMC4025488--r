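test_that("binning thresholds are closed on the left genotype", {
  expect_equal(bin_estimates(c(1.5, 1.51, 2.5, 2.51)), c(1L, 2L, 2L, 3L))
  expect_equal(bin_estimates(c(-0.4, 3.7, 2.0)), c(1L, 3L, 2L))
  expect_equal(bin_estimates(1:3), 1:3)               # idempotent on codes
  withr::with_seed(1, {
    v <- runif(100, -2, 5)
    expect_identical(bin_estimates(bin_estimates(v)), bin_estimates(v))
  })
  expect_error(bin_estimates(c(1, NaN)), "position 2")
  expect_identical(bin_estimates(numeric(0)), integer(0))
})

test_that("PPCA on a complete matrix equals the truncated-SVD reconstruction", {
  g <- rand_geno(30, 15, seed = 2)
  r <- impute_ppca(g, n_pcs = 2, tol = 1e-12, max_iter = 5000, seed = 1)
  x <- unclass(g) * 1.0
  xc <- scale(x, scale = FALSE)
  sv <- svd(xc)
  svd_rec <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
  svd_rec <- sweep(svd_rec, 2, attr(xc, "scaled:center"), "+")
  expect_lt(max(abs(r$fitted - svd_rec)), 1e-6)
})

test_that("NIPALS on a complete matrix equals classical PCA", {
  g <- rand_geno(25, 12, seed = 3)
  r <- impute_nipals(g, n_pcs = 2, tol = 1e-12, max_iter = 10000)
  x <- unclass(g) * 1.0
  xc <- scale(x, scale = FALSE)
  sv <- svd(xc)
  svd_rec <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
  svd_rec <- sweep(svd_rec, 2, attr(xc, "scaled:center"), "+")
  expect_lt(max(abs(r$fitted - svd_rec)), 1e-6)
  # leading component matches the SVD direction up to sign
  p1 <- svd(unclass(r$fitted) - rep(1, 25) %o% colMeans(x))$v[, 1]
  expect_lt(min(sum((p1 - sv$v[, 1])^2), sum((p1 + sv$v[, 1])^2)), 1e-10)
})

test_that("masked cells of an exactly rank-1 matrix are recovered", {
  # two mirrored row patterns in equal numbers: the centered matrix is
  # exactly rank 1; masking one cell per pattern in the same column keeps
  # the observed column mean equal to the full mean, preserving the rank
  g <- patterned_geno(list(c(1, 3, 1, 3, 1, 3, 1, 1),
                           c(3, 1, 3, 1, 3, 1, 3, 3)), c(10, 10))
  truths <- c(unclass(g)[3, 4], unclass(g)[15, 4])
  gm <- g; gm[3, 4] <- NA; gm[15, 4] <- NA
  rp <- impute_ppca(gm, n_pcs = 1, tol = 1e-12, max_iter = 5000, seed = 4)
  expect_lt(max(abs(rp$continuous$estimate - truths)), 1e-4)
  rn <- impute_nipals(gm, n_pcs = 1, tol = 1e-12, max_iter = 10000)
  expect_lt(max(abs(rn$continuous$estimate - truths)), 1e-4)
})

test_that("a constant marker imputes to its constant", {
  codes <- cbind(matrix(2L, 12, 1), unclass(rand_geno(12, 4, seed = 6)))
  colnames(codes) <- NULL
  g <- genotype_matrix(codes)
  g[5, 1] <- NA
  for (r in list(impute_ppca(g, n_pcs = 1, seed = 1),
                 impute_nipals(g, n_pcs = 1))) {
    est <- r$continuous$estimate[r$continuous$marker == "M1"]
    expect_equal(est, 2, tolerance = 1e-6)
    expect_equal(unclass(r$imputed)[5, 1], 2L)
  }
})

test_that("NIPALS with zero components is column-mean imputation", {
  g <- rand_geno(10, 6, miss = 0.2, seed = 7)
  r <- impute_nipals(g, n_pcs = 0)
  mu <- colMeans(unclass(g), na.rm = TRUE)
  cols <- arrayInd(which(is.na(g)), dim(g))[, 2]
  expect_equal(r$continuous$estimate, unname(mu[cols]), tolerance = 1e-12)
})

test_that("RF recovers a masked cell from a perfectly predictive marker", {
  withr::with_seed(8, {
    A <- sample(1:3, 40, replace = TRUE)
    codes <- matrix(c(A, A, sample(1:3, 40 * 4, TRUE)), nrow = 40)
    g <- genotype_matrix(codes)
    g[5, 2] <- NA
    r <- impute_rf(g, n_trees = 200, seed = 9)
    expect_equal(unclass(r$imputed)[5, 2], A[5])
  })
})

test_that("RF on independent noise predicts near the marker mean", {
  withr::with_seed(10, {
    g <- rand_geno(60, 6)
    masked <- apply_random_missing(g, 0.05, seed = 11)
    r <- impute_rf(masked$genotypes, n_trees = 300, seed = 12)
    mu <- colMeans(unclass(masked$genotypes), na.rm = TRUE)
    cols <- arrayInd(which(is.na(masked$genotypes)), dim(g))[, 2]
    devs <- abs(r$continuous$estimate - mu[cols])
    expect_lt(mean(devs), 0.35)
    # binned predictions mostly fall in the marker's mean bin
    expect_gt(mean(r$continuous$code == bin_estimates(mu[cols])), 0.7)
  })
})

test_that("imputers never alter observed cells, fill all cells, and are deterministic", {
  g <- rand_geno(25, 15, miss = 0.3, seed = 13)
  obs <- !is.na(g)
  res <- list(PP = impute_ppca(g, seed = 14),
              NI = impute_nipals(g),
              RF = impute_rf(g, n_trees = 50, seed = 15))
  for (r in res) {
    expect_identical(unclass(r$imputed)[obs], unclass(g)[obs])
    expect_false(anyNA(r$imputed))
    expect_true(all(r$imputed %in% 1:3))
  }
  expect_identical(impute_ppca(g, seed = 14)$imputed, res$PP$imputed)
  expect_identical(impute_nipals(g)$imputed, res$NI$imputed)
  expect_identical(impute_rf(g, n_trees = 50, seed = 15)$imputed,
                   res$RF$imputed)
  full <- rand_geno(10, 5, seed = 16)
  rid <- impute_rf(full, n_trees = 20, seed = 17)
  expect_identical(rid$imputed, full)
  expect_equal(nrow(rid$continuous), 0L)
})

test_that("PCA imputers recover >= 95% of masked genotypes on low-rank data", {
  # three row patterns -> centered rank 2
  withr::with_seed(18, {
    pats <- list(sample(c(1, 3), 40, TRUE), sample(c(1, 3), 40, TRUE),
                 sample(c(1, 3), 40, TRUE))
    g <- patterned_geno(pats, c(20, 20, 20))
    masked <- apply_random_missing(g, 0.3, seed = 19)
    for (r in list(impute_ppca(masked$genotypes, n_pcs = 2, seed = 20),
                   impute_nipals(masked$genotypes, n_pcs = 2))) {
      agree <- unclass(r$imputed)[masked$mask] == unclass(g)[masked$mask]
      expect_gte(mean(agree), 0.95)
    }
  })
})
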