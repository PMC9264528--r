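masked_fixture <- function(n_proteins = 30, rate = 0.15, seed = 5) {
  dat <- small_complete(n_proteins = n_proteins, n_samples = 20, seed = seed)
  introduce_mixture(dat$matrix, rate, seed = seed + 1)
}

test_that("zero and mean imputation are exact by definition", {
  v <- matrix(c(2, NA, 4, 1, 3, NA), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  m <- abundance_matrix(v)
  z <- impute(m, "zero")
  expect_identical(unname(z$values["A", "S2"]), 0)
  expect_identical(unname(z$values["B", "S3"]), 0)
  mm <- impute(m, "mean")
  expect_identical(unname(mm$values["A", "S2"]), 3)   # mean(2, 4)
  expect_identical(unname(mm$values["B", "S3"]), 2)   # mean(1, 3)
})

test_that("every method is the identity on a complete matrix", {
  dat <- small_complete(n_proteins = 15, n_samples = 12, seed = 6)
  for (meth in si_methods()) {
    out <- impute(dat$matrix, method = meth, rank = 3)
    expect_identical(out$values, dat$matrix$values)
    expect_equal(attr(out, "provenance")$iterations, 0L)
  }
})

test_that("observed cells pass through bit-exact for every method", {
  inj <- masked_fixture()
  obs <- !is.na(inj$masked_matrix$values)
  for (meth in si_methods()) {
    out <- suppressWarnings(impute(inj$masked_matrix, method = meth,
                                   rank = 5, seed = 3))
    expect_false(anyNA(out$values))
    expect_identical(out$values[obs], inj$masked_matrix$values[obs])
  }
})

test_that("methods are deterministic given their parameters", {
  inj <- masked_fixture(seed = 11)
  for (meth in si_methods()) {
    a <- suppressWarnings(impute(inj$masked_matrix, meth, rank = 5, seed = 9))
    b <- suppressWarnings(impute(inj$masked_matrix, meth, rank = 5, seed = 9))
    expect_identical(a$values, b$values)
  }
  r1 <- impute(inj$masked_matrix, "rf", seed = 1)
  r2 <- impute(inj$masked_matrix, "rf", seed = 2)
  expect_false(identical(r1$values, r2$values))
})

test_that("LLS recovers exact linear relations between proteins", {
  set.seed(3)
  base <- rnorm(12, 20)
  v <- rbind(target = base, dup = base, double = 2 * base,
             noise1 = rnorm(12, 20), noise2 = rnorm(12, 20),
             noise3 = rnorm(12, 20))
  colnames(v) <- sprintf("S%02d", 1:12)
  # duplicated row: imputed value equals the duplicate's value
  m1 <- abundance_matrix(v)
  m1$values["target", "S05"] <- NA
  out1 <- suppressWarnings(impute(m1, "lls", k_neighbors = 1))
  expect_equal(unname(out1$values["target", "S05"]), base[5],
               tolerance = 1e-8)
  # neighbour = 2 x target: one-predictor least squares gives neighbour / 2
  v2 <- v[c("target", "double"), ]
  m2 <- abundance_matrix(v2)
  m2$values["target", "S07"] <- NA
  out2 <- suppressWarnings(impute(m2, "lls", k_neighbors = 1))
  expect_equal(unname(out2$values["target", "S07"]), 2 * base[7] / 2,
               tolerance = 1e-8)
})

test_that("GRR matches LLS as the penalty vanishes and the mean at infinity", {
  # well-conditioned neighbour sets: modest correlation, few predictors
  dat <- small_complete(n_proteins = 20, n_samples = 30, seed = 21,
                        rho = 0.3)
  inj <- introduce_mcar(dat$matrix, 0.1, seed = 22)
  lls <- suppressWarnings(impute(inj$masked_matrix, "lls", k_neighbors = 5))
  g0 <- suppressWarnings(impute(inj$masked_matrix, "grr", k_neighbors = 5,
                                ridge_lambda = 1e-10))
  expect_equal(g0$values, lls$values, tolerance = 1e-5)

  ginf <- suppressWarnings(impute(inj$masked_matrix, "grr", k_neighbors = 5,
                                  ridge_lambda = 1e12))
  miss <- which(is.na(inj$masked_matrix$values), arr.ind = TRUE)
  mu <- rowMeans(inj$masked_matrix$values, na.rm = TRUE)
  expect_equal(unname(ginf$values[miss]), unname(mu[miss[, 1]]),
               tolerance = 1e-6)
})

test_that("GRR handles perfectly collinear neighbours", {
  set.seed(8)
  base <- rnorm(15, 20)
  v <- rbind(t1 = base + rnorm(15, 0, 0.05), d1 = base, d2 = base,
             d3 = base, n1 = rnorm(15, 20))
  m <- abundance_matrix(v)
  m$values["t1", 3] <- NA
  out <- suppressWarnings(impute(m, "grr", k_neighbors = 4))
  expect_true(is.finite(out$values["t1", 3]))
  expect_lt(abs(out$values["t1", 3] - base[3]), 0.5)
})

test_that("iterative SVD completes a noiseless rank-1 matrix exactly", {
  set.seed(4)
  v <- outer(runif(30, 1, 2), runif(8, 18, 22))
  m <- abundance_matrix(v)
  m$values[3, 5] <- NA
  out <- impute(m, "svd", rank = 1, tol = 1e-9, max_iter = 500)
  expect_lt(abs(out$values[3, 5] - v[3, 5]) / diff(range(v)), 1e-6)
})

test_that("full-rank SVD reproduces the mean-filled matrix at iteration 1", {
  set.seed(5)
  v <- outer(runif(10, 1, 2), runif(6, 18, 22))   # rank deficient
  m <- abundance_matrix(v)
  m$values[cbind(c(2, 7), c(1, 4))] <- NA
  out <- impute(m, "svd", rank = 6, tol = 1e-9, max_iter = 50)
  fill <- v
  mv <- rowMeans(m$values, na.rm = TRUE)
  fill[2, 1] <- mv[2]; fill[7, 4] <- mv[7]
  expect_equal(out$values, fill, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(attr(out, "provenance")$iterations, 1L)
})

test_that("BPCA completes a noiseless rank-1 matrix and shrinks pure noise", {
  set.seed(4)
  v <- outer(runif(30, 1, 2), runif(8, 18, 22))
  m <- abundance_matrix(v)
  m$values[3, 5] <- NA
  out <- impute(m, "bpca", rank = 1, tol = 1e-9, max_iter = 1000)
  expect_lt(abs(out$values[3, 5] - v[3, 5]) / diff(range(v)), 1e-6)

  # structureless data: ARD suppresses the factors and imputations sit in
  # a shrinkage band around the protein means (well inside one noise SD)
  set.seed(10)
  vn <- matrix(rnorm(2000), 200, 10)
  injn <- introduce_mcar(abundance_matrix(vn), 0.1, seed = 9)
  bn <- impute(injn$masked_matrix, "bpca", tol = 1e-7, max_iter = 300)
  idx <- which(is.na(injn$masked_matrix$values), arr.ind = TRUE)
  mu <- rowMeans(injn$masked_matrix$values, na.rm = TRUE)
  expect_lt(mean(abs(bn$values[idx] - mu[idx[, 1]])), 0.5)
})

test_that("kNN degenerates to the across-protein average when k = p - 1", {
  set.seed(12)
  v <- matrix(rnorm(5 * 8, 20), 5, 8)
  m <- abundance_matrix(v)
  m$values[2, 3] <- NA
  out <- impute(m, "knn", k_neighbors = 4)
  expect_equal(unname(out$values[2, 3]), mean(v[-2, 3]), tolerance = 1e-12)
})

test_that("seqknn equals knn when a single protein is incomplete", {
  set.seed(13)
  v <- matrix(rnorm(8 * 10, 20), 8, 10)
  m <- abundance_matrix(v)
  m$values[4, c(2, 6)] <- NA
  a <- impute(m, "knn", k_neighbors = 3)
  b <- impute(m, "seqknn", k_neighbors = 3)
  expect_equal(a$values, b$values)
})

test_that("sequential methods fail structurally without complete proteins", {
  set.seed(14)
  v <- matrix(rnorm(6 * 8, 20), 6, 8)
  diag(v) <- NA   # every protein has a hole
  m <- abundance_matrix(v)
  expect_error(impute(m, "seqknn"), class = "lfq_impute_error")
  expect_error(impute(m, "impseq"), class = "lfq_impute_error")
})

test_that("impseq imputes correlated data via robust sequential regression", {
  inj <- masked_fixture(seed = 31, rate = 0.1)
  out <- suppressWarnings(impute(inj$masked_matrix, "impseq"))
  expect_false(anyNA(out$values))
  expect_gt(injected_fraction_correct(inj, out), 0.7)
})

test_that("random-forest imputation recovers a low-rank structure", {
  set.seed(15)
  v <- outer(runif(20, 1, 2), runif(10, 18, 22))
  inj <- introduce_mcar(abundance_matrix(v), 0.1, seed = 3)
  out <- impute(inj$masked_matrix, "rf", seed = 1)
  expect_gte(injected_fraction_correct(inj, out), 0.8)
  prov <- attr(out, "provenance")
  expect_true(prov$iterations >= 1)
})

test_that("informative imputers are never less accurate than zero-fill", {
  inj <- masked_fixture(n_proteins = 40, rate = 0.2, seed = 41)
  fc_zero <- injected_fraction_correct(inj, impute(inj$masked_matrix, "zero"))
  for (meth in c("grr", "lls", "bpca", "rf")) {
    out <- suppressWarnings(impute(inj$masked_matrix, meth, seed = 2))
    expect_gte(injected_fraction_correct(inj, out), fc_zero)
  }
})

test_that("dispatcher validates inputs", {
  v <- matrix(c(NA, 1, NA, 2), 2, 2)   # first protein fully unobserved
  expect_error(impute(abundance_matrix(v), "mean"),
               class = "lfq_validation_error")
  expect_error(impute(abundance_matrix(matrix(1:4 + 0, 2, 2)), "nope"))
})
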