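test_that("percent bias follows its definition and is scale invariant", {
  expect_equal(percent_bias(21, 20), 5)
  expect_equal(percent_bias(19, 20), 5)
  expect_equal(percent_bias(7.3, 7.3), 0)
  expect_identical(percent_bias(1, 0), Inf)
  set.seed(1)
  imp <- rnorm(50, 20); tr <- rnorm(50, 20)
  for (c0 in c(0.01, 1, 250)) {
    expect_equal(percent_bias(c0 * imp, c0 * tr), percent_bias(imp, tr))
  }
})

test_that("fraction correct counts strictly-below-threshold biases", {
  expect_equal(fraction_correct(c(4.9, 5.0, 5.1)), 1 / 3)
  expect_equal(fraction_correct(rep(0, 4)), 1)
  expect_equal(fraction_correct(c(3, 80, 40), threshold = Inf), 1)
  expect_equal(fraction_correct(c(1, Inf)), 0.5)  # zero-truth never correct
  expect_error(fraction_correct(numeric(0)), class = "lfq_validation_error")
})

test_that("per-protein OLS matches closed forms and the lm oracle", {
  meta3 <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                          age_years = c(1, 2, 3))
  m1 <- abundance_matrix(matrix(c(2, 4, 6), 1, 3,
                                dimnames = list("A", meta3$sample_id)))
  f1 <- regress_covariate(m1, meta3)
  expect_equal(f1$estimate, 2)
  expect_equal(f1$std_error, 0)

  m2 <- abundance_matrix(matrix(c(5, 5, 5), 1, 3,
                                dimnames = list("A", meta3$sample_id)))
  expect_equal(regress_covariate(m2, meta3)$estimate, 0)

  m3 <- abundance_matrix(matrix(c(1, 2, 2), 1, 3,
                                dimnames = list("A", meta3$sample_id)))
  expect_equal(regress_covariate(m3, meta3)$estimate, 0.5)

  # independent oracle: stats::lm on random data
  dat <- small_complete(n_proteins = 12, n_samples = 18, seed = 31)
  fits <- regress_covariate(dat$matrix, dat$metadata)
  for (i in seq_len(12)) {
    lmf <- summary(stats::lm(dat$matrix$values[i, ] ~ dat$metadata$age_years))
    expect_equal(fits$estimate[i], unname(lmf$coefficients[2, 1]),
                 tolerance = 1e-10)
    expect_equal(fits$std_error[i], unname(lmf$coefficients[2, 2]),
                 tolerance = 1e-10)
    expect_equal(fits$p_value[i], unname(lmf$coefficients[2, 4]),
                 tolerance = 1e-10)
  }
  expect_error(regress_covariate(m1, transform(meta3, age_years = 2)),
               class = "lfq_validation_error")
})

test_that("Cronbach's alpha matches its closed form and a covariance oracle", {
  # two items with unit variances and covariance 1/2 -> alpha = 2/3
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  L <- chol(S)
  set.seed(41)
  z <- matrix(rnorm(2 * 20000), 20000, 2) %*% L
  a <- cronbach_alpha(abundance_matrix(t(z)))
  expect_equal(a, 2 / 3, tolerance = 0.02)

  # identical items -> alpha = 1 exactly
  x <- rnorm(10, 20)
  expect_equal(cronbach_alpha(abundance_matrix(rbind(a = x, b = x))), 1)

  # brute-force covariance-matrix oracle on random 5 x 20 matrices
  for (s in 1:10) {
    set.seed(s)
    v <- matrix(rnorm(100, 20), 5, 20)
    Sg <- stats::cov(t(v))
    k <- 5
    oracle <- k / (k - 1) * (1 - sum(diag(Sg)) / sum(Sg))
    expect_equal(cronbach_alpha(abundance_matrix(v)), oracle,
                 tolerance = 1e-10)
  }

  # independent items: population alpha 0, Monte-Carlo mean near 0
  set.seed(42)
  alphas <- replicate(300, cronbach_alpha(
    abundance_matrix(matrix(rnorm(2 * 60), 2, 60))))
  expect_lt(abs(mean(alphas)), 0.1)

  expect_error(cronbach_alpha(abundance_matrix(matrix(1:3 + 0, 1, 3))),
               class = "lfq_validation_error")
})

test_that("bias t-test handles edge cases and is calibrated under the null", {
  expect_equal(bias_ttest(rep(0, 5))$p_value, 1)
  expect_false(bias_ttest(rep(0, 5))$significant)
  set.seed(6)
  shifted <- bias_ttest(1 + rnorm(20, 0, 1e-3))
  expect_true(shifted$significant)
  expect_equal(bias_ttest(rep(2, 4))$p_value, 0)   # zero variance, mean != 0

  # Bonferroni scales the p-value by the family size
  d <- rnorm(30, 0.5)
  expect_equal(bias_ttest(d, n_tests = 10)$p_bonferroni,
               min(1, bias_ttest(d)$p_value * 10))

  # type-I calibration of the harness: ~5% rejections at uncorrected 0.05
  set.seed(7)
  rej <- mean(replicate(400, bias_ttest(rnorm(100))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("regression comparisons record per-protein deltas", {
  dat <- small_complete(n_proteins = 8, seed = 51)
  fits <- regress_covariate(dat$matrix, dat$metadata)
  same <- compare_regressions(fits, fits)
  expect_true(all(same$delta_beta == 0))
  expect_true(all(same$delta_p == 0))
})

test_that("leave-one-out evaluation is exact for mean imputation", {
  dat <- small_complete(n_proteins = 6, n_samples = 10, seed = 61)
  m <- dat$matrix
  rec <- loo_structural_eval(m, method = "mean", n_iter = 1, seed = 2)
  v <- m$values
  i <- match(rec$protein, rownames(v)); j <- match(rec$sample, colnames(v))
  expected <- 100 * abs(v[i, j] - mean(v[i, -j])) / abs(v[i, j])
  expect_equal(rec$pct_bias, expected, tolerance = 1e-12)
  expect_equal(rec$imputed_value, mean(v[i, -j]), tolerance = 1e-12)
  # the held-out cell is restored: the input matrix is untouched
  expect_identical(m$values, dat$matrix$values)
  expect_error(loo_structural_eval(m, "mean", n_iter = 61),
               class = "lfq_validation_error")
})

test_that("leave-one-out on a structured matrix reports finite strata", {
  cfg <- synth_config(n_proteins = 60, seed = 71)
  s <- generate_structured_dataset(cfg, missingness_spec("MIX", 0.3, seed = 72))
  rec <- loo_structural_eval(s, method = "mean", n_iter = 40, seed = 3)
  expect_equal(nrow(rec), 40L)
  expect_true(all(is.finite(rec$pct_bias)))
  sm <- summarise_loo(rec)
  expect_true(all(is.finite(sm$mean_pct_bias)))
  expect_equal(sum(sm$n), 40L)
  # duplicated-cell protection: cells are sampled without replacement
  expect_false(any(duplicated(rec[c("protein", "sample")])))
})
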