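test_that("MCAR removes exactly round(rate * observed) cells, none twice", {
  m <- tiny_matrix(matrix(rnorm(100, 20), 10, 10))
  r <- introduce_mcar(m, 0.1, seed = 1)
  expect_equal(nrow(r$deleted_cells), 10L)
  expect_equal(sum(is.na(r$masked_matrix$values)), 10L)
  expect_false(any(duplicated(r$deleted_cells[c("protein", "sample")])))
  expect_equal(r$realized_global_rate, 0.1)
  # deleted true values match the original matrix
  idx <- deleted_index(r$deleted_cells, m)
  expect_identical(r$deleted_cells$true_value, unname(m$values[idx]))

  r0 <- introduce_mcar(m, 0, seed = 1)
  expect_identical(r0$masked_matrix$values, m$values)
})

test_that("MCAR removal frequencies are uniform across cells", {
  m <- tiny_matrix(matrix(rnorm(60, 20), 6, 10))
  counts <- matrix(0, 6, 10)
  for (s in 1:500) {
    r <- introduce_mcar(m, 0.1, seed = s)
    idx <- deleted_index(r$deleted_cells, m)
    counts[idx] <- counts[idx] + 1
  }
  # 500 draws of 6 cells from 60: expected 50 hits per cell
  gof <- stats::chisq.test(as.vector(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("MAR removals are driven by an above-cutpoint partner protein", {
  dat <- small_complete(n_proteins = 100, n_samples = 45, seed = 4)
  r <- introduce_mar(dat$matrix, 0.1, seed = 11)
  cells <- r$deleted_cells
  expect_true(all(cells$mechanism == "MAR"))
  expect_true(all(cells$driver != cells$protein))
  expect_true(all(cells$driver_z > cells$cutpoint))
  # realized rate in [rate, rate + one pairing's worth of cells]
  total <- prod(dim(dat$matrix))
  expect_gte(r$realized_global_rate, 0.1 - 1e-12)
  expect_lte(r$realized_global_rate, 0.1 + ncol(dat$matrix$values) / total)

  expect_identical(introduce_mar(dat$matrix, 0, seed = 2)$masked_matrix$values,
                   dat$matrix$values)
  one <- tiny_matrix(matrix(rnorm(10, 20), 1, 10))
  expect_error(introduce_mar(one, 0.2, seed = 1),
               class = "lfq_injection_error")
})

test_that("MNAR removes exactly each affected protein's smallest values", {
  dat <- small_complete(n_proteins = 50, n_samples = 45, seed = 9)
  r <- introduce_mnar(dat$matrix, 0.2, seed = 5)
  v <- dat$matrix$values
  by_protein <- split(r$deleted_cells$sample, r$deleted_cells$protein)
  for (pr in names(by_protein)) {
    k <- length(by_protein[[pr]])
    removed_vals <- sort(v[pr, by_protein[[pr]]])
    bottom_k <- sort(v[pr, ])[seq_len(k)]
    expect_equal(removed_vals, bottom_k, ignore_attr = TRUE)
  }
  expect_lt(mean(r$deleted_cells$true_value),
            mean(r$masked_matrix$values, na.rm = TRUE))
  expect_equal(r$realized_global_rate, 0.2)
})

test_that("mixture layers the three mechanisms at equal proportions", {
  dat <- small_complete(n_proteins = 60, n_samples = 45, seed = 2)
  r <- introduce_mixture(dat$matrix, 0.3, seed = 7)
  total <- prod(dim(dat$matrix))
  counts <- table(r$deleted_cells$mechanism)
  expect_setequal(names(counts), c("MCAR", "MAR", "MNAR"))
  # each mechanism contributes ~10% of cells (one pairing of slack)
  for (mech in names(counts)) {
    expect_lt(abs(counts[[mech]] / total - 0.1),
              ncol(dat$matrix$values) / total)
  }
  # deleted cells partition the missing set, disjointly
  expect_false(any(duplicated(r$deleted_cells[c("protein", "sample")])))
  expect_equal(nrow(r$deleted_cells), sum(is.na(r$masked_matrix$values)))
  expect_lte(abs(r$realized_global_rate - 0.3), 1 / total + 1e-12)

  expect_identical(
    introduce_mixture(dat$matrix, 0, seed = 1)$masked_matrix$values,
    dat$matrix$values)
})

test_that("injections are deterministic and monotone in the rate", {
  dat <- small_complete(n_proteins = 40, n_samples = 30, seed = 3)
  for (mech in c("MCAR", "MAR", "MNAR", "MIX")) {
    s1 <- inject_missing(dat$matrix, missingness_spec(mech, 0.15, seed = 21))
    s2 <- inject_missing(dat$matrix, missingness_spec(mech, 0.15, seed = 21))
    expect_identical(s1$masked_matrix$values, s2$masked_matrix$values)
    s3 <- inject_missing(dat$matrix, missingness_spec(mech, 0.15, seed = 22))
    expect_false(identical(s1$masked_matrix$values,
                           s3$masked_matrix$values))
    rates <- vapply(c(0.05, 0.1, 0.2, 0.3), function(rt) {
      inject_missing(dat$matrix,
                     missingness_spec(mech, rt, seed = 21))$realized_global_rate
    }, 0)
    expect_false(is.unsorted(rates))
  }
})

test_that("every deleted cell was observed before injection", {
  dat <- small_complete(n_proteins = 30, seed = 8)
  pre <- introduce_mcar(dat$matrix, 0.1, seed = 1)$masked_matrix
  r <- introduce_mnar(pre, 0.1, seed = 2)
  idx <- deleted_index(r$deleted_cells, pre)
  expect_false(anyNA(pre$values[idx]))
})

test_that("protein-missingness strata use half-open bins", {
  v <- matrix(rnorm(4 * 45, 20), 4, 45,
              dimnames = list(paste0("P", 1:4), sprintf("S%02d", 1:45)))
  m <- abundance_matrix(v)
  # hand-build an injection result: P1 loses 2/45, P2 loses 9/45, P4 none
  deleted <- tibble::tibble(
    protein = c(rep("P1", 2), rep("P2", 9)),
    sample = c(sprintf("S%02d", 1:2), sprintf("S%02d", 1:9)))
  deleted$true_value <- v[cbind(match(deleted$protein, rownames(v)),
                                match(deleted$sample, colnames(v)))]
  deleted$mechanism <- "MCAR"
  masked <- m
  masked$values[cbind(match(deleted$protein, rownames(v)),
                      match(deleted$sample, colnames(v)))] <- NA
  r <- structure(list(masked_matrix = masked, deleted_cells = deleted,
                      realized_global_rate = 11 / 180,
                      per_protein_rates = c(2, 9, 0, 0) / 45),
                 class = "injection_result")
  strat <- stratify_protein_missingness(r)
  expect_equal(nrow(strat), 2L)   # untouched proteins are excluded
  expect_equal(as.character(strat$bin[strat$protein == "P1"]), "[0%,5%)")
  # 9/45 = 20% sits in the [20%,30%) bin under the half-open convention
  expect_equal(as.character(strat$bin[strat$protein == "P2"]), "[20%,30%)")
  expect_error(stratify_protein_missingness(r, bins = c(0.1, 0.05)),
               class = "lfq_validation_error")
})
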