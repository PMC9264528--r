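#' Single imputation of a protein abundance matrix
#'
#' Fills every missing cell of a log-scale abundance matrix with one value,
#' leaving observed cells untouched (bit-exact pass-through). Proteins are
#' the imputation unit (rows); samples are the observations.
#'
#' Methods:
#' * `zero` — missing values become 0.
#' * `mean` — the protein's observed mean.
#' * `knn` — average of the k nearest proteins (Euclidean distance over
#'   shared observed samples) at that sample.
#' * `seqknn` — sequential kNN: proteins imputed in order of increasing
#'   missingness against the pool of complete proteins, each completed
#'   protein joining the pool.
#' * `svd` — iterative rank-`rank` SVD reconstruction from a mean-filled
#'   start, re-estimated until the imputed values stabilise.
#' * `bpca` — Bayesian PCA: EM for a probabilistic PCA model with an
#'   automatic-relevance-determination prior that prunes unneeded factors;
#'   missing cells get their posterior-mean reconstruction. See
#'   [bpca_impute()].
#' * `lls` — local least squares: regression of each incomplete protein on
#'   its `k_neighbors` most-correlated complete-in-the-relevant-samples
#'   proteins.
#' * `grr` — generalized ridge regression: as `lls` but ridge-penalized in
#'   the principal-component basis, the penalty chosen by generalized
#'   cross-validation (or fixed via `ridge_lambda`).
#' * `rf` — iterative random-forest imputation (the missForest scheme):
#'   median start, proteins visited by increasing missingness, each
#'   regressed on all others, iterated until the change in imputed values
#'   first rises.
#' * `impseq` — sequential robust-regression imputation ordered by
#'   missingness, using M-estimation on the most-correlated complete
#'   proteins.
#'
#' @param m An [abundance_matrix()] (log scale); every protein needs at
#'   least one observed value (except for `zero`).
#' @param method Method name, see above.
#' @param k_neighbors Neighbour count for `knn`, `seqknn`, `lls`, `grr`,
#'   `impseq`. Default 10.
#' @param rank Factor/rank cap for `svd` and `bpca`. Default
#'   `min(dim) - 1`; ARD prunes surplus factors in `bpca`.
#' @param max_iter Iteration cap (default 10 for `rf`, 100 for
#'   `svd`/`bpca`).
#' @param tol Relative-change convergence tolerance (default 1e-3).
#' @param ridge_lambda Optional fixed scalar ridge penalty for `grr`;
#'   `NULL` (default) selects the penalty by GCV with a per-component
#'   Hoerl-Kennard refinement.
#' @param seed Seed for the stochastic methods (`rf`).
#' @param n_trees Trees per random forest (default 100).
#' @return A complete [abundance_matrix()]; attribute `provenance` records
#'   method, parameters, iterations and convergence.
#' @export
impute <- function(m, method = c("zero", "mean", "knn", "seqknn", "svd",
                                 "bpca", "lls", "grr", "rf", "impseq"),
                   k_neighbors = 10L, rank = NULL, max_iter = NULL,
                   tol = 1e-3, ridge_lambda = NULL, seed = 1L,
                   n_trees = 100L) {
  method <- match.arg(method)
  v <- m$values
  if (method != "zero" && any(rowSums(!is.na(v)) == 0)) {
    rlang::abort(sprintf(
      "method `%s` requires every protein to have >= 1 observed value.",
      method), class = "lfq_validation_error")
  }
  if (!anyNA(v)) {
    return(with_provenance(m, method, iterations = 0L, converged = TRUE))
  }
  out <- switch(method,
    zero = { w <- v; w[is.na(w)] <- 0; list(values = w) },
    mean = mean_impute_values(v),
    knn = knn_impute_values(v, k_neighbors),
    seqknn = seqknn_impute_values(v, k_neighbors),
    svd = svd_impute_values(v, rank, max_iter %||% 100L, tol),
    bpca = bpca_impute_values(v, rank, max_iter %||% 100L, tol),
    lls = lls_impute_values(v, k_neighbors, ridge = "none"),
    grr = lls_impute_values(v, k_neighbors, ridge = "grr",
                            ridge_lambda = ridge_lambda),
    rf = rf_impute_values(v, max_iter %||% 10L, seed, n_trees),
    impseq = impseq_impute_values(v, k_neighbors))
  w <- out$values
  w[!is.na(v)] <- v[!is.na(v)]   # observed cells are never altered
  res <- abundance_matrix(w, scale = m$scale, truth = m$truth)
  with_provenance(res, method,
                  iterations = out$iterations %||% NA_integer_,
                  converged = out$converged %||% TRUE)
}

with_provenance <- function(m, method, iterations, converged) {
  attr(m, "provenance") <- list(method = method, iterations = iterations,
                                converged = converged)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

impute_error <- function(method, msg) {
  rlang::abort(sprintf("imputation method `%s` failed: %s", method, msg),
               class = c("lfq_impute_error", "lfq_error"), method = method)
}

mean_impute_values <- function(v) {
  fill <- rowMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- fill[idx[, 1]]
  list(values = v)
}

median_fill <- function(v) {
  fill <- apply(v, 1, stats::median, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- fill[idx[, 1]]
  v
}

# squared distance between protein i and all other rows over shared
# observed samples, normalized by the number of shared samples
protein_distances <- function(v, i) {
  xi <- v[i, ]
  d2 <- rep(Inf, nrow(v))
  for (l in seq_len(nrow(v))) {
    if (l == i) next
    shared <- !is.na(xi) & !is.na(v[l, ])
    if (any(shared)) d2[l] <- mean((xi[shared] - v[l, shared])^2)
  }
  d2
}

knn_impute_values <- function(v, k) {
  p <- nrow(v)
  if (p < 2) impute_error("knn", "needs >= 2 proteins")
  out <- v
  for (i in which(rowSums(is.na(v)) > 0)) {
    d2 <- protein_distances(v, i)
    if (all(!is.finite(d2))) {
      impute_error("knn", sprintf("protein %s shares no samples with any other",
                                  rownames(v)[i]))
    }
    ord <- order(d2)
    for (j in which(is.na(v[i, ]))) {
      nb <- ord[!is.na(v[ord, j]) & is.finite(d2[ord])]
      if (!length(nb)) {
        out[i, j] <- mean(v[i, ], na.rm = TRUE)
        next
      }
      use <- nb[seq_len(min(k, length(nb)))]
      out[i, j] <- mean(v[use, j])
    }
  }
  list(values = out)
}

seqknn_impute_values <- function(v, k) {
  complete <- rowSums(is.na(v)) == 0
  if (!any(complete)) {
    impute_error("seqknn", "no complete proteins to seed the neighbour pool")
  }
  pool <- which(complete)
  todo <- order(rowSums(is.na(v)))
  todo <- todo[rowSums(is.na(v))[todo] > 0]
  out <- v
  for (i in todo) {
    xi <- out[i, ]
    obs <- !is.na(xi)
    d2 <- vapply(pool, function(l) mean((xi[obs] - out[l, obs])^2), 0)
    use <- pool[order(d2)][seq_len(min(k, length(pool)))]
    miss <- which(!obs)
    out[i, miss] <- colMeans(out[use, miss, drop = FALSE])
    pool <- c(pool, i)
  }
  list(values = out)
}

svd_impute_values <- function(v, rank, max_iter, tol) {
  r <- min(rank %||% (min(dim(v)) - 1L), min(dim(v)))
  if (r < 1) impute_error("svd", "rank must be >= 1")
  miss <- is.na(v)
  sd_obs <- max(stats::sd(v[!miss]), 1e-12)
  x <- mean_impute_values(v)$values
  prev <- x[miss]
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    s <- svd(x, nu = r, nv = r)
    recon <- s$u %*% (s$d[seq_len(r)] * t(s$v))
    x[miss] <- recon[miss]
    delta <- sqrt(mean((x[miss] - prev)^2)) / sd_obs
    prev <- x[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  list(values = x, iterations = it, converged = converged)
}

# Neighbour-regression imputation shared by LLS and GRR. For each target
# protein the k most |Pearson|-correlated proteins (pairwise-complete
# correlations, >= min_overlap joint observations) are the predictors.
# Neighbour rows enter the regression from a row-mean prefilled copy, so a
# neighbour's own missing cells never disqualify it; the fit uses the
# target's observed samples and predicts at its missing ones.
lls_impute_values <- function(v, k, ridge = c("none", "grr"),
                              ridge_lambda = NULL, min_overlap = 5L) {
  ridge <- match.arg(ridge)
  p <- nrow(v)
  filled <- mean_impute_values(v)$values
  out <- v
  for (i in which(rowSums(is.na(v)) > 0)) {
    miss <- which(is.na(v[i, ]))
    obs <- which(!is.na(v[i, ]))
    overlap <- tcrossprod(!is.na(v[i, , drop = FALSE]) * 1,
                          !is.na(v) * 1)[1, ]
    cand <- setdiff(which(overlap >= min_overlap), i)
    if (!length(cand)) {
      rlang::warn(sprintf(
        "protein %s: no usable neighbours; falling back to protein mean.",
        rownames(v)[i]))
      out[i, miss] <- mean(v[i, obs])
      next
    }
    cors <- suppressWarnings(stats::cor(v[i, ], t(v[cand, , drop = FALSE]),
                                        use = "pairwise.complete.obs"))[1, ]
    cors[is.na(cors)] <- 0
    if (length(cand) < k) {
      rlang::warn(sprintf(
        "protein %s: only %d usable neighbours (requested %d); using all.",
        rownames(v)[i], length(cand), k))
      nb <- cand
    } else {
      nb <- cand[order(abs(cors), decreasing = TRUE)][seq_len(k)]
    }
    y <- v[i, obs]
    X <- t(filled[nb, obs, drop = FALSE])
    Xnew <- t(filled[nb, miss, drop = FALSE])
    out[i, miss] <- if (ridge == "none") {
      ols_predict(y, X, Xnew)
    } else {
      grr_predict(y, X, Xnew, ridge_lambda)
    }
  }
  list(values = out)
}

ols_predict <- function(y, X, Xnew) {
  fit <- stats::lm.fit(cbind(1, X), y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0   # aliased columns dropped
  drop(cbind(1, Xnew) %*% coefs)
}

# Ridge in the principal-component basis. With a fixed scalar lambda the
# shrinkage is d/(d^2 + lambda) per component; otherwise lambda is chosen
# by closed-form GCV over a log grid and refined once with the
# Hoerl-Kennard per-component penalties lambda_j = sigma^2 / alpha_j^2.
grr_predict <- function(y, X, Xnew, ridge_lambda = NULL) {
  n <- length(y)
  my <- mean(y); mx <- colMeans(X)
  yc <- y - my
  Xc <- sweep(X, 2, mx)
  s <- svd(Xc)
  pos <- s$d > max(s$d) * 1e-10
  d <- s$d[pos]
  U <- s$u[, pos, drop = FALSE]
  V <- s$v[, pos, drop = FALSE]
  a <- drop(crossprod(U, yc))          # component responses
  shrink_beta <- function(lam) V %*% ((d / (d^2 + lam)) * a)
  if (!is.null(ridge_lambda)) {
    beta <- shrink_beta(ridge_lambda)
  } else {
    grid <- 10^seq(-6, 6, length.out = 40) * mean(d^2)
    gcv <- vapply(grid, function(lam) {
      w <- d^2 / (d^2 + lam)
      rss <- sum((a * (1 - w))^2) + sum(yc^2) - sum(a^2)
      edf <- sum(w)
      n * rss / (n - min(edf, n - 1))^2
    }, 0)
    lam <- grid[which.min(gcv)]
    w <- d^2 / (d^2 + lam)
    rss <- sum((a * (1 - w))^2) + max(sum(yc^2) - sum(a^2), 0)
    sigma2 <- rss / max(n - sum(w) - 1, 1)
    alpha <- (d / (d^2 + lam)) * a     # shrunk component coefficients
    lam_j <- pmin(sigma2 / pmax(alpha^2, 1e-12), 1e12)
    beta <- V %*% ((d / (d^2 + lam_j)) * a)
  }
  drop(sweep(Xnew, 2, mx) %*% beta) + my
}

impseq_impute_values <- function(v, k) {
  complete <- rowSums(is.na(v)) == 0
  if (!any(complete)) {
    impute_error("impseq", "no complete proteins to start the sequence")
  }
  pool <- which(complete)
  todo <- order(rowSums(is.na(v)))
  todo <- todo[rowSums(is.na(v))[todo] > 0]
  out <- v
  for (i in todo) {
    obs <- which(!is.na(out[i, ]))
    miss <- which(is.na(out[i, ]))
    cors <- vapply(pool, function(l)
      suppressWarnings(stats::cor(out[i, obs], out[l, obs])), 0)
    cors[is.na(cors)] <- 0
    kk <- min(k, length(pool), max(1L, length(obs) - 2L))
    nb <- pool[order(abs(cors), decreasing = TRUE)][seq_len(kk)]
    df <- data.frame(y = out[i, obs], t(out[nb, obs, drop = FALSE]))
    names(df) <- c("y", paste0("x", seq_along(nb)))
    newdf <- as.data.frame(t(out[nb, miss, drop = FALSE]))
    names(newdf) <- paste0("x", seq_along(nb))
    pred <- tryCatch({
      fit <- MASS::rlm(y ~ ., data = df, maxit = 50)
      stats::predict(fit, newdata = newdf)
    }, error = function(e) {
      impute_error("impseq", conditionMessage(e))
    })
    if (any(!is.finite(pred))) {
      impute_error("impseq", "non-finite robust-regression prediction")
    }
    out[i, miss] <- pred
    pool <- c(pool, i)
  }
  list(values = out)
}

# missForest-style iterative random-forest imputation, forests via ranger.
rf_impute_values <- function(v, max_iter, seed, n_trees) {
  withr::local_seed(seed)
  miss_count <- rowSums(is.na(v))
  ord <- order(miss_count)
  ord <- ord[miss_count[ord] > 0]
  x <- median_fill(v)
  miss <- is.na(v)
  best <- x
  prev_diff <- Inf
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    old <- x
    for (i in ord) {
      obs_j <- which(!miss[i, ])
      mis_j <- which(miss[i, ])
      xtrain <- t(x[-i, obs_j, drop = FALSE])
      colnames(xtrain) <- paste0("p", seq_len(nrow(v) - 1L))
      xpred <- t(x[-i, mis_j, drop = FALSE])
      colnames(xpred) <- colnames(xtrain)
      fit <- ranger::ranger(x = xtrain, y = v[i, obs_j],
                            num.trees = n_trees, num.threads = 1L,
                            seed = sample.int(.Machine$integer.max, 1L))
      x[i, mis_j] <- stats::predict(fit, data = xpred,
                                    num.threads = 1L)$predictions
    }
    diff <- sum((x[miss] - old[miss])^2) / max(sum(x[miss]^2), 1e-12)
    if (diff > prev_diff) {      # stopping rule: first increase in change
      x <- old
      converged <- TRUE
      it <- it - 1L
      break
    }
    best <- x
    prev_diff <- diff
  }
  list(values = best, iterations = it, converged = converged || it < max_iter)
}
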