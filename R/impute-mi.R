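#' Multiple imputation by chained equations
#'
#' Generates `n_imputations` completed matrices by cycling a conditional
#' model over the proteins: each protein with missing values is regressed
#' on all other proteins (samples are the observations), its missing
#' entries are replaced by draws from the fitted conditional, and the cycle
#' repeats `maxit` times. Two conditional models are provided:
#'
#' * `mice_norm` — Bayesian normal linear regression: the residual variance
#'   is drawn from its scaled inverse-chi-squared posterior, coefficients
#'   from their normal posterior, and imputations add a fresh noise draw,
#'   so the imputed values carry full predictive uncertainty.
#' * `mice_rf` — random-forest conditional: a forest predicts the target,
#'   and each imputation draws a donor from the terminal node the missing
#'   sample lands in, in a randomly chosen tree.
#'
#' With all-protein predictors the normal conditional becomes singular once
#' the protein count approaches the sample count; this raises a structured
#' `lfq_singular_error` ("system is computationally singular") rather than
#' failing uncontrolled. The optional `predictor_top_k` filter restricts
#' predictors to the most-correlated proteins, trading fidelity to the
#' all-predictor model for feasibility; it is off by default.
#'
#' @param m An [abundance_matrix()]; needs >= 2 proteins and >= 2 observed
#'   values per protein.
#' @param method `"mice_norm"` or `"mice_rf"`.
#' @param n_imputations Number of completed datasets, default 5.
#' @param maxit Chained-equation cycles per imputation, default 5.
#' @param seed Integer seed.
#' @param predictor_top_k Optional predictor-selection cap (`NULL` = all
#'   other proteins).
#' @param n_trees Trees for the `mice_rf` forests, default 100.
#' @return An object of class `mi_result`: list of completed
#'   [abundance_matrix()] objects plus method metadata.
#' @export
mice_impute <- function(m, method = c("mice_norm", "mice_rf"),
                        n_imputations = 5L, maxit = 5L, seed = 1L,
                        predictor_top_k = NULL, n_trees = 100L) {
  method <- match.arg(method)
  v <- m$values
  if (nrow(v) < 2) {
    rlang::abort("multiple imputation needs >= 2 proteins.",
                 class = "lfq_validation_error")
  }
  if (any(rowSums(!is.na(v)) < 2)) {
    rlang::abort("every protein needs >= 2 observed values.",
                 class = "lfq_validation_error")
  }
  if (n_imputations < 2) {
    rlang::abort("`n_imputations` must be >= 2.",
                 class = "lfq_validation_error")
  }
  withr::local_seed(seed)
  x_full <- t(v)                       # samples x proteins
  miss <- is.na(x_full)
  targets <- which(colSums(miss) > 0)
  imputations <- vector("list", n_imputations)
  for (l in seq_len(n_imputations)) {
    x <- x_full
    for (j in targets) {               # random starting draws
      x[miss[, j], j] <- sample(x_full[!miss[, j], j],
                                sum(miss[, j]), replace = TRUE)
    }
    if (length(targets)) {
      for (cycle in seq_len(maxit)) {
        for (j in targets) {
          pred <- select_predictors(x_full, j, predictor_top_k)
          ry <- !miss[, j]
          Xr <- x[ry, pred, drop = FALSE]
          Xm <- x[!ry, pred, drop = FALSE]
          yr <- x[ry, j]
          x[!ry, j] <- if (method == "mice_norm") {
            draw_norm(Xr, yr, Xm)
          } else {
            draw_rf_donor(Xr, yr, Xm, n_trees)
          }
        }
      }
    }
    w <- t(x)
    dimnames(w) <- dimnames(v)
    imputations[[l]] <- abundance_matrix(w, scale = m$scale, truth = m$truth)
  }
  structure(list(imputations = imputations, method = method,
                 n_imputations = n_imputations, maxit = maxit,
                 converged = rep(TRUE, n_imputations), seed = seed,
                 missing_mask = is.na(v)),
            class = "mi_result")
}

select_predictors <- function(x_full, j, top_k) {
  pred <- setdiff(seq_len(ncol(x_full)), j)
  if (!is.null(top_k) && length(pred) > top_k) {
    cors <- abs(suppressWarnings(stats::cor(
      x_full[, j], x_full[, pred], use = "pairwise.complete.obs")))
    cors[is.na(cors)] <- 0
    pred <- pred[order(cors, decreasing = TRUE)][seq_len(top_k)]
  }
  pred
}

singular_error <- function() {
  rlang::abort(paste(
    "system is computationally singular: the normal conditional model has",
    "more predictor proteins than informative observations. Reduce the",
    "number of proteins or set `predictor_top_k`."),
    class = c("lfq_singular_error", "lfq_impute_error", "lfq_error"))
}

# Bayesian normal linear regression draw (the classic chained-equations
# normal conditional): sigma^2 from its inverse-chi-squared posterior,
# beta from N(beta_hat, sigma^2 (X'X)^-1), plus fresh noise.
draw_norm <- function(Xr, yr, Xm) {
  X <- cbind(1, Xr)
  p <- ncol(X)
  n <- nrow(X)
  if (n <= p) singular_error()
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < 1e-8 * max(diag(ch))) singular_error()
  beta_hat <- backsolve(ch, forwardsolve(t(ch), crossprod(X, yr)))
  resid <- yr - drop(X %*% beta_hat)
  nu <- n - p
  sigma2 <- sum(resid^2) / stats::rchisq(1, nu)
  Rinv <- backsolve(ch, diag(p))
  beta <- drop(beta_hat) + drop(Rinv %*% stats::rnorm(p)) * sqrt(sigma2)
  drop(cbind(1, Xm) %*% beta) + stats::rnorm(nrow(Xm), 0, sqrt(sigma2))
}

# Random-forest conditional draw: each missing sample receives the response
# of a random donor from its terminal node in a randomly selected tree.
draw_rf_donor <- function(Xr, yr, Xm, n_trees) {
  colnames(Xr) <- colnames(Xm) <- paste0("p", seq_len(ncol(Xr)))
  fit <- ranger::ranger(x = Xr, y = yr, num.trees = n_trees,
                        num.threads = 1L,
                        seed = sample.int(.Machine$integer.max, 1L))
  nodes_tr <- stats::predict(fit, data = Xr, type = "terminalNodes",
                             num.threads = 1L)$predictions
  nodes_ms <- stats::predict(fit, data = Xm, type = "terminalNodes",
                             num.threads = 1L)$predictions
  out <- numeric(nrow(Xm))
  for (i in seq_len(nrow(Xm))) {
    tr <- sample.int(n_trees, 1L)
    donors <- yr[nodes_tr[, tr] == nodes_ms[i, tr]]
    out[i] <- if (length(donors)) donors[sample.int(length(donors), 1L)]
              else mean(yr)
  }
  out
}

#' Pool estimates across multiple imputations (Rubin's rules)
#'
#' Pools m per-imputation estimates of one scalar quantity (typically a
#' regression slope) and their standard errors: the pooled estimate is the
#' mean; the total variance is the within-imputation variance plus
#' (1 + 1/m) times the between-imputation variance; the reference t
#' distribution uses the Barnard-Rubin small-sample degrees of freedom
#' when the complete-data df is supplied.
#'
#' @param estimates Numeric vector of per-imputation estimates (m >= 2).
#' @param std_errors Positive per-imputation standard errors.
#' @param df_complete Complete-data degrees of freedom (e.g. n - 2 for a
#'   simple regression); `Inf` (default) gives the classic large-sample df.
#' @return A `pooled_estimate`: estimate, within/between/total variance,
#'   df, t statistic and two-sided p-value.
#' @export
pool_rubin <- function(estimates, std_errors, df_complete = Inf) {
  m <- length(estimates)
  if (m < 2 || length(std_errors) != m) {
    rlang::abort("pooling needs m >= 2 estimates with matching SEs.",
                 class = "lfq_validation_error")
  }
  if (any(std_errors < 0)) {
    rlang::abort("standard errors must be non-negative.",
                 class = "lfq_validation_error")
  }
  qbar <- mean(estimates)
  ubar <- mean(std_errors^2)
  b <- stats::var(estimates)
  t_var <- ubar + (1 + 1/m) * b
  lambda <- if (t_var > 0) (1 + 1/m) * b / t_var else 0
  df_old <- if (lambda > 0) (m - 1) / lambda^2 else Inf
  df <- if (is.finite(df_complete)) {
    df_obs <- (df_complete + 1) / (df_complete + 3) * df_complete *
      (1 - lambda)
    if (is.finite(df_old)) df_old * df_obs / (df_old + df_obs) else df_obs
  } else df_old
  statistic <- if (t_var > 0) qbar / sqrt(t_var) else Inf * sign(qbar)
  p <- if (t_var > 0) {
    if (is.finite(df)) 2 * stats::pt(-abs(statistic), df)
    else 2 * stats::pnorm(-abs(statistic))
  } else as.numeric(qbar != 0) * 0 + as.numeric(qbar == 0)
  structure(list(estimate = qbar, within_var = ubar, between_var = b,
                 total_var = t_var, std_error = sqrt(t_var), df = df,
                 statistic = statistic, p_value = p, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> Q = %.4g (SE %.4g), T = %.4g (U %.4g, B %.4g), df %.1f, p = %.3g\n",
    x$estimate, x$std_error, x$total_var, x$within_var, x$between_var,
    x$df, x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pooled estimate
#' @param x A `pooled_estimate`.
#' @param ... Unused.
#' @return One-row tibble with estimate, std.error, statistic, df, p.value
#'   and the variance components.
#' @method tidy pooled_estimate
#' @export
tidy.pooled_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, std.error = x$std_error,
                 statistic = x$statistic, df = x$df, p.value = x$p_value,
                 within_var = x$within_var, between_var = x$between_var,
                 total_var = x$total_var, m = x$m)
}

#' Summarise a multiple-imputation result
#' @param x An `mi_result`.
#' @param ... Unused.
#' @return One-row tibble: method, m, maxit, cells imputed, mean
#'   between-imputation SD of the imputed cells.
#' @method glance mi_result
#' @export
glance.mi_result <- function(x, ...) {
  miss <- x$missing_mask
  n_cells <- sum(miss)
  spread <- if (n_cells) {
    cells <- vapply(x$imputations, function(m) m$values[miss],
                    numeric(n_cells))
    mean(apply(matrix(cells, nrow = n_cells), 1, stats::sd))
  } else 0
  tibble::tibble(method = x$method, m = x$n_imputations, maxit = x$maxit,
                 n_imputed_cells = n_cells, mean_imputation_sd = spread)
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result> %s: %d imputations, maxit %d, %d x %d\n",
              x$method, x$n_imputations, x$maxit,
              nrow(x$imputations[[1]]$values),
              ncol(x$imputations[[1]]$values)))
  invisible(x)
}
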