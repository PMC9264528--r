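# Bayesian PCA imputation.
#
# Model: each protein's sample profile y_i (length d = n_samples) follows
#   y_i = W x_i + mu + eps,  x_i ~ N(0, I_q),  eps ~ N(0, sigma^2 I_d),
# with an automatic-relevance-determination (ARD) prior on the columns of
# W (alpha_j = d / ||w_j||^2) that shrinks unneeded factors to zero, so the
# effective rank is learned rather than fixed at q. EM handles missing
# entries exactly: the E-step conditions each protein's latent score on its
# observed samples only; missing cells are filled with the posterior-mean
# reconstruction mu + W <x_i>. Proteins sharing a missingness pattern share
# the same posterior precision, so the E-step is grouped by pattern and the
# sufficient statistics are accumulated with matrix products.

bpca_impute_values <- function(v, rank, max_iter, tol) {
  d <- ncol(v); n <- nrow(v)
  miss <- is.na(v)
  obs <- !miss
  # Default latent dimension: half the mean per-protein observation count.
  # The sigma^2 EM update carries a posterior-uncertainty term of order
  # sigma^2 * q / mean(|obs_i|); with q at or above the observation count
  # the iteration is marginally unstable and can drift into a degenerate
  # all-factors-dead optimum, so the default keeps a factor-of-two margin.
  # An explicit `rank` is honoured up to min(dims) - 1.
  q_default <- max(1L, floor(0.5 * mean(rowSums(obs))))
  q <- min(rank %||% q_default, min(d, n) - 1L)
  if (q < 1) impute_error("bpca", "matrix too small for a latent factor")
  obs_num <- matrix(as.numeric(obs), n, d)
  n_obs_total <- sum(obs)
  sd_obs <- max(stats::sd(v[obs]), 1e-12)   # scale for convergence checks
  var_obs <- stats::var(v[obs])

  x0 <- mean_impute_values(v)$values
  mu <- colMeans(x0)
  xc <- sweep(x0, 2, mu)
  s <- svd(xc, nu = q, nv = q)
  W <- s$v %*% diag(s$d[seq_len(q)] / sqrt(n), q, q)       # d x q
  sigma2 <- max(mean(xc^2) - sum(s$d[seq_len(q)]^2) / (n * d), 1e-6)
  alpha <- d / pmax(colSums(W^2), 1e-12)

  # group proteins by missingness pattern
  key <- apply(obs, 1, function(r) paste0(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), key)
  G <- length(groups)
  o_list <- lapply(groups, function(rows) which(obs[rows[1], ]))
  n_g <- vapply(groups, length, 0L)
  P <- matrix(0, G, d)                 # pattern x sample indicator
  for (g in seq_len(G)) P[g, o_list[[g]]] <- 1
  ai <- rep(seq_len(q), times = q)     # vec(x x') index helpers
  bi <- rep(seq_len(q), each = q)

  fill <- x0
  prev_fill <- fill[miss]
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    Z <- v - matrix(mu, n, d, byrow = TRUE)
    Z[miss] <- 0
    # E-step, grouped by missingness pattern
    Ex <- matrix(0, n, q)
    Mflat <- matrix(0, G, q * q)
    Minv_list <- vector("list", G)
    for (g in seq_len(G)) {
      o <- o_list[[g]]
      rows <- groups[[g]]
      Wo <- W[o, , drop = FALSE]
      M <- crossprod(Wo) + diag(sigma2 + 1e-12, q)
      Minv <- chol2inv(chol(M))
      Ex[rows, ] <- (Z[rows, o, drop = FALSE] %*% Wo) %*% Minv
      Mflat[g, ] <- as.vector(Minv)
      Minv_list[[g]] <- Minv
    }
    # sufficient statistics per sample column
    H <- Ex[, ai, drop = FALSE] * Ex[, bi, drop = FALSE]   # n x q^2
    Sxx <- crossprod(H, obs_num)                           # q^2 x d
    Sminv <- crossprod(Mflat * n_g, P)                     # q^2 x d
    sum_xy <- crossprod(Ex, Z)                             # q x d
    # M-step: W row-wise, then mu, sigma^2, ARD
    for (k in seq_len(d)) {
      A <- matrix(Sxx[, k] + sigma2 * Sminv[, k], q, q) +
        sigma2 * diag(alpha, q, q)
      eps <- 1e-10 * max(diag(A))        # keeps A invertible as sigma^2 -> 0
      W[k, ] <- drop(solve(A + diag(eps, q, q), sum_xy[, k]))
    }
    fitted <- tcrossprod(Ex, W)
    R <- v - fitted
    R[miss] <- 0
    mu <- colSums(R) / colSums(obs_num)
    E <- R - matrix(mu, n, d, byrow = TRUE)
    E[miss] <- 0
    # posterior-uncertainty term with the UPDATED loadings:
    # sum_i sum_{k in o_i} w_k' (sigma2_old Minv_i) w_k
    trace_term <- sigma2 * sum(vapply(seq_len(G), function(g) {
      Cg <- crossprod(W[o_list[[g]], , drop = FALSE])
      n_g[g] * sum(Minv_list[[g]] * Cg)
    }, 0))
    sigma2 <- max((sum(E^2) + max(trace_term, 0)) / n_obs_total, 1e-12)
    alpha <- d / pmax(colSums(W^2), 1e-12)

    recon <- fitted + matrix(mu, n, d, byrow = TRUE)
    fill[miss] <- recon[miss]
    delta <- sqrt(mean((fill[miss] - prev_fill)^2)) / sd_obs
    prev_fill <- fill[miss]
    if (delta < tol) { converged <- TRUE; break }
    if (sigma2 > var_obs) {   # noise estimate exceeds the data variance:
      rlang::warn("bpca: noise variance diverged; returning current fill.")
      break
    }
  }
  fill[obs] <- v[obs]
  list(values = fill, iterations = it, converged = converged)
}
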