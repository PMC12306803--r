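# Shared fixtures and independent dense-linear-algebra oracles.

# Small random long-format dataset (scalar covariates).
make_toy_df <- function(N = 2, n_i = 3, L = 4, q = 1, family = "gaussian",
                        seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    s <- seq(0, 1, length.out = L)
    rows <- expand.grid(s = s, obs = seq_len(n_i), id = seq_len(N))
    df <- data.frame(id = rows$id, obs = rows$obs, s = rows$s)
    for (r in seq_len(q)) {
      xr <- stats::rnorm(N * n_i)                      # constant over s
      df[[paste0("x", r)]] <- rep(xr, each = L)
    }
    y <- stats::rnorm(nrow(df))
    df$y <- switch(family,
      gaussian = y,
      binomial = as.numeric(y > 0),
      poisson = stats::rpois(nrow(df), 2))
    df
  })
}

make_toy_data <- function(N = 2, n_i = 3, L = 4, q = 1, family = "gaussian",
                          seed = 1) {
  df <- make_toy_df(N, n_i, L, q, family, seed)
  covs <- if (q > 0) paste0("x", seq_len(q)) else character()
  fgee_data(df, covariates = covs, family = family)
}

# Dense n x n working covariance block V(s) = A^{1/2} R A^{1/2}.
dense_V_block <- function(kind, rho, a) {
  n <- length(a)
  R <- switch(kind,
    independence = diag(n),
    exchangeable = matrix(rho, n, n) + diag(1 - rho, n),
    ar1 = rho^abs(outer(seq_len(n), seq_len(n), "-")))
  diag(sqrt(a), nrow = n) %*% R %*% diag(sqrt(a), nrow = n)
}

# Dense s-major stacked design D_i (n_i L x p) and block-diagonal V_i
# (n_i L x n_i L) for one cluster; brute-force W_i and b_i.
dense_cluster_Wb <- function(data, basis, theta, cov, i) {
  fam <- data$family
  idx <- data$rows[[i]]
  ni <- length(idx)
  L <- data$L
  m <- basis$m
  p <- m * (data$q + 1L)
  eta <- fgee:::linear_predictor(data, basis, theta)[idx, , drop = FALSE]
  mu <- matrix(fgee:::clamp_mu(fam$linkinv(eta), fam), ni, L)
  dmu <- matrix(pmax(fam$mu.eta(eta), 1e-10), ni, L)
  v <- matrix(fam$variance(mu), ni, L)
  D <- matrix(0, ni * L, p)
  Vd <- matrix(0, ni * L, ni * L)
  resid <- numeric(ni * L)
  for (l in seq_len(L)) {
    rows_l <- ((l - 1L) * ni + 1L):(l * ni)
    for (j in seq_len(ni)) {
      x <- if (data$q > 0) data$X[idx[j], l, ] else numeric()
      D[rows_l[j], ] <- dmu[j, l] * design_row(basis, data$grid[l], x)
    }
    Vd[rows_l, rows_l] <- dense_V_block(cov$kind, cov$rho[l], v[, l])
    resid[rows_l] <- data$Y[idx, l] - mu[, l]
  }
  Vi <- solve(Vd)
  list(W = t(D) %*% Vi %*% D, b = as.vector(t(D) %*% Vi %*% resid))
}

# Exact (non-shared-Hessian) fold-specific one-step estimate: fold-local
# Hessian average and proportionally rescaled penalty.
exact_fold_estimate <- function(theta0, summaries, lambda1, heldout, basis, q) {
  N <- ncol(summaries$b)
  keep <- setdiff(seq_len(N), heldout)
  cscale <- sum(summaries$n_i[keep]) / sum(summaries$n_i)
  lamS <- fgee:::lambda_S(basis, q, lambda1)
  Wk <- Reduce(`+`, summaries$W[keep]) / length(keep)
  bk <- rowMeans(summaries$b[, keep, drop = FALSE])
  as.vector(theta0 + solve(Wk + cscale * lamS, bk - cscale * lamS %*% theta0))
}
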