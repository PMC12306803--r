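test_that("exchangeable moment estimator matches its formula and truncates", {
  # single cluster, n = 2: ordered pairs (1,2),(2,1) sum to 2ab over divisor 2
  E <- matrix(c(0.3, -1.2), nrow = 2)
  expect_equal(estimate_rho_exchangeable(E, cluster = c(1, 1)),
               0.3 * -1.2)
  # perfectly correlated unit-scale residuals truncate at 1 - eps
  E2 <- matrix(1, nrow = 40, ncol = 3)
  cl <- rep(1:10, each = 4)
  expect_equal(estimate_rho_exchangeable(E2, cl, eps = 1e-3),
               rep(1 - 1e-3, 3))
  # independent residuals give near-zero estimates
  set.seed(5)
  E3 <- matrix(rnorm(500 * 10), nrow = 500 * 10, ncol = 4)
  expect_lt(max(abs(estimate_rho_exchangeable(E3, rep(1:500, each = 10)))), 0.05)
  expect_warning(
    estimate_rho_exchangeable(rbind(E, 1), cluster = c(1, 1, 2)),
    "n_i < 2")
})

test_that("AR1 Yule-Walker estimator matches its formula, truncates and is consistent", {
  expect_equal(estimate_rho_ar1(matrix(c(1, 1, 1, 1)), rep(1, 4)), 3 / 4)
  # alternating series: raw -3/4 truncated to 0
  expect_equal(estimate_rho_ar1(matrix(c(1, -1, 1, -1)), rep(1, 4)), 0)
  expect_warning(estimate_rho_ar1(matrix(rep(0, 4)), rep(1, 4)), "all-zero")
  set.seed(6)
  n <- 100; N <- 500
  E <- matrix(0, N * n, 1)
  for (i in seq_len(N)) {
    z <- as.vector(arima.sim(list(ar = 0.5), n))
    E[((i - 1) * n + 1):(i * n), 1] <- z
  }
  rho_hat <- estimate_rho_ar1(E, rep(seq_len(N), each = n))
  expect_gt(rho_hat, 0.45)
  expect_lt(rho_hat, 0.55)
})

test_that("the running-mean smoother preserves constants, damps spikes and reduces noise", {
  expect_equal(smooth_rho(rep(0.4, 30)), rep(0.4, 30))
  spike <- c(rep(0.2, 10), 0.9, rep(0.2, 10))
  sm <- smooth_rho(spike, window = 5)
  expect_lt(sm[11] - 0.2, (0.9 - 0.2) / 4)     # attenuated by the window
  set.seed(8)
  noisy <- pmin(pmax(0.5 + rnorm(100, sd = 0.1), 0), 1)
  expect_lt(var(smooth_rho(noisy)), var(noisy))
  # re-truncation to the structure range
  expect_true(all(smooth_rho(c(-0.5, rep(0.1, 20)), range = c(0, 1)) >= 0))
})

test_that("closed-form exchangeable inverse matches dense linear algebra", {
  expect_equal(apply_inverse_exchangeable(c(1, 2), rho = 0, a = c(2, 4)),
               c(0.5, 0.5))
  expect_equal(apply_inverse_exchangeable(c(1, 1), rho = 0.5, a = c(1, 1)),
               c(2 / 3, 2 / 3))
  set.seed(9)
  n <- 25
  a <- runif(n, 0.5, 2)
  r <- rnorm(n)
  for (rho in c(-0.03, 0, 0.3, 0.9)) {
    V <- dense_V_block("exchangeable", rho, a)
    expect_equal(apply_inverse_exchangeable(r, rho, a),
                 as.vector(solve(V, r)), tolerance = 1e-10)
  }
  expect_error(apply_inverse_exchangeable(r, rho = -0.1, a = a), "truncate")
})

test_that("AR1 inverse matches the known tridiagonal form and dense solves", {
  expect_equal(apply_inverse_ar1(c(1, 2), rho = 0, a = c(2, 4)), c(0.5, 0.5))
  expect_equal(apply_inverse_ar1(c(1, 0, 0), rho = 0.5, a = rep(1, 3)),
               c(4 / 3, -2 / 3, 0), tolerance = 1e-12)
  set.seed(10)
  n <- 200
  a <- runif(n, 0.5, 2)
  r <- rnorm(n)
  for (rho in c(0, 0.4, 0.95)) {
    V <- dense_V_block("ar1", rho, a)
    expect_equal(apply_inverse_ar1(r, rho, a), as.vector(solve(V, r)),
                 tolerance = 1e-8)
  }
  expect_error(apply_inverse_ar1(r, rho = 1, a = a), "rho")
})

test_that("inverse composed with dense multiplication is the identity", {
  set.seed(11)
  for (kind in c("exchangeable", "ar1")) {
    for (n in c(1, 2, 7)) {
      a <- runif(n, 0.5, 2)
      r <- rnorm(n)
      rho <- 0.6
      V <- dense_V_block(kind, rho, a)
      y <- switch(kind,
        exchangeable = apply_inverse_exchangeable(r, rho, a),
        ar1 = apply_inverse_ar1(r, rho, a))
      expect_equal(as.vector(V %*% y), r, tolerance = 1e-8)
    }
  }
})

test_that("blockwise quadratic forms match dense assembly of D'V^{-1}D", {
  for (family in c("gaussian", "binomial")) {
    d <- make_toy_data(N = 3, n_i = 4, L = 6, q = 1, family = family, seed = 13)
    bs <- build_basis(d$grid, n_knots = 1, order = 3)  # m = 3, p = 6
    set.seed(14)
    theta <- rnorm(6, sd = 0.3)
    for (kind in c("independence", "exchangeable", "ar1")) {
      cov <- working_cov(kind)
      cov$rho <- switch(kind, independence = rep(0, 6),
                        exchangeable = seq(0.1, 0.6, length.out = 6),
                        ar1 = seq(0.2, 0.7, length.out = 6))
      summ <- cluster_summaries(d, bs, theta, cov)
      for (i in 1:3) {
        oracle <- dense_cluster_Wb(d, bs, theta, cov, i)
        expect_equal(summ$W[[i]], oracle$W, tolerance = 1e-10,
                     ignore_attr = TRUE)
        expect_equal(summ$b[, i], oracle$b, tolerance = 1e-10)
        # W_i is symmetric PSD
        expect_equal(summ$W[[i]], t(summ$W[[i]]))
        expect_gte(min(eigen(summ$W[[i]], symmetric = TRUE,
                             only.values = TRUE)$values), -1e-8)
      }
    }
  }
})

test_that("quadratic forms reduce to least squares under independence and vanish at the truth", {
  d <- make_toy_data(N = 2, n_i = 3, L = 8, q = 1, seed = 15)
  bs <- build_basis(d$grid, n_knots = 2, order = 3)
  p <- bs$m * 2
  set.seed(16)
  theta <- rnorm(p, sd = 0.2)
  cov <- working_cov("independence"); cov$rho <- rep(0, d$L)
  summ <- cluster_summaries(d, bs, theta, cov)
  for (i in 1:2) {
    ni <- d$n_i[i]
    Xi <- do.call(rbind, lapply(seq_len(d$L), function(l)
      t(vapply(seq_len(ni), function(j)
        design_row(bs, d$grid[l], d$X[d$rows[[i]][j], l, ]), numeric(p)))))
    yi <- fgee:::flatten_cluster(d, i)
    expect_equal(summ$W[[i]], crossprod(Xi), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(summ$b[, i], as.vector(crossprod(Xi, yi - Xi %*% theta)),
                 tolerance = 1e-10)
  }
  # residual score vanishes when Y equals the fitted mean exactly
  d2 <- d
  d2$Y <- fgee:::linear_predictor(d, bs, theta)
  summ2 <- cluster_summaries(d2, bs, theta, cov)
  expect_equal(max(abs(summ2$b)), 0, tolerance = 1e-10)
})

test_that("correlation estimates are invariant to cluster relabeling and within-cluster permutation", {
  set.seed(17)
  E <- matrix(rnorm(60), nrow = 20, ncol = 3)
  cl <- rep(1:5, each = 4)
  base_ex <- estimate_rho_exchangeable(E, cl)
  # relabel clusters
  perm <- c(3, 5, 1, 2, 4)
  ord <- order(perm[cl])
  expect_equal(estimate_rho_exchangeable(E[ord, ], sort(perm[cl])), base_ex)
  # permute j within each cluster (exchangeable only)
  ord2 <- as.vector(vapply(split(seq_len(20), cl), sample, numeric(4)))
  expect_equal(estimate_rho_exchangeable(E[ord2, ], cl), base_ex)
})
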