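test_that("the sandwich variance matches a dense GEE oracle on a toy instance", {
  d <- make_toy_data(N = 5, n_i = 2, L = 3, q = 1, seed = 41)
  bs <- build_basis(d$grid, n_knots = 1, order = 3)   # m = 3, p = 6
  p <- 6
  theta <- fit_initial(d, bs, lambda0 = 0)$theta      # OLS
  cov <- working_cov("independence"); cov$rho <- rep(0, d$L)
  V <- sandwich_variance(d, bs, theta, cov, lambda = 0)
  # classic dense sandwich: (X'X)^-1 (sum_i X_i' r_i r_i' X_i) (X'X)^-1
  Xi <- lapply(seq_len(d$N), function(i) {
    do.call(rbind, lapply(seq_len(d$L), function(l)
      t(vapply(d$rows[[i]], function(row)
        design_row(bs, d$grid[l], d$X[row, l, ]), numeric(p)))))
  })
  yi <- lapply(seq_len(d$N), function(i) fgee:::flatten_cluster(d, i))
  XtX <- Reduce(`+`, lapply(Xi, crossprod))
  meat <- Reduce(`+`, lapply(seq_len(d$N), function(i) {
    u <- crossprod(Xi[[i]], yi[[i]] - Xi[[i]] %*% theta)
    tcrossprod(u)
  }))
  oracle <- solve(XtX) %*% meat %*% solve(XtX)
  expect_equal(V$var_theta, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  # curve SEs are the square roots of B Sigma_r B' diagonals
  expect_equal(V$se_beta[, 1],
               sqrt(diag(bs$B %*% V$Sigma_theta[[1]] %*% t(bs$B))),
               tolerance = 1e-12)
})

test_that("zero residuals give zero variance and duplication halves it", {
  d <- make_toy_data(N = 5, n_i = 2, L = 4, q = 1, seed = 42)
  bs <- build_basis(d$grid, n_knots = 1, order = 3)
  theta <- fit_initial(d, bs, lambda0 = 0)$theta
  cov <- working_cov("independence"); cov$rho <- rep(0, d$L)
  dz <- d
  dz$Y <- fgee:::linear_predictor(d, bs, theta)
  Vz <- sandwich_variance(dz, bs, theta, cov, lambda = 0)
  expect_equal(max(abs(Vz$var_theta)), 0, tolerance = 1e-12)
  # duplicate every cluster: same Lambda1 S (per-cluster scale) -> Var halves
  V1 <- sandwich_variance(d, bs, theta, cov, lambda = 0.1)
  df <- make_toy_df(N = 5, n_i = 2, L = 4, q = 1, seed = 42)
  df2 <- df; df2$id <- df2$id + 5
  d2 <- fgee_data(rbind(df, df2), covariates = "x1")
  V2 <- sandwich_variance(d2, bs, theta, cov, lambda = 0.1)
  expect_equal(V2$var_theta, V1$var_theta / 2, tolerance = 1e-10)
})

test_that("pointwise intervals use the normal quantile and handle zero SEs", {
  ci <- pointwise_ci(beta = matrix(0), se = matrix(1), alpha = 0.05)
  expect_equal(ci$lower[1], -1.959964, tolerance = 1e-6)
  expect_equal(ci$upper[1], 1.959964, tolerance = 1e-6)
  ci0 <- pointwise_ci(beta = matrix(2.5), se = matrix(0))
  expect_equal(ci0$lower[1], 2.5)
  expect_equal(ci0$upper[1], 2.5)
  expect_error(pointwise_ci(matrix(0), matrix(-1)), "non-negative")
})

test_that("the max-statistic quantile approaches the normal quantile for one basis function", {
  # with a single spline coefficient the max statistic is |N(0,1)|
  g <- seq(0, 1, length.out = 10)
  bs <- list(B = matrix(1, 10, 1), m = 1L)
  variance <- fgee:::finalize_variance(matrix(4), structure(bs, class = "fgee_basis"), q = 0)
  jt <- joint_ci(beta = matrix(0, 10, 1), variance = variance,
                 basis = structure(bs, class = "fgee_basis"),
                 alpha = 0.05, T = 1e5, seed = 44)
  expect_lt(abs(jt$q[1] - 1.96), 0.03)
})

test_that("joint bands contain pointwise intervals at every point", {
  d <- gen_sim1(N = 12, n_i = 4, L = 30, seed = 45)
  f <- fgee(d, correlation = "exchangeable", T_joint = 100, seed = 46)
  expect_true(all(f$joint$lower <= f$pointwise$lower + 1e-12))
  expect_true(all(f$joint$upper >= f$pointwise$upper - 1e-12))
  expect_true(all(f$joint$q >= qnorm(0.975)))
  # theta-space variant is also a valid band multiplier
  jt <- joint_ci(f$beta, f$variance, f$basis, T = 500, seed = 47,
                 statistic = "theta")
  expect_true(all(jt$q >= qnorm(0.975)))
})

test_that("the fast cluster bootstrap is deterministic and degenerates to the one-step", {
  d <- gen_sim1(N = 10, n_i = 4, L = 25, seed = 48)
  bs <- build_basis(d$grid)
  init <- fit_initial(d, bs)
  cov <- estimate_rho(d, bs, init$theta, working_cov("exchangeable"))
  summ <- cluster_summaries(d, bs, init$theta, cov)
  lam <- 0.01
  onestep <- one_step_update(init$theta, summ, lam, bs, d$q)$theta
  # identity resample reproduces theta-hat(1) exactly
  ident <- fast_cluster_bootstrap(init$theta, summ, lam, bs, d$q,
                                  indices = matrix(1:10, nrow = 1))
  expect_equal(as.vector(ident$draws[1, ]), onestep, tolerance = 1e-12)
  b1 <- fast_cluster_bootstrap(init$theta, summ, lam, bs, d$q, T = 50, seed = 7)
  b2 <- fast_cluster_bootstrap(init$theta, summ, lam, bs, d$q, T = 50, seed = 7)
  expect_identical(b1$draws, b2$draws)
  # the bootstrap covariance stabilizes in T
  c1 <- fast_cluster_bootstrap(init$theta, summ, lam, bs, d$q, T = 2000,
                               seed = 100)$var_boot
  c2 <- fast_cluster_bootstrap(init$theta, summ, lam, bs, d$q, T = 2000,
                               seed = 200)$var_boot
  expect_lt(norm(c1 - c2, "F") / norm(c1, "F"), 0.05)
})

test_that("bootstrap and sandwich standard errors agree on simulated data", {
  d <- gen_sim1(N = 100, n_i = 25, L = 100, seed = 49)
  f <- fgee(d, correlation = "exchangeable", ci = "pointwise",
            boot = TRUE, T_boot = 500, seed = 50)
  rel <- abs(colMeans(f$boot$se_beta) - colMeans(f$se)) / colMeans(f$se)
  expect_lt(max(rel), 0.15)
})
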