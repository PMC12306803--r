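test_that("unpenalized Gaussian initial fit equals ordinary least squares", {
  d <- make_toy_data(N = 4, n_i = 3, L = 12, q = 1, seed = 21)
  bs <- build_basis(d$grid, n_knots = 3, order = 3)
  p <- bs$m * 2
  fit <- fit_initial(d, bs, lambda0 = 0)
  # stacked design over all (i, j, s)
  X <- do.call(rbind, lapply(seq_len(d$N), function(i) {
    do.call(rbind, lapply(d$rows[[i]], function(row)
      t(vapply(seq_len(d$L), function(l)
        design_row(bs, d$grid[l], d$X[row, l, ]), numeric(p)))))
  }))
  y <- as.vector(t(d$Y))
  expect_equal(fit$theta, as.vector(solve(crossprod(X), crossprod(X, y))),
               tolerance = 1e-8)
})

test_that("the initial fit is a root of the penalized independence estimating equation", {
  d <- gen_sim1(N = 30, n_i = 8, L = 50, seed = 22)
  bs <- build_basis(d$grid)
  # score residual: sum_i D_i' A_i^{-1} (Y_i - mu_i) - Lambda0 S theta
  score_norm <- function(fit) {
    cov <- working_cov("independence"); cov$rho <- rep(0, d$L)
    summ <- cluster_summaries(d, bs, fit$theta, cov)
    score <- d$N * summ$bbar -
      as.vector(fgee:::lambda_S(bs, d$q, fit$lambda0) %*% fit$theta)
    sqrt(sum(score^2)) / max(1, sqrt(sum(fit$theta^2)))
  }
  fit_g <- fit_initial(d, bs, lambda0 = "auto", method = "gcv")
  expect_true(fit_g$converged)
  expect_lt(score_norm(fit_g), 1e-6)
  # the REML route satisfies the same equation at its own lambda, to the
  # optimizer's (looser) tolerance
  fit_r <- fit_initial(d, bs, lambda0 = "auto", method = "reml")
  expect_lt(score_norm(fit_r), 1e-4)
})

test_that("separated binomial fits stay finite under a ridge floor", {
  df <- make_toy_df(N = 3, n_i = 3, L = 10, q = 0, seed = 23)
  df$y <- 0
  d <- fgee_data(df, covariates = character(), family = "binomial")
  bs <- build_basis(d$grid, n_knots = 2, order = 3)
  fit <- fit_initial(d, bs, lambda0 = 1, max_iter = 60)
  expect_true(all(is.finite(fit$theta)))
  expect_true(all(coef_curves(bs, fit$theta) < -2))   # strongly negative logit
})

test_that("one Newton step is exact for quadratic objectives and fixed points", {
  d <- make_toy_data(N = 4, n_i = 3, L = 12, q = 1, seed = 24)
  bs <- build_basis(d$grid, n_knots = 3, order = 3)
  q <- d$q
  cov <- working_cov("independence"); cov$rho <- rep(0, d$L)
  ols <- fit_initial(d, bs, lambda0 = 0)$theta
  # from an arbitrary start, one step with V = I, Lambda1 = 0 lands on OLS
  set.seed(25)
  start <- rnorm(length(ols), sd = 0.5)
  summ <- cluster_summaries(d, bs, start, cov)
  upd <- one_step_update(start, summ, 0, bs, q)
  expect_equal(upd$theta, ols, tolerance = 1e-8)
  # a root of the penalized weighted equation is a Newton fixed point
  lam <- c(0.3, 2)
  covx <- working_cov("exchangeable")
  gls <- fit_gls(d, "exchangeable", n_knots = 3, order = 3, lambda = lam,
                 ci = "pointwise")
  covx$rho <- NULL
  covx <- estimate_rho(d, bs, gls$theta, covx)
  summ_fp <- cluster_summaries(d, bs, gls$theta, covx)
  upd_fp <- one_step_update(gls$theta, summ_fp, lam, bs, q)
  expect_equal(upd_fp$theta, gls$theta, tolerance = 1e-8)
})

test_that("one step with fixed working correlation solves the Gaussian GEE exactly", {
  d <- gen_sim1(N = 15, n_i = 5, L = 30, seed = 26)
  bs <- build_basis(d$grid)
  init <- fit_initial(d, bs)
  cov <- estimate_rho(d, bs, init$theta, working_cov("exchangeable"))
  summ <- cluster_summaries(d, bs, init$theta, cov)
  upd <- one_step_update(init$theta, summ, 1e-4, bs, d$q)
  # iterate the same equation at *fixed* rho: already converged
  summ2 <- cluster_summaries(d, bs, upd$theta, cov)
  upd2 <- one_step_update(upd$theta, summ2, 1e-4, bs, d$q)
  expect_equal(upd2$theta, upd$theta, tolerance = 1e-8)
})

test_that("cluster folds are balanced, deterministic and validated", {
  f <- make_folds(10, 10, seed = 1)
  expect_equal(sort(lengths(f)), rep(1L, 10))
  f2 <- make_folds(25, 10, seed = 2)
  expect_equal(sum(lengths(f2)), 25)
  expect_true(all(lengths(f2) %in% 2:3))
  expect_setequal(unlist(f2), 1:25)
  expect_identical(make_folds(25, 10, seed = 3), make_folds(25, 10, seed = 3))
  expect_error(make_folds(5, 6), "K must not exceed")
})

test_that("fast fold estimates reduce correctly and rescale cluster weights", {
  d <- gen_sim1(N = 12, n_i = 4, L = 25, seed = 27)
  bs <- build_basis(d$grid)
  init <- fit_initial(d, bs)
  cov <- estimate_rho(d, bs, init$theta, working_cov("exchangeable"))
  summ <- cluster_summaries(d, bs, init$theta, cov)
  lam <- 0.01
  # degenerate fold: held-out empty -> the full one-step estimate
  full <- one_step_update(init$theta, summ, lam, bs, d$q)$theta
  expect_equal(fold_estimate(init$theta, summ, lam, integer(0), bs, d$q),
               full, tolerance = 1e-12)
  # manual replication of the rescaled held-in score
  held <- c(2, 5, 9)
  keep <- setdiff(1:12, held)
  ntilde <- sum(d$n_i) / sum(d$n_i[keep])
  expect_equal(ntilde, 12 / 9)  # equal cluster sizes: K/(K-1) pattern
  lamS <- fgee:::lambda_S(bs, d$q, rep(lam, d$q + 1))
  manual <- init$theta + solve(summ$Wbar + lamS,
    (ntilde / 12) * rowSums(summ$b[, keep]) - lamS %*% init$theta)
  expect_equal(fold_estimate(init$theta, summ, lam, held, bs, d$q),
               as.vector(manual), tolerance = 1e-10)
  expect_error(fold_estimate(init$theta, summ, lam, 1:12, bs, d$q), "empty")
})

test_that("the CV score is the mean held-out negative working log-likelihood", {
  d <- make_toy_data(N = 3, n_i = 2, L = 10, q = 0, seed = 28)
  bs <- build_basis(d$grid, n_knots = 2, order = 3)
  # gaussian: constant prediction at the held-out mean gives half the
  # (population) variance
  held <- 2L
  y <- d$Y[d$rows[[held]], ]
  ybar <- mean(y)
  theta_const <- rep(ybar, bs$m)   # partition of unity -> constant curve
  expect_equal(cv_score(theta_const, d, bs, held),
               0.5 * mean((y - ybar)^2), tolerance = 1e-12)
  # binomial: perfect clamped prediction scores ~ -log(1 - 1e-6) per point
  dfb <- make_toy_df(N = 2, n_i = 2, L = 6, q = 0, seed = 29)
  dfb$y <- 1
  db <- fgee_data(dfb, covariates = character(), family = "binomial")
  bsb <- build_basis(db$grid, n_knots = 2, order = 3)
  theta_big <- rep(40, bsb$m)      # expit -> 1, clamped
  expect_equal(cv_score(theta_big, db, bsb, 1L), -log(1 - 1e-6),
               tolerance = 1e-9)
  # proper scoring: the truth beats a perturbed mean on average
  set.seed(30)
  d3 <- gen_sim1(N = 20, n_i = 4, L = 25, seed = 31)
  bs3 <- build_basis(d3$grid)
  fit <- fit_initial(d3, bs3)
  expect_lt(cv_score(fit$theta, d3, bs3, 1:20),
            cv_score(fit$theta + 0.5, d3, bs3, 1:20))
})

test_that("smoothing-parameter CV selects the grid argmin, breaks ties smooth, and factors once per candidate", {
  d <- gen_sim1(N = 15, n_i = 4, L = 30, seed = 32)
  bs <- build_basis(d$grid)
  init <- fit_initial(d, bs)
  cov <- estimate_rho(d, bs, init$theta, working_cov("exchangeable"))
  summ <- cluster_summaries(d, bs, init$theta, cov)
  fgee_solve_count(reset = TRUE)
  tuned <- tune_lambda1(d, bs, init$theta, summ, init$lambda0,
                        K = 5, seed = 33, stage2 = FALSE)
  # exactly one p x p factorization per Lambda1 candidate
  expect_equal(tuned$n_factorizations, nrow(tuned$scores))
  # the returned multiplier attains the minimum of the CV profile, and the
  # largest (smoothest) candidate is picked among exact ties
  sc <- tuned$scores
  minset <- sc$c[sc$cv <= min(sc$cv) + 1e-12 * max(1, abs(min(sc$cv)))]
  expect_equal(tuned$c_opt, max(minset))
})

test_that("the one-step estimate is invariant to cluster ordering", {
  d <- gen_sim1(N = 10, n_i = 4, L = 25, seed = 34)
  fit <- function(data) {
    bs <- build_basis(data$grid)
    init <- fit_initial(data, bs)
    cov <- estimate_rho(data, bs, init$theta, working_cov("exchangeable"))
    summ <- cluster_summaries(data, bs, init$theta, cov)
    one_step_update(init$theta, summ, 0.01, bs, data$q)$theta
  }
  # rebuild the same data with clusters relabeled in reverse
  df <- data.frame(
    id = rep(11 - d$cluster_levels[d$cluster], each = d$L),
    obs = rep(d$obs, each = d$L),
    s = rep(d$grid_orig, times = nrow(d$Y)),
    y = as.vector(t(d$Y)),
    x1 = as.vector(t(d$X[, , 1])),
    x2 = as.vector(t(d$X[, , 2])))
  d_perm <- fgee_data(df, covariates = c("x1", "x2"))
  expect_equal(fit(d_perm), fit(d), tolerance = 1e-10)
})
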