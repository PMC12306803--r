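#' Fully-iterated penalized GLS for Gaussian outcomes
#'
#' The benchmark estimator: for a Gaussian identity-link model the penalized
#' weighted normal equations can be iterated to convergence at modest cost,
#' alternating
#' \enumerate{
#'   \item \eqn{\theta \leftarrow (\sum_i W_i + N\Lambda S)^{-1}
#'     \sum_i (W_i \theta + b_i)} at the current \eqn{\hat\rho(s)}, and
#'   \item re-estimation of \eqn{\hat\rho(s)} from the new residuals,
#' }
#' until the relative change in \eqn{\theta} falls below `tol`.  With an
#' independence structure the first step is the closed-form penalized least
#' squares solution and no iteration is needed.  Inference uses the same
#' sandwich estimator as the one-step, with the structure's working
#' covariance evaluated at the converged fit.
#'
#' @param data an `fgee_data` with `family = "gaussian"`.
#' @param correlation `"independence"` or `"exchangeable"`.
#' @param n_knots,order,diff_order basis settings.
#' @param lambda `"cv"` (tuned by the same fast K-fold CV as the one-step,
#'   for comparability) or fixed values (per-cluster scale).
#' @param K CV folds.
#' @param tol,max_iter convergence controls for the outer
#'   \eqn{\theta}/\eqn{\rho} alternation.
#' @param alpha,ci,T_joint confidence-interval settings as in [fgee()].
#' @param seed integer seed.
#' @return An `fgee_fit` with `estimator = "gls"` plus `iterations`.
#' @export
fit_gls <- function(data, correlation = c("exchangeable", "independence"),
                    n_knots = 10, order = 4, diff_order = 2,
                    lambda = "cv", K = 10L, tol = 1e-8, max_iter = 50L,
                    alpha = 0.05, ci = c("pointwise", "joint"),
                    T_joint = 1000L, seed = NULL) {
  stopifnot(inherits(data, "fgee_data"))
  if (data$family$name != "gaussian")
    stop("the penalized GLS benchmark is defined for Gaussian outcomes only",
         call. = FALSE)
  correlation <- match.arg(correlation)
  basis <- build_basis(data$grid, n_knots = n_knots, order = order,
                       diff_order = diff_order)
  q <- data$q

  init <- fit_initial(data, basis, lambda0 = "auto")
  cov <- estimate_rho(data, basis, init$theta, working_cov(correlation))
  summ <- cluster_summaries(data, basis, init$theta, cov)
  if (identical(lambda, "cv")) {
    cv <- tune_lambda1(data, basis, init$theta, summ, init$lambda0,
                       K = K, seed = seed)
    lambda <- cv$lambda1
  } else {
    cv <- NULL
    lambda <- expand_lambda(lambda, q)
  }

  theta <- init$theta
  iter <- 0L
  prev_change <- Inf
  rho_prev <- cov$rho
  repeat {
    iter <- iter + 1L
    upd <- one_step_update(theta, summ, lambda, basis, q)
    change <- sqrt(sum(upd$step^2)) / max(sqrt(sum(theta^2)), 1e-10)
    theta <- upd$theta
    if (change < tol || iter >= max_iter) break
    cov_new <- estimate_rho(data, basis, theta, working_cov(correlation))
    if (iter > 2L && change > prev_change) {
      # dampen an oscillating correlation estimate
      warning("oscillating rho-hat(s); averaging the last two estimates")
      cov_new$rho <- (cov_new$rho + rho_prev) / 2
    }
    rho_prev <- cov_new$rho
    prev_change <- change
    cov <- cov_new
    summ <- cluster_summaries(data, basis, theta, cov)
    if (correlation == "independence") break  # quadratic objective: one exact step
  }

  cov1 <- estimate_rho(data, basis, theta, working_cov(correlation))
  summ1 <- cluster_summaries(data, basis, theta, cov1)
  variance <- sandwich_variance(data, basis, theta, cov1, lambda,
                                summaries = summ1)
  beta <- coef_curves(basis, theta)
  colnames(beta) <- c("(Intercept)", data$covariates)
  se <- variance$se_beta
  pw <- if ("pointwise" %in% ci) pointwise_ci(beta, se, alpha) else NULL
  jt <- if ("joint" %in% ci)
    joint_ci(beta, variance, basis, alpha = alpha, T = T_joint,
             seed = if (is.null(seed)) NULL else seed + 211L) else NULL

  structure(
    list(estimator = "gls", correlation = correlation,
         theta0 = init$theta, theta = theta, beta = beta, se = se,
         pointwise = pw, joint = jt,
         rho0 = NULL, rho1 = cov1$rho,
         lambda0 = init$lambda0, lambda1 = lambda,
         variance = variance, boot = NULL, cv = cv,
         basis = basis, grid = data$grid, grid_orig = data$grid_orig,
         family = data$family$name, alpha = alpha, iterations = iter,
         N = data$N, seed = seed),
    class = "fgee_fit")
}

#' Function-on-scalar regression with robust sandwich inference
#'
#' The initial working-independence fit \eqn{\hat\theta^{(0)}_{\Lambda_0}}
#' reported as an estimator in its own right, with the sandwich variance
#' computed under the same working-independence covariance (V = I) and the
#' initial penalty.  This is the natural "fast" baseline that ignores
#' intra-cluster correlation at the estimation stage and relies on the robust
#' variance for validity.
#'
#' @param data an `fgee_data`.
#' @param n_knots,order,diff_order basis settings.
#' @param lambda0 `"auto"` or fixed initial smoothing parameters.
#' @param alpha,ci,T_joint confidence-interval settings as in [fgee()].
#' @param seed integer seed (joint-band draws).
#' @return An `fgee_fit` with `estimator = "fosr"`.
#' @export
fosr_sandwich <- function(data, n_knots = 10, order = 4, diff_order = 2,
                          lambda0 = "auto", alpha = 0.05,
                          ci = c("pointwise", "joint"), T_joint = 1000L,
                          seed = NULL) {
  stopifnot(inherits(data, "fgee_data"))
  basis <- build_basis(data$grid, n_knots = n_knots, order = order,
                       diff_order = diff_order)
  q <- data$q
  init <- fit_initial(data, basis, lambda0 = lambda0)
  cov <- working_cov("independence")
  cov$rho <- rep(0, data$L)
  summ <- cluster_summaries(data, basis, init$theta, cov)
  # the initial fit penalizes on the summed scale; per-cluster scale is /N
  lam_pc <- expand_lambda(init$lambda0, q) / data$N
  variance <- sandwich_variance(data, basis, init$theta, cov, lam_pc,
                                summaries = summ)
  beta <- coef_curves(basis, init$theta)
  colnames(beta) <- c("(Intercept)", data$covariates)
  se <- variance$se_beta
  pw <- if ("pointwise" %in% ci) pointwise_ci(beta, se, alpha) else NULL
  jt <- if ("joint" %in% ci)
    joint_ci(beta, variance, basis, alpha = alpha, T = T_joint,
             seed = if (is.null(seed)) NULL else seed + 211L) else NULL
  structure(
    list(estimator = "fosr", correlation = "independence",
         theta0 = init$theta, theta = init$theta, beta = beta, se = se,
         pointwise = pw, joint = jt,
         rho0 = NULL, rho1 = rep(0, data$L),
         lambda0 = init$lambda0, lambda1 = lam_pc,
         variance = variance, boot = NULL, cv = NULL,
         basis = basis, grid = data$grid, grid_orig = data$grid_orig,
         family = data$family$name, alpha = alpha,
         init_iterations = init$iterations, init_converged = init$converged,
         N = data$N, seed = seed),
    class = "fgee_fit")
}
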