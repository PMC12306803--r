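#' Fit a one-step penalized functional GEE
#'
#' The full pipeline for marginal function-on-scalar regression with
#' longitudinal functional outcomes:
#' \enumerate{
#'   \item initial penalized working-independence fit
#'     \eqn{\hat\theta^{(0)}_{\Lambda_0}} ([fit_initial()]);
#'   \item first correlation pass: \eqn{\hat\rho^{(0)}(s)} from Pearson
#'     residuals at \eqn{\hat\theta^{(0)}};
#'   \item per-cluster quadratic forms \eqn{W_i, b_i}
#'     ([cluster_summaries()]);
#'   \item smoothing-parameter tuning for the update by fast K-fold cluster
#'     CV ([tune_lambda1()]), unless `lambda1` is given;
#'   \item one Newton-Raphson step to \eqn{\hat\theta^{(1)}_{\Lambda_1}}
#'     ([one_step_update()]);
#'   \item second correlation pass at \eqn{\hat\theta^{(1)}}, then the
#'     sandwich variance ([sandwich_variance()]) and, optionally, the fast
#'     cluster bootstrap;
#'   \item pointwise and joint confidence bands.
#' }
#'
#' @param data an `fgee_data` (see [fgee_data()] / [read_fgee_data()]).
#' @param correlation working correlation structure: `"independence"`,
#'   `"exchangeable"` or `"ar1"`.
#' @param n_knots,order,diff_order basis/penalty settings ([build_basis()]).
#' @param lambda0 `"auto"` (GCV) or fixed values for the initial fit.
#' @param lambda1 `"cv"` (fast K-fold CV) or fixed values for the update.
#' @param K number of CV folds.
#' @param alpha miscoverage level for the confidence bands.
#' @param ci character vector among `"pointwise"`, `"joint"`.
#' @param joint_mode `"parametric"` or `"nonparametric"` joint bands.
#' @param T_joint draws for the joint band max statistic.
#' @param boot logical; also run the fast cluster bootstrap and report
#'   bootstrap SEs.
#' @param T_boot bootstrap replicates.
#' @param smooth_rho logical; smooth \eqn{\hat\rho(s)} over the domain.
#' @param rho_eps truncation bound for \eqn{\hat\rho(s)}.
#' @param seed integer seed driving fold assignment, joint-band draws and the
#'   bootstrap.
#' @param stage2 logical; per-coefficient refinement in the CV search.
#' @return An object of class `fgee_fit`; see the package vignette.  Key
#'   elements: `theta0`, `theta` (one-step), `beta` (L x (q+1) curves), `se`,
#'   `pointwise`, `joint`, `rho0`, `rho1`, `lambda0`, `lambda1`, `variance`,
#'   `boot`, `cv`.
#' @examples
#' d <- gen_sim1(N = 12, n_i = 4, L = 25, seed = 1)
#' f <- fgee(d, correlation = "exchangeable", T_joint = 200, seed = 2)
#' print(f)
#' @export
fgee <- function(data,
                 correlation = c("exchangeable", "ar1", "independence"),
                 n_knots = 10, order = 4, diff_order = 2,
                 lambda0 = "auto", lambda1 = "cv", K = 10L,
                 alpha = 0.05, ci = c("pointwise", "joint"),
                 joint_mode = c("parametric", "nonparametric"),
                 T_joint = 1000L, boot = FALSE, T_boot = 1000L,
                 smooth_rho = FALSE, rho_eps = 1e-3,
                 seed = NULL, stage2 = TRUE) {
  stopifnot(inherits(data, "fgee_data"))
  correlation <- match.arg(correlation)
  joint_mode <- match.arg(joint_mode)
  basis <- build_basis(data$grid, n_knots = n_knots, order = order,
                       diff_order = diff_order)
  q <- data$q

  init <- fit_initial(data, basis, lambda0 = lambda0)
  cov0 <- estimate_rho(data, basis, init$theta,
                       working_cov(correlation, eps = rho_eps,
                                   smooth_rho = smooth_rho))
  summ <- cluster_summaries(data, basis, init$theta, cov0)

  cv <- NULL
  if (identical(lambda1, "cv")) {
    cv <- tune_lambda1(data, basis, init$theta, summ, init$lambda0,
                       K = K, seed = seed, stage2 = stage2)
    lambda1 <- cv$lambda1
  } else {
    lambda1 <- expand_lambda(lambda1, q)
  }

  upd <- one_step_update(init$theta, summ, lambda1, basis, q)
  theta1 <- upd$theta

  cov1 <- estimate_rho(data, basis, theta1,
                       working_cov(correlation, eps = rho_eps,
                                   smooth_rho = smooth_rho))
  summ1 <- cluster_summaries(data, basis, theta1, cov1)
  variance <- sandwich_variance(data, basis, theta1, cov1, lambda1,
                                summaries = summ1)

  boot_out <- NULL
  if (isTRUE(boot)) {
    boot_out <- fast_cluster_bootstrap(init$theta, summ, lambda1, basis, q,
                                       T = T_boot,
                                       seed = if (is.null(seed)) NULL else seed + 101L)
    boot_out$se_beta <- finalize_variance(boot_out$var_boot, basis, q)$se_beta
  }

  beta <- coef_curves(basis, theta1)
  colnames(beta) <- c("(Intercept)", data$covariates)
  se <- variance$se_beta
  pw <- if ("pointwise" %in% ci) pointwise_ci(beta, se, alpha) else NULL
  jt <- NULL
  if ("joint" %in% ci) {
    jt <- joint_ci(beta, variance, basis, alpha = alpha, T = T_joint,
                   mode = joint_mode,
                   seed = if (is.null(seed)) NULL else seed + 211L,
                   draws = if (joint_mode == "nonparametric") {
                     if (is.null(boot_out))
                       stop("nonparametric joint bands require boot = TRUE", call. = FALSE)
                     boot_out$draws
                   } else NULL)
  }

  structure(
    list(estimator = "onestep", correlation = correlation,
         theta0 = init$theta, theta = theta1, beta = beta, se = se,
         pointwise = pw, joint = jt,
         rho0 = cov0$rho, rho1 = cov1$rho,
         lambda0 = init$lambda0, lambda1 = lambda1,
         variance = variance, boot = boot_out, cv = cv,
         basis = basis, grid = data$grid, grid_orig = data$grid_orig,
         family = data$family$name, alpha = alpha,
         init_iterations = init$iterations, init_converged = init$converged,
         N = data$N, seed = seed),
    class = "fgee_fit")
}

#' @export
print.fgee_fit <- function(x, ...) {
  cat("fgee fit (", x$estimator, "), family = ", x$family,
      ", working correlation = ", x$correlation, "\n", sep = "")
  cat("  N =", x$N, "clusters; basis m =", x$basis$m,
      "; coefficients:", paste(colnames(x$beta), collapse = ", "), "\n")
  if (!is.null(x$rho1))
    cat(sprintf("  rho-hat(s): mean %.3f (range %.3f to %.3f)\n",
                mean(x$rho1), min(x$rho1), max(x$rho1)))
  cat("  lambda1:", paste(signif(x$lambda1, 3), collapse = ", "), "\n")
  if (!is.null(x$joint))
    cat("  joint band multipliers:",
        paste(signif(x$joint$q, 4), collapse = ", "),
        sprintf("(z = %.3f)", stats::qnorm(1 - x$alpha / 2)), "\n")
  invisible(x)
}

#' Plot coefficient curves with confidence bands
#'
#' Base-graphics display of each fitted coefficient function with its
#' pointwise interval (dashed) and joint band (shaded), one panel per
#' coefficient.
#'
#' @param x an `fgee_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fgee_fit <- function(x, ...) {
  qq <- ncol(x$beta)
  op <- graphics::par(mfrow = c(1, qq), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (r in seq_len(qq)) {
    yl <- range(x$beta[, r],
                if (!is.null(x$joint)) c(x$joint$lower[, r], x$joint$upper[, r])
                else if (!is.null(x$pointwise)) c(x$pointwise$lower[, r], x$pointwise$upper[, r]))
    graphics::plot(x$grid_orig, x$beta[, r], type = "n", ylim = yl,
                   xlab = "s", ylab = colnames(x$beta)[r], ...)
    if (!is.null(x$joint))
      graphics::polygon(c(x$grid_orig, rev(x$grid_orig)),
                        c(x$joint$lower[, r], rev(x$joint$upper[, r])),
                        col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    if (!is.null(x$pointwise)) {
      graphics::lines(x$grid_orig, x$pointwise$lower[, r], lty = 2)
      graphics::lines(x$grid_orig, x$pointwise$upper[, r], lty = 2)
    }
    graphics::lines(x$grid_orig, x$beta[, r], lwd = 2)
    graphics::abline(h = 0, col = "grey60")
  }
  invisible(x)
}
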