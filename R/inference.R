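#' Robust sandwich variance of the one-step estimator
#'
#' Computes
#' \eqn{\widehat{\mathrm{Var}}(\hat\theta) =
#'   N^{-1} \hat H^{-1} \hat M \hat H^{-1}} with bread
#' \eqn{\hat H = P_N[D_i^\top \hat V_i^{-1} D_i] + \Lambda S} and meat
#' \eqn{\hat M = P_N[U_\Lambda U_\Lambda^\top]}, where
#' \eqn{U_\Lambda(X_i, Y_i; \theta) = D_i^\top \hat V_i^{-1}(Y_i - \mu_i) -
#' \Lambda S \theta} and \eqn{P_N} is the sample average over clusters.  The
#' estimator is valid under working-correlation misspecification (given a
#' correctly specified mean model).  The working covariance should be
#' evaluated at the final estimate, i.e. with \eqn{\hat\rho(s)} re-estimated
#' at \eqn{\hat\theta^{(1)}}.
#'
#' @param data an `fgee_data`.
#' @param basis an `fgee_basis`.
#' @param theta coefficient estimate at which the variance is evaluated.
#' @param cov an `fgee_workcov`; if its `rho` is unset it is estimated at
#'   `theta`.
#' @param lambda smoothing parameters used in the estimating equation
#'   (per-cluster scale, length 1 or q+1).
#' @param summaries optional precomputed [cluster_summaries()] at `theta`
#'   under `cov`.
#' @return An object of class `fgee_variance`: list with `var_theta` (p x p),
#'   `Sigma_theta` (per-coefficient m x m blocks), `se_beta` (L x (q+1)
#'   pointwise curve SEs) and `basis`.
#' @export
sandwich_variance <- function(data, basis, theta, cov, lambda,
                              summaries = NULL) {
  q <- data$q
  if (is.null(summaries)) {
    cov <- if (is.null(cov$rho)) estimate_rho(data, basis, theta, cov) else cov
    summaries <- cluster_summaries(data, basis, theta, cov)
  }
  N <- ncol(summaries$b)
  lamS <- lambda_S(basis, q, lambda)
  pen <- as.vector(lamS %*% theta)
  U <- summaries$b - pen                      # p x N, one U_Lambda per cluster
  M <- tcrossprod(U) / N
  H <- summaries$Wbar + lamS
  Hi <- tryCatch(solve(H), error = function(e)
    stop("sandwich bread matrix is singular", call. = FALSE))
  V <- (Hi %*% M %*% Hi) / N
  V <- (V + t(V)) / 2
  finalize_variance(V, basis, q)
}

# Package a p x p covariance into per-coefficient blocks and curve SEs.
finalize_variance <- function(V, basis, q) {
  m <- basis$m
  Sigma_theta <- vector("list", q + 1L)
  se_beta <- matrix(NA_real_, nrow(basis$B), q + 1L)
  for (r in seq_len(q + 1L)) {
    idx <- ((r - 1L) * m + 1L):(r * m)
    Sr <- V[idx, idx, drop = FALSE]
    Sigma_theta[[r]] <- Sr
    se_beta[, r] <- sqrt(pmax(rowSums((basis$B %*% Sr) * basis$B), 0))
  }
  structure(list(var_theta = V, Sigma_theta = Sigma_theta, se_beta = se_beta,
                 basis = basis),
            class = "fgee_variance")
}

#' Fast cluster bootstrap of the one-step estimator
#'
#' Resamples clusters with replacement and recomputes the one-step estimate
#' for each replicate from the precomputed per-cluster scores, keeping the
#' initial estimate and the penalized Hessian factorization fixed across
#' replicates:
#' \deqn{\tilde\theta^{t} = \hat\theta^{(0)} +
#'  \Big(N^{-1}\textstyle\sum_i W_i + \Lambda_1 S\Big)^{-1}
#'  \Big(N^{-1}\textstyle\sum_{i \in \mathcal{R}_t} \tilde n_t b_i -
#'   \Lambda_1 S \hat\theta^{(0)}\Big),}
#' with \eqn{\mathcal{R}_t} a multiset of N cluster indices and
#' \eqn{\tilde n_t = \sum_i n_i / \sum_{i \in \mathcal{R}_t} n_i}.  Each draw
#' costs one matrix-vector product; the identity resample reproduces
#' \eqn{\hat\theta^{(1)}} exactly.
#'
#' @param theta0 initial estimate.
#' @param summaries [cluster_summaries()] at `theta0`.
#' @param lambda1 smoothing parameters (length 1 or q+1).
#' @param basis an `fgee_basis`.
#' @param q number of covariates.
#' @param T number of bootstrap replicates.
#' @param seed integer seed.
#' @param indices optional T x N integer matrix of resampled cluster indices
#'   (overrides the random resampling; used for degeneracy checks).
#' @return list with `draws` (T x p matrix), `var_boot` (p x p sample
#'   covariance) and `indices`.
#' @export
fast_cluster_bootstrap <- function(theta0, summaries, lambda1, basis, q,
                                   T = 1000L, seed = NULL, indices = NULL) {
  N <- ncol(summaries$b)
  if (is.null(indices))
    indices <- with_seed(seed,
      matrix(sample.int(N, T * N, replace = TRUE), nrow = T))
  T <- nrow(indices)
  lamS <- lambda_S(basis, q, lambda1)
  solver <- penalized_solver(summaries$Wbar + lamS)
  counts <- apply(indices, 1L, tabulate, nbins = N)  # N x T
  ntilde <- sum(summaries$n_i) / colSums(counts * summaries$n_i)
  scores <- summaries$b %*% counts                   # p x T
  scores <- sweep(scores, 2L, ntilde / N, "*") - as.vector(lamS %*% theta0)
  draws <- t(theta0 + solver(scores))
  list(draws = draws, var_boot = stats::cov(draws), indices = indices)
}

#' Pointwise normal confidence intervals for coefficient curves
#'
#' \eqn{\hat\beta_r(s) \pm z_{1-\alpha/2} \, \hat\sigma_r^{(\beta)}(s)}.
#'
#' @param beta L x (q+1) matrix (or vector) of curve estimates.
#' @param se matching matrix of pointwise standard errors (all >= 0).
#' @param alpha miscoverage level (default 0.05).
#' @return list with `lower` and `upper` of the same shape as `beta`.
#' @export
pointwise_ci <- function(beta, se, alpha = 0.05) {
  if (any(se < 0)) stop("standard errors must be non-negative", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  list(lower = beta - z * se, upper = beta + z * se)
}

#' Joint (simultaneous) confidence bands via the max statistic
#'
#' Builds per-coefficient bands
#' \eqn{\hat\beta_r(s) \pm \tilde q_{1-\alpha}^{(r)} \hat\sigma_r^{(\beta)}(s)}
#' where \eqn{\tilde q_{1-\alpha}^{(r)}} is the empirical \eqn{(1-\alpha)}
#' quantile of max statistics computed on draws from the sampling
#' distribution of \eqn{\hat\theta_r}.  In `parametric` mode the draws are
#' \eqn{\tilde\theta_r^t \sim N_m(0, \hat\Sigma_r^{(\theta)})}; in
#' `nonparametric` mode they are centered fast-cluster-bootstrap draws.
#'
#' The default max statistic is studentized on the curve scale,
#' \eqn{m_r^t = \max_s |B\tilde\theta_r^t|(s) / \hat\sigma_r^{(\beta)}(s)},
#' because the band itself multiplies \eqn{\hat\sigma_r^{(\beta)}(s)} and is
#' two-sided; `statistic = "theta"` instead studentizes the spline
#' coefficients by their standard errors.  The quantile is floored at
#' \eqn{z_{1-\alpha/2}} so joint bands always contain the pointwise
#' intervals.
#'
#' @param beta L x (q+1) matrix of curve estimates.
#' @param variance an `fgee_variance` (sandwich or bootstrap-based).
#' @param basis an `fgee_basis`.
#' @param alpha miscoverage level.
#' @param T number of draws (parametric mode).
#' @param mode `"parametric"` or `"nonparametric"`.
#' @param seed integer seed.
#' @param draws centered bootstrap draws (T x p matrix), required for
#'   `mode = "nonparametric"` (e.g. `boot$draws`; they are centered
#'   internally).
#' @param statistic `"beta"` (default, curve-scale studentization) or
#'   `"theta"`.
#' @return list with `lower`, `upper` (L x (q+1)) and `q` (length q+1 vector
#'   of band multipliers).
#' @export
joint_ci <- function(beta, variance, basis, alpha = 0.05, T = 1000L,
                     mode = c("parametric", "nonparametric"), seed = NULL,
                     draws = NULL, statistic = c("beta", "theta")) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  m <- basis$m
  qq <- ncol(beta)
  z <- stats::qnorm(1 - alpha / 2)
  lower <- upper <- beta
  qband <- numeric(qq)
  if (mode == "nonparametric") {
    if (is.null(draws)) stop("nonparametric mode requires bootstrap draws", call. = FALSE)
    draws <- sweep(draws, 2L, colMeans(draws))
  }
  for (r in seq_len(qq)) {
    Sr <- variance$Sigma_theta[[r]]
    se_r <- variance$se_beta[, r]
    if (mode == "parametric") {
      Th <- with_seed(if (is.null(seed)) NULL else seed + r,
                      matrix(stats::rnorm(T * m), T, m) %*% chol_psd(Sr))
    } else {
      Th <- draws[, ((r - 1L) * m + 1L):(r * m), drop = FALSE]
    }
    if (max(abs(Sr)) == 0) {              # degenerate: pointwise-degenerate band
      qband[r] <- z
    } else if (statistic == "beta") {
      curves <- abs(Th %*% t(basis$B))    # T x L
      ok <- se_r > 0
      stat <- apply(sweep(curves[, ok, drop = FALSE], 2L, se_r[ok], "/"), 1L, max)
      qband[r] <- max(stats::quantile(stat, 1 - alpha, names = FALSE), z)
    } else {
      se_th <- sqrt(pmax(diag(Sr), 0))
      ok <- se_th > 0
      stat <- apply(sweep(abs(Th[, ok, drop = FALSE]), 2L, se_th[ok], "/"), 1L, max)
      qband[r] <- max(stats::quantile(stat, 1 - alpha, names = FALSE), z)
    }
    lower[, r] <- beta[, r] - qband[r] * se_r
    upper[, r] <- beta[, r] + qband[r] * se_r
  }
  list(lower = lower, upper = upper, q = qband)
}

# Upper-triangular factor of a symmetric PSD matrix, tolerant of zero or
# numerically tiny eigenvalues.
chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(out)) return(out)
  ei <- eigen(S, symmetric = TRUE)
  vals <- pmax(ei$values, 0)
  t(ei$vectors %*% (t(ei$vectors) * sqrt(vals)))
}
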