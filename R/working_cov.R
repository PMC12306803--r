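#' Working covariance model
#'
#' Describes the block working covariance
#' \eqn{V_i = \mathrm{bdiag}(V_i(s_1), \ldots, V_i(s_L))} with
#' \eqn{V_i(s) = A_i^{1/2}(s) R_i(s) A_i^{1/2}(s)}, where \eqn{A_i(s)} holds
#' the variance-function values and \eqn{R_i(s)} is an intra-cluster
#' correlation matrix governed by one parameter \eqn{\rho(s)} per grid point:
#' * `independence`: \eqn{R_i(s) = I}, so \eqn{V_i(s) = A_i(s)} and the
#'   estimating equation reduces to the penalized GLM score of the
#'   working-independence initial fit (for Gaussian outcomes, \eqn{V = I});
#' * `exchangeable`: equal correlation \eqn{\rho(s)} between all pairs of
#'   longitudinal observations, with the closed-form O(n) inverse;
#' * `ar1`: \eqn{\mathrm{Cor}(Y_{i,j}(s), Y_{i,j'}(s)) = \rho(s)^{|j-j'|}},
#'   inverted through the analytic tridiagonal form of the Toeplitz
#'   correlation inverse.
#'
#' @param kind correlation structure.
#' @param eps truncation bound: estimated \eqn{\hat\rho(s)} are truncated to
#'   \eqn{[-1+\epsilon, 1-\epsilon]} (exchangeable) or \eqn{[0, 1-\epsilon]}
#'   (AR1).
#' @param smooth_rho logical; apply a centered running-mean smoother to
#'   \eqn{\hat\rho(s)} over the functional domain (off by default).
#' @param window smoother window in grid points; default
#'   `max(5, round(L/10))`, resolved when the smoother runs.
#' @return An object of class `fgee_workcov` with a `rho` slot filled in by
#'   [estimate_rho()].
#' @export
working_cov <- function(kind = c("independence", "exchangeable", "ar1"),
                        eps = 1e-3, smooth_rho = FALSE, window = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, eps = eps, smooth_rho = smooth_rho,
                 window = window, rho = NULL),
            class = "fgee_workcov")
}

#' @export
print.fgee_workcov <- function(x, ...) {
  cat("fgee working covariance:", x$kind)
  if (!is.null(x$rho))
    cat(sprintf("; rho(s) in [%.3f, %.3f]", min(x$rho), max(x$rho)))
  cat("\n")
  invisible(x)
}

# Fitted-model arrays at theta: linear predictor, clamped mean, mean
# derivative, variance-function values, raw residuals and Pearson residuals.
model_arrays <- function(data, basis, theta) {
  fam <- data$family
  eta <- linear_predictor(data, basis, theta)
  if (!all(is.finite(eta))) {
    bad <- data$cluster[which(!is.finite(rowSums(eta)))[1L]]
    stop("non-finite linear predictor in cluster ",
         data$cluster_levels[bad], call. = FALSE)
  }
  mu <- clamp_mu(fam$linkinv(eta), fam)
  # some stats::family functions drop matrix dims; restore them
  dmu <- matrix(pmax(fam$mu.eta(eta), 1e-10), nrow(eta), ncol(eta))
  v <- matrix(fam$variance(mu), nrow(eta), ncol(eta))
  resid <- data$Y - mu
  list(eta = eta, mu = mu, dmu = dmu, v = v, resid = resid,
       pearson = resid / sqrt(v))
}

#' Moment estimator of the exchangeable correlation parameter
#'
#' Per grid point \eqn{s}, averages the cross products of Pearson residuals
#' over ordered within-cluster pairs \eqn{j \neq k}:
#' \eqn{\hat\rho(s) = N^{-1} \sum_i [n_i(n_i-1)]^{-1}
#' \sum_{j \neq k} \hat e_{i,j}(s) \hat e_{i,k}(s)}, then truncates to
#' \eqn{[-1+\epsilon, 1-\epsilon]}.  Clusters with \eqn{n_i < 2} carry no
#' pairs and are excluded with a warning.
#'
#' @param residuals n x L matrix of Pearson residuals (rows are (i,j) pairs).
#' @param cluster integer cluster index per row.
#' @param eps truncation bound.
#' @return numeric vector \eqn{\hat\rho(s)} of length L.
#' @export
estimate_rho_exchangeable <- function(residuals, cluster, eps = 1e-3) {
  residuals <- as.matrix(residuals)
  n_i <- tabulate(cluster)
  use <- which(n_i >= 2L)
  if (length(use) < length(n_i))
    warning(length(n_i) - length(use),
            " cluster(s) with n_i < 2 excluded from the exchangeable moment estimator")
  if (!length(use)) stop("no cluster has n_i >= 2", call. = FALSE)
  acc <- 0
  for (i in use) {
    Ei <- residuals[cluster == i, , drop = FALSE]
    ni <- nrow(Ei)
    # sum over ordered pairs j != k equals (colsum)^2 - sum of squares
    acc <- acc + (colSums(Ei)^2 - colSums(Ei^2)) / (ni * (ni - 1))
  }
  rho <- acc / length(use)
  pmin(pmax(rho, -1 + eps), 1 - eps)
}

#' Yule-Walker estimator of the AR(1) correlation parameter
#'
#' Per cluster and grid point, the lag-1 Yule-Walker ratio
#' \eqn{\hat\rho_i(s) = \sum_{j < n_i} \hat e_{i,j}(s)\hat e_{i,j+1}(s) /
#' \sum_j \hat e_{i,j}(s)^2}; the per-cluster estimates are averaged over
#' clusters and truncated to \eqn{[0, 1-\epsilon]}.  Requires longitudinal
#' observations sampled at regular intervals.  An all-zero residual series
#' contributes \eqn{\hat\rho_i(s) = 0} with a warning.
#'
#' @inheritParams estimate_rho_exchangeable
#' @return numeric vector \eqn{\hat\rho(s)} of length L.
#' @export
estimate_rho_ar1 <- function(residuals, cluster, eps = 1e-3) {
  residuals <- as.matrix(residuals)
  n_i <- tabulate(cluster)
  use <- which(n_i >= 2L)
  if (length(use) < length(n_i))
    warning(length(n_i) - length(use),
            " cluster(s) with n_i < 2 excluded from the AR1 estimator")
  if (!length(use)) stop("no cluster has n_i >= 2", call. = FALSE)
  acc <- 0
  warned <- FALSE
  for (i in use) {
    Ei <- residuals[cluster == i, , drop = FALSE]
    ni <- nrow(Ei)
    num <- colSums(Ei[-ni, , drop = FALSE] * Ei[-1L, , drop = FALSE])
    den <- colSums(Ei^2)
    zero <- den == 0
    if (any(zero) && !warned) {
      warning("all-zero residual series in at least one cluster; treating its rho_i(s) as 0")
      warned <- TRUE
    }
    r <- ifelse(zero, 0, num / pmax(den, .Machine$double.xmin))
    acc <- acc + r
  }
  rho <- acc / length(use)
  pmin(pmax(rho, 0), 1 - eps)
}

#' Running-mean smoother for the correlation curve
#'
#' Centered running mean over the functional domain with partial windows at
#' the edges; the output is re-truncated to the structure's valid range.
#'
#' @param rho numeric vector \eqn{\hat\rho(s)} of length L (L >= 5).
#' @param window window width in grid points; default `max(5, round(L/10))`.
#' @param range valid range to re-truncate to, e.g. `c(0, 1 - eps)` for AR1.
#' @return smoothed vector of length L.
#' @export
smooth_rho <- function(rho, window = NULL, range = c(-1, 1)) {
  L <- length(rho)
  if (L < 5L) stop("smoothing requires L >= 5", call. = FALSE)
  if (is.null(window)) window <- max(5L, round(L / 10))
  h <- floor(window / 2)
  cs <- cumsum(c(0, rho))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  pmin(pmax(out, range[1L]), range[2L])
}

#' Closed-form exchangeable working-covariance inverse applied to a vector
#'
#' Computes \eqn{V(s)^{-1} r} for
#' \eqn{V(s) = A^{1/2}(s) R(s) A^{1/2}(s)} with exchangeable \eqn{R(s)} in
#' O(n) time without forming the matrix:
#' \deqn{V^{-1} r = \frac{1}{1-\rho} A^{-1} r -
#'   \frac{\rho}{(1-\rho)(1-\rho+n\rho)} A^{-1/2}\mathbf{1}\mathbf{1}^\top
#'   A^{-1/2} r.}
#'
#' @param r numeric vector (or matrix of right-hand-side columns) of length n.
#' @param rho exchangeable correlation, in \eqn{(-1/(n-1), 1)}.
#' @param a positive variance diagonal of length n.
#' @return \eqn{V^{-1} r}, same shape as `r`.
#' @export
apply_inverse_exchangeable <- function(r, rho, a) {
  r <- as.matrix(r)
  n <- nrow(r)
  if (n > 1L && rho <= -1 / (n - 1))
    stop("rho <= -1/(n-1): exchangeable correlation is not positive definite; ",
         "truncate rho upstream", call. = FALSE)
  if (rho >= 1) stop("rho must be < 1", call. = FALSE)
  if (any(a <= 0)) stop("variance diagonal must be positive", call. = FALSE)
  sa <- sqrt(a)
  out <- (r / a) / (1 - rho) -
    (rho / ((1 - rho) * (1 - rho + n * rho))) *
      (1 / sa) * matrix(colSums(r / sa), nrow = n, ncol = ncol(r), byrow = TRUE)
  drop(out)
}

#' AR(1) working-covariance inverse applied to a vector
#'
#' Computes \eqn{V(s)^{-1} r} for AR(1) correlation
#' \eqn{R_{jj'} = \rho^{|j-j'|}} by rescaling with \eqn{A^{-1/2}} and solving
#' the Toeplitz system \eqn{R y = x} through the analytic tridiagonal form of
#' \eqn{R^{-1}} (main diagonal \eqn{(1, 1+\rho^2, \ldots, 1+\rho^2, 1)},
#' off-diagonal \eqn{-\rho}, all over \eqn{1-\rho^2}).  O(n) time and memory;
#' the \eqn{n \times n} matrix is never materialized.  Assumes equally spaced
#' longitudinal observations.
#'
#' @param r numeric vector (or matrix of right-hand-side columns) of length n.
#' @param rho AR(1) correlation in \eqn{[0, 1)}.
#' @param a positive variance diagonal of length n.
#' @return \eqn{V^{-1} r}, same shape as `r`.
#' @export
apply_inverse_ar1 <- function(r, rho, a) {
  if (rho < 0 || rho >= 1) stop("AR1 requires rho in [0, 1)", call. = FALSE)
  if (any(a <= 0)) stop("variance diagonal must be positive", call. = FALSE)
  r <- as.matrix(r)
  n <- nrow(r)
  sa <- sqrt(a)
  x <- r / sa
  if (n == 1L) return(drop(x / sa))
  y <- x * (1 + rho^2)
  y[1L, ] <- x[1L, ]
  y[n, ] <- x[n, ]
  y <- y - rho * (rbind(0, x[-n, , drop = FALSE]) + rbind(x[-1L, , drop = FALSE], 0))
  drop((y / (1 - rho^2)) / sa)
}

# Vectorized-over-s application of V(s)^{-1} to the columns of an n x L
# matrix, with per-point correlation rho (length L) and variance diagonals A
# (n x L).  This is the inner kernel of the blockwise quadratic forms.
vinv_all_s <- function(Xmat, kind, rho, A) {
  n <- nrow(Xmat)
  if (kind == "independence") return(Xmat / A)
  if (kind == "exchangeable") {
    sA <- sqrt(A)
    c1 <- 1 / (1 - rho)
    c2 <- rho / ((1 - rho) * (1 - rho + n * rho))
    csum <- colSums(Xmat / sA)
    return(sweep(Xmat / A, 2L, c1, "*") -
             (1 / sA) * matrix(c2 * csum, nrow = n, ncol = length(rho), byrow = TRUE))
  }
  # ar1: tridiagonal inverse of the Toeplitz correlation, per column
  sA <- sqrt(A)
  x <- Xmat / sA
  if (n == 1L) return(x / sA)
  rr <- matrix(rho, nrow = n, ncol = length(rho), byrow = TRUE)
  y <- x * (1 + rr^2)
  y[1L, ] <- x[1L, ]
  y[n, ] <- x[n, ]
  y <- y - rr * (rbind(0, x[-n, , drop = FALSE]) + rbind(x[-1L, , drop = FALSE], 0))
  (y / (1 - rr^2)) / sA
}

#' Estimate the working correlation curve from a fitted mean
#'
#' Computes Pearson residuals at `theta`, applies the structure's correlation
#' estimator, optionally smooths the curve, and returns the model with `rho`
#' filled in.  For the exchangeable structure, \eqn{\hat\rho(s)} is
#' additionally bounded below by \eqn{-1/(\max_i n_i - 1) + \epsilon} so every
#' cluster's working correlation stays positive definite.
#'
#' @param data an `fgee_data`.
#' @param basis an `fgee_basis`.
#' @param theta coefficient vector at which residuals are taken.
#' @param cov an `fgee_workcov`.
#' @return the `fgee_workcov` with `rho` set (length-L vector).
#' @export
estimate_rho <- function(data, basis, theta, cov) {
  if (cov$kind == "independence") {
    cov$rho <- rep(0, data$L)
    return(cov)
  }
  E <- model_arrays(data, basis, theta)$pearson
  # standardize to unit scale per grid point: the working variance uses
  # v(mu) with dispersion 1, so Pearson residuals carry the (pointwise)
  # dispersion phi(s); the moment estimator needs correlation-scale inputs.
  # (The Yule-Walker ratio is scale-invariant, so this only affects the
  # exchangeable estimator.)
  phi <- colMeans(E^2)
  E <- sweep(E, 2L, sqrt(pmax(phi, 1e-12)), "/")
  rho <- switch(cov$kind,
    exchangeable = estimate_rho_exchangeable(E, data$cluster, cov$eps),
    ar1 = estimate_rho_ar1(E, data$cluster, cov$eps))
  rng <- if (cov$kind == "ar1") c(0, 1 - cov$eps) else c(-1 + cov$eps, 1 - cov$eps)
  if (isTRUE(cov$smooth_rho)) rho <- smooth_rho(rho, cov$window, rng)
  if (cov$kind == "exchangeable") {
    lb <- -1 / (max(data$n_i) - 1) + cov$eps
    if (any(rho < lb)) {
      warning("exchangeable rho(s) raised to ", signif(lb, 4),
              " to keep every cluster's working correlation positive definite")
      rho <- pmax(rho, lb)
    }
  }
  cov$rho <- rho
  cov
}

#' Per-cluster quadratic forms of the estimating equation
#'
#' Pre-computes, for each cluster \eqn{i},
#' \eqn{W_i = \sum_s D_i(s)^\top \hat V_i(s)^{-1} D_i(s) \in R^{p \times p}}
#' and
#' \eqn{b_i = \sum_s D_i(s)^\top \hat V_i(s)^{-1} (Y_i(s) - \hat\mu_i(s)) \in
#' R^p}, where row \eqn{j} of \eqn{D_i(s)} is
#' \eqn{(\partial\mu/\partial\eta)(\eta_{i,j}(s)) \cdot (B(s)^\top,
#' x_{i,j,1}(s) B(s)^\top, \ldots)}.  The Kronecker structure of the design is
#' exploited: each m x m block of \eqn{W_i} is a weighted cross product of the
#' basis matrix, so the cost is \eqn{O(L(n_i q^2 + m^2 L))} per cluster and the
#' \eqn{n_i L \times n_i L} covariance is never formed.
#'
#' These summaries are the shared input of the one-step update, the fast
#' K-fold cross-validation, the fast cluster bootstrap and the sandwich
#' variance.
#'
#' @param data an `fgee_data`.
#' @param basis an `fgee_basis`.
#' @param theta coefficient vector (length p) at which to evaluate.
#' @param cov an `fgee_workcov` with `rho` set (see [estimate_rho()]).
#' @return list with `W` (list of p x p matrices), `b` (p x N matrix),
#'   `Wbar` (= \eqn{N^{-1}\sum_i W_i}), `bbar`, `n_i`, and `pearson`
#'   residuals.
#' @export
cluster_summaries <- function(data, basis, theta, cov) {
  if (is.null(cov$rho)) cov <- estimate_rho(data, basis, theta, cov)
  arr <- model_arrays(data, basis, theta)
  B <- basis$B; m <- basis$m; q <- data$q; p <- m * (q + 1L)
  N <- data$N; L <- data$L
  W <- vector("list", N)
  b <- matrix(0, p, N)
  blk <- function(r) ((r - 1L) * m + 1L):(r * m)
  for (i in seq_len(N)) {
    idx <- data$rows[[i]]
    ni <- length(idx)
    dmu <- arr$dmu[idx, , drop = FALSE]
    A <- arr$v[idx, , drop = FALSE]
    # G_r = dmu * z_r where z_0 = 1, z_r = covariate r
    G <- vector("list", q + 1L)
    G[[1L]] <- dmu
    if (q > 0L)
      for (r in seq_len(q)) {
        Xr <- data$X[idx, , r, drop = FALSE]
        dim(Xr) <- c(ni, L)
        G[[r + 1L]] <- dmu * Xr
      }
    VG <- lapply(G, vinv_all_s, kind = cov$kind, rho = cov$rho, A = A)
    Vres <- vinv_all_s(arr$resid[idx, , drop = FALSE], cov$kind, cov$rho, A)
    Wi <- matrix(0, p, p)
    for (r in seq_len(q + 1L)) {
      gr <- G[[r]]
      for (r2 in r:(q + 1L)) {
        Mrr <- colSums(gr * VG[[r2]])          # length-L weight curve
        block <- crossprod(B, B * Mrr)          # B^T diag(Mrr) B
        Wi[blk(r), blk(r2)] <- block
        if (r2 != r) Wi[blk(r2), blk(r)] <- t(block)
      }
      b[blk(r), i] <- crossprod(B, colSums(gr * Vres))
    }
    W[[i]] <- (Wi + t(Wi)) / 2
  }
  Wbar <- Reduce(`+`, W) / N
  list(W = W, b = b, Wbar = Wbar, bbar = rowMeans(b), n_i = data$n_i,
       pearson = arr$pearson)
}
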