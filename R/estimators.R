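#' Initial penalized working-independence fit
#'
#' The function-on-scalar regression that ignores intra-cluster correlation:
#' a penalized GLM whose root solves
#' \eqn{\sum_i D_i^\top A_i^{-1} (Y_i - \mu_i) - \Lambda_0 S \theta = 0}
#' (for canonical links the score is \eqn{\sum_i \mathbb{X}_i^\top (Y_i -
#' \mu_i)}; under the Gaussian family this is ordinary penalized least
#' squares).  Any consistent initial estimate suffices for the one-step
#' update, and this one is cheap because no working covariance is inverted.
#'
#' With `lambda0 = "auto"` the smoothing parameters are selected by fast
#' REML (`method = "reml"`, the default), delegating to [mgcv::bam()] with
#' P-spline smooths constructed on exactly this basis's knots, so the
#' returned spline coefficients live in this package's basis
#' parameterization and the REML smoothing parameters are mapped back to the
#' penalty scale used here.  `method = "gcv"` instead selects each
#' coefficient's smoothing parameter by GCV on the working linearized
#' problem inside the performance iteration (a shared log-grid multiplier
#' followed by per-coefficient coordinate sweeps).  Supplying numeric
#' `lambda0` fits at those fixed values by penalized IRLS.
#'
#' Note the penalty here is on the summed (not averaged) estimating-equation
#' scale; [tune_lambda1()] anchors its per-cluster-scale grid at
#' `lambda0 / N`.
#'
#' @param data an `fgee_data`.
#' @param basis an `fgee_basis`.
#' @param lambda0 `"auto"` or a non-negative vector of length 1 or q+1.
#' @param method smoothing-parameter selector for `lambda0 = "auto"`:
#'   `"reml"` (fast REML via mgcv) or `"gcv"`.
#' @param tol relative-change convergence tolerance for IRLS.
#' @param max_iter maximum IRLS iterations.
#' @return list with `theta` (length p), `lambda0` (length q+1), `edf`,
#'   `iterations`, `converged`.
#' @export
fit_initial <- function(data, basis, lambda0 = "auto",
                        method = c("reml", "gcv"), tol = 1e-8,
                        max_iter = 100L) {
  method <- match.arg(method)
  if (identical(lambda0, "auto") && method == "reml")
    return(fit_initial_reml(data, basis))
  fam <- data$family
  B <- basis$B; m <- basis$m; q <- data$q; p <- m * (q + 1L)
  n <- nrow(data$Y); L <- data$L
  ntot <- n * L
  auto <- identical(lambda0, "auto")
  if (!auto) lambda0 <- expand_lambda(lambda0, q)

  Zl <- vector("list", q + 1L)
  Zl[[1L]] <- matrix(1, n, L)
  if (q > 0L)
    for (r in seq_len(q)) {
      Xr <- data$X[, , r, drop = FALSE]
      dim(Xr) <- c(n, L)
      Zl[[r + 1L]] <- Xr
    }
  blk <- function(r) ((r - 1L) * m + 1L):(r * m)

  # one L-vector weight curve per coefficient-block pair -> m x m blocks
  assemble <- function(w, z) {
    H <- matrix(0, p, p)
    rhs <- numeric(p)
    for (r in seq_len(q + 1L)) {
      for (r2 in r:(q + 1L)) {
        C <- colSums(w * Zl[[r]] * Zl[[r2]])
        block <- crossprod(B, B * C)
        H[blk(r), blk(r2)] <- block
        if (r2 != r) H[blk(r2), blk(r)] <- t(block)
      }
      rhs[blk(r)] <- crossprod(B, colSums(w * Zl[[r]] * z))
    }
    list(H = H, rhs = rhs, zwz = sum(w * z^2))
  }

  # ridge fallback: if the penalized system is singular (IRLS weights can
  # collapse under complete separation, and the difference penalty leaves
  # polynomial directions unpenalized), retry with a tiny ridge floor
  solve_or_ridge <- function(K) {
    Ki <- tryCatch(solve(K), error = function(e) NULL)
    if (!is.null(Ki) && all(is.finite(Ki))) return(Ki)
    r <- 1e-9 * (sum(diag(K)) / p + 1)
    tryCatch(solve(K + r * diag(p)), error = function(e) NULL)
  }

  gcv_select <- function(H, rhs, zwz, lam_cur) {
    grid <- 10^seq(-4, 6, length.out = 21)
    score_of <- function(lam) {
      K <- H + lambda_S(basis, q, lam)
      Ki <- solve_or_ridge(K)
      if (is.null(Ki)) return(list(score = Inf, theta = NULL))
      th <- Ki %*% rhs
      rss <- max(zwz - 2 * sum(th * rhs) + sum(th * (H %*% th)), 0)
      edf <- sum(Ki * t(H))  # tr(K^{-1} H)
      list(score = ntot * rss / (ntot - edf)^2, theta = th, edf = edf)
    }
    # stage 1: shared multiplier
    best <- NULL; best_lam <- rep(grid[1L], q + 1L)
    for (cc in grid) {
      res <- score_of(rep(cc, q + 1L))
      if (is.null(best) || res$score <= best$score + 1e-12 * max(1, abs(best$score))) {
        best <- res; best_lam <- rep(cc, q + 1L)
      }
    }
    # stage 2: per-coefficient coordinate sweep on the same grid
    for (sweep_i in 1:2) {
      for (r in seq_len(q + 1L)) {
        for (cc in grid) {
          cand <- best_lam; cand[r] <- cc
          res <- score_of(cand)
          if (res$score <= best$score + 1e-12 * max(1, abs(best$score))) {
            best <- res; best_lam <- cand
          }
        }
      }
    }
    list(lambda = best_lam, theta = best$theta, edf = best$edf)
  }

  # starting value: linearization at the observed response
  mu0 <- switch(fam$name,
    gaussian = data$Y,
    binomial = (data$Y + 0.5) / 2,
    poisson  = data$Y + 0.1)
  eta <- fam$linkfun(clamp_mu(mu0, fam))
  theta <- numeric(p)
  lam <- if (auto) rep(1, q + 1L) else lambda0
  edf <- NA_real_
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- matrix(clamp_mu(fam$linkinv(eta), fam), n, L)
    dmu <- matrix(pmax(fam$mu.eta(eta), 1e-10), n, L)
    v <- matrix(fam$variance(mu), n, L)
    w <- dmu^2 / v
    z <- eta + (data$Y - mu) / dmu
    pieces <- assemble(w, z)
    if (auto) {
      sel <- gcv_select(pieces$H, pieces$rhs, pieces$zwz, lam)
      lam <- sel$lambda
      theta_new <- as.vector(sel$theta)
      edf <- sel$edf
    } else {
      Ki <- solve_or_ridge(pieces$H + lambda_S(basis, q, lam))
      if (is.null(Ki))
        stop("singular penalized system in the initial fit", call. = FALSE)
      theta_new <- as.vector(Ki %*% pieces$rhs)
      edf <- NA_real_
    }
    # step-halving if the update leaves the linear predictor non-finite
    step <- 1
    repeat {
      cand <- theta + step * (theta_new - theta)
      eta_new <- linear_predictor(data, basis, cand)
      if (all(is.finite(eta_new)) && all(abs(eta_new) < 1e8)) break
      step <- step / 2
      if (step < 1e-8)
        stop("IRLS diverged: linear predictor not finite even after step-halving",
             call. = FALSE)
    }
    delta <- sqrt(sum((cand - theta)^2)) / max(sqrt(sum(theta^2)), 1e-10)
    theta <- cand
    eta <- eta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(theta = theta, lambda0 = lam, edf = edf, iterations = iter,
       converged = converged)
}

# REML route for the initial fit: delegate to mgcv::bam with P-spline
# smooths built on this basis's exact knot vector (so the spline space is
# identical), then read the fitted coefficient curves back into this
# package's basis and map the REML smoothing parameters onto the local
# penalty scale (mgcv rescales each penalty block by S.scale; the score
# identity X^T(y - mu) = (sp / S.scale) S theta holds on this scale for
# both families, with the dispersion absorbed in sp).
fit_initial_reml <- function(data, basis) {
  fam <- data$family
  q <- data$q
  n <- nrow(data$Y)
  long <- data.frame(y = as.vector(t(data$Y)), s = rep(data$grid, n))
  covnames <- if (q > 0L) paste0("x", seq_len(q)) else character()
  for (r in seq_len(q)) long[[covnames[r]]] <- as.vector(t(data$X[, , r]))
  deg <- basis$order - 2L
  sm <- sprintf("s(s, bs = 'ps', k = %d, m = c(%d, %d))", basis$m, deg,
                basis$diff_order)
  smr <- vapply(covnames, function(v)
    sprintf("s(s, by = %s, bs = 'ps', k = %d, m = c(%d, %d))", v, basis$m,
            deg, basis$diff_order), character(1))
  form <- stats::as.formula(paste("y ~", paste(c(sm, smr), collapse = " + ")))
  base_fam <- switch(fam$name, gaussian = stats::gaussian(),
                     binomial = stats::binomial(), poisson = stats::poisson())
  g <- tryCatch(
    mgcv::bam(form, family = base_fam, data = long,
              knots = list(s = basis$knots), method = "fREML",
              discrete = TRUE),
    error = function(e)
      mgcv::gam(form, family = base_fam, data = long,
                knots = list(s = basis$knots), method = "REML"))
  nd <- as.data.frame(matrix(0, data$L, max(q, 1)))
  names(nd) <- if (q > 0L) covnames else "xdummy"
  nd$s <- data$grid
  curves <- matrix(0, data$L, q + 1L)
  curves[, 1L] <- as.vector(stats::predict(g, newdata = nd, type = "link"))
  for (r in seq_len(q)) {
    nd_r <- nd
    nd_r[[covnames[r]]] <- 1
    curves[, r + 1L] <- as.vector(stats::predict(g, newdata = nd_r,
                                                 type = "link")) - curves[, 1L]
  }
  # fitted curves lie exactly in the basis span: recover theta by solving
  theta <- as.vector(solve(crossprod(basis$B), crossprod(basis$B, curves)))
  sscale <- vapply(g$smooth, function(s) s$S.scale, numeric(1))
  lambda0 <- pmax(as.vector(g$sp) / sscale, 0)
  list(theta = theta, lambda0 = lambda0, edf = sum(g$edf),
       iterations = NA_integer_, converged = TRUE)
}

#' One-step (single Newton-Raphson) update of the fGEE
#'
#' Applies one Newton step from the initial estimate using the precomputed
#' cluster summaries at \eqn{\hat\theta^{(0)}}:
#' \deqn{\hat\theta^{(1)} = \hat\theta^{(0)} +
#'   \Big(N^{-1}\textstyle\sum_i W_i + \Lambda_1 S\Big)^{-1}
#'   \Big(N^{-1}\textstyle\sum_i b_i - \Lambda_1 S \hat\theta^{(0)}\Big),}
#' a single p x p linear solve.  For a Gaussian identity-link model with fixed
#' working correlation the estimating equation is linear in \eqn{\theta}, so
#' this step lands exactly on the fully-iterated solution; in general it is
#' asymptotically as efficient as full iteration.
#'
#' @param theta0 initial estimate (length p).
#' @param summaries output of [cluster_summaries()] at `theta0`.
#' @param lambda1 smoothing parameters for the update (length 1 or q+1), on
#'   the per-cluster (averaged) estimating-equation scale.
#' @param basis an `fgee_basis`.
#' @param q number of covariates.
#' @return list with `theta` (the updated estimate) and `step` (the Newton
#'   increment).
#' @export
one_step_update <- function(theta0, summaries, lambda1, basis, q) {
  lamS <- lambda_S(basis, q, lambda1)
  K <- summaries$Wbar + lamS
  solver <- penalized_solver(K)
  step <- as.vector(solver(summaries$bbar - lamS %*% theta0))
  list(theta = theta0 + step, step = step)
}

#' Random cluster folds for cross-validation
#'
#' Assigns the N clusters to K folds of near-equal size (sizes differ by at
#' most one), deterministically for a given seed.
#'
#' @param N number of clusters (or a vector of cluster ids).
#' @param K number of folds (K <= N).
#' @param seed integer seed.
#' @return list of K integer vectors of cluster indices (the held-out sets).
#' @export
make_folds <- function(N, K, seed = NULL) {
  if (length(N) > 1L) N <- length(N)
  if (K > N) stop("K must not exceed the number of clusters N = ", N, call. = FALSE)
  perm <- with_seed(seed, sample.int(N))
  unname(split(perm, rep(seq_len(K), length.out = N)))
}

#' Fast fold-specific one-step estimate
#'
#' Fold estimate sharing the full-sample Hessian factorization: with held-out
#' cluster set \eqn{\mathcal{K}_k} and rescaling
#' \eqn{\tilde n_k = \sum_i n_i / \sum_{i \notin \mathcal{K}_k} n_i},
#' \deqn{\hat\theta^{k} = \hat\theta^{(0)} +
#'  \Big(N^{-1}\textstyle\sum_{i=1}^N W_i + \Lambda_1 S\Big)^{-1}
#'  \Big(N^{-1}\textstyle\sum_{i \notin \mathcal{K}_k} \tilde n_k b_i -
#'   \Lambda_1 S\hat\theta^{(0)}\Big).}
#' The p x p factorization is computed once per \eqn{\Lambda_1} value and
#' shared across folds; pass it via `solver`.
#'
#' @param theta0 initial estimate.
#' @param summaries full-sample [cluster_summaries()] at `theta0`.
#' @param lambda1 smoothing parameters (length 1 or q+1).
#' @param heldout integer vector of held-out cluster indices (may be empty,
#'   in which case the full one-step estimate is returned).
#' @param basis an `fgee_basis`.
#' @param q number of covariates.
#' @param solver optional solver closure (a factored penalized Hessian) for
#'   \eqn{N^{-1}\sum W_i + \Lambda_1 S}; built (and counted) if omitted.
#' @return fold coefficient vector of length p.
#' @export
fold_estimate <- function(theta0, summaries, lambda1, heldout, basis, q,
                          solver = NULL) {
  N <- ncol(summaries$b)
  if (length(heldout) >= N) stop("held-in cluster set is empty", call. = FALSE)
  lamS <- lambda_S(basis, q, lambda1)
  if (is.null(solver)) solver <- penalized_solver(summaries$Wbar + lamS)
  keep <- setdiff(seq_len(N), heldout)
  ntilde <- sum(summaries$n_i) / sum(summaries$n_i[keep])
  score <- (ntilde / N) * rowSums(summaries$b[, keep, drop = FALSE])
  as.vector(theta0 + solver(score - lamS %*% theta0))
}

#' Cross-validation score: mean held-out negative working log-likelihood
#'
#' Per held-out point: gaussian \eqn{(y-\hat\mu)^2/2}; binomial
#' \eqn{-[y\log\hat\mu + (1-y)\log(1-\hat\mu)]} with \eqn{\hat\mu} clamped
#' away from 0 and 1; poisson \eqn{\hat\mu - y\log\hat\mu}.
#'
#' @param theta coefficient vector used for prediction.
#' @param data an `fgee_data`.
#' @param basis an `fgee_basis`.
#' @param clusters integer vector of held-out cluster indices.
#' @return scalar mean score over held-out (i, j, s) points.
#' @export
cv_score <- function(theta, data, basis, clusters) {
  idx <- unlist(data$rows[clusters], use.names = FALSE)
  fam <- data$family
  curves <- coef_curves(basis, theta)
  nsub <- length(idx)
  eta <- matrix(curves[, 1L], nsub, data$L, byrow = TRUE)
  if (data$q > 0L)
    for (r in seq_len(data$q)) {
      Xr <- data$X[idx, , r, drop = FALSE]
      dim(Xr) <- c(nsub, data$L)
      eta <- eta + Xr * matrix(curves[, r + 1L], nsub, data$L, byrow = TRUE)
    }
  mu <- clamp_mu(fam$linkinv(eta), fam)
  y <- data$Y[idx, , drop = FALSE]
  nll <- switch(fam$name,
    gaussian = 0.5 * (y - mu)^2,
    binomial = -(y * log(mu) + (1 - y) * log1p(-mu)),
    poisson  = mu - y * log(mu))
  mean(nll)
}

#' Tune the one-step smoothing parameters by fast K-fold cluster CV
#'
#' Two-stage search over \eqn{\Lambda_1} using the fast fold estimates of
#' [fold_estimate()], so the cluster summaries are computed once and exactly
#' one p x p factorization is performed per candidate.  Stage 1 searches a
#' shared multiplier \eqn{c} on the initial-fit anchor
#' \eqn{\Lambda_0 / N} over a log-spaced grid (default 15 points spanning
#' \eqn{10^{-4}} to \eqn{10^{4}}).  Stage 2 (optional, on by default) refines
#' with per-coefficient coordinate descent: up to two sweeps of 3-point local
#' moves at the stage-1 grid spacing.  Ties are broken toward the larger
#' (smoother) candidate.  The CV criterion is the held-out negative working
#' log-likelihood of [cv_score()], pooled over folds.
#'
#' @param data an `fgee_data`.
#' @param basis an `fgee_basis`.
#' @param theta0 initial estimate.
#' @param summaries [cluster_summaries()] at `theta0` under the working
#'   covariance being tuned.
#' @param lambda0 initial-fit smoothing parameters (summed scale; anchored as
#'   `lambda0 / N`).
#' @param K number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param c_grid multiplier grid for stage 1.
#' @param stage2 logical; run the per-coefficient coordinate descent.
#' @return list with `lambda1` (length q+1), `c_opt`, `scores` (stage-1 CV
#'   profile), `folds`, and `n_factorizations`.
#' @export
tune_lambda1 <- function(data, basis, theta0, summaries, lambda0,
                         K = 10L, seed = NULL,
                         c_grid = 10^seq(-4, 4, length.out = 15), stage2 = TRUE) {
  q <- data$q
  N <- data$N
  K <- min(K, N)
  anchor <- pmax(expand_lambda(lambda0, q) / N, 1e-10)
  folds <- make_folds(N, K, seed)
  count0 <- fgee_solve_count()

  eval_lambda <- function(lam) {
    lamS <- lambda_S(basis, q, lam)
    solver <- penalized_solver(summaries$Wbar + lamS)
    tot <- 0; npts <- 0
    for (k in seq_len(K)) {
      th_k <- fold_estimate(theta0, summaries, lam, folds[[k]], basis, q,
                            solver = solver)
      nk <- sum(data$n_i[folds[[k]]]) * data$L
      tot <- tot + cv_score(th_k, data, basis, folds[[k]]) * nk
      npts <- npts + nk
    }
    tot / npts
  }

  scores <- vapply(c_grid, function(cc) eval_lambda(cc * anchor), numeric(1))
  if (diff(range(scores)) < 1e-10 * max(1, abs(scores[1L])))
    warning("flat CV profile across the candidate grid; returning the smoothest candidate")
  best_i <- max(which(scores <= min(scores) + 1e-12 * max(1, abs(min(scores)))))
  best_lam <- c_grid[best_i] * anchor
  best_score <- scores[best_i]

  if (isTRUE(stage2)) {
    gfac <- if (length(c_grid) > 1L) c_grid[2L] / c_grid[1L] else 10
    for (sweep_i in 1:2) {
      moved <- FALSE
      for (r in seq_len(q + 1L)) {
        for (mult in c(gfac, 1 / gfac)) {  # larger first: ties prefer smoother
          cand <- best_lam
          cand[r] <- cand[r] * mult
          sc <- eval_lambda(cand)
          if (sc < best_score - 1e-12 * max(1, abs(best_score)) ||
              (sc <= best_score + 1e-12 * max(1, abs(best_score)) && mult > 1)) {
            best_score <- sc; best_lam <- cand; moved <- TRUE
          }
        }
      }
      if (!moved) break
    }
  }
  list(lambda1 = best_lam, c_opt = c_grid[best_i],
       scores = data.frame(c = c_grid, cv = scores), folds = folds,
       n_factorizations = fgee_solve_count() - count0)
}
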