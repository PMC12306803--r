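#' Model family for functional GEE
#'
#' A thin wrapper around [stats::family()] objects exposing the pieces the
#' estimating equations need: the link \eqn{g}, its inverse \eqn{g^{-1}}, the
#' derivative \eqn{d\mu/d\eta}, and the variance function \eqn{v(\mu)}.
#' Supported families are `gaussian` (identity link, \eqn{v(\mu)=1}),
#' `binomial` (logit link, \eqn{v(\mu)=\mu(1-\mu)}), and `poisson` (log link,
#' \eqn{v(\mu)=\mu}).  The working dispersion is fixed at 1; robust sandwich
#' inference is insensitive to a scalar dispersion factor.
#'
#' @param family character; one of `"gaussian"`, `"binomial"`, `"poisson"`.
#' @return An object of class `fgee_family`: a list with elements `name`,
#'   `linkfun`, `linkinv`, `mu.eta` and `variance`.
#' @examples
#' fam <- fgee_family("binomial")
#' fam$linkinv(0)      # 0.5
#' fam$variance(0.5)   # 0.25
#' @export
fgee_family <- function(family = c("gaussian", "binomial", "poisson")) {
  if (inherits(family, "fgee_family")) return(family)
  family <- match.arg(family)
  base <- switch(family,
    gaussian = stats::gaussian(),
    binomial = stats::binomial(),
    poisson  = stats::poisson())
  structure(
    list(name = family,
         linkfun = base$linkfun,
         linkinv = base$linkinv,
         mu.eta = base$mu.eta,
         variance = base$variance),
    class = "fgee_family")
}

#' @export
print.fgee_family <- function(x, ...) {
  link <- switch(x$name, gaussian = "identity", binomial = "logit", poisson = "log")
  cat("fgee family:", x$name, "(link:", link, ", dispersion fixed at 1)\n")
  invisible(x)
}

# Clamp fitted means away from the boundary of the parameter space so that
# v(mu) stays strictly positive (binomial: mu in [1e-6, 1-1e-6]; poisson:
# mu >= 1e-10).  The clamp affects only the working weights; it vanishes
# asymptotically.
clamp_mu <- function(mu, family) {
  switch(family$name,
    gaussian = mu,
    binomial = pmin(pmax(mu, 1e-6), 1 - 1e-6),
    poisson  = pmax(mu, 1e-10))
}

# Evaluate seeded expressions without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Instrumentation: count p x p penalized-system factorizations so tests can
# verify the fast CV/bootstrap perform exactly one per smoothing-parameter
# candidate.
.fgee_counters <- new.env(parent = emptyenv())
.fgee_counters$psolve <- 0L

#' Reset or read the p x p factorization counter
#'
#' The fast cross-validation and bootstrap reuse a single factorization of the
#' penalized Hessian per smoothing-parameter value.  This counter instruments
#' that contract.
#' @param reset logical; reset the counter to zero before returning the
#'   previous value.
#' @return integer count of factorizations since the last reset.
#' @export
fgee_solve_count <- function(reset = FALSE) {
  n <- .fgee_counters$psolve
  if (reset) .fgee_counters$psolve <- 0L
  n
}

# Factor a symmetric positive-definite penalized Hessian once and return a
# solver closure.  Falls back to a generic solve if the Cholesky fails.
penalized_solver <- function(K) {
  .fgee_counters$psolve <- .fgee_counters$psolve + 1L
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    Ki <- tryCatch(solve(K), error = function(e)
      stop("penalized system is singular; increase the smoothing parameter or reduce the basis dimension", call. = FALSE))
    function(x) Ki %*% x
  } else {
    function(x) backsolve(ch, forwardsolve(t(ch), x))
  }
}
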