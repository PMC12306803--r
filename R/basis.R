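#' Build the B-spline basis and difference penalty
#'
#' Constructs the \eqn{L \times m} B-spline evaluation matrix over the grid and
#' the d-th order difference penalty block \eqn{D_d^\top D_d} shared by every
#' coefficient function.  Knots are equally spaced: `n_knots` knot spans
#' partition the grid range, giving `n_knots - 1` interior knots and basis
#' dimension \eqn{m = n_knots - 1 + order} (the default 10 spans with cubic
#' splines gives \eqn{m = 13}).  Boundary knots are replicated to full
#' multiplicity.
#'
#' @param grid strictly increasing vector of functional-domain points.
#' @param n_knots number of equally spaced knot spans (default 10).
#' @param order spline order (4 = cubic, the default).
#' @param diff_order order of the difference penalty (default 2, penalizing
#'   curvature; its null space holds constant and linear functions).
#' @return An object of class `fgee_basis`: list with `B` (L x m), `m`,
#'   `order`, `knots` (full replicated knot vector), `grid`, `diff_order`,
#'   `D` (difference matrix) and `P` (= \eqn{D^\top D}, the m x m penalty
#'   block).
#' @export
build_basis <- function(grid, n_knots = 10, order = 4, diff_order = 2) {
  L <- length(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  m <- n_knots - 1L + order
  if (m < order) stop("n_knots must give at least 'order' basis functions", call. = FALSE)
  if (m > L)
    stop("basis dimension m = ", m, " exceeds the number of grid points L = ", L,
         "; the basis cannot have full column rank", call. = FALSE)
  a <- grid[1L]; b <- grid[L]
  breaks <- seq(a, b, length.out = n_knots + 1L)
  knots <- c(rep(a, order), breaks[-c(1L, n_knots + 1L)], rep(b, order))
  B <- splines::splineDesign(knots, grid, ord = order)
  D <- diff(diag(m), differences = diff_order)
  structure(
    list(B = B, m = m, order = order, knots = knots, grid = grid,
         diff_order = diff_order, D = D, P = crossprod(D)),
    class = "fgee_basis")
}

#' @export
print.fgee_basis <- function(x, ...) {
  cat("fgee_basis: m =", x$m, "B-splines of order", x$order,
      "on", length(x$grid), "grid points; difference penalty of order",
      x$diff_order, "\n")
  invisible(x)
}

#' Block-diagonal penalty matrix
#'
#' The full \eqn{p \times p} penalty \eqn{S}, \eqn{p = m(q+1)}, with one
#' \eqn{D_d^\top D_d} block per coefficient function.
#'
#' @param basis an `fgee_basis`.
#' @param q number of covariates (so there are q + 1 coefficient functions).
#' @return symmetric positive semidefinite p x p matrix.
#' @export
penalty_matrix <- function(basis, q) {
  kronecker(diag(q + 1L), basis$P)
}

# Lambda * S for a per-coefficient smoothing vector lambda (length q+1):
# block r of S scaled by lambda_r.  Returns the p x p matrix.
lambda_S <- function(basis, q, lambda) {
  lambda <- expand_lambda(lambda, q)
  kronecker(diag(lambda, nrow = q + 1L), basis$P)
}

# Recycle a scalar smoothing parameter to the q+1 coefficient blocks and
# validate non-negativity.
expand_lambda <- function(lambda, q) {
  if (length(lambda) == 1L) lambda <- rep(lambda, q + 1L)
  if (length(lambda) != q + 1L)
    stop("lambda must have length 1 or q + 1 = ", q + 1L, call. = FALSE)
  if (any(lambda < 0)) stop("smoothing parameters must be non-negative", call. = FALSE)
  lambda
}

#' Design row of the stacked spline expansion
#'
#' For covariate values \eqn{x} at a point \eqn{s}, returns
#' \eqn{(B(s)^\top, x_1 B(s)^\top, \ldots, x_q B(s)^\top)} — one row of the
#' \eqn{L \times p} cluster design block, so that
#' \eqn{\eta_{i,j}(s) = } `design_row(basis, s, x) %*% theta`.
#'
#' @param basis an `fgee_basis`.
#' @param s scalar functional-domain location (within the basis range).
#' @param x numeric vector of q covariate values (may be empty).
#' @return numeric vector of length \eqn{p = m(q+1)}.
#' @export
design_row <- function(basis, s, x = numeric()) {
  Bs <- as.vector(splines::splineDesign(basis$knots, s, ord = basis$order))
  as.vector(kronecker(c(1, x), Bs))
}

#' Coefficient curves from a stacked spline coefficient vector
#'
#' @param basis an `fgee_basis`.
#' @param theta numeric vector of length \eqn{p = m(q+1)}; blocks are the
#'   per-coefficient spline coefficients \eqn{\theta_0, \ldots, \theta_q}.
#' @return L x (q+1) matrix of curves \eqn{\hat\beta_r = B\theta_r}.
#' @export
coef_curves <- function(basis, theta) {
  if (length(theta) %% basis$m != 0L)
    stop("length(theta) must be a multiple of m = ", basis$m, call. = FALSE)
  Theta <- matrix(theta, nrow = basis$m)
  basis$B %*% Theta
}

# Linear predictor matrix eta (n x L) for data at theta.
linear_predictor <- function(data, basis, theta) {
  curves <- coef_curves(basis, theta)
  if (ncol(curves) != data$q + 1L)
    stop("theta has ", ncol(curves), " coefficient blocks but data has q = ",
         data$q, " covariates", call. = FALSE)
  n <- nrow(data$Y)
  eta <- matrix(curves[, 1L], nrow = n, ncol = data$L, byrow = TRUE)
  if (data$q > 0L)
    for (r in seq_len(data$q))
      eta <- eta + data$X[, , r] * matrix(curves[, r + 1L], nrow = n,
                                          ncol = data$L, byrow = TRUE)
  eta
}
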