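#' Construct a longitudinal functional dataset
#'
#' Builds the canonical in-memory representation of clustered longitudinal
#' functional data from a long-format data frame with one row per
#' (cluster \eqn{i}, longitudinal observation \eqn{j}, functional point
#' \eqn{s}).  Every \eqn{(i,j)} pair must be observed at the same regular,
#' strictly increasing grid of \eqn{L} functional-domain points; cluster sizes
#' \eqn{n_i} may differ.  Covariates may be scalar (repeated across \eqn{s}) or
#' concurrent functional (varying with \eqn{s}).
#'
#' Internally outcomes are stored as an \eqn{n \times L} matrix whose rows are
#' the \eqn{(i,j)} pairs, so the flattened outcome vector of cluster \eqn{i}
#' stacks grid points in the order
#' \eqn{Y_i = (Y_i(s_1)^\top, \ldots, Y_i(s_L)^\top)^\top} (s-major).  Grid
#' locations are rescaled to \eqn{[0,1]} for spline conditioning; the original
#' units are retained for reporting.
#'
#' @param df long-format data frame.
#' @param id,obs,arg,value column names for the cluster identifier, the
#'   longitudinal observation index, the functional-domain location and the
#'   outcome.
#' @param covariates character vector of covariate column names (may be empty).
#' @param family outcome family; see [fgee_family()].
#' @return An object of class `fgee_data` with elements `Y` (n x L matrix),
#'   `X` (n x L x q array or `NULL`), `cluster` (integer index per row),
#'   `cluster_levels`, `obs`, `grid` (rescaled), `grid_orig`, `family`, `N`,
#'   `L`, `q`, `n_i` and `rows` (row indices per cluster).
#' @export
fgee_data <- function(df, id = "id", obs = "obs", arg = "s", value = "y",
                      covariates = character(), family = "gaussian") {
  family <- fgee_family(family)
  needed <- c(id, obs, arg, value, covariates)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)

  grid_orig <- sort(unique(df[[arg]]))
  L <- length(grid_orig)
  if (L < 2L) stop("functional grid must contain at least two points", call. = FALSE)
  if (any(diff(grid_orig) <= 0)) stop("grid is not strictly increasing", call. = FALSE)

  ord <- order(df[[id]], df[[obs]], df[[arg]])
  df <- df[ord, , drop = FALSE]
  key <- paste(df[[id]], df[[obs]], sep = "\r")
  ukey <- unique(key)
  n <- length(ukey)
  if (nrow(df) != n * L || !identical(rep(ukey, each = L), key)) {
    counts <- table(key)
    bad <- names(counts)[counts != L][1L]
    bad_id <- strsplit(bad, "\r", fixed = TRUE)[[1L]][1L]
    stop("ragged grid: cluster ", bad_id,
         " has an (i,j) pair without exactly L = ", L, " grid points",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(df[[arg]], rep(grid_orig, n), check.attributes = FALSE)))
    stop("grid locations differ across (i,j) pairs; a single shared grid is required",
         call. = FALSE)

  y <- df[[value]]
  if (anyNA(y) || !all(is.finite(y)))
    stop("outcome contains missing or non-finite values", call. = FALSE)
  if (family$name == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial outcomes must lie in {0, 1}", call. = FALSE)
  if (family$name == "poisson" && (any(y < 0) || any(y != round(y))))
    stop("poisson outcomes must be non-negative integers", call. = FALSE)

  Y <- matrix(y, nrow = n, ncol = L, byrow = TRUE)
  q <- length(covariates)
  X <- NULL
  if (q > 0L) {
    X <- array(NA_real_, dim = c(n, L, q), dimnames = list(NULL, NULL, covariates))
    for (r in seq_len(q)) {
      xr <- df[[covariates[r]]]
      if (anyNA(xr) || !all(is.finite(xr)))
        stop("covariate ", covariates[r], " contains missing or non-finite values",
             call. = FALSE)
      X[, , r] <- matrix(xr, nrow = n, ncol = L, byrow = TRUE)
    }
  }

  row_id <- df[[id]][seq(1L, nrow(df), by = L)]
  row_obs <- df[[obs]][seq(1L, nrow(df), by = L)]
  cluster_levels <- unique(row_id)
  cluster <- match(row_id, cluster_levels)
  n_i <- as.integer(tabulate(cluster, nbins = length(cluster_levels)))

  span <- diff(range(grid_orig))
  grid <- (grid_orig - grid_orig[1L]) / span

  structure(
    list(Y = Y, X = X, covariates = covariates,
         cluster = cluster, cluster_levels = cluster_levels, obs = row_obs,
         grid = grid, grid_orig = grid_orig, family = family,
         N = length(cluster_levels), L = L, q = q, n_i = n_i,
         rows = split(seq_len(n), cluster)),
    class = "fgee_data")
}

#' @export
print.fgee_data <- function(x, ...) {
  cat("fgee_data:", x$N, "clusters,", nrow(x$Y), "longitudinal observations,",
      "L =", x$L, "grid points, q =", x$q, "covariate(s), family =",
      x$family$name, "\n")
  cat("  cluster sizes:", paste(range(x$n_i), collapse = "-"),
      " grid range:", paste(signif(range(x$grid_orig), 4), collapse = " to "), "\n")
  invisible(x)
}

#' Read a longitudinal functional dataset from delimited text
#'
#' Reads CSV (comma) or TSV (`.tsv`/`.txt`, tab) by file extension and
#' validates it with [fgee_data()].
#'
#' @param path file path.
#' @param schema named list mapping the roles `id`, `obs`, `arg`, `value` to
#'   column names.
#' @param covariates character vector of covariate column names.
#' @param family outcome family tag.
#' @return An `fgee_data` object.
#' @export
read_fgee_data <- function(path,
                           schema = list(id = "id", obs = "obs", arg = "s", value = "y"),
                           covariates = character(), family = "gaussian") {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          comment.char = "#")
  fgee_data(df, id = schema$id, obs = schema$obs, arg = schema$arg,
            value = schema$value, covariates = covariates, family = family)
}

#' Write a long-format dataset to delimited text
#'
#' Inverse of [read_fgee_data()]: writes one row per (cluster, observation,
#' grid point) with the original grid units, suitable for round-tripping.
#'
#' @param data an `fgee_data` object.
#' @param path output path (`.csv` for comma, `.tsv`/`.txt` for tab).
#' @return `path`, invisibly.
#' @export
write_fgee_data <- function(data, path) {
  n <- nrow(data$Y)
  df <- data.frame(
    id = rep(data$cluster_levels[data$cluster], each = data$L),
    obs = rep(data$obs, each = data$L),
    s = rep(data$grid_orig, times = n),
    y = as.vector(t(data$Y)))
  if (data$q > 0L)
    for (r in seq_len(data$q)) df[[data$covariates[r]]] <- as.vector(t(data$X[, , r]))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Full-precision numeric formatting for lossless text round trips.
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a fitted coefficient table
#'
#' Writes one row per (coefficient, grid point) with the estimate, standard
#' error, pointwise CI bounds and (when present) joint band bounds.  Numbers
#' are written with 17 significant digits so a read-back reproduces the stored
#' doubles exactly.  A `#`-prefixed header line records whether joint bands
#' are present.
#'
#' @param fit an `fgee_fit` object (see [fgee()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fgee_fit <- function(fit, path) {
  L <- length(fit$grid)
  qq <- ncol(fit$beta)
  has_joint <- !is.null(fit$joint)
  df <- data.frame(
    coef = rep(colnames(fit$beta), each = L),
    s = rep(fit$grid_orig, times = qq),
    estimate = as.vector(fit$beta),
    se = as.vector(fit$se),
    pw_lower = as.vector(fit$pointwise$lower),
    pw_upper = as.vector(fit$pointwise$upper),
    joint_lower = if (has_joint) as.vector(fit$joint$lower) else NA_real_,
    joint_upper = if (has_joint) as.vector(fit$joint$upper) else NA_real_)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fgee coefficient table; joint_ci: ",
                    if (has_joint) "present" else "none"), con)
  writeLines(paste(names(df), collapse = ","), con)
  num <- vapply(df, is.numeric, logical(1))
  for (j in names(df)[num]) df[[j]] <- fmt_full(df[[j]])
  writeLines(do.call(paste, c(unname(df), sep = ",")), con)
  invisible(path)
}

#' Read back a coefficient table written by [write_fgee_fit()]
#'
#' @param path CSV path.
#' @return A data frame with one row per (coefficient, grid point).
#' @export
read_fgee_fit <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

# Y_i flattened s-major: (Y_i(s_1)^T, ..., Y_i(s_L)^T)^T.
flatten_cluster <- function(data, i) {
  as.vector(data$Y[data$rows[[i]], , drop = FALSE])
}
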