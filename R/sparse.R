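# Weighted l1-regularized least squares by cyclic coordinate descent, plus
# the two per-atom weight constructions used by the classifiers.
#
# The objective is taken literally as
#     f(a) = ||y - A a||_2^2 + mu * sum_i w_i |a_i|
# (squared l2 residual, no 1/2 factor), so with A = I and w = 1 the solution
# is elementwise soft-thresholding at mu / 2.

#' Solver settings for the weighted l1 problem
#'
#' @param mu Positive l1 regularization strength. The default 0.001 keeps
#'   the reconstruction term dominant for unit-scale contour rasters.
#' @param max_iter Maximum number of full coordinate sweeps.
#' @param tol Convergence tolerance on the largest coefficient change in a
#'   sweep.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(mu = 0.001, max_iter = 10000L, tol = 1e-8) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    abort("`mu` must be a single positive number.")
  }
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be positive.")
  if (!is.numeric(max_iter) || max_iter < 1) abort("`max_iter` must be >= 1.")
  structure(list(mu = mu, max_iter = as.integer(max_iter), tol = tol),
            class = "solver_config")
}

# Weights are capped before entering the solver so that exp() overflow on
# very distant atoms degrades gracefully into "coefficient forced to zero".
WEIGHT_CAP <- 1e12

#' Gaussian distance weights for the weighted l1 penalty
#'
#' Computes per-atom penalty weights `w_i = exp(||y - x_i||^2 / (2 * beta1^2))`
#' (note the positive exponent): atoms far from the test vector receive a
#' large l1 penalty and are thereby discouraged from entering the sparse
#' code, so the representation stays local to the test sample. An atom
#' identical to `y` has weight 1. Weights are capped at `1e12`, which in
#' practice forces the corresponding coefficient to zero.
#'
#' @param y A contour raster (matrix) or flat numeric vector.
#' @param atoms A subdictionary (see [build_subdictionaries()]), or a
#'   numeric matrix whose columns are atoms.
#' @param beta1 Positive kernel width controlling the decay speed; see
#'   [auto_kernel_width()] for the data-driven choice.
#' @return A positive numeric vector, one weight per atom, with attribute
#'   `scheme = "gaussian"`.
#' @export
weights_gaussian <- function(y, atoms, beta1) {
  if (!is.numeric(beta1) || length(beta1) != 1L || beta1 <= 0) {
    abort("`beta1` must be a single positive number.")
  }
  A <- atom_matrix(atoms)
  yv <- as.numeric(y)
  d2 <- colSums((A - yv)^2)
  w <- pmin(exp(d2 / (2 * beta1^2)), WEIGHT_CAP)
  structure(w, scheme = "gaussian")
}

#' Thresholded similarity weights for the weighted l1 penalty
#'
#' Computes per-atom weights `w_i = s(x_i, y)` when the Gaussian-kernel
#' similarity exceeds the threshold and 0 otherwise. A zero weight leaves
#' that atom's coefficient unpenalized in the l1 term. This is the classical
#' weighted-SRC weighting; with these weights the weighted baseline and the
#' two-stage classifier coincide when there is a single group.
#'
#' @inheritParams weights_gaussian
#' @param beta Positive kernel width for the similarity.
#' @param threshold Similarity threshold in (0, 1) below which the weight is
#'   set to zero.
#' @return A non-negative numeric vector with attribute
#'   `scheme = "similarity"`.
#' @export
weights_similarity <- function(y, atoms, beta, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.")
  }
  A <- atom_matrix(atoms)
  yv <- as.numeric(y)
  s <- exp(-colSums((A - yv)^2) / (2 * beta^2))
  structure(ifelse(s > threshold, s, 0), scheme = "similarity")
}

#' Solve the weighted l1-minimization problem
#'
#' Minimizes `||y - A a||_2^2 + mu * sum_i w_i |a_i|` by cyclic coordinate
#' descent with per-coordinate soft-thresholding. Covariance updates (on the
#' Gram matrix `A'A`) make each sweep O(n^2) independent of the atom
#' dimension, which suits tall, thin dictionaries of vectorized contours.
#' The solve is deterministic: coefficients start at zero and coordinates
#' are visited in column order.
#'
#' Atoms with zero penalty weight are updated without thresholding (their
#' coefficients are unregularized); atoms with zero norm keep a zero
#' coefficient.
#'
#' @param y Numeric response vector (a flattened contour raster).
#' @param A Numeric matrix with `length(y)` rows; columns are atoms.
#' @param w Non-negative per-atom weights of length `ncol(A)`, e.g. from
#'   [weights_gaussian()] or [weights_similarity()].
#' @param config A [solver_config()].
#' @return An object of class `sparse_code`: a list with elements `a`
#'   (coefficients), `objective`, `nnz` (coefficients with |a_i| > 1e-8),
#'   `iterations`, `converged`, `mu` and `weights`.
#' @export
solve_weighted_l1 <- function(y, A, w, config = solver_config()) {
  y <- as.numeric(y)
  if (!is.matrix(A) || nrow(A) != length(y)) {
    abort("`A` must be a matrix with `length(y)` rows.")
  }
  n <- ncol(A)
  w <- as.numeric(w)
  if (length(w) != n) abort("`w` must have one entry per column of `A`.")
  if (any(!is.finite(w)) || any(w < 0)) abort("Weights must be finite and >= 0.")
  w <- pmin(w, WEIGHT_CAP)

  G <- crossprod(A)
  g0 <- as.numeric(crossprod(A, y))
  fit <- cd_weighted_l1(G, g0, config$mu * w / 2, config$tol, config$max_iter)
  a <- fit$a
  iter <- fit$iterations
  converged <- fit$converged
  if (!converged) {
    warn(sprintf("Coordinate descent did not converge in %d sweeps; returning best iterate.",
                 config$max_iter))
  }
  resid <- y - A %*% a
  structure(
    list(a = a,
         objective = sum(resid^2) + config$mu * sum(w * abs(a)),
         nnz = sum(abs(a) > 1e-8),
         iterations = iter,
         converged = converged,
         mu = config$mu,
         weights = w),
    class = "sparse_code")
}

#' Solve the unweighted l1-minimization problem
#'
#' The classical sparse-representation objective
#' `||y - A a||_2^2 + mu * ||a||_1`, i.e. [solve_weighted_l1()] with unit
#' weights.
#'
#' @inheritParams solve_weighted_l1
#' @return A `sparse_code`; see [solve_weighted_l1()].
#' @export
solve_src <- function(y, A, config = solver_config()) {
  solve_weighted_l1(y, A, rep(1, ncol(A)), config)
}

#' @export
print.sparse_code <- function(x, ...) {
  cat(sprintf("<sparse_code> %d atoms, nnz = %d, objective = %.6g, %s in %d sweeps\n",
              length(x$a), x$nnz, x$objective,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Tidy a sparse code
#'
#' Coefficients as a tibble (`atom`, `coefficient`, `weight`).
#'
#' @param x A `sparse_code` from [solve_weighted_l1()] or [solve_src()].
#' @param ... Unused.
#' @return A tibble with one row per atom.
#' @export
tidy.sparse_code <- function(x, ...) {
  tibble(atom = seq_along(x$a), coefficient = x$a, weight = x$weights)
}

# Accept either a subdictionary or a bare matrix of atom columns.
atom_matrix <- function(atoms) {
  if (inherits(atoms, "subdictionary")) return(atoms$atoms)
  if (is.matrix(atoms)) return(atoms)
  abort("`atoms` must be a subdictionary or a numeric matrix of atom columns.")
}
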