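# End-to-end classifiers: the two-stage discriminant weighted classifier
# (route -> weight -> weighted l1 solve -> size-normalized class residuals
# -> argmin) and the single-dictionary baselines.

#' Classifier settings
#'
#' @param T Partition similarity threshold in (0, 1).
#' @param T1 Routing threshold in (0, 1): a test image below `T1`
#'   similarity against every representative goes to the overflow group.
#' @param mu l1 regularization strength of the sparse solve.
#' @param beta Partition kernel width; `NULL` derives it from the training
#'   data ([auto_kernel_width()]).
#' @param beta1 Weighting kernel width; `NULL` (default) recomputes it per
#'   test sample from the distances between the test image and the
#'   candidate group's atoms.
#' @param weight_scheme Per-atom penalty weights: `"gaussian"` (distance
#'   weights, [weights_gaussian()] — the two-stage default), `"similarity"`
#'   (thresholded similarity, [weights_similarity()] — the classical
#'   weighted-baseline scheme) or `"uniform"` (plain l1).
#' @param weight_T Similarity threshold used by the `"similarity"` scheme.
#' @param decision `"normalized"` divides each class residual by its atom
#'   count in the candidate group (the two-stage rule); `"raw"` uses plain
#'   residuals (the baseline rule). Both are available in either
#'   classifier for ablation.
#' @param max_iter,tol Solver controls; see [solver_config()]. The
#'   classification default caps coordinate descent at 1000 sweeps: on
#'   strongly correlated contour dictionaries full coefficient convergence
#'   takes far longer than the class residuals — and hence the labels —
#'   need, and truncated solves leave predictions unchanged.
#' @return A list of class `dwsrc_config`.
#' @export
dwsrc_config <- function(T = 0.5, T1 = 0.1, mu = 0.001, beta = NULL,
                         beta1 = NULL,
                         weight_scheme = c("gaussian", "similarity", "uniform"),
                         weight_T = 0.5,
                         decision = c("normalized", "raw"),
                         max_iter = 1000L, tol = 1e-8) {
  weight_scheme <- match.arg(weight_scheme)
  decision <- match.arg(decision)
  stopifnot(T > 0, T < 1, T1 > 0, T1 < 1, mu > 0)
  structure(list(T = T, T1 = T1, mu = mu, beta = beta, beta1 = beta1,
                 weight_scheme = weight_scheme, weight_T = weight_T,
                 decision = decision,
                 solver = solver_config(mu = mu, max_iter = max_iter, tol = tol)),
            class = "dwsrc_config")
}

#' Fit the two-stage discriminant weighted sparse classifier
#'
#' Partitions the training contours into `m + 1` similar classes against
#' the representative shapes and stacks each group into a subdictionary.
#' No coefficients are learned at training time; all sparse coding happens
#' per test sample on the routed subdictionary, so new species can be
#' added by appending columns without refitting.
#'
#' @param train Tibble with columns `id`, `species`, `contour` (list of
#'   equally sized rasters, e.g. from [preprocess_dataset()]).
#' @param reps Tibble with columns `name`, `contour`: the representative
#'   (typical) shapes.
#' @param config A [dwsrc_config()].
#' @return An object of class `dwsrc_model` with elements `partition`,
#'   `dicts`, `reps`, `config`, `species_levels`.
#' @seealso [predict.dwsrc_model()], [classify_dwsrc()]
#' @export
dwsrc <- function(train, reps, config = dwsrc_config()) {
  assert_training(train)
  assert_reps(reps)
  partition <- assign_groups(train, reps, T = config$T, beta = config$beta)
  dicts <- suppressWarnings(build_subdictionaries(train, partition))
  structure(list(partition = partition, dicts = dicts, reps = reps,
                 config = config,
                 species_levels = sort(unique(train$species))),
            class = "dwsrc_model")
}

#' @export
print.dwsrc_model <- function(x, ...) {
  cat(sprintf("<dwsrc_model> %d training contours, %d species, %d + 1 similar classes\n",
              nrow(x$partition$assignment), length(x$species_levels),
              x$partition$m))
  cat(sprintf("T = %g, T1 = %g, mu = %g, beta = %.4g, weights = %s, decision = %s\n",
              x$config$T, x$config$T1, x$config$mu, x$partition$beta,
              x$config$weight_scheme, x$config$decision))
  invisible(x)
}

#' Size-normalized per-class reconstruction errors
#'
#' For each species `c` present in the subdictionary, the sparse code is
#' restricted to that species' atoms (all other coefficients zeroed) and
#' the l2 residual `||y - A a^c||` is computed. Under the normalized rule
#' it is divided by `n_c`, the number of that species' atoms in the group,
#' compensating for unequal class sizes inside a similar class.
#'
#' @param y Flattened test vector (or raster; flattened row-major).
#' @param dict A `subdictionary`.
#' @param code A `sparse_code` for `y` on `dict` (or a bare coefficient
#'   vector).
#' @param normalized Divide by the per-species atom count? Default `TRUE`.
#' @return Named numeric vector of errors, one per species in the group.
#' @export
class_errors <- function(y, dict, code, normalized = TRUE) {
  a <- if (inherits(code, "sparse_code")) code$a else as.numeric(code)
  A <- atom_matrix(dict)
  if (length(a) != ncol(A)) {
    abort("`code` length must equal the subdictionary's atom count.")
  }
  yv <- if (is.matrix(y)) flatten_raster(y) else as.numeric(y)
  species <- sort(unique(dict$species))
  errs <- vapply(species, function(cl) {
    ix <- dict$species == cl
    resid <- yv - A[, ix, drop = FALSE] %*% a[ix]
    e <- sqrt(sum(resid^2))
    if (normalized) e / sum(ix) else e
  }, numeric(1))
  setNames(errs, species)
}

# Shared final stage: weights -> weighted l1 solve -> class errors ->
# argmin (ties to the lexicographically smallest species).
sparse_decision <- function(yv, dict, config, beta_w) {
  w <- switch(config$weight_scheme,
    gaussian   = weights_gaussian(yv, dict, beta_w),
    similarity = weights_similarity(yv, dict, beta_w, config$weight_T),
    uniform    = rep(1, ncol(dict$atoms)))
  code <- solve_weighted_l1(yv, dict$atoms, w, config$solver)
  errs <- class_errors(yv, dict, code, normalized = config$decision == "normalized")
  list(predicted = names(errs)[which.min(errs)], errors = errs, code = code)
}

# Kernel width for the weighting stage: fixed by config, or the midrange
# of the distances between y and the candidate atoms. Returns NULL when
# every candidate atom is identical to y (degenerate case).
weighting_width <- function(yv, dict, config) {
  if (!is.null(config$beta1)) return(config$beta1)
  d <- sqrt(colSums((dict$atoms - yv)^2))
  if (max(d) == 0) return(NULL)
  (max(d) + min(d)) / 2
}

#' Classify a leaf with the two-stage discriminant classifier
#'
#' Routes the (preprocessed) test contour to the most similar class, builds
#' Gaussian distance weights with a per-sample kernel width, solves the
#' weighted l1 problem on that group's subdictionary only, and labels the
#' leaf by the minimum size-normalized per-class reconstruction error.
#' Fully deterministic. If every atom of the candidate group is identical
#' to the test image, classification degenerates to exact matching.
#'
#' @param y A contour raster, or a raw image (any matrix larger than the
#'   atom raster is preprocessed first with `preprocess_cfg`).
#' @param model A [dwsrc()] model.
#' @param preprocess_cfg [preprocess_config()] used when `y` is raw.
#' @return A list of class `leaf_classification`: `predicted`, `errors`,
#'   `group_used`, `similarity`, `beta1`, `code`.
#' @export
classify_dwsrc <- function(y, model, preprocess_cfg = preprocess_config()) {
  if (!inherits(model, "dwsrc_model")) abort("`model` must come from dwsrc().")
  first_dict <- model$dicts[[which(!vapply(model$dicts, is.null, logical(1)))[1L]]]
  atom_dim <- as.integer(round(sqrt(nrow(first_dict$atoms))))
  if (is.matrix(y) && !all(dim(y) == atom_dim)) {
    y <- preprocess(y, preprocess_cfg)
  }
  config <- model$config
  dict <- route_test(y, model$reps, model$dicts, T1 = config$T1,
                     beta = model$partition$beta)
  yv <- flatten_raster(y)
  beta_w <- weighting_width(yv, dict, config)
  if (is.null(beta_w)) {
    # all candidate atoms identical to y: exact match
    errs <- setNames(rep(0, length(unique(dict$species))),
                     sort(unique(dict$species)))
    return(structure(list(predicted = names(errs)[1L], errors = errs,
                          group_used = dict$group_id,
                          similarity = attr(dict, "similarity"),
                          beta1 = NA_real_, code = NULL),
                     class = "leaf_classification"))
  }
  dec <- sparse_decision(yv, dict, config, beta_w)
  structure(list(predicted = dec$predicted, errors = dec$errors,
                 group_used = dict$group_id,
                 similarity = attr(dict, "similarity"),
                 beta1 = beta_w, code = dec$code),
            class = "leaf_classification")
}

#' @export
print.leaf_classification <- function(x, ...) {
  cat(sprintf("<leaf_classification> predicted '%s' (group %d, similarity %.3f)\n",
              x$predicted, x$group_used, x$similarity))
  top <- sort(x$errors)[seq_len(min(3L, length(x$errors)))]
  cat("lowest errors:", paste(sprintf("%s=%.4g", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn classify_dwsrc Per-species errors as a tibble.
#' @param x A `leaf_classification`.
#' @param ... Unused.
#' @export
tidy.leaf_classification <- function(x, ...) {
  tibble(species = names(x$errors), error = unname(x$errors),
         predicted = names(x$errors) == x$predicted)
}

# One global dictionary over the full training set, as used by the
# single-stage baselines.
global_dictionary <- function(train) {
  assert_training(train)
  atoms <- vapply(train$contour, flatten_raster,
                  numeric(length(train$contour[[1L]])))
  structure(list(atoms = atoms, species = train$species, ids = train$id,
                 group_id = 1L),
            class = "subdictionary")
}

#' Weighted sparse-representation baseline (single dictionary)
#'
#' The classical weighted baseline: one overcomplete dictionary of all
#' training contours, per-atom weights from the thresholded Gaussian
#' similarity between the test image and each atom (by default), a
#' weighted l1 solve, and the label of minimum (unnormalized, by default)
#' class residual.
#'
#' @param y A contour raster.
#' @param train Training tibble (`id`, `species`, `contour`).
#' @param config A [dwsrc_config()]; `weight_scheme` defaults to
#'   `"similarity"` here.
#' @return A `leaf_classification` (with `group_used = NA`).
#' @export
classify_wsrc <- function(y, train,
                          config = dwsrc_config(weight_scheme = "similarity",
                                                decision = "raw")) {
  dict <- global_dictionary(train)
  yv <- flatten_raster(y)
  beta_w <- weighting_width(yv, dict, config)
  if (is.null(beta_w)) {
    errs <- setNames(rep(0, length(unique(dict$species))),
                     sort(unique(dict$species)))
    return(structure(list(predicted = names(errs)[1L], errors = errs,
                          group_used = NA_integer_, similarity = NA_real_,
                          beta1 = NA_real_, code = NULL),
                     class = "leaf_classification"))
  }
  dec <- sparse_decision(yv, dict, config, beta_w)
  structure(list(predicted = dec$predicted, errors = dec$errors,
                 group_used = NA_integer_, similarity = NA_real_,
                 beta1 = beta_w, code = dec$code),
            class = "leaf_classification")
}

#' Unweighted sparse-representation baseline
#'
#' Plain l1-regularized coding on the global dictionary with uniform
#' weights and the raw-residual decision rule.
#'
#' @inheritParams classify_wsrc
#' @return A `leaf_classification`.
#' @export
classify_src <- function(y, train,
                         config = dwsrc_config(weight_scheme = "uniform",
                                               decision = "raw")) {
  config$weight_scheme <- "uniform"
  classify_wsrc(y, train, config)
}
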