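# Similar-class partition: divide the training images into m + 1 shape
# groups against m representative "typical" leaves, build one subdictionary
# of vectorized contours per group, and route test images to a candidate
# subdictionary.

# Training data travels as a tibble with columns `id`, `species` and
# `contour` (list of equally sized rasters); representatives as a tibble
# with `name` and `contour`. These checks centralize the contract.
assert_training <- function(train, arg = "train") {
  if (!is.data.frame(train) || nrow(train) == 0L) {
    abort(sprintf("`%s` must be a non-empty data frame.", arg))
  }
  miss <- setdiff(c("id", "species", "contour"), names(train))
  if (length(miss)) {
    abort(sprintf("`%s` lacks column(s): %s.", arg, paste(miss, collapse = ", ")))
  }
  invisible(train)
}

assert_reps <- function(reps) {
  if (!is.data.frame(reps) || nrow(reps) == 0L) {
    abort("`reps` must be a non-empty data frame.")
  }
  miss <- setdiff(c("name", "contour"), names(reps))
  if (length(miss)) {
    abort(sprintf("`reps` lacks column(s): %s.", paste(miss, collapse = ", ")))
  }
  invisible(reps)
}

#' Partition training images into similar classes
#'
#' Every training image is compared with each of the m representative
#' shapes by Gaussian-kernel similarity. An image whose best similarity
#' reaches the threshold `T` joins the group of its most similar
#' representative (ties broken by the lower group index); an image below
#' `T` against every representative falls into the overflow group `m + 1`.
#' The partition is exhaustive and exclusive.
#'
#' @param train Tibble with columns `id`, `species` and `contour` (list of
#'   equally sized numeric matrices).
#' @param reps Tibble with columns `name` and `contour`: the representative
#'   (typical) shapes, one per named group.
#' @param T Similarity threshold in (0, 1); default 0.5.
#' @param beta Gaussian kernel width; `NULL` (default) derives it from the
#'   data via [auto_kernel_width()] over all (training, representative)
#'   pairs.
#' @return An object of class `similar_class_partition`: list with
#'   `assignment` (tibble: `id`, `species`, `group`, `similarity`),
#'   `threshold_T`, `beta`, `m`, and `rep_names`.
#' @export
assign_groups <- function(train, reps, T = 0.5, beta = NULL) {
  assert_training(train)
  assert_reps(reps)
  if (!is.numeric(T) || T <= 0 || T >= 1) {
    abort("`T` must lie strictly between 0 and 1.")
  }
  if (is.null(beta)) beta <- auto_kernel_width(reps$contour, train$contour)
  m <- nrow(reps)
  S <- cross_similarities(reps$contour, train$contour, beta)   # m x n
  best <- apply(S, 2L, which.max)
  smax <- S[cbind(best, seq_len(ncol(S)))]
  group <- ifelse(smax >= T, best, m + 1L)
  structure(
    list(assignment = tibble(id = train$id, species = train$species,
                             group = as.integer(group), similarity = smax),
         threshold_T = T, beta = beta, m = m, rep_names = reps$name),
    class = "similar_class_partition")
}

#' @export
print.similar_class_partition <- function(x, ...) {
  sizes <- table(factor(x$assignment$group, levels = seq_len(x$m + 1L)))
  cat(sprintf("<similar_class_partition> n = %d over %d + 1 groups (T = %g, beta = %.4g)\n",
              nrow(x$assignment), x$m, x$threshold_T, x$beta))
  cat("group sizes:", paste(as.integer(sizes), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn assign_groups The assignment tibble of the partition.
#' @param x A `similar_class_partition`.
#' @param ... Unused.
#' @export
tidy.similar_class_partition <- function(x, ...) {
  x$assignment
}

#' Build one subdictionary per similar class
#'
#' Stacks the vectorized (row-major flattened) contours of every group
#' member as the columns of that group's subdictionary matrix. Groups with
#' no members are kept as empty placeholders so group indices stay aligned;
#' a warning reports them.
#'
#' @param train Tibble with `id`, `species`, `contour`, in the same order
#'   used for [assign_groups()].
#' @param partition A `similar_class_partition` for `train`.
#' @return A list of `m + 1` objects of class `subdictionary` (elements
#'   `atoms` — d x n_j matrix, `species`, `ids`, `group_id`), or `NULL` for
#'   empty groups. The overflow group is the last element.
#' @export
build_subdictionaries <- function(train, partition) {
  assert_training(train)
  if (!inherits(partition, "similar_class_partition")) {
    abort("`partition` must come from assign_groups().")
  }
  if (nrow(train) != nrow(partition$assignment) ||
      !identical(train$id, partition$assignment$id)) {
    abort("`train` does not match the partition's assignment.")
  }
  groups <- partition$assignment$group
  n_groups <- partition$m + 1L
  dicts <- vector("list", n_groups)
  for (j in seq_len(n_groups)) {
    ix <- which(groups == j)
    if (length(ix) == 0L) next
    atoms <- vapply(train$contour[ix], function(r) as.numeric(t(r)),
                    numeric(length(train$contour[[1L]])))
    dicts[[j]] <- structure(
      list(atoms = atoms, species = train$species[ix], ids = train$id[ix],
           group_id = j),
      class = "subdictionary")
  }
  empty <- which(vapply(dicts, is.null, logical(1)))
  if (length(empty)) {
    warn(sprintf("Empty similar class(es): %s.", paste(empty, collapse = ", ")))
  }
  dicts
}

#' @export
print.subdictionary <- function(x, ...) {
  cat(sprintf("<subdictionary> group %d: %d atoms x %d dims, %d species\n",
              x$group_id, ncol(x$atoms), nrow(x$atoms),
              length(unique(x$species))))
  invisible(x)
}

# Flatten a raster the same way subdictionary atoms are flattened
# (row-major, matching the t() in build_subdictionaries).
flatten_raster <- function(r) as.numeric(t(r))

#' Route a test image to a candidate subdictionary
#'
#' The test contour is compared with every representative shape; the group
#' of maximum similarity is selected if that similarity reaches `T1`,
#' otherwise the overflow group. A selected group that happens to be empty
#' falls back to the overflow group; if the overflow group is empty too,
#' routing fails.
#'
#' @param y A contour raster (same size as the dictionary atoms).
#' @param reps Tibble with `name` and `contour`.
#' @param dicts Subdictionary list from [build_subdictionaries()].
#' @param T1 Routing threshold in (0, 1); default 0.1.
#' @param beta Gaussian kernel width (use the partition's width).
#' @return The selected `subdictionary`, with attribute `similarity` (the
#'   winning similarity) attached.
#' @export
route_test <- function(y, reps, dicts, T1 = 0.1, beta) {
  assert_reps(reps)
  if (!is.numeric(T1) || T1 <= 0 || T1 >= 1) {
    abort("`T1` must lie strictly between 0 and 1.")
  }
  s <- vapply(reps$contour, gaussian_similarity, numeric(1), x = y, beta = beta)
  r <- which.max(s)
  overflow <- length(dicts)
  grp <- if (s[r] >= T1) r else overflow
  if (is.null(dicts[[grp]])) {
    if (grp != overflow && !is.null(dicts[[overflow]])) {
      grp <- overflow
    } else {
      abort("Routing failed: selected similar class and overflow are both empty.")
    }
  }
  structure_dict <- dicts[[grp]]
  attr(structure_dict, "similarity") <- unname(s[r])
  structure_dict
}
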