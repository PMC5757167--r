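# Gaussian-kernel shape similarity between contour rasters.
#
# Images are compared as flat vectors; the kernel width is either supplied
# or derived from the data as the midrange of pairwise Euclidean distances.

#' Euclidean distance between two images
#'
#' Frobenius (flattened l2) distance between two equally sized intensity
#' arrays. This is the base metric underlying all shape similarities in the
#' package.
#'
#' @param x,y Numeric matrices of identical dimensions.
#' @return A single non-negative number; zero if and only if `x == y`.
#' @examples
#' a <- matrix(0, 32, 32)
#' b <- matrix(1, 32, 32)
#' raster_distance(a, b) # sqrt(1024) = 32
#' @export
raster_distance <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    abort("`x` and `y` must be numeric arrays.")
  }
  if (!identical(dim(x), dim(y))) {
    abort("`x` and `y` must have identical dimensions.")
  }
  sqrt(sum((x - y)^2))
}

#' Gaussian-kernel similarity between two images
#'
#' Computes `s(x, y) = exp(-||x - y||^2 / (2 * beta^2))`, a similarity in
#' (0, 1] that equals 1 exactly when the images are identical and decays
#' with their Euclidean distance at a rate controlled by the kernel width.
#'
#' @param x,y Numeric matrices of identical dimensions.
#' @param beta Positive kernel width. Larger widths flatten the similarity,
#'   making distant shapes look more alike; see [auto_kernel_width()] for a
#'   data-driven choice.
#' @return A number in (0, 1].
#' @seealso [auto_kernel_width()]
#' @export
gaussian_similarity <- function(x, y, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    abort("`beta` must be a single positive number.")
  }
  d <- raster_distance(x, y)
  exp(-d^2 / (2 * beta^2))
}

#' Data-driven Gaussian kernel width
#'
#' The kernel width is set to the midrange `(d_max + d_min) / 2` of the
#' Euclidean distances over all cross pairs between two image sets. Used
#' with (training images, representative images) to fix the partitioning
#' width, and with (test image, candidate-group members) to fix the
#' weighting width for each classification.
#'
#' @param refs,others Lists of numeric matrices (all of identical
#'   dimensions). Every pair `(refs[[i]], others[[j]])` contributes one
#'   distance.
#' @return A single positive number in `[d_min, d_max]`.
#' @examples
#' a <- matrix(0, 4, 4); b <- matrix(1 / 4, 4, 4); c <- matrix(3 / 4, 4, 4)
#' auto_kernel_width(list(a), list(b, c)) # midrange of {1, 3} = 2
#' @export
auto_kernel_width <- function(refs, others) {
  if (length(refs) == 0L || length(others) == 0L) {
    abort("Both image lists must be non-empty.")
  }
  d <- cross_distances(refs, others)
  dmax <- max(d)
  if (dmax == 0) {
    abort("All cross-pair distances are zero; the dataset is degenerate.")
  }
  (dmax + min(d)) / 2
}

# All pairwise distances between two lists of equally shaped images,
# computed on the stacked flat vectors. Returns a length(refs) x
# length(others) matrix.
cross_distances <- function(refs, others) {
  R <- vapply(refs, as.numeric, numeric(length(refs[[1L]])))
  X <- vapply(others, as.numeric, numeric(length(refs[[1L]])))
  d2 <- outer(colSums(R^2), colSums(X^2), "+") - 2 * crossprod(R, X)
  sqrt(pmax(d2, 0))
}

# Similarity matrix between two lists of images for a given width.
cross_similarities <- function(refs, others, beta) {
  exp(-cross_distances(refs, others)^2 / (2 * beta^2))
}
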