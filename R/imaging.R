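# Leaf-image preprocessing: grayscale -> background removal -> median
# denoising -> petiole (footstalk) removal -> principal-axis alignment ->
# edge extraction -> 32x32 contour normalization.
#
# Images are plain numeric arrays on the 8-bit scale [0, 255]: matrices
# (rows = image height, row-major, origin top-left) for grayscale, h x w x 3
# arrays for RGB. The final product of the chain is a 32x32 matrix in [0, 1],
# the atom unit of every dictionary in the package.

#' Preprocessing settings
#'
#' Collects the tunable parameters of the preprocessing chain.
#'
#' @param bg_thresh Background threshold on the 8-bit scale: pixels darker
#'   than this are set to 0. Suited to photographs of leaves on a
#'   near-black background after grayscale conversion.
#' @param median_radius Radius (pixels) of the median denoising filter. On
#'   small images the effective radius is capped at `floor(min(h, w) / 4)`
#'   so the filter cannot swallow the leaf itself.
#' @param stalk_width Narrowness threshold (pixels): protrusions thinner
#'   than this are candidate footstalks.
#' @param stalk_min_length Minimum length (pixels) for a thin protrusion to
#'   be treated as a footstalk.
#' @param canny_sigma Gaussian smoothing scale for edge extraction.
#' @param canny_low,canny_high Hysteresis thresholds as fractions of the
#'   maximum gradient magnitude.
#' @param out_size Side of the square output raster.
#' @param atom Whether dictionary atoms are the filled `"silhouette"` of
#'   the aligned leaf (the default) or its `"contour"` (edge map). The
#'   silhouette is the default because Euclidean distance — the base of
#'   the Gaussian shape similarity — is nearly uninformative between thin
#'   edge maps, whose supports barely overlap even for similar outlines.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(bg_thresh = 30, median_radius = 10,
                              stalk_width = 5, stalk_min_length = 10,
                              canny_sigma = 1, canny_low = 0.1,
                              canny_high = 0.3, out_size = 32,
                              atom = c("silhouette", "contour")) {
  atom <- match.arg(atom)
  stopifnot(bg_thresh >= 0, median_radius > 0, stalk_width >= 1,
            canny_sigma > 0, 0 < canny_low, canny_low < canny_high,
            canny_high <= 1, out_size >= 8)
  structure(list(bg_thresh = bg_thresh, median_radius = median_radius,
                 stalk_width = stalk_width,
                 stalk_min_length = stalk_min_length,
                 canny_sigma = canny_sigma, canny_low = canny_low,
                 canny_high = canny_high, out_size = as.integer(out_size),
                 atom = atom),
            class = "preprocess_config")
}

assert_raw_image <- function(img, arg = "img") {
  if (!is.numeric(img) || is.null(dim(img))) {
    abort(sprintf("`%s` must be a numeric matrix or h x w x 3 array.", arg))
  }
  d <- dim(img)
  if (any(d[1:2] == 0)) abort(sprintf("`%s` is empty.", arg))
  if (length(d) == 3L && d[3L] != 3L) {
    abort(sprintf("`%s` must have 3 channels if 3-dimensional.", arg))
  }
  invisible(img)
}

#' Convert a leaf photograph to grayscale
#'
#' RGB images are reduced to luminance with the standard Rec. 601 weights
#' (0.299, 0.587, 0.114); grayscale input is returned unchanged.
#'
#' @param img Numeric matrix (grayscale) or h x w x 3 array on \[0, 255\].
#' @return A numeric matrix of the same height and width.
#' @export
to_grayscale <- function(img) {
  assert_raw_image(img)
  if (length(dim(img)) == 2L) return(img)
  img[, , 1L] * 0.299 + img[, , 2L] * 0.587 + img[, , 3L] * 0.114
}

#' Suppress the dark background
#'
#' Pixels darker than the threshold are set to 0; all others are untouched.
#'
#' @param img Grayscale matrix on \[0, 255\].
#' @param thresh Intensity threshold (default 30).
#' @return Matrix of the same size.
#' @export
remove_background <- function(img, thresh = 30) {
  assert_raw_image(img)
  if (length(dim(img)) != 2L) abort("`img` must be grayscale; see to_grayscale().")
  img[img < thresh] <- 0
  img
}

#' Median-filter denoising
#'
#' Square-window median filter (side `2 * radius + 1`, replicate padding at
#' the borders) via the constant-time median filter in EBImage. To keep tiny
#' images usable the radius is capped at `floor(min(h, w) / 4)`.
#'
#' @param img Grayscale matrix on \[0, 255\].
#' @param radius Positive filter radius in pixels.
#' @return Matrix of the same size.
#' @export
denoise <- function(img, radius = 10) {
  assert_raw_image(img)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    abort("`radius` must be a single positive number.")
  }
  cap <- floor(min(dim(img)[1:2]) / 4)
  r <- as.integer(min(radius, cap))
  if (r < radius) {
    inform(sprintf("Median radius capped at %d for a %d x %d image.",
                   r, nrow(img), ncol(img)))
  }
  if (r < 1L) return(img)
  x <- pmin(pmax(img / 255, 0), 1)
  out <- EBImage::medianFilter(x, r) * 255
  dimnames(out) <- NULL
  as.matrix(out)
}

#' Binarize a leaf image
#'
#' Otsu threshold after background removal; returns a 0/255 mask. A constant
#' image degenerates to foreground = positive pixels.
#'
#' @param img Grayscale matrix on \[0, 255\].
#' @return 0/255 matrix of the same size.
#' @export
binarize <- function(img) {
  assert_raw_image(img)
  x <- pmin(pmax(img / 255, 0), 1)
  if (max(x) == min(x)) return((img > 0) * 255)
  th <- EBImage::otsu(x, range = c(0, 1))
  (x > th) * 255
}

#' Remove the footstalk (petiole) from a leaf mask
#'
#' Thin protrusions are isolated by morphological opening with a disc whose
#' diameter is the narrowness threshold; connected components of the
#' difference image are the candidate "chains", and the single longest chain
#' (bounding-box length at least `min_length`) is removed. Fine blade detail
#' such as marginal teeth produces short chains and is left intact, as is a
#' leaf too thin to survive the opening at all.
#'
#' @param mask Binary foreground mask (any positive value is foreground).
#' @param stalk_width Narrowness threshold in pixels.
#' @param min_length Minimum chain length in pixels.
#' @return The mask with the longest thin protrusion zeroed.
#' @export
remove_footstalk <- function(mask, stalk_width = 5, min_length = 10) {
  assert_raw_image(mask)
  fg <- mask > 0
  if (!any(fg)) abort("`mask` has no foreground.")
  size <- as.integer(stalk_width)
  if (size %% 2L == 0L) size <- size + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  opened <- EBImage::opening(fg * 1, brush) > 0
  if (!any(opened)) {
    warn("Leaf is thinner than the narrowness threshold everywhere; no footstalk removed.")
    return(mask)
  }
  thin <- fg & !opened
  if (!any(thin)) return(mask)
  lab <- EBImage::bwlabel(thin * 1)
  n_fg <- sum(fg)
  best <- 0L
  best_len <- -Inf
  for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) > 0.5 * n_fg) next     # never remove the leaf body
    len <- max(diff(range(px[, 1L])), diff(range(px[, 2L]))) + 1L
    if (len >= min_length && len > best_len) {
      best <- k
      best_len <- len
    }
  }
  if (best > 0L) mask[lab == best] <- 0
  mask
}

# Signed deviation (degrees, in (-90, 90]) of the foreground's second-moment
# major axis from the vertical (row) axis, plus the axis-length ratio.
principal_axis <- function(fg) {
  px <- which(fg, arr.ind = TRUE)
  y <- px[, 1L]
  x <- px[, 2L]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi   # from column axis
  dev <- if (theta > 0) theta - 90 else theta + 90
  common <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
  lam1 <- (mu20 + mu02 + common) / 2
  lam2 <- (mu20 + mu02 - common) / 2
  list(deviation = dev, ratio = sqrt(lam1 / max(lam2, .Machine$double.eps)))
}

#' Align the leaf's major axis with the vertical
#'
#' The orientation of the foreground is estimated from its second central
#' moments and the image is rotated (bilinear interpolation) so the major
#' axis is vertical. The remaining 180-degree ambiguity is resolved by
#' placing the heavier half of the leaf in the lower image half. The result
#' is tightly cropped to the foreground. Nearly isotropic shapes (axis
#' ratio below `min_ratio`) are not rotated, only cropped.
#'
#' @param img Grayscale or mask matrix on \[0, 255\]; foreground is `> fg_thresh`.
#' @param min_ratio Minimum major/minor axis-length ratio required to
#'   attempt a rotation.
#' @param min_angle Deviations (degrees) smaller than this are treated as
#'   already aligned: below the raster's angular resolution a rotation
#'   would only inject interpolation noise.
#' @param fg_thresh Intensity above which a pixel counts as foreground
#'   (default 1, which also discards interpolation dust).
#' @return Aligned, cropped matrix.
#' @export
align_major_axis <- function(img, min_ratio = 1.05, min_angle = 0.5,
                             fg_thresh = 1) {
  assert_raw_image(img)
  fg <- img > fg_thresh
  if (!any(fg)) abort("`img` has no foreground.")
  ax <- principal_axis(fg)
  if (ax$ratio < min_ratio) {
    inform("Foreground is nearly isotropic; skipping rotation.")
    return(crop_foreground(img, fg_thresh))
  }
  if (abs(ax$deviation) < min_angle) {
    return(crop_foreground(img, fg_thresh))
  }
  out <- EBImage::rotate(img / 255, ax$deviation, filter = "bilinear",
                         bg.col = 0) * 255
  dimnames(out) <- NULL
  out <- as.matrix(out)
  # 180-degree disambiguation: heavier half goes to the bottom.
  fg2 <- out > fg_thresh
  if (any(fg2)) {
    rows <- which(fg2, arr.ind = TRUE)[, 1L]
    cen <- mean(range(rows))
    if (sum(rows < cen) > sum(rows > cen)) {
      out <- out[nrow(out):1L, ncol(out):1L]
    }
  }
  crop_foreground(out, fg_thresh)
}

crop_foreground <- function(img, fg_thresh = 1) {
  px <- which(img > fg_thresh, arr.ind = TRUE)
  if (nrow(px) == 0L) abort("`img` has no foreground.")
  img[min(px[, 1L]):max(px[, 1L]), min(px[, 2L]):max(px[, 2L]), drop = FALSE]
}

# Shift a matrix by (di, dj) with zero fill.
shift_mat <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ri <- max(1, 1 + di):min(h, h + di)
  ci <- max(1, 1 + dj):min(w, w + dj)
  out[ri, ci] <- m[ri - di, ci - dj]
  out
}

#' Extract the leaf contour (Canny edges)
#'
#' Canny edge detection: Gaussian smoothing, central-difference gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' hysteresis thresholding (weak-edge components are kept only if they touch
#' a strong edge). On a binarized leaf this yields a thin closed boundary.
#'
#' @param img Grayscale or mask matrix on \[0, 255\].
#' @param sigma Gaussian smoothing scale.
#' @param low,high Hysteresis thresholds as fractions of the maximum
#'   gradient magnitude.
#' @return Binary 0/255 edge map of the same size.
#' @export
extract_contour <- function(img, sigma = 1, low = 0.1, high = 0.3) {
  assert_raw_image(img)
  if (!any(img > 0)) abort("`img` has no foreground.")
  x <- pmin(pmax(img / 255, 0), 1)
  g <- EBImage::gblur(x, sigma = sigma)
  gu <- (shift_mat(g, -1, 0) - shift_mat(g, 1, 0)) / 2   # d/d(row)
  gv <- (shift_mat(g, 0, -1) - shift_mat(g, 0, 1)) / 2   # d/d(col)
  # the one-pixel frame has no two-sided neighborhood; its "gradient" is a
  # padding artifact, so it is excluded
  gu[c(1L, nrow(gu)), ] <- 0; gu[, c(1L, ncol(gu))] <- 0
  gv[c(1L, nrow(gv)), ] <- 0; gv[, c(1L, ncol(gv))] <- 0
  mag <- sqrt(gu^2 + gv^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(0, nrow(img), ncol(img)))

  # Non-maximum suppression with bilinear interpolation of the magnitude
  # along the true gradient direction (keeps the ridge one pixel thin).
  h <- nrow(img); w <- ncol(img)
  nbr <- list()
  for (du in -1:1) for (dv in -1:1) {
    nbr[[paste(du, dv)]] <- shift_mat(mag, -du, -dv)   # value at (i+du, j+dv)
  }
  pick <- function(du_m, dv_m) {
    val <- matrix(0, h, w)
    for (du in -1:1) for (dv in -1:1) {
      msk <- du_m == du & dv_m == dv
      if (any(msk)) val[msk] <- nbr[[paste(du, dv)]][msk]
    }
    val
  }
  su <- sign(gu); sv <- sign(gv)
  au <- abs(gu); av <- abs(gv)
  row_dom <- au >= av
  f <- ifelse(row_dom, av / pmax(au, .Machine$double.eps),
              au / pmax(av, .Machine$double.eps))
  du_ax <- ifelse(row_dom, su, 0); dv_ax <- ifelse(row_dom, 0, sv)
  fwd <- (1 - f) * pick(du_ax, dv_ax) + f * pick(su, sv)
  bwd <- (1 - f) * pick(-du_ax, -dv_ax) + f * pick(-su, -sv)
  nms <- mag * (mag >= fwd & mag >= bwd)

  strong <- nms >= high * mmax
  weak <- nms >= low * mmax
  if (!any(strong)) return(matrix(0, nrow(img), ncol(img)))
  lab <- EBImage::bwlabel(weak * 1)
  ok <- sort(unique(lab[strong]))
  ok <- ok[ok > 0]
  edge <- matrix(lab %in% ok, nrow(img), ncol(img))
  edge * 255
}

#' Normalize a contour image to a fixed-size raster
#'
#' Tightly crops the image to the extents of its foreground, scales its
#' longer side to `size` by bilinear interpolation preserving the aspect
#' ratio, centers it on a `size x size` zero canvas, and rescales
#' intensities from \[0, 255\] to \[0, 1\]. Cropping first makes the result
#' invariant to where the leaf sat in the frame; preserving the aspect
#' ratio keeps elongation — the main discriminator between gross shape
#' categories such as linear and elliptic — visible to the raster metric.
#'
#' @param img Matrix on \[0, 255\] with non-empty foreground.
#' @param size Output side length (default 32).
#' @return A `size x size` matrix in \[0, 1\].
#' @export
normalize_raster <- function(img, size = 32) {
  assert_raw_image(img)
  cropped <- crop_foreground(img, fg_thresh = 0)
  sc <- size / max(dim(cropped))
  h <- max(1L, round(nrow(cropped) * sc))
  w <- max(1L, round(ncol(cropped) * sc))
  out <- EBImage::resize(cropped / 255, w = h, h = w, filter = "bilinear")
  dimnames(out) <- NULL
  out <- pmin(pmax(as.matrix(out), 0), 1)
  canvas <- matrix(0, size, size)
  r0 <- floor((size - h) / 2)
  c0 <- floor((size - w) / 2)
  canvas[r0 + seq_len(h), c0 + seq_len(w)] <- out
  canvas
}

#' Run the full preprocessing chain
#'
#' Applies, in order: grayscale conversion, background removal, median
#' denoising, Otsu binarization, footstalk removal, major-axis alignment,
#' contour extraction (skipped when `config$atom = "silhouette"`), and
#' normalization to a `out_size` square raster in \[0, 1\]. A failure in any
#' stage is rethrown with the stage name attached.
#'
#' @param img Raw leaf image: grayscale matrix or h x w x 3 array on \[0, 255\].
#' @param config A [preprocess_config()].
#' @return A `out_size` x `out_size` matrix in \[0, 1\].
#' @examples
#' leaf <- render_prototype(leaf_families()$family[[1]], size = 96)
#' r <- preprocess(leaf)
#' dim(r)
#' @export
preprocess <- function(img, config = preprocess_config()) {
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Preprocessing failed at stage '%s': %s",
                    stage, conditionMessage(e)))
    })
  }
  x <- run("to_grayscale", to_grayscale(img))
  x <- run("remove_background", remove_background(x, config$bg_thresh))
  x <- run("denoise", denoise(x, config$median_radius))
  x <- run("binarize", binarize(x))
  x <- run("remove_footstalk",
           remove_footstalk(x, config$stalk_width, config$stalk_min_length))
  x <- run("align_major_axis", align_major_axis(x))
  if (config$atom == "contour") {
    x <- run("extract_contour",
             extract_contour(x, config$canny_sigma, config$canny_low,
                             config$canny_high))
  }
  run("normalize_raster", normalize_raster(x, config$out_size))
}
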