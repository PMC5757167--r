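# Shared fixtures: small deterministic rasters and lazily built synthetic
# datasets (each built at most once per test run).

fixture_env <- new.env(parent = emptyenv())

rand_raster <- function(seed, n = 32) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

# Filled 0/255 ellipse mask, row-major image convention.
ellipse_mask <- function(h = 140, w = 120, cy = 50, cx = 60, ry = 40, rx = 20) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(rep(seq_len(w), each = h), h, w)
  (((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1) * 255
}

# The default synthetic benchmark (4 families x 3 species x 20 samples),
# preprocessed once.
get_benchmark <- function() {
  if (is.null(fixture_env$benchmark)) {
    ds <- synth_dataset(synth_spec())
    imgs <- suppressMessages(preprocess_dataset(ds$images))
    reps <- suppressMessages(preprocess_dataset(ds$reps))
    fixture_env$benchmark <- list(
      data = imgs[, c("id", "species", "contour")],
      family = imgs$family,
      reps = reps[, c("name", "contour")])
  }
  fixture_env$benchmark
}

# A small, well-separated two-family fixture (elliptic vs linear).
get_two_family <- function() {
  if (is.null(fixture_env$two_family)) {
    ds <- synth_dataset(synth_spec(n_families = 2, species_per_family = 2,
                                   samples_per_species = 10, size = 128))
    imgs <- suppressMessages(preprocess_dataset(ds$images))
    reps <- suppressMessages(preprocess_dataset(ds$reps))
    fixture_env$two_family <- list(
      data = imgs[, c("id", "species", "contour")],
      family = imgs$family,
      reps = reps[, c("name", "contour")])
  }
  fixture_env$two_family
}

# Objective of the weighted l1 problem, for oracle comparisons.
weighted_l1_objective <- function(y, A, a, w, mu) {
  sum((y - A %*% a)^2) + mu * sum(w * abs(a))
}

# Independent convex-optimization oracle for the weighted lasso, via
# glmnet's elastic net with per-atom penalty factors. glmnet minimizes
# (1/2n)||y - Xb||^2 + lambda * sum(pf_i * p / sum(pf) * |b_i|), so
# lambda = mu * sum(w) / (2 n p) reproduces
# ||y - Aa||^2 + mu * sum(w_i |a_i|) up to the constant factor 1/(2n).
glmnet_oracle <- function(y, A, w, mu) {
  lam <- mu * sum(w) / (2 * nrow(A) * ncol(A))
  fit <- glmnet::glmnet(A, y, lambda = lam, penalty.factor = w,
                        intercept = FALSE, standardize = FALSE,
                        thresh = 1e-14, maxit = 1e7)
  as.numeric(stats::coef(fit))[-1L]
}
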