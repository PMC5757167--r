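# Deterministic synthetic leaf-shape generator.
#
# Leaves are simple closed curves in warped polar form
#     rho(theta) = 1 + sum_k amp_k * cos(k * theta + phase_k)
#                    + tooth_amp * cos(tooth_freq * theta)
# drawn on an ellipse basis (vertical semi-axis ay, horizontal ax = ay /
# aspect), rasterized by an exact inside test, optionally rotated and given
# a thin footstalk. Low-order harmonics span lobed and asymmetric (cordate,
# obovate) outlines; a high-frequency low-amplitude term produces toothed
# (dentate) margins. Within-species variation is applied in parameter
# space, mimicking biological shape variation rather than pixel noise.

#' Built-in leaf shape families
#'
#' Eight parametric families covering the classical gross leaf-shape
#' categories. Each `family` entry is a parameter list understood by
#' [render_prototype()] and [render_leaf()]: `aspect` (height/width ratio),
#' `harmonics` (data frame of `k`, `amp`, `phase`), and `tooth_freq`,
#' `tooth_amp` for marginal teeth.
#'
#' @return A tibble with columns `name` and `family` (list column).
#' @export
leaf_families <- function() {
  h <- function(k = integer(), amp = numeric(), phase = numeric()) {
    data.frame(k = k, amp = amp, phase = phase)
  }
  fam <- function(aspect, harmonics = h(), tooth_freq = 0, tooth_amp = 0) {
    list(aspect = aspect, harmonics = harmonics,
         tooth_freq = tooth_freq, tooth_amp = tooth_amp)
  }
  # Lobed margins use an even harmonic (k = 6) so the outline is invariant
  # under the 180-degree flip left open by principal-axis alignment;
  # cordate/obovate are mass-asymmetric, which pins the flip instead. All
  # families keep aspect clearly above 1: principal-axis alignment is
  # ill-posed for near-circular (orbicular) leaves, whose raster then
  # depends on the arbitrary photographed orientation.
  tibble(
    name = c("elliptic", "linear", "oval", "lobed",
             "cordate", "dentate", "obovate", "oblong"),
    family = list(
      fam(2.0),
      fam(4.0),
      fam(1.3),
      fam(1.2, h(6, 0.25, 0)),
      fam(1.3, h(c(1, 2), c(0.22, 0.08), c(pi / 2, 0))),
      fam(1.6, tooth_freq = 24, tooth_amp = 0.06),
      fam(1.7, h(1, 0.2, -pi / 2)),
      fam(2.9)
    )
  )
}

# Boundary modulation rho(theta) for a parameter list.
shape_modulation <- function(params, theta) {
  m <- rep(1, length(theta))
  hs <- params$harmonics
  if (!is.null(hs) && nrow(hs) > 0) {
    for (i in seq_len(nrow(hs))) {
      m <- m + hs$amp[i] * cos(hs$k[i] * theta + hs$phase[i])
    }
  }
  if (isTRUE(params$tooth_amp > 0)) {
    m <- m + params$tooth_amp * cos(params$tooth_freq * theta)
  }
  m
}

#' Rasterize a parametric leaf
#'
#' Renders the filled silhouette of a parametric leaf contour as a binary
#' 0/255 image, by an exact per-pixel inside test (no interpolation, fully
#' deterministic). The unrotated leaf has its major axis vertical and is
#' centered; `rotation` turns it counterclockwise about the image center. A
#' footstalk, when requested, is a thin rectangle attached at the base
#' (bottom tip) of the blade, rotated with it.
#'
#' @param params Parameter list as in [leaf_families()].
#' @param size Side of the square output image in pixels.
#' @param rotation Rotation angle in degrees.
#' @param stalk `NULL` for no footstalk, or a list with `width` and
#'   `length` in pixels.
#' @return A `size x size` binary matrix with values 0/255.
#' @export
render_leaf <- function(params, size = 96, rotation = 0, stalk = NULL) {
  theta_grid <- seq(0, 2 * pi, length.out = 721L)
  mod_grid <- shape_modulation(params, theta_grid)
  if (min(mod_grid) < 0.05) {
    abort("Shape parameters yield a self-intersecting contour.")
  }
  m_max <- max(mod_grid)
  margin <- size / 2 - 2
  stalk_len <- if (is.null(stalk)) 0 else stalk$length
  m_bottom <- shape_modulation(params, pi / 2)
  ay <- min(margin / m_max, (margin - stalk_len) / m_bottom)
  if (ay <= 2) abort("Image too small for the requested shape and stalk.")
  ax <- ay / params$aspect

  ctr <- (size + 1) / 2
  xg <- matrix(rep(seq_len(size) - ctr, each = size), size, size)   # col offset
  yg <- matrix(rep(seq_len(size) - ctr, times = size), size, size)  # row offset
  phi <- -rotation * pi / 180
  xr <- xg * cos(phi) - yg * sin(phi)
  yr <- xg * sin(phi) + yg * cos(phi)

  xs <- xr / ax
  ys <- yr / ay
  rho <- sqrt(xs^2 + ys^2)
  theta <- atan2(ys, xs)
  inside <- rho <= shape_modulation(params, theta)

  if (!is.null(stalk)) {
    y0 <- ay * m_bottom - 2   # overlap into the blade keeps it attached
    inside <- inside |
      (abs(xr) <= stalk$width / 2 & yr >= y0 & yr <= y0 + stalk$length + 2)
  }
  inside * 255
}

#' Render a noise-free family prototype
#'
#' The canonical member of a shape family: no parameter noise, no rotation,
#' no footstalk, major axis vertical.
#'
#' @inheritParams render_leaf
#' @return A `size x size` binary 0/255 matrix.
#' @export
render_prototype <- function(params, size = 96) {
  render_leaf(params, size = size, rotation = 0, stalk = NULL)
}

#' Specification of a synthetic leaf dataset
#'
#' @param n_families Number of shape families (up to 8 built-ins, taken in
#'   the order of [leaf_families()]).
#' @param species_per_family Species per family. Each species receives its
#'   own deterministic parameter draw around the family prototype.
#' @param samples_per_species Images generated per species.
#' @param noise Within-species relative standard deviation applied to
#'   harmonic amplitudes, tooth amplitude and (log) aspect.
#' @param species_sd Between-species spread: sd of the species-level log
#'   aspect factor and of the species-level even-harmonic signature
#'   amplitudes. Kept well below the between-family parameter gaps, so
#'   families remain coherent shape groups — which is what makes them
#'   usable as similar classes.
#' @param rotation_range Images are rotated by an angle drawn uniformly
#'   from `[0, rotation_range)` degrees.
#' @param stalk Attach a footstalk to every sampled leaf?
#' @param stalk_width,stalk_length Footstalk geometry; `stalk_length` is a
#'   fraction of the image size.
#' @param size Image side in pixels.
#' @param seed Root seed; every prototype, species and sample draw derives
#'   its own child seed from it, so the dataset is reproducible at every
#'   granularity and adding species does not shift earlier draws.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_families = 4, species_per_family = 3,
                       samples_per_species = 20, noise = 0.05,
                       species_sd = 0.06, rotation_range = 180,
                       stalk = TRUE, stalk_width = 3, stalk_length = 0.12,
                       size = 160, seed = 7) {
  stopifnot(n_families >= 1, n_families <= 8, species_per_family >= 1,
            samples_per_species >= 1, noise >= 0, rotation_range >= 0,
            size >= 32)
  structure(list(n_families = as.integer(n_families),
                 species_per_family = as.integer(species_per_family),
                 samples_per_species = as.integer(samples_per_species),
                 noise = noise, species_sd = species_sd,
                 rotation_range = rotation_range, stalk = stalk,
                 stalk_width = stalk_width, stalk_length = stalk_length,
                 size = as.integer(size), seed = as.integer(seed)),
            class = "synth_spec")
}

# Hierarchical child seeds: a fixed arithmetic schedule below 2^31 keeps
# every draw independent of how many families/species follow it.
child_seed <- function(seed, fam, sp = 0L, sample = 0L, retry = 0L) {
  (as.double(seed) * 7919 + fam * 100003 + sp * 1009 + sample * 17 +
     retry * 3) %% 2147483629
}

# Draw species-level parameters around a family prototype. Species of a
# family share its gross outline and differ in two controlled ways:
#
# * aspect: species are spread on a deterministic log-scale ladder around
#   the family aspect (step 2 * species_sd), so every pair of congeneric
#   species differs in elongation by a guaranteed margin — random draws
#   can land arbitrarily close together, which would make two "species"
#   indistinguishable by construction rather than by difficulty;
# * a random harmonic signature on orders k = 4 and 8. These orders are
#   even (flip-invariant, so the signature survives the 180-degree
#   alignment ambiguity) and are deliberately not the orders that define
#   any family: k = 1 asymmetry, k = 2 elongation (which would fight the
#   family aspect), k = 6 lobes, or high-frequency teeth. Species
#   variation therefore never mimics another family's defining feature.
species_params <- function(fam_params, seed, species_sd, sp_index = 1L,
                           n_species = 1L) {
  set.seed(seed)
  p <- fam_params
  ladder <- 2 * species_sd * (sp_index - (n_species + 1) / 2)
  p$aspect <- clamp_aspect(p$aspect * exp(ladder))
  hs <- p$harmonics
  if (is.null(hs)) hs <- data.frame(k = integer(), amp = numeric(), phase = numeric())
  for (k in c(4, 8)) {
    sd_k <- if (k == 8) species_sd / 2 else species_sd
    if (k %in% hs$k) {
      hs$amp[hs$k == k] <- hs$amp[hs$k == k] + stats::rnorm(1, 0, sd_k)
    } else {
      hs <- rbind(hs, data.frame(k = k, amp = stats::rnorm(1, 0, sd_k),
                                 phase = stats::runif(1, 0, 2 * pi)))
    }
  }
  p$harmonics <- hs
  p
}

# Perturb species parameters for one sample.
# Aspect ratios are kept in a range where the thinnest (linear) leaves
# still survive the default median denoising at the default image size.
clamp_aspect <- function(a) min(max(a, 1.0), 5.2)

# Perturb species parameters for one sample: relative noise on every
# harmonic amplitude (the documented meaning of `noise`) plus a half-scale
# log-normal jitter of the aspect.
perturb_params <- function(sp_params, seed, noise) {
  set.seed(seed)
  p <- sp_params
  p$aspect <- clamp_aspect(p$aspect * exp(stats::rnorm(1, 0, noise / 2)))
  if (nrow(p$harmonics) > 0) {
    p$harmonics$amp <- p$harmonics$amp *
      (1 + stats::rnorm(nrow(p$harmonics), 0, noise))
  }
  if (p$tooth_amp > 0) p$tooth_amp <- p$tooth_amp * (1 + stats::rnorm(1, 0, noise))
  p
}

#' Generate a synthetic leaf dataset
#'
#' Draws `n_families * species_per_family` species, each a deterministic
#' parameter perturbation of its family prototype, and renders
#' `samples_per_species` leaves per species with i.i.d. parameter noise,
#' random rotation, and an optional footstalk. The representative set
#' contains the noise-free family prototypes — the "typical leaves" against
#' which shape similarity is measured.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `images` (tibble: `id`, `family`,
#'   `species`, `sample`, `rotation`, `raster` list column of 0/255
#'   matrices) and `reps` (tibble: `name`, `raster`), plus the `spec`.
#' @examples
#' ds <- synth_dataset(synth_spec(n_families = 2, species_per_family = 1,
#'                                samples_per_species = 2, size = 48))
#' ds$images
#' @export
synth_dataset <- function(spec = synth_spec()) {
  fams <- utils::head(leaf_families(), spec$n_families)
  stalk <- if (spec$stalk) {
    list(width = spec$stalk_width, length = spec$stalk_length * spec$size)
  } else NULL

  rows <- list()
  for (f in seq_len(spec$n_families)) {
    for (s in seq_len(spec$species_per_family)) {
      sp_par <- species_params(fams$family[[f]],
                               child_seed(spec$seed, f, s), spec$species_sd,
                               sp_index = s,
                               n_species = spec$species_per_family)
      sp_name <- sprintf("%s_sp%d", fams$name[f], s)
      for (i in seq_len(spec$samples_per_species)) {
        leaf <- NULL
        for (retry in 0:5) {
          cs <- child_seed(spec$seed, f, s, i, retry)
          par_i <- perturb_params(sp_par, cs, spec$noise)
          set.seed(cs + 1)
          rot <- stats::runif(1, 0, max(spec$rotation_range, 1e-9))
          if (spec$rotation_range == 0) rot <- 0
          leaf <- tryCatch(
            render_leaf(par_i, size = spec$size, rotation = rot, stalk = stalk),
            error = function(e) NULL)
          if (!is.null(leaf)) break
        }
        if (is.null(leaf)) {
          abort(sprintf("Could not render a valid leaf for %s after retries.",
                        sp_name))
        }
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("%s_%02d", sp_name, i),
          family = fams$name[f], species = sp_name,
          sample = i, rotation = rot, raster = list(leaf))
      }
    }
  }
  reps <- tibble(
    name = fams$name,
    raster = lapply(fams$family, render_prototype, size = spec$size))
  list(images = dplyr::bind_rows(rows), reps = reps, spec = spec)
}

#' Preprocess every image of a dataset tibble
#'
#' Maps [preprocess()] over the `raster` list column, adding a `contour`
#' list column of normalized rasters. Works for both the `images` and the
#' `reps` tibbles of [synth_dataset()].
#'
#' @param data A tibble with a `raster` list column of raw images.
#' @param config A [preprocess_config()].
#' @return `data` with an added `contour` list column.
#' @export
preprocess_dataset <- function(data, config = preprocess_config()) {
  data$contour <- lapply(data$raster, preprocess, config = config)
  data
}
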