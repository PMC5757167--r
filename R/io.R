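# File interfaces: image reading/writing, config JSON, and a plain-text
# model directory (partition JSON + one CSV of atoms per group).

#' Read a leaf image from disk
#'
#' Reads PNG/JPEG/BMP/TIFF via EBImage and returns it on the package's
#' in-memory convention: a numeric matrix (grayscale) or h x w x 3 array
#' (RGB) on the 8-bit scale, rows = image height.
#'
#' @param path Image file path.
#' @return Numeric matrix or array on \[0, 255\].
#' @export
read_leaf_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- as.array(img) * 255
  if (length(d) == 2L) return(t(a))
  if (d[3L] >= 3L) {
    return(aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L)))
  }
  t(a[, , 1L])
}

#' Write a raster (or any image matrix) as PNG
#'
#' Rasters in \[0, 1\] are written as-is; images on \[0, 255\] are rescaled.
#'
#' @param img Numeric matrix.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_leaf_image <- function(img, path) {
  x <- if (max(img) > 1) img / 255 else img
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(x, 0), 1))), path)
  invisible(path)
}

#' Write / read preprocessing settings as JSON
#'
#' @param config A [preprocess_config()].
#' @param path JSON file path.
#' @return `read_preprocess_config()` returns a [preprocess_config()].
#' @export
write_preprocess_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preprocess_config
#' @export
read_preprocess_config <- function(path) {
  do.call(preprocess_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Save / load a fitted model as a plain-text directory
#'
#' The directory holds `config.json` (classifier settings, kernel width,
#' threshold), `partition.csv` (sample id, species, group, similarity),
#' `reps.csv` (flattened representative rasters) and one `group_<j>.csv`
#' per non-empty subdictionary (first two columns id and species, then the
#' flattened atom).
#'
#' @param model A [dwsrc()] model.
#' @param dir Directory to create.
#' @return `load_model()` returns a `dwsrc_model`.
#' @export
save_model <- function(model, dir) {
  if (!inherits(model, "dwsrc_model")) abort("`model` must come from dwsrc().")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$config
  jsonlite::write_json(
    list(T = cfg$T, T1 = cfg$T1, mu = cfg$mu,
         weight_scheme = cfg$weight_scheme, weight_T = cfg$weight_T,
         decision = cfg$decision, beta = model$partition$beta,
         m = model$partition$m, rep_names = model$partition$rep_names,
         species_levels = model$species_levels),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(model$partition$assignment,
                   file.path(dir, "partition.csv"), row.names = FALSE)
  reps_flat <- t(vapply(model$reps$contour, flatten_raster,
                        numeric(length(model$reps$contour[[1L]]))))
  utils::write.csv(data.frame(name = model$reps$name, reps_flat),
                   file.path(dir, "reps.csv"), row.names = FALSE)
  for (j in seq_along(model$dicts)) {
    d <- model$dicts[[j]]
    if (is.null(d)) next
    utils::write.csv(data.frame(id = d$ids, species = d$species, t(d$atoms)),
                     file.path(dir, sprintf("group_%02d.csv", j)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  config <- dwsrc_config(T = meta$T, T1 = meta$T1, mu = meta$mu,
                         beta = meta$beta,
                         weight_scheme = meta$weight_scheme,
                         weight_T = meta$weight_T, decision = meta$decision)
  assignment <- as_tibble(utils::read.csv(file.path(dir, "partition.csv")))
  partition <- structure(
    list(assignment = assignment, threshold_T = meta$T, beta = meta$beta,
         m = meta$m, rep_names = meta$rep_names),
    class = "similar_class_partition")
  reps_df <- utils::read.csv(file.path(dir, "reps.csv"), check.names = FALSE)
  side <- as.integer(round(sqrt(ncol(reps_df) - 1L)))
  unflatten <- function(v) matrix(as.numeric(v), side, side, byrow = TRUE)
  reps <- tibble(name = reps_df$name,
                 contour = lapply(seq_len(nrow(reps_df)),
                                  function(i) unflatten(reps_df[i, -1L])))
  dicts <- vector("list", meta$m + 1L)
  for (j in seq_len(meta$m + 1L)) {
    f <- file.path(dir, sprintf("group_%02d.csv", j))
    if (!file.exists(f)) next
    g <- utils::read.csv(f, check.names = FALSE)
    dicts[[j]] <- structure(
      list(atoms = t(as.matrix(g[, -(1:2), drop = FALSE])),
           species = g$species, ids = g$id, group_id = j),
      class = "subdictionary")
  }
  structure(list(partition = partition, dicts = dicts, reps = reps,
                 config = config, species_levels = meta$species_levels),
            class = "dwsrc_model")
}
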