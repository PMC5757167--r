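# Evaluation harness: train/test splitting presets, single-split scoring,
# and repeated-split summaries.

#' Split a dataset for evaluation
#'
#' Two protocols: `"holdout_per_species"` holds out a fixed number of
#' images from every species (stratified); `"random"` holds out a fixed
#' total number of images drawn uniformly.
#'
#' @param data Tibble with at least `id` and `species`.
#' @param protocol Splitting protocol.
#' @param n_per_species Held-out images per species (stratified protocol).
#' @param n_test Total held-out images (random protocol).
#' @param seed Integer seed for the split.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(data, protocol = c("holdout_per_species", "random"),
                          n_per_species = 5, n_test = NULL, seed = 1) {
  protocol <- match.arg(protocol)
  if (!is.data.frame(data) || nrow(data) == 0L) abort("`data` is empty.")
  set.seed(seed)
  if (protocol == "holdout_per_species") {
    test_ix <- unlist(lapply(split(seq_len(nrow(data)), data$species),
                             function(ix) {
      if (length(ix) <= n_per_species) {
        abort("A species has too few images for the requested holdout.")
      }
      sample(ix, n_per_species)
    }), use.names = FALSE)
  } else {
    if (is.null(n_test)) abort("`n_test` is required for the random protocol.")
    if (n_test < 1 || n_test >= nrow(data)) abort("`n_test` out of range.")
    test_ix <- sample(seq_len(nrow(data)), n_test)
  }
  list(train = data[-test_ix, , drop = FALSE],
       test = data[test_ix, , drop = FALSE])
}

#' Score a classifier on one train/test split
#'
#' Runs the chosen classifier over every test contour and summarizes
#' accuracy, per-species accuracy, the confusion table and the mean number
#' of nonzero sparse coefficients. Test species absent from the training
#' set are counted as errors and reported.
#'
#' @param train,test Tibbles with `id`, `species`, `contour`.
#' @param method `"dwsrc"`, `"wsrc"` or `"src"`.
#' @param reps Representative shapes (required for `"dwsrc"`).
#' @param config A [dwsrc_config()]; defaults depend on the method.
#' @return An object of class `leaf_eval`: `accuracy` (percent),
#'   `per_class` tibble, `confusion` table, `predictions` tibble,
#'   `n_test`, `mean_nnz`, `method`.
#' @export
evaluate_split <- function(train, test, method = c("dwsrc", "wsrc", "src"),
                           reps = NULL, config = NULL) {
  method <- match.arg(method)
  assert_training(train)
  assert_training(test, "test")
  if (nrow(test) == 0L) abort("`test` is empty.")
  missing_sp <- setdiff(unique(test$species), unique(train$species))
  if (length(missing_sp)) {
    inform(sprintf("Test species absent from training (always errors): %s.",
                   paste(missing_sp, collapse = ", ")))
  }
  if (method == "dwsrc") {
    if (is.null(reps)) abort("`reps` are required for the two-stage classifier.")
    if (is.null(config)) config <- dwsrc_config()
    model <- dwsrc(train, reps, config)
    results <- lapply(test$contour, classify_dwsrc, model = model)
  } else {
    if (is.null(config)) {
      config <- if (method == "wsrc") {
        dwsrc_config(weight_scheme = "similarity", decision = "raw")
      } else {
        dwsrc_config(weight_scheme = "uniform", decision = "raw")
      }
    }
    classify_fun <- if (method == "wsrc") classify_wsrc else classify_src
    results <- lapply(test$contour, classify_fun, train = train,
                      config = config)
  }
  predictions <- tibble(
    id = test$id,
    truth = test$species,
    predicted = vapply(results, `[[`, character(1), "predicted"),
    group_used = vapply(results, `[[`, integer(1), "group_used"),
    nnz = vapply(results, function(r) {
      if (is.null(r$code)) NA_integer_ else r$code$nnz
    }, integer(1)),
    group_size = vapply(results, function(r) {
      if (is.null(r$code)) NA_integer_ else length(r$code$a)
    }, integer(1)))
  correct <- predictions$truth == predictions$predicted
  levels_all <- sort(unique(c(predictions$truth, predictions$predicted)))
  confusion <- table(truth = factor(predictions$truth, levels_all),
                     predicted = factor(predictions$predicted, levels_all))
  per_class <- predictions |>
    dplyr::group_by(.data$truth) |>
    dplyr::summarise(n = dplyr::n(), accuracy = 100 * mean(.data$truth == .data$predicted)) |>
    dplyr::rename(species = "truth")
  structure(list(accuracy = 100 * mean(correct),
                 per_class = per_class,
                 confusion = confusion,
                 predictions = predictions,
                 n_test = nrow(test),
                 mean_nnz = mean(predictions$nnz, na.rm = TRUE),
                 method = method),
            class = "leaf_eval")
}

#' @export
print.leaf_eval <- function(x, ...) {
  cat(sprintf("<leaf_eval> %s: accuracy %.2f%% on %d test images (mean nnz %.1f)\n",
              x$method, x$accuracy, x$n_test, x$mean_nnz))
  invisible(x)
}

#' @describeIn evaluate_split Per-species accuracy tibble.
#' @param x A `leaf_eval`.
#' @param ... Unused.
#' @export
tidy.leaf_eval <- function(x, ...) x$per_class

#' @describeIn evaluate_split One-row summary tibble.
#' @export
glance.leaf_eval <- function(x, ...) {
  tibble(method = x$method, accuracy = x$accuracy, n_test = x$n_test,
         mean_nnz = x$mean_nnz)
}

#' Repeated-split evaluation
#'
#' Repeats a split protocol with derived seeds and scores each repeat,
#' mirroring the usual "randomly hold out, repeat, average" recognition
#' protocol.
#'
#' @inheritParams evaluate_split
#' @inheritParams split_dataset
#' @param data Full dataset tibble (`id`, `species`, `contour`).
#' @param repeats Number of random splits.
#' @return An object of class `leaf_eval_repeated`: `runs` (tibble with
#'   per-repeat accuracy and mean nnz), `mean_accuracy`, `sd_accuracy`,
#'   `method`, plus the last repeat's `leaf_eval` as `last`.
#' @export
evaluate <- function(data, method = c("dwsrc", "wsrc", "src"), reps = NULL,
                     config = NULL,
                     protocol = c("holdout_per_species", "random"),
                     n_per_species = 5, n_test = NULL, repeats = 1, seed = 1) {
  method <- match.arg(method)
  protocol <- match.arg(protocol)
  runs <- vector("list", repeats)
  ev <- NULL
  for (r in seq_len(repeats)) {
    sp <- split_dataset(data, protocol, n_per_species, n_test,
                        seed = seed + 1000L * (r - 1L))
    ev <- evaluate_split(sp$train, sp$test, method, reps, config)
    runs[[r]] <- tibble(repeat_ = r, accuracy = ev$accuracy,
                        mean_nnz = ev$mean_nnz, n_test = ev$n_test)
  }
  runs <- dplyr::bind_rows(runs)
  structure(list(runs = runs,
                 mean_accuracy = mean(runs$accuracy),
                 sd_accuracy = if (repeats > 1) sd(runs$accuracy) else NA_real_,
                 method = method, last = ev),
            class = "leaf_eval_repeated")
}

#' @export
print.leaf_eval_repeated <- function(x, ...) {
  cat(sprintf("<leaf_eval_repeated> %s: %.2f%% +/- %s over %d repeat(s)\n",
              x$method, x$mean_accuracy,
              ifelse(is.na(x$sd_accuracy), "NA", sprintf("%.2f", x$sd_accuracy)),
              nrow(x$runs)))
  invisible(x)
}

#' @describeIn evaluate Per-repeat accuracies.
#' @param x A `leaf_eval_repeated`.
#' @param ... Unused.
#' @export
tidy.leaf_eval_repeated <- function(x, ...) x$runs

#' @describeIn evaluate One-row summary (mean and sd of accuracy).
#' @export
glance.leaf_eval_repeated <- function(x, ...) {
  tibble(method = x$method, mean_accuracy = x$mean_accuracy,
         sd_accuracy = x$sd_accuracy, repeats = nrow(x$runs))
}
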