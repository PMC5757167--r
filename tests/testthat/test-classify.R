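test_that("class errors match a per-class restriction oracle", {
  set.seed(61)
  atoms <- matrix(runif(16 * 6), 16, 6)
  dict <- structure(list(atoms = atoms,
                         species = c("a", "a", "b", "b", "b", "c"),
                         ids = sprintf("x%d", 1:6), group_id = 1L),
                    class = "subdictionary")
  y <- runif(16)
  a <- rnorm(6)
  errs <- class_errors(y, dict, a)
  for (cl in c("a", "b", "c")) {
    ix <- dict$species == cl
    ac <- a; ac[!ix] <- 0
    expect_equal(errs[[cl]], sqrt(sum((y - atoms %*% ac)^2)) / sum(ix),
                 tolerance = 1e-12)
  }
  raw <- class_errors(y, dict, a, normalized = FALSE)
  expect_equal(raw[["b"]], errs[["b"]] * 3)
  # an exactly representable single-atom class has zero error
  y2 <- atoms[, 6L]
  code2 <- c(0, 0, 0, 0, 0, 1)
  expect_equal(class_errors(y2, dict, code2)[["c"]], 0)
  # a zero code leaves ||y|| / n_c for every class
  errs0 <- class_errors(y, dict, rep(0, 6))
  expect_equal(unname(errs0), sqrt(sum(y^2)) / c(2, 3, 1), tolerance = 1e-12)
})

test_that("a training atom is classified as its own species", {
  fx <- get_two_family()
  model <- dwsrc(fx$data, fx$reps)
  for (i in c(1, 15, 25, 38)) {
    res <- classify_dwsrc(fx$data$contour[[i]], model)
    expect_equal(res$predicted, fx$data$species[i])
  }
})

test_that("with overwhelming regularization the largest class wins", {
  fx <- get_two_family()
  cfg <- dwsrc_config(mu = 1e9)
  # drop some atoms of one species so class sizes differ inside a group
  keep <- !(fx$data$species == fx$data$species[1] &
              seq_len(nrow(fx$data)) > 5)
  train <- fx$data[keep, , drop = FALSE]
  model <- dwsrc(train, fx$reps, cfg)
  y <- train$contour[[1L]]
  res <- classify_dwsrc(y, model)
  expect_equal(res$code$nnz, 0L)
  grp_species <- model$dicts[[res$group_used]]$species
  counts <- table(grp_species)
  expect_equal(res$predicted, names(counts)[which.max(counts)])
  expect_equal(unname(res$errors[names(counts)]),
               sqrt(sum(leafsrc:::flatten_raster(y)^2)) / as.numeric(counts),
               tolerance = 1e-9)
})

test_that("with one group the two-stage classifier reduces to the baseline", {
  fx <- get_two_family()
  cfg <- dwsrc_config(T = 0.01, T1 = 0.01, weight_scheme = "gaussian",
                      decision = "raw")
  one_rep <- fx$reps[1L, , drop = FALSE]
  model <- dwsrc(fx$data, one_rep, cfg)
  expect_equal(model$partition$m, 1L)
  expect_true(all(model$partition$assignment$group == 1L))
  for (i in seq(2, nrow(fx$data), by = 9)) {
    y <- fx$data$contour[[i]]
    r1 <- classify_dwsrc(y, model)
    r2 <- classify_wsrc(y, fx$data, cfg)
    expect_identical(r1$predicted, r2$predicted)
    expect_equal(r1$errors, r2$errors, tolerance = 1e-9)
  }
})

test_that("the weighted baseline recovers training atoms and rejects empty input", {
  fx <- get_two_family()
  y <- fx$data$contour[[7L]]
  res <- classify_wsrc(y, fx$data)
  expect_equal(res$predicted, fx$data$species[7L])
  expect_error(classify_wsrc(y, fx$data[0L, ]), "non-empty")
})

test_that("resubstitution on separable data is perfect and deterministic", {
  fx <- get_two_family()
  ev1 <- evaluate_split(fx$data, fx$data[seq(1, 40, 4), ], "dwsrc",
                        reps = fx$reps)
  expect_equal(ev1$accuracy, 100)
  ev2 <- evaluate_split(fx$data, fx$data[seq(1, 40, 4), ], "dwsrc",
                        reps = fx$reps)
  expect_identical(ev1$predictions, ev2$predictions)
  expect_equal(sum(ev1$confusion), ev1$n_test)
  expect_true(all(rowSums(ev1$confusion)[unique(ev1$predictions$truth)] > 0))
})

test_that("label permutation drops accuracy to chance level", {
  fx <- get_two_family()
  perm <- fx$data
  set.seed(77)
  perm$species <- sample(perm$species)
  ev <- suppressMessages(suppressWarnings(
    evaluate(perm, "dwsrc", reps = fx$reps, n_per_species = 3,
             repeats = 2, seed = 3)))
  expect_lt(ev$mean_accuracy, 60)   # 4 species, chance 25%, binomial spread
})

test_that("evaluation flags unknown test species and empty test sets", {
  fx <- get_two_family()
  train <- fx$data[fx$data$species != fx$data$species[1L], ]
  test <- fx$data[fx$data$species == fx$data$species[1L], ][1:3, ]
  expect_message(
    ev <- suppressWarnings(evaluate_split(train, test, "wsrc")),
    "absent")
  expect_equal(ev$accuracy, 0)
  expect_error(evaluate_split(fx$data, fx$data[0L, ], "wsrc"), "non-empty")
})

test_that("tidiers and glance return well-formed tibbles", {
  fx <- get_two_family()
  model <- dwsrc(fx$data, fx$reps)
  td <- tidy(model$partition)
  expect_named(td, c("id", "species", "group", "similarity"))
  ev <- evaluate_split(fx$data, fx$data[seq(1, 40, 10), ], "dwsrc",
                       reps = fx$reps)
  g <- glance(ev)
  expect_named(g, c("method", "accuracy", "n_test", "mean_nnz"))
  expect_equal(g$accuracy, ev$accuracy)
  res <- classify_dwsrc(fx$data$contour[[1L]], model)
  tr <- tidy(res)
  expect_true(all(c("species", "error", "predicted") %in% names(tr)))
  p1 <- autoplot(model$partition)
  p2 <- autoplot(ev)
  p3 <- autoplot(res)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_s3_class(p3, "ggplot")
})
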