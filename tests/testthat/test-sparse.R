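test_that("gaussian distance weights grow with distance from the test vector", {
  y <- matrix(0, 4, 4)
  atoms <- vapply(c(0, 1, 2, 3), function(v) rep(v / 4, 16), numeric(16))
  w <- weights_gaussian(y, atoms, beta1 = 2)
  d2 <- colSums((atoms - as.numeric(y))^2)
  expect_equal(as.numeric(w), pmin(exp(d2 / 8), 1e12), tolerance = 1e-12)
  expect_equal(w[[1]], 1)                      # identical atom -> exp(0)
  expect_true(all(diff(w) >= 0))               # monotone in distance
  expect_error(weights_gaussian(y, atoms, 0), "positive")
})

test_that("similarity weights threshold the Gaussian kernel", {
  y <- rand_raster(31)
  atoms <- cbind(as.numeric(y), as.numeric(rand_raster(32)),
                 as.numeric(rand_raster(33)))
  beta <- 3
  w <- weights_similarity(y, atoms, beta, threshold = 0.5)
  s <- exp(-colSums((atoms - as.numeric(y))^2) / (2 * beta^2))
  expect_equal(as.numeric(w), ifelse(s > 0.5, s, 0), tolerance = 1e-12)
  expect_equal(w[[1]], 1)                      # identical atom, s = 1 > T
  # a pair engineered below threshold gets weight zero
  far <- matrix(10, 32, 32)
  w2 <- weights_similarity(y, cbind(as.numeric(far)), beta, 0.5)
  expect_identical(w2[[1]], 0)
})

test_that("the weighted l1 solver matches the scalar soft-threshold closed form", {
  set.seed(101)
  d <- 40
  y <- rnorm(d)
  A <- diag(d)
  mu <- 0.3
  sol <- solve_weighted_l1(y, A, rep(1, d), solver_config(mu = mu))
  soft <- sign(y) * pmax(abs(y) - mu / 2, 0)
  expect_lt(max(abs(sol$a - soft)), 1e-10)
  expect_equal(sol$nnz, sum(abs(soft) > 1e-8))
})

test_that("large regularization yields the null solution and zero input a zero code", {
  set.seed(102)
  A <- matrix(rnorm(200), 10, 20)
  y <- rnorm(10)
  w <- runif(20, 0.5, 2)
  mu_big <- 2 * max(abs(crossprod(A, y)) / w) + 1
  sol <- solve_weighted_l1(y, A, w, solver_config(mu = mu_big))
  expect_identical(sol$a, numeric(20))
  sol0 <- solve_src(rep(0, 10), A, solver_config())
  expect_identical(sol0$a, numeric(20))
  expect_equal(sol0$objective, 0)
})

test_that("the solver agrees with an independent convex-optimization oracle", {
  skip_if_not_installed("glmnet")
  for (s in 1:5) {
    set.seed(300 + s)
    A <- matrix(rnorm(200), 10, 20)
    y <- rnorm(10)
    w <- runif(20, 0.2, 3)
    mu <- 10^runif(1, -3, 0)
    sol <- solve_weighted_l1(y, A, w, solver_config(mu = mu, tol = 1e-10, max_iter = 2e5))
    a_or <- glmnet_oracle(y, A, w, mu)
    f_ours <- weighted_l1_objective(y, A, sol$a, w, mu)
    f_or <- weighted_l1_objective(y, A, a_or, w, mu)
    expect_lt(abs(f_ours - f_or) / f_or, 1e-6)
  }
})

test_that("solve_src is solve_weighted_l1 with unit weights, exactly", {
  set.seed(103)
  A <- matrix(rnorm(150), 10, 15)
  y <- rnorm(10)
  s1 <- solve_src(y, A, solver_config(mu = 0.05))
  s2 <- solve_weighted_l1(y, A, rep(1, 15), solver_config(mu = 0.05))
  expect_identical(s1$a, s2$a)
  expect_identical(s1$objective, s2$objective)
})

test_that("an atom identical to the input dominates an orthogonal dictionary", {
  A <- diag(8)[, 1:6]
  y <- A[, 3]
  sol <- solve_src(y, A, solver_config(mu = 1e-4))
  expect_gt(sol$a[3], 0.99)
  expect_lt(max(abs(sol$a[-3])), 0.01)
})

test_that("sparsity is non-increasing in the regularization strength", {
  set.seed(104)
  A <- matrix(rnorm(300), 15, 20)
  y <- rnorm(15)
  nnz <- vapply(c(0.001, 0.01, 0.1, 1, 10), function(mu) {
    solve_src(y, A, solver_config(mu = mu))$nnz
  }, integer(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("raising one atom's weight never increases its coefficient", {
  for (s in 1:5) {
    set.seed(400 + s)
    A <- matrix(rnorm(120), 8, 15)
    y <- rnorm(8)
    w <- rep(1, 15)
    base <- solve_weighted_l1(y, A, w, solver_config(mu = 0.2, tol = 1e-10))
    j <- which.max(abs(base$a))
    w2 <- w; w2[j] <- 2
    up <- solve_weighted_l1(y, A, w2, solver_config(mu = 0.2, tol = 1e-10))
    expect_lte(abs(up$a[j]), abs(base$a[j]) + 1e-9)
  }
})

test_that("zero-weight atoms are unregularized and zero-norm atoms stay out", {
  set.seed(105)
  A <- cbind(diag(4), 0)          # last atom has zero norm
  y <- c(2, -1, 0.5, 0)
  w <- c(0, 1, 1, 1, 1)           # first atom unpenalized
  sol <- solve_weighted_l1(y, A, w, solver_config(mu = 0.4))
  expect_equal(sol$a[1], y[1], tolerance = 1e-10)   # exact least squares
  expect_identical(sol$a[5], 0)
  soft <- sign(y[2:4]) * pmax(abs(y[2:4]) - 0.2, 0)
  expect_equal(sol$a[2:4], soft, tolerance = 1e-10)
})

test_that("the solver is deterministic and reports diagnostics", {
  set.seed(106)
  A <- matrix(rnorm(200), 10, 20)
  y <- rnorm(10)
  w <- runif(20, 0.5, 2)
  s1 <- solve_weighted_l1(y, A, w, solver_config(mu = 0.01))
  s2 <- solve_weighted_l1(y, A, w, solver_config(mu = 0.01))
  expect_identical(s1$a, s2$a)
  expect_true(s1$converged)
  expect_true(is.finite(s1$objective))
  expect_lte(s1$nnz, 20)
  td <- tidy(s1)
  expect_named(td, c("atom", "coefficient", "weight"))
  expect_equal(nrow(td), 20)
})
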