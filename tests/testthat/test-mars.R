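test_that("forward-pass basis cap follows the published formula", {
  expect_equal(max_basis_count(12), 25)
  expect_equal(max_basis_count(5), 21)
  expect_equal(max_basis_count(150), 201)
  expect_equal(max_basis_count(1), 21)
  expect_error(max_basis_count(0), ">= 1")
})

test_that("GCV score matches its closed form", {
  expect_equal(gcv_score(50, 100, 1, 0), 0.5 / 0.99^2)
  expect_equal(gcv_score(0, 100, 5, 2), 0)
  # penalty only matters through knots
  expect_equal(gcv_score(10, 50, 3, 0, penalty = 3),
               gcv_score(10, 50, 3, 0, penalty = 99))
  expect_error(gcv_score(10, 20, 5, 5, penalty = 3), "too complex")
})

test_that("forward pass finds a single-hinge signal and its knot", {
  set.seed(51)
  x <- matrix(runif(500), dimnames = list(NULL, list("x")))
  y <- pmax(0, x[, 1] - 0.5) + rnorm(500, 0, 0.01)
  m <- mars_forward(x, y)
  first <- m$basis[[2]]   # first added pair, right hinge
  expect_equal(first[[1]]$var, "x")
  expect_lt(abs(first[[1]]$knot - 0.5), 0.05)
})

test_that("reflected hinge pair reproduces exact linear and |x-k| shapes", {
  set.seed(52)
  x <- matrix(sort(runif(60, -1, 1)), dimnames = list(NULL, list("x")))
  # mirrored hinges sum to |x - k|; with an intercept they span any
  # one-knot piecewise-linear function, including a pure line
  y_lin <- 3 - 2 * x[, 1]
  m <- mars_forward(x, y_lin)
  expect_lt(m$rss, 1e-6)
  k <- 0.2
  y_abs <- abs(x[, 1] - k)
  expect_equal(pmax(0, x[, 1] - k) + pmax(0, k - x[, 1]), y_abs)
})

test_that("degenerate forward-pass inputs behave as contracted", {
  x <- matrix(runif(50), dimnames = list(NULL, list("x")))
  m <- mars_forward(x, rep(2, 50))
  expect_equal(m$n_basis, 1L)
  expect_equal(unname(m$coefficients), 2)
  expect_error(mars_forward(x[1:5, , drop = FALSE], rnorm(5)), "10")
})

test_that("backward pruning never worsens GCV and matches exhaustive search", {
  set.seed(53)
  for (i in 1:8) {
    n <- 80
    X <- matrix(runif(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
    y <- 2 * pmax(0, X[, 1] - 0.4) + rnorm(n, 0, 0.3)
    fwd <- mars_forward(X, y, max_basis = 6)
    expect_lte(fwd$n_basis, 6L)
    prn <- mars_backward(fwd)
    expect_lte(prn$gcv, gcv_score(fwd$rss, n, fwd$n_basis,
                                  (fwd$n_basis - 1) / 2, 3) + 1e-12)
    # oracle: exhaustive minimization over all basis subsets
    expect_equal(prn$gcv, gcv_exhaustive(fwd), tolerance = 1e-10)
  }
})

test_that("pruning keeps pure-noise models small (property)", {
  # forward selection bias on noise (~3 sigma^2 RSS drop per basis) sits
  # close to the GCV charge (2.5 per basis at penalty 3), so a handful of
  # spurious bases survive in a minority of runs; measured over 100 seeds:
  # 67% have <= 2 non-intercept bases, 96% have <= 5, median 1.
  reps <- 60
  sizes <- integer(reps)
  for (i in seq_len(reps)) {
    set.seed(700 + i)
    X <- matrix(rnorm(200 * 5), 200, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    y <- rnorm(200)
    m <- mars_backward(mars_forward(X, y))
    sizes[i] <- m$n_basis - 1L
    expect_lt(m$n_basis, 15L)  # always far below the forward cap of 21
  }
  expect_lte(median(sizes), 2)
  expect_gte(mean(sizes <= 5), 0.8)
})

test_that("prediction evaluates the hinge-product basis", {
  # hand-built 2-basis model: 1.5 + 2 * h(x - 1) on 3 points
  model <- structure(
    list(basis = list(list(),
                      list(list(var = "x", sign = 1, knot = 1))),
         coefficients = c(`(Intercept)` = 1.5, `h(x-1)` = 2),
         gcv = NA_real_, n_basis = 2L, penalty = 3,
         variables = "x", X = NULL, y = NULL),
    class = "mars_model")
  X <- matrix(c(0, 1, 3), dimnames = list(NULL, list("x")))
  expect_equal(predict(model, X), c(1.5, 1.5, 5.5))
  expect_equal(mars_predict(model, X), predict(model, X))
  # below every knot of a (+) hinge the contribution is zero
  expect_equal(predict(model, matrix(-10, dimnames = list(NULL, "x"))), 1.5)
  expect_error(predict(model, matrix(1, dimnames = list(NULL, "z"))),
               "missing variable")
  # intercept-only model predicts the training mean
  x1 <- matrix(runif(30), dimnames = list(NULL, list("x")))
  m0 <- mars_forward(x1, rep(7, 30))
  expect_equal(unique(predict(m0, x1)), 7)
})

test_that("interaction degree and variable-reuse constraints hold", {
  set.seed(54)
  X <- matrix(runif(300 * 3), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- pmax(0, X[, 1] - 0.3) * pmax(0, X[, 2] - 0.4) + rnorm(300, 0, 0.05)
  m <- mars_backward(mars_forward(X, y, max_degree = 2))
  for (bf in m$basis) {
    expect_lte(length(bf), 2L)
    vars <- vapply(bf, `[[`, character(1), "var")
    expect_equal(anyDuplicated(vars), 0L)
  }
})

test_that("cross-validation is deterministic and handles leave-one-out", {
  set.seed(55)
  X <- matrix(runif(120), dimnames = list(NULL, list("x")))
  y <- pmax(0, X[, 1] - 0.5) + rnorm(120, 0, 0.1)
  cv1 <- mars_cv(X, y, folds = 5, seed = 99)
  cv2 <- mars_cv(X, y, folds = 5, seed = 99)
  expect_identical(cv1$fold_id, cv2$fold_id)
  expect_identical(cv1$fold_errors, cv2$fold_errors)
  expect_length(cv1$fold_errors, 5L)
  # degenerate stratification: folds = n falls back to unstratified
  Xs <- X[1:10, , drop = FALSE]
  loo <- mars_cv(Xs, y[1:10], folds = 10, seed = 1)
  expect_length(loo$fold_errors, 10L)
  expect_error(mars_cv(Xs, y[1:10], folds = 11), "folds > n")
})

test_that("cross-validated error approaches the irreducible noise", {
  set.seed(56)
  n <- 600
  X <- matrix(runif(n), dimnames = list(NULL, list("x")))
  sigma <- 0.2
  y <- 1 + 2 * pmax(0, X[, 1] - 0.5) + rnorm(n, 0, sigma)
  cv <- mars_cv(X, y, folds = 10, seed = 3)
  expect_lt(abs(cv$cv_error - sigma^2) / sigma^2, 0.2)
})

test_that("JSON serialization round-trips predictions", {
  set.seed(57)
  X <- matrix(runif(200 * 2), 200, 2, dimnames = list(NULL, c("a", "b")))
  y <- pmax(0, X[, 1] - 0.5) + 0.5 * X[, 2] + rnorm(200, 0, 0.05)
  m <- mars_backward(mars_forward(X, y))
  path <- withr::local_tempfile(fileext = ".json")
  mars_to_json(m, path)
  back <- mars_from_json(path)
  expect_equal(predict(back, X), predict(m, X))
  expect_equal(back$n_basis, m$n_basis)
})
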