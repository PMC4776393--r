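test_that("2x2 design recovers the closed-form log odds ratio", {
  # exposed: 10 events / 10 non-events; unexposed: 10 events / 20 non-events
  x <- c(rep(1, 20), rep(0, 30))
  y <- c(rep(1, 10), rep(0, 10), rep(1, 10), rep(0, 20))
  fit <- fit_logistic(matrix(x, dimnames = list(NULL, "exposed")), y)
  expect_equal(unname(fit$coefficients["exposed"]), log(2),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(10 / 20),
               tolerance = 1e-6)
})

test_that("IRLS agrees with glm on coefficients, SEs and likelihood", {
  dat <- logistic_data(500, c(-0.3, 0.9, -0.6, 0.2), seed = 41)
  fit <- fit_logistic(dat$X, dat$y)
  g <- glm(dat$y ~ dat$X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(fit$standard_errors),
               unname(summary(g)$coefficients[, 2]), tolerance = 1e-4)
  expect_equal(fit$log_likelihood, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_true(all(fit$p_values >= 0 & fit$p_values <= 1))
})

test_that("degenerate designs raise the contracted errors", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_logistic(X, rep(1, 20)), "single class")
  Xd <- cbind(X, a2 = X[, "a"])
  expect_error(fit_logistic(Xd, rep_len(c(0, 1), 20)), "collinear.*a2")
  # perfectly separated outcome
  xs <- c(rnorm(30, -0.5, 0.1), rnorm(30, 0.5, 0.1))
  ys <- c(rep(0, 30), rep(1, 30))
  expect_error(fit_logistic(matrix(xs, dimnames = list(NULL, "s")), ys),
               "separation")
})

test_that("parameter recovery: true coefficients inside +/-2 SE (property)", {
  beta <- c(-0.4, 0.7, -0.5)
  hits <- c(0, 0, 0)
  reps <- 40
  for (i in seq_len(reps)) {
    dat <- logistic_data(1500, beta, seed = 500 + i)
    fit <- fit_logistic(dat$X, dat$y)
    hits <- hits + (abs(fit$coefficients - beta) <= 2 * fit$standard_errors)
  }
  expect_true(all(hits / reps >= 0.85))
})

test_that("interaction expansion produces all pairwise products", {
  X <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "b")))
  E <- expand_interactions(X)
  expect_equal(colnames(E), c("a", "b", "a:b"))
  expect_equal(E[, "a:b"], X[, "a"] * X[, "b"])
  X3 <- cbind(X, c = 7:9)
  expect_equal(ncol(expand_interactions(X3)), 6L)
})

test_that("backward elimination removes noise terms and respects hierarchy", {
  # truth: y depends on x1 only; x2 and products are noise
  # truth: y ~ x1 only. Removing both null terms takes two sequential LRTs
  # at alpha = 0.1 (hierarchy forces the product out first), so the
  # all-removed rate is ~(1 - 0.1)^2 = 0.81; measured 0.813 over 600 reps.
  removed_all <- 0
  reps <- 150
  for (i in seq_len(reps)) {
    dat <- logistic_data(2000, c(-0.2, 1.0, 0), seed = 600 + i)
    fit <- fit_logistic(expand_interactions(dat$X), dat$y)
    red <- backward_eliminate(fit, removal_p = 0.1)
    kept <- names(red$terms)
    removed_all <- removed_all +
      (!("x2" %in% kept) && !("x1:x2" %in% kept) && ("x1" %in% kept))
    # hierarchy: a main effect never leaves while its product stays
    for (nm in kept) {
      vars <- red$terms[[nm]]
      if (length(vars) == 2L) expect_true(all(vars %in% kept))
    }
  }
  expect_gte(removed_all / reps, 0.70)   # 0.81 - 4 binomial SE
  expect_lte(removed_all / reps, 0.93)   # 0.81 + 4 binomial SE
})

test_that("elimination endpoints: removal_p extremes and fixed points", {
  dat <- logistic_data(800, c(0.2, 1.5, -1.2), seed = 44)
  fit <- fit_logistic(dat$X, dat$y)
  # removal_p = 1: everything is removable down to the intercept
  null_fit <- backward_eliminate(fit, removal_p = 1.0)
  expect_length(null_fit$terms, 0L)
  expect_equal(unname(null_fit$coefficients["(Intercept)"]),
               qlogis(mean(dat$y)), tolerance = 1e-8)
  # strong effects: nothing removable at p < 0.1 -> unchanged
  kept <- backward_eliminate(fit, removal_p = 0.1)
  expect_equal(names(kept$terms), names(fit$terms))
  expect_equal(kept$coefficients, fit$coefficients)
})

test_that("elimination is invariant to column order", {
  dat <- logistic_data(1200, c(-0.1, 0.9, 0, 0.4), seed = 45)
  X <- expand_interactions(dat$X)
  f1 <- backward_eliminate(fit_logistic(X, dat$y), 0.1)
  perm <- c(4, 2, 6, 1, 5, 3)
  f2 <- backward_eliminate(fit_logistic(X[, perm], dat$y), 0.1)
  expect_setequal(names(f1$terms), names(f2$terms))
  expect_equal(f1$coefficients[sort(names(f1$coefficients))],
               f2$coefficients[sort(names(f2$coefficients))],
               tolerance = 1e-6)
})

test_that("prediction rebuilds interaction columns from base features", {
  dat <- logistic_data(300, c(0, 0.8, -0.5), seed = 46)
  fit <- fit_logistic(expand_interactions(dat$X), dat$y)
  nd <- as.data.frame(dat$X)
  manual <- fit$coefficients["(Intercept)"] +
    fit$coefficients["x1"] * nd$x1 + fit$coefficients["x2"] * nd$x2 +
    fit$coefficients["x1:x2"] * nd$x1 * nd$x2
  expect_equal(predict(fit, nd), unname(manual))
  expect_equal(predict(fit, nd, type = "response"), plogis(unname(manual)))
  expect_error(predict(fit, nd["x1"]), "missing feature")
})

test_that("published score reproduces the fixed coefficients", {
  zero <- data.frame(n_d2 = 0, tcv_d2 = 0, frag_d2 = 0, n_d3_dev = 0,
                     cod_d2 = 0, cod_d3 = 0, parity_d2 = 0)
  expect_equal(published_score(zero, male_age = 0), 12.070)
  one_n2 <- transform(zero, n_d2 = 1)
  expect_equal(published_score(one_n2, male_age = 0), 12.070 + 0.817)
  # with male age 0, increasing fragmentation strictly decreases the score
  s <- vapply(seq(0, 0.5, 0.1), function(fr)
    published_score(transform(zero, frag_d2 = fr), male_age = 0),
    numeric(1))
  expect_true(all(diff(s) < 0))
  # TCV scale factor is configurable
  tcv <- transform(zero, tcv_d2 = 1e5)
  expect_equal(published_score(tcv, male_age = 0, tcv_scale = 1e-5),
               12.070 - 1.572)
  expect_error(published_score(zero[, -1], male_age = 0), "n_d2")
  # cass_features input works
  f <- derive_cass_features(conserved_embryo())
  expect_equal(published_score(f, male_age = 33),
               published_score(as.data.frame(unclass(f)[c(
                 "n_d2", "tcv_d2", "frag_d2", "n_d3_dev", "cod_d2",
                 "cod_d3", "parity_d2")]), male_age = 33))
})

test_that("published coefficient table is complete and typed", {
  tab <- published_coefficients()
  expect_equal(nrow(tab), 12L)
  expect_equal(tab$estimate[tab$term == "(Intercept)"], 12.070)
  expect_equal(tab$estimate[tab$term == "Parity_Day2:Number_Day3"], 0.730)
  expect_true(all(is.finite(tab$se)))
})
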