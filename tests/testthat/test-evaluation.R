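test_that("AUC handles perfect separation and total ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(2, 10), rep_len(c(0, 1), 10))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both outcome classes")
})

test_that("AUC equals the brute-force pairwise count (oracle)", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    expect_equal(roc_auc(scores, labels)$auc, auc_brute(scores, labels))
  }
})

test_that("ROC curve is monotone from (0,0) to (1,1)", {
  set.seed(62)
  r <- roc_auc(rnorm(100), rbinom(100, 1, 0.4))
  expect_equal(r$sensitivity[1], 0)
  expect_equal(r$fpr[1], 0)
  expect_equal(r$sensitivity[length(r$sensitivity)], 1)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_true(all(diff(r$sensitivity) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
})

test_that("AUC invariances: negation and increasing transforms", {
  set.seed(63)
  for (i in 1:10) {
    s <- rnorm(60)
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- roc_auc(s, y)$auc
    expect_equal(roc_auc(-s, y)$auc, 1 - a)
    expect_equal(roc_auc(exp(2 * s) + 5, y)$auc, a)
  }
})

test_that("AUC grading bands are lower-inclusive", {
  expect_equal(grade_auc(0.69), "poor")   # the headline validation value
  expect_equal(grade_auc(0.95), "excellent")
  expect_equal(grade_auc(c(0.5, 0.6, 0.7, 0.8, 0.9)),
               c("fail", "poor", "fair", "good", "excellent"))
  expect_equal(grade_auc(0.3), "fail")
  expect_error(grade_auc(1.2), "\\[0, 1\\]")
})

test_that("paired AUC comparison is exact under identity", {
  set.seed(64)
  s <- rnorm(80)
  y <- rbinom(80, 1, 0.5)
  cmp <- compare_auc(s, y, s, y, paired = TRUE)
  expect_equal(cmp$auc_a, cmp$auc_b)
  expect_equal(cmp$p, 1)
  expect_error(compare_auc(s, y, s, rev(y), paired = TRUE), "identical")
})

test_that("DeLong type-I error is calibrated (paired null simulation)", {
  reps <- 600
  rej <- 0
  set.seed(65)
  y <- rep_len(c(0, 1), 200)
  for (i in seq_len(reps)) {
    rej <- rej + (compare_auc(rnorm(200), y, rnorm(200), y,
                              paired = TRUE)$p < 0.05)
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})

test_that("unpaired comparison p-values are null-uniform (KS check)", {
  reps <- 400
  set.seed(66)
  ps <- replicate(reps, {
    ya <- rep_len(c(0, 1), 150)
    sa <- rnorm(150) + 0.5 * ya      # same score model, two cohorts
    yb <- rep_len(c(0, 1), 150)
    sb <- rnorm(150) + 0.5 * yb
    compare_auc(sa, ya, sb, yb, paired = FALSE)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("agreement grading matches the published bands", {
  expect_equal(grade_agreement(0.747), "good")
  expect_equal(grade_agreement(c(0.85, 0.6, 0.4, 0.2, 0.1)),
               c("excellent", "good", "moderate", "poor", "very poor"))
  expect_error(grade_agreement(1.5), "<= 1")
})

test_that("ICC(A,1) matches the reference implementation (frozen oracle)", {
  # fixture generated from subject + rater-shift + noise; expected value
  # 0.805374 computed with an independent two-way mixed absolute-agreement
  # single-measure reference
  r1 <- c(44.487096, 52.282182, 43.456282, 41.907875, 45.923545, 39.522742,
          43.051157, 61.786074, 44.932432, 44.135178, 50.308013, 52.13561,
          48.118585, 38.268808, 52.890178, 54.530428, 36.460289, 48.077012,
          29.236971, 36.769517)
  r2 <- c(51.843694, 54.678801, 45.083454, 42.822502, 51.029762, 36.9421,
          54.679584, 65.260215, 44.653524, 51.296501, 58.6852, 51.471003,
          52.777691, 43.925388, 50.641135, 60.501763, 37.858303, 48.925585,
          36.80334, 36.577636)
  res <- icc(cbind(r1, r2))
  expect_equal(res$value, 0.805374, tolerance = 1e-6)
  expect_equal(res$grade, "excellent")
})

test_that("ICC degenerate and null behaviour", {
  x <- rnorm(30, 50, 8)
  dup <- icc(cbind(x, x))
  expect_equal(dup$value, 1.0)
  expect_equal(dup$grade, "excellent")
  expect_error(icc(cbind(rep(1, 10), rep(1, 10))), "undefined")
  expect_error(icc(cbind(1:2, 2:1)), "3 subjects")
  # independent permutation: ICC near zero
  set.seed(67)
  vals <- replicate(20, {
    a <- rnorm(100)
    icc(cbind(a, sample(a)))$value
  })
  # ICC of permuted columns is centred on 0 with sd ~ 1/sqrt(n)
  expect_lt(abs(mean(vals)), 0.1)
  expect_lt(max(abs(vals)), 0.4)   # ~4 sd guard for 20 draws at n = 100
})

test_that("Cohen's kappa follows its closed form", {
  expect_equal(cohen_kappa(c(1, 2, 1, 2), c(1, 2, 1, 2))$value, 1.0)
  # constructed table: p_o = 0.8, p_e = 0.5 -> kappa 0.6
  r1 <- c(rep("A", 50), rep("B", 50))
  r2 <- c(rep("A", 40), rep("B", 10), rep("B", 40), rep("A", 10))
  k <- cohen_kappa(r1, r2)
  expect_equal(k$value, (0.8 - 0.5) / (1 - 0.5))
  expect_equal(k$grade, "good")
  # kappa <= observed agreement
  expect_lte(k$value, 0.8)
  expect_error(cohen_kappa(rep(1, 5), rep(1, 5)), "undefined")
  # independent ratings: near zero
  set.seed(68)
  k0 <- cohen_kappa(sample(1:4, 5000, TRUE), sample(1:4, 5000, TRUE))
  expect_lt(abs(k0$value), 0.05)
})

test_that("collinearity diagnostics: VIF closed form and band flags", {
  set.seed(69)
  n <- 200
  # orthogonal design
  X <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n)
  colnames(X) <- c("a", "b", "c")
  rep0 <- collinearity_diagnostics(X)
  expect_true(all(abs(rep0$vif - 1) < 0.05))
  expect_true(all(rep0$condition_indices < 30))
  expect_true(all(rep0$flags == "weak"))
  # near-duplicate column: VIF approaches 1/(1-r^2)
  a <- rnorm(n)
  for (sd_noise in c(0.5, 0.1, 0.02)) {
    b <- a + rnorm(n, 0, sd_noise)
    rep1 <- collinearity_diagnostics(cbind(a = a, b = b))
    r2 <- summary(lm(b ~ a))$r.squared
    expect_equal(unname(rep1$vif["b"]), 1 / (1 - r2), tolerance = 1e-6)
  }
  # variance decomposition columns each sum to 1
  Xg <- cbind(a = a, b = a + rnorm(n, 0, 0.1), c = rnorm(n))
  repg <- collinearity_diagnostics(Xg)
  expect_equal(unname(colSums(repg$variance_decomposition)),
               rep(1, 4), tolerance = 1e-9)
  expect_true(all(repg$condition_indices >= 1 - 1e-12))
  # exact singularity: infinite VIF flagged, no crash
  reps <- collinearity_diagnostics(cbind(a = a, b = 2 * a, c = rnorm(n)))
  expect_true(is.infinite(reps$vif[["b"]]) || is.infinite(reps$vif[["a"]]))
})

test_that("condition-index bands match the printed scale", {
  flags <- collinearity_diagnostics(
    matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b"))))$flags
  expect_true(all(flags %in% c("weak", "moderate to strong", "severe")))
  # a condition index of 92 sits in the moderate-to-strong 30-100 band
  flag_of <- function(ci) if (ci > 100) "severe" else
    if (ci >= 30) "moderate to strong" else "weak"
  expect_equal(flag_of(92), "moderate to strong")
})

test_that("mutual information: closed forms and independence null", {
  y <- rep_len(c(0, 1), 1000)
  expect_equal(mutual_information(y, y), 1.0)      # identical, balanced
  expect_equal(mutual_information(rep(3, 100), rbinom(100, 1, 0.5)), 0)
  # constructed joint: feature = outcome for half the rows, coin otherwise
  set.seed(70)
  n <- 4000
  yy <- rbinom(n, 1, 0.5)
  f <- ifelse(seq_len(n) <= n / 2, yy, rbinom(n, 1, 0.5))
  tab <- table(f, yy) / n
  manual <- sum(tab * log2(tab / outer(rowSums(tab), colSums(tab))))
  expect_equal(mutual_information(f, yy), manual)
  # independent continuous feature: MI below the permutation-null 95th pct
  x <- rnorm(2000)
  y2 <- rbinom(2000, 1, 0.4)
  mi <- mutual_information(x, y2)
  null_mi <- replicate(100, mutual_information(x, sample(y2)))
  expect_lte(mi, quantile(null_mi, 0.99))
})
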