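#' Model evaluation: ROC/AUC, agreement, collinearity, mutual information
#'
#' Discrimination is measured by the area under the ROC curve, computed as
#' the normalized Mann-Whitney statistic (ties count one half) with DeLong
#' variance, and graded on the conventional academic scale. AUCs of two
#' models are compared by DeLong's covariance-based z-test (paired on shared
#' cases) or an independent-variance z-test (disjoint cohorts). Agreement of
#' repeated measurements uses ICC(A,1) for continuous and Cohen's kappa for
#' categorical variables, graded on the same published bands. Collinearity
#' diagnostics follow the Belsley-Kuh-Welsch condition-index /
#' variance-decomposition approach plus per-predictor VIFs.
#'
#' @name evaluation
NULL

# AUC + DeLong structural components via midranks
.auc_components <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  if (length(scores) != length(labels) || any(!labels %in% c(0, 1))) {
    stop("roc: labels must be 0/1 and aligned with scores", call. = FALSE)
  }
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) {
    stop("roc: both outcome classes must be present", call. = FALSE)
  }
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  V10 <- (r_all[seq_len(m)] - r_pos) / n
  V01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  v10 <- if (m > 1) stats::var(V10) else 0
  v01 <- if (n > 1) stats::var(V01) else 0
  list(auc = auc, V10 = V10, V01 = V01, m = m, n = n,
       variance = v10 / m + v01 / n)
}

#' ROC curve and AUC
#'
#' The curve is the empirical ROC over the distinct score thresholds; AUC is
#' computed as the normalized Mann-Whitney U (concordant pairs plus half the
#' tied pairs), which equals the trapezoidal area under the empirical curve.
#' The AUC variance is DeLong's estimate.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary 0/1 outcomes.
#' @return An object of class `roc_result` with `thresholds`, `sensitivity`,
#'   `fpr` (1 - specificity), `auc`, `auc_variance`, `grade`.
#' @export
roc_auc <- function(scores, labels) {
  comp <- .auc_components(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  sens <- c(0, vapply(thr, function(t) mean(pos >= t), numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(neg >= t), numeric(1)))
  structure(
    list(thresholds = c(Inf, thr), sensitivity = sens, fpr = fpr,
         auc = comp$auc, auc_variance = comp$variance,
         grade = grade_auc(comp$auc),
         n_positive = comp$m, n_negative = comp$n),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (SE %.3f), grade \"%s\"; %d positives / %d negatives\n",
              x$auc, sqrt(x$auc_variance), x$grade, x$n_positive,
              x$n_negative))
  invisible(x)
}

#' Qualitative grade of an AUC
#'
#' Conventional academic bands, lower edge inclusive: 0.9-1 excellent,
#' 0.8-0.9 good, 0.7-0.8 fair, 0.6-0.7 poor, 0.5-0.6 fail. Values below 0.5
#' (worse than chance) are also graded "fail".
#'
#' @param auc AUC in \[0, 1\].
#' @return One of "excellent", "good", "fair", "poor", "fail".
#' @export
grade_auc <- function(auc) {
  if (any(!is.finite(auc)) || any(auc < 0) || any(auc > 1)) {
    stop("grade_auc: auc must be in [0, 1]", call. = FALSE)
  }
  cut_one <- function(a) {
    if (a >= 0.9) "excellent" else if (a >= 0.8) "good" else
      if (a >= 0.7) "fair" else if (a >= 0.6) "poor" else "fail"
  }
  vapply(auc, cut_one, character(1))
}

#' Compare two AUCs
#'
#' Paired: DeLong's test using the joint covariance of the two AUCs on the
#' shared cases (labels must be identical and rows aligned). Unpaired (e.g.
#' training vs validation cohorts): z-test with the sum of the independent
#' DeLong variances. The null is a true AUC difference of zero.
#'
#' @param scores_a,labels_a First model's scores and outcomes.
#' @param scores_b,labels_b Second model's scores and outcomes.
#' @param paired Logical; `TRUE` when both models score the same cases.
#' @return List with `auc_a`, `auc_b`, `z`, `p`, `method`.
#' @export
compare_auc <- function(scores_a, labels_a, scores_b, labels_b,
                        paired = FALSE) {
  ca <- .auc_components(scores_a, labels_a)
  cb <- .auc_components(scores_b, labels_b)
  if (paired) {
    if (length(labels_a) != length(labels_b) ||
        any(labels_a != labels_b)) {
      stop("compare_auc: paired comparison needs identical, aligned labels",
           call. = FALSE)
    }
    cov10 <- if (ca$m > 1) stats::cov(ca$V10, cb$V10) else 0
    cov01 <- if (ca$n > 1) stats::cov(ca$V01, cb$V01) else 0
    v <- ca$variance + cb$variance - 2 * (cov10 / ca$m + cov01 / ca$n)
    method <- "DeLong paired"
  } else {
    v <- ca$variance + cb$variance
    method <- "DeLong unpaired (independent variances)"
  }
  d <- ca$auc - cb$auc
  if (v <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), method = method)
}

#' Grade an agreement statistic on the published bands
#'
#' Lower edge inclusive: >= 0.8 excellent, 0.60-0.79 good, 0.40-0.59
#' moderate, 0.20-0.39 poor, < 0.20 very poor.
#'
#' @param value ICC or kappa value (<= 1).
#' @return Character grade.
#' @export
grade_agreement <- function(value) {
  if (any(!is.finite(value)) || any(value > 1)) {
    stop("grade_agreement: value must be finite and <= 1", call. = FALSE)
  }
  cut_one <- function(v) {
    if (v >= 0.8) "excellent" else if (v >= 0.6) "good" else
      if (v >= 0.4) "moderate" else if (v >= 0.2) "poor" else "very poor"
  }
  vapply(value, cut_one, character(1))
}

#' Intra-class correlation for repeated continuous measurements
#'
#' ICC(A,1): two-way mixed effects, absolute agreement, single measure —
#' the form matching one observer measuring the same subjects twice.
#'
#' @param ratings Numeric matrix, n subjects x 2 repeated measurements.
#' @return An `agreement_result` list: `statistic_type` ("ICC"), `value`,
#'   `grade`.
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L || k != 2L) {
    stop("icc: need >= 3 subjects and exactly 2 measurement columns",
         call. = FALSE)
  }
  if (any(!is.finite(ratings))) stop("icc: ratings must be finite",
                                     call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (ss_rows <= 0 || denom <= 0) {
    stop("icc: zero between-subject variance; ICC undefined", call. = FALSE)
  }
  value <- (msr - mse) / denom
  structure(list(statistic_type = "ICC", value = value,
                 grade = grade_agreement(value)),
            class = "agreement_result")
}

#' Cohen's kappa for repeated categorical ratings
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` over the shared category
#' space.
#'
#' @param r1,r2 Equal-length vectors of categorical ratings.
#' @return An `agreement_result` list: `statistic_type` ("kappa"), `value`,
#'   `grade`.
#' @export
cohen_kappa <- function(r1, r2) {
  if (length(r1) != length(r2) || length(r1) == 0L) {
    stop("cohen_kappa: ratings must be non-empty and equal length",
         call. = FALSE)
  }
  cats <- sort(unique(c(r1, r2)))
  f1 <- factor(r1, levels = cats)
  f2 <- factor(r2, levels = cats)
  tab <- table(f1, f2) / length(r1)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (p_e >= 1) {
    stop("cohen_kappa: chance agreement is 1 (both raters constant); ",
         "kappa undefined", call. = FALSE)
  }
  value <- (p_o - p_e) / (1 - p_e)
  structure(list(statistic_type = "kappa", value = value,
                 grade = grade_agreement(value)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (%s)\n", x$statistic_type, x$value, x$grade))
  invisible(x)
}

#' Collinearity diagnostics for a design matrix
#'
#' Belsley-Kuh-Welsch diagnostics: columns (plus an intercept) are scaled to
#' unit length, the condition indices are the ratio of the largest singular
#' value to each singular value, and the variance-decomposition proportions
#' attribute each coefficient's variance across the singular values (each
#' predictor's proportions sum to 1). Per-predictor variance inflation
#' factors are `1 / (1 - R^2)` from regressing the column on the others.
#' Condition-index bands: < 30 weak, 30-100 moderate to strong, > 100
#' severe.
#'
#' @param X Numeric predictor matrix (no intercept column; one is added).
#' @return A `collinearity_report` list with `condition_indices`,
#'   `variance_decomposition` (rows = condition indices, columns =
#'   coefficients), `vif`, `flags`, `max_condition_index`.
#' @export
collinearity_diagnostics <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) stop("collinearity_diagnostics: need n > columns + 1",
                        call. = FALSE)
  Xi <- cbind(`(Intercept)` = 1, X)
  Xs <- sweep(Xi, 2, sqrt(colSums(Xi^2)), "/")
  sv <- svd(Xs)
  d <- sv$d
  d_safe <- pmax(d, max(d) * 1e-300)
  cond_idx <- max(d) / d_safe
  # variance decomposition: phi[j,k] = v[j,k]^2 / d[k]^2
  phi <- sweep(sv$v^2, 2, d_safe^2, "/")
  vdp <- t(sweep(phi, 1, rowSums(phi), "/"))   # rows: sv index; cols: coef
  colnames(vdp) <- colnames(Xi)
  vif <- vapply(seq_len(p), function(j) {
    yj <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    fit <- .ls_fit(others, yj)
    sst <- sum((yj - mean(yj))^2)
    if (sst <= 0) return(1)
    r2 <- 1 - fit$rss / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  flag_one <- function(ci) {
    if (ci > 100) "severe" else if (ci >= 30) "moderate to strong"
    else "weak"
  }
  structure(
    list(condition_indices = cond_idx,
         variance_decomposition = vdp,
         vif = vif,
         flags = vapply(cond_idx, flag_one, character(1)),
         max_condition_index = max(cond_idx)),
    class = "collinearity_report"
  )
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Collinearity diagnostics\n")
  cat("  condition indices:",
      paste(sprintf("%.1f", x$condition_indices), collapse = ", "), "\n")
  cat("  worst:", sprintf("%.1f", x$max_condition_index),
      paste0("(", x$flags[which.max(x$condition_indices)], ")"), "\n")
  cat("  VIF:\n")
  print(round(x$vif, 2))
  invisible(x)
}

#' Plug-in mutual information between a feature and a binary outcome
#'
#' Continuous features (more than five distinct values) are discretized to
#' quintile bins first; the plug-in estimator is applied to the empirical
#' joint distribution, in bits (log base 2). A constant feature carries no
#' information and returns 0.
#'
#' @param feature Numeric or categorical feature vector.
#' @param outcome Binary 0/1 outcome vector.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(feature, outcome) {
  if (length(feature) == 0L || length(feature) != length(outcome)) {
    stop("mutual_information: non-empty, aligned vectors required",
         call. = FALSE)
  }
  if (any(!outcome %in% c(0, 1))) {
    stop("mutual_information: outcome must be 0/1", call. = FALSE)
  }
  if (length(unique(feature)) < 2L) return(0)
  if (is.numeric(feature) && length(unique(feature)) > 5L) {
    brk <- unique(stats::quantile(feature, probs = seq(0, 1, 0.2)))
    feature <- cut(feature, breaks = brk, include.lowest = TRUE)
  }
  tab <- table(feature, outcome)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log2(p / outer(px, py))
  sum(terms[p > 0])
}
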