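#' Logistic regression with two-way interactions and backward elimination
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares (IRLS), a full two-way interaction expansion, and a
#' backward stepwise procedure that removes a term only when the
#' likelihood-ratio test for its removal is non-significant (p >= 0.1 by
#' default), respecting the model hierarchy (a main effect cannot leave
#' while an interaction containing it stays). The fixed published scoring
#' equation (12 coefficients, intercept 12.070) is exposed as
#' [published_score()].
#'
#' @name lr_model
NULL

.IRLS_MAX_ITER <- 100L
.IRLS_REL_TOL <- 1e-8
.SEPARATION_BETA <- 15

# expand a main-effect matrix with all pairwise product columns "a:b"
#' All two-way products of a main-effect matrix
#'
#' Appends a column `a:b` (elementwise product) for every unordered pair of
#' distinct columns, preserving the original columns first.
#'
#' @param X Numeric matrix with column names (main effects only).
#' @return Expanded numeric matrix.
#' @export
expand_interactions <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("expand_interactions: X needs column names",
                                 call. = FALSE)
  p <- ncol(X)
  if (p < 2L) return(X)
  extra <- list()
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      extra[[paste(colnames(X)[i], colnames(X)[j], sep = ":")]] <-
        X[, i] * X[, j]
    }
  }
  cbind(X, do.call(cbind, extra))
}

# term descriptor list: name -> character vector of component variables
.terms_from_colnames <- function(nms) {
  out <- lapply(strsplit(nms, ":", fixed = TRUE), identity)
  names(out) <- nms
  out
}

#' Fit a logistic regression by IRLS
#'
#' Plain maximum-likelihood logistic regression. Convergence is declared
#' when the relative change in log-likelihood falls below 1e-8 (at most 100
#' iterations). Wald standard errors, t-statistics and p-values are reported
#' per term. Errors are raised for a single-class outcome, for a
#' rank-deficient design (naming the collinear columns) and for complete or
#' quasi-complete separation (any |beta| above 15 at convergence).
#'
#' @param X Numeric predictor matrix with column names; the intercept is
#'   added internally. Interaction columns may be present (names `a:b`).
#' @param y Binary 0/1 outcome vector.
#' @return An object of class `logistic_fit` with fields `terms`,
#'   `coefficients`, `standard_errors`, `t_statistics`, `p_values`,
#'   `log_likelihood`, `n_observations`, plus the training `X`/`y` kept for
#'   stepwise refits and prediction.
#' @export
fit_logistic <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  n <- nrow(X)
  if (length(y) != n) stop("fit_logistic: X and y lengths differ",
                           call. = FALSE)
  if (any(!y %in% c(0, 1))) stop("fit_logistic: y must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("fit_logistic: outcome has a single class", call. = FALSE)
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  if (n <= p) stop("fit_logistic: need n > number of terms", call. = FALSE)
  qrX <- qr(Xi)
  if (qrX$rank < p) {
    bad <- colnames(Xi)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("fit_logistic: rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- rep(0, p)
  eta <- drop(Xi %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  for (it in seq_len(.IRLS_MAX_ITER)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- qr(Xi * sw)
    beta_new <- qr.coef(fit, z * sw)
    eta_new <- drop(Xi %*% beta_new)
    ll_new <- sum(y * eta_new - log1p(exp(eta_new)))
    # step-halve if the likelihood would decrease (rare, heavy separation)
    step <- 1
    while (ll_new < ll && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      eta_new <- drop(Xi %*% beta_new)
      ll_new <- sum(y * eta_new - log1p(exp(eta_new)))
    }
    converged <- abs(ll_new - ll) < .IRLS_REL_TOL * (abs(ll) + .IRLS_REL_TOL)
    beta <- beta_new; eta <- eta_new; ll <- ll_new
    if (converged) break
  }
  if (any(abs(beta) > .SEPARATION_BETA)) {
    stop("fit_logistic: separation detected (diverging coefficients: ",
         paste(colnames(Xi)[abs(beta) > .SEPARATION_BETA], collapse = ", "),
         ")", call. = FALSE)
  }
  if (all(abs(y - stats::plogis(eta)) < 1e-6)) {
    stop("fit_logistic: separation detected (fitted probabilities ",
         "saturated at the labels)", call. = FALSE)
  }
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(Xi * sqrt(w))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e)
    stop("fit_logistic: information matrix not invertible", call. = FALSE))
  se <- sqrt(diag(cov))
  tstat <- beta / se
  pval <- 2 * stats::pnorm(-abs(tstat))
  names(beta) <- names(se) <- names(tstat) <- names(pval) <- colnames(Xi)
  structure(
    list(terms = .terms_from_colnames(colnames(X)),
         coefficients = beta, standard_errors = se,
         t_statistics = tstat, p_values = pval,
         log_likelihood = ll, n_observations = n,
         vcov = cov, X = X, y = y),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression fit (", x$n_observations, " obs, logLik ",
      sprintf("%.3f", x$log_likelihood), ")\n", sep = "")
  tab <- data.frame(Estimate = sprintf("%.3f", x$coefficients),
                    SE = sprintf("%.3f", x$standard_errors),
                    t = sprintf("%.3f", x$t_statistics),
                    p = sprintf("%.3f", x$p_values))
  rownames(tab) <- names(x$coefficients)
  print(tab)
  invisible(x)
}

#' Predict from a logistic fit
#'
#' Interaction columns named in the fit are rebuilt as products of the base
#' columns of `newdata`, so validation data only needs the main-effect
#' columns.
#'
#' @param object A `logistic_fit`.
#' @param newdata Data.frame or matrix with the base predictor columns;
#'   omitted for training-data predictions.
#' @param type `"link"` (log-odds) or `"response"` (probability).
#' @param ... Ignored.
#' @return Numeric vector of scores.
#' @export
predict.logistic_fit <- function(object, newdata = NULL,
                                 type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    M <- object$X
  } else if (length(object$terms) == 0L) {
    M <- matrix(numeric(0), nrow = nrow(as.data.frame(newdata)), ncol = 0)
  } else {
    newdata <- as.data.frame(newdata)
    cols <- lapply(object$terms, function(vars) {
      miss <- setdiff(vars, names(newdata))
      if (length(miss)) {
        stop("predict: missing feature(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      Reduce(`*`, lapply(vars, function(v) as.numeric(newdata[[v]])))
    })
    M <- do.call(cbind, cols)
    colnames(M) <- names(object$terms)
  }
  eta <- drop(cbind(1, M) %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

# refit on a subset of term names, preserving term definitions
.refit_terms <- function(fit, keep) {
  fit_logistic(fit$X[, keep, drop = FALSE], fit$y)
}

#' Backward stepwise elimination by likelihood-ratio tests
#'
#' Starting from a fit containing main effects and (typically) all pairwise
#' products among them, repeatedly removes the single eligible term whose
#' removal LRT has the largest p-value, as long as that p-value is at least
#' `removal_p`. A main effect is eligible only when no retained product term
#' contains it (hierarchy). Ties are broken by largest p, then by
#' lexicographic term name. A reduced fit that fails (e.g. separation)
#' renders that term non-removable at that step.
#'
#' @param fit A [fit_logistic()] result.
#' @param removal_p Removal threshold (default 0.1): a term leaves only if
#'   its removal does not significantly worsen the model at this level.
#' @return The final `logistic_fit`, with attribute `"eliminated"` listing
#'   removed term names in order.
#' @export
backward_eliminate <- function(fit, removal_p = 0.1) {
  stopifnot(inherits(fit, "logistic_fit"))
  eliminated <- character(0)
  repeat {
    term_names <- names(fit$terms)
    if (length(term_names) == 0L) break
    in_products <- unique(unlist(fit$terms[lengths(fit$terms) > 1L]))
    eligible <- vapply(term_names, function(nm) {
      vars <- fit$terms[[nm]]
      length(vars) > 1L || !(nm %in% in_products)
    }, logical(1))
    cand <- sort(term_names[eligible])  # lexicographic for deterministic ties
    if (length(cand) == 0L) break
    pvals <- vapply(cand, function(nm) {
      keep <- setdiff(term_names, nm)
      red <- tryCatch(
        if (length(keep)) .refit_terms(fit, keep) else {
          # intercept-only log-likelihood in closed form
          n1 <- sum(fit$y); n <- length(fit$y)
          ll0 <- n1 * log(n1 / n) + (n - n1) * log(1 - n1 / n)
          list(log_likelihood = ll0)
        },
        error = function(e) NULL)
      if (is.null(red)) return(-Inf)  # cannot remove this term now
      stat <- 2 * (fit$log_likelihood - red$log_likelihood)
      stats::pchisq(max(stat, 0), df = 1L, lower.tail = FALSE)
    }, numeric(1))
    best <- which.max(pvals)  # first of ties in lexicographic order
    removable <- is.finite(pvals[best]) &&
      (removal_p >= 1 || pvals[best] >= removal_p)
    if (!removable) break
    drop_nm <- cand[best]
    eliminated <- c(eliminated, drop_nm)
    keep <- setdiff(term_names, drop_nm)
    if (length(keep) == 0L) {
      # intercept-only endpoint: represent as a fit with zero predictor terms
      n1 <- sum(fit$y); n <- length(fit$y)
      b0 <- stats::qlogis(n1 / n)
      ll0 <- n1 * log(n1 / n) + (n - n1) * log(1 - n1 / n)
      fit <- structure(
        list(terms = stats::setNames(list(), character(0)),
             coefficients = c(`(Intercept)` = b0),
             standard_errors = c(`(Intercept)` = sqrt(1 / (n1 * (1 - n1 / n)))),
             t_statistics = NA_real_, p_values = NA_real_,
             log_likelihood = ll0, n_observations = n,
             X = fit$X[, 0, drop = FALSE], y = fit$y),
        class = "logistic_fit")
      break
    }
    fit <- .refit_terms(fit, keep)
  }
  attr(fit, "eliminated") <- eliminated
  fit
}

# ---- published fixed scoring equation ------------------------------------

.table7_env <- new.env(parent = emptyenv())

#' The published fixed logistic scoring coefficients
#'
#' Twelve coefficients (intercept plus five main effects plus six two-way
#' products) loaded from the versioned constants file shipped with the
#' package. `Number_Day3` in the equation is the transformed count
#' `|n_d3 - 8.4|`, and `Fragmentation_Day2` is the volume-loss fraction.
#'
#' @return Data.frame with columns `term`, `estimate`, `se`, `t`, `p`.
#' @export
published_coefficients <- function() {
  if (is.null(.table7_env$tab)) {
    path <- system.file("extdata", "table7_coefficients.csv",
                        package = "embryoselect")
    if (!nzchar(path)) stop("constants file table7_coefficients.csv not found",
                            call. = FALSE)
    .table7_env$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .table7_env$tab
}

# term -> value mapping for the published equation, given scaled features
.published_terms <- function(n_d2, tcv_d2_scaled, frag_d2, age_male,
                             n_d3_dev, cod_d2, cod_d3, parity_d2) {
  list(
    "(Intercept)" = rep(1, length(n_d2)),
    "Number_Day2" = n_d2,
    "TCV_Day2" = tcv_d2_scaled,
    "Fragmentation_Day2" = frag_d2,
    "Age_male" = age_male,
    "Number_Day3" = n_d3_dev,
    "Number_Day2:COD_Day3" = n_d2 * cod_d3,
    "TCV_Day2*Age_male" = tcv_d2_scaled * age_male,
    "COD_Day2:Age_male" = cod_d2 * age_male,
    "Fragmentation_Day2*Age_male" = frag_d2 * age_male,
    "COD_Day2:Number_Day3" = cod_d2 * n_d3_dev,
    "Parity_Day2:Number_Day3" = parity_d2 * n_d3_dev
  )
}

#' Score embryos with the published fixed equation
#'
#' Evaluates the published 12-coefficient logistic scoring equation. TCV is
#' multiplied by `tcv_scale` before entering the linear predictor (the
#' original model's TCV units are not stated; default 1e-5, i.e. TCV in
#' units of 1e5 um^3, which puts the TCV term on the same order as the
#' other terms).
#'
#' @param f A `cass_features` object, or a data.frame with columns `n_d2`,
#'   `tcv_d2`, `frag_d2`, `n_d3_dev`, `cod_d2`, `cod_d3`, `parity_d2` (and
#'   `male_age` unless supplied separately).
#' @param male_age Paternal age in years; taken from `f$male_age` if absent.
#' @param tcv_scale Scale factor applied to TCV (um^3) before scoring.
#' @param type `"link"` for the log-odds score, `"response"` for the
#'   implantation probability.
#' @return Numeric score(s).
#' @export
published_score <- function(f, male_age = NULL, tcv_scale = 1e-5,
                            type = c("link", "response")) {
  type <- match.arg(type)
  if (inherits(f, "cass_features")) {
    f <- as.data.frame(unclass(f)[c("n_d2", "tcv_d2", "frag_d2", "n_d3_dev",
                                    "cod_d2", "cod_d3", "parity_d2")])
  }
  f <- as.data.frame(f)
  need <- c("n_d2", "tcv_d2", "frag_d2", "n_d3_dev", "cod_d2", "cod_d3",
            "parity_d2")
  if (is.null(male_age)) need <- c(need, "male_age")
  miss <- setdiff(need, names(f))
  if (length(miss)) {
    stop("published_score: missing feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(male_age)) male_age <- f$male_age
  coefs <- published_coefficients()
  terms <- .published_terms(f$n_d2, f$tcv_d2 * tcv_scale, f$frag_d2,
                            male_age, f$n_d3_dev, f$cod_d2, f$cod_d3,
                            f$parity_d2)
  stopifnot(identical(sort(names(terms)), sort(coefs$term)))
  lp <- Reduce(`+`, Map(function(nm, val)
    coefs$estimate[coefs$term == nm] * val, names(terms), terms))
  if (type == "link") lp else stats::plogis(lp)
}
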