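#' Multivariate adaptive regression splines (MARS)
#'
#' From-scratch MARS: the forward pass greedily adds reflected pairs of
#' hinge functions `max(0, x - k)` / `max(0, k - x)` (knots restricted to
#' observed data values), products of hinges give interactions up to a
#' configurable degree (default 2), and the backward pass prunes basis
#' functions by the generalized cross-validation (GCV) criterion with a
#' per-knot penalty (default 3). A binary outcome is fitted by least squares
#' on the 0/1 label; the resulting score is used for ranking and ROC
#' analysis, so no link function is required. 10-fold cross-validation
#' estimates prediction error and the final model is refit on all data.
#'
#' @name mars_model
NULL

#' Maximum number of basis functions for the forward pass
#'
#' `min(200, max(20, 2 d)) + 1` where `d` is the number of input variables
#' (the +1 is the intercept).
#'
#' @param d Number of input variables, >= 1.
#' @return Integer basis cap.
#' @export
max_basis_count <- function(d) {
  if (length(d) != 1L || !is.finite(d) || d < 1) {
    stop("max_basis_count: d must be >= 1", call. = FALSE)
  }
  min(200, max(20, 2 * floor(d))) + 1
}

#' Generalized cross-validation score
#'
#' `(rss/n) / (1 - C/n)^2` with effective parameter count
#' `C = n_basis + penalty * n_knots`.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param n_basis Number of basis functions (incl. intercept).
#' @param n_knots Number of knots charged to the model.
#' @param penalty GCV penalty per knot (default 3).
#' @return GCV score (>= 0).
#' @export
gcv_score <- function(rss, n, n_basis, n_knots, penalty = 3) {
  C <- n_basis + penalty * n_knots
  if (C >= n) {
    stop("gcv_score: effective parameters (", C, ") >= observations (", n,
         "): model too complex for sample", call. = FALSE)
  }
  (rss / n) / (1 - C / n)^2
}

# knots charged to a pruned model: one knot per reflected pair of terms
.model_knots <- function(n_basis) (n_basis - 1) / 2

# one hinge factor
.hinge_factor <- function(var, sign, knot) list(var = var, sign = sign,
                                                knot = knot)

# evaluate a single basis function (list of factors; empty = intercept)
.basis_eval <- function(factors, X) {
  n <- nrow(X)
  out <- rep(1, n)
  for (f in factors) {
    if (!f$var %in% colnames(X)) {
      stop("mars: missing variable `", f$var, "` in data", call. = FALSE)
    }
    out <- out * pmax(0, f$sign * (as.numeric(X[, f$var]) - f$knot))
  }
  out
}

.basis_matrix <- function(basis, dat) {
  vapply(basis, function(f) .basis_eval(f, dat), numeric(nrow(dat)))
}

.basis_label <- function(factors) {
  if (length(factors) == 0L) return("(Intercept)")
  paste(vapply(factors, function(f) {
    if (f$sign > 0) sprintf("h(%s-%g)", f$var, f$knot)
    else sprintf("h(%g-%s)", f$knot, f$var)
  }, character(1)), collapse = "*")
}

# least-squares fit of y on B; returns list(coef, rss)
.ls_fit <- function(B, y) {
  qrB <- qr(B)
  cf <- qr.coef(qrB, y)
  cf[is.na(cf)] <- 0
  res <- y - drop(B %*% cf)
  list(coef = cf, rss = sum(res^2))
}

#' MARS forward pass
#'
#' Greedy addition of reflected hinge pairs. At each step every (parent
#' basis, variable, knot) triple is scored by the training RSS of the model
#' extended with the pair; the best triple is added (ties: lowest variable
#' name, then smallest knot). Knot candidates are observed values of the
#' variable on the support of the parent basis, thinned to at most
#' `max_knot_candidates` evenly spaced order statistics. The pass stops at
#' `max_basis` functions or when the RSS improvement drops below
#' `1e-8 * var(y)`.
#'
#' @param X Numeric matrix or data.frame of predictors (column names
#'   required).
#' @param y Numeric response (0/1 labels allowed).
#' @param max_basis Basis cap incl. intercept; default [max_basis_count()]
#'   of `ncol(X)`.
#' @param max_degree Maximum interaction degree (default 2).
#' @param max_knot_candidates Cap on knot candidates per (parent, variable)
#'   pair (default 128).
#' @param minspan,endspan Minimum observation span between knot candidates
#'   and number of observations excluded at each end of a variable's range;
#'   `NULL` (default) uses the standard automatic values (alpha = 0.05
#'   runs-of-noise guard), 1/0 considers every observed value.
#' @param .min_n Minimum observations (internal; cross-validation relaxes
#'   the default of 10 for small held-in folds).
#' @return An unpruned object of class `mars_model`.
#' @export
mars_forward <- function(X, y, max_basis = NULL, max_degree = 2,
                         max_knot_candidates = 128, minspan = NULL,
                         endspan = NULL, .min_n = 10L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < .min_n) stop("mars_forward: need at least ", .min_n,
                       " observations", call. = FALSE)
  if (length(y) != n) stop("mars_forward: X and y lengths differ",
                           call. = FALSE)
  if (is.null(max_basis)) max_basis <- max_basis_count(ncol(X))
  nvars <- ncol(X)
  if (is.null(endspan)) {
    endspan <- max(1L, ceiling(3 - log2(0.05 / nvars)))
  }
  vary <- stats::var(y)
  basis <- list(list())            # intercept
  B <- matrix(1, n, 1)
  if (vary == 0) {
    return(.finalize_mars(basis, B, X, y, penalty = 3))
  }
  tol <- 1e-8 * vary
  vars_sorted <- sort(colnames(X))
  repeat {
    if (length(basis) + 2L > max_basis) break
    qrB <- qr(B)
    Q <- qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
    rss_cur <- sum((y - Q %*% crossprod(Q, y))^2)
    best <- NULL
    for (v in vars_sorted) {
      x <- X[, v]
      for (pi in seq_along(basis)) {
        parent <- basis[[pi]]
        if (length(parent) >= max_degree) next
        if (v %in% vapply(parent, `[[`, character(1), "var")) next
        b <- B[, pi]
        supp <- b != 0
        if (!any(supp)) next
        xs <- sort(x[supp])
        m_obs <- length(xs)
        # runs-of-noise guards (Friedman's minspan/endspan at alpha 0.05)
        ms <- if (is.null(minspan)) {
          max(1L, floor(-log2(-log(0.95) / (nvars * m_obs)) / 2.5))
        } else max(1L, minspan)
        pos <- if (endspan + 1L <= m_obs - endspan) {
          seq.int(endspan + 1L, m_obs - endspan, by = ms)
        } else ceiling(m_obs / 2)
        kx <- unique(xs[pos])
        if (m_obs < 2L) next
        if (length(kx) > max_knot_candidates) {
          kx <- kx[unique(round(seq(1, length(kx),
                                    length.out = max_knot_candidates)))]
        }
        # span{B, c1, c2} = span{B, b*x, c1}: orthonormalize w = b*x first
        w <- b * x
        w_perp <- w - Q %*% crossprod(Q, w)
        wn <- sqrt(sum(w_perp^2))
        if (wn > 1e-10 * sqrt(sum(w^2)) && wn > 0) {
          Q2 <- cbind(Q, w_perp / wn)
        } else {
          Q2 <- Q
        }
        r <- y - Q2 %*% crossprod(Q2, y)
        rss0 <- sum(r^2)
        # all candidate right hinges at once: C[, j] = b * max(0, x - k_j)
        C <- b * pmax(outer(x, kx, `-`), 0)  # pmax(M, 0) keeps dim(M)
        Cp <- C - Q2 %*% crossprod(Q2, C)
        num <- drop(crossprod(Cp, r))
        den <- colSums(Cp^2)
        csc <- colSums(C^2)
        ok <- den > 1e-12 * pmax(csc, 1)
        delta <- ifelse(ok, num^2 / den, 0)
        rss_k <- rss0 - delta
        j <- which.min(rss_k)     # smallest knot wins ties (kx sorted)
        if (is.null(best) || rss_k[j] < best$rss - 1e-12) {
          best <- list(rss = rss_k[j], parent = pi, var = v, knot = kx[j])
        }
      }
    }
    if (is.null(best) || (rss_cur - best$rss) < tol) break
    parent <- basis[[best$parent]]
    b <- B[, best$parent]
    x <- X[, best$var]
    c1 <- b * pmax(0, x - best$knot)
    c2 <- b * pmax(0, best$knot - x)
    added <- FALSE
    for (sgn in c(1, -1)) {
      cc <- if (sgn > 0) c1 else c2
      if (sum(cc^2) <= 1e-12) next
      cand_basis <- c(parent, list(.hinge_factor(best$var, sgn, best$knot)))
      B <- cbind(B, cc)
      basis[[length(basis) + 1L]] <- cand_basis
      added <- TRUE
    }
    if (!added) break
  }
  .finalize_mars(basis, B, X, y, penalty = 3)
}

# build a mars_model object with LS coefficients and model-level GCV
.finalize_mars <- function(basis, B, X, y, penalty) {
  fit <- .ls_fit(B, y)
  n <- length(y)
  m <- length(basis)
  gcv <- tryCatch(gcv_score(fit$rss, n, m, .model_knots(m), penalty),
                  error = function(e) NA_real_)
  structure(
    list(basis = basis, coefficients = stats::setNames(
      fit$coef, vapply(basis, .basis_label, character(1))),
      gcv = gcv, n_basis = m, penalty = penalty, rss = fit$rss,
      n_observations = n, variables = colnames(X), X = X, y = y),
    class = "mars_model"
  )
}

#' @export
print.mars_model <- function(x, ...) {
  cat("MARS model: ", x$n_basis, " basis function(s), GCV ",
      format(x$gcv, digits = 6), " (penalty ", x$penalty, ")\n", sep = "")
  for (i in seq_along(x$basis)) {
    cat(sprintf("  %+.4g * %s\n", x$coefficients[i],
                .basis_label(x$basis[[i]])))
  }
  invisible(x)
}

#' MARS backward pruning by GCV
#'
#' Classic stepwise deletion: starting from the forward model, repeatedly
#' remove the non-intercept basis function whose removal yields the lowest
#' GCV; over the whole deletion path (including the unpruned model) the
#' subset with the global minimum GCV is returned, with coefficients refit.
#' When the forward model has at most 6 basis functions the deletion path
#' is replaced by exhaustive enumeration of all subsets (at most 32), so
#' the pruned model is the exact GCV optimum at that size.
#'
#' @param model A `mars_model` from [mars_forward()].
#' @param penalty GCV penalty per knot (default 3).
#' @return The pruned `mars_model`.
#' @export
mars_backward <- function(model, penalty = 3) {
  stopifnot(inherits(model, "mars_model"))
  B_full <- .basis_matrix(model$basis, model$X)
  y <- model$y
  n <- length(y)
  gcv_of <- function(idx) {
    fit <- .ls_fit(B_full[, idx, drop = FALSE], y)
    m <- length(idx)
    gcv_score(fit$rss, n, m, .model_knots(m), penalty)
  }
  current <- seq_along(model$basis)
  best_idx <- current
  best_gcv <- gcv_of(current)
  if (length(current) <= 6L) {
    # small model: exact subset optimum (greedy path can miss it)
    m <- length(current)
    for (mask in 0:(2^(m - 1L) - 1L)) {
      idx <- c(1L, which(bitwAnd(mask, 2^(0:(m - 2L))) > 0) + 1L)
      g <- gcv_of(idx)
      if (g < best_gcv) {
        best_gcv <- g
        best_idx <- idx
      }
    }
    return(.finalize_mars(model$basis[best_idx],
                          B_full[, best_idx, drop = FALSE],
                          model$X, y, penalty))
  }
  while (length(current) > 1L) {
    cand_gcv <- vapply(seq_along(current)[-1L], function(pos)
      gcv_of(current[-pos]), numeric(1))
    pos <- which.min(cand_gcv) + 1L
    current <- current[-pos]
    g <- cand_gcv[pos - 1L]
    if (g < best_gcv) {
      best_gcv <- g
      best_idx <- current
    }
  }
  pruned <- .finalize_mars(model$basis[best_idx],
                           B_full[, best_idx, drop = FALSE],
                           model$X, y, penalty)
  pruned
}

#' Predict from a MARS model
#'
#' @param object A `mars_model`.
#' @param newdata Matrix or data.frame holding every variable named in the
#'   basis; defaults to the training data.
#' @param ... Ignored.
#' @return Numeric score vector (for binary outcomes this is the ranking
#'   score, not a probability).
#' @export
predict.mars_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$X
  newdata <- as.matrix(newdata)
  drop(.basis_matrix(object$basis, newdata) %*% object$coefficients)
}

#' @rdname predict.mars_model
#' @param model A `mars_model`.
#' @param X New data.
#' @export
mars_predict <- function(model, X) predict(model, X)

#' Fit MARS with k-fold cross-validated error estimation
#'
#' Folds are stratified by outcome class for binary labels (falling back to
#' unstratified assignment when a class has fewer members than folds);
#' assignment is drawn from `seed` and is fully reproducible. Each fold's
#' model is a forward + backward fit on the remaining folds; the held-out
#' mean squared error is recorded. The returned model is refit on all data.
#'
#' @inheritParams mars_forward
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param penalty GCV penalty per knot (default 3).
#' @return List with `cv_error` (mean of fold MSEs), `fold_errors`, and
#'   `model` (final `mars_model` on all data).
#' @export
mars_cv <- function(X, y, folds = 10, seed = 1, max_basis = NULL,
                    max_degree = 2, penalty = 3,
                    max_knot_candidates = 128) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (folds > n) stop("mars_cv: folds > n", call. = FALSE)
  rng <- .new_rng(seed)
  assign_in <- function(idx) {
    # round-robin fold sizes over a shuffled index set
    idx[.rng_sample(rng, length(idx))]
  }
  fold_id <- integer(n)
  classes <- unique(y)
  stratified <- all(y %in% c(0, 1)) &&
    all(vapply(classes, function(cl) sum(y == cl), numeric(1)) >= folds)
  if (stratified) {
    for (cl in classes) {
      idx <- which(y == cl)
      fold_id[assign_in(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    fold_id[assign_in(seq_len(n))] <- rep_len(seq_len(folds), n)
  }
  fold_errors <- vapply(seq_len(folds), function(k) {
    tr <- fold_id != k
    fit <- mars_backward(
      mars_forward(X[tr, , drop = FALSE], y[tr], max_basis = max_basis,
                   max_degree = max_degree,
                   max_knot_candidates = max_knot_candidates, .min_n = 5L),
      penalty = penalty)
    pred <- predict(fit, X[!tr, , drop = FALSE])
    mean((y[!tr] - pred)^2)
  }, numeric(1))
  final <- mars_backward(
    mars_forward(X, y, max_basis = max_basis, max_degree = max_degree,
                 max_knot_candidates = max_knot_candidates),
    penalty = penalty)
  list(cv_error = mean(fold_errors), fold_errors = fold_errors,
       model = final, fold_id = fold_id)
}

#' Serialize a MARS model to JSON
#'
#' Writes the basis factors (variable, sign, knot) and coefficients; the
#' inverse is [mars_from_json()].
#'
#' @param model A `mars_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
mars_to_json <- function(model, path = NULL) {
  doc <- list(
    n_basis = model$n_basis, penalty = model$penalty, gcv = model$gcv,
    variables = model$variables,
    basis = lapply(seq_along(model$basis), function(i) list(
      label = .basis_label(model$basis[[i]]),
      coefficient = unname(model$coefficients[i]),
      factors = lapply(model$basis[[i]], function(f)
        list(var = f$var, sign = f$sign, knot = f$knot))))
  )
  if (is.null(path)) {
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Deserialize a MARS model written by [mars_to_json()]
#'
#' The result supports [predict.mars_model()] but carries no training data.
#'
#' @param path File path or JSON string.
#' @return A `mars_model` (prediction-only).
#' @export
mars_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  basis <- lapply(doc$basis, function(b)
    lapply(b$factors, function(f)
      .hinge_factor(f$var, f$sign, f$knot)))
  coefs <- vapply(doc$basis, function(b) as.numeric(b$coefficient),
                  numeric(1))
  structure(
    list(basis = basis,
         coefficients = stats::setNames(
           coefs, vapply(basis, .basis_label, character(1))),
         gcv = doc$gcv, n_basis = doc$n_basis, penalty = doc$penalty,
         variables = unlist(doc$variables), X = NULL, y = NULL),
    class = "mars_model"
  )
}
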