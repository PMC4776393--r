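# Shared fixtures, built in code.

# an embryo that conserves volume exactly: d_child = d_parent * n^(-1/3)
conserved_embryo <- function(id = "E1", d1 = 110, n2 = 4, n3 = 8,
                             extra_d3 = numeric(0)) {
  embryo_measurements(id, d1,
                      rep(d1 * n2^(-1 / 3), n2),
                      c(rep(d1 * n3^(-1 / 3), n3), extra_d3))
}

# a quick profile with only the modeled covariates mattering
quick_profile <- function(female_age = 30, male_age = 33) {
  clinical_profile(female_age = female_age, male_age = male_age,
                   female_pathology = 0, male_pathology = 0,
                   ovulation_disorder = 0, implantation_problem = 0,
                   endometriosis_stage = 0, infertility_type = 0,
                   infertility_duration = 2)
}

# design matrix + outcome from a known logistic model, plain R RNG
logistic_data <- function(n, beta, seed) {
  withr::with_seed(seed, {
    p <- length(beta) - 1L
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    eta <- beta[1] + drop(X %*% beta[-1])
    list(X = X, y = rbinom(n, 1, plogis(eta)))
  })
}

# brute-force AUC over all positive-negative pairs (independent oracle)
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# exhaustive GCV subset search over non-intercept bases (oracle for pruning)
gcv_exhaustive <- function(model, penalty = 3) {
  B <- embryoselect:::.basis_matrix(model$basis, model$X)
  y <- model$y
  n <- length(y)
  m <- ncol(B)
  best <- Inf
  for (mask in 0:(2^(m - 1) - 1)) {
    idx <- c(1L, which(bitwAnd(mask, 2^(0:(m - 2))) > 0) + 1L)
    fit <- embryoselect:::.ls_fit(B[, idx, drop = FALSE], y)
    g <- gcv_score(fit$rss, n, length(idx), (length(idx) - 1) / 2, penalty)
    if (g < best) best <- g
  }
  best
}
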