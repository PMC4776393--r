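#' Synthetic embryo cohorts with volume-conserving geometry
#'
#' Generates cohorts whose geometry matches the assumptions the morphometric
#' pipeline relies on: a Day-1 zygote volume is partitioned among Day-2 and
#' Day-3 blastomeres (with configurable size asymmetry), a drawn
#' fragmentation fraction of the volume is shed as explicit small fragment
#' objects below the day's blastomere size threshold, volumes are converted
#' back to diameters and measurement noise is added. Visual (SSS) grades are
#' derived deterministically from the realized geometry, optionally
#' corrupted by a mis-grading rate emulating observer variability. Outcomes
#' are drawn from a known logistic model — by default the published fixed
#' scoring equation — so every pipeline stage can be validated against
#' ground truth.
#'
#' @name synthetic_cohort
NULL

# polynomial rolling hash of a deparsed object, for provenance metadata
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Build a simulation configuration
#'
#' Defaults describe a plausible single-embryo-transfer cohort: zygote
#' diameter ~ N(115, 5) um, Day-2 / Day-3 target counts 4 and 8 with
#' dispersion, mean fragmentation 8\% by Day 2 plus ~5\% further loss by
#' Day 3 (Beta-distributed), log-normal blastomere size asymmetry tuned so
#' Day-3 8-cell embryos have COD near 1.26, 1 um diameter measurement
#' noise, maternal age < 36 (study inclusion), and outcomes drawn from the
#' published scoring equation, which yields a clinical pregnancy prevalence
#' near one third.
#'
#' @param n_patients Number of patients.
#' @param embryos_per_patient Probability vector over 1, 2, 3, ... embryos
#'   (default `1`: always one embryo).
#' @param day1_mean,day1_sd Zygote diameter distribution, um.
#' @param n_d2_target,n_d2_sd,n_d3_target,n_d3_sd Blastomere count targets
#'   and dispersion per day (counts are rounded normal draws, clamped to
#'   2-8 on Day 2 and 4-13 on Day 3).
#' @param frag_mean_d2 Mean Day-2 fragmentation fraction.
#' @param frag_extra_d3 Mean additional fractional loss between Day 2 and 3.
#' @param frag_conc Beta concentration of the fragmentation draws.
#' @param asymmetry Log-normal sigma of blastomere volume weights
#'   (0 = perfectly even split).
#' @param noise_sd Measurement noise on drawn diameters, um.
#' @param misgrade_rate Probability that a visual grade item is off by one
#'   level (default 0.10).
#' @param female_age_mean,female_age_sd Maternal age distribution, years
#'   (truncated to (18, 36)).
#' @param outcome_model `"published_table7"`, a named coefficient vector
#'   over CASS feature columns (must include `"(Intercept)"`) defining a
#'   linear logistic truth, or a function `(cass_features, male_age) ->
#'   log-odds` for nonlinear truths.
#' @param tcv_scale TCV scale factor used when scoring with the published
#'   equation.
#' @param seed Integer master seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 200,
                              embryos_per_patient = 1,
                              day1_mean = 115, day1_sd = 5,
                              n_d2_target = 4, n_d2_sd = 0.8,
                              n_d3_target = 8, n_d3_sd = 1.2,
                              frag_mean_d2 = 0.08, frag_extra_d3 = 0.05,
                              frag_conc = 20,
                              asymmetry = 0.25,
                              noise_sd = 1,
                              misgrade_rate = 0.10,
                              female_age_mean = 31, female_age_sd = 3,
                              outcome_model = "published_table7",
                              tcv_scale = 1e-5,
                              seed = 1) {
  if (n_patients < 1) stop("simulation_config: n_patients < 1", call. = FALSE)
  stopifnot(day1_mean > 0, day1_sd >= 0, frag_conc > 0, asymmetry >= 0,
            noise_sd >= 0, misgrade_rate >= 0, misgrade_rate <= 1)
  if (frag_mean_d2 < 0 || frag_mean_d2 >= 1 ||
      frag_extra_d3 < 0 || frag_extra_d3 >= 1 ||
      1 - (1 - frag_mean_d2) * (1 - frag_extra_d3) >= 1) {
    stop("simulation_config: fragmentation configuration forces a fraction ",
         ">= 1", call. = FALSE)
  }
  epp <- embryos_per_patient / sum(embryos_per_patient)
  structure(
    list(n_patients = as.integer(n_patients),
         embryos_per_patient = epp,
         day1_mean = day1_mean, day1_sd = day1_sd,
         n_d2_target = n_d2_target, n_d2_sd = n_d2_sd,
         n_d3_target = n_d3_target, n_d3_sd = n_d3_sd,
         frag_mean_d2 = frag_mean_d2, frag_extra_d3 = frag_extra_d3,
         frag_conc = frag_conc, asymmetry = asymmetry,
         noise_sd = noise_sd, misgrade_rate = misgrade_rate,
         female_age_mean = female_age_mean, female_age_sd = female_age_sd,
         outcome_model = outcome_model, tcv_scale = tcv_scale,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# beta draw with given mean and concentration (uses the active RNG state)
.draw_frac <- function(mean, conc) {
  if (mean <= 0) return(0)
  stats::rbeta(1, mean * conc, (1 - mean) * conc)
}

# split a volume into n blastomere volumes with log-normal asymmetry
.split_volume <- function(volume, n, asymmetry) {
  w <- if (asymmetry > 0) exp(stats::rnorm(n, 0, asymmetry)) else rep(1, n)
  volume * w / sum(w)
}

# shed `volume` as fragment diameters strictly below `thr` um
.make_fragments <- function(volume, thr) {
  out <- numeric(0)
  vmin <- blastomere_volume(1)       # ignore dust below 1 um
  while (volume > vmin) {
    d <- stats::runif(1, 15, min(35, thr - 5))
    v <- min(blastomere_volume(d), volume)
    out <- c(out, (6 * v / pi)^(1 / 3))
    volume <- volume - v
  }
  out
}

.clamp_count <- function(x, lo, hi) max(lo, min(hi, round(x)))

#' Simulate one embryo's measurements and visual grades
#'
#' Draws the Day-1 zygote, partitions its volume into Day-2 and Day-3
#' blastomeres after removing the drawn fragmentation losses, emits explicit
#' fragment objects, adds measurement noise, and derives consistent SSS
#' grades from the realized geometry (fragmentation fraction to category
#' 0-4, COD to symmetry grade), optionally perturbed at the mis-grading
#' rate.
#'
#' @param config A [simulation_config()].
#' @param rng Internal RNG stream (from the cohort generator); `NULL` to
#'   derive one from `config$seed`.
#' @param embryo_id Identifier.
#' @return List with `measurements` ([embryo_measurements]), `grades`
#'   ([sss_grades]) and `latent` (true fragmentation fractions, counts,
#'   CODs before measurement noise).
#' @export
simulate_embryo <- function(config, rng = NULL, embryo_id = "E1") {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(rng)) rng <- .new_rng(config$seed)
  .rng_eval(rng, .simulate_embryo_state(config, embryo_id))
}

# embryo generation using the active RNG state (hot path: no seed swapping)
.simulate_embryo_state <- function(config, embryo_id) {
  d1 <- max(stats::rnorm(1, config$day1_mean, config$day1_sd),
            config$day1_mean / 2)
  v1 <- blastomere_volume(d1)
  n2 <- .clamp_count(stats::rnorm(1, config$n_d2_target, config$n_d2_sd),
                     2, 8)
  n3 <- .clamp_count(stats::rnorm(1, config$n_d3_target, config$n_d3_sd),
                     4, 13)
  frag2 <- .draw_frac(config$frag_mean_d2, config$frag_conc)
  extra <- .draw_frac(config$frag_extra_d3, config$frag_conc)
  frag3 <- 1 - (1 - frag2) * (1 - extra)
  if (frag2 >= 1 || frag3 >= 1) {
    stop("simulate_embryo: configuration forces fragmentation >= 1",
         call. = FALSE)
  }
  vols2 <- .split_volume(v1 * (1 - frag2), n2, config$asymmetry)
  vols3 <- .split_volume(v1 * (1 - frag3), n3, config$asymmetry)
  d2_blast <- (6 * vols2 / pi)^(1 / 3)
  d3_blast <- (6 * vols3 / pi)^(1 / 3)
  d2_frag <- .make_fragments(v1 * frag2, .BLASTOMERE_MIN_UM[["2"]])
  d3_frag <- .make_fragments(v1 * frag3, .BLASTOMERE_MIN_UM[["3"]])
  jitter <- function(d) pmax(d + stats::rnorm(length(d), 0, config$noise_sd),
                             1)
  # values are valid by construction: skip constructor validation (hot path)
  m <- structure(
    list(embryo_id = embryo_id, day1_diameter = jitter(d1),
         day2_diameters = jitter(c(d2_blast, d2_frag)),
         day3_diameters = jitter(c(d3_blast, d3_frag))),
    class = "embryo_measurements")
  cod2 <- max(d2_blast) / min(d2_blast)
  cod3 <- max(d3_blast) / min(d3_blast)
  misgrade <- function(x, lo, hi) {
    if (stats::runif(1) < config$misgrade_rate) {
      x <- x + sign(stats::runif(1) - 0.5)
    }
    max(lo, min(hi, x))
  }
  g <- structure(
    list(embryo_id = embryo_id,
         n_d2 = as.integer(misgrade(n2, 1, 64)),
         n_d3 = as.integer(misgrade(n3, 1, 64)),
         frag_cat_d2 = as.integer(misgrade(fragmentation_category(frag2),
                                           0, 4)),
         frag_cat_d3 = as.integer(misgrade(fragmentation_category(frag3),
                                           0, 4)),
         symmetry_d2 = as.integer(misgrade(symmetry_grade(cod2), 0, 2)),
         symmetry_d3 = as.integer(misgrade(symmetry_grade(cod3), 0, 2))),
    class = "sss_grades")
  list(measurements = m, grades = g,
       latent = list(day1_diameter = d1, n_d2 = n2, n_d3 = n3,
                     frag_d2 = frag2, frag_d3 = frag3,
                     cod_d2 = cod2, cod_d3 = cod3))
}

# draw one clinical profile using the active RNG state
.simulate_profile_state <- function(config) {
  fa <- min(max(stats::rnorm(1, config$female_age_mean,
                             config$female_age_sd), 18.5), 35.9)
  ma <- min(max(fa + stats::rnorm(1, 2.5, 3.5), 18.5), 59.5)
  draw_ind <- function(p, miss = 0) {
    if (miss > 0 && stats::runif(1) < miss) return(NA_integer_)
    stats::rbinom(1, 1, p)
  }
  # weighted stages: absence-heavy, severe rare
  endo_stage <- which(stats::runif(1) <=
                        cumsum(c(0.80, 0.08, 0.06, 0.03, 0.03)))[1L] - 1L
  clinical_profile(
    female_age = fa, male_age = ma,
    female_pathology = draw_ind(0.35),
    male_pathology = draw_ind(0.40),
    ovulation_disorder = draw_ind(0.25),
    transport_problem = draw_ind(0.15, miss = 0.30),
    implantation_problem = draw_ind(0.08),
    endometriosis_stage = endo_stage,
    infertility_type = draw_ind(0.30),
    infertility_duration = round(stats::rgamma(1, shape = 3, rate = 1), 1)
  )
}

# vectorized truth over a list of cass_features (one cohort-level call)
.true_score_vec <- function(config, cass_list, male_ages) {
  if (is.function(config$outcome_model)) {
    return(vapply(seq_along(cass_list), function(i)
      as.numeric(config$outcome_model(cass_list[[i]], male_ages[i])),
      numeric(1)))
  }
  fields <- c("n_d2", "tcv_d2", "frag_d2", "n_d3_dev", "cod_d2", "cod_d3",
              "parity_d2", "tcv_d1", "tcv_d3", "frag_d3", "n_d3")
  df <- as.data.frame(lapply(stats::setNames(fields, fields), function(fl)
    vapply(cass_list, function(cf) as.numeric(cf[[fl]]), numeric(1))))
  df$male_age <- male_ages
  if (identical(config$outcome_model, "published_table7")) {
    return(published_score(df, tcv_scale = config$tcv_scale))
  }
  coefs <- config$outcome_model
  if (is.null(names(coefs)) || !"(Intercept)" %in% names(coefs)) {
    stop("simulation_config: custom outcome model needs named coefficients ",
         "including \"(Intercept)\"", call. = FALSE)
  }
  df[["(Intercept)"]] <- 1
  miss <- setdiff(names(coefs), names(df))
  if (length(miss)) {
    stop("custom outcome model names unknown feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  drop(as.matrix(df[, names(coefs), drop = FALSE]) %*% coefs)
}

# evaluate the configured truth on derived CASS features + male age
.true_score <- function(config, cass, male_age) {
  if (identical(config$outcome_model, "published_table7")) {
    return(published_score(cass, male_age = male_age,
                           tcv_scale = config$tcv_scale))
  }
  if (is.function(config$outcome_model)) {
    return(as.numeric(config$outcome_model(cass, male_age)))
  }
  coefs <- config$outcome_model
  if (is.null(names(coefs)) || !"(Intercept)" %in% names(coefs)) {
    stop("simulation_config: custom outcome model needs named coefficients ",
         "including \"(Intercept)\"", call. = FALSE)
  }
  feats <- c(unclass(cass), list(male_age = male_age, `(Intercept)` = 1))
  vals <- vapply(names(coefs), function(nm) {
    if (is.null(feats[[nm]])) {
      stop("custom outcome model names unknown feature `", nm, "`",
           call. = FALSE)
    }
    as.numeric(feats[[nm]])
  }, numeric(1))
  sum(coefs * vals)
}

#' Simulate a full cohort with known ground truth
#'
#' Assembles embryos and clinical profiles, evaluates the configured true
#' outcome model on each embryo's derived CASS features, and draws the
#' clinical-pregnancy outcome from the logistic probability. All randomness
#' derives from `config$seed` through per-patient counter substreams, so
#' identical configs reproduce identical cohorts.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort` list: `measurements`, `grades`, `profiles`,
#'   `cass` (derived features), `patient_id`, `embryo_id`, `latent_score`,
#'   `outcome`, and metadata (`seed`, `config_hash`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  master <- .new_rng(config$seed)
  epp <- cumsum(config$embryos_per_patient)
  np <- config$n_patients
  cap <- np * length(config$embryos_per_patient)
  measurements <- vector("list", cap); grades <- vector("list", cap)
  profiles <- vector("list", cap); cass <- vector("list", cap)
  patient_id <- character(cap); embryo_id <- character(cap)
  latent_score <- numeric(cap); outcome <- integer(cap)
  row <- 0L
  for (p in seq_len(np)) {
    prng <- .sub_rng(master, p)   # per-patient counter substream
    drawn <- .rng_eval(prng, {
      profile <- .simulate_profile_state(config)
      k <- which(stats::runif(1) <= epp)[1L]
      embryos <- lapply(seq_len(k), function(e)
        .simulate_embryo_state(config, sprintf("P%04d-E%d", p, e)))
      # outcome draws as uniforms, compared to p(score) after derivation
      list(profile = profile, embryos = embryos, u = stats::runif(k))
    })
    for (e in seq_along(drawn$embryos)) {
      sim <- drawn$embryos[[e]]
      row <- row + 1L
      measurements[[row]] <- sim$measurements
      grades[[row]] <- sim$grades
      profiles[[row]] <- drawn$profile
      cass[[row]] <- derive_cass_features(sim$measurements)
      patient_id[row] <- sprintf("P%04d", p)
      embryo_id[row] <- sim$measurements$embryo_id
      latent_score[row] <- drawn$u[e]   # uniform, replaced by score below
    }
  }
  keep <- seq_len(row)
  measurements <- measurements[keep]; grades <- grades[keep]
  profiles <- profiles[keep]; cass <- cass[keep]
  patient_id <- patient_id[keep]; embryo_id <- embryo_id[keep]
  u <- latent_score[keep]
  male_ages <- vapply(profiles, `[[`, numeric(1), "male_age")
  latent_score <- .true_score_vec(config, cass, male_ages)
  outcome <- as.integer(u < stats::plogis(latent_score))
  structure(
    list(measurements = measurements, grades = grades, profiles = profiles,
         cass = cass, patient_id = patient_id, embryo_id = embryo_id,
         latent_score = latent_score, outcome = outcome,
         seed = config$seed, config_hash = .config_hash(unclass(config))),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$embryo_id), " embryos / ",
      length(unique(x$patient_id)), " patients; prevalence ",
      sprintf("%.3f", mean(x$outcome)), "; seed ", x$seed,
      "; config ", x$config_hash, "\n", sep = "")
  invisible(x)
}

#' Feature table of a synthetic cohort
#'
#' Convenience wrapper around [build_feature_table()].
#'
#' @param cohort A [simulate_cohort()] result.
#' @param system `"CASS"` or `"SSS"`.
#' @return A `feature_table`.
#' @export
cohort_feature_table <- function(cohort, system = c("CASS", "SSS")) {
  system <- match.arg(system)
  emb <- if (system == "CASS") cohort$cass else cohort$grades
  build_feature_table(emb, cohort$profiles, cohort$outcome, system = system)
}

#' Parameter / structure recovery experiment
#'
#' Simulates a training and a validation cohort from the same configured
#' truth, fits the requested model on the training features, and reports
#' recovery diagnostics: per-coefficient estimate, SE, bias and +/-2 SE
#' coverage for LR (fitted on the true model's terms), or the selected
#' knots per variable for MARS; plus training and validation AUC and their
#' gap for both.
#'
#' @param config A [simulation_config()] with a custom coefficient truth
#'   (required for LR coefficient recovery; the published truth is allowed
#'   for AUC-gap reports).
#' @param model `"LR"` or `"MARS"`.
#' @param n_validation Validation cohort size (default: same as training).
#' @param max_basis,max_degree MARS controls (passed through).
#' @return A `recovery_report` list.
#' @export
recovery_experiment <- function(config, model = c("LR", "MARS"),
                                n_validation = NULL,
                                max_basis = NULL, max_degree = 2) {
  model <- match.arg(model)
  stopifnot(inherits(config, "simulation_config"))
  val_config <- config
  val_config$n_patients <- as.integer(
    if (is.null(n_validation)) config$n_patients else n_validation)
  val_config$seed <- as.integer((config$seed + 999983) %% 2147483647)
  train <- simulate_cohort(config)
  valid <- simulate_cohort(val_config)
  ft_train <- cohort_feature_table(train, "CASS")
  ft_valid <- cohort_feature_table(valid, "CASS")
  preds <- attr(ft_train, "predictors")
  custom <- !identical(config$outcome_model, "published_table7")
  if (model == "LR") {
    fit_cols <- if (custom) {
      setdiff(names(config$outcome_model), "(Intercept)")
    } else preds
    X <- as.matrix(ft_train[, fit_cols, drop = FALSE])
    fit <- fit_logistic(X, ft_train$outcome)
    score_tr <- predict(fit, ft_train)
    score_va <- predict(fit, ft_valid)
    coef_tab <- NULL
    if (custom) {
      truth <- config$outcome_model[names(fit$coefficients)]
      coef_tab <- data.frame(
        term = names(fit$coefficients),
        truth = as.numeric(truth),
        estimate = as.numeric(fit$coefficients),
        se = as.numeric(fit$standard_errors))
      coef_tab$bias <- coef_tab$estimate - coef_tab$truth
      coef_tab$covered <- abs(coef_tab$bias) <= 2 * coef_tab$se
    }
    structure_info <- list(coefficients = coef_tab)
  } else {
    X <- as.matrix(ft_train[, preds, drop = FALSE])
    m <- mars_backward(mars_forward(X, ft_train$outcome,
                                    max_basis = max_basis,
                                    max_degree = max_degree))
    fit <- m
    score_tr <- predict(m, ft_train[, preds, drop = FALSE])
    score_va <- predict(m, ft_valid[, preds, drop = FALSE])
    knots <- do.call(rbind, lapply(m$basis, function(bf)
      if (length(bf)) data.frame(
        var = vapply(bf, `[[`, character(1), "var"),
        knot = vapply(bf, `[[`, numeric(1), "knot"))))
    structure_info <- list(knots = knots)
  }
  auc_tr <- roc_auc(score_tr, ft_train$outcome)$auc
  auc_va <- roc_auc(score_va, ft_valid$outcome)$auc
  structure(
    c(list(model = model, fit = fit,
           auc_train = auc_tr, auc_validation = auc_va,
           auc_gap = auc_tr - auc_va,
           n_train = nrow(ft_train), n_validation = nrow(ft_valid)),
      structure_info),
    class = "recovery_report"
  )
}
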