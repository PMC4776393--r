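#' End-to-end experiment pipeline
#'
#' Binds the modules into the four-model experiment: for each scoring
#' system (SSS, CASS) build the feature table, screen candidates with the
#' liberal univariate filter, fit a stepwise logistic regression (two-way
#' interactions, LRT backward elimination) and a MARS model (GCV pruning,
#' optional 10-fold CV), score the temporally separate validation cohort,
#' and report the 2x2x2 matrix of training/validation AUCs with qualitative
#' grades and train-vs-validation comparison p-values. Train and validation
#' are always distinct cohorts, never an internal split.
#'
#' @name pipeline_cli
NULL

#' Assemble an experiment configuration
#'
#' @param train,validation Each either a [simulation_config()] (cohort is
#'   generated at run time) or a ready `synthetic_cohort`.
#' @param systems Scoring systems to run (subset of `"CASS"`, `"SSS"`).
#' @param models Model types to run (subset of `"LR"`, `"MARS"`).
#' @param screen_alpha Univariate screen threshold (default 0.3).
#' @param removal_p Stepwise removal threshold (default 0.1).
#' @param folds MARS cross-validation folds (default 10; 0 skips CV and
#'   fits forward + backward once).
#' @param seed Seed for MARS fold assignment.
#' @param interactions Offer two-way interactions to the LR model
#'   (default TRUE).
#' @param max_basis,max_degree,max_knot_candidates MARS controls.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(train, validation,
                              systems = c("CASS", "SSS"),
                              models = c("LR", "MARS"),
                              screen_alpha = 0.3, removal_p = 0.1,
                              folds = 10, seed = 1, interactions = TRUE,
                              max_basis = NULL, max_degree = 2,
                              max_knot_candidates = 128) {
  if (length(systems) == 0L || length(models) == 0L) {
    stop("experiment_config: select at least one system and one model",
         call. = FALSE)
  }
  systems <- match.arg(systems, c("CASS", "SSS"), several.ok = TRUE)
  models <- match.arg(models, c("LR", "MARS"), several.ok = TRUE)
  ok <- function(x) inherits(x, "simulation_config") ||
    inherits(x, "synthetic_cohort")
  if (!ok(train) || !ok(validation)) {
    stop("experiment_config: train/validation must be simulation_config or ",
         "synthetic_cohort", call. = FALSE)
  }
  structure(
    list(train = train, validation = validation, systems = systems,
         models = models, screen_alpha = screen_alpha,
         removal_p = removal_p, folds = folds, seed = as.integer(seed),
         interactions = interactions, max_basis = max_basis,
         max_degree = max_degree,
         max_knot_candidates = max_knot_candidates),
    class = "experiment_config"
  )
}

.as_cohort <- function(x) {
  if (inherits(x, "synthetic_cohort")) x else simulate_cohort(x)
}

# stepwise LR with graceful handling of collinear expansions
.fit_stepwise_lr <- function(X, y, removal_p, interactions) {
  if (interactions && ncol(X) >= 2L) X <- expand_interactions(X)
  for (attempt in 1:20) {
    fit <- tryCatch(fit_logistic(X, y), error = function(e) e)
    if (!inherits(fit, "error")) break
    msg <- conditionMessage(fit)
    if (grepl("collinear column", msg)) {
      bad <- strsplit(sub(".*collinear column\\(s\\): ", "", msg), ", ")[[1]]
      X <- X[, setdiff(colnames(X), bad), drop = FALSE]
      next
    }
    if (grepl("separation", msg) && interactions) {
      # interactions can separate small cohorts; retreat to main effects
      keep <- !grepl(":", colnames(X), fixed = TRUE)
      X <- X[, keep, drop = FALSE]
      interactions <- FALSE
      next
    }
    stop(fit)
  }
  if (inherits(fit, "error")) stop(fit)
  backward_eliminate(fit, removal_p = removal_p)
}

#' Run the full train/validate experiment
#'
#' @param config An [experiment_config()].
#' @return An `experiment_report`: `table` (one row per system x model with
#'   training and validation AUC, grades and the unpaired train-vs-
#'   validation AUC comparison p), `details` (per-cell fits, screen
#'   results, eliminated terms, dropped-row counts), `seed`,
#'   `config_hash`. Identical config and seed reproduce the report
#'   exactly.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  train <- .as_cohort(config$train)
  valid <- .as_cohort(config$validation)
  rows <- list()
  details <- list()
  for (system in config$systems) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop("[", system, "/", what, "] ", conditionMessage(e),
             call. = FALSE))
    }
    ft_tr <- stage("features", cohort_feature_table(train, system))
    ft_va <- stage("features", cohort_feature_table(valid, system))
    preds <- attr(ft_tr, "predictors")
    if (length(unique(ft_tr$outcome)) < 2L) {
      stop("[", system, "/features] training outcome has one class",
           call. = FALSE)
    }
    scr <- stage("screen",
                 univariate_screen(ft_tr[, c(preds, "outcome")],
                                   alpha = config$screen_alpha))
    selected <- scr$selected
    if (length(selected) < 2L) selected <- preds
    details[[system]] <- list(
      screen = scr, selected = selected,
      n_dropped_train = attr(ft_tr, "n_dropped"),
      n_dropped_validation = attr(ft_va, "n_dropped"))
    for (model in config$models) {
      if (model == "LR") {
        fit <- stage("fit-lr", .fit_stepwise_lr(
          as.matrix(ft_tr[, selected, drop = FALSE]), ft_tr$outcome,
          removal_p = config$removal_p,
          interactions = config$interactions))
        s_tr <- predict(fit, ft_tr)
        s_va <- stage("score", predict(fit, ft_va))
        details[[system]]$lr <- list(
          fit = fit, eliminated = attr(fit, "eliminated"))
      } else {
        Xtr <- as.matrix(ft_tr[, selected, drop = FALSE])
        if (config$folds > 0) {
          cv <- stage("fit-mars", mars_cv(
            Xtr, ft_tr$outcome, folds = config$folds, seed = config$seed,
            max_basis = config$max_basis, max_degree = config$max_degree,
            max_knot_candidates = config$max_knot_candidates))
          fit <- cv$model
          details[[system]]$mars <- list(fit = fit, cv_error = cv$cv_error,
                                         fold_errors = cv$fold_errors)
        } else {
          fit <- stage("fit-mars", mars_backward(mars_forward(
            Xtr, ft_tr$outcome, max_basis = config$max_basis,
            max_degree = config$max_degree,
            max_knot_candidates = config$max_knot_candidates)))
          details[[system]]$mars <- list(fit = fit)
        }
        s_tr <- predict(fit, Xtr)
        s_va <- stage("score",
                      predict(fit, as.matrix(ft_va[, selected,
                                                   drop = FALSE])))
      }
      roc_tr <- stage("evaluate", roc_auc(s_tr, ft_tr$outcome))
      roc_va <- stage("evaluate", roc_auc(s_va, ft_va$outcome))
      cmp <- stage("evaluate", compare_auc(s_tr, ft_tr$outcome,
                                           s_va, ft_va$outcome,
                                           paired = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        system = system, model = model,
        auc_train = roc_tr$auc, auc_validation = roc_va$auc,
        grade_train = roc_tr$grade, grade_validation = roc_va$grade,
        auc_gap = roc_tr$auc - roc_va$auc, p_train_vs_validation = cmp$p,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(table = do.call(rbind, rows), details = details,
         seed = config$seed,
         config_hash = .config_hash(list(config$systems, config$models,
                                         config$screen_alpha,
                                         config$removal_p, config$folds,
                                         config$seed))),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Discrimination of the fitted models (AUC)\n")
  tab <- x$table
  tab$auc_train <- sprintf("%.3f", tab$auc_train)
  tab$auc_validation <- sprintf("%.3f", tab$auc_validation)
  tab$p_train_vs_validation <- sprintf("%.3f", tab$p_train_vs_validation)
  print(tab[, c("system", "model", "auc_train", "auc_validation",
                "grade_validation", "p_train_vs_validation")],
        row.names = FALSE)
  invisible(x)
}

# ---- cohort CSV round trip ------------------------------------------------

#' Write a synthetic cohort to the pipeline's CSV dialect
#'
#' Writes `<prefix>_embryos.csv` (diameter lists, semicolon-separated
#' within cells), `<prefix>_grades.csv`, `<prefix>_profiles.csv` and
#' `<prefix>_outcomes.csv`. UTF-8, comma separated, header row, '.'
#' decimal.
#'
#' @param cohort A `synthetic_cohort`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_cohort_csv <- function(cohort, prefix) {
  write_embryo_csv(cohort$measurements, paste0(prefix, "_embryos.csv"))
  gdf <- do.call(rbind, lapply(cohort$grades, function(g)
    as.data.frame(unclass(g), stringsAsFactors = FALSE)))
  utils::write.csv(gdf, paste0(prefix, "_grades.csv"), row.names = FALSE)
  pdf <- do.call(rbind, lapply(cohort$profiles, function(p)
    as.data.frame(lapply(unclass(p), function(v)
      if (is.null(v)) NA else v), stringsAsFactors = FALSE)))
  pdf$patient_id <- cohort$patient_id
  utils::write.csv(pdf, paste0(prefix, "_profiles.csv"), row.names = FALSE)
  odf <- data.frame(embryo_id = cohort$embryo_id,
                    patient_id = cohort$patient_id,
                    latent_score = cohort$latent_score,
                    outcome = cohort$outcome)
  utils::write.csv(odf, paste0(prefix, "_outcomes.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `synthetic_cohort`-shaped list (without generation metadata).
#' @export
read_cohort_csv <- function(prefix) {
  measurements <- read_embryo_csv(paste0(prefix, "_embryos.csv"))
  gdf <- utils::read.csv(paste0(prefix, "_grades.csv"),
                         stringsAsFactors = FALSE)
  grades <- lapply(seq_len(nrow(gdf)), function(i)
    sss_grades(gdf$n_d2[i], gdf$n_d3[i], gdf$frag_cat_d2[i],
               gdf$frag_cat_d3[i], gdf$symmetry_d2[i], gdf$symmetry_d3[i],
               embryo_id = gdf$embryo_id[i]))
  pdf <- utils::read.csv(paste0(prefix, "_profiles.csv"),
                         stringsAsFactors = FALSE)
  profiles <- lapply(seq_len(nrow(pdf)), function(i)
    clinical_profile(pdf$female_age[i], pdf$male_age[i],
                     pdf$female_pathology[i], pdf$male_pathology[i],
                     pdf$ovulation_disorder[i], pdf$transport_problem[i],
                     pdf$implantation_problem[i],
                     pdf$endometriosis_stage[i], pdf$infertility_type[i],
                     pdf$infertility_duration[i]))
  odf <- utils::read.csv(paste0(prefix, "_outcomes.csv"),
                         stringsAsFactors = FALSE)
  structure(
    list(measurements = measurements, grades = grades, profiles = profiles,
         cass = lapply(measurements, derive_cass_features),
         patient_id = odf$patient_id, embryo_id = odf$embryo_id,
         latent_score = odf$latent_score, outcome = odf$outcome,
         seed = NA_integer_, config_hash = NA_character_),
    class = "synthetic_cohort"
  )
}
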