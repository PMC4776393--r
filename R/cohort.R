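#' Cohort representation and variable screening
#'
#' Couples are described by clinical covariates with fixed encodings:
#' indicators are 0 = absence / 1 = presence, endometriosis is ordinal 0-4
#' (absence, stages I-IV), infertility type is 0 = primary / 1 = secondary,
#' ages and infertility duration are in years. Embryos carry either visual
#' standard-scoring grades (SSS) or derived morphometric features (CASS).
#' `build_feature_table()` assembles the model-ready predictor matrix per
#' scoring system and `univariate_screen()` performs the liberal p < 0.3
#' single-predictor logistic screen used before multivariable modelling.
#'
#' @name cohort
NULL

#' Construct a couple's clinical covariate profile
#'
#' @param female_age,male_age Ages in years (15-60 exclusive).
#' @param female_pathology,male_pathology,ovulation_disorder,transport_problem,implantation_problem
#'   Indicators, 0/1 or `NA`.
#' @param endometriosis_stage Ordinal 0 (absent) to 4 (stage IV).
#' @param infertility_type 0 = primary, 1 = secondary (or `NA`).
#' @param infertility_duration Years (or `NA`).
#' @return An object of class `clinical_profile`.
#' @export
clinical_profile <- function(female_age, male_age,
                             female_pathology = NA, male_pathology = NA,
                             ovulation_disorder = NA, transport_problem = NA,
                             implantation_problem = NA,
                             endometriosis_stage = 0,
                             infertility_type = NA,
                             infertility_duration = NA) {
  chk_age <- function(a, what) {
    if (length(a) != 1L || !is.finite(a) || a <= 15 || a >= 60) {
      stop("clinical_profile: ", what, " must be in (15, 60) years",
           call. = FALSE)
    }
    as.numeric(a)
  }
  chk_ind <- function(x, what) {
    if (length(x) != 1L) stop("clinical_profile: scalar expected for ", what,
                              call. = FALSE)
    if (is.na(x)) return(NA_integer_)
    if (!x %in% c(0, 1)) stop("clinical_profile: ", what, " must be 0/1 or NA",
                              call. = FALSE)
    as.integer(x)
  }
  if (length(endometriosis_stage) != 1L ||
      !endometriosis_stage %in% 0:4) {
    stop("clinical_profile: endometriosis_stage must be in 0..4",
         call. = FALSE)
  }
  structure(
    list(female_age = chk_age(female_age, "female_age"),
         male_age = chk_age(male_age, "male_age"),
         female_pathology = chk_ind(female_pathology, "female_pathology"),
         male_pathology = chk_ind(male_pathology, "male_pathology"),
         ovulation_disorder = chk_ind(ovulation_disorder, "ovulation_disorder"),
         transport_problem = chk_ind(transport_problem, "transport_problem"),
         implantation_problem = chk_ind(implantation_problem,
                                        "implantation_problem"),
         endometriosis_stage = as.integer(endometriosis_stage),
         infertility_type = chk_ind(infertility_type, "infertility_type"),
         infertility_duration = if (is.na(infertility_duration))
           NA_real_ else as.numeric(infertility_duration)),
    class = "clinical_profile"
  )
}

#' Construct visual standard-scoring grades for one embryo
#'
#' @param n_d2,n_d3 Blastomere counts on Day 2 / Day 3.
#' @param frag_cat_d2,frag_cat_d3 Fragmentation category 0-4
#'   (0 none; 1 = 0-10%; 2 = 10-20%; 3 = 20-50%; 4 = >50%).
#' @param symmetry_d2,symmetry_d3 Symmetry grade 0-2 (0 symmetrical;
#'   1 slightly unequal; 2 uneven).
#' @param embryo_id Optional identifier.
#' @return An object of class `sss_grades`.
#' @export
sss_grades <- function(n_d2, n_d3, frag_cat_d2, frag_cat_d3,
                       symmetry_d2, symmetry_d3, embryo_id = NA_character_) {
  chk <- function(x, lo, hi, what) {
    if (length(x) != 1L || is.na(x) || !x %in% lo:hi) {
      stop("sss_grades: ", what, " must be an integer in ", lo, "..", hi,
           call. = FALSE)
    }
    as.integer(x)
  }
  structure(
    list(embryo_id = as.character(embryo_id)[1L],
         n_d2 = chk(n_d2, 1L, 64L, "n_d2"),
         n_d3 = chk(n_d3, 1L, 64L, "n_d3"),
         frag_cat_d2 = chk(frag_cat_d2, 0L, 4L, "frag_cat_d2"),
         frag_cat_d3 = chk(frag_cat_d3, 0L, 4L, "frag_cat_d3"),
         symmetry_d2 = chk(symmetry_d2, 0L, 2L, "symmetry_d2"),
         symmetry_d3 = chk(symmetry_d3, 0L, 2L, "symmetry_d3")),
    class = "sss_grades"
  )
}

#' Map a realized fragmentation fraction to the visual category
#'
#' Bands: 0 = no fragmentation; 1 = 0-10%; 2 = 10-20%; 3 = 20-50%;
#' 4 = more than 50%. Edges are lower-exclusive (a fraction of exactly 0.10
#' is category 1).
#'
#' @param frac Fragmentation fraction in \[0, 1\] (vectorised).
#' @return Integer category 0-4.
#' @export
fragmentation_category <- function(frac) {
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1)) {
    stop("fragmentation_category: fraction must be in [0, 1]", call. = FALSE)
  }
  as.integer(cut(frac, breaks = c(-Inf, 0, 0.10, 0.20, 0.50, Inf),
                 labels = FALSE, right = TRUE)) - 1L
}

#' Map a realized COD to the visual symmetry grade
#'
#' 0 = symmetrical; 1 = slightly unequal (25-50% size difference);
#' 2 = uneven (more than 50% difference). The size difference of a COD r is
#' taken as `1 - 1/r` (relative deficit of the smallest vs largest
#' blastomere).
#'
#' @param cod Coefficient of diversity, >= 1 (vectorised).
#' @return Integer grade 0-2.
#' @export
symmetry_grade <- function(cod) {
  if (any(!is.finite(cod)) || any(cod < 1)) {
    stop("symmetry_grade: COD must be >= 1", call. = FALSE)
  }
  diff <- 1 - 1 / cod
  as.integer(cut(diff, breaks = c(-Inf, 0.25, 0.50, Inf), labels = FALSE)) - 1L
}

# canonical predictor column sets per scoring system
.CASS_PREDICTORS <- c("tcv_d1", "tcv_d2", "tcv_d3", "n_d2", "parity_d2",
                      "frag_d2", "frag_d3", "cod_d2", "cod_d3", "n_d3_dev",
                      "male_age", "female_age")
.SSS_PREDICTORS <- c("n_d2", "n_d3_dev", "frag_cat_d2", "frag_cat_d3",
                     "symmetry_d2", "symmetry_d3", "parity_d2",
                     "male_age", "female_age")

#' Build the model-ready feature table for one scoring system
#'
#' Emits one row per embryo with the encoded predictors of the chosen system
#' plus the binary clinical-pregnancy outcome. CASS rows require
#' [derive_cass_features()] output; SSS rows require [sss_grades()]. Rows
#' with a missing value in any retained column are dropped (complete-case)
#' and the dropped count is reported in the `"n_dropped"` attribute.
#' `transport_problem` is never offered to models (excluded for
#' missingness in the source data); it stays available in the profile.
#'
#' @param embryos List of `cass_features` (system `"CASS"`) or `sss_grades`
#'   (system `"SSS"`), one per row.
#' @param profiles List of [clinical_profile] objects, one per embryo.
#' @param outcome Binary vector (1 = clinical pregnancy), one per embryo.
#' @param system `"SSS"` or `"CASS"`.
#' @param day3_optimum Day-3 optimum used for the SSS count transform
#'   (default 8.4, matching CASS).
#' @return A `feature_table`: a data.frame of predictors plus `outcome`,
#'   with attributes `scoring_system`, `predictors`, `n_dropped`.
#' @export
build_feature_table <- function(embryos, profiles, outcome,
                                system = c("CASS", "SSS"),
                                day3_optimum = .DAY3_OPTIMUM_DEFAULT) {
  system <- match.arg(system)
  n <- length(embryos)
  if (length(profiles) != n || length(outcome) != n) {
    stop("build_feature_table: embryos, profiles and outcome lengths differ",
         call. = FALSE)
  }
  if (n > 0L && !all(stats::na.omit(outcome) %in% c(0, 1))) {
    stop("build_feature_table: outcome must be binary 0/1", call. = FALSE)
  }
  preds <- if (system == "CASS") .CASS_PREDICTORS else .SSS_PREDICTORS
  if (n == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(preds) + 1L), c(preds, "outcome")))
    return(structure(df, scoring_system = system, predictors = preds,
                     n_dropped = 0L, class = c("feature_table", "data.frame")))
  }
  want_class <- if (system == "CASS") "cass_features" else "sss_grades"
  ok <- vapply(embryos, inherits, logical(1), want_class)
  if (!all(ok)) {
    stop("build_feature_table: system ", system, " requires ", want_class,
         " rows", call. = FALSE)
  }
  col <- function(src, field, fn = identity)
    vapply(src, function(e) as.numeric(fn(e[[field]])), numeric(1))
  df <- if (system == "CASS") {
    data.frame(tcv_d1 = col(embryos, "tcv_d1"),
               tcv_d2 = col(embryos, "tcv_d2"),
               tcv_d3 = col(embryos, "tcv_d3"),
               n_d2 = col(embryos, "n_d2"),
               parity_d2 = col(embryos, "parity_d2"),
               frag_d2 = col(embryos, "frag_d2"),
               frag_d3 = col(embryos, "frag_d3"),
               cod_d2 = col(embryos, "cod_d2"),
               cod_d3 = col(embryos, "cod_d3"),
               n_d3_dev = col(embryos, "n_d3_dev"))
  } else {
    n_d2 <- col(embryos, "n_d2")
    data.frame(n_d2 = n_d2,
               n_d3_dev = abs(col(embryos, "n_d3") - day3_optimum),
               frag_cat_d2 = col(embryos, "frag_cat_d2"),
               frag_cat_d3 = col(embryos, "frag_cat_d3"),
               symmetry_d2 = col(embryos, "symmetry_d2"),
               symmetry_d3 = col(embryos, "symmetry_d3"),
               parity_d2 = as.numeric(n_d2 %% 2 == 0))
  }
  df$male_age <- col(profiles, "male_age")
  df$female_age <- col(profiles, "female_age")
  df <- df[, preds, drop = FALSE]
  df$outcome <- as.numeric(outcome)
  df$embryo_id <- vapply(embryos, function(e)
    if (is.null(e$embryo_id)) NA_character_ else e$embryo_id, character(1))
  complete <- stats::complete.cases(df[, c(preds, "outcome")])
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message("build_feature_table: dropped ", n_dropped,
            " incomplete row(s) (complete-case)")
  }
  df <- df[complete, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, scoring_system = system, predictors = preds,
            n_dropped = n_dropped, class = c("feature_table", "data.frame"))
}

#' Assemble the clinical covariate table for univariate screening
#'
#' One row per embryo transfer with the ten couple-level covariates and the
#' outcome, mirroring the layout of a univariate screening table.
#'
#' @param profiles List of [clinical_profile] objects.
#' @param outcome Binary outcome vector.
#' @return A data.frame with the clinical columns plus `outcome`.
#' @export
build_clinical_table <- function(profiles, outcome) {
  if (length(profiles) != length(outcome)) {
    stop("build_clinical_table: lengths differ", call. = FALSE)
  }
  cols <- c("female_pathology", "ovulation_disorder", "endometriosis_stage",
            "transport_problem", "implantation_problem", "male_pathology",
            "male_age", "female_age", "infertility_type",
            "infertility_duration")
  df <- as.data.frame(lapply(stats::setNames(cols, cols), function(cl)
    vapply(profiles, function(p) as.numeric(p[[cl]]), numeric(1))))
  df$outcome <- as.numeric(outcome)
  df
}

#' Univariate logistic screen of candidate predictors
#'
#' Fits a single-predictor logistic regression per feature and retains those
#' with Wald p below `alpha` (default 0.3 — deliberately liberal so that
#' potentially useful predictors are not discarded prematurely). Constant
#' features are excluded with a warning, not an error.
#'
#' @param table Data.frame with feature columns and an `outcome` column
#'   (e.g. a [build_feature_table()] or [build_clinical_table()] result).
#' @param alpha Retention threshold on the Wald p-value (default 0.3).
#' @param features Columns to screen; defaults to all non-outcome numeric
#'   columns.
#' @return List with `selected` (character vector of retained names) and
#'   `table` (per-feature beta, OR, 95% CI, p), classed `univariate_screen`.
#' @export
univariate_screen <- function(table, alpha = 0.3, features = NULL) {
  if (!"outcome" %in% names(table)) {
    stop("univariate_screen: table needs an `outcome` column", call. = FALSE)
  }
  y_all <- table$outcome
  if (length(unique(stats::na.omit(y_all))) < 2L) {
    stop("univariate_screen: outcome must contain both classes", call. = FALSE)
  }
  if (is.null(features)) {
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        "outcome")
  }
  one <- function(f) {
    x <- table[[f]]
    keep <- !is.na(x) & !is.na(y_all)
    x <- x[keep]; y <- y_all[keep]
    if (length(unique(x)) < 2L) {
      warning("univariate_screen: feature `", f, "` is constant; excluded",
              call. = FALSE)
      return(NULL)
    }
    fit <- tryCatch(fit_logistic(matrix(x, dimnames = list(NULL, f)), y),
                    error = function(e) {
                      warning("univariate_screen: feature `", f,
                              "` could not be fitted (", conditionMessage(e),
                              "); excluded", call. = FALSE)
                      NULL
                    })
    if (is.null(fit)) return(NULL)
    b <- fit$coefficients[[f]]
    se <- fit$standard_errors[[f]]
    data.frame(feature = f, beta = b, or = exp(b),
               ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
               p = fit$p_values[[f]], stringsAsFactors = FALSE)
  }
  recs <- Filter(Negate(is.null), lapply(features, one))
  tab <- if (length(recs)) do.call(rbind, recs) else
    data.frame(feature = character(0), beta = numeric(0), or = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0), p = numeric(0))
  rownames(tab) <- NULL
  structure(list(selected = tab$feature[tab$p < alpha], table = tab,
                 alpha = alpha),
            class = "univariate_screen")
}

#' @export
print.univariate_screen <- function(x, ...) {
  cat("Univariate logistic screen (retain p <", format(x$alpha), ")\n")
  tab <- x$table
  tab$beta <- sprintf("%.2f", tab$beta)
  tab$or <- sprintf("%.2f", tab$or)
  tab$ci <- sprintf("%.2f-%.2f", x$table$ci_low, x$table$ci_high)
  tab$p <- sprintf("%.2f", x$table$p)
  print(tab[, c("feature", "beta", "or", "ci", "p")], row.names = FALSE)
  cat("retained:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Location-and-shape sensitive comparison of two empirical distributions,
#' used to check baseline comparability (e.g. maternal age) between cohorts.
#'
#' @param x,y Numeric samples.
#' @param alpha Rejection level (default 0.05).
#' @return List with `statistic` (D), `p`, and `reject` (0/1 at `alpha`).
#' @export
ks_two_sample <- function(x, y, alpha = 0.05) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("ks_two_sample: samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p = kt$p.value,
       reject = as.integer(kt$p.value < alpha))
}

#' Pregnancy rate as a printed percentage
#'
#' @param n_pregnant,n_total Counts.
#' @param digits Decimal places (default 1).
#' @return Percentage rounded to `digits`.
#' @export
pregnancy_rate <- function(n_pregnant, n_total, digits = 1) {
  if (n_total <= 0 || n_pregnant < 0 || n_pregnant > n_total) {
    stop("pregnancy_rate: need 0 <= n_pregnant <= n_total, n_total > 0",
         call. = FALSE)
  }
  round(100 * n_pregnant / n_total, digits)
}
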