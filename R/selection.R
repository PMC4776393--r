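#' Per-patient embryo ranking and selection comparison
#'
#' Ranks a patient's embryos by a model score (descending, deterministic
#' tie-break by lower embryo id) and compares the model-based choice with
#' the visual standard-scoring choice across a cohort of patients who each
#' have at least two top-quality embryos — the setting in which a
#' quantitative score can actually change the transfer decision.
#'
#' @name selection
NULL

#' Rank one patient's embryos by score
#'
#' @param embryos List of scoreable embryo objects (each with an
#'   `embryo_id`).
#' @param scorer Function mapping one embryo object to a numeric score.
#' @return The list reordered descending by score; ties broken by lower
#'   `embryo_id`. The scores are attached as attribute `"scores"`.
#' @export
rank_embryos <- function(embryos, scorer) {
  if (length(embryos) == 0L) {
    stop("rank_embryos: no scoreable embryo", call. = FALSE)
  }
  scores <- vapply(embryos, function(e) as.numeric(scorer(e)), numeric(1))
  if (any(!is.finite(scores))) {
    stop("rank_embryos: scorer returned a non-finite score", call. = FALSE)
  }
  ids <- vapply(embryos, function(e)
    as.character(e$embryo_id %||% NA_character_), character(1))
  ord <- order(-scores, ids)
  structure(embryos[ord], scores = scores[ord], embryo_ids = ids[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default SSS preference: higher grade = better embryo.
# Top quality = 8 cells Day 3, low fragmentation, symmetrical; encode as a
# composite to maximise (negated penalties), ties by lower embryo id.
.default_sss_rule <- function(g) {
  -(abs(g$n_d3 - 8) * 100 + g$frag_cat_d3 * 10 + g$symmetry_d3 +
      abs(g$n_d2 - 4) * 0.5)
}

#' Compare model-based and standard-scoring transfer decisions
#'
#' For each patient the SSS choice (best by `sss_rule`, ties by lower
#' embryo id) and the model choice ([rank_embryos()] top by `model_scorer`)
#' are determined; the patients where both choices coincide are counted as
#' concordant. Patients with fewer than two embryos are excluded with a
#' warning.
#'
#' @param patients List of patients; each a list with `grades` (list of
#'   [sss_grades]) and `embryos` (aligned list of scoreable objects for the
#'   model, e.g. `cass_features`).
#' @param sss_rule Function mapping `sss_grades` to a numeric preference
#'   (higher = better); default: 8 cells on Day 3, then least
#'   fragmentation, then best symmetry.
#' @param model_scorer Function mapping a model embryo object to a score.
#' @return A `selection_comparison` list: `n_patients`, `n_concordant`,
#'   `n_discordant`, `concordance_fraction`, `discordance_fraction`,
#'   `per_patient` data.frame. Ties among equal top-quality embryos are
#'   broken by lowest embryo id (flagged in the printout).
#' @export
compare_decisions <- function(patients, sss_rule = .default_sss_rule,
                              model_scorer) {
  records <- list()
  for (pt in patients) {
    if (length(pt$embryos) < 2L) {
      warning("compare_decisions: patient with < 2 embryos excluded",
              call. = FALSE)
      next
    }
    stopifnot(length(pt$grades) == length(pt$embryos))
    sss_scores <- vapply(pt$grades, function(g) as.numeric(sss_rule(g)),
                         numeric(1))
    ids <- vapply(pt$grades, function(g) as.character(g$embryo_id),
                  character(1))
    sss_choice <- ids[order(-sss_scores, ids)][1L]
    ranked <- rank_embryos(pt$embryos, model_scorer)
    model_choice <- attr(ranked, "embryo_ids")[1L]
    records[[length(records) + 1L]] <- data.frame(
      sss_choice = sss_choice, model_choice = model_choice,
      sss_score = max(sss_scores),
      model_score = attr(ranked, "scores")[1L],
      concordant = identical(sss_choice, model_choice),
      stringsAsFactors = FALSE)
  }
  per_patient <- if (length(records)) do.call(rbind, records) else
    data.frame(sss_choice = character(0), model_choice = character(0),
               sss_score = numeric(0), model_score = numeric(0),
               concordant = logical(0))
  n <- nrow(per_patient)
  n_con <- sum(per_patient$concordant)
  structure(
    list(n_patients = n, n_concordant = n_con, n_discordant = n - n_con,
         concordance_fraction = if (n) n_con / n else NA_real_,
         discordance_fraction = if (n) (n - n_con) / n else NA_real_,
         per_patient = per_patient,
         tie_break = "lowest embryo_id"),
    class = "selection_comparison"
  )
}

#' @export
print.selection_comparison <- function(x, ...) {
  cat(sprintf(
    "Selection comparison over %d patients: %d (%.1f%%) concordant, %d (%.1f%%) discordant\n",
    x$n_patients, x$n_concordant, 100 * x$concordance_fraction,
    x$n_discordant, 100 * x$discordance_fraction))
  cat("  (ties among equal top-quality embryos broken by", x$tie_break,
      ")\n")
  invisible(x)
}
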