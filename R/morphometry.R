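#' Morphometric (CASS) feature derivation for cleavage-stage embryos
#'
#' The computer-assisted scoring system (CASS) reduces an embryo to manually
#' drawn diameters: one zygote diameter on Day 1 and one diameter per visible
#' object on Day 2 and Day 3. Objects at least 45 um across on Day 2
#' (40 um on Day 3) count as blastomeres; smaller objects are fragments.
#' From the blastomere diameters the package derives total cytoplasmic volume
#' (TCV), the coefficient of diversity (COD, largest/smallest blastomere), and
#' fragmentation as the fractional loss of TCV relative to Day 1 — early
#' cleavage conserves cytoplasmic volume, so any deficit is read as
#' fragmentation.
#'
#' @name morphometry
NULL

# size thresholds (um) separating blastomeres from fragments
.BLASTOMERE_MIN_UM <- c(`2` = 45, `3` = 40)

# optimum Day-3 blastomere count of the published quadratic fit
.DAY3_OPTIMUM_DEFAULT <- 8.4

#' Construct per-embryo diameter measurements
#'
#' Bundles the raw CASS input for one embryo: the Day-1 zygote diameter and
#' the per-object diameters drawn on Day 2 and Day 3 (blastomeres and
#' fragments together, in micrometres).
#'
#' @param embryo_id Opaque identifier (coerced to character).
#' @param day1_diameter Zygote diameter on Day 1, um.
#' @param day2_diameters,day3_diameters Numeric vectors of object diameters,
#'   um, one value per visible object (unclassified).
#' @return An object of class `embryo_measurements`.
#' @export
embryo_measurements <- function(embryo_id, day1_diameter,
                                day2_diameters, day3_diameters) {
  day1_diameter <- as.numeric(day1_diameter)
  day2_diameters <- as.numeric(day2_diameters)
  day3_diameters <- as.numeric(day3_diameters)
  if (length(day1_diameter) != 1L || !is.finite(day1_diameter) ||
      day1_diameter <= 0) {
    stop("invalid measurement: day1_diameter must be a single positive value",
         call. = FALSE)
  }
  for (d in list(day2 = day2_diameters, day3 = day3_diameters)) {
    if (length(d) == 0L || any(!is.finite(d)) || any(d <= 0)) {
      stop("invalid measurement: diameter lists must be non-empty and positive",
           call. = FALSE)
    }
  }
  structure(
    list(embryo_id = as.character(embryo_id)[1L],
         day1_diameter = day1_diameter,
         day2_diameters = day2_diameters,
         day3_diameters = day3_diameters),
    class = "embryo_measurements"
  )
}

#' @export
print.embryo_measurements <- function(x, ...) {
  cat("<embryo_measurements>", x$embryo_id, "\n")
  cat("  Day 1 zygote: ", format(x$day1_diameter), " um\n", sep = "")
  cat("  Day 2 objects:", paste(format(x$day2_diameters), collapse = ", "),
      "um\n")
  cat("  Day 3 objects:", paste(format(x$day3_diameters), collapse = ", "),
      "um\n")
  invisible(x)
}

#' Volume of a blastomere modelled as a sphere
#'
#' @param diameter Diameter in um (vectorised).
#' @return Volume in um^3, `(pi/6) d^3`.
#' @export
blastomere_volume <- function(diameter) {
  diameter <- as.numeric(diameter)
  if (length(diameter) == 0L || any(!is.finite(diameter)) ||
      any(diameter <= 0)) {
    stop("invalid measurement: diameter must be positive", call. = FALSE)
  }
  (pi / 6) * diameter^3
}

#' Partition drawn objects into blastomeres and fragments
#'
#' Applies the day-specific minimum blastomere diameter (45 um on Day 2,
#' 40 um on Day 3, threshold inclusive); order and multiplicity are preserved.
#'
#' @param diameters Numeric vector of object diameters, um.
#' @param day 2 or 3.
#' @return List with `blastomeres` and `fragments` diameter vectors.
#' @export
classify_objects <- function(diameters, day) {
  diameters <- as.numeric(diameters)
  if (length(diameters) == 0L) {
    stop("classify_objects: empty diameter list", call. = FALSE)
  }
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("invalid measurement: diameters must be positive", call. = FALSE)
  }
  if (length(day) != 1L || !day %in% c(2, 3)) {
    stop("classify_objects: day must be 2 or 3", call. = FALSE)
  }
  thr <- .BLASTOMERE_MIN_UM[[as.character(day)]]
  keep <- diameters >= thr
  list(blastomeres = diameters[keep], fragments = diameters[!keep])
}

#' Total cytoplasmic volume of a set of blastomeres
#'
#' @param blastomere_diameters Numeric vector of blastomere diameters, um
#'   (already classified; for Day 1 pass the single zygote diameter).
#' @return Summed sphere volume, um^3.
#' @export
total_cytoplasmic_volume <- function(blastomere_diameters) {
  if (length(blastomere_diameters) == 0L) {
    stop("total_cytoplasmic_volume: empty blastomere list", call. = FALSE)
  }
  sum(blastomere_volume(blastomere_diameters))
}

#' Coefficient of diversity of blastomere size
#'
#' Ratio of the largest to the smallest blastomere diameter; 1 means
#' perfectly even blastomeres.
#'
#' @param blastomere_diameters Numeric vector of blastomere diameters, um.
#' @return max/min diameter ratio, >= 1.
#' @export
coefficient_of_diversity <- function(blastomere_diameters) {
  if (length(blastomere_diameters) == 0L) {
    stop("coefficient_of_diversity: empty blastomere list", call. = FALSE)
  }
  d <- as.numeric(blastomere_diameters)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("invalid measurement: diameters must be positive", call. = FALSE)
  }
  max(d) / min(d)
}

#' Fragmentation as fractional TCV loss from Day 1
#'
#' Early cleavage conserves cytoplasmic volume, so the relative reduction of
#' TCV on a later day is interpreted as the fragmented fraction. Measurement
#' noise can make the later TCV exceed Day 1; the value is then clamped to 0
#' with a warning and the raw (negative) value is kept in the
#' `"raw"` attribute.
#'
#' @param tcv_day1 Day-1 total cytoplasmic volume, um^3.
#' @param tcv_dayX Day-2 or Day-3 blastomere TCV, um^3.
#' @return Fraction in \[0, 1\]; attribute `"raw"` holds the unclamped value.
#' @export
fragmentation_fraction <- function(tcv_day1, tcv_dayX) {
  if (length(tcv_day1) != 1L || length(tcv_dayX) != 1L ||
      !is.finite(tcv_day1) || !is.finite(tcv_dayX) ||
      tcv_day1 <= 0 || tcv_dayX <= 0) {
    stop("fragmentation_fraction: volumes must be single positive values",
         call. = FALSE)
  }
  raw <- (tcv_day1 - tcv_dayX) / tcv_day1
  val <- raw
  if (raw < 0) {
    warning("fragmentation clamped to 0: later TCV exceeds Day-1 TCV ",
            "(measurement noise)", call. = FALSE)
    val <- 0
  }
  structure(val, raw = raw)
}

#' Derive the full CASS feature set for one embryo
#'
#' Classifies the Day-2/Day-3 objects, computes TCV per day, COD per day,
#' fragmentation per day (TCV loss relative to Day 1), the Day-2 blastomere
#' count and its parity indicator, the Day-3 count and its absolute deviation
#' from the model optimum (default 8.4, the published quadratic optimum).
#'
#' @param m An [embryo_measurements] object.
#' @param day3_optimum Optimal Day-3 blastomere count (default 8.4).
#' @return An object of class `cass_features`: a named list with fields
#'   `tcv_d1`, `tcv_d2`, `tcv_d3` (um^3), `n_d2`, `n_d3`, `cod_d2`, `cod_d3`,
#'   `frag_d2`, `frag_d3` (fractions), `parity_d2` (0/1), `n_d3_dev`
#'   (`|n_d3 - day3_optimum|`), plus raw unclamped fragmentation values in
#'   `frag_d2_raw`/`frag_d3_raw`.
#' @export
derive_cass_features <- function(m, day3_optimum = .DAY3_OPTIMUM_DEFAULT) {
  stopifnot(inherits(m, "embryo_measurements"))
  c2 <- classify_objects(m$day2_diameters, 2)
  c3 <- classify_objects(m$day3_diameters, 3)
  if (length(c2$blastomeres) == 0L || length(c3$blastomeres) == 0L) {
    stop("degenerate embryo: no blastomeres above the size threshold on day ",
         if (length(c2$blastomeres) == 0L) 2 else 3, call. = FALSE)
  }
  tcv_d1 <- blastomere_volume(m$day1_diameter)
  tcv_d2 <- total_cytoplasmic_volume(c2$blastomeres)
  tcv_d3 <- total_cytoplasmic_volume(c3$blastomeres)
  frag2 <- fragmentation_fraction(tcv_d1, tcv_d2)
  frag3 <- fragmentation_fraction(tcv_d1, tcv_d3)
  n_d2 <- length(c2$blastomeres)
  n_d3 <- length(c3$blastomeres)
  structure(
    list(embryo_id = m$embryo_id,
         tcv_d1 = tcv_d1, tcv_d2 = tcv_d2, tcv_d3 = tcv_d3,
         n_d2 = n_d2, n_d3 = n_d3,
         cod_d2 = coefficient_of_diversity(c2$blastomeres),
         cod_d3 = coefficient_of_diversity(c3$blastomeres),
         frag_d2 = as.numeric(frag2), frag_d3 = as.numeric(frag3),
         frag_d2_raw = attr(frag2, "raw"), frag_d3_raw = attr(frag3, "raw"),
         parity_d2 = as.integer(n_d2 %% 2L == 0L),
         n_d3_dev = abs(n_d3 - day3_optimum)),
    class = "cass_features"
  )
}

#' @export
print.cass_features <- function(x, ...) {
  cat("<cass_features>", x$embryo_id, "\n")
  cat(sprintf("  TCV (um^3): D1 %.0f  D2 %.0f  D3 %.0f\n",
              x$tcv_d1, x$tcv_d2, x$tcv_d3))
  cat(sprintf("  counts: D2 %d (parity %d)  D3 %d (|n-opt| = %.1f)\n",
              x$n_d2, x$parity_d2, x$n_d3, x$n_d3_dev))
  cat(sprintf("  COD: D2 %.3f  D3 %.3f   fragmentation: D2 %.3f  D3 %.3f\n",
              x$cod_d2, x$cod_d3, x$frag_d2, x$frag_d3))
  invisible(x)
}

#' Read embryo measurements from CSV
#'
#' One row per embryo with columns `embryo_id`, `day1_diameter`,
#' `day2_diameters`, `day3_diameters`; the per-day lists are
#' semicolon-separated um values within the cell. UTF-8, header required.
#'
#' @param path CSV file path.
#' @return List of [embryo_measurements] objects.
#' @export
read_embryo_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("embryo_id", "day1_diameter", "day2_diameters", "day3_diameters")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("embryo CSV missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  parse_list <- function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1L]])
  lapply(seq_len(nrow(df)), function(i) {
    embryo_measurements(df$embryo_id[i], df$day1_diameter[i],
                        parse_list(df$day2_diameters[i]),
                        parse_list(df$day3_diameters[i]))
  })
}

#' Write embryo measurements to CSV
#'
#' Inverse of [read_embryo_csv()].
#'
#' @param embryos List of [embryo_measurements] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_embryo_csv <- function(embryos, path) {
  df <- data.frame(
    embryo_id = vapply(embryos, `[[`, character(1), "embryo_id"),
    day1_diameter = vapply(embryos, `[[`, numeric(1), "day1_diameter"),
    day2_diameters = vapply(embryos, function(e)
      paste(format(e$day2_diameters, trim = TRUE, digits = 10),
            collapse = ";"), character(1)),
    day3_diameters = vapply(embryos, function(e)
      paste(format(e$day3_diameters, trim = TRUE, digits = 10),
            collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
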