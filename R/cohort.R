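# Cohort data model, CSV I/O, and the nested case-control extreme-lipid
# selection rule.

#' Binary (tristate) clinical covariates of the cohort schema
#'
#' Each is coded `"yes"`, `"no"` or `NA` (missing); analyses use complete
#' cases per variable, so per-variable denominators may differ.
#'
#' @return Character vector of column names.
#' @export
cohort_binary_covariates <- function() {
  c(
    "tobacco_ever", "dm_on_medication", "htn_on_medication",
    "obesity_on_medication", "stroke_history", "angina_mi_history",
    "heart_failure_history", "famhx_htn", "famhx_dm", "famhx_stroke",
    "famhx_angina", "famhx_hyperlipidemia", "famhx_heart_disease",
    "famhx_cvd"
  )
}

#' Continuous covariates of the cohort schema
#'
#' Lipids and fasting glucose are in mmol/L, age in years, BMI in kg/m2.
#' Fasting glucose is carried in mmol/L throughout: reported values around
#' 6.5-7.2 are physiologically plausible only on that scale, although some
#' published summaries label the same quantity "mg/L".
#'
#' @return Character vector of column names.
#' @export
cohort_continuous_covariates <- function() {
  c("age_years", "tc_mmol_l", "ldl_mmol_l", "hdl_mmol_l", "tg_mmol_l",
    "fasting_glucose_mmol_l", "bmi_kg_m2")
}

cohort_mandatory_columns <- function() {
  c("id", "sex", cohort_continuous_covariates(), cohort_binary_covariates())
}

#' Selection criteria for the extreme-lipid nested case-control design
#'
#' Cases (HLDL) must exceed both the LDL-C and TC hypercholesterolemia
#' cut-offs (Simon Broome-derived); controls (LLDL) must fall below the TC
#' maximum with LDL-C inside a normal window. Defaults are in mmol/L.
#'
#' @param hldl_ldl_cutoff LDL-C cut-off for case eligibility (exclusive, >).
#' @param hldl_tc_cutoff TC cut-off for case eligibility (exclusive, >).
#' @param lldl_tc_max TC maximum for control eligibility (exclusive, <).
#' @param lldl_ldl_range Inclusive LDL-C window for control eligibility.
#' @param k_per_arm Number of participants selected per arm.
#' @return An object of class `selection_criteria`.
#' @export
#' @examples
#' selection_criteria(k_per_arm = 25)
selection_criteria <- function(hldl_ldl_cutoff = 4.9, hldl_tc_cutoff = 7.5,
                               lldl_tc_max = 5.2,
                               lldl_ldl_range = c(2.6, 3.4),
                               k_per_arm = 25L) {
  stopifnot(
    hldl_ldl_cutoff > 0, hldl_tc_cutoff > 0, lldl_tc_max > 0,
    length(lldl_ldl_range) == 2L, lldl_ldl_range[1] <= lldl_ldl_range[2],
    k_per_arm >= 1L
  )
  structure(
    list(
      hldl_ldl_cutoff = hldl_ldl_cutoff, hldl_tc_cutoff = hldl_tc_cutoff,
      lldl_tc_max = lldl_tc_max, lldl_ldl_range = as.numeric(lldl_ldl_range),
      k_per_arm = as.integer(k_per_arm)
    ),
    class = "selection_criteria"
  )
}

#' @export
print.selection_criteria <- function(x, ...) {
  cat("Extreme-lipid selection criteria (mmol/L)\n")
  cat(sprintf("  HLDL-eligible: LDL-C > %.2f AND TC > %.2f\n",
              x$hldl_ldl_cutoff, x$hldl_tc_cutoff))
  cat(sprintf("  LLDL-eligible: TC < %.2f AND LDL-C in [%.2f, %.2f]\n",
              x$lldl_tc_max, x$lldl_ldl_range[1], x$lldl_ldl_range[2]))
  cat(sprintf("  k per arm: %d\n", x$k_per_arm))
  invisible(x)
}

#' Classify lipid-panel eligibility for the extreme arms
#'
#' @param tc Total cholesterol, mmol/L (vectorised).
#' @param ldl LDL cholesterol, mmol/L (vectorised).
#' @param criteria A [selection_criteria()] object.
#' @return Character vector in `{"HLDL-eligible", "LLDL-eligible",
#'   "neither"}`; every participant maps to exactly one class (the two
#'   eligibility windows are disjoint for any valid criteria).
#' @export
#' @examples
#' classify_eligibility(c(8.0, 5.0, 6.0), c(5.2, 3.0, 4.0))
classify_eligibility <- function(tc, ldl, criteria = selection_criteria()) {
  if (length(tc) != length(ldl)) stop("tc and ldl must have equal length")
  if (any(!is.finite(tc)) || any(!is.finite(ldl))) {
    stop("non-finite lipid value")
  }
  if (any(tc < 0) || any(ldl < 0)) stop("negative lipid value")
  hldl <- ldl > criteria$hldl_ldl_cutoff & tc > criteria$hldl_tc_cutoff
  lldl <- tc < criteria$lldl_tc_max &
    ldl >= criteria$lldl_ldl_range[1] & ldl <= criteria$lldl_ldl_range[2]
  out <- rep("neither", length(tc))
  out[hldl] <- "HLDL-eligible"
  out[lldl & !hldl] <- "LLDL-eligible"
  out
}

#' Select phenotype extremes for the nested case-control design
#'
#' Among HLDL-eligible participants the `k_per_arm` highest-ranked by LDL-C
#' are taken as cases; among LLDL-eligible participants the `k_per_arm`
#' lowest-ranked as controls. Ties on LDL-C break by TC (higher TC ranks
#' higher), then lexicographically by id so the selection is deterministic.
#'
#' @param participants Data frame with at least `id`, `tc_mmol_l`,
#'   `ldl_mmol_l`.
#' @param criteria A [selection_criteria()] object.
#' @return List with data frames `cases` and `controls` (disjoint), each
#'   with a `group` column set to `"HLDL"` / `"LLDL"`.
#' @export
select_extremes <- function(participants, criteria = selection_criteria()) {
  stopifnot(is.data.frame(participants))
  need <- c("id", "tc_mmol_l", "ldl_mmol_l")
  miss <- setdiff(need, names(participants))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  elig <- classify_eligibility(participants$tc_mmol_l,
                               participants$ldl_mmol_l, criteria)
  k <- criteria$k_per_arm
  hldl <- participants[elig == "HLDL-eligible", , drop = FALSE]
  lldl <- participants[elig == "LLDL-eligible", , drop = FALSE]
  if (nrow(hldl) < k) {
    stop(sprintf("only %d HLDL-eligible participants for k = %d",
                 nrow(hldl), k))
  }
  if (nrow(lldl) < k) {
    stop(sprintf("only %d LLDL-eligible participants for k = %d",
                 nrow(lldl), k))
  }
  # cases: highest LDL-C first; controls: lowest LDL-C first
  ord_case <- order(-hldl$ldl_mmol_l, -hldl$tc_mmol_l, hldl$id)
  ord_ctrl <- order(lldl$ldl_mmol_l, lldl$tc_mmol_l, lldl$id)
  cases <- hldl[ord_case[seq_len(k)], , drop = FALSE]
  controls <- lldl[ord_ctrl[seq_len(k)], , drop = FALSE]
  cases$group <- "HLDL"
  controls$group <- "LLDL"
  rownames(cases) <- rownames(controls) <- NULL
  list(cases = cases, controls = controls)
}

#' Read a cohort CSV
#'
#' Parses the documented cohort schema. Tristate covariates accept
#' `yes`/`no`; empty cells become `NA` ("missing") and are excluded from
#' that variable's complete-case analyses. Unknown columns (for example
#' genotype columns `gt_*`) are preserved verbatim.
#'
#' @param path CSV path.
#' @return Data frame of participant records.
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE,
                na.strings = c("", "NA", "missing"))
  miss <- setdiff(cohort_mandatory_columns(), names(x))
  if (length(miss)) {
    stop("cohort file lacks mandatory columns: ", paste(miss, collapse = ", "))
  }
  for (v in cohort_continuous_covariates()) {
    if (!is.numeric(x[[v]])) {
      suppressWarnings(num <- as.numeric(x[[v]]))
      bad <- which(!is.na(x[[v]]) & is.na(num))
      if (length(bad)) {
        stop(sprintf("unparseable numeric in column %s, rows %s", v,
                     paste(head(bad, 5), collapse = ", ")))
      }
      x[[v]] <- num
    }
  }
  for (v in cohort_binary_covariates()) {
    vals <- x[[v]]
    bad <- !is.na(vals) & !vals %in% c("yes", "no")
    if (any(bad)) {
      stop(sprintf("column %s has values outside {yes, no, missing}", v))
    }
  }
  x$id <- as.character(x$id)
  x
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: missing tristate values are written as empty
#' cells, so a write/read round trip is the identity on the schema columns.
#'
#' @param participants Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(participants, path) {
  write.csv(participants, path, row.names = FALSE, na = "")
  invisible(path)
}
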