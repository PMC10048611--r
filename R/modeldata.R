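# Helpers bridging the cohort schema and the modelling functions: numeric
# encoding of tristate covariates and alignment of simulated genotypes.

#' Encode cohort covariates for modelling
#'
#' Converts the tristate (`yes`/`no`/missing) covariates to 0/1 numerics,
#' `sex` to a `sex_male` indicator, adds the binary outcome
#' `hldl` (1 = HLDL case), and carries continuous covariates through
#' unchanged (entered per-unit).
#'
#' @param cohort Cohort data frame with a `group` column.
#' @param variables Columns to encode/carry (default: all schema
#'   covariates plus any genotype `gt_*` columns).
#' @return Data frame with `hldl` plus numeric predictor columns.
#' @export
encode_covariates <- function(cohort, variables = NULL) {
  if (is.null(variables)) {
    variables <- c(cohort_continuous_covariates(), "sex_male",
                   cohort_binary_covariates(),
                   grep("^gt_", names(cohort), value = TRUE))
  }
  out <- data.frame(hldl = as.integer(cohort$group == "HLDL"))
  for (v in variables) {
    col <- if (v == "sex_male") {
      ifelse(is.na(cohort$sex), NA_real_,
             as.numeric(cohort$sex == "male"))
    } else if (!v %in% names(cohort)) {
      stop("variable absent from cohort: ", v)
    } else if (is.numeric(cohort[[v]])) {
      cohort[[v]]
    } else {
      ifelse(is.na(cohort[[v]]), NA_real_,
             as.numeric(cohort[[v]] == "yes"))
    }
    out[[v]] <- col
  }
  out
}

#' Attach a simulated genotype to a synthetic cohort
#'
#' Draws one marker with [generate_genotypes()] for the cohort's group
#' sizes and appends it as a carrier-indicator column `gt_<name>` (1 = any
#' non-reference genotype, the default coding of the validation analyses)
#' or as an allele-count column when `coding = "additive"`.
#'
#' @param cohort Synthetic cohort data frame (`group` column).
#' @param spec A [genotype_spec()].
#' @param name Marker name (column becomes `gt_<name>`).
#' @param coding `"carrier"` (indicator vs reference genotype, default) or
#'   `"additive"` (0/1/2 copies).
#' @return The cohort with the genotype column appended.
#' @export
add_genotype <- function(cohort, spec, name = "variant",
                         coding = c("carrier", "additive")) {
  coding <- match.arg(coding)
  n1 <- sum(cohort$group == "HLDL")
  n0 <- sum(cohort$group == "LLDL")
  g <- generate_genotypes(n1, n0, spec)
  val <- if (coding == "carrier") as.integer(g$copies > 0) else g$copies
  col <- integer(nrow(cohort))
  col[cohort$group == "HLDL"] <- val[g$phenotype == 1]
  col[cohort$group == "LLDL"] <- val[g$phenotype == 0]
  cohort[[paste0("gt_", name)]] <- col
  cohort
}
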