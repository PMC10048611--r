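# Seeded genotype generator for a single marker under retrospective
# case-control sampling: controls follow Hardy-Weinberg at the stated MAF,
# cases are drawn from the HWE distribution tilted by the genotype odds
# ratios, so the per-genotype sample odds ratio equals the target in
# expectation (this tilt is the exact retrospective sampling distribution of
# a logistic disease model when the comparison group is a population
# reference at HWE).

#' Hardy-Weinberg genotype probabilities
#'
#' @param maf Risk/minor allele frequency in (0, 1).
#' @return Numeric vector `(p0, p1, p2)` of probabilities for 0, 1, 2 copies.
#' @export
#' @examples
#' hwe_probs(0.2)  # 0.64 0.32 0.04
hwe_probs <- function(maf) {
  stopifnot(maf > 0, maf < 1)
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Specify a single-marker genotype effect
#'
#' @param maf Risk allele frequency in (0, 1).
#' @param effect_or Odds ratio: under `model = "additive"` a scalar
#'   per-allele OR (genotype OR is `effect_or^k` for k copies); under
#'   `model = "genotypic"` a scalar carrier OR applied to both heterozygote
#'   and homozygote, or a length-2 vector `(OR_het, OR_hom)`.
#' @param model `"additive"` or `"genotypic"`.
#' @param hwe If `TRUE` (default) control genotypes follow Hardy-Weinberg
#'   proportions at `maf`.
#' @param seed Integer seed.
#' @return A `genotype_spec` object.
#' @export
genotype_spec <- function(maf, effect_or, model = c("additive", "genotypic"),
                          hwe = TRUE, seed = 1L) {
  model <- match.arg(model)
  stopifnot(maf > 0, maf < 1, all(effect_or > 0), all(is.finite(effect_or)))
  if (model == "additive" && length(effect_or) != 1L) {
    stop("additive model takes a scalar per-allele effect_or")
  }
  if (model == "genotypic" && !length(effect_or) %in% 1:2) {
    stop("genotypic model takes 1 or 2 odds ratios")
  }
  structure(
    list(maf = maf, effect_or = effect_or, model = model, hwe = hwe,
         seed = as.integer(seed)),
    class = "genotype_spec"
  )
}

genotype_or_vector <- function(spec) {
  if (spec$model == "additive") {
    spec$effect_or^(0:2)
  } else {
    or <- rep(spec$effect_or, length.out = 2L)
    c(1, or)
  }
}

#' Generate case-control genotypes for one marker
#'
#' Controls are drawn from Hardy-Weinberg proportions at `spec$maf`; cases
#' from the same distribution tilted by the per-genotype odds ratios, so
#' that each genotype's odds ratio versus the reference genotype equals the
#' specified effect in expectation.
#'
#' @param n_case,n_control Group sizes.
#' @param spec A [genotype_spec()].
#' @return Data frame with columns `phenotype` (1 = case, 0 = control),
#'   `copies` (0/1/2 risk-allele copies) and `genotype`
#'   (`"ref"`/`"het"`/`"hom"`).
#' @export
#' @examples
#' g <- generate_genotypes(300, 300, genotype_spec(0.2, 1.8, seed = 11))
#' table(g$genotype, g$phenotype)
generate_genotypes <- function(n_case, n_control, spec) {
  stopifnot(inherits(spec, "genotype_spec"), n_case > 0, n_control > 0)
  p_ctrl <- hwe_probs(spec$maf)
  tilt <- p_ctrl * genotype_or_vector(spec)
  p_case <- tilt / sum(tilt)
  withr::with_seed(spec$seed, {
    g_case <- sample(0:2, n_case, replace = TRUE, prob = p_case)
    g_ctrl <- sample(0:2, n_control, replace = TRUE, prob = p_ctrl)
  })
  copies <- c(g_case, g_ctrl)
  data.frame(
    phenotype = rep(c(1L, 0L), c(n_case, n_control)),
    copies = copies,
    genotype = c("ref", "het", "hom")[copies + 1L],
    stringsAsFactors = FALSE
  )
}
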