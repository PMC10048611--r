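# Case-control genetic sample-size calculation under an additive
# (log-odds) model with perfect (or r2-deflated) linkage disequilibrium
# between risk and marker allele.

#' Specify a genetic power calculation
#'
#' The additive model acts on the log-odds scale: each risk-allele copy
#' multiplies the disease odds by `genetic_risk_ratio`. Controls are a
#' population reference in Hardy-Weinberg proportions at `maf`; the case
#' allele distribution is the HWE distribution tilted by the per-allele
#' odds — the same retrospective sampling model as
#' [generate_genotypes()], so simulated power at the returned sample size
#' matches the target. `prevalence` fixes the intercept of the underlying
#' disease model (it does not alter the case/control allele contrast under
#' this sampling design).
#'
#' @param genetic_risk_ratio Per-allele odds ratio (> 0; 1 means no
#'   effect).
#' @param maf Risk allele frequency in (0, 1).
#' @param prevalence Disease prevalence in (0, 1) (study default 0.477).
#' @param power Target power in (0, 1).
#' @param alpha Two-sided type-I error rate.
#' @param ld r-squared between risk and marker allele (1 = perfect LD).
#' @return A `power_spec` object.
#' @export
power_spec <- function(genetic_risk_ratio, maf, prevalence = 0.477,
                       power = 0.80, alpha = 0.05, ld = 1.0) {
  stopifnot(genetic_risk_ratio > 0, maf > 0, maf < 1,
            prevalence > 0, prevalence < 1, power > 0, power < 1,
            alpha > 0, alpha < 1, ld > 0, ld <= 1)
  structure(
    list(genetic_risk_ratio = genetic_risk_ratio, maf = maf,
         prevalence = prevalence, power = power, alpha = alpha,
         model = "additive", ld = ld),
    class = "power_spec"
  )
}

case_control_allele_freqs <- function(spec) {
  p0 <- spec$maf
  or <- spec$genetic_risk_ratio
  p1 <- p0 * or / ((1 - p0) + p0 * or)  # case allele odds = OR x control
  list(p_case = p1, p_control = p0)
}

#' Required sample size per group
#'
#' Smallest n per group giving the target power for the allele-based
#' two-proportion normal-approximation test (2n alleles per group) at the
#' specified alpha; ceiling-rounded and deflated by the LD r-squared. A
#' risk ratio of 1 has no detectable contrast and returns `Inf`.
#'
#' @param spec A [power_spec()].
#' @return Integer count per group (`Inf` for a null effect).
#' @export
#' @examples
#' required_n(power_spec(14.78, 0.0056))  # rare, large-effect allele
#' required_n(power_spec(1.77, 0.190))    # common, modest-effect allele
required_n <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  f <- case_control_allele_freqs(spec)
  diff <- f$p_case - f$p_control
  if (abs(diff) < .Machine$double.eps^0.5) return(Inf)
  pbar <- (f$p_case + f$p_control) / 2
  za <- qnorm(1 - spec$alpha / 2)
  zb <- qnorm(spec$power)
  m_alleles <- (za * sqrt(2 * pbar * (1 - pbar)) +
                  zb * sqrt(f$p_case * (1 - f$p_case) +
                              f$p_control * (1 - f$p_control)))^2 / diff^2
  as.integer(ceiling(m_alleles / (2 * spec$ld)))
}

#' Analytic power at a given sample size
#'
#' @param spec A [power_spec()].
#' @param n Sample size per group.
#' @return Power of the allele-based two-proportion test.
#' @export
power_at_n <- function(spec, n) {
  f <- case_control_allele_freqs(spec)
  m <- 2 * n * spec$ld
  se <- sqrt((f$p_case * (1 - f$p_case) +
                f$p_control * (1 - f$p_control)) / m)
  se0 <- sqrt(2 * mean(c(f$p_case, f$p_control)) *
                (1 - mean(c(f$p_case, f$p_control))) / m)
  za <- qnorm(1 - spec$alpha / 2)
  pnorm((abs(f$p_case - f$p_control) - za * se0) / se)
}

#' Simulated power at a given sample size
#'
#' Draws replicate case-control samples with [generate_genotypes()]
#' (additive model at the spec's MAF and odds ratio) and applies the
#' allele-count two-proportion z-test at the spec's alpha.
#'
#' @param spec A [power_spec()].
#' @param n Sample size per group.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @return Empirical rejection fraction.
#' @export
simulate_power <- function(spec, n, reps = 2000L, seed = 1L) {
  gs <- genotype_spec(spec$maf, spec$genetic_risk_ratio, model = "additive")
  za <- qnorm(1 - spec$alpha / 2)
  withr::with_seed(seed, {
    rej <- vapply(seq_len(reps), function(i) {
      gs$seed <- sample.int(.Machine$integer.max, 1L)
      g <- generate_genotypes(n, n, gs)
      a1 <- sum(g$copies[g$phenotype == 1])
      a0 <- sum(g$copies[g$phenotype == 0])
      p1 <- a1 / (2 * n)
      p0 <- a0 / (2 * n)
      pb <- (a1 + a0) / (4 * n)
      if (pb == 0 || pb == 1) return(FALSE)
      z <- (p1 - p0) / sqrt(2 * pb * (1 - pb) / (2 * n))
      abs(z) > za
    }, logical(1))
    mean(rej)
  })
}
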