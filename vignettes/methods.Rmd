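---
title: "Methods: tiered variant triage and case-control risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered variant triage and case-control risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhtriage)
```

# The study design this package models

`fhtriage` implements a two-stage analysis of hypercholesterolemia in a
nested case-control design built from phenotype extremes of a population
cohort. In the **discovery stage**, a small number of participants with the
most extreme lipid values — a high-LDL case group ("HLDL": LDL-C > 4.9
mmol/L **and** TC > 7.5 mmol/L, Simon Broome-derived cut-offs) and a
low-LDL control group ("LLDL": TC < 5.2 mmol/L with LDL-C in 2.6–3.4
mmol/L) — are exome-sequenced, and their annotated variant call sets are
pushed through a filtering cascade. In the **validation stage**, a panel of
surviving variants is genotyped in a larger cohort (338 cases vs 339
controls in the design we default to) and analysed with crude odds ratios,
multivariable logistic models, and gene–environment interaction tests.

Everything downstream of sequencing and annotation is in scope: the
package consumes VCF 4.2 plus ANNOVAR-style annotation tables, never raw
reads, and treats pathogenicity predictor outputs (SIFT, PolyPhen-2,
MutationTaster, FATHMM) and ClinVar categories as given annotation
columns.

# Extreme-phenotype selection

`classify_eligibility()` applies the two windows above; the HLDL rule
conjoins both cut-offs (the two criteria are always quoted together for
case definition), and the windows are mutually exclusive by construction.
`select_extremes()` ranks eligible participants by LDL-C — the primary
lipid of the design — with ties broken by TC and then lexicographically by
participant id, so selection is a deterministic function of the input.
When fewer than `k_per_arm` participants are eligible the function fails
loudly, naming the shortfall. Because the original report does not state
whether the validation arm reused the discovery thresholds verbatim, the
criteria are a configurable object rather than constants.

# The triage cascade

`prioritize_cascade()` applies, in order:

1. **Exonic filter** — non-exonic calls are dropped.
2. **Synonymous filter** — synonymous SNVs are dropped.
3. **Deleteriousness filter** — a variant is dropped only when SIFT says
   *tolerated* **and** PolyPhen-2 says *benign*. The AND rule is this
   package's operationalisation: the source protocol names both tools and
   says variants "with tolerable effects" were removed, without stating a
   combination rule; requiring both tools to exonerate a variant is the
   conservative reading. Truncating classes (frameshift,
   stop-gain/stop-loss) bypass the filter because the predictors are
   undefined for them, and *missing* predictions never cause removal —
   unknown tool strings are harmonized to "missing", never silently to
   damaging. MutationTaster, FATHMM and ClinVar are carried as report
   columns, not filters: in the protocol they assess already-shortlisted
   variants.
4. **FH-gene tier filter** — variants outside the configured tier-1/2/3
   panels are dropped. Tier 1 (`LDLR`, `APOB`, `PCSK9`, `LDLRAP1`) is
   directly causal for familial hypercholesterolemia; tier 2 genes
   regulate LDL; tier 3 covers other lipid-implicated genes. The full
   published tier-2/3 universes are cited to external gene lists that are
   not enumerated in the report, so the shipped defaults are exactly the
   genes named in its tables; anything wider must be configured
   explicitly (`tier3 = "complement"` with a user universe is supported).
5. **Case-exclusivity** — variants carried only by HLDL samples are
   *risk-increasing* (causative), only by LLDL samples *risk-reducing*
   (protective); anything carried in both groups (or neither) is dropped.
   A carrier is any sample with a non-reference genotype at the allele;
   dosage is not modelled in discovery.
6. **Tier-3 high-frequency rule** — among tier-3 risk-increasing
   variants only those with strictly more than 10 HLDL carriers, at
   least 40% of the group, and zero LLDL carriers are retained. The
   strict `> 10` matches the printed "(>10 individuals/variant, ≥40%)"
   convention.

Filters 1–3 key on disjoint predicates and therefore commute — a property
the test suite checks by permuting their order. Each stage logs
input/removed/surviving counts, and the telescoping identity is asserted
in tests.

Ranking (`rank_class_priority()`) is stable and lexicographic: tier, then
class priority (1 = frameshift/stop-gain/stop-loss, 2 = non-synonymous
SNV, 3 = non-frameshift indel/substitution), then carrier count
descending, then position. How exactly the original study narrowed its
(76 + 56 + 16 risk-increasing, 108 risk-reducing) discovery survivors to
a 27 + 18 genotyping panel is unstated; `select_validation_panel()`
documents this ranking as the package's own deterministic convention.

# Association statistics

`crude_or()` computes the cross-product odds ratio with
`SE(lnOR) = sqrt(1/a + 1/b + 1/c + 1/d)`, a 95% CI as
`exp(lnOR ± 1.96·SE)` (1.96 exactly — this reproduces the published
intervals at 2 decimal places), and a **Wald** chi-squared
`(lnOR/SE)²` on 1 df. The Wald form, not Pearson's, is what the published
univariable table prints: for the tobacco row (102/228 vs 70/260) the
Wald statistic is 7.98 where Pearson's would be 8.05. Zero cells are an
error by default; an explicit Haldane–Anscombe 0.5 correction is
available. `bonferroni_threshold(0.05, 27)` gives the panel-wide 0.002
threshold.

Two printed confidence bounds in the source univariable table are
internally inconsistent with their own OR and chi-squared (family history
of hyperlipidemia, lower bound printed 1.20 where the row's lnOR/SE give
1.10; obesity-with-medication, printed 0.42 where they give 0.41), and
one p-value (family history of stroke, chi-squared 1.87 printed with
p 0.704 rather than ≈0.17) is a typographical slip; the package
reproduces the self-consistent values and does not chase the typos. The
fasting-glucose rows are treated as mmol/L throughout: the printed values
(≈6.5–7.2) are physiologically plausible only on that scale, although one
table labels them "mg/L".

`univariable_table()` analyses each covariate on its own complete cases,
so per-variable denominators vary exactly as they do in a design with
per-item questionnaire missingness. Continuous covariates are entered
untransformed per unit (per year, per mmol/L); k-unit contrasts (e.g.
per 5 years, `OR^5`) are a reporting option in
`round_model_summary()`, not a refit.

# Logistic risk models

`fit_logistic()` wraps the standard IRLS maximum-likelihood fit and
exposes the quantities the analysis needs: coefficients, observed-
information SEs, fitted probabilities, and the fitted and null
log-likelihoods. Rank deficiency is an error naming the collinear
columns. Quasi-complete separation is detected (fitted probabilities at
the boundary together with runaway coefficients) and flagged; the
reporting layer then suppresses the affected CIs rather than printing
meaningless ±thousands intervals.

*Nagelkerke pseudo-R²* rescales Cox–Snell
`1 − exp(2(ll₀ − ll₁)/n)` by its maximum `1 − exp(2·ll₀/n)`.
*AUROC* is the Mann–Whitney statistic (ties ½) — the probability a random
case outscores a random control — with a 95% CI from the DeLong placement
variance, truncated to [0, 1]; the implementation is cross-checked in the
test suite against both exhaustive pair counting and the `pROC`
reference.

`backward_select()` builds the parsimonious model: predictors with Wald
p ≥ 0.20 are candidates for removal, worst first, but a removal that
shifts any remaining predictor coefficient by more than 15% (relative) is
vetoed and the confounder locked in. The 0.20 screening threshold is the
protocol's; the 15% change-in-estimate tolerance is the standard
epidemiologic heuristic, made explicit and configurable because the
protocol only says removals must cause "no substantive changes". The
intercept is excluded from the change-in-estimate comparison — it
re-centres freely whenever a covariate leaves and carries no confounding
information. Note one statistical fact the tests encode: a pure-noise
predictor has a uniform p-value under the null, so with a 0.20 threshold
backward selection removes it in ~80% of datasets, not more.

`delta_r2()` gives the increment in Nagelkerke R² from adding genetic
predictors to a clinical model. It refuses fits computed on different
complete-case rows — otherwise the "increment" would confound predictor
information with sample composition — so callers align on common cases
first. Whether the original three published models shared one
complete-case subset is unstated; this package enforces alignment.

`interaction_test()` fits the mains-plus-product logistic model and
returns the Wald p of the product term, flagging inestimable products
(empty exposure cells) instead of returning a spurious number.

The published multivariable coefficients themselves (e.g. adjusted OR
16.60 for the *OSBPL7* frameshift carrier, Nagelkerke R² 0.11 → 0.20)
are **not** reproducible without the real individual-level cohort; the
package's test surface is instead property-based — on synthetic cohorts
with a planted carrier OR of 16.89 at the validation carrier regime
(~1.2% control carrier frequency), the reported genotype CI covers the
truth at its nominal rate and the R² increment is positive essentially
always, with a median increment of ~0.10, consistent in magnitude with
the published 0.11 → 0.20 shift.

# Synthetic data: what it emulates and what it does not

`generate_cohort()` has two modes. **Exact mode** reproduces requested
per-group yes/no/missing counts bit-for-bit, randomising only the
assignment of values to participants, so every published 2×2 marginal is
recovered exactly — `table1_cohort_spec()` ships the validation-cohort
marginals (e.g. tobacco 102/228 vs 70/260 with 8 + 9 missing) as
defaults. **Stochastic mode** draws per-group Bernoulli/Normal values.
Continuous covariates are truncated Normals (ages rejected outside the
35–70 inclusion window); lipids are drawn inside each arm's eligibility
window so derived group labels agree with the design.

`generate_genotypes()` draws control genotypes from exact Hardy–Weinberg
proportions at the stated MAF and case genotypes from the same
distribution tilted by the per-genotype odds (`OR^k` per allele copy
under the additive model). This tilt is the exact retrospective sampling
distribution of a logistic disease model when the comparison group is a
population reference — it fixes both required properties at once:
controls are exactly HWE, and every genotype's case-control odds ratio
equals its target in expectation. The generator intentionally does **not**
simulate linkage-disequilibrium structure (beyond the perfect-LD
assumption of the power model), genotyping error, or
covariate-genotype correlation; passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to artefacts of real genotyping.

`generate_callset()` plants tiered case-exclusive variants whose
annotations survive the cascade by construction, plus decoys that each
violate exactly one named filter (synonymous; tolerated-and-benign;
carried in both groups; non-exonic), and emits the expected survivor set
as ground truth. The test suite closes the loop three ways: generator
ground truth, the package cascade, and an independently written
brute-force predicate walk must all agree on every random call set.

All generators draw through one seeded RNG scope per call
(`withr::with_seed`), leaving global RNG state untouched: identical
spec + seed means byte-identical output.

# Sample-size calculation

`required_n()` sizes the allele-based two-proportion
normal-approximation test: controls contribute allele frequency `maf`;
cases contribute the tilted frequency `maf·OR / (1 − maf + maf·OR)`
(per-allele odds multiplied by the genetic risk ratio, i.e. the additive
log-odds model); with 2n alleles per group,
`n = (z_{1−α/2}√(2p̄q̄) + z_{power}√(p₁q₁ + p₀q₀))² / (2·(p₁−p₀)²)`,
ceiling-rounded and inflated by 1/r² under imperfect LD. Prevalence is
carried in the specification — it fixes the intercept of the underlying
disease model — but cancels from the case/control allele contrast under
this case-enrichment sampling design. We considered the alternative of
conditioning controls on being non-diseased at 47.7% prevalence and
rejected it: at a rare MAF it collapses the absolute allele-frequency
contrast and makes the required n for a rare large-effect allele *larger*
than for a common modest one, inverting the published ordering (22 ≪
184). The adopted model is also exactly the generator's sampling scheme,
so simulated power at the returned n hits the 80% target; the published
22 and 184 (computed with an uncited method) are treated as ordering and
order-of-magnitude anchors, which the adopted computation (61 and 135
per group) respects.

# Numerical conventions and problem sizes

* 1.96 exactly for all 95% intervals; report rounding is 2 dp for
  ORs/CIs/chi-squared and 3 dp for p-values, with full precision kept
  internally.
* Logistic fits use the standard IRLS convergence criterion; the
  coefficient of a one-predictor fit on a 2×2 agrees with the closed-form
  cross-product OR to better than 6 significant digits.
* Genotype predictors default to indicator-vs-reference coding (the
  published per-genotype layout); additive allele-count coding is an
  option.
* Stochastic test surfaces use fixed seeds and modest replicate counts
  chosen to keep the whole suite fast while leaving binomial noise well
  inside the asserted bands: 500 replicates for CI coverage of the
  planted large-effect variant, 1000 for interaction-test type-I error,
  2000 for CI coverage of the null OR and for simulated power, 100
  random call sets for cascade/oracle equivalence.

# Known limitations

* The cascade consumes annotation tables as given; it does not re-derive
  pathogenicity, parse HGVS strings, or lift coordinates.
* Depth-based QC (the 50× germline-coverage rule) is upstream of this
  package; call sets are taken as depth-qualified.
* Fisher exact and Mantel–Haenszel estimators are deliberately absent —
  the analysis this package reproduces uses Wald statistics throughout.
* The power model is single-marker; no haplotype or multi-marker designs.
* Synthetic cohorts draw covariates independently of one another and of
  genotype; real cohorts have correlation structure the generator does
  not emulate.
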