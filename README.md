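# fhtriage

Tiered exome-variant triage and case-control risk modelling for
hypercholesterolemia studies.

## The problem

Nested case-control studies of hypercholesterolemia compare phenotype
extremes drawn from a population cohort: a high-LDL case group (**HLDL**,
LDL-C > 4.9 mmol/L and total cholesterol > 7.5 mmol/L, Simon
Broome-derived cut-offs) against a low-LDL control group (**LLDL**,
TC < 5.2 mmol/L, LDL-C 2.6–3.4 mmol/L). The analysis then runs in two
stages:

1. **Discovery.** Annotated exome variant call sets from the extremes are
   filtered through a cascade — exonic only, synonymous SNVs removed,
   variants predicted tolerable by *both* SIFT and PolyPhen-2 removed,
   restriction to tiered familial-hypercholesterolemia (FH) gene panels
   (tier 1: *LDLR*, *APOB*, *PCSK9*, *LDLRAP1*; tier 2: LDL-regulating
   genes; tier 3: other lipid-implicated genes) — and classified by
   case-exclusivity: variants carried only by HLDL samples are
   risk-increasing (causative), only by LLDL samples risk-reducing
   (protective). Tier-3 risk-increasing variants additionally need
   > 10 carriers and ≥ 40% of the case group.
2. **Validation.** A panel of surviving variants is genotyped in a larger
   cohort and analysed with crude odds ratios from 2×2 tables
   (OR = ad/bc, Wald χ² = (lnOR/SE)², SE = √(1/a+1/b+1/c+1/d),
   Bonferroni-corrected thresholds α/m), multivariable logistic models
   selected backwards at p ≥ 0.20 with a 15% change-in-estimate guard,
   Nagelkerke pseudo-R², AUROC with DeLong 95% CI, gene–environment
   multiplicative interaction tests, and additive-model genetic
   sample-size calculations.

`fhtriage` implements both stages as composable R functions, plus seeded
synthetic-data generators (cohorts, genotypes, annotated call sets with
planted ground truth) so the whole pipeline is testable without access to
individual-level data. It is aimed at genetic-epidemiology analysts who
want the published analysis surface as reusable, tested code.

## Worked example

Generate the validation cohort at its published marginal counts, run the
univariable analysis, and fit the combined clinical + genetic model:

```r
library(fhtriage)

co  <- generate_cohort(table1_cohort_spec(seed = 1))
tab <- univariable_table(co)
round_association_table(
  tab[tab$variable %in% c("age_years", "tobacco_ever",
                          "dm_on_medication", "famhx_hyperlipidemia"), ])
#>              variable       kind n_hldl n_lldl   or ci_low ci_high wald_chi2 df p_value
#>             age_years continuous    338    339 1.04   1.02    1.07     11.30  1   0.001
#>          tobacco_ever     binary    330    330 1.66   1.17    2.36      7.98  1   0.005
#>      dm_on_medication     binary    337    339 0.62   0.42    0.91      5.97  1   0.015
#>  famhx_hyperlipidemia     binary    337    339 2.44   1.10    5.40      4.81  1   0.028
```

Tobacco use carries 1.66-fold odds of hypercholesterolemia (Wald χ² 7.98,
p = 0.005); diabetes on medication is protective (OR 0.62); the
per-variable denominators differ because each covariate is analysed on
its own complete cases. The same numbers come straight from the 2×2:

```r
crude_or(two_by_two(102, 228, 70, 260))
#> OR 1.66 (95% CI 1.17, 2.36), Wald chi2 7.98 (1 df), p 0.00473
```

Discovery: generate a synthetic call set (planted case-exclusive variants
plus filter-violating decoys), run the cascade, and inspect the tier-1
report:

```r
cs       <- generate_callset(callset_plan(seed = 1))
files    <- write_callset(cs, tempdir())
variants <- read_callset(files$vcf, files$annotation, cs$sample_groups)
res      <- prioritize_cascade(variants)
head(build_reports(res$survivors)$tier1[, c("gene", "variant_type",
                                            "n_hldl", "n_lldl", "novel")])
#>   gene   variant_type n_hldl n_lldl novel
#>   APOB   stopgain_snv      2      0  TRUE
#>  PCSK9 frameshift_del      2      0  TRUE
#>  PCSK9 frameshift_del      2      0  TRUE
#>   LDLR   stopgain_snv      2      0  TRUE
```

Frameshift/stop variants lead the report, carriers are case-exclusive,
and `res$audit` logs per-stage counts (here 26 in, 3 non-exonic decoys
removed at the first stage, 15 final survivors — exactly the generator's
planted ground truth).

Validation model with a planted large-effect carrier variant
(OR 16.89 at ~1.2% control carrier frequency):

```r
co2 <- add_genotype(co, genotype_spec(0.0059, 16.89, model = "genotypic",
                                      seed = 2), "osbpl7_fs")
d <- encode_covariates(co2)
d <- d[complete.cases(d[c("hldl", "age_years", "fasting_glucose_mmol_l",
                          "tobacco_ever", "dm_on_medication",
                          "famhx_hyperlipidemia", "gt_osbpl7_fs")]), ]
plus <- fit_logistic(d, hldl ~ age_years + fasting_glucose_mmol_l +
                       tobacco_ever + dm_on_medication +
                       famhx_hyperlipidemia + gt_osbpl7_fs)
plus
#> Logistic fit: n = 658, logLik = -400.323 (null -456.088)
#>                predictor   aor ci_low ci_high p_value
#> 1              age_years  1.04   1.01    1.06   0.007
#> 2 fasting_glucose_mmol_l  1.14   1.07    1.22   0.000
#> 3           tobacco_ever  1.80   1.24    2.63   0.002
#> 4       dm_on_medication  0.64   0.42    0.98   0.040
#> 5   famhx_hyperlipidemia  2.19   0.89    5.41   0.089
#> 6           gt_osbpl7_fs 18.59   6.59   52.46   0.000
#> Nagelkerke R2 = 0.208; AUC = 0.715 (95% CI 0.677, 0.754)
```

The carrier variant multiplies the odds ~19-fold in this draw (truth:
16.89) and lifts the Nagelkerke R² of the clinical-only model by 0.11
(`delta_r2()`). Sample-size planning for a common modest-effect marker:

```r
required_n(power_spec(1.77, 0.190))   # per-allele OR 1.77, MAF 0.19
#> [1] 135
```

A command-line wrapper over the same functions (subcommands `simulate`,
`prioritize`, `associate`, `model`, `power`, each writing a JSON run
manifest) is installed at `inst/cli/fhtriage`.

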