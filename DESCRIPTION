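Package: fhtriage
Title: Tiered Exome-Variant Triage and Case-Control Risk Modelling for
    Hypercholesterolemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-stage analysis pipeline for nested case-control studies
    of hypercholesterolemia. The discovery stage triages annotated
    whole-exome variant call sets through a filtering cascade (exonic,
    non-synonymous, deleteriousness by SIFT/PolyPhen-2) and classifies
    case-exclusive variants as risk-increasing or risk-reducing across
    tiered familial-hypercholesterolemia gene panels (tier 1: LDLR, APOB,
    PCSK9, LDLRAP1). The validation stage provides crude odds ratios with
    Wald tests and Bonferroni correction, multivariable logistic risk
    models with backward selection, Nagelkerke pseudo-R-squared, AUROC
    with DeLong confidence intervals, gene-environment interaction tests,
    and additive-model genetic sample-size calculation. Seeded synthetic
    cohort and call-set generators reproduce the statistical structure the
    analysis assumes, so the whole pipeline is testable without access to
    individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
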