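# Independent oracles, written directly from the predicate/statistic
# definitions and kept free of the package's own code paths.

# Brute-force triage cascade: plain per-variant predicate walk.
bf_cascade_keep <- function(ann, n_hldl, n_lldl, n_group_h = 25,
                            cfg = tier_config(),
                            min_carriers = 10, min_fraction = 0.40) {
  truncating <- c("frameshift_del", "frameshift_ins", "stopgain_snv",
                  "stoploss_snv")
  keep <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    fc <- ann$func_class[i]
    if (fc == "non_exonic") next
    if (fc == "synonymous_snv") next
    if (!fc %in% truncating &&
        identical(ann$sift[i], "tolerated") &&
        identical(ann$polyphen[i], "benign")) next
    g <- ann$gene[i]
    tier <- if (g %in% cfg$tier1) 1L else if (g %in% cfg$tier2) 2L else
      if (g %in% cfg$tier3) 3L else next
    nh <- n_hldl[i]
    nl <- n_lldl[i]
    dir <- if (nh >= 1 && nl == 0) "risk_increasing" else
      if (nl >= 1 && nh == 0) "risk_reducing" else next
    if (tier == 3L && dir == "risk_increasing" &&
        !(nh > min_carriers && nh / n_group_h >= min_fraction && nl == 0)) {
      next
    }
    keep[i] <- TRUE
  }
  keep
}

# Brute-force AUC: exhaustive case-control pair counting, ties 1/2.
bf_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  }
  tot / (length(x) * length(y))
}

# Coarse grid-search maximiser of the binomial log-likelihood for a
# one-predictor logistic model (intercept + slope).
bf_logistic_grid <- function(y, x, b0_range = c(-4, 4),
                             b1_range = c(-4, 4), steps = 3L) {
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  best <- c(mean(b0_range), mean(b1_range))
  width <- c(diff(b0_range), diff(b1_range)) / 2
  for (s in seq_len(steps + 5L)) {
    b0s <- seq(best[1] - width[1], best[1] + width[1], length.out = 41)
    b1s <- seq(best[2] - width[2], best[2] + width[2], length.out = 41)
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    vals <- mapply(ll, grid$b0, grid$b1)
    best <- unlist(grid[which.max(vals), ])
    width <- width / 8
  }
  best
}

# Random small annotated-variant tables exercising every cascade branch.
random_variant_table <- function(n, n_h = 25, n_l = 25) {
  fc <- sample(func_classes(), n, replace = TRUE)
  genes <- sample(c(tier_config()$tier1, tier_config()$tier2,
                    tier_config()$tier3, "ZZZ1", "ZZZ2"), n, replace = TRUE)
  nh <- sample(0:n_h, n, replace = TRUE)
  nl <- ifelse(runif(n) < 0.5, 0L, sample(0:n_l, n, replace = TRUE))
  data.frame(
    chrom = as.character(sample(1:22, n, TRUE)),
    pos = sample.int(1e7, n), ref = "A", alt = "T",
    gene = genes, transcript = "NM_1.1", hgvs_c = "c.1A>T",
    hgvs_p = "p.X1", func_class = fc,
    dbsnp_id = ifelse(runif(n) < 0.5, NA, "rs1"),
    known_in_databases = runif(n) < 0.5,
    sift = sample(c("damaging", "tolerated", "missing"), n, TRUE),
    polyphen = sample(c("probably_damaging", "possibly_damaging", "benign",
                        "missing"), n, TRUE),
    mutation_taster = "missing", fathmm = "missing", clinvar = "",
    n_hldl = nh, n_lldl = nl,
    stringsAsFactors = FALSE
  )
}
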