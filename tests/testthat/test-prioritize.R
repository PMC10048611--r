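make_var <- function(func_class = "nonsynonymous_snv", gene = "LDLR",
                     sift = "damaging", polyphen = "probably_damaging",
                     n_hldl = 2L, n_lldl = 0L, chrom = "1", pos = 1000L) {
  data.frame(
    chrom = chrom, pos = pos, ref = "A", alt = "T", gene = gene,
    transcript = "NM_1.1", hgvs_c = "c.1A>T", hgvs_p = "p.X1",
    func_class = func_class, dbsnp_id = NA_character_,
    known_in_databases = FALSE, sift = sift, polyphen = polyphen,
    mutation_taster = "missing", fathmm = "missing", clinvar = "",
    n_hldl = n_hldl, n_lldl = n_lldl, stringsAsFactors = FALSE
  )
}

test_that("single-predicate filters remove exactly their targets", {
  v <- rbind(
    make_var("non_exonic"),
    make_var("synonymous_snv"),
    make_var("stopgain_snv", sift = "missing", polyphen = "missing"),
    make_var("nonsynonymous_snv", sift = "tolerated", polyphen = "benign"),
    make_var("nonsynonymous_snv", sift = "damaging", polyphen = "benign"),
    make_var("frameshift_del", sift = "missing", polyphen = "missing"),
    make_var("nonsynonymous_snv", sift = "missing", polyphen = "benign")
  )
  expect_equal(filter_exonic(v)$func_class,
               v$func_class[v$func_class != "non_exonic"])
  expect_equal(nrow(filter_exonic(v[0, ])), 0)
  expect_equal(filter_synonymous(v)$func_class,
               v$func_class[v$func_class != "synonymous_snv"])
  surv <- filter_tolerable(v)
  # only the tolerated-AND-benign non-synonymous record is removed;
  # missing predictions and truncating classes never cause removal
  expect_equal(nrow(surv), nrow(v) - 1)
  expect_false(any(surv$sift == "tolerated" & surv$polyphen == "benign" &
                     surv$func_class == "nonsynonymous_snv"))
})

test_that("exclusivity classification and its monotonicity", {
  expect_equal(classify_direction(c(2, 0, 1, 0), c(0, 3, 1, 0)),
               c("risk_increasing", "risk_reducing", "none", "none"))
  # adding an opposite-group carrier can only move direction to none
  withr::with_seed(9, {
    for (i in 1:50) {
      nh <- sample(0:25, 1)
      nl <- sample(0:25, 1)
      d0 <- classify_direction(nh, nl)
      d_inc <- classify_direction(nh, nl + 1L)
      if (d0 == "risk_increasing") expect_equal(d_inc, "none")
      if (d0 == "none" && nh > 0) expect_equal(d_inc, "none")
    }
  })
})

test_that("tier-3 high-frequency rule keeps only >10 carriers at >=40%", {
  v <- do.call(rbind, lapply(c(19L, 18L, 17L, 16L, 15L, 10L, 11L),
                             function(n) {
    out <- make_var("frameshift_del", gene = "WDR74", sift = "missing",
                    polyphen = "missing", n_hldl = n, pos = 1000L + n)
    out
  }))
  v$tier <- 3L
  v$direction <- "risk_increasing"
  kept <- filter_tier3_high_frequency(v, n_group = 25L)
  expect_setequal(kept$n_hldl, c(19L, 18L, 17L, 16L, 15L, 11L))
  # 11 of 40 fails the 40% fraction even though > 10 carriers
  expect_equal(filter_tier3_high_frequency(v, n_group = 40L)$n_hldl,
               c(19L, 18L, 17L, 16L))
  # a single LLDL carrier disqualifies
  v$n_lldl <- 1L
  expect_equal(nrow(filter_tier3_high_frequency(v, n_group = 25L)), 0)
  expect_error(filter_tier3_high_frequency(v, n_group = 0L), "positive")
})

test_that("ranking puts tiers, then truncating classes, first and is stable", {
  v <- rbind(
    make_var("nonsynonymous_snv", gene = "LDLR", pos = 5L),
    make_var("frameshift_del", gene = "OSBPL7", pos = 4L),
    make_var("frameshift_del", gene = "LDLR", pos = 3L),
    make_var("nonsynonymous_snv", gene = "OSBPL7", pos = 2L),
    make_var("nonsynonymous_snv", gene = "LDLR", pos = 1L)
  )
  v$class_priority <- class_priority(v$func_class)
  v$tier <- assign_tier(v$gene)
  r <- rank_class_priority(v)
  # tier 1 first; within tier, frameshift before non-synonymous
  expect_equal(r$gene, c("LDLR", "LDLR", "LDLR", "OSBPL7", "OSBPL7"))
  expect_equal(r$func_class[1], "frameshift_del")
  # identical keys preserve input order (stable)
  same <- rbind(make_var(pos = 10L), make_var(pos = 10L))
  same$ref <- c("A", "C")
  same$class_priority <- class_priority(same$func_class)
  same$tier <- assign_tier(same$gene)
  expect_equal(rank_class_priority(same)$ref, c("A", "C"))
})

test_that("cascade equals the brute-force predicate oracle on random tables", {
  for (s in 1:20) {
    withr::with_seed(1000 + s, {
      v <- random_variant_table(sample(20:120, 1))
    })
    res <- prioritize_cascade(v)
    keep <- bf_cascade_keep(v, v$n_hldl, v$n_lldl)
    expect_setequal(
      paste(res$survivors$chrom, res$survivors$pos, res$survivors$gene,
            res$survivors$func_class),
      paste(v$chrom, v$pos, v$gene, v$func_class)[keep]
    )
    # count bookkeeping: per-stage removed + survivors telescopes
    audit <- res$audit
    expect_equal(audit$exonic$input, nrow(v))
    for (st in names(audit)) {
      expect_equal(audit[[st]]$input - audit[[st]]$removed,
                   audit[[st]]$surviving)
    }
    expect_equal(audit$tier3_high_frequency$surviving,
                 nrow(res$survivors))
  }
})

test_that("the three annotation filters commute", {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  fns <- list(filter_exonic, filter_synonymous, filter_tolerable)
  for (s in 1:5) {
    withr::with_seed(2000 + s, v <- random_variant_table(80))
    ref <- filter_tolerable(filter_synonymous(filter_exonic(v)))
    for (p in perms) {
      out <- fns[[p[3]]](fns[[p[2]]](fns[[p[1]]](v)))
      expect_identical(out[order(out$pos), ], ref[order(ref$pos), ])
    }
  }
})

test_that("reports and panel selection mirror the ranked survivors", {
  cs <- generate_callset(callset_plan(
    planted = data.frame(
      tier = c(1L, 1L, 2L, 3L),
      direction = c("risk_increasing", "risk_reducing", "risk_increasing",
                    "risk_increasing"),
      n_variants = c(5L, 3L, 8L, 4L),
      n_carriers = c(2L, 3L, 6L, 15L)
    ), seed = 77))
  v <- as_annotated_variants(cs)
  res <- prioritize_cascade(v)
  reports <- build_reports(res$survivors)
  expect_named(reports, c("tier1", "tier2", "tier3"))
  expect_equal(sum(vapply(reports, nrow, 0L)), nrow(res$survivors))
  expect_equal(nrow(reports$tier1), 8)
  # frameshift/stop rows precede non-synonymous rows inside a tier
  cp <- class_priority(reports$tier1$variant_type)
  expect_true(all(diff(cp) >= 0))
  # novel flag: no dbSNP id and absent from the population databases
  expect_equal(reports$tier1$novel,
               is.na(reports$tier1$dbsnp_id) &
                 !cs$annotation$known_in_databases[
                   match(paste(reports$tier1$chrom, reports$tier1$pos),
                         paste(cs$annotation$chrom, cs$annotation$pos))])

  panel <- select_validation_panel(res$survivors, n_inc = 10L, n_red = 3L)
  expect_equal(nrow(panel), 13)
  inc <- res$survivors[res$survivors$direction == "risk_increasing", ]
  expect_equal(panel$pos[1:10], inc$pos[1:10])
  expect_error(select_validation_panel(res$survivors, n_inc = 99L),
               "available")

  # empty survivor set keeps headers
  empty <- build_reports(res$survivors[0, ])
  expect_equal(nrow(empty$tier1), 0)
  expect_true("gene" %in% names(empty$tier1))
})
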