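# Seeded synthetic call-set generator: plants tiered case-exclusive
# variants whose annotations survive the triage cascade, plus decoys that
# each violate exactly one named filter, and emits the expected survivor
# set as ground truth.

#' Plan a synthetic annotated call set
#'
#' @param planted Data frame with columns `tier` (1/2/3), `direction`
#'   (`"risk_increasing"` / `"risk_reducing"`), `n_variants` and
#'   `n_carriers` (carriers per variant, all in the exclusive group).
#' @param decoys Named counts of filter-violating decoys:
#'   `synonymous` (synonymous SNVs), `tolerated` (non-synonymous with
#'   SIFT tolerated and PolyPhen benign), `shared` (deleterious but carried
#'   in both groups, so direction "none"), `intronic` (non-exonic).
#' @param n_hldl,n_lldl Group sizes (discovery design default 25 vs 25).
#' @param config [tier_config()] supplying gene symbols per tier.
#' @param seed Integer seed.
#' @return A `callset_plan` object.
#' @export
callset_plan <- function(planted = data.frame(
                           tier = c(1L, 2L, 3L),
                           direction = "risk_increasing",
                           n_variants = c(4L, 6L, 5L),
                           n_carriers = c(2L, 6L, 16L)
                         ),
                         decoys = c(synonymous = 3L, tolerated = 3L,
                                    shared = 2L, intronic = 3L),
                         n_hldl = 25L, n_lldl = 25L,
                         config = tier_config(), seed = 1L) {
  stopifnot(is.data.frame(planted),
            all(c("tier", "direction", "n_variants", "n_carriers") %in%
                  names(planted)))
  stopifnot(all(planted$tier %in% 1:3),
            all(planted$direction %in% c("risk_increasing",
                                         "risk_reducing")),
            all(planted$n_variants >= 0), all(planted$n_carriers >= 1))
  dec <- c(synonymous = 0L, tolerated = 0L, shared = 0L, intronic = 0L)
  dec[names(decoys)] <- as.integer(decoys)
  if (any(dec < 0)) stop("negative decoy count")
  grp_size <- ifelse(planted$direction == "risk_increasing", n_hldl, n_lldl)
  if (any(planted$n_carriers > grp_size)) {
    stop("carrier count exceeds group size")
  }
  structure(
    list(planted = planted, decoys = dec, n_hldl = as.integer(n_hldl),
         n_lldl = as.integer(n_lldl), config = config,
         seed = as.integer(seed)),
    class = "callset_plan"
  )
}

bases <- c("A", "C", "G", "T")

random_alleles <- function(class) {
  r <- sample(bases, 1)
  switch(class,
    frameshift_del = list(ref = paste0(r, paste(sample(bases, 2, TRUE),
                                                collapse = "")), alt = r),
    frameshift_ins = list(ref = r, alt = paste0(r, sample(bases, 1))),
    nonframeshift_del = list(ref = paste0(r, paste(sample(bases, 3, TRUE),
                                                   collapse = "")), alt = r),
    nonframeshift_ins = list(ref = r, alt = paste0(r, paste(
      sample(bases, 3, TRUE), collapse = ""))),
    nonframeshift_sub = list(ref = paste(sample(bases, 3, TRUE),
                                         collapse = ""),
                             alt = paste(sample(bases, 3, TRUE),
                                         collapse = "")),
    # SNV classes
    {
      ref <- sample(bases, 1)
      list(ref = ref, alt = sample(setdiff(bases, ref), 1))
    }
  )
}

#' Generate a synthetic annotated call set
#'
#' Planted variants are case-exclusive (or control-exclusive for
#' risk-reducing plants) and carry annotations consistent with surviving
#' the triage cascade: exonic, non-synonymous/frameshift/stop-gain, and
#' damaging predictor calls for non-synonymous SNVs. Each decoy violates
#' exactly one named filter. The expected survivor set, derived by
#' construction (tier-3 risk-increasing plants survive only when they pass
#' the high-frequency rule), is emitted alongside as ground truth.
#'
#' @param plan A [callset_plan()].
#' @return List with `vcf_lines` (VCF 4.2 text), `annotation` (data frame),
#'   `sample_groups` (named vector), `truth` (data frame of planted/decoy
#'   bookkeeping incl. `expected_survivor`), and `seed`.
#' @seealso [write_callset()] to materialise files for [read_callset()].
#' @export
generate_callset <- function(plan) {
  stopifnot(inherits(plan, "callset_plan"))
  cfg <- plan$config
  samples_h <- sprintf("H%02d", seq_len(plan$n_hldl))
  samples_l <- sprintf("L%02d", seq_len(plan$n_lldl))
  sample_groups <- setNames(
    c(rep("HLDL", plan$n_hldl), rep("LLDL", plan$n_lldl)),
    c(samples_h, samples_l)
  )

  withr::with_seed(plan$seed, {
    recs <- list()
    add_rec <- function(gene, tier, func_class, sift, polyphen, carr_h,
                        carr_l, kind, expected) {
      al <- random_alleles(func_class)
      known <- func_class %in% c("synonymous_snv", "nonsynonymous_snv") &&
        runif(1) < 0.4
      recs[[length(recs) + 1L]] <<- list(
        chrom = as.character(sample(1:22, 1)),
        pos = sample(1e4:5e7, 1),
        ref = al$ref, alt = al$alt, gene = gene,
        transcript = sprintf("NM_%06d.1", sample(1e5:9e5, 1)),
        hgvs_c = sprintf("c.%dX", sample(10:5000, 1)),
        hgvs_p = sprintf("p.X%d", sample(5:1500, 1)),
        func_class = func_class,
        dbsnp_id = if (known) sprintf("rs%d", sample(1e6:1e8, 1)) else "",
        known_in_databases = known,
        sift = sift, polyphen = polyphen,
        mutation_taster = if (sift == "damaging") "disease_causing" else "",
        fathmm = sift,
        clinvar = if (known) sample(c("Pathogenic", "Uncertain significance",
                                      "Benign"), 1) else "",
        carriers_hldl = list(carr_h), carriers_lldl = list(carr_l),
        kind = kind, expected_survivor = expected
      )
    }
    tier_genes <- list(`1` = cfg$tier1, `2` = cfg$tier2, `3` = cfg$tier3)
    surviving_classes <- c("frameshift_del", "stopgain_snv",
                           "nonsynonymous_snv")
    for (r in seq_len(nrow(plan$planted))) {
      pr <- plan$planted[r, ]
      for (v in seq_len(pr$n_variants)) {
        fc <- sample(surviving_classes, 1)
        damaging <- fc == "nonsynonymous_snv"
        inc <- pr$direction == "risk_increasing"
        carr <- if (inc) sample(samples_h, pr$n_carriers) else
          sample(samples_l, pr$n_carriers)
        grp_n <- if (inc) plan$n_hldl else plan$n_lldl
        # tier-3 risk-increasing plants survive only past the
        # high-frequency rule (> 10 carriers and >= 40% of the group)
        expected <- pr$tier != 3L || !inc ||
          (pr$n_carriers > 10L && pr$n_carriers / grp_n >= 0.40)
        add_rec(sample(tier_genes[[as.character(pr$tier)]], 1), pr$tier, fc,
                if (damaging) "damaging" else "",
                if (damaging) "probably_damaging" else "",
                if (inc) carr else character(0),
                if (inc) character(0) else carr,
                sprintf("planted_tier%d_%s", pr$tier, pr$direction),
                expected)
      }
    }
    all_genes <- unlist(tier_genes, use.names = FALSE)
    dk <- plan$decoys
    for (i in seq_len(dk[["synonymous"]])) {
      add_rec(sample(all_genes, 1), NA, "synonymous_snv", "", "",
              sample(samples_h, sample(1:3, 1)), character(0),
              "decoy_synonymous", FALSE)
    }
    for (i in seq_len(dk[["tolerated"]])) {
      add_rec(sample(all_genes, 1), NA, "nonsynonymous_snv", "tolerated",
              "benign", sample(samples_h, sample(1:3, 1)), character(0),
              "decoy_tolerated", FALSE)
    }
    for (i in seq_len(dk[["shared"]])) {
      add_rec(sample(all_genes, 1), NA, "nonsynonymous_snv", "damaging",
              "probably_damaging", sample(samples_h, sample(1:3, 1)),
              sample(samples_l, sample(1:3, 1)), "decoy_shared", FALSE)
    }
    for (i in seq_len(dk[["intronic"]])) {
      add_rec(sample(all_genes, 1), NA, "non_exonic", "", "",
              sample(samples_h, sample(1:3, 1)), character(0),
              "decoy_intronic", FALSE)
    }

    ann <- do.call(rbind, lapply(recs, function(r) {
      data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
                 gene = r$gene, transcript = r$transcript, hgvs_c = r$hgvs_c,
                 hgvs_p = r$hgvs_p, func_class = r$func_class,
                 dbsnp_id = r$dbsnp_id,
                 known_in_databases = r$known_in_databases, sift = r$sift,
                 polyphen = r$polyphen, mutation_taster = r$mutation_taster,
                 fathmm = r$fathmm, clinvar = r$clinvar,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(ann)) {
      ann <- as.data.frame(setNames(
        rep(list(character(0)), length(annotation_columns())),
        annotation_columns()))
      ann$pos <- integer(0)
      ann$known_in_databases <- logical(0)
    } else {
      # unique (chrom, pos, ref, alt) keys
      key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
      while (anyDuplicated(key)) {
        dup <- duplicated(key)
        ann$pos[dup] <- ann$pos[dup] + sample(1:1000, sum(dup), TRUE)
        for (i in which(dup)) recs[[i]]$pos <- ann$pos[i]
        key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
      }
    }

    all_samples <- names(sample_groups)
    vcf_lines <- c(
      "##fileformat=VCFv4.2",
      "##source=fhtriage synthetic call-set generator",
      sprintf("##fhtriage_seed=%d", plan$seed),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", all_samples), collapse = "\t")
    )
    if (length(recs)) {
      ord <- order(as.integer(ann$chrom), ann$pos)
      for (i in ord) {
        r <- recs[[i]]
        carriers <- c(r$carriers_hldl[[1]], r$carriers_lldl[[1]])
        gts <- ifelse(all_samples %in% carriers, "0/1", "0/0")
        vcf_lines <- c(vcf_lines, paste(
          c(r$chrom, ann$pos[i], ifelse(nzchar(r$dbsnp_id), r$dbsnp_id, "."),
            r$ref, r$alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t"))
      }
    }
    truth <- if (length(recs)) {
      data.frame(
        key = variant_key(ann$chrom, ann$pos, ann$ref, ann$alt),
        kind = vapply(recs, `[[`, "", "kind"),
        n_hldl = vapply(recs, function(r) length(r$carriers_hldl[[1]]), 0L),
        n_lldl = vapply(recs, function(r) length(r$carriers_lldl[[1]]), 0L),
        expected_survivor = vapply(recs, `[[`, TRUE, "expected_survivor"),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(key = character(0), kind = character(0),
                 n_hldl = integer(0), n_lldl = integer(0),
                 expected_survivor = logical(0))
    }
    list(vcf_lines = vcf_lines, annotation = ann,
         sample_groups = sample_groups, truth = truth, seed = plan$seed)
  })
}

#' Write a generated call set to disk
#'
#' Materialises `generate_callset()` output as a plain-text VCF 4.2 file
#' and an annotation TSV suitable for [read_callset()].
#'
#' @param callset Output of [generate_callset()].
#' @param dir Output directory (created if needed).
#' @param stem File name stem.
#' @return Named list of the two paths.
#' @export
write_callset <- function(callset, dir, stem = "callset") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, paste0(stem, ".vcf"))
  ann <- file.path(dir, paste0(stem, ".annotation.tsv"))
  writeLines(callset$vcf_lines, vcf)
  write.table(callset$annotation, ann, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(vcf = vcf, annotation = ann)
}

#' Convert a generated call set to an annotated-variant table
#'
#' Produces the same `annotated_variants` shape as [read_callset()] —
#' harmonized predictor calls, `NA` dbSNP ids for novel variants, carrier
#' counts per group — directly from [generate_callset()] output, without
#' touching disk.
#'
#' @param callset Output of [generate_callset()].
#' @return An `annotated_variants` data frame.
#' @export
as_annotated_variants <- function(callset) {
  out <- callset$annotation
  out$dbsnp_id[!nzchar(out$dbsnp_id)] <- NA
  for (tool in c("sift", "polyphen", "mutation_taster", "fathmm")) {
    out[[tool]] <- harmonize_predictor(out[[tool]], tool)
  }
  out$n_hldl <- callset$truth$n_hldl
  out$n_lldl <- callset$truth$n_lldl
  structure(out, class = c("annotated_variants", "data.frame"))
}
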