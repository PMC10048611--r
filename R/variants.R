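# Variant data model: tiered FH gene panels, predictor-call harmonization,
# and the VCF + annotation-table join producing annotated variants with
# per-group carrier sets.

#' Functional classes recognised by the triage cascade
#' @return Character vector of the functional-class enumeration.
#' @export
func_classes <- function() {
  c("synonymous_snv", "nonsynonymous_snv", "stopgain_snv", "stoploss_snv",
    "frameshift_del", "frameshift_ins", "nonframeshift_sub",
    "nonframeshift_del", "nonframeshift_ins", "non_exonic")
}

#' Tiered FH gene panel configuration
#'
#' Tier 1 genes are directly causal for familial hypercholesterolemia
#' (autosomal dominant LDLR/APOB/PCSK9, recessive LDLRAP1); tier 2 genes
#' regulate LDL or the expression of LDL-regulating genes; tier 3 covers
#' other lipid-implicated genes. `tier3 = "complement"` assigns tier 3 to
#' any gene of `universe` not already in tiers 1-2. The full published
#' tier-2/3 universes are not enumerated anywhere; the defaults ship the
#' genes named in the source report tables, and anything wider must be
#' configured explicitly.
#'
#' @param tier1,tier2 Character vectors of gene symbols.
#' @param tier3 Character vector, or `"complement"`.
#' @param universe Lipid-gene universe used when `tier3 = "complement"`.
#' @return A `tier_config` object (tiers pairwise disjoint).
#' @export
tier_config <- function(
    tier1 = c("LDLR", "APOB", "PCSK9", "LDLRAP1"),
    tier2 = c("NYNRIN", "CELSR2", "PARP10", "MAF1", "OSBPL7", "DCPS",
              "GPAA1", "LPA", "OPLAH", "SPATC1"),
    tier3 = c("WDR74", "FRG1BP", "SEC13", "KEAP1", "GLMP", "MUC12", "UBR1",
              "GBP7", "RNF212", "DPCR1", "HEATR5A", "TIMELESS", "GTF3C1"),
    universe = NULL) {
  complement <- identical(tier3, "complement")
  if (complement) {
    if (is.null(universe)) stop("tier3 = \"complement\" needs a universe")
    tier3 <- setdiff(universe, c(tier1, tier2))
  }
  overlap <- c(intersect(tier1, tier2), intersect(tier1, tier3),
               intersect(tier2, tier3))
  if (length(overlap)) {
    stop("tier gene sets overlap: ", paste(unique(overlap), collapse = ", "))
  }
  structure(list(tier1 = tier1, tier2 = tier2, tier3 = tier3),
            class = "tier_config")
}

#' Assign FH tier to gene symbols
#'
#' @param gene Character vector of gene symbols.
#' @param config A [tier_config()].
#' @return Integer vector: 1, 2, 3, or `NA` for genes outside all panels
#'   ("none").
#' @export
#' @examples
#' assign_tier(c("LDLR", "OSBPL7", "WDR74", "TP53"))
assign_tier <- function(gene, config = tier_config()) {
  if (any(is.na(gene) | !nzchar(gene))) stop("empty gene symbol")
  out <- rep(NA_integer_, length(gene))
  out[gene %in% config$tier1] <- 1L
  out[gene %in% config$tier2] <- 2L
  out[gene %in% config$tier3] <- 3L
  out
}

#' Harmonize raw in-silico predictor strings
#'
#' Raw tool outputs are mapped onto the documented enumerations; unknown or
#' empty strings become `"missing"`, never silently damaging.
#'
#' @param x Character vector of raw calls.
#' @param tool One of `"sift"`, `"polyphen"`, `"mutation_taster"`,
#'   `"fathmm"`.
#' @return Character vector on the harmonized scale.
#' @export
harmonize_predictor <- function(x, tool = c("sift", "polyphen",
                                            "mutation_taster", "fathmm")) {
  tool <- match.arg(tool)
  x <- tolower(trimws(as.character(x)))
  map <- switch(tool,
    sift = c(d = "damaging", damaging = "damaging",
             deleterious = "damaging", t = "tolerated",
             tolerated = "tolerated", tolerable = "tolerated"),
    polyphen = c(d = "probably_damaging",
                 probably_damaging = "probably_damaging",
                 `probably damaging` = "probably_damaging",
                 p = "possibly_damaging",
                 possibly_damaging = "possibly_damaging",
                 `possibly damaging` = "possibly_damaging",
                 b = "benign", benign = "benign"),
    mutation_taster = c(a = "disease_causing_automatic",
                        d = "disease_causing",
                        disease_causing = "disease_causing",
                        n = "polymorphism", p = "polymorphism_automatic",
                        polymorphism = "polymorphism"),
    fathmm = c(d = "damaging", damaging = "damaging", t = "tolerated",
               tolerated = "tolerated")
  )
  out <- unname(map[x])
  out[is.na(out)] <- "missing"
  out
}

annotation_columns <- function() {
  c("chrom", "pos", "ref", "alt", "gene", "transcript", "hgvs_c", "hgvs_p",
    "func_class", "dbsnp_id", "known_in_databases", "sift", "polyphen",
    "mutation_taster", "fathmm", "clinvar")
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# GT string -> does the call carry allele `allele_idx` (1-based ALT index)?
gt_carries_allele <- function(gt, allele_idx) {
  gt <- sub(":.*$", "", gt)
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) any(p == as.character(allele_idx)), logical(1))
}

#' Read and join a variant call set with its annotation table
#'
#' Joins VCF 4.2 records (read with `vcfR`) to an ANNOVAR-style annotation
#' TSV keyed by (chrom, pos, ref, alt). Multi-allelic sites yield one
#' record per ALT allele. A carrier is any sample with a non-reference
#' genotype call carrying that allele (het or hom; dosage is not modelled
#' in discovery). Carriers are split into the HLDL/LLDL groups by
#' `sample_groups`.
#'
#' @param vcf_path Path to a VCF file with GT genotypes.
#' @param annotation_path Path to the annotation TSV (columns
#'   `annotation_columns()`; predictor columns may carry raw tool strings,
#'   which are harmonized on read).
#' @param sample_groups Named character vector mapping sample id to
#'   `"HLDL"` or `"LLDL"`.
#' @return Data frame of class `annotated_variants`: one row per joined
#'   allele with annotation columns, carrier counts `n_hldl`/`n_lldl`, and
#'   list-columns `carriers_hldl`/`carriers_lldl`. Annotation rows with no
#'   VCF match are attached as attribute `"orphans"`; VCF alleles with no
#'   annotation row as attribute `"unannotated"`.
#' @export
read_callset <- function(vcf_path, annotation_path, sample_groups) {
  stopifnot(!is.null(names(sample_groups)),
            all(sample_groups %in% c("HLDL", "LLDL")))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  miss <- setdiff(annotation_columns(), names(ann))
  if (length(miss)) {
    stop("annotation table lacks columns: ", paste(miss, collapse = ", "))
  }
  ann$pos <- as.integer(ann$pos)
  akey <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(akey)) {
    stop("duplicate annotation keys: ",
         paste(unique(akey[duplicated(akey)]), collapse = ", "))
  }

  samples <- if (is.null(gt)) character(0) else colnames(gt)[-1]
  unknown <- setdiff(samples, names(sample_groups))
  if (length(unknown)) {
    stop("VCF samples absent from group map: ",
         paste(unknown, collapse = ", "))
  }

  rows <- list()
  if (nrow(fix) > 0) {
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      for (j in seq_along(alts)) {
        carriers <- character(0)
        if (length(samples)) {
          carry <- gt_carries_allele(gt[i, -1], j)
          carriers <- samples[carry]
        }
        rows[[length(rows) + 1L]] <- list(
          chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[j], carriers = carriers
        )
      }
    }
  }
  vkey <- vapply(rows, function(r) variant_key(r$chrom, r$pos, r$ref, r$alt),
                 "")
  if (anyDuplicated(vkey)) {
    stop("duplicate VCF alleles: ",
         paste(unique(vkey[duplicated(vkey)]), collapse = ", "))
  }

  matched <- match(vkey, akey)
  unannotated <- vkey[is.na(matched)]
  keep <- which(!is.na(matched))
  out <- ann[matched[keep], , drop = FALSE]
  rownames(out) <- NULL
  hldl_samples <- names(sample_groups)[sample_groups == "HLDL"]
  carr <- lapply(rows[keep], `[[`, "carriers")
  out$carriers_hldl <- I(lapply(carr, function(x) x[x %in% hldl_samples]))
  out$carriers_lldl <- I(lapply(carr, function(x) x[!x %in% hldl_samples]))
  out$n_hldl <- vapply(out$carriers_hldl, length, 0L)
  out$n_lldl <- vapply(out$carriers_lldl, length, 0L)
  out$known_in_databases <- out$known_in_databases %in% c("TRUE", "true", "1",
                                                          "yes")
  out$dbsnp_id[!nzchar(out$dbsnp_id) | is.na(out$dbsnp_id)] <- NA
  for (tool in c("sift", "polyphen", "mutation_taster", "fathmm")) {
    out[[tool]] <- harmonize_predictor(out[[tool]], tool)
  }
  bad <- !out$func_class %in% func_classes()
  if (any(bad)) {
    stop("unknown func_class values: ",
         paste(unique(out$func_class[bad]), collapse = ", "))
  }
  orphans <- ann[!akey %in% vkey, , drop = FALSE]
  structure(out, orphans = orphans, unannotated = unannotated,
            class = c("annotated_variants", "data.frame"))
}
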