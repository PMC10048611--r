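# The discovery-phase triage cascade: exonic -> non-synonymous ->
# deleteriousness -> FH-gene tier -> case-exclusivity direction ->
# tier-3 high-frequency rule, with class-priority ranking and tiered
# report tables.

truncating_classes <- function() {
  c("frameshift_del", "frameshift_ins", "stopgain_snv", "stoploss_snv")
}

#' Class priority of exonic variant calls
#'
#' Frameshift and stop-gain/stop-loss variants are shortlisted ahead of
#' non-synonymous SNVs, which precede non-frameshift indels/substitutions.
#'
#' @param func_class Character vector of functional classes.
#' @return Integer 1/2/3 (`NA` for classes outside the exonic survivors).
#' @export
class_priority <- function(func_class) {
  out <- rep(NA_integer_, length(func_class))
  out[func_class %in% truncating_classes()] <- 1L
  out[func_class == "nonsynonymous_snv"] <- 2L
  out[func_class %in% c("nonframeshift_sub", "nonframeshift_del",
                        "nonframeshift_ins")] <- 3L
  out
}

#' Keep only exonic variants
#' @param variants Annotated-variant data frame with `func_class`.
#' @return Surviving rows.
#' @export
filter_exonic <- function(variants) {
  variants[variants$func_class != "non_exonic", , drop = FALSE]
}

#' Remove synonymous SNVs
#' @inheritParams filter_exonic
#' @return Surviving rows.
#' @export
filter_synonymous <- function(variants) {
  variants[variants$func_class != "synonymous_snv", , drop = FALSE]
}

#' Remove variants with tolerable predicted effects
#'
#' A variant is removed only when SIFT calls it tolerated AND PolyPhen-2
#' calls it benign. Truncating classes (frameshift, stop-gain/stop-loss)
#' bypass the filter — the predictors are undefined for them — and missing
#' predictions never cause removal.
#'
#' @inheritParams filter_exonic
#' @return Surviving rows.
#' @export
filter_tolerable <- function(variants) {
  tolerable <- variants$sift == "tolerated" & variants$polyphen == "benign" &
    !variants$func_class %in% truncating_classes()
  variants[!tolerable, , drop = FALSE]
}

#' Classify case-exclusivity direction
#'
#' Variants carried exclusively by HLDL samples are risk-increasing
#' (causative); variants carried exclusively by LLDL samples are
#' risk-reducing (protective); variants carried in both groups or in
#' neither have direction "none".
#'
#' @param n_hldl,n_lldl Carrier counts per group (vectorised).
#' @return Character vector in `{"risk_increasing", "risk_reducing",
#'   "none"}`.
#' @export
#' @examples
#' classify_direction(c(2, 0, 1, 0), c(0, 3, 1, 0))
classify_direction <- function(n_hldl, n_lldl) {
  stopifnot(length(n_hldl) == length(n_lldl),
            all(n_hldl >= 0), all(n_lldl >= 0))
  out <- rep("none", length(n_hldl))
  out[n_hldl >= 1 & n_lldl == 0] <- "risk_increasing"
  out[n_lldl >= 1 & n_hldl == 0] <- "risk_reducing"
  out
}

#' Tier-3 high-frequency rule
#'
#' Among tier-3 risk-increasing variants, only high-frequency
#' case-exclusive variants are retained: strictly more than
#' `min_carriers` HLDL carriers, at least `min_fraction` of the HLDL
#' group, and no LLDL carriers. Other tiers and risk-reducing variants
#' pass through untouched.
#'
#' @param triage Triage data frame (columns `tier`, `direction`, `n_hldl`,
#'   `n_lldl`).
#' @param n_group HLDL group size.
#' @param min_carriers Exclusive lower bound on carriers (default 10).
#' @param min_fraction Minimum carrier fraction of the group (default
#'   0.40).
#' @return Surviving rows.
#' @export
filter_tier3_high_frequency <- function(triage, n_group,
                                        min_carriers = 10L,
                                        min_fraction = 0.40) {
  if (n_group <= 0) stop("group size must be positive")
  applies <- !is.na(triage$tier) & triage$tier == 3L &
    triage$direction == "risk_increasing"
  keep <- !applies |
    (triage$n_hldl > min_carriers &
       triage$n_hldl / n_group >= min_fraction &
       triage$n_lldl == 0)
  triage[keep, , drop = FALSE]
}

#' Rank triaged variants by tier and class priority
#'
#' Stable sort by (tier ascending, class priority ascending, carrier count
#' descending, chromosome, position); ties beyond that preserve input
#' order.
#'
#' @param triage Triage data frame (columns `tier`, `class_priority`,
#'   `n_hldl`, `n_lldl`, `chrom`, `pos`).
#' @return The rows in rank order.
#' @export
rank_class_priority <- function(triage) {
  if (nrow(triage) == 0) return(triage)
  tier <- ifelse(is.na(triage$tier), 99L, triage$tier)
  carriers <- triage$n_hldl + triage$n_lldl
  chrom_num <- suppressWarnings(as.numeric(triage$chrom))
  chrom_num[is.na(chrom_num)] <- 1e6 + as.integer(factor(
    triage$chrom[is.na(chrom_num)]))
  ord <- order(tier, triage$class_priority, -carriers, chrom_num,
               triage$pos)
  triage[ord, , drop = FALSE]
}

#' Run the full discovery triage cascade
#'
#' Applies, in order: the exonic filter, the synonymous filter, the
#' tolerable-effect filter, the FH-gene tier filter (variants outside all
#' configured tiers are dropped), the case-exclusivity direction rule
#' (direction "none" is dropped), and the tier-3 high-frequency rule;
#' survivors are ranked by [rank_class_priority()]. The first three
#' filters key on disjoint predicates and therefore commute.
#'
#' @param variants Annotated-variant data frame (as from [read_callset()]
#'   or a generated call set joined with carrier counts).
#' @param config [tier_config()].
#' @param n_hldl,n_lldl Group sizes (used by the tier-3 frequency rule).
#' @param tier3_min_carriers,tier3_min_fraction Tier-3 rule parameters.
#' @return List: `survivors` (ranked triage table with `tier`,
#'   `direction`, `class_priority`, `novel` columns added), `audit`
#'   (per-stage input/removed/surviving counts).
#' @export
prioritize_cascade <- function(variants, config = tier_config(),
                               n_hldl = 25L, n_lldl = 25L,
                               tier3_min_carriers = 10L,
                               tier3_min_fraction = 0.40) {
  audit <- list()
  log_stage <- function(name, before, after) {
    audit[[name]] <<- list(input = before, removed = before - after,
                           surviving = after)
  }
  n0 <- nrow(variants)
  v <- filter_exonic(variants)
  log_stage("exonic", n0, nrow(v))
  n1 <- nrow(v); v <- filter_synonymous(v)
  log_stage("synonymous", n1, nrow(v))
  n2 <- nrow(v); v <- filter_tolerable(v)
  log_stage("tolerable", n2, nrow(v))
  v$class_priority <- class_priority(v$func_class)
  v$tier <- assign_tier(v$gene, config)
  n3 <- nrow(v); v <- v[!is.na(v$tier), , drop = FALSE]
  log_stage("fh_gene_tier", n3, nrow(v))
  v$direction <- classify_direction(v$n_hldl, v$n_lldl)
  n4 <- nrow(v); v <- v[v$direction != "none", , drop = FALSE]
  log_stage("exclusivity", n4, nrow(v))
  n5 <- nrow(v)
  v <- filter_tier3_high_frequency(v, n_hldl, tier3_min_carriers,
                                   tier3_min_fraction)
  log_stage("tier3_high_frequency", n5, nrow(v))
  v$novel <- is.na(v$dbsnp_id) & !v$known_in_databases
  v <- rank_class_priority(v)
  rownames(v) <- NULL
  list(survivors = v, audit = audit)
}

#' Build tiered report tables
#'
#' One table per tier in the published report shape: gene, nomenclature,
#' variant type, dbSNP id, ClinVar significance, carrier counts per group,
#' and a novelty flag (no dbSNP id and absent from the population
#' databases). Rows are in [rank_class_priority()] order, so frameshift /
#' stop variants lead each tier.
#'
#' @param survivors Ranked triage table from [prioritize_cascade()].
#' @return Named list of data frames `tier1`, `tier2`, `tier3` (empty
#'   tables keep their headers).
#' @export
build_reports <- function(survivors) {
  shape <- function(x) {
    nomen <- if (nrow(x)) {
      paste0(x$transcript, ":", x$hgvs_c, ":", x$hgvs_p)
    } else {
      character(0)
    }
    data.frame(
      gene = x$gene, chrom = x$chrom, pos = x$pos,
      nomenclature = nomen,
      variant_type = x$func_class, dbsnp_id = x$dbsnp_id,
      clinvar = x$clinvar, direction = x$direction,
      n_hldl = x$n_hldl, n_lldl = x$n_lldl, novel = x$novel,
      stringsAsFactors = FALSE
    )
  }
  out <- lapply(1:3, function(t) {
    shape(survivors[!is.na(survivors$tier) & survivors$tier == t, ,
                    drop = FALSE])
  })
  names(out) <- paste0("tier", 1:3)
  out
}

#' Select the validation genotyping panel
#'
#' Takes the top `n_inc` risk-increasing and top `n_red` risk-reducing
#' survivors in [rank_class_priority()] order (the published study carried
#' 27 + 18 = 45 variants forward). The ranking convention — tier, class
#' priority, carrier count, position — is this package's documented,
#' deterministic tie-break chain.
#'
#' @param survivors Ranked triage table from [prioritize_cascade()].
#' @param n_inc,n_red Panel sizes per direction.
#' @return Data frame of selected variants with a `panel_direction`
#'   column.
#' @export
select_validation_panel <- function(survivors, n_inc = 27L, n_red = 18L) {
  inc <- survivors[survivors$direction == "risk_increasing", , drop = FALSE]
  red <- survivors[survivors$direction == "risk_reducing", , drop = FALSE]
  if (n_inc > nrow(inc)) {
    stop(sprintf("requested %d risk-increasing variants, %d available",
                 n_inc, nrow(inc)))
  }
  if (n_red > nrow(red)) {
    stop(sprintf("requested %d risk-reducing variants, %d available",
                 n_red, nrow(red)))
  }
  out <- rbind(inc[seq_len(n_inc), , drop = FALSE],
               red[seq_len(n_red), , drop = FALSE])
  out$panel_direction <- rep(c("risk_increasing", "risk_reducing"),
                             c(n_inc, n_red))
  rownames(out) <- NULL
  out
}
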