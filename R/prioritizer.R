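# Five-tier causal-gene ranking and nearest-gene tie-breaking.

#' Tier levels in increasing order of evidence
#' @export
tier_levels <- function() {
  c("NONE", "VERY_WEAK", "WEAK", "MODERATE", "HIGH", "VERY_HIGH")
}

#' Default prioritization thresholds
#'
#' `h4_threshold`: colocalization evidence requires `PP_H4 > h4_threshold`
#' (strict, default 0.80). `mr_q`: MR significance (q < 0.05).
#' `coloc_multi`: the multi-dataset colocalization criteria require strictly
#' more than `coloc_multi` datasets (default 2, i.e. at least 3).
#' @export
priority_thresholds <- function(h4_threshold = 0.80, mr_q = 0.05,
                                coloc_multi = 2L) {
  list(h4_threshold = h4_threshold, mr_q = mr_q, coloc_multi = coloc_multi)
}

#' Build per-gene evidence profiles for a locus
#'
#' Joins annotation flags, MR significance by molecule type, and the count
#' of molQTL datasets colocalizing above the H4 threshold into one profile
#' per candidate gene. Genes absent from the MR or colocalization tables get
#' false flags / zero counts.
#'
#' @param locus A `locus`.
#' @param candidates Its `candidate_set`.
#' @param annotations Output of [annotate_gene_locus()] for this locus.
#' @param mr_results Output of [mr_scan()].
#' @param coloc_results Output of [coloc_scan()].
#' @param thresholds See [priority_thresholds()].
#' @return Data frame, one row per candidate gene, with all evidence fields
#'   used by [assign_rank()].
#' @export
build_profiles <- function(locus, candidates, annotations, mr_results,
                           coloc_results, thresholds = priority_thresholds()) {
  for (nm in c("annotations", "mr_results", "coloc_results")) {
    if (is.null(get(nm))) stop("missing upstream table: ", nm)
  }
  prof <- annotations[annotations$locus_id == locus$id, , drop = FALSE]
  co <- coloc_results[coloc_results$locus_id == locus$id &
                        coloc_results$status == "ok" &
                        !is.na(coloc_results$pp_h4) &
                        coloc_results$pp_h4 > thresholds$h4_threshold, ,
                      drop = FALSE]
  prof$n_coloc <- vapply(prof$gene_id, function(g) {
    length(unique(co$dataset_id[co$gene_id == g]))
  }, integer(1))
  sig <- mr_results[mr_results$qvalue < thresholds$mr_q, , drop = FALSE]
  prof$mr_pqtl_sig <- vapply(prof$gene_id, function(g) {
    any(sig$gene_id == g & sig$molecule_type == "pQTL")
  }, logical(1))
  prof$mr_eqtl_sig <- vapply(prof$gene_id, function(g) {
    any(sig$gene_id == g & sig$molecule_type == "eQTL")
  }, logical(1))
  rownames(prof) <- NULL
  prof
}

#' Assign the five-tier evidence rank to one gene profile
#'
#' Evaluates the rank table top-down and returns the first tier whose
#' criteria are met:
#' \itemize{
#'   \item VERY HIGH: lead pathogenic variant; or colocalization in more
#'     than `coloc_multi` datasets together with the maximum ABC score at
#'     the lead variant.
#'   \item HIGH: lead coding variant; or associated pathogenic variant; or
#'     multi-dataset colocalization with ABCmax at an associated variant; or
#'     colocalization in at least one dataset with ABCmax at the lead.
#'   \item MODERATE: colocalization in at least one dataset; or significant
#'     MR with a protein QTL; or ABCmax at the lead; or associated coding
#'     variant.
#'   \item WEAK: nearest gene; or ABCmax at an associated variant; or an
#'     ABC link of any score at the lead.
#'   \item VERY WEAK: significant MR with an eQTL; or an ABC link of any
#'     score at an associated variant.
#'   \item NONE otherwise.
#' }
#'
#' @param p A profile: a list or one-row data frame with the logical fields
#'   `lead_pathogenic`, `lead_coding`, `assoc_pathogenic`, `assoc_coding`,
#'   `abcmax_lead`, `abcmax_assoc`, `abc_any_lead`, `abc_any_assoc`,
#'   `mr_pqtl_sig`, `mr_eqtl_sig`, `is_nearest` and the count `n_coloc`.
#' @param thresholds See [priority_thresholds()].
#' @return List with `tier` (one of [tier_levels()]) and
#'   `satisfied_criteria` (labels of all satisfied criteria, any tier).
#' @export
assign_rank <- function(p, thresholds = priority_thresholds()) {
  p <- as.list(p)
  cm <- thresholds$coloc_multi
  crit <- c(
    lead_pathogenic = isTRUE(p$lead_pathogenic),
    `coloc_multi+abcmax_lead` = p$n_coloc > cm && isTRUE(p$abcmax_lead),
    lead_coding = isTRUE(p$lead_coding),
    assoc_pathogenic = isTRUE(p$assoc_pathogenic),
    `coloc_multi+abcmax_assoc` = p$n_coloc > cm && isTRUE(p$abcmax_assoc),
    `coloc+abcmax_lead` = p$n_coloc >= 1 && isTRUE(p$abcmax_lead),
    coloc = p$n_coloc >= 1,
    mr_pqtl = isTRUE(p$mr_pqtl_sig),
    abcmax_lead = isTRUE(p$abcmax_lead),
    assoc_coding = isTRUE(p$assoc_coding),
    nearest = isTRUE(p$is_nearest),
    abcmax_assoc = isTRUE(p$abcmax_assoc),
    abc_any_lead = isTRUE(p$abc_any_lead),
    mr_eqtl = isTRUE(p$mr_eqtl_sig),
    abc_any_assoc = isTRUE(p$abc_any_assoc)
  )
  tier_of <- c(
    lead_pathogenic = "VERY_HIGH", `coloc_multi+abcmax_lead` = "VERY_HIGH",
    lead_coding = "HIGH", assoc_pathogenic = "HIGH",
    `coloc_multi+abcmax_assoc` = "HIGH", `coloc+abcmax_lead` = "HIGH",
    coloc = "MODERATE", mr_pqtl = "MODERATE", abcmax_lead = "MODERATE",
    assoc_coding = "MODERATE",
    nearest = "WEAK", abcmax_assoc = "WEAK", abc_any_lead = "WEAK",
    mr_eqtl = "VERY_WEAK", abc_any_assoc = "VERY_WEAK"
  )
  sat <- names(crit)[crit]
  tier <- if (length(sat) == 0L) "NONE" else {
    tiers <- tier_of[sat]
    tier_levels()[max(match(tiers, tier_levels()))]
  }
  list(tier = tier, satisfied_criteria = sat)
}

# Criteria counting as mechanism support (coding variant or colocalization)
# for the "supported" flag on the prioritization table.
.mechanism_criteria <- c("lead_pathogenic", "lead_coding", "assoc_pathogenic",
                         "assoc_coding", "coloc", "coloc+abcmax_lead",
                         "coloc_multi+abcmax_lead", "coloc_multi+abcmax_assoc")

#' Rank all profiles of a locus
#'
#' @param profiles Output of [build_profiles()].
#' @param thresholds See [priority_thresholds()].
#' @return `profiles` with `tier` (ordered factor), `criteria`
#'   (comma-separated satisfied labels) and `supported_coding_or_coloc`
#'   columns added.
#' @export
rank_profiles <- function(profiles, thresholds = priority_thresholds()) {
  ranks <- lapply(seq_len(nrow(profiles)),
                  function(i) assign_rank(profiles[i, ], thresholds))
  profiles$tier <- factor(vapply(ranks, `[[`, character(1), "tier"),
                          levels = tier_levels(), ordered = TRUE)
  profiles$criteria <- vapply(ranks, function(r) {
    paste(r$satisfied_criteria, collapse = ",")
  }, character(1))
  profiles$supported_coding_or_coloc <- vapply(ranks, function(r) {
    any(r$satisfied_criteria %in% .mechanism_criteria)
  }, logical(1))
  profiles
}

#' Prioritize the best gene(s) at a locus
#'
#' Identifies the top tier among candidate profiles; if the nearest gene is
#' in the top-tier set it alone is prioritized, otherwise all top-tier genes
#' are prioritized equally. When no criterion fires for any gene, the
#' nearest gene is prioritized as a fallback.
#'
#' @param ranked Output of [rank_profiles()] for one locus.
#' @return List with `prioritized` (gene ids), `tier` (the top tier), and
#'   the ranked table with an `is_prioritized` column.
#' @export
prioritize_locus <- function(ranked) {
  stopifnot(nrow(ranked) >= 1)
  ranked <- ranked[order(-as.integer(ranked$tier), ranked$distance_to_lead,
                         ranked$gene_id), , drop = FALSE]
  top_tier <- ranked$tier[1]
  if (top_tier == "NONE") {
    pri <- ranked$gene_id[ranked$is_nearest]
    if (length(pri) == 0L) pri <- ranked$gene_id[1]
  } else {
    top <- ranked$gene_id[ranked$tier == top_tier]
    nearest <- ranked$gene_id[ranked$is_nearest]
    pri <- if (length(nearest) && nearest %in% top) nearest else top
  }
  ranked$is_prioritized <- ranked$gene_id %in% pri
  rownames(ranked) <- NULL
  list(prioritized = pri, tier = as.character(top_tier), table = ranked)
}

#' Per-locus prioritization table for a study
#'
#' Drives profile building, ranking and tie-breaking across all loci of a
#' GWAS and emits one row per candidate gene with its tier, satisfied
#' criteria and prioritization flag. When the GWAS carries synthetic truth
#' records, a `causal_gene_truth` column is joined in.
#'
#' @param gwas A `gwas_dataset`.
#' @param loci List of loci.
#' @param candidates Parallel list of `candidate_set`s.
#' @param annotations Row-bound [annotate_gene_locus()] output for all loci.
#' @param mr_results,coloc_results Upstream MR / colocalization tables.
#' @param thresholds See [priority_thresholds()].
#' @param truth_by_locus Optional named character vector locus id ->
#'   true causal gene (for synthetic studies).
#' @return Data frame across loci with columns `gwas_id`, `locus_id`,
#'   `lead_variant`, `lead_pvalue`, `n_candidates`, `gene_id`, `tier`,
#'   `criteria`, `is_prioritized`, `supported_coding_or_coloc`,
#'   `distance_to_lead`, `is_nearest`, `n_coloc` and the evidence flags.
#' @export
prioritize_study <- function(gwas, loci, candidates, annotations, mr_results,
                             coloc_results,
                             thresholds = priority_thresholds(),
                             truth_by_locus = NULL) {
  out <- list()
  for (i in seq_along(loci)) {
    prof <- build_profiles(loci[[i]], candidates[[i]], annotations,
                           mr_results, coloc_results, thresholds)
    if (nrow(prof) == 0L) next
    res <- prioritize_locus(rank_profiles(prof, thresholds))
    tab <- res$table
    tab$gwas_id <- gwas$study_id
    tab$lead_variant <- loci[[i]]$lead
    tab$lead_pvalue <- loci[[i]]$lead_pvalue
    tab$n_candidates <- nrow(tab)
    if (!is.null(truth_by_locus)) {
      tab$causal_gene_truth <- unname(truth_by_locus[loci[[i]]$id])
    }
    out[[length(out) + 1L]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  front <- c("gwas_id", "locus_id", "lead_variant", "lead_pvalue",
             "n_candidates", "gene_id", "tier", "criteria", "is_prioritized")
  res[, c(front, setdiff(names(res), front)), drop = FALSE]
}
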