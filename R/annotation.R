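# Variant consequence/pathogenicity classification, associated-variant
# eligibility, and ABC enhancer-overlap features per gene x locus.

#' Controlled consequence vocabulary
#'
#' Consequence terms accepted by [classify_consequence()]; pathogenicity
#' flags are consumed from upstream predictors, never computed here.
#' @export
consequence_vocabulary <- function() {
  c("missense_variant", "synonymous_variant", "stop_gained", "stop_lost",
    "start_lost", "splice_acceptor_variant", "splice_donor_variant",
    "frameshift_variant", "transcript_ablation", "inframe_deletion",
    "inframe_insertion", "intron_variant", "intergenic_variant",
    "upstream_gene_variant", "downstream_gene_variant",
    "3_prime_UTR_variant", "5_prime_UTR_variant", "non_coding_transcript_variant")
}

.impact_levels <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Classify a variant consequence as coding / pathogenic
#'
#' A variant is coding when it is a missense variant or its predicted impact
#' is HIGH (stop gain, splice-site, frameshift and similar). It is pathogenic
#' when impact is HIGH, or when it is coding and flagged as predicted
#' pathogenic, protein-destabilizing, or in a conserved region.
#'
#' @param consequence Consequence term(s) from [consequence_vocabulary()].
#' @param impact `HIGH`, `MODERATE`, `LOW` or `MODIFIER`.
#' @param pathogenic,destabilizing,conserved Logical prediction flags.
#' @return Data frame with logical columns `is_coding`, `is_pathogenic`.
#' @examples
#' classify_consequence("missense_variant", "MODERATE", pathogenic = TRUE)
#' @export
classify_consequence <- function(consequence, impact,
                                 pathogenic = FALSE, destabilizing = FALSE,
                                 conserved = FALSE) {
  unknown <- setdiff(unique(consequence), consequence_vocabulary())
  if (length(unknown) > 0L) {
    stop("unknown consequence term(s): ", paste(unknown, collapse = ", "),
         "; vocabulary: ", paste(consequence_vocabulary(), collapse = ", "))
  }
  stopifnot(all(impact %in% .impact_levels))
  n <- max(length(consequence), length(impact))
  consequence <- rep_len(consequence, n)
  impact <- rep_len(impact, n)
  pathogenic <- rep_len(as.logical(pathogenic), n)
  destabilizing <- rep_len(as.logical(destabilizing), n)
  conserved <- rep_len(as.logical(conserved), n)
  is_coding <- consequence == "missense_variant" | impact == "HIGH"
  is_pathogenic <- impact == "HIGH" |
    (is_coding & (pathogenic | destabilizing | conserved))
  data.frame(is_coding = is_coding, is_pathogenic = is_pathogenic)
}

#' Variants eligible for annotation at a locus
#'
#' Returns the locus variants with `pvalue < p_assoc` that are within
#' `magnitude_window` orders of magnitude of the lead variant's p-value
#' (`p <= p_lead * 10^magnitude_window`, boundary inclusive). The lead
#' variant is always a member of the returned set.
#'
#' @param locus A `locus`.
#' @param gwas The `gwas_dataset` the locus was defined on.
#' @param p_assoc Association threshold (default `1e-6`).
#' @param magnitude_window Orders of magnitude (default 5).
#' @return Character vector of variant ids.
#' @export
eligible_associated_variants <- function(locus, gwas, p_assoc = 1e-6,
                                         magnitude_window = 5) {
  rec <- gwas$records
  inreg <- rec[rec$chrom == locus$chrom &
                 rec$pos >= locus$start & rec$pos <= locus$end, , drop = FALSE]
  if (!locus$lead %in% inreg$variant) stop("locus lead not present in gwas")
  p_lead <- inreg$pvalue[inreg$variant == locus$lead]
  keep <- inreg$pvalue < p_assoc &
    inreg$pvalue <= p_lead * 10^magnitude_window
  inreg$variant[keep]
}

normalize_abc <- function(abc) {
  names(abc) <- tolower(names(abc))
  if ("abc_score" %in% names(abc) && !"score" %in% names(abc)) {
    abc$score <- abc$abc_score
  }
  stopifnot(all(c("chrom", "start", "end", "gene_id", "score") %in% names(abc)))
  stopifnot(all(abc$start < abc$end), all(abc$score >= 0))
  abc
}

normalize_consequences <- function(cq) {
  names(cq) <- tolower(names(cq))
  if ("variant_id" %in% names(cq) && !"variant" %in% names(cq)) {
    cq$variant <- cq$variant_id
  }
  stopifnot(all(c("variant", "gene_id", "consequence", "impact") %in% names(cq)))
  for (fl in c("pathogenic", "destabilizing", "conserved")) {
    if (!fl %in% names(cq)) cq[[fl]] <- FALSE
    cq[[fl]] <- as.logical(cq[[fl]])
  }
  cq
}

# Genes linked by ABC at one variant: enhancer overlap tested on the 0-based
# coordinate (pos - 1 in [start, end)); per-gene max score across cell types.
abc_links_at <- function(chrom, pos, abc) {
  hit <- abc[strip_chr(abc$chrom) == strip_chr(chrom) &
               (pos - 1) >= abc$start & (pos - 1) < abc$end, , drop = FALSE]
  if (nrow(hit) == 0L) return(data.frame(gene_id = character(), score = numeric()))
  sc <- tapply(hit$score, hit$gene_id, max)
  data.frame(gene_id = names(sc), score = as.numeric(sc),
             stringsAsFactors = FALSE)
}

#' ABC overlap features per candidate gene
#'
#' For every eligible associated variant (and the lead specifically), finds
#' enhancers overlapping it, takes the maximum ABC score per gene across cell
#' types, and flags, per candidate gene: whether the gene holds the maximum
#' score at the lead (`abcmax_lead`) or at any eligible variant
#' (`abcmax_assoc`; score ties flag all tied genes), and whether any link of
#' any score exists at the lead (`abc_any_lead`) or at any eligible variant
#' (`abc_any_assoc`).
#'
#' @param locus A `locus`.
#' @param gwas The `gwas_dataset`.
#' @param eligible_variants Variant ids from [eligible_associated_variants()].
#' @param abc ABC map data frame (`CHROM`, `START`, `END` 0-based half-open,
#'   `GENE_ID`, `CELL_TYPE`, `ABC_SCORE`; case-insensitive).
#' @param candidates A `candidate_set`.
#' @return Data frame, one row per candidate gene, with the four logical
#'   ABC feature columns.
#' @export
abc_features <- function(locus, gwas, eligible_variants, abc, candidates) {
  abc <- normalize_abc(abc)
  genes <- candidates$genes$gene_id
  out <- data.frame(gene_id = genes,
                    abcmax_lead = FALSE, abcmax_assoc = FALSE,
                    abc_any_lead = FALSE, abc_any_assoc = FALSE,
                    stringsAsFactors = FALSE)
  rec <- gwas$records
  vars <- unique(c(locus$lead, eligible_variants))
  for (v in vars) {
    i <- match(v, rec$variant)
    if (is.na(i)) next
    links <- abc_links_at(rec$chrom[i], rec$pos[i], abc)
    links <- links[links$gene_id %in% genes, , drop = FALSE]
    if (nrow(links) == 0L) next
    topg <- links$gene_id[links$score == max(links$score)]
    at_lead <- v == locus$lead
    any_idx <- match(links$gene_id, out$gene_id)
    max_idx <- match(topg, out$gene_id)
    out$abc_any_assoc[any_idx] <- TRUE
    out$abcmax_assoc[max_idx] <- TRUE
    if (at_lead) {
      out$abc_any_lead[any_idx] <- TRUE
      out$abcmax_lead[max_idx] <- TRUE
    }
  }
  out
}

#' Assemble coding/pathogenicity and ABC evidence per gene at a locus
#'
#' Computes, per candidate gene, the coding and pathogenic flags over the
#' lead variant and over all eligible associated variants, plus the four ABC
#' feature flags from [abc_features()]. Consequence rows for non-candidate
#' genes are ignored with a reported count.
#'
#' @param locus A `locus`.
#' @param gwas The `gwas_dataset`.
#' @param consequences Consequence table (`VARIANT_ID`, `GENE_ID`,
#'   `CONSEQUENCE`, `IMPACT`, `PATHOGENIC`, `DESTABILIZING`, `CONSERVED`).
#' @param abc ABC map (see [abc_features()]).
#' @param candidates A `candidate_set`.
#' @param p_assoc,magnitude_window Eligibility rule parameters, see
#'   [eligible_associated_variants()].
#' @return Data frame, one row per candidate gene: `gene_id`, `locus_id`,
#'   `lead_coding`, `lead_pathogenic`, `assoc_coding`, `assoc_pathogenic`,
#'   ABC flags, `distance_to_lead`, `is_nearest`.
#' @export
annotate_gene_locus <- function(locus, gwas, consequences, abc, candidates,
                                p_assoc = 1e-6, magnitude_window = 5) {
  cq <- normalize_consequences(consequences)
  eligible <- eligible_associated_variants(locus, gwas, p_assoc,
                                           magnitude_window)
  genes <- candidates$genes$gene_id
  n_foreign <- sum(cq$variant %in% eligible & !cq$gene_id %in% genes)
  if (n_foreign > 0L) {
    message("annotate_gene_locus: ignoring ", n_foreign,
            " consequence row(s) for non-candidate genes")
  }
  cq <- cq[cq$gene_id %in% genes & cq$variant %in% eligible, , drop = FALSE]
  if (nrow(cq) > 0L) {
    cls <- classify_consequence(cq$consequence, cq$impact, cq$pathogenic,
                                cq$destabilizing, cq$conserved)
    cq$is_coding <- cls$is_coding
    cq$is_pathogenic <- cls$is_pathogenic
  }
  flag <- function(gene, at_lead, what) {
    if (nrow(cq) == 0L) return(FALSE)
    sel <- cq$gene_id == gene
    if (at_lead) sel <- sel & cq$variant == locus$lead
    any(cq[[what]][sel])
  }
  out <- data.frame(
    gene_id = genes, locus_id = locus$id,
    lead_coding = vapply(genes, flag, logical(1), at_lead = TRUE, what = "is_coding"),
    lead_pathogenic = vapply(genes, flag, logical(1), at_lead = TRUE, what = "is_pathogenic"),
    assoc_coding = vapply(genes, flag, logical(1), at_lead = FALSE, what = "is_coding"),
    assoc_pathogenic = vapply(genes, flag, logical(1), at_lead = FALSE, what = "is_pathogenic"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ab <- abc_features(locus, gwas, eligible, abc, candidates)
  out <- merge(out, ab, by = "gene_id", sort = FALSE)
  out <- merge(out, candidates$genes, by = "gene_id", sort = FALSE)
  out[order(out$distance_to_lead, out$gene_id), , drop = FALSE]
}
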