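# Downstream translational analytics: Fisher exact machinery, the three
# contingency-cube enrichments, gold-standard evaluation, ontology semantic
# similarity, drug linkage, clinical-phase risk ratios and MoA directionality.

#' Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test. Two-sided p-values sum the probabilities of
#' all tables as or less probable than the observed one; `"greater"` is the
#' upper tail on the `a` cell. The odds ratio is the sample cross-product
#' ratio `(a d)/(b c)`, with a Haldane-Anscombe 0.5 correction applied only
#' when a zero cell occurs.
#'
#' @param a,b,c_,d Non-negative integer cell counts; `a` is the focal
#'   co-occurrence cell.
#' @param sidedness `"two_sided"` (default) or `"greater"`.
#' @return List with `odds_ratio` and `pvalue`. A zero margin yields
#'   `odds_ratio = NA` and `pvalue = 1`.
#' @export
fisher_exact <- function(a, b, c_, d, sidedness = c("two_sided", "greater")) {
  sidedness <- match.arg(sidedness)
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0, a + b + c_ + d > 0)
  if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) {
    return(list(odds_ratio = NA_real_, pvalue = 1))
  }
  or <- if (any(c(a, b, c_, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  alt <- if (sidedness == "two_sided") "two.sided" else "greater"
  p <- stats::fisher.test(matrix(c(a, c_, b, d), 2L), alternative = alt)$p.value
  list(odds_ratio = or, pvalue = min(p, 1))
}

# Shared core of the three contingency-cube enrichments. `cube` is a binary
# 3-d array; the first dimension is summed over, the remaining two are the
# focal axes. For focal slice (X, Y):
#   a = sum_i cube[i, X, Y]            b = (row X total) - a
#   c = (col Y total) - a              d = grand total - rowX - colY + a
# Only slices with a >= 1 are tested; BH across all tested slices.
cube_enrichment <- function(cube, sidedness = "two_sided") {
  stopifnot(length(dim(cube)) == 3L)
  cube <- (cube != 0) * 1L
  m <- apply(cube, c(2, 3), sum)  # summed over dim 1
  row_tot <- rowSums(m)
  col_tot <- colSums(m)
  tot <- sum(m)
  rows <- list()
  for (x in seq_len(nrow(m))) {
    for (y in seq_len(ncol(m))) {
      a <- m[x, y]
      if (a < 1) next
      b <- row_tot[x] - a
      cc <- col_tot[y] - a
      d <- tot - row_tot[x] - col_tot[y] + a
      ft <- fisher_exact(a, b, cc, d, sidedness)
      rows[[length(rows) + 1L]] <- data.frame(
        focal_x = dimnames(m)[[1]][x], focal_y = dimnames(m)[[2]][y],
        a = a, b = b, c = cc, d = d,
        odds_ratio = ft$odds_ratio, pvalue = ft$pvalue,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(focal_x = character(), focal_y = character(), a = integer(),
               b = integer(), c = integer(), d = integer(),
               odds_ratio = numeric(), pvalue = numeric(), qvalue = numeric())
  if (nrow(res)) res$qvalue <- bh_fdr(res$pvalue)
  rownames(res) <- NULL
  res
}

long_to_cube <- function(df, dims) {
  fs <- lapply(dims, function(d) factor(df[[d]]))
  tab <- table(fs[[1]], fs[[2]], fs[[3]])
  (tab != 0) * 1L
}

#' Cell-type molQTL enrichment per prioritized gene
#'
#' For each gene J and molQTL dataset K, tests whether the indications for
#' which J is prioritized colocalize with dataset K more often than
#' prioritized indications do genome-wide. Diseases are collapsed to unique
#' ontology terms so a gene counts once per indication.
#'
#' @param coloc_evidence Long data frame with one row per (disease, gene,
#'   dataset) colocalization event above the H4 threshold; columns
#'   `disease`, `gene_id`, `dataset_id`.
#' @param sidedness Passed to [fisher_exact()].
#' @return Data frame per tested (gene, dataset): counts `a`-`d`,
#'   `odds_ratio`, `pvalue`, `qvalue` (BH across tested pairs).
#' @export
gene_celltype_enrichment <- function(coloc_evidence, sidedness = "two_sided") {
  cube <- long_to_cube(unique(coloc_evidence[, c("disease", "gene_id",
                                                 "dataset_id")]),
                       c("disease", "gene_id", "dataset_id"))
  res <- cube_enrichment(cube, sidedness)
  names(res)[1:2] <- c("gene_id", "dataset_id")
  res
}

#' Disease-category enrichment per prioritized gene
#'
#' For each gene J and ontology category C, tests whether the GWAS in which
#' J is prioritized belong to C more often than prioritized GWAS do overall.
#'
#' @param prioritized Long data frame with one row per (GWAS, gene,
#'   category): columns `gwas_id`, `gene_id`, `category`.
#' @param sidedness Passed to [fisher_exact()].
#' @return Data frame per tested (gene, category) with counts, odds ratio,
#'   p-value and BH q-value.
#' @export
gene_disease_category_enrichment <- function(prioritized,
                                             sidedness = "two_sided") {
  cube <- long_to_cube(unique(prioritized[, c("gwas_id", "gene_id",
                                              "category")]),
                       c("gwas_id", "gene_id", "category"))
  res <- cube_enrichment(cube, sidedness)
  names(res)[1:2] <- c("gene_id", "category")
  res
}

#' Colocalizing cell-type enrichment per disease category
#'
#' For each disease category I and molQTL dataset (or grouped tissue) K,
#' tests whether genes colocalizing in K do so for category I more often
#' than for other categories. A grouping map may collapse datasets into
#' broader tissue labels before testing (a grouped cell is the OR over its
#' member datasets).
#'
#' @param coloc_evidence Long data frame with columns `category`, `gene_id`,
#'   `dataset_id` (one row per colocalization event).
#' @param grouping Optional named character vector dataset_id -> group
#'   label.
#' @param sidedness Passed to [fisher_exact()].
#' @return Data frame per tested (category, dataset/group).
#' @export
category_celltype_enrichment <- function(coloc_evidence, grouping = NULL,
                                         sidedness = "two_sided") {
  ev <- coloc_evidence
  if (!is.null(grouping)) {
    mapped <- unname(grouping[ev$dataset_id])
    ev$dataset_id <- ifelse(is.na(mapped), ev$dataset_id, mapped)
  }
  cube <- long_to_cube(unique(ev[, c("gene_id", "category", "dataset_id")]),
                       c("gene_id", "category", "dataset_id"))
  res <- cube_enrichment(cube, sidedness)
  names(res)[1:2] <- c("category", "dataset_id")
  res
}

#' Gold-standard benchmark of prioritization selectors
#'
#' Restricts to genome-wide significant loci (lead `P < p_genomewide`) and,
#' per indication, to loci containing at least one gold-standard gene for
#' that indication; then, for each selector (a feature flag or tier cut over
#' the prioritization table), computes Fisher enrichment of gold-standard
#' genes among selected genes plus precision, recall and F1.
#'
#' @param results Prioritization table ([prioritize_study()] output,
#'   row-bound across GWAS) with an `efo` column giving each GWAS's disease
#'   term.
#' @param gold Data frame of gold-standard pairs (`gene_id`, `efo_id`).
#' @param selectors Named list; each element is a function taking the
#'   restricted table and returning a logical selection vector, or the name
#'   of a logical column.
#' @param p_genomewide Genome-wide significance threshold (default `5e-8`).
#' @return Data frame per selector: `a`-`d`, `odds_ratio`, `pvalue`,
#'   `precision`, `recall`, `f1`. Selectors with an empty universe are
#'   skipped with a message.
#' @export
evaluate_gold_standards <- function(results, gold, selectors,
                                    p_genomewide = 5e-8) {
  stopifnot("efo" %in% names(results))
  uni <- results[results$lead_pvalue < p_genomewide, , drop = FALSE]
  keep <- logical(nrow(uni))
  for (efo in unique(uni$efo)) {
    gg <- gold$gene_id[gold$efo_id == efo]
    sel <- uni$efo == efo
    loci_with_gold <- unique(uni$locus_id[sel & uni$gene_id %in% gg])
    keep[sel & uni$locus_id %in% loci_with_gold] <- TRUE
  }
  uni <- uni[keep, , drop = FALSE]
  is_gold <- mapply(function(g, e) any(gold$gene_id == g & gold$efo_id == e),
                    uni$gene_id, uni$efo)
  rows <- list()
  for (nm in names(selectors)) {
    s <- selectors[[nm]]
    picked <- if (is.function(s)) s(uni) else as.logical(uni[[s]])
    if (length(picked) == 0L) {
      message("evaluate_gold_standards: empty universe for selector ", nm)
      next
    }
    a <- sum(picked & is_gold); b <- sum(picked & !is_gold)
    cc <- sum(!picked & is_gold); d <- sum(!picked & !is_gold)
    ft <- fisher_exact(a, b, cc, d)
    precision <- if (a + b > 0) a / (a + b) else NA_real_
    recall <- if (a + cc > 0) a / (a + cc) else 0
    f1 <- if (!is.na(precision) && (precision + recall) > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      selector = nm, a = a, b = b, c = cc, d = d,
      odds_ratio = ft$odds_ratio, pvalue = ft$pvalue,
      precision = precision, recall = recall, f1 = f1,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
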