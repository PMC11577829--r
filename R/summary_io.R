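# Summary-statistic ingestion, variant filtering, locus definition and
# candidate gene assignment.

.summary_cols <- c(chrom = "CHROM", pos = "POS", ref = "REF", alt = "ALT",
                   effect_allele = "EFFECT_ALLELE", other_allele = "OTHER_ALLELE",
                   eaf = "EAF", beta = "BETA", se = "SE", pvalue = "PVAL",
                   n = "N")

#' Read GWAS or molQTL summary statistics
#'
#' Reads the tab-separated summary format (header `CHROM, POS, REF, ALT,
#' EFFECT_ALLELE, OTHER_ALLELE, EAF, BETA, SE, PVAL, N`, 1-based positions;
#' molQTL files add `GENE_ID` and `DATASET_ID`). Rows with unparseable
#' numeric fields are dropped with a reported count; duplicated variants keep
#' the record with the smaller p-value.
#'
#' @param path Path to a tab-separated file.
#' @param column_map Named character vector mapping the standard field names
#'   (`chrom`, `pos`, ..., `n`) to the file's column names; defaults to the
#'   package's own writer convention.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param study_id,trait,efo_codes Labels for the returned dataset.
#' @return A [gwas_dataset()]; the number of dropped malformed rows is
#'   available as `attr(x, "n_dropped")`.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_type = c("binary", "quantitative"),
                               study_id = basename(path), trait = study_id,
                               efo_codes = character()) {
  trait_type <- match.arg(trait_type)
  stopifnot(file.exists(path))
  cmap <- .summary_cols
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(cmap), names(raw))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  rec <- data.frame(
    chrom = as.character(raw[[cmap["chrom"]]]),
    pos = suppressWarnings(as.integer(raw[[cmap["pos"]]])),
    ref = toupper(as.character(raw[[cmap["ref"]]])),
    alt = toupper(as.character(raw[[cmap["alt"]]])),
    effect_allele = toupper(as.character(raw[[cmap["effect_allele"]]])),
    other_allele = toupper(as.character(raw[[cmap["other_allele"]]])),
    eaf = suppressWarnings(as.numeric(raw[[cmap["eaf"]]])),
    beta = suppressWarnings(as.numeric(raw[[cmap["beta"]]])),
    se = suppressWarnings(as.numeric(raw[[cmap["se"]]])),
    pvalue = suppressWarnings(as.numeric(raw[[cmap["pvalue"]]])),
    n = suppressWarnings(as.numeric(raw[[cmap["n"]]])),
    stringsAsFactors = FALSE
  )
  for (extra in c("GENE_ID", "DATASET_ID", "MOLECULE_TYPE", "CELL_TYPE")) {
    if (extra %in% names(raw)) rec[[tolower(extra)]] <- raw[[extra]]
  }
  ok <- !is.na(rec$pos) & !is.na(rec$eaf) & !is.na(rec$beta) &
    !is.na(rec$se) & !is.na(rec$pvalue) & !is.na(rec$n)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message("read_summary_stats: dropped ", n_dropped, " malformed row(s)")
  }
  rec <- rec[ok, , drop = FALSE]
  rec$variant <- variant_id(rec$chrom, rec$pos, rec$ref, rec$alt)
  # duplicate variant keys: keep the smaller p-value
  rec <- rec[order(rec$pvalue), , drop = FALSE]
  rec <- rec[!duplicated(rec$variant), , drop = FALSE]
  rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  out <- gwas_dataset(rec, study_id = study_id, trait = trait,
                      trait_type = trait_type, efo_codes = efo_codes)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write summary statistics in the package's tab-separated format
#'
#' @param x A `gwas_dataset` or a records data frame (molQTL slices carry
#'   `gene_id`/`dataset_id` columns, written as `GENE_ID`/`DATASET_ID`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  rec <- if (inherits(x, "gwas_dataset")) x$records else x
  out <- data.frame(
    CHROM = rec$chrom, POS = rec$pos, REF = rec$ref, ALT = rec$alt,
    EFFECT_ALLELE = rec$effect_allele, OTHER_ALLELE = rec$other_allele,
    EAF = rec$eaf, BETA = rec$beta, SE = rec$se, PVAL = rec$pvalue, N = rec$n,
    stringsAsFactors = FALSE
  )
  for (extra in c("gene_id", "dataset_id", "molecule_type", "cell_type")) {
    if (extra %in% names(rec)) out[[toupper(extra)]] <- rec[[extra]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default HLA exclusion region
#'
#' The human leukocyte antigen region excluded from all analyses; the
#' interval is a configurable default (chr6:25,000,000-34,000,000).
#'
#' @return One-row data frame with `chrom`, `start`, `end`.
#' @export
hla_region <- function() {
  data.frame(chrom = "6", start = 25e6, end = 34e6, stringsAsFactors = FALSE)
}

strip_chr <- function(x) sub("^chr", "", x)

#' Filter association records by MAF and excluded regions
#'
#' Removes records with minor allele frequency below `maf_min`, records
#' falling inside any excluded region (the HLA region by default), and
#' records carrying the non-finite standard-error sentinel emitted for
#' monomorphic simulated variants.
#'
#' @param gwas A `gwas_dataset`.
#' @param maf_min Minimum minor allele frequency (records with
#'   `maf < maf_min` are excluded); default `1e-4`.
#' @param exclude_regions Data frame with `chrom`, `start`, `end` (1-based,
#'   inclusive); default [hla_region()]. Use `NULL` for no region exclusion.
#' @return The filtered `gwas_dataset`.
#' @export
filter_variants <- function(gwas, maf_min = 1e-4, exclude_regions = hla_region()) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  rec <- gwas$records
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  keep <- maf >= maf_min & is.finite(rec$se) & is.finite(rec$beta)
  if (!is.null(exclude_regions) && nrow(exclude_regions) > 0L) {
    for (i in seq_len(nrow(exclude_regions))) {
      inside <- strip_chr(rec$chrom) == strip_chr(exclude_regions$chrom[i]) &
        rec$pos >= exclude_regions$start[i] & rec$pos <= exclude_regions$end[i]
      keep <- keep & !inside
    }
  }
  gwas$records <- rec[keep, , drop = FALSE]
  rownames(gwas$records) <- NULL
  gwas
}

# Merge 1-based inclusive intervals; input data frame with chrom/start/end.
merge_intervals <- function(iv) {
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  out <- list()
  for (ch in unique(iv$chrom)) {
    x <- iv[iv$chrom == ch, , drop = FALSE]
    cs <- x$start[1]; ce <- x$end[1]
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] <= ce) {
        ce <- max(ce, x$end[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cs, end = ce)
        cs <- x$start[i]; ce <- x$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cs, end = ce)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Define merged association loci
#'
#' Places a `[pos - window, pos + window]` interval around every variant with
#' `pvalue < p_threshold`, merges overlapping intervals per chromosome, and
#' reports each merged locus with its lead (minimum p-value) variant.
#'
#' @param gwas A `gwas_dataset` (typically after [filter_variants()]).
#' @param p_threshold Locus-defining p-value threshold (default `1e-6`).
#' @param window Flank in base pairs on each side of a qualifying variant
#'   (default 250,000).
#' @return A list of `locus` objects sorted by `(chrom, start)`; each is a
#'   list with `id`, `chrom`, `start`, `end`, `lead` (variant id),
#'   `lead_pos`, `lead_pvalue` and `members` (data frame of qualifying
#'   records in the locus). Lead ties on p-value are broken by smaller SE,
#'   then lexicographic variant id.
#' @export
define_loci <- function(gwas, p_threshold = 1e-6, window = 250000) {
  stopifnot(window > 0)
  rec <- gwas$records
  q <- rec[is.finite(rec$pvalue) & rec$pvalue < p_threshold, , drop = FALSE]
  if (nrow(q) == 0L) return(list())
  iv <- data.frame(chrom = q$chrom,
                   start = pmax(1, q$pos - window),
                   end = q$pos + window)
  merged <- merge_intervals(iv)
  loci <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    m <- q[q$chrom == merged$chrom[i] &
             q$pos >= merged$start[i] & q$pos <= merged$end[i], , drop = FALSE]
    m <- m[order(m$pvalue, m$se, m$variant), , drop = FALSE]
    rownames(m) <- NULL
    loci[[i]] <- structure(
      list(id = sprintf("locus_%s_%d", merged$chrom[i], as.integer(merged$start[i])),
           chrom = merged$chrom[i],
           start = merged$start[i], end = merged$end[i],
           lead = m$variant[1], lead_pos = m$pos[1],
           lead_pvalue = m$pvalue[1], members = m),
      class = "locus"
    )
  }
  loci
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("locus %s [%s:%d-%d], lead %s (p = %.3g), %d member variant(s)\n",
              x$id, x$chrom, as.integer(x$start), as.integer(x$end),
              x$lead, x$lead_pvalue, nrow(x$members)))
  invisible(x)
}

# Distance from a position to a gene footprint [start, end]; 0 if inside.
footprint_distance <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos > end, pos - end, 0))
}

normalize_gene_models <- function(genes) {
  nm <- names(genes)
  low <- tolower(nm)
  names(genes) <- low
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% low))
  genes
}

#' Assign candidate genes to a locus
#'
#' A gene is a candidate when the minimum distance from its footprint
#' (`start`-`end`) to any member variant of the locus is at most `window`
#' base pairs (boundary inclusive). The nearest gene is the one with the
#' smallest distance to the lead variant, ties broken lexicographically by
#' gene id.
#'
#' @param locus A `locus` from [define_loci()].
#' @param genes Gene models data frame (`GENE_ID`, `SYMBOL`, `CHROM`,
#'   `START`, `END`, `STRAND`; case-insensitive column names, 1-based
#'   inclusive coordinates).
#' @param window Maximum footprint-to-variant distance (default 250,000).
#' @return A `candidate_set`: list with `locus_id`, `genes` (data frame of
#'   `gene_id`, `distance_to_lead`, `is_nearest`), and `nearest`.
#' @export
assign_candidate_genes <- function(locus, genes, window = 250000) {
  g <- normalize_gene_models(genes)
  g <- g[strip_chr(g$chrom) == strip_chr(locus$chrom), , drop = FALSE]
  mem_pos <- locus$members$pos
  keep <- vapply(seq_len(nrow(g)), function(i) {
    min(footprint_distance(mem_pos, g$start[i], g$end[i])) <= window
  }, logical(1))
  g <- g[keep, , drop = FALSE]
  d_lead <- if (nrow(g)) {
    footprint_distance(locus$lead_pos, g$start, g$end)
  } else numeric()
  out <- data.frame(gene_id = g$gene_id, distance_to_lead = d_lead,
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance_to_lead, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out$is_nearest <- seq_len(nrow(out)) == 1L
  structure(
    list(locus_id = locus$id,
         genes = out,
         nearest = if (nrow(out)) out$gene_id[1] else NA_character_),
    class = "candidate_set"
  )
}
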