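# Readers/writers for the auxiliary tab-separated formats: gene models,
# ABC maps, consequence tables, gold standards, drug tables and ontology
# edge lists. All are plain TSV with header; column names are written
# upper-case and read case-insensitively.

read_tsv_upper <- function(path, required) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s) in ", basename(path), ": ",
         paste(toupper(missing), collapse = ", "))
  }
  df
}

write_tsv_upper <- function(df, path) {
  names(df) <- toupper(names(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write gene models
#'
#' Tab-separated `GENE_ID, SYMBOL, CHROM, START, END, STRAND` with 1-based
#' inclusive coordinates.
#'
#' @param path File path.
#' @return Data frame of gene models (lower-case column names).
#' @export
read_gene_models <- function(path) {
  read_tsv_upper(path, c("gene_id", "chrom", "start", "end"))
}

#' @rdname read_gene_models
#' @param genes Gene models data frame.
#' @export
write_gene_models <- function(genes, path) write_tsv_upper(genes, path)

#' Read/write an ABC enhancer-gene map
#'
#' BED-like tab-separated `CHROM, START, END, GENE_ID, CELL_TYPE,
#' ABC_SCORE` with 0-based half-open intervals.
#'
#' @param path File path.
#' @return Data frame with a `score` column (lower-case names).
#' @export
read_abc_map <- function(path) {
  df <- read_tsv_upper(path, c("chrom", "start", "end", "gene_id"))
  normalize_abc(df)
}

#' @rdname read_abc_map
#' @param abc ABC map data frame (`score` written as `ABC_SCORE`).
#' @export
write_abc_map <- function(abc, path) {
  names(abc) <- tolower(names(abc))
  if ("score" %in% names(abc)) {
    names(abc)[names(abc) == "score"] <- "abc_score"
  }
  write_tsv_upper(abc, path)
}

#' Read/write a variant consequence table
#'
#' Tab-separated `VARIANT_ID, GENE_ID, CONSEQUENCE, IMPACT, PATHOGENIC,
#' DESTABILIZING, CONSERVED`.
#'
#' @param path File path.
#' @return Data frame with a `variant` column and logical flags.
#' @export
read_consequences <- function(path) {
  df <- read_tsv_upper(path, c("gene_id", "consequence", "impact"))
  normalize_consequences(df)
}

#' @rdname read_consequences
#' @param consequences Consequence table (`variant` written as
#'   `VARIANT_ID`).
#' @export
write_consequences <- function(consequences, path) {
  names(consequences) <- tolower(names(consequences))
  if ("variant" %in% names(consequences)) {
    names(consequences)[names(consequences) == "variant"] <- "variant_id"
  }
  write_tsv_upper(consequences, path)
}

#' Read/write gold-standard gene-disease pairs
#'
#' Tab-separated `GENE_ID, EFO_ID`.
#' @param path File path.
#' @return Data frame with `gene_id`, `efo_id`.
#' @export
read_gold_standard <- function(path) {
  read_tsv_upper(path, c("gene_id", "efo_id"))
}

#' @rdname read_gold_standard
#' @param gold Gold-standard pair data frame.
#' @export
write_gold_standard <- function(gold, path) write_tsv_upper(gold, path)

#' Read/write a drug target-indication table
#'
#' Tab-separated `DRUG_ID, TARGET_GENE, INDICATION_EFO, PHASE, MOA`;
#' `PHASE` is one of `1`, `2`, `3`, `approved`.
#'
#' @param path File path.
#' @return Data frame of drug records.
#' @export
read_drug_table <- function(path) {
  df <- read_tsv_upper(path, c("drug_id", "target_gene", "indication_efo",
                               "phase", "moa"))
  df$phase <- as.character(df$phase)
  stopifnot(all(df$phase %in% c("1", "2", "3", "approved")))
  df
}

#' @rdname read_drug_table
#' @param drugs Drug table data frame.
#' @export
write_drug_table <- function(drugs, path) write_tsv_upper(drugs, path)

#' Read/write an ontology is-a edge list
#'
#' Tab-separated `CHILD, PARENT`, one edge per row.
#' @param path File path.
#' @return Data frame with `child`, `parent`, suitable for
#'   [ontology_graph()].
#' @export
read_ontology_edges <- function(path) {
  read_tsv_upper(path, c("child", "parent"))
}

#' @rdname read_ontology_edges
#' @param edges Edge data frame.
#' @export
write_ontology_edges <- function(edges, path) write_tsv_upper(edges, path)

#' Read/write an LD pair table
#'
#' Tab-separated upper-triangle list `VARIANT_A, VARIANT_B, R`; pairs not
#' listed are treated as uncorrelated by [clump()].
#'
#' @param path File path.
#' @return Data frame usable as the `ld` argument of [clump()].
#' @export
read_ld_pairs <- function(path) {
  df <- read_tsv_upper(path, c("variant_a", "variant_b", "r"))
  names(df) <- toupper(names(df))
  df
}

#' @rdname read_ld_pairs
#' @param panel An `ld_panel` whose non-zero correlations are exported.
#' @export
write_ld_pairs <- function(panel, path) {
  R <- panel$R
  ut <- which(upper.tri(R) & R != 0, arr.ind = TRUE)
  df <- data.frame(VARIANT_A = rownames(R)[ut[, 1]],
                   VARIANT_B = colnames(R)[ut[, 2]],
                   R = R[ut], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
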