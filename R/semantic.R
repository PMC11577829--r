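# Ontology semantic similarity (Resnik + Lin over information content) and
# genetics-to-drug linkage.

#' Build an ontology graph from an is-a edge list
#'
#' @param edges Data frame with `child`, `parent` columns (case-insensitive;
#'   `CHILD`/`PARENT` accepted), each edge meaning child is-a parent.
#' @param usage_counts Optional named numeric vector of term usage counts;
#'   defaults to one count per term. Information content of a term is
#'   `-log(p)` where `p` is the probability mass of the term and all its
#'   descendants.
#' @return Object of class `ontology_graph` with `terms`, `parents`
#'   (adjacency list), `ancestors` (inclusive transitive closure), `root`
#'   and `ic`.
#' @export
ontology_graph <- function(edges, usage_counts = NULL) {
  names(edges) <- tolower(names(edges))
  stopifnot(all(c("child", "parent") %in% names(edges)))
  terms <- unique(c(edges$child, edges$parent))
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  roots <- terms[vapply(parents, length, integer(1)) == 0L]
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  }
  anc <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    hit <- mget(t, envir = anc, ifnotfound = list(NULL))[[1]]
    if (!is.null(hit)) return(hit)
    if (isTRUE(mget(t, envir = visiting, ifnotfound = list(FALSE))[[1]])) {
      stop("ontology contains a directed cycle at term ", t)
    }
    assign(t, TRUE, envir = visiting)
    res <- unique(c(t, unlist(lapply(parents[[t]], get_anc))))
    assign(t, FALSE, envir = visiting)
    assign(t, res, envir = anc)
    res
  }
  ancestors <- lapply(terms, get_anc)
  names(ancestors) <- terms
  counts <- setNames(rep(1, length(terms)), terms)
  if (!is.null(usage_counts)) {
    counts[] <- 0
    counts[names(usage_counts)] <- usage_counts
  }
  # mass of a term = counts of all terms having it as an ancestor
  mass <- setNames(numeric(length(terms)), terms)
  for (t in terms) {
    for (a in ancestors[[t]]) mass[a] <- mass[a] + counts[t]
  }
  total <- mass[roots]
  ic <- -log(mass / total)
  ic[!is.finite(ic)] <- Inf
  structure(
    list(terms = terms, parents = parents, ancestors = ancestors,
         root = roots, ic = ic),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, root %s\n", length(x$terms), x$root))
  invisible(x)
}

#' Raw semantic similarity between two ontology terms
#'
#' The mean of Resnik similarity (information content of the most
#' informative common ancestor, MICA) and Lin similarity
#' (`2 IC(MICA) / (IC(a) + IC(b))`, 0 when both ICs are zero). Use
#' [similarity_matrix()] for the per-disease standardized values used for
#' linkage.
#'
#' @param term_a,term_b Term ids present in the ontology.
#' @param ontology An [ontology_graph()].
#' @return Non-negative similarity (0 when the only common ancestor is the
#'   root).
#' @export
semantic_similarity <- function(term_a, term_b, ontology) {
  for (t in c(term_a, term_b)) {
    if (!t %in% ontology$terms) stop("unknown ontology term: ", t)
  }
  common <- intersect(ontology$ancestors[[term_a]],
                      ontology$ancestors[[term_b]])
  resnik <- max(ontology$ic[common], 0)
  denom <- ontology$ic[[term_a]] + ontology$ic[[term_b]]
  lin <- if (denom > 0) 2 * resnik / denom else 0
  unname((resnik + lin) / 2)
}

#' Standardized semantic-similarity matrix
#'
#' Computes raw similarities for all row x column term pairs and, when
#' `standardize = TRUE`, divides each row by its maximum over all ontology
#' terms (so a disease's self-match scores exactly 1).
#'
#' @param row_terms,col_terms Term id vectors.
#' @param ontology An [ontology_graph()].
#' @param standardize Apply per-row standardization (default TRUE).
#' @return Numeric matrix `length(row_terms)` x `length(col_terms)`.
#' @export
similarity_matrix <- function(row_terms, col_terms, ontology,
                              standardize = TRUE) {
  sim <- outer(row_terms, col_terms,
               Vectorize(function(a, b) semantic_similarity(a, b, ontology)))
  dimnames(sim) <- list(row_terms, col_terms)
  if (standardize) {
    row_max <- vapply(row_terms, function(a) {
      semantic_similarity(a, a, ontology)
    }, numeric(1))
    sim <- sweep(sim, 1, ifelse(row_max > 0, row_max, 1), "/")
  }
  sim
}

#' Link prioritized gene-disease pairs to drug target-indication pairs
#'
#' A (target, indication) pair in the drug table is genetically supported
#' when some prioritized (gene = target, disease) pair has standardized
#' semantic similarity at least `threshold` to the indication. When several
#' GWAS support one pair, the one with the most significant locus p-value is
#' kept. Cancer indications are excluded by listing their terms in
#' `exclude_terms`.
#'
#' @param prioritized Data frame of prioritized gene-disease pairs: columns
#'   `gene_id`, `efo`, `gwas_id`, `lead_pvalue`.
#' @param drugs Drug table (`drug_id`, `target_gene`, `indication_efo`,
#'   `phase`, `moa`).
#' @param ontology An [ontology_graph()].
#' @param threshold Similarity linkage threshold (default 0.7, inclusive).
#' @param exclude_terms Indication terms to drop before linkage.
#' @return Data frame of unique target-indication pairs: `target_gene`,
#'   `indication_efo`, `max_phase`, `supported`, and for supported pairs
#'   the matched `gwas_id`, `efo`, `lead_pvalue`, `similarity`.
#' @export
link_genetics_to_drugs <- function(prioritized, drugs, ontology,
                                   threshold = 0.7,
                                   exclude_terms = character()) {
  drugs <- drugs[!drugs$indication_efo %in% exclude_terms, , drop = FALSE]
  phase_rank <- c("1" = 1L, "2" = 2L, "3" = 3L, approved = 4L)
  pairs <- unique(drugs[, c("target_gene", "indication_efo")])
  pairs$max_phase <- mapply(function(t, ind) {
    max(phase_rank[drugs$phase[drugs$target_gene == t &
                                 drugs$indication_efo == ind]])
  }, pairs$target_gene, pairs$indication_efo)
  diseases <- unique(prioritized$efo)
  indications <- unique(pairs$indication_efo)
  sim <- similarity_matrix(diseases, indications, ontology)
  pairs$supported <- FALSE
  pairs$gwas_id <- NA_character_
  pairs$efo <- NA_character_
  pairs$lead_pvalue <- NA_real_
  pairs$similarity <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    hits <- prioritized[prioritized$gene_id == pairs$target_gene[i], ,
                        drop = FALSE]
    if (nrow(hits) == 0L) next
    hits$similarity <- sim[hits$efo, pairs$indication_efo[i]]
    hits <- hits[hits$similarity >= threshold, , drop = FALSE]
    if (nrow(hits) == 0L) next
    best <- hits[order(hits$lead_pvalue), , drop = FALSE][1, ]
    pairs$supported[i] <- TRUE
    pairs$gwas_id[i] <- best$gwas_id
    pairs$efo[i] <- best$efo
    pairs$lead_pvalue[i] <- best$lead_pvalue
    pairs$similarity[i] <- best$similarity
  }
  rownames(pairs) <- NULL
  pairs
}

#' Clinical-phase risk ratios for genetically supported targets
#'
#' For each cumulative phase threshold, the risk ratio is the probability of
#' a target-indication pair reaching at least that phase given genetic
#' support, over the same probability without support, with a Fisher exact
#' p-value from the corresponding 2x2 table.
#'
#' @param linked Output of [link_genetics_to_drugs()].
#' @param phases Phase thresholds to evaluate (default all four).
#' @return Data frame per phase: counts, `risk_ratio` (NA when a stratum is
#'   empty), `pvalue`.
#' @export
clinical_phase_risk_ratios <- function(linked,
                                       phases = c("1", "2", "3", "approved")) {
  phase_rank <- c("1" = 1L, "2" = 2L, "3" = 3L, approved = 4L)
  rows <- list()
  for (ph in phases) {
    reach <- linked$max_phase >= phase_rank[ph]
    a <- sum(linked$supported & reach)
    b <- sum(linked$supported & !reach)
    cc <- sum(!linked$supported & reach)
    d <- sum(!linked$supported & !reach)
    p_sup <- if (a + b > 0) a / (a + b) else NA_real_
    p_uns <- if (cc + d > 0) cc / (cc + d) else NA_real_
    rr <- if (!is.na(p_sup) && !is.na(p_uns) && p_uns > 0) p_sup / p_uns
      else NA_real_
    ft <- fisher_exact(a, b, cc, d)
    rows[[length(rows) + 1L]] <- data.frame(
      phase = ph, a = a, b = b, c = cc, d = d, risk_ratio = rr,
      pvalue = ft$pvalue, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Beneficial MoA direction from a low-frequency lead coding variant
#'
#' Assumes a low-frequency (MAF below `maf_limit`) lead coding variant is
#' disruptive (loss of function). The effect is re-expressed for the minor
#' allele: a risk-increasing minor allele implies activation would be
#' beneficial, a protective one implies inhibition.
#'
#' @param beta Effect size for the record's effect allele.
#' @param eaf Effect-allele frequency.
#' @param maf_limit Maximum MAF for a prediction (default 0.05, exclusive).
#' @return List with `prediction` (`"activation"`/`"inhibition"` or NA),
#'   `basis_sign`, `source = "coding_variant"`, and a `reason` when no
#'   prediction is made.
#' @export
moa_direction_from_coding <- function(beta, eaf, maf_limit = 0.05) {
  maf <- min(eaf, 1 - eaf)
  if (maf >= maf_limit) {
    return(list(prediction = NA_character_, basis_sign = NA_character_,
                source = "coding_variant", reason = "maf_above_limit"))
  }
  beta_minor <- if (eaf <= 0.5) beta else -beta
  if (beta_minor == 0) {
    return(list(prediction = NA_character_, basis_sign = NA_character_,
                source = "coding_variant", reason = "null_effect"))
  }
  list(
    prediction = if (beta_minor > 0) "activation" else "inhibition",
    basis_sign = if (beta_minor > 0) "+" else "-",
    source = "coding_variant", reason = NA_character_
  )
}

#' Beneficial MoA direction from an MR consensus across molQTL
#'
#' Considers only MR results that are significant (`qvalue < q_threshold`)
#' and colocalize with the GWAS signal (`pp_h4 > h4_threshold`). A consensus
#' direction requires the MR sign to agree across strictly more than
#' `consensus_frac` of qualifying datasets: a negative consensus (more
#' expression, less risk) predicts activation as beneficial; positive
#' predicts inhibition.
#'
#' @param mr_rows Data frame with `beta`, `qvalue`, `pp_h4` for one gene x
#'   disease across molQTL datasets.
#' @param h4_threshold,q_threshold,consensus_frac Gates as described
#'   (defaults 0.8, 0.05, 0.75).
#' @return List with `prediction`, `basis_sign`, `source = "mr_consensus"`,
#'   `n_qualifying`, and a `reason` when no prediction is made.
#' @export
moa_direction_from_mr <- function(mr_rows, h4_threshold = 0.8,
                                  q_threshold = 0.05,
                                  consensus_frac = 0.75) {
  q <- mr_rows[mr_rows$qvalue < q_threshold &
                 !is.na(mr_rows$pp_h4) & mr_rows$pp_h4 > h4_threshold, ,
               drop = FALSE]
  if (nrow(q) == 0L) {
    return(list(prediction = NA_character_, basis_sign = NA_character_,
                source = "mr_consensus", n_qualifying = 0L,
                reason = "no_qualifying_datasets"))
  }
  frac_pos <- mean(q$beta > 0)
  frac_neg <- mean(q$beta < 0)
  if (max(frac_pos, frac_neg) <= consensus_frac) {
    return(list(prediction = NA_character_, basis_sign = NA_character_,
                source = "mr_consensus", n_qualifying = nrow(q),
                reason = "no_consensus"))
  }
  pos <- frac_pos > frac_neg
  list(
    prediction = if (pos) "inhibition" else "activation",
    basis_sign = if (pos) "+" else "-",
    source = "mr_consensus", n_qualifying = nrow(q), reason = NA_character_
  )
}

#' Default MoA keyword mapping
#'
#' Maps drug MoA keywords to the inhibition class (`antagonist`,
#' `inhibitor`, `degrader`) or the activation class (`agonist`,
#' `activator`); other keywords are excluded from concordance.
#' @export
moa_keyword_map <- function() {
  c(antagonist = "inhibition", inhibitor = "inhibition",
    degrader = "inhibition", agonist = "activation",
    activator = "activation")
}

#' Concordance between predicted and actual drug MoA
#'
#' Cross-tabulates the genetically predicted beneficial direction against
#' the drug's MoA class for drugs at or above `min_phase`; drugs whose MoA
#' keyword maps to neither class are excluded. Reports the concordant
#' fraction and a Fisher exact p-value on the 2x2 prediction x MoA-class
#' table.
#'
#' @param predictions Data frame with `target_gene`, `indication_efo`,
#'   `prediction` (`"inhibition"`/`"activation"`).
#' @param drugs Drug table (`target_gene`, `indication_efo`, `phase`,
#'   `moa`).
#' @param keyword_map Named map keyword -> class; see [moa_keyword_map()].
#' @param min_phase Minimum clinical phase (default `"2"`).
#' @return List with `table` (2x2 prediction x class counts), `n`,
#'   `concordance` (fraction), `pvalue`.
#' @export
moa_concordance <- function(predictions, drugs,
                            keyword_map = moa_keyword_map(),
                            min_phase = "2") {
  phase_rank <- c("1" = 1L, "2" = 2L, "3" = 3L, approved = 4L)
  d <- drugs[phase_rank[drugs$phase] >= phase_rank[min_phase], , drop = FALSE]
  d$class <- unname(keyword_map[d$moa])
  d <- d[!is.na(d$class), , drop = FALSE]
  m <- merge(predictions[!is.na(predictions$prediction), ,
                         drop = FALSE], d,
             by = c("target_gene", "indication_efo"))
  classes <- c("inhibition", "activation")
  tab <- table(factor(m$prediction, classes), factor(m$class, classes))
  n <- sum(tab)
  concordance <- if (n > 0) sum(diag(tab)) / n else NA_real_
  pvalue <- if (n > 0) {
    fisher_exact(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$pvalue
  } else NA_real_
  list(table = tab, n = n, concordance = concordance, pvalue = pvalue)
}
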