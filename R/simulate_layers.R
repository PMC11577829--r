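# Synthetic annotation evidence (gene models, consequence rows, ABC rows)
# and toy translational tables (drugs, gold standards, ontology).

#' Deterministic gene models around a panel's causal variant
#'
#' Lays out gene footprints so that the first gene in `genes` contains the
#' causal variant (distance 0, the nearest gene) and the remaining genes sit
#' at increasing distances on alternating sides, all within the candidate
#' window.
#'
#' @param panel An `ld_panel`.
#' @param genes Character vector of gene ids; the first is placed nearest.
#' @param causal_index Index of the causal variant in the panel.
#' @param width Gene footprint width in bp (default 20,000).
#' @param step Distance increment between successive decoys (default 30,000).
#' @return Gene models data frame (`gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`).
#' @export
simulate_gene_models <- function(panel, genes, causal_index,
                                 width = 20000L, step = 30000L) {
  v <- panel$variants
  cp <- v$pos[causal_index]
  n <- length(genes)
  start <- integer(n); end <- integer(n)
  start[1] <- max(1L, cp - as.integer(width / 2))
  end[1] <- start[1] + width
  if (n > 1) {
    for (k in seq(2L, n)) {
      side <- if (k %% 2 == 0) 1L else -1L
      offset <- step * ((k %/% 2)) + width
      center <- cp + side * offset
      start[k] <- max(1L, center - as.integer(width / 2))
      end[k] <- start[k] + width
    }
  }
  data.frame(gene_id = genes, symbol = genes, chrom = v$chrom[1],
             start = start, end = end, strand = "+",
             stringsAsFactors = FALSE)
}

.evidence_features <- c("lead_pathogenic", "lead_coding", "assoc_pathogenic",
                        "assoc_coding", "abcmax_lead", "abcmax_assoc",
                        "abc_any_lead", "abc_any_assoc")

#' Plant annotation evidence for chosen genes
#'
#' Builds consequence and ABC tables in which the features named by
#' `evidence_plan` are literally detectable by the annotation module at the
#' GWAS causal variant (or a tightly linked neighbour for `assoc_*`
#' features), while decoy genes receive no planted evidence.
#'
#' @param panel An `ld_panel`.
#' @param genes Character vector of gene ids present at the locus.
#' @param gwas_truth The GWAS `truth_record` (identifies the causal/lead
#'   variant the plan refers to).
#' @param evidence_plan Named list mapping feature names (any of
#'   `lead_pathogenic`, `lead_coding`, `assoc_pathogenic`, `assoc_coding`,
#'   `abcmax_lead`, `abcmax_assoc`, `abc_any_lead`, `abc_any_assoc`) to a
#'   gene id. An empty list plants nothing.
#' @param seed Integer seed (layout is deterministic; the seed fixes
#'   the cell-type label draw).
#' @param cell_type Cell-type label for planted ABC rows.
#' @return List with `consequences`, `abc`, and `genes` (gene models from
#'   [simulate_gene_models()], first plan-free gene placement).
#' @export
simulate_annotation_layers <- function(panel, genes, gwas_truth,
                                       evidence_plan = list(), seed = 1L,
                                       cell_type = "planted_tissue") {
  stopifnot(all(names(evidence_plan) %in% .evidence_features))
  plan_genes <- unlist(evidence_plan, use.names = FALSE)
  if (length(plan_genes) && !all(plan_genes %in% genes)) {
    stop("evidence_plan references absent gene(s): ",
         paste(setdiff(plan_genes, genes), collapse = ", "))
  }
  v <- panel$variants
  ci <- match(gwas_truth$causal_variant, v$id)
  stopifnot(!is.na(ci))
  gene_models <- simulate_gene_models(panel, genes, ci)
  # neighbour in the same LD block: an associated (but non-lead) variant
  ni <- if (ci < nrow(v) && v$block[ci + 1L] == v$block[ci]) ci + 1L else ci - 1L
  cq <- list(); ab <- list()
  add_cq <- function(idx, gene, pathogenic) {
    cq[[length(cq) + 1L]] <<- data.frame(
      variant = v$id[idx], gene_id = gene, consequence = "missense_variant",
      impact = "MODERATE", pathogenic = pathogenic, destabilizing = FALSE,
      conserved = FALSE, stringsAsFactors = FALSE
    )
  }
  add_abc <- function(idx, gene, score) {
    ab[[length(ab) + 1L]] <<- data.frame(
      chrom = v$chrom[idx], start = v$pos[idx] - 1L - 500L,
      end = v$pos[idx] + 500L, gene_id = gene, cell_type = cell_type,
      score = score, stringsAsFactors = FALSE
    )
  }
  other_gene <- function(g) {
    alt <- setdiff(genes, g)
    if (length(alt)) alt[1] else NA_character_
  }
  for (feat in names(evidence_plan)) {
    g <- evidence_plan[[feat]]
    switch(feat,
      lead_pathogenic = add_cq(ci, g, TRUE),
      lead_coding = add_cq(ci, g, FALSE),
      assoc_pathogenic = add_cq(ni, g, TRUE),
      assoc_coding = add_cq(ni, g, FALSE),
      abcmax_lead = {
        add_abc(ci, g, 0.12)
        og <- other_gene(g)
        if (!is.na(og)) add_abc(ci, og, 0.03)
      },
      abcmax_assoc = {
        add_abc(ni, g, 0.12)
        og <- other_gene(g)
        if (!is.na(og)) add_abc(ni, og, 0.03)
      },
      abc_any_lead = {
        add_abc(ci, g, 0.02)
        og <- other_gene(g)
        if (!is.na(og)) add_abc(ci, og, 0.10)
      },
      abc_any_assoc = {
        add_abc(ni, g, 0.02)
        og <- other_gene(g)
        if (!is.na(og)) add_abc(ni, og, 0.10)
      }
    )
  }
  empty_cq <- data.frame(variant = character(), gene_id = character(),
                         consequence = character(), impact = character(),
                         pathogenic = logical(), destabilizing = logical(),
                         conserved = logical(), stringsAsFactors = FALSE)
  empty_ab <- data.frame(chrom = character(), start = integer(),
                         end = integer(), gene_id = character(),
                         cell_type = character(), score = numeric(),
                         stringsAsFactors = FALSE)
  list(
    consequences = if (length(cq)) do.call(rbind, cq) else empty_cq,
    abc = if (length(ab)) do.call(rbind, ab) else empty_ab,
    genes = gene_models
  )
}

.moa_keywords <- list(
  inhibition = c("antagonist", "inhibitor", "degrader"),
  activation = c("agonist", "activator"),
  other = c("modulator", "other")
)

# Rooted toy disease ontology: root -> categories -> binary subdivisions per
# extra depth level -> disease terms as leaves (round-robin).
build_toy_ontology <- function(diseases, n_categories = 3L, depth = 3L) {
  stopifnot(depth >= 2L)
  root <- "EFO:ROOT"
  edges <- list()
  level <- paste0("EFO:CAT", seq_len(n_categories))
  for (t in level) edges[[length(edges) + 1L]] <- c(t, root)
  for (d in seq_len(max(0L, depth - 2L))) {
    nxt <- character()
    for (t in level) {
      for (s in 1:2) {
        child <- paste0(t, ".", s)
        edges[[length(edges) + 1L]] <- c(child, t)
        nxt <- c(nxt, child)
      }
    }
    level <- nxt
  }
  for (i in seq_along(diseases)) {
    parent <- level[((i - 1L) %% length(level)) + 1L]
    edges[[length(edges) + 1L]] <- c(diseases[i], parent)
  }
  m <- do.call(rbind, edges)
  data.frame(child = m[, 1], parent = m[, 2], stringsAsFactors = FALSE)
}

#' Simulate toy translational tables
#'
#' Generates a rooted disease ontology DAG, a gold-standard gene-disease
#' table, and a drug target-indication-phase-MoA table with controllable
#' planted structure: drug targets in `supported_genes` advance through
#' clinical phases at `advance_prob[1]` per step (others at
#' `advance_prob[2]`), and for targets listed in `moa_truth` the MoA keyword
#' is drawn from the beneficial class with probability `moa_concordance`.
#'
#' @param genes Gene ids drugs may target.
#' @param diseases Disease term ids (become ontology leaves).
#' @param n_drugs Number of drug rows.
#' @param ontology_depth Levels from root to disease terms (>= 2).
#' @param seed Integer seed.
#' @param n_categories Top-level ontology categories.
#' @param gold_pairs Optional data frame (`gene_id`, `efo_id`); default
#'   samples one gold gene per disease.
#' @param moa_truth Optional named character vector gene ->
#'   `"inhibition"`/`"activation"` (the genetically beneficial direction).
#' @param moa_concordance Probability a drug's MoA matches `moa_truth` for
#'   its target (default 1).
#' @param supported_genes Genes whose drugs advance faster (default none).
#' @param advance_prob Per-step phase advancement probabilities
#'   `c(supported, unsupported)`.
#' @return List with `drugs` (`drug_id`, `target_gene`, `indication_efo`,
#'   `phase`, `moa`), `gold` (`gene_id`, `efo_id`), `ontology` (child ->
#'   parent edge data frame), `disease_terms`.
#' @export
simulate_translation_tables <- function(genes, diseases, n_drugs = 100L,
                                        ontology_depth = 3L, seed = 1L,
                                        n_categories = 3L, gold_pairs = NULL,
                                        moa_truth = NULL, moa_concordance = 1,
                                        supported_genes = character(),
                                        advance_prob = c(0.5, 0.25)) {
  stopifnot(ontology_depth >= 2L, n_drugs >= 1L)
  with_seed(seed, {
    ontology <- build_toy_ontology(diseases, n_categories, ontology_depth)
    if (is.null(gold_pairs)) {
      gold_pairs <- data.frame(
        gene_id = sample(genes, length(diseases), replace = TRUE),
        efo_id = diseases, stringsAsFactors = FALSE
      )
    }
    target <- sample(genes, n_drugs, replace = TRUE)
    indication <- sample(diseases, n_drugs, replace = TRUE)
    p_adv <- ifelse(target %in% supported_genes, advance_prob[1],
                    advance_prob[2])
    steps <- matrix(rbinom(3L * n_drugs, 1L, rep(p_adv, each = 3L)),
                    nrow = 3L)
    phase_num <- 1L + colSums(apply(steps, 2, cumprod))
    phase <- c("1", "2", "3", "approved")[phase_num]
    moa <- vapply(target, function(g) {
      if (!is.null(moa_truth) && g %in% names(moa_truth)) {
        cls <- moa_truth[[g]]
        if (runif(1) > moa_concordance) {
          cls <- setdiff(c("inhibition", "activation"), cls)
        }
        sample(.moa_keywords[[cls]], 1L)
      } else {
        sample(unlist(.moa_keywords), 1L)
      }
    }, character(1))
    drugs <- data.frame(
      drug_id = sprintf("DRUG%04d", seq_len(n_drugs)),
      target_gene = target, indication_efo = indication,
      phase = phase, moa = moa, stringsAsFactors = FALSE
    )
    list(drugs = drugs, gold = gold_pairs, ontology = ontology,
         disease_terms = diseases)
  })
}
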