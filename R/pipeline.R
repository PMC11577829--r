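# Scenario-level synthetic study generation and the end-to-end
# prioritization pipeline driver.

#' One locus specification for a synthetic study
#'
#' @param plan Evidence plan for the causal gene: `"lead_pathogenic"`,
#'   `"coding"` (lead coding variant only), `"coloc_abcmax"` (three shared
#'   molQTL datasets plus ABCmax at the lead), `"nearest"` (no planted
#'   evidence; the causal gene is the nearest gene), or `"null"` (no causal
#'   signal at all).
#' @param n_genes Candidate genes at the locus (>= 2 recommended).
#' @param causal_nearest Place the causal gene nearest to the lead variant.
#'   Defaults to TRUE for `"nearest"`, FALSE otherwise, so evidence-planted
#'   loci test evidence rather than distance.
#' @param n_variants,block_size,rho,maf_range LD panel parameters.
#' @param beta_gwas,n_gwas GWAS effect size (trait-SD units) and sample
#'   size.
#' @param beta_molqtl,n_molqtl molQTL effect size and sample size for
#'   `"coloc_abcmax"` loci.
#' @return A `locus_spec` list.
#' @export
locus_spec <- function(plan = c("lead_pathogenic", "coding", "coloc_abcmax",
                                "nearest", "null"),
                       n_genes = 4L, causal_nearest = NULL,
                       n_variants = 60L, block_size = 10L, rho = 0.9,
                       maf_range = c(0.1, 0.5),
                       beta_gwas = 0.5, n_gwas = 10000L,
                       beta_molqtl = 0.4, n_molqtl = 5000L) {
  plan <- match.arg(plan)
  if (is.null(causal_nearest)) causal_nearest <- plan %in% c("nearest", "null")
  structure(
    list(plan = plan, n_genes = n_genes, causal_nearest = causal_nearest,
         n_variants = n_variants, block_size = block_size, rho = rho,
         maf_range = maf_range, beta_gwas = beta_gwas, n_gwas = n_gwas,
         beta_molqtl = beta_molqtl, n_molqtl = n_molqtl),
    class = "locus_spec"
  )
}

# Expected rank-table tier for each evidence plan.
plan_expected_tier <- function(plan) {
  switch(plan,
         lead_pathogenic = "VERY_HIGH",
         coloc_abcmax = "VERY_HIGH",
         coding = "HIGH",
         nearest = "WEAK",
         null = NA_character_)
}

#' Simulate a multi-locus study with planted ground truth
#'
#' Generates, per locus specification, an LD panel on its own chromosome, a
#' GWAS signal with a planted causal variant, the evidence layers the plan
#' asks for (consequence rows, ABC rows, shared molQTL datasets), decoy
#' genes with no planted evidence, and assembles everything into a single
#' GWAS dataset plus the study-wide annotation, molQTL and gene-model
#' tables.
#'
#' @param specs List of [locus_spec()]s, one per locus.
#' @param seed Integer master seed; every locus derives its own sub-seeds
#'   from it deterministically.
#' @param study_id,trait,efo_codes GWAS labels.
#' @param molqtl_datasets Data frame describing the molQTL datasets planted
#'   at `"coloc_abcmax"` loci: columns `dataset_id`, `molecule_type`,
#'   `cell_type` (default three eQTL tissues and one pQTL).
#' @return List with `gwas` (a `gwas_dataset`), `genes`, `consequences`,
#'   `abc`, `molqtl` (long data frame, possibly empty), `panels` (list of
#'   `ld_panel`s for LD lookups), and `truth` (per-locus data frame with
#'   chromosome, causal variant, causal gene, plan and expected tier).
#' @export
simulate_study <- function(specs, seed = 1L, study_id = "SIM_STUDY",
                           trait = study_id, efo_codes = character(),
                           molqtl_datasets = data.frame(
                             dataset_id = c("eqtl_blood", "eqtl_liver",
                                            "eqtl_brain", "pqtl_plasma"),
                             molecule_type = c("eQTL", "eQTL", "eQTL", "pQTL"),
                             cell_type = c("blood", "liver", "brain", "plasma"),
                             stringsAsFactors = FALSE
                           )) {
  records <- list(); genes <- list(); cqs <- list(); abcs <- list()
  mols <- list(); panels <- list(); truth <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sseed <- (seed * 1000L + i) %% .Machine$integer.max
    panel <- simulate_ld_panel(sp$n_variants, sp$block_size, sp$rho,
                               maf_range = sp$maf_range, seed = sseed,
                               chrom = as.character(i))
    causal_index <- as.integer(ceiling(sp$n_variants / 2))
    beta <- if (sp$plan == "null") 0 else sp$beta_gwas
    g <- simulate_gwas(panel, causal_index, beta, sp$n_gwas,
                       trait_type = "quantitative", seed = sseed + 1L,
                       study_id = study_id)
    gene_ids <- sprintf("L%dG%d", i, seq_len(sp$n_genes))
    causal_gene <- if (sp$plan == "null") NA_character_ else
      if (sp$causal_nearest) gene_ids[1] else gene_ids[2]
    plan_list <- if (sp$plan == "lead_pathogenic") {
      list(lead_pathogenic = causal_gene)
    } else if (sp$plan == "coding") {
      list(lead_coding = causal_gene)
    } else if (sp$plan == "coloc_abcmax") {
      list(abcmax_lead = causal_gene)
    } else {
      list()
    }
    layers <- simulate_annotation_layers(panel, gene_ids, g$truth,
                                         evidence_plan = plan_list,
                                         seed = sseed + 2L)
    if (sp$plan == "coloc_abcmax") {
      for (k in seq_len(nrow(molqtl_datasets))) {
        mq <- simulate_molqtl(
          panel, causal_gene, mode = "shared", gwas_truth = g$truth,
          beta_true = sp$beta_molqtl, n = sp$n_molqtl,
          dataset_id = molqtl_datasets$dataset_id[k],
          seed = sseed + 10L + k,
          molecule_type = molqtl_datasets$molecule_type[k],
          cell_type = molqtl_datasets$cell_type[k]
        )
        mols[[length(mols) + 1L]] <- mq$records
      }
    }
    records[[i]] <- g$records
    genes[[i]] <- layers$genes
    cqs[[i]] <- layers$consequences
    abcs[[i]] <- layers$abc
    panels[[i]] <- panel
    truth[[i]] <- data.frame(
      chrom = as.character(i), causal_variant = g$truth$causal_variant,
      causal_gene = causal_gene, plan = sp$plan,
      expected_tier = plan_expected_tier(sp$plan), stringsAsFactors = FALSE
    )
  }
  gwas <- gwas_dataset(do.call(rbind, records), study_id = study_id,
                       trait = trait, trait_type = "quantitative",
                       efo_codes = efo_codes)
  list(
    gwas = gwas,
    genes = do.call(rbind, genes),
    consequences = do.call(rbind, cqs),
    abc = do.call(rbind, abcs),
    molqtl = if (length(mols)) do.call(rbind, mols) else NULL,
    panels = panels,
    truth = do.call(rbind, truth)
  )
}

#' Run the full prioritization pipeline on one GWAS
#'
#' Filters variants, defines merged loci, assigns candidate genes,
#' annotates coding/pathogenicity and ABC features, runs the MR scan and
#' the MR-gated colocalization scan, and emits the per-locus prioritization
#' table.
#'
#' @param gwas A `gwas_dataset`.
#' @param genes Gene models data frame.
#' @param consequences,abc Annotation tables (may have zero rows).
#' @param molqtl Long molQTL data frame or NULL.
#' @param ld LD source for clumping (panel, list of panels, or pair table).
#' @param config Named list of thresholds; recognized keys (with defaults):
#'   `maf_min` (1e-4), `hla` ([hla_region()]), `p_locus` (1e-6),
#'   `window_bp` (250000), `p_instrument` (1e-4), `molqtl_maf_min` (0.01),
#'   `mr_q` (0.05), `h4_threshold` (0.8), `coloc_multi` (2),
#'   `magnitude_window` (5).
#' @param truth Optional truth data frame from [simulate_study()]; when
#'   given, the planted causal gene is joined into the output per locus.
#' @return List with `loci`, `candidates`, `annotations`, `mr`, `coloc`
#'   and `table` (the [prioritize_study()] output).
#' @export
run_prioritization <- function(gwas, genes, consequences, abc, molqtl, ld,
                               config = list(), truth = NULL) {
  cfg <- utils::modifyList(list(
    maf_min = 1e-4, hla = hla_region(), p_locus = 1e-6, window_bp = 250000,
    p_instrument = 1e-4, molqtl_maf_min = 0.01, mr_q = 0.05,
    h4_threshold = 0.8, coloc_multi = 2L, magnitude_window = 5
  ), config)
  gwas <- filter_variants(gwas, cfg$maf_min, cfg$hla)
  loci <- define_loci(gwas, cfg$p_locus, cfg$window_bp)
  if (length(loci) == 0L) {
    return(list(loci = loci, candidates = list(), annotations = NULL,
                mr = NULL, coloc = NULL, table = NULL))
  }
  candidates <- lapply(loci, assign_candidate_genes, genes = genes,
                       window = cfg$window_bp)
  annotations <- do.call(rbind, lapply(seq_along(loci), function(i) {
    annotate_gene_locus(loci[[i]], gwas, consequences, abc, candidates[[i]],
                        p_assoc = cfg$p_locus,
                        magnitude_window = cfg$magnitude_window)
  }))
  if (!is.null(molqtl) && nrow(molqtl) > 0L) {
    mr <- mr_scan(gwas, molqtl, ld, candidates,
                  p_instrument = cfg$p_instrument,
                  maf_min = cfg$molqtl_maf_min)
    coloc <- coloc_scan(gwas, molqtl, loci, candidates, mr,
                        mr_q = cfg$mr_q, window = cfg$window_bp)
  } else {
    mr <- data.frame(gene_id = character(), dataset_id = character(),
                     molecule_type = character(), gwas_id = character(),
                     method = character(), n_instruments = integer(),
                     beta = numeric(), se = numeric(), pvalue = numeric(),
                     qvalue = numeric())
    coloc <- data.frame(gene_id = character(), dataset_id = character(),
                        gwas_id = character(), locus_id = character(),
                        n_snps = integer(), pp_h0 = numeric(),
                        pp_h1 = numeric(), pp_h2 = numeric(),
                        pp_h3 = numeric(), pp_h4 = numeric(),
                        status = character())
  }
  thr <- priority_thresholds(cfg$h4_threshold, cfg$mr_q, cfg$coloc_multi)
  tbl <- if (is.null(truth)) NULL else truth_by_locus(loci, truth)
  tab <- prioritize_study(gwas, loci, candidates, annotations, mr, coloc,
                          thresholds = thr, truth_by_locus = tbl)
  list(loci = loci, candidates = candidates, annotations = annotations,
       mr = mr, coloc = coloc, table = tab)
}

#' Truth lookup keyed by locus for a simulated study
#'
#' Matches each defined locus to the simulated truth table by chromosome.
#'
#' @param loci List of loci from [define_loci()].
#' @param truth The `truth` data frame from [simulate_study()].
#' @return Named character vector locus id -> planted causal gene.
#' @export
truth_by_locus <- function(loci, truth) {
  out <- vapply(loci, function(l) {
    hit <- truth$causal_gene[truth$chrom == l$chrom]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  names(out) <- vapply(loci, `[[`, character(1), "id")
  out
}
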