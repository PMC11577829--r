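# Marginal association statistics from individual-level simulation.
#
# Quantitative traits use per-variant simple linear regression in closed form;
# binary traits use the logistic score test (one-step estimate), the fast
# approximation biobank GWAS pipelines rely on, so betas are log-odds.

marginal_stats_quantitative <- function(G, y) {
  n <- length(y)
  gbar <- colMeans(G)
  yc <- y - mean(y)
  Sxx <- colSums(G^2) - n * gbar^2
  Sxy <- drop(crossprod(G, yc))
  Syy <- sum(yc^2)
  mono <- Sxx <= .Machine$double.eps * n
  beta <- ifelse(mono, 0, Sxy / Sxx)
  sse <- pmax(Syy - beta * Sxy, 0)
  sigma2 <- sse / (n - 2)
  se <- ifelse(mono, Inf, sqrt(sigma2 / Sxx))
  tval <- ifelse(mono, 0, beta / se)
  p <- ifelse(mono, 1, 2 * pt(-abs(tval), df = n - 2))
  list(beta = beta, se = se, pvalue = pmin(pmax(p, .Machine$double.xmin), 1))
}

marginal_stats_binary <- function(G, y) {
  n <- length(y)
  mu <- mean(y)
  gbar <- colMeans(G)
  Sxx <- colSums(G^2) - n * gbar^2
  V <- mu * (1 - mu) * Sxx
  U <- drop(crossprod(G, y - mu))
  mono <- V <= .Machine$double.eps * n
  beta <- ifelse(mono, 0, U / V)
  se <- ifelse(mono, Inf, 1 / sqrt(V))
  z <- ifelse(mono, 0, U / sqrt(V))
  p <- ifelse(mono, 1, 2 * pnorm(-abs(z)))
  list(beta = beta, se = se, pvalue = pmin(pmax(p, .Machine$double.xmin), 1))
}

assoc_records <- function(panel, G, stats, n) {
  v <- panel$variants
  data.frame(
    variant = v$id, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    effect_allele = v$alt, other_allele = v$ref,
    eaf = colMeans(G) / 2,
    beta = stats$beta, se = stats$se, pvalue = stats$pvalue,
    n = n, row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Construct a GWAS dataset container
#'
#' @param records Data frame of per-variant association records (columns
#'   `variant`, `chrom`, `pos`, `ref`, `alt`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`).
#' @param study_id,trait Labels.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param efo_codes Character vector of ontology term ids for the trait.
#' @param truth Optional `truth_record` for simulated data.
#' @return An object of class `gwas_dataset`.
#' @export
gwas_dataset <- function(records, study_id = "GWAS", trait = study_id,
                         trait_type = c("binary", "quantitative"),
                         efo_codes = character(), truth = NULL) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records), !anyDuplicated(records$variant))
  structure(
    list(study_id = study_id, trait = trait, trait_type = trait_type,
         efo_codes = efo_codes, records = records, truth = truth),
    class = "gwas_dataset"
  )
}

#' @export
print.gwas_dataset <- function(x, ...) {
  cat(sprintf("gwas_dataset '%s' (%s): %d variants, trait '%s'\n",
              x$study_id, x$trait_type, nrow(x$records), x$trait))
  invisible(x)
}

truth_record <- function(causal_variant, beta_true, seed,
                         causal_gene = NA_character_,
                         shared_with_gwas = NA) {
  structure(
    list(causal_variant = causal_variant, causal_gene = causal_gene,
         beta_true = beta_true, shared_with_gwas = shared_with_gwas,
         seed = as.integer(seed)),
    class = "truth_record"
  )
}

#' Simulate GWAS summary statistics with a planted causal variant
#'
#' Draws individual-level genotypes from an [simulate_ld_panel()] panel, adds
#' a single additive causal effect plus noise (logistic link for binary
#' traits), and reduces to per-variant marginal summary statistics, emulating
#' the biobank GWAS inputs of the prioritization pipeline.
#'
#' @param panel An `ld_panel`.
#' @param causal_index Index (or vector of indices) of the causal variant(s)
#'   in the panel.
#' @param beta_true Per-ALT-allele effect, recycled along `causal_index`:
#'   trait-SD (residual SD) units for quantitative traits, log-odds for
#'   binary. Zero gives a null GWAS.
#' @param n Sample size (>= 100).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param case_fraction Expected case fraction for binary traits.
#' @param seed Integer seed; output is a deterministic function of
#'   `(seed, parameters)`.
#' @param study_id,trait,efo_codes Labels stored on the dataset.
#' @return A `gwas_dataset` whose `truth` field is the `truth_record`
#'   (causal variant id, true beta, seed). Monomorphic simulated variants are
#'   emitted with `se = Inf` and `pvalue = 1` so the filtering path is
#'   exercised downstream rather than silently dropped here.
#' @examples
#' p <- simulate_ld_panel(50, 10, 0.8, seed = 1)
#' g <- simulate_gwas(p, causal_index = 25, beta_true = 0.5, n = 2000, seed = 2)
#' g$records[which.min(g$records$pvalue), c("variant", "beta", "pvalue")]
#' @export
simulate_gwas <- function(panel, causal_index, beta_true, n,
                          trait_type = c("quantitative", "binary"),
                          case_fraction = 0.5, seed = 1L,
                          study_id = "SIM_GWAS", trait = study_id,
                          efo_codes = character()) {
  trait_type <- match.arg(trait_type)
  m <- nrow(panel$variants)
  stopifnot(n >= 100, all(causal_index >= 1), all(causal_index <= m))
  beta_true <- rep_len(beta_true, length(causal_index))
  if (trait_type == "binary") {
    stopifnot(case_fraction > 0, case_fraction < 1)
  }
  with_seed(seed, {
    G <- simulate_genotypes(panel, n)
    eta_g <- drop(G[, causal_index, drop = FALSE] %*% beta_true)
    if (trait_type == "quantitative") {
      y <- eta_g + rnorm(n)
      stats <- marginal_stats_quantitative(G, y)
    } else {
      f <- panel$variants$maf[causal_index]
      alpha <- qlogis(case_fraction) - sum(beta_true * 2 * f)
      y <- rbinom(n, 1L, plogis(alpha + eta_g))
      stats <- marginal_stats_binary(G, y)
    }
    rec <- assoc_records(panel, G, stats, n)
    gwas_dataset(
      rec, study_id = study_id, trait = trait, trait_type = trait_type,
      efo_codes = efo_codes,
      truth = truth_record(panel$variants$id[causal_index], beta_true, seed)
    )
  })
}

#' Simulate a molecular QTL dataset for one gene
#'
#' Same generative scheme as [simulate_gwas()] applied to a quantitative
#' molecular trait (expression or protein level), with the causal variant
#' either shared with a GWAS truth record, distinct from it (LD `|r| < 0.1`),
#' or absent (null gene).
#'
#' @param panel An `ld_panel` (the same LD structure as the GWAS).
#' @param gene Gene identifier the molecular trait belongs to.
#' @param mode `"shared"`, `"distinct"`, or `"null"`.
#' @param gwas_truth The GWAS `truth_record`; required for `"shared"` and
#'   `"distinct"`.
#' @param beta_true Per-allele effect on the molecular trait (SD units).
#' @param n molQTL sample size.
#' @param dataset_id Label of the molQTL dataset (e.g. a tissue).
#' @param seed Integer seed.
#' @param molecule_type `"eQTL"` or `"pQTL"`.
#' @param cell_type Cell-type / tissue label carried to enrichment analyses.
#' @return List with `records` (association records plus `gene_id`,
#'   `dataset_id`, `molecule_type`, `cell_type` columns) and `truth`
#'   (with `shared_with_gwas` set).
#' @export
simulate_molqtl <- function(panel, gene, mode = c("shared", "distinct", "null"),
                            gwas_truth = NULL, beta_true = 0.4, n = 5000,
                            dataset_id = "molqtl_1", seed = 1L,
                            molecule_type = c("eQTL", "pQTL"),
                            cell_type = dataset_id) {
  mode <- match.arg(mode)
  molecule_type <- match.arg(molecule_type)
  v <- panel$variants
  if (mode %in% c("shared", "distinct")) {
    if (is.null(gwas_truth)) stop("mode='", mode, "' requires gwas_truth")
    gidx <- match(gwas_truth$causal_variant, v$id)
    if (is.na(gidx)) stop("GWAS causal variant not in panel")
  }
  res <- with_seed(seed, {
    causal_index <- switch(mode,
      shared = gidx,
      distinct = {
        ok <- which(abs(panel$R[gidx, ]) < 0.1)
        if (length(ok) == 0L) {
          stop("mode='distinct': no variant with |r| < 0.1 to the GWAS causal variant")
        }
        ok[sample.int(length(ok), 1L)]
      },
      null = NA_integer_
    )
    G <- simulate_genotypes(panel, n)
    y <- if (mode == "null") rnorm(n) else G[, causal_index] * beta_true + rnorm(n)
    stats <- marginal_stats_quantitative(G, y)
    rec <- assoc_records(panel, G, stats, n)
    rec$gene_id <- gene
    rec$dataset_id <- dataset_id
    rec$molecule_type <- molecule_type
    rec$cell_type <- cell_type
    tr <- truth_record(
      if (mode == "null") NA_character_ else v$id[causal_index],
      if (mode == "null") 0 else beta_true,
      seed, causal_gene = gene,
      shared_with_gwas = (mode == "shared")
    )
    list(records = rec, truth = tr)
  })
  res
}
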