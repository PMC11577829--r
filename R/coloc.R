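# Approximate-Bayes-factor colocalization (H0-H4 posteriors) of a GWAS locus
# against one molQTL gene signal. All accumulation is in log space: ABFs
# overflow double range at biobank z-scores.

#' Wakefield log approximate Bayes factor
#'
#' For effect estimate `beta` with standard error `se` and effect-scale
#' prior SD `prior_sd`: with `V = se^2`, `W = prior_sd^2`, `r = W/(V + W)`
#' and `z = beta/se`, the log ABF (alternative over null) is
#' `0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se Effect estimates and standard errors (vectorized).
#' @param prior_sd Prior standard deviation of true effects (> 0).
#' @return Numeric vector of log Bayes factors.
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (!all(is.finite(beta)) || !all(is.finite(se)) || !is.finite(prior_sd)) {
    stop("log_abf: non-finite input")
  }
  stopifnot(all(se > 0), prior_sd > 0)
  v <- se^2
  w <- prior_sd^2
  r <- w / (v + w)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

#' Colocalization posteriors from per-variant summary statistics
#'
#' Computes the five posterior probabilities (H0: no association; H1/H2:
#' association with trait 1/2 only; H3: both, distinct causal variants;
#' H4: both, shared causal variant) under the single-causal-variant
#' approximate-Bayes-factor model, from the two traits' per-variant betas and
#' standard errors over the shared variant set.
#'
#' @param beta1,se1 Trait 1 (GWAS) effects and SEs.
#' @param beta2,se2 Trait 2 (molQTL) effects and SEs, same variant order.
#' @param p1,p2 Prior probability a variant is causal for trait 1 / trait 2
#'   only (defaults `1e-4`).
#' @param p12 Prior probability a variant is causal for both (default `1e-5`).
#' @param prior_sd1,prior_sd2 Effect-scale prior SDs (defaults 0.2 for a
#'   binary trait 1 on the log-odds scale, 0.15 for a quantitative trait 2).
#' @return Object of class `coloc_result`: list with `pp` (named numeric
#'   `PP_H0`..`PP_H4`, summing to 1) and `n_snps`. With a single shared
#'   variant `PP_H3` is exactly 0 (empty sum).
#' @examples
#' coloc_abf(beta1 = c(0.4, 0.01), se1 = c(0.05, 0.05),
#'           beta2 = c(0.5, 0.02), se2 = c(0.06, 0.06))$pp
#' @export
coloc_abf <- function(beta1, se1, beta2, se2,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.2, prior_sd2 = 0.15) {
  stopifnot(length(beta1) == length(beta2), length(beta1) >= 1,
            p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 1)
  la1 <- log_abf(beta1, se1, prior_sd1)
  la2 <- log_abf(beta2, se2, prior_sd2)
  s1 <- logsumexp(la1)
  s2 <- logsumexp(la2)
  s_same <- logsumexp(la1 + la2)
  l0 <- 0
  l1 <- log(p1) + s1
  l2 <- log(p2) + s2
  l3 <- if (length(la1) == 1L) -Inf else
    log(p1) + log(p2) + logdiffexp(s1 + s2, s_same)
  l4 <- log(p12) + s_same
  l <- c(l0, l1, l2, l3, l4)
  pp <- exp(l - logsumexp(l))
  names(pp) <- paste0("PP_H", 0:4)
  structure(list(pp = pp, n_snps = length(la1)), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  if (identical(x$status, "no_overlap")) {
    cat("coloc_result: no shared variants in region\n")
  } else {
    cat(sprintf("coloc_result (%d SNPs): %s\n", x$n_snps,
                paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " ")))
  }
  invisible(x)
}

#' Colocalize a GWAS locus with one molQTL gene signal
#'
#' Intersects the two datasets' variants within `window` base pairs of the
#' locus lead variant and runs [coloc_abf()] on the shared set. The prior SD
#' for the GWAS trait follows its trait type (0.2 binary, 0.15 quantitative).
#'
#' @param gwas A `gwas_dataset`.
#' @param locus A `locus` from [define_loci()].
#' @param molqtl_slice molQTL records for one gene x dataset.
#' @param window Flank around the lead variant (default 250,000 bp).
#' @param p1,p2,p12 Colocalization priors, see [coloc_abf()].
#' @return A `coloc_result` with `gene_id`/`dataset_id` attached, or an
#'   object with `status = "no_overlap"` when the datasets share no variant
#'   in the window.
#' @export
coloc_region <- function(gwas, locus, molqtl_slice, window = 250000,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  rec <- gwas$records
  lo <- locus$lead_pos - window
  hi <- locus$lead_pos + window
  g <- rec[rec$chrom == locus$chrom & rec$pos >= lo & rec$pos <= hi &
             is.finite(rec$se), , drop = FALSE]
  q <- molqtl_slice[is.finite(molqtl_slice$se), , drop = FALSE]
  shared <- intersect(g$variant, q$variant)
  meta <- list(gene_id = q$gene_id[1] %||% NA_character_,
               dataset_id = q$dataset_id[1] %||% NA_character_,
               gwas_id = gwas$study_id, locus_id = locus$id)
  if (length(shared) == 0L) {
    return(structure(c(meta, list(status = "no_overlap", n_snps = 0L)),
                     class = "coloc_result"))
  }
  gi <- match(shared, g$variant)
  qi <- match(shared, q$variant)
  res <- coloc_abf(
    beta1 = g$beta[gi], se1 = g$se[gi],
    beta2 = q$beta[qi], se2 = q$se[qi],
    p1 = p1, p2 = p2, p12 = p12,
    prior_sd1 = if (gwas$trait_type == "binary") 0.2 else 0.15,
    prior_sd2 = 0.15
  )
  res[names(meta)] <- meta
  res$status <- "ok"
  res
}

#' Colocalization scan gated on MR significance
#'
#' Runs [coloc_region()] for every gene x dataset whose MR q-value is below
#' `mr_q` (colocalization is only attempted where MR was significant), at
#' the locus where the gene is a candidate.
#'
#' @param gwas A `gwas_dataset`.
#' @param molqtl Long molQTL data frame (as in [mr_scan()]).
#' @param loci List of loci from [define_loci()].
#' @param candidates List of `candidate_set`s parallel to `loci`.
#' @param mr_results Output of [mr_scan()].
#' @param mr_q MR significance gate (default 0.05).
#' @param window,p1,p2,p12 Passed to [coloc_region()].
#' @return Data frame with `gene_id`, `dataset_id`, `gwas_id`, `locus_id`,
#'   `n_snps`, `pp_h0`..`pp_h4`, `status` (rows with `status = "no_overlap"`
#'   carry NA posteriors and are excluded from evidence downstream).
#' @export
coloc_scan <- function(gwas, molqtl, loci, candidates, mr_results,
                       mr_q = 0.05, window = 250000,
                       p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  sig <- mr_results[mr_results$qvalue < mr_q, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    gene <- sig$gene_id[i]; ds <- sig$dataset_id[i]
    li <- which(vapply(candidates,
                       function(cs) gene %in% cs$genes$gene_id, logical(1)))
    if (length(li) == 0L) next
    for (l in li) {
      slice <- molqtl[molqtl$gene_id == gene & molqtl$dataset_id == ds, ,
                      drop = FALSE]
      res <- coloc_region(gwas, loci[[l]], slice, window, p1, p2, p12)
      pp <- if (identical(res$status, "ok")) unname(res$pp) else rep(NA_real_, 5)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene, dataset_id = ds, gwas_id = gwas$study_id,
        locus_id = loci[[l]]$id, n_snps = res$n_snps,
        pp_h0 = pp[1], pp_h1 = pp[2], pp_h2 = pp[3], pp_h3 = pp[4],
        pp_h4 = pp[5], status = res$status, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), dataset_id = character(),
               gwas_id = character(), locus_id = character(),
               n_snps = integer(), pp_h0 = numeric(), pp_h1 = numeric(),
               pp_h2 = numeric(), pp_h3 = numeric(), pp_h4 = numeric(),
               status = character())
}
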