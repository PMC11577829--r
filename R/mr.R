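# Two-sample MR: LD clumping, instrument selection, allele harmonization,
# Wald-ratio and IVW estimation, and BH false discovery rate.

#' Greedy LD clumping of association records
#'
#' PLINK-style clumping: repeatedly take the smallest-p unassigned variant as
#' an index and remove all unassigned variants within `kb_window` kilobases
#' whose LD with it exceeds `r2_max`. P-value ties are broken by variant id,
#' so output is independent of input row order. Variants not covered by the
#' LD source are dropped with a reported count.
#'
#' @param records Association records data frame (needs `variant`, `chrom`,
#'   `pos`, `pvalue`).
#' @param ld An `ld_panel`, a list of panels, or a long-format pair table
#'   with columns `VARIANT_A`, `VARIANT_B`, `R` (absent pairs mean r = 0).
#' @param r2_max LD pruning threshold (default 0.01).
#' @param kb_window Window in kilobases (default 10,000).
#' @param p1 Maximum p-value for a variant to seed a clump (default 1).
#' @param p2 Maximum p-value for a variant to be absorbed into a clump
#'   (default 1).
#' @return Character vector of index variant ids in selection order.
#' @export
clump <- function(records, ld, r2_max = 0.01, kb_window = 10000,
                  p1 = 1, p2 = 1) {
  if (is.list(ld) && !is.data.frame(ld) && !inherits(ld, "ld_panel")) {
    lks <- lapply(ld, ld_lookup)
    ids <- unlist(lapply(lks, `[[`, "ids"), use.names = FALSE)
    lk <- list(ids = ids, r2 = function(a, b) {
      for (l in lks) {
        if (a %in% l$ids && b %in% l$ids) return(l$r2(a, b))
      }
      0
    })
  } else {
    lk <- ld_lookup(ld)
  }
  covered <- records$variant %in% lk$ids
  if (any(!covered)) {
    message("clump: dropped ", sum(!covered),
            " variant(s) not covered by the LD reference")
  }
  rec <- records[covered, , drop = FALSE]
  rec <- rec[order(rec$pvalue, rec$variant), , drop = FALSE]
  assigned <- rep(FALSE, nrow(rec))
  idx <- character()
  for (i in seq_len(nrow(rec))) {
    if (assigned[i] || rec$pvalue[i] > p1) next
    assigned[i] <- TRUE
    idx <- c(idx, rec$variant[i])
    near <- which(!assigned & rec$chrom == rec$chrom[i] &
                    abs(rec$pos - rec$pos[i]) <= kb_window * 1000 &
                    rec$pvalue <= p2)
    for (j in near) {
      if (lk$r2(rec$variant[i], rec$variant[j]) > r2_max) assigned[j] <- TRUE
    }
  }
  idx
}

#' Select MR instruments from a molQTL gene slice
#'
#' Excludes variants with MAF < `maf_min` and the non-finite SE sentinel,
#' keeps associations with `pvalue < p_instrument`, and clumps the remainder.
#' An empty result means MR is skipped for the gene x dataset, not an error.
#'
#' @param records molQTL association records for one gene in one dataset.
#' @param ld LD source, see [clump()].
#' @param p_instrument Instrument p-value threshold (default `1e-4`).
#' @param maf_min Minimum MAF for molQTL variants (default 0.01).
#' @param r2_max,kb_window Clumping parameters, see [clump()].
#' @return Character vector of instrument variant ids (possibly empty).
#' @export
select_instruments <- function(records, ld, p_instrument = 1e-4,
                               maf_min = 0.01, r2_max = 0.01,
                               kb_window = 10000) {
  maf <- pmin(records$eaf, 1 - records$eaf)
  rec <- records[maf >= maf_min & is.finite(records$se) &
                   records$pvalue < p_instrument, , drop = FALSE]
  if (nrow(rec) == 0L) return(character())
  clump(rec, ld, r2_max = r2_max, kb_window = kb_window)
}

#' Harmonize one exposure/outcome record pair to a common effect allele
#'
#' If the effect alleles differ but the allele sets match, the outcome beta
#' is sign-flipped and its frequency complemented. Palindromic variants
#' (A/T, C/G) are retained only when both allele frequencies lie on the same
#' side of 0.5 and both are outside the ambiguity band
#' `[palindromic_eaf_limit, 1 - palindromic_eaf_limit]`.
#'
#' @param exp,out Single association records (one-row data frames or lists
#'   with `effect_allele`, `other_allele`, `beta`, `se`, `eaf`, `variant`).
#' @param palindromic_eaf_limit Ambiguity band edge (default 0.42).
#' @return A `harmonized_pair` (list with `variant`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, `flipped`) or a
#'   `harmonize_drop` with a `reason` of `"allele_mismatch"` or
#'   `"palindromic_ambiguous"`.
#' @export
harmonize <- function(exp, out, palindromic_eaf_limit = 0.42) {
  drop_with <- function(reason) {
    structure(list(variant = exp$variant %||% NA_character_, reason = reason),
              class = "harmonize_drop")
  }
  if (identical(out$effect_allele, exp$effect_allele) &&
      identical(out$other_allele, exp$other_allele)) {
    beta_out <- out$beta; eaf_out <- out$eaf; flipped <- FALSE
  } else if (identical(out$effect_allele, exp$other_allele) &&
             identical(out$other_allele, exp$effect_allele)) {
    beta_out <- -out$beta; eaf_out <- 1 - out$eaf; flipped <- TRUE
  } else {
    return(drop_with("allele_mismatch"))
  }
  if (is_palindromic(exp$effect_allele, exp$other_allele)) {
    lo <- palindromic_eaf_limit; hi <- 1 - palindromic_eaf_limit
    same_side <- (exp$eaf - 0.5) * (eaf_out - 0.5) > 0
    outside <- (exp$eaf < lo | exp$eaf > hi) & (eaf_out < lo | eaf_out > hi)
    if (!isTRUE(same_side) || !isTRUE(outside)) {
      return(drop_with("palindromic_ambiguous"))
    }
  }
  structure(
    list(variant = exp$variant, beta_exp = exp$beta, se_exp = exp$se,
         beta_out = beta_out, se_out = out$se,
         eaf_exp = exp$eaf, eaf_out = eaf_out, flipped = flipped),
    class = "harmonized_pair"
  )
}

#' Wald-ratio causal estimate from a single instrument
#'
#' `beta = beta_out / beta_exp`, with the first-order delta-method standard
#' error `se = se_out / |beta_exp|` and a two-sided normal p-value.
#'
#' @param pair A `harmonized_pair`.
#' @return List with `beta`, `se`, `pvalue`, `method = "wald_ratio"`,
#'   `n_instruments = 1`.
#' @export
wald_ratio <- function(pair) {
  if (pair$beta_exp == 0) stop("null exposure effect")
  beta <- pair$beta_out / pair$beta_exp
  se <- pair$se_out / abs(pair$beta_exp)
  z <- beta / se
  list(beta = beta, se = se, pvalue = 2 * pnorm(-abs(z)),
       method = "wald_ratio", n_instruments = 1L)
}

#' Inverse-variance-weighted causal estimate from multiple instruments
#'
#' Fixed-effect IVW: the slope of the zero-intercept regression of outcome
#' on exposure betas with weights `1/se_out^2`. The `"random"` model applies
#' a multiplicative over-dispersion scaling `max(1, sqrt(Q/(k-1)))` to the
#' standard error.
#'
#' @param pairs List of `harmonized_pair` objects (length >= 2).
#' @param model `"fixed"` (default) or `"random"`.
#' @return List with `beta`, `se`, `pvalue`, `method = "ivw"`,
#'   `n_instruments`.
#' @export
ivw <- function(pairs, model = c("fixed", "random")) {
  model <- match.arg(model)
  if (length(pairs) < 2L) stop("ivw needs >= 2 instruments; use wald_ratio")
  bx <- vapply(pairs, `[[`, numeric(1), "beta_exp")
  by <- vapply(pairs, `[[`, numeric(1), "beta_out")
  sy <- vapply(pairs, `[[`, numeric(1), "se_out")
  if (any(bx == 0)) stop("null exposure effect")
  w <- 1 / sy^2
  denom <- sum(bx^2 * w)
  beta <- sum(bx * by * w) / denom
  se <- sqrt(1 / denom)
  if (model == "random") {
    q <- sum(w * (by - beta * bx)^2)
    se <- se * max(1, sqrt(q / (length(pairs) - 1)))
  }
  z <- beta / se
  list(beta = beta, se = se, pvalue = 2 * pnorm(-abs(z)),
       method = "ivw", n_instruments = length(pairs))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment preserving input order.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH")
}

#' Transcriptome-wide MR scan
#'
#' Runs MR for every candidate gene x molQTL dataset with at least one
#' instrument: instruments are selected per gene slice, harmonized against
#' the GWAS, estimated with the Wald ratio (one instrument) or IVW (two or
#' more), and q-values are computed by BH across all tests within the GWAS.
#'
#' @param gwas A `gwas_dataset` (the outcome).
#' @param molqtl Long data frame of molQTL association records with
#'   `gene_id`, `dataset_id` and `molecule_type` columns (the exposures).
#' @param ld LD source for clumping, see [clump()].
#' @param candidates A `candidate_set` or list of them; genes outside the
#'   candidate union are not tested.
#' @param p_instrument,maf_min,r2_max,kb_window Instrument selection
#'   parameters.
#' @param ivw_model See [ivw()].
#' @return Data frame with one row per tested gene x dataset: `gene_id`,
#'   `dataset_id`, `molecule_type`, `gwas_id`, `method`, `n_instruments`,
#'   `beta`, `se`, `pvalue`, `qvalue`. Skipped pairs (no instruments or no
#'   harmonizable overlap) are recorded in `attr(, "skipped")`.
#' @export
mr_scan <- function(gwas, molqtl, ld, candidates,
                    p_instrument = 1e-4, maf_min = 0.01,
                    r2_max = 0.01, kb_window = 10000,
                    ivw_model = c("fixed", "random")) {
  ivw_model <- match.arg(ivw_model)
  if (inherits(candidates, "candidate_set")) candidates <- list(candidates)
  cand_genes <- unique(unlist(lapply(candidates, function(cs) cs$genes$gene_id)))
  out_rec <- gwas$records
  rows <- list(); skipped <- list()
  combos <- unique(molqtl[molqtl$gene_id %in% cand_genes,
                          c("gene_id", "dataset_id"), drop = FALSE])
  for (i in seq_len(nrow(combos))) {
    gene <- combos$gene_id[i]; ds <- combos$dataset_id[i]
    slice <- molqtl[molqtl$gene_id == gene & molqtl$dataset_id == ds, ,
                    drop = FALSE]
    inst <- select_instruments(slice, ld, p_instrument, maf_min,
                               r2_max, kb_window)
    if (length(inst) == 0L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = gene, dataset_id = ds, reason = "no_instruments")
      next
    }
    pairs <- list()
    for (v in inst) {
      j <- match(v, out_rec$variant)
      if (is.na(j) || !is.finite(out_rec$se[j])) next
      h <- harmonize(as.list(slice[slice$variant == v, ]),
                     as.list(out_rec[j, ]))
      if (inherits(h, "harmonized_pair") && h$beta_exp != 0) {
        pairs[[length(pairs) + 1L]] <- h
      }
    }
    if (length(pairs) == 0L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = gene, dataset_id = ds, reason = "no_harmonized_overlap")
      next
    }
    est <- if (length(pairs) == 1L) wald_ratio(pairs[[1]]) else
      ivw(pairs, model = ivw_model)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene, dataset_id = ds,
      molecule_type = slice$molecule_type[1] %||% NA_character_,
      gwas_id = gwas$study_id, method = est$method,
      n_instruments = est$n_instruments,
      beta = est$beta, se = est$se, pvalue = est$pvalue,
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), dataset_id = character(),
               molecule_type = character(), gwas_id = character(),
               method = character(), n_instruments = integer(),
               beta = numeric(), se = numeric(), pvalue = numeric(),
               qvalue = numeric())
  if (nrow(res)) res$qvalue <- bh_fdr(res$pvalue)
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  res
}
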