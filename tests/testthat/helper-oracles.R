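# Independent oracles used across tests. These are deliberately naive
# (direct-space sums, brute-force loops, literal transcriptions) and must
# stay independent of the package implementations they check.

# Wakefield ABF in direct space (no log-sum-exp), for moderate z only.
abf_direct <- function(beta, se, prior_sd) {
  v <- se^2; w <- prior_sd^2; r <- w / (v + w); z <- beta / se
  sqrt(1 - r) * exp(r * z^2 / 2)
}

# Exhaustive enumeration of the (m+1)^2 causal-configuration pairs for
# colocalization posteriors.
coloc_enum_oracle <- function(beta1, se1, beta2, se2,
                              p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                              prior_sd1 = 0.2, prior_sd2 = 0.15) {
  m <- length(beta1)
  a1 <- abf_direct(beta1, se1, prior_sd1)
  a2 <- abf_direct(beta2, se2, prior_sd2)
  w <- matrix(0, m + 1, m + 1)  # rows: trait1 config (0 = none); cols: trait2
  w[1, 1] <- 1
  for (i in seq_len(m)) w[i + 1, 1] <- p1 * a1[i]
  for (j in seq_len(m)) w[1, j + 1] <- p2 * a2[j]
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      w[i + 1, j + 1] <- if (i == j) p12 * a1[i] * a2[j] else
        p1 * p2 * a1[i] * a2[j]
    }
  }
  wb <- w[-1, -1, drop = FALSE]
  h <- c(
    w[1, 1],
    sum(w[-1, 1]),
    sum(w[1, -1]),
    sum(wb[row(wb) != col(wb)]),
    sum(diag(wb))
  )
  h / sum(h)
}

# Two-sided / greater Fisher p by hypergeometric enumeration.
fisher_enum_oracle <- function(a, b, c_, d, sidedness = "two_sided") {
  m <- a + b      # row 1 total
  n <- c_ + d     # row 2 total
  k <- a + c_     # column 1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n, k)
  if (sidedness == "greater") {
    sum(probs[xs >= a])
  } else {
    cutoff <- dhyper(a, m, n, k) * (1 + 1e-7)
    sum(probs[probs <= cutoff])
  }
}

# Sort-based Benjamini-Hochberg definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ranked <- p[o] * m / seq_len(m)
  q[o] <- rev(cummin(rev(ranked)))
  pmin(q, 1)
}

# Greedy clumping reference that re-scans the remaining set after each
# index selection.
clump_oracle <- function(records, R, r2_max = 0.01, kb_window = 10000) {
  rec <- records[order(records$pvalue, records$variant), , drop = FALSE]
  remaining <- rec$variant
  idx <- character()
  while (length(remaining) > 0L) {
    sub <- rec[rec$variant %in% remaining, , drop = FALSE]
    top <- sub$variant[1]
    idx <- c(idx, top)
    ti <- match(top, rec$variant)
    drop <- vapply(remaining, function(v) {
      vi <- match(v, rec$variant)
      v == top ||
        (rec$chrom[vi] == rec$chrom[ti] &&
           abs(rec$pos[vi] - rec$pos[ti]) <= kb_window * 1000 &&
           R[top, v]^2 > r2_max)
    }, logical(1))
    remaining <- remaining[!drop]
  }
  idx
}

# Literal, straight-line transcription of the five-tier rank table,
# independent of assign_rank's criterion bookkeeping.
rank_oracle <- function(p, coloc_multi = 2) {
  if (p$lead_pathogenic ||
      (p$n_coloc > coloc_multi && p$abcmax_lead)) return("VERY_HIGH")
  if (p$lead_coding || p$assoc_pathogenic ||
      (p$n_coloc > coloc_multi && p$abcmax_assoc) ||
      (p$n_coloc >= 1 && p$abcmax_lead)) return("HIGH")
  if (p$n_coloc >= 1 || p$mr_pqtl_sig || p$abcmax_lead ||
      p$assoc_coding) return("MODERATE")
  if (p$is_nearest || p$abcmax_assoc || p$abc_any_lead) return("WEAK")
  if (p$mr_eqtl_sig || p$abc_any_assoc) return("VERY_WEAK")
  "NONE"
}

# Triple-loop contingency construction over a binary cube, summing over the
# first dimension with focal slices on dimensions 2 and 3.
cube_oracle <- function(cube, x, y) {
  di <- dim(cube)
  a <- b <- cc <- d <- 0L
  for (i in seq_len(di[1])) {
    for (j in seq_len(di[2])) {
      for (k in seq_len(di[3])) {
        v <- cube[i, j, k]
        if (v == 0) next
        if (j == x && k == y) a <- a + 1L
        else if (j == x && k != y) b <- b + 1L
        else if (j != x && k == y) cc <- cc + 1L
        else d <- d + 1L
      }
    }
  }
  c(a = a, b = b, c = cc, d = d)
}

# All evidence-profile flag fields used by assign_rank.
profile_flags <- c("lead_pathogenic", "lead_coding", "assoc_pathogenic",
                   "assoc_coding", "abcmax_lead", "abcmax_assoc",
                   "abc_any_lead", "abc_any_assoc", "mr_pqtl_sig",
                   "mr_eqtl_sig", "is_nearest")

make_profile <- function(bits, n_coloc = 0L) {
  p <- as.list(setNames(as.logical(bits), profile_flags))
  p$n_coloc <- n_coloc
  p$gene_id <- "G"
  p$distance_to_lead <- 0
  p
}

# Small association record helper for hand-built fixtures.
mk_rec <- function(variant, chrom = "1", pos = 1e6, ref = "A", alt = "G",
                   eaf = 0.3, beta = 0, se = 0.05, pvalue = 0.5, n = 1000) {
  data.frame(variant = variant, chrom = chrom, pos = pos, ref = ref,
             alt = alt, effect_allele = alt, other_allele = ref,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
             stringsAsFactors = FALSE)
}
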