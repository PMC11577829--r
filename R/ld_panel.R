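# LD panel simulation.
#
# Haplotypes are generated by thresholding latent Gaussian variables with
# AR(1) correlation rho^|i-j| inside blocks (independence between blocks) at
# the allele-frequency quantile. The allelic (dosage-scale) correlation
# implied by a latent correlation is computed analytically from the bivariate
# normal orthant probability, so the panel's correlation matrix describes the
# LD the genotype simulator actually produces.

# Standard bivariate normal CDF P(X < h, Y < k | cor = rho) via Drezner-style
# reduction to a 1-D integral over the correlation parameter.
pbinorm <- function(h, k, rho) {
  if (abs(rho) < .Machine$double.eps) return(pnorm(h) * pnorm(k))
  stopifnot(abs(rho) < 1)
  f <- function(r) {
    exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  }
  pnorm(h) * pnorm(k) +
    integrate(f, 0, rho, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Correlation between allele indicators 1{Z1 < qnorm(f1)}, 1{Z2 < qnorm(f2)}
# for latent correlation rho.
allelic_correlation <- function(f1, f2, rho) {
  if (rho == 0) return(0)
  p11 <- pbinorm(qnorm(f1), qnorm(f2), rho)
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

# Non-palindromic allele pairs only: the generator never emits A/T or C/G
# SNPs, so harmonization of its own output is never frequency-ambiguous.
.allele_pairs <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)

#' Simulate a block-structured LD reference panel
#'
#' Creates a panel of biallelic SNPs with AR(1) linkage disequilibrium inside
#' consecutive blocks and independence between blocks, standing in for an
#' external LD reference (e.g. a 1000 Genomes ancestry subset) for clumping
#' and genotype simulation.
#'
#' @param n_variants Number of variants (>= 1).
#' @param block_size Variants per LD block (>= 1); the final block may be
#'   shorter.
#' @param rho Latent AR(1) correlation between adjacent variants within a
#'   block, in `[0, 1)`. The allelic correlation stored in the panel is
#'   derived from it analytically and is slightly attenuated.
#' @param maf_range Length-2 interval from which per-variant minor allele
#'   frequencies are drawn uniformly; must lie in `(0, 0.5]`.
#' @param seed Integer seed; the panel is a deterministic function of
#'   `(seed, parameters)`.
#' @param chrom Chromosome label for all variants.
#' @param start_pos 1-based position of the first variant.
#' @param spacing Base pairs between consecutive variants.
#' @return An object of class `ld_panel`: a list with `variants` (data frame
#'   with `id`, `chrom`, `pos`, `ref`, `alt`, `maf`, `block`), `R` (allelic
#'   correlation matrix), and the generating `rho` and `block_size`.
#' @examples
#' p <- simulate_ld_panel(20, block_size = 5, rho = 0.8, seed = 1)
#' range(eigen(p$R, only.values = TRUE)$values)
#' @export
simulate_ld_panel <- function(n_variants, block_size, rho,
                              maf_range = c(0.05, 0.5), seed = 1L,
                              chrom = "1", start_pos = 1e6L, spacing = 2500L) {
  stopifnot(n_variants >= 1, block_size >= 1, rho >= 0)
  if (rho >= 1) stop("rho must be < 1 (degenerate correlation)")
  stopifnot(length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  with_seed(seed, {
    maf <- runif(n_variants, maf_range[1], maf_range[2])
    pair <- .allele_pairs[sample.int(nrow(.allele_pairs), n_variants,
                                     replace = TRUE), , drop = FALSE]
    pos <- as.integer(start_pos + spacing * (seq_len(n_variants) - 1L))
    block <- ceiling(seq_len(n_variants) / block_size)
    variants <- data.frame(
      id = variant_id(chrom, pos, pair[, 1], pair[, 2]),
      chrom = chrom, pos = pos, ref = pair[, 1], alt = pair[, 2],
      maf = maf, block = block, stringsAsFactors = FALSE
    )
    R <- diag(n_variants)
    if (rho > 0 && block_size > 1) {
      for (b in unique(block)) {
        idx <- which(block == b)
        if (length(idx) < 2L) next
        for (a in seq_along(idx)[-length(idx)]) {
          for (z in seq(a + 1L, length(idx))) {
            i <- idx[a]; j <- idx[z]
            r <- allelic_correlation(maf[i], maf[j], rho^(z - a))
            R[i, j] <- R[j, i] <- r
          }
        }
      }
    }
    dimnames(R) <- list(variants$id, variants$id)
    structure(
      list(variants = variants, R = R, rho = rho, block_size = block_size,
           seed = as.integer(seed)),
      class = "ld_panel"
    )
  })
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf(
    "ld_panel: %d variants, block size %d, latent rho %.3g, chrom %s\n",
    nrow(x$variants), x$block_size, x$rho, x$variants$chrom[1]
  ))
  invisible(x)
}

# Draw n diploid genotype dosages (n x m matrix, ALT-allele counts) from the
# panel's latent model, using the caller's RNG stream. Two independent
# haplotypes per individual; within a block the latent Gaussian follows the
# AR(1) recursion, so cost is O(n * m).
simulate_genotypes <- function(panel, n) {
  v <- panel$variants
  m <- nrow(v)
  rho <- panel$rho
  Z <- matrix(rnorm(2L * n * m), nrow = 2L * n, ncol = m)
  if (rho > 0) {
    for (b in unique(v$block)) {
      idx <- which(v$block == b)
      if (length(idx) < 2L) next
      for (k in idx[-1L]) {
        Z[, k] <- rho * Z[, k - 1L] + sqrt(1 - rho^2) * Z[, k]
      }
    }
  }
  thr <- matrix(qnorm(v$maf), nrow = 2L * n, ncol = m, byrow = TRUE)
  H <- Z < thr
  G <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
  storage.mode(G) <- "double"
  colnames(G) <- v$id
  G
}

# r^2 lookup table from either an ld_panel or a long-format pair list
# (VARIANT_A, VARIANT_B, R). Returns function(id_a, id_b) -> r2 and the set
# of covered variant ids.
ld_lookup <- function(ld) {
  if (inherits(ld, "ld_panel")) {
    R <- ld$R
    ids <- rownames(R)
    list(ids = ids, r2 = function(a, b) R[a, b]^2)
  } else if (is.data.frame(ld)) {
    nm <- toupper(names(ld))
    stopifnot(all(c("VARIANT_A", "VARIANT_B", "R") %in% nm))
    names(ld) <- nm
    key <- c(paste(ld$VARIANT_A, ld$VARIANT_B), paste(ld$VARIANT_B, ld$VARIANT_A))
    val <- rep(ld$R, 2L)
    env <- new.env(parent = emptyenv())
    for (i in seq_along(key)) assign(key[i], val[i], envir = env)
    ids <- unique(c(ld$VARIANT_A, ld$VARIANT_B))
    list(ids = ids, r2 = function(a, b) {
      if (a == b) return(1)
      r <- mget(paste(a, b), envir = env, ifnotfound = list(0))[[1]]
      r^2
    })
  } else {
    stop("ld must be an ld_panel or a VARIANT_A/VARIANT_B/R data frame")
  }
}
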