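#' @keywords internal
"_PACKAGE"

# Numerically safe log(sum(exp(x))).
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, clamped at -Inf when the difference
# underflows (a == b up to rounding).
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Canonical variant identifier
#'
#' Builds the `"chrom:pos:ref:alt"` identifier used to key variants across
#' GWAS, molQTL, annotation and LD tables.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based base-pair position.
#' @param ref,alt Uppercase allele strings (A/C/G/T sequences).
#' @return Character vector of identifiers.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  stopifnot(all(grepl("^[ACGT]+$", ref)), all(grepl("^[ACGT]+$", alt)))
  paste(chrom, pos, ref, alt, sep = ":")
}

dna_complement <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# A biallelic SNP is palindromic when its two alleles are reverse
# complements of each other (A/T or C/G): strand cannot be resolved
# from alleles alone.
is_palindromic <- function(a1, a2) {
  nchar(a1) == 1L & nchar(a2) == 1L & dna_complement(a1) == a2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed helper: all generators accept an integer seed and restore the
# caller's RNG state on exit so simulation calls compose predictably.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
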