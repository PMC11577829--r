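test_that("clumping follows the greedy LD-pruning rule", {
  p <- simulate_ld_panel(2, 2, 0.9, seed = 1)
  r <- p$R[1, 2]
  rec <- data.frame(variant = p$variants$id, chrom = p$variants$chrom,
                    pos = p$variants$pos, pvalue = c(1e-10, 1e-8),
                    stringsAsFactors = FALSE)
  # strongly linked pair keeps only the smaller-p index
  expect_gt(r^2, 0.01)
  expect_identical(clump(rec, p), p$variants$id[1])
  # essentially unlinked pair keeps both
  ld_indep <- data.frame(VARIANT_A = rec$variant[1], VARIANT_B = rec$variant[2],
                         R = 0.01)
  expect_identical(clump(rec, ld_indep), rec$variant[order(rec$pvalue)])
})

test_that("clumping matches the re-scanning reference on a seeded panel", {
  p <- simulate_ld_panel(50, 10, 0.9, seed = 2)
  set.seed(3)
  rec <- data.frame(variant = p$variants$id, chrom = p$variants$chrom,
                    pos = p$variants$pos,
                    pvalue = runif(50)^3, stringsAsFactors = FALSE)
  got <- clump(rec, p)
  expected <- clump_oracle(rec, p$R)
  expect_identical(got, expected)
  # output is invariant to input row order
  expect_identical(clump(rec[sample(50), ], p), expected)
})

test_that("instrument selection applies MAF and p-value gates", {
  p <- simulate_ld_panel(5, 1, 0, seed = 4)
  rec <- data.frame(
    variant = p$variants$id, chrom = p$variants$chrom, pos = p$variants$pos,
    eaf = c(0.3, 0.3, 0.005, 0.3, 0.3), se = 0.05,
    pvalue = c(2e-4, 1e-3, 1e-9, 1e-5, 0.5), stringsAsFactors = FALSE
  )
  # all p >= 1e-4 -> empty
  expect_length(select_instruments(rec[1:2, ], p), 0)
  # MAF < 1% excluded even at p = 1e-9; the p=1e-5 variant survives
  expect_identical(select_instruments(rec, p), p$variants$id[4])
})

test_that("harmonization flips, drops, and inverts as specified", {
  ex <- list(variant = "1:1:A:G", effect_allele = "A", other_allele = "G",
             beta = 0.5, se = 0.1, eaf = 0.2)
  out_swapped <- list(variant = "1:1:A:G", effect_allele = "G",
                      other_allele = "A", beta = 0.3, se = 0.05, eaf = 0.7)
  h <- harmonize(ex, out_swapped)
  expect_s3_class(h, "harmonized_pair")
  expect_equal(h$beta_out, -0.3)
  expect_equal(h$eaf_out, 0.3)
  expect_true(h$flipped)
  # involution: re-expressing the harmonized outcome on the swapped alleles
  # reproduces the original record, and harmonizing it again is a fixed point
  out_back <- list(variant = "1:1:A:G", effect_allele = "G",
                   other_allele = "A", beta = -h$beta_out, se = h$se_out,
                   eaf = 1 - h$eaf_out)
  expect_equal(out_back$beta, out_swapped$beta)
  expect_equal(out_back$eaf, out_swapped$eaf)
  h2 <- harmonize(ex, out_back)
  expect_equal(h2, h)
  # incompatible allele sets
  bad <- list(variant = "1:1:A:G", effect_allele = "C", other_allele = "T",
              beta = 0.3, se = 0.05, eaf = 0.7)
  hd <- harmonize(ex, bad)
  expect_s3_class(hd, "harmonize_drop")
  expect_equal(hd$reason, "allele_mismatch")
  # palindromic near 0.5: ambiguous
  pal_ex <- list(variant = "1:1:A:T", effect_allele = "A", other_allele = "T",
                 beta = 0.5, se = 0.1, eaf = 0.50)
  pal_out <- list(variant = "1:1:A:T", effect_allele = "A",
                  other_allele = "T", beta = 0.3, se = 0.05, eaf = 0.49)
  hp <- harmonize(pal_ex, pal_out)
  expect_s3_class(hp, "harmonize_drop")
  expect_equal(hp$reason, "palindromic_ambiguous")
  # palindromic far from 0.5 on the same side: retained
  pal_ex$eaf <- 0.1; pal_out$eaf <- 0.12
  expect_s3_class(harmonize(pal_ex, pal_out), "harmonized_pair")
})

test_that("Wald ratio implements the delta-method formula", {
  pair <- structure(list(variant = "v", beta_exp = 0.1, se_exp = 0.02,
                         beta_out = 0.2, se_out = 0.05),
                    class = "harmonized_pair")
  w <- wald_ratio(pair)
  expect_equal(w$beta, 2.0)
  expect_equal(w$se, 0.5)
  expect_equal(w$method, "wald_ratio")
  # null outcome
  pair$beta_out <- 0
  w0 <- wald_ratio(pair)
  expect_equal(w0$beta, 0)
  expect_equal(w0$pvalue, 1)
  # ratio invariance under joint sign flip
  flipped <- pair; flipped$beta_exp <- -0.1; flipped$beta_out <- -0.2
  pair$beta_out <- 0.2
  expect_equal(wald_ratio(flipped)$beta, wald_ratio(pair)$beta)
  # null exposure is an error
  pair$beta_exp <- 0
  expect_error(wald_ratio(pair), "null exposure")
})

test_that("IVW equals the weighted zero-intercept regression slope", {
  mkpair <- function(bx, by, sy) {
    structure(list(variant = "v", beta_exp = bx, se_exp = 0.02,
                   beta_out = by, se_out = sy), class = "harmonized_pair")
  }
  set.seed(5)
  pairs <- lapply(1:6, function(i) mkpair(runif(1, 0.05, 0.3),
                                          rnorm(1, 0.1, 0.05),
                                          runif(1, 0.02, 0.1)))
  est <- ivw(pairs)
  bx <- vapply(pairs, `[[`, numeric(1), "beta_exp")
  by <- vapply(pairs, `[[`, numeric(1), "beta_out")
  sy <- vapply(pairs, `[[`, numeric(1), "se_out")
  fit <- lm(by ~ bx - 1, weights = 1 / sy^2)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)
  # two identical pairs: IVW beta = Wald beta, se = Wald se / sqrt(2)
  p1 <- mkpair(0.1, 0.2, 0.05)
  est2 <- ivw(list(p1, p1))
  w <- wald_ratio(p1)
  expect_equal(est2$beta, w$beta, tolerance = 1e-12)
  expect_equal(est2$se, w$se / sqrt(2), tolerance = 1e-12)
  # one pair must route to wald_ratio
  expect_error(ivw(list(p1)), "wald_ratio")
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_equal(q, bh_oracle(p), tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("the MR scan recovers a planted shared-variant effect", {
  p <- simulate_ld_panel(40, 10, 0.9, seed = 7, maf_range = c(0.2, 0.5))
  g <- simulate_gwas(p, 20, 0.2, 10000, seed = 8)
  mq <- simulate_molqtl(p, "GC", mode = "shared", gwas_truth = g$truth,
                        beta_true = 0.4, n = 5000, dataset_id = "eqtl_1",
                        seed = 9)
  cand <- structure(
    list(locus_id = "L1",
         genes = data.frame(gene_id = "GC", distance_to_lead = 0,
                            is_nearest = TRUE, stringsAsFactors = FALSE),
         nearest = "GC"),
    class = "candidate_set"
  )
  res <- mr_scan(g, mq$records, p, cand)
  expect_equal(nrow(res), 1)
  expect_lt(res$qvalue, 0.05)
  # gamma = beta_gwas / beta_molqtl at a shared causal variant
  expect_lt(abs(res$beta - 0.2 / 0.4), 4 * res$se)
  # single instrument implies the Wald path
  if (res$n_instruments == 1) expect_equal(res$method, "wald_ratio")
  # null molQTL yields no instruments, hence no rows
  mq0 <- simulate_molqtl(p, "GC", mode = "null", n = 1000, seed = 10)
  res0 <- mr_scan(g, mq0$records, p, cand)
  expect_equal(nrow(res0), 0)
  expect_equal(attr(res0, "skipped")$reason, "no_instruments")
})
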