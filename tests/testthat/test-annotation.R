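make_locus <- function(members, lead_idx = which.min(members$pvalue)) {
  structure(
    list(id = "L1", chrom = members$chrom[1],
         start = min(members$pos) - 250000, end = max(members$pos) + 250000,
         lead = members$variant[lead_idx], lead_pos = members$pos[lead_idx],
         lead_pvalue = members$pvalue[lead_idx], members = members),
    class = "locus"
  )
}

test_that("coding and pathogenic classification follows the stated rules", {
  expect_equal(classify_consequence("missense_variant", "MODERATE"),
               data.frame(is_coding = TRUE, is_pathogenic = FALSE))
  expect_equal(classify_consequence("stop_gained", "HIGH"),
               data.frame(is_coding = TRUE, is_pathogenic = TRUE))
  expect_equal(classify_consequence("synonymous_variant", "LOW"),
               data.frame(is_coding = FALSE, is_pathogenic = FALSE))
  expect_error(classify_consequence("made_up_term", "LOW"), "vocabulary")
})

test_that("classification matches a hand decision table exhaustively", {
  grid <- expand.grid(
    consequence = consequence_vocabulary(),
    impact = c("HIGH", "MODERATE", "LOW", "MODIFIER"),
    pathogenic = c(FALSE, TRUE), destabilizing = c(FALSE, TRUE),
    conserved = c(FALSE, TRUE), stringsAsFactors = FALSE
  )
  got <- classify_consequence(grid$consequence, grid$impact,
                              grid$pathogenic, grid$destabilizing,
                              grid$conserved)
  # independent transcription of the definitions
  exp_coding <- grid$consequence == "missense_variant" | grid$impact == "HIGH"
  any_flag <- grid$pathogenic | grid$destabilizing | grid$conserved
  exp_path <- grid$impact == "HIGH" | (exp_coding & any_flag)
  expect_identical(got$is_coding, exp_coding)
  expect_identical(got$is_pathogenic, exp_path)
  # monotonicity: turning any flag on never revokes pathogenicity
  base <- classify_consequence(grid$consequence, grid$impact,
                               FALSE, FALSE, FALSE)
  flagged <- classify_consequence(grid$consequence, grid$impact,
                                  TRUE, grid$destabilizing, grid$conserved)
  expect_true(all(flagged$is_pathogenic >= base$is_pathogenic))
  expect_true(all(got$is_pathogenic >= base$is_pathogenic))
})

test_that("associated-variant eligibility honours both bounds inclusively", {
  members <- rbind(
    mk_rec("1:1000000:A:G", pos = 1000000, pvalue = 1e-12),
    mk_rec("1:1001000:A:G", pos = 1001000, pvalue = 1e-7),
    mk_rec("1:1002000:A:G", pos = 1002000, pvalue = 5e-7),
    mk_rec("1:1003000:A:G", pos = 1003000, pvalue = 0.5)
  )
  g <- gwas_dataset(members, trait_type = "binary")
  locus <- make_locus(members)
  elig <- eligible_associated_variants(locus, g)
  # 1e-7 == 1e-12 * 1e5 exactly: inside; 5e-7 beyond 5 orders: outside
  expect_setequal(elig, c("1:1000000:A:G", "1:1001000:A:G"))
  # shallower lead: the magnitude bound is not binding below 1e-6
  members2 <- members
  members2$pvalue <- c(1e-8, 9e-7, 5e-7, 0.5)
  g2 <- gwas_dataset(members2, trait_type = "binary")
  elig2 <- eligible_associated_variants(make_locus(members2), g2)
  expect_setequal(elig2, members2$variant[1:3])
})

test_that("ABC argmax and any-link flags follow the per-variant definition", {
  members <- mk_rec("1:1000000:A:G", pos = 1000000, pvalue = 1e-9)
  g <- gwas_dataset(members, trait_type = "binary")
  locus <- make_locus(members)
  cand <- structure(
    list(locus_id = "L1",
         genes = data.frame(gene_id = c("G1", "G2", "G3"),
                            distance_to_lead = c(0, 1000, 2000),
                            is_nearest = c(TRUE, FALSE, FALSE),
                            stringsAsFactors = FALSE),
         nearest = "G1"),
    class = "candidate_set"
  )
  abc <- data.frame(
    chrom = "1", start = 999000, end = 1000500,
    gene_id = c("G1", "G2"), cell_type = "t1", score = c(0.12, 0.03),
    stringsAsFactors = FALSE
  )
  f <- abc_features(locus, g, members$variant, abc, cand)
  expect_true(f$abcmax_lead[f$gene_id == "G1"])
  expect_false(f$abcmax_lead[f$gene_id == "G2"])
  expect_true(all(f$abc_any_lead[f$gene_id %in% c("G1", "G2")]))
  expect_false(any(f[f$gene_id == "G3", -1] == TRUE))
  # tie at the top score flags both genes
  abc_tie <- abc; abc_tie$score <- c(0.12, 0.12)
  f2 <- abc_features(locus, g, members$variant, abc_tie, cand)
  expect_true(all(f2$abcmax_lead[f2$gene_id %in% c("G1", "G2")]))
  # no overlapping enhancer: all flags false
  abc_off <- abc; abc_off$start <- 2e6; abc_off$end <- 2e6 + 500
  f3 <- abc_features(locus, g, members$variant, abc_off, cand)
  expect_false(any(as.matrix(f3[, -1])))
  # abcmax implies any-link for the same scope
  for (ff in list(f, f2, f3)) {
    expect_true(all(!ff$abcmax_lead | ff$abc_any_lead))
    expect_true(all(!ff$abcmax_assoc | ff$abc_any_assoc))
  }
})

test_that("enhancer overlap uses BED half-open intervals after conversion", {
  members <- mk_rec("1:1001:A:G", pos = 1001, pvalue = 1e-9)
  g <- gwas_dataset(members, trait_type = "binary")
  locus <- make_locus(members)
  cand <- structure(
    list(locus_id = "L1",
         genes = data.frame(gene_id = "G1", distance_to_lead = 0,
                            is_nearest = TRUE, stringsAsFactors = FALSE),
         nearest = "G1"),
    class = "candidate_set"
  )
  # pos 1001 -> 0-based 1000; [1000, 1001) contains it, [900, 1000) does not
  abc_in <- data.frame(chrom = "1", start = 1000, end = 1001, gene_id = "G1",
                       cell_type = "t", score = 0.1)
  abc_out <- data.frame(chrom = "1", start = 900, end = 1000, gene_id = "G1",
                        cell_type = "t", score = 0.1)
  expect_true(abc_features(locus, g, members$variant, abc_in, cand)$abc_any_lead)
  expect_false(abc_features(locus, g, members$variant, abc_out, cand)$abc_any_lead)
})

test_that("gene-locus annotation plants flags only on the intended gene", {
  p <- simulate_ld_panel(30, 10, 0.9, seed = 5, maf_range = c(0.2, 0.5))
  g <- simulate_gwas(p, 15, 0.6, 10000, seed = 6)
  layers <- simulate_annotation_layers(p, c("GC", "GD1", "GD2"), g$truth,
                                       evidence_plan = list(lead_pathogenic = "GC"))
  fg <- filter_variants(g, exclude_regions = NULL)
  locus <- define_loci(fg)[[1]]
  cand <- assign_candidate_genes(locus, layers$genes)
  ann <- annotate_gene_locus(locus, fg, layers$consequences, layers$abc, cand)
  expect_true(ann$lead_pathogenic[ann$gene_id == "GC"])
  expect_false(any(ann$lead_pathogenic[ann$gene_id != "GC"]))
  # lead flags imply associated flags
  expect_true(all(!ann$lead_coding | ann$assoc_coding))
  expect_true(all(!ann$lead_pathogenic | ann$assoc_pathogenic))
  # locus with no consequence rows: all coding flags false
  ann0 <- annotate_gene_locus(locus, fg, layers$consequences[0, ],
                              layers$abc, cand)
  expect_false(any(ann0$lead_coding | ann0$assoc_coding |
                     ann0$lead_pathogenic | ann0$assoc_pathogenic))
})
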