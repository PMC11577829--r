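test_that("Fisher exact matches closed-form and symmetric corner cases", {
  # fully concentrated table, upper tail: 1/C(10,5)
  ft <- fisher_exact(5, 0, 0, 5, "greater")
  expect_equal(ft$pvalue, 1 / choose(10, 5), tolerance = 1e-12)
  # perfectly balanced table
  expect_equal(fisher_exact(1, 1, 1, 1)$pvalue, 1)
  # zero margin sentinel
  z <- fisher_exact(0, 0, 3, 4)
  expect_true(is.na(z$odds_ratio))
  expect_equal(z$pvalue, 1)
  # cross-product odds ratio, Haldane-corrected only at zero cells
  expect_equal(fisher_exact(6, 2, 3, 4)$odds_ratio, 24 / 6)
  expect_equal(fisher_exact(5, 0, 2, 3)$odds_ratio,
               (5.5 * 3.5) / (0.5 * 2.5))
})

test_that("Fisher p-values equal hypergeometric enumeration on a grid", {
  for (a in 0:6) {
    for (b in 0:6) {
      for (cc in 0:6) {
        for (d in 0:6) {
          if (a + b + cc + d == 0) next
          if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 ||
              (b + d) == 0) next
          for (side in c("two_sided", "greater")) {
            expect_equal(fisher_exact(a, b, cc, d, side)$pvalue,
                         fisher_enum_oracle(a, b, cc, d, side),
                         tolerance = 1e-9,
                         info = paste(a, b, cc, d, side))
          }
        }
      }
    }
  }
})

test_that("contingency cubes match triple-loop summation", {
  set.seed(31)
  for (trial in 1:20) {
    cube <- array(rbinom(20 * 10 * 5, 1, 0.15), dim = c(20, 10, 5),
                  dimnames = list(paste0("i", 1:20), paste0("j", 1:10),
                                  paste0("k", 1:5)))
    res <- locus2gene:::cube_enrichment(cube)
    for (r in seq_len(nrow(res))) {
      want <- cube_oracle(cube, match(res$focal_x[r], dimnames(cube)[[2]]),
                          match(res$focal_y[r], dimnames(cube)[[3]]))
      expect_equal(c(a = res$a[r], b = res$b[r], c = res$c[r], d = res$d[r]),
                   want)
    }
    if (nrow(res) > 1) {
      expect_true(all(res$qvalue >= res$pvalue - 1e-15))
      expect_equal(res$qvalue, bh_oracle(res$pvalue), tolerance = 1e-12)
    }
  }
})

test_that("the three enrichment constructions reproduce the toy examples", {
  # gene-celltype: single events at (i1, J, K) and (i2, J', K')
  ev <- data.frame(disease = c("i1", "i2"), gene_id = c("J", "Jp"),
                   dataset_id = c("K", "Kp"), stringsAsFactors = FALSE)
  res <- gene_celltype_enrichment(ev)
  row <- res[res$gene_id == "J" & res$dataset_id == "K", ]
  expect_equal(unlist(row[c("a", "b", "c", "d")], use.names = FALSE),
               c(1, 0, 0, 1))
  # gene-category: 3 GWAS prioritized for J all in C; 7 others in C; 90 rest
  prio <- rbind(
    data.frame(gwas_id = paste0("g", 1:3), gene_id = "J", category = "C"),
    data.frame(gwas_id = paste0("h", 1:7), gene_id = "X", category = "C"),
    data.frame(gwas_id = paste0("r", 1:90), gene_id = "X", category = "D")
  )
  res2 <- gene_disease_category_enrichment(prio)
  row2 <- res2[res2$gene_id == "J" & res2$category == "C", ]
  expect_equal(unlist(row2[c("a", "b", "c", "d")], use.names = FALSE),
               c(3, 0, 7, 90))
  # category-celltype with grouping: grouped cell is the OR over members
  ev3 <- data.frame(category = "I", gene_id = c("g1", "g1"),
                    dataset_id = c("k1", "k2"), stringsAsFactors = FALSE)
  grp <- c(k1 = "artery", k2 = "artery")
  res3 <- category_celltype_enrichment(ev3, grouping = grp)
  expect_equal(res3$a[res3$dataset_id == "artery"], 1)
})

test_that("gold-standard evaluation applies restriction and definitions", {
  tab <- data.frame(
    gwas_id = "S", efo = "d1",
    locus_id = rep(c("L1", "L2"), each = 2),
    lead_pvalue = c(1e-9, 1e-9, 1e-4, 1e-4),  # L2 not genome-wide
    gene_id = c("G1", "G2", "G3", "G4"),
    is_prioritized = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  gold <- data.frame(gene_id = "G1", efo_id = "d1", stringsAsFactors = FALSE)
  res <- evaluate_gold_standards(tab, gold,
                                 selectors = list(prioritized = "is_prioritized"))
  # L2 drops by the genome-wide rule; universe = {G1, G2}; picked both
  expect_equal(res$a, 1); expect_equal(res$b, 1)
  expect_equal(res$precision, 0.5)
  expect_equal(res$recall, 1.0)
  expect_equal(res$f1, 2 / 3)
  # loci without a gold gene for the indication are excluded entirely
  gold2 <- data.frame(gene_id = "NOPE", efo_id = "d1")
  expect_message(
    res2 <- evaluate_gold_standards(tab, gold2,
                                    selectors = list(p = "is_prioritized")),
    "empty universe"
  )
  expect_null(res2)
})

test_that("semantic similarity matches a hand-worked 7-term ontology", {
  edges <- data.frame(
    child = c("A", "B", "A1", "A2", "B1", "B2"),
    parent = c("R", "R", "A", "A", "B", "B"), stringsAsFactors = FALSE
  )
  ont <- ontology_graph(edges)
  # uniform usage: mass(A) = 3, mass(R) = 7, leaves 1
  ic_a <- -log(3 / 7); ic_leaf <- -log(1 / 7)
  expect_equal(unname(ont$ic["A"]), ic_a)
  expect_equal(unname(ont$ic["A1"]), ic_leaf)
  # siblings: MICA = A
  resnik <- ic_a; lin <- 2 * ic_a / (2 * ic_leaf)
  expect_equal(semantic_similarity("A1", "A2", ont), (resnik + lin) / 2)
  # only common ancestor is the root: similarity 0
  expect_equal(semantic_similarity("A1", "B1", ont), 0)
  # symmetric
  expect_equal(semantic_similarity("A1", "B2", ont),
               semantic_similarity("B2", "A1", ont))
  # standardized matrix: self-match is exactly 1, rows max at 1
  sm <- similarity_matrix(c("A1", "B1"), c("A1", "A2", "B1"), ont)
  expect_equal(sm["A1", "A1"], 1)
  expect_equal(sm["B1", "B1"], 1)
  expect_true(all(sm <= 1 + 1e-12))
  expect_error(semantic_similarity("A1", "ZZ", ont), "unknown")
  # malformed ontologies are rejected
  expect_error(ontology_graph(data.frame(child = c("A", "B"),
                                         parent = c("B", "A"))),
               "root|cycle")
})

test_that("drug linkage applies the similarity threshold and best-GWAS rule", {
  edges <- data.frame(child = c("A", "B", "A1", "A2", "B1"),
                      parent = c("R", "R", "A", "A", "B"))
  ont <- ontology_graph(edges)
  drugs <- data.frame(
    drug_id = c("D1", "D2", "D3"), target_gene = c("G1", "G1", "G2"),
    indication_efo = c("A1", "B1", "A1"),
    phase = c("2", "3", "1"), moa = "inhibitor", stringsAsFactors = FALSE
  )
  prio <- data.frame(
    gene_id = "G1", efo = "A1", gwas_id = c("S1", "S2"),
    lead_pvalue = c(1e-9, 1e-12), stringsAsFactors = FALSE
  )
  linked <- link_genetics_to_drugs(prio, drugs, ont)
  sup <- linked[linked$supported, ]
  # identical term: linked, keeping the more significant GWAS
  expect_equal(sup$indication_efo, "A1")
  expect_equal(sup$gwas_id, "S2")
  # dissimilar branch term not linked; untargeted gene not linked
  expect_false(linked$supported[linked$indication_efo == "B1"])
  expect_false(any(linked$target_gene == "G2" & linked$supported))
  # cancer-style exclusion removes the pair from the universe
  linked2 <- link_genetics_to_drugs(prio, drugs, ont,
                                    exclude_terms = "A1")
  expect_false("A1" %in% linked2$indication_efo)
})

test_that("clinical-phase risk ratios follow the definition", {
  linked <- data.frame(
    target_gene = paste0("G", 1:100), indication_efo = "A1",
    max_phase = c(rep(2L, 10), rep(1L, 10), rep(2L, 10), rep(1L, 70)),
    supported = c(rep(TRUE, 20), rep(FALSE, 80)), stringsAsFactors = FALSE
  )
  rr <- clinical_phase_risk_ratios(linked, phases = "2")
  expect_equal(rr$risk_ratio, (10 / 20) / (10 / 80))  # 4.0
  # identical rates: RR = 1
  linked$max_phase <- rep(c(2L, 1L), 50)
  linked$supported <- rep(c(TRUE, FALSE), each = 50)
  rr2 <- clinical_phase_risk_ratios(linked, phases = "2")
  expect_equal(rr2$risk_ratio, 1)
})

test_that("coding-variant MoA calls follow the minor-allele sign rule", {
  act <- moa_direction_from_coding(beta = 0.3, eaf = 0.02)
  expect_equal(act$prediction, "activation")
  inh <- moa_direction_from_coding(beta = -0.3, eaf = 0.02)
  expect_equal(inh$prediction, "inhibition")
  # effect allele is the major allele: sign re-expressed for the minor
  flip <- moa_direction_from_coding(beta = 0.3, eaf = 0.98)
  expect_equal(flip$prediction, "inhibition")
  # MAF at or above the limit: no call
  none <- moa_direction_from_coding(beta = 0.3, eaf = 0.10)
  expect_true(is.na(none$prediction))
  expect_equal(none$reason, "maf_above_limit")
  boundary <- moa_direction_from_coding(beta = 0.3, eaf = 0.05)
  expect_true(is.na(boundary$prediction))
})

test_that("MR consensus MoA calls require a strict majority fraction", {
  mk_rows <- function(betas, q = 0.01, pp = 0.9) {
    data.frame(beta = betas, qvalue = q, pp_h4 = pp)
  }
  # 4/5 negative: activation
  r <- moa_direction_from_mr(mk_rows(c(-1, -1, -1, -1, 1)))
  expect_equal(r$prediction, "activation")
  # 3/4 = 0.75 exactly: no call
  r2 <- moa_direction_from_mr(mk_rows(c(-1, -1, -1, 1)))
  expect_true(is.na(r2$prediction))
  expect_equal(r2$reason, "no_consensus")
  # singleton positive: inhibition
  r3 <- moa_direction_from_mr(mk_rows(1))
  expect_equal(r3$prediction, "inhibition")
  # gates: non-colocalizing or non-significant rows never qualify
  r4 <- moa_direction_from_mr(mk_rows(c(-1, -1), pp = 0.5))
  expect_equal(r4$reason, "no_qualifying_datasets")
  r5 <- moa_direction_from_mr(mk_rows(c(-1, -1), q = 0.2))
  expect_equal(r5$reason, "no_qualifying_datasets")
  # sign equivariance: negating betas flips every call, drops none
  set.seed(41)
  for (i in 1:50) {
    rows <- mk_rows(sample(c(-1, 1), 7, replace = TRUE) * runif(7))
    a <- moa_direction_from_mr(rows)
    rows$beta <- -rows$beta
    b <- moa_direction_from_mr(rows)
    expect_identical(is.na(a$prediction), is.na(b$prediction))
    if (!is.na(a$prediction)) {
      expect_false(identical(a$prediction, b$prediction))
    }
  }
})

test_that("MoA concordance classifies keywords and excludes unmapped ones", {
  preds <- data.frame(
    target_gene = c("G1", "G2", "G3"), indication_efo = "A1",
    prediction = c("inhibition", "activation", "inhibition"),
    stringsAsFactors = FALSE
  )
  drugs <- data.frame(
    drug_id = c("D1", "D2", "D3"),
    target_gene = c("G1", "G2", "G3"), indication_efo = "A1",
    phase = c("2", "3", "approved"),
    moa = c("inhibitor", "degrader", "modulator"),  # G3 unmapped: excluded
    stringsAsFactors = FALSE
  )
  res <- moa_concordance(preds, drugs)
  expect_equal(res$n, 2)
  # G1 concordant (inhibition/inhibitor); G2 discordant (activation/degrader)
  expect_equal(res$concordance, 0.5)
  # below-phase drugs are excluded
  drugs$phase <- "1"
  expect_equal(moa_concordance(preds, drugs)$n, 0)
})
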