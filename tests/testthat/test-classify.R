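hits_for <- function(sv, k = 0, phenotype = NULL, ...) {
  b <- fixture_bundle()
  rg <- regions_for_sv(sv, b$tads, k = k)
  dplyr::bind_rows(lapply(seq_len(nrow(rg)), function(i) {
    collect_elements(rg[i, ], b$genes, b$clusters, b$loops)
  }))
}

test_that("phenotype-overlap flag applies ratio and alpha thresholds", {
  expect_true(phenotype_overlap_flag(1, 1, 0))
  # reported similarity triples for a disrupted candidate and a position-
  # effect candidate with a weak p-value
  expect_true(phenotype_overlap_flag(2.64, 4.01, 0.02))   # ratio 0.658
  expect_false(phenotype_overlap_flag(1.33, 4.2, 0.3))    # fails both defaults
  expect_true(phenotype_overlap_flag(1.33, 4.2, 0.3, force = TRUE))
  expect_warning(f <- phenotype_overlap_flag(0, 0, 0), "maxssc of 0")
  expect_false(f)
  # monotone in r and alpha: tightening can only clear the flag
  set.seed(3)
  for (i in 1:100) {
    ph <- runif(1, 0, 4); mx <- ph + runif(1, 0, 2); p <- runif(1)
    base <- phenotype_overlap_flag(ph, mx, p, r = 0.5, alpha = 0.1)
    tighter <- phenotype_overlap_flag(ph, mx, p, r = 0.7, alpha = 0.05)
    expect_true(!tighter || base)
  }
})

test_that("rule engine applies the five-level precedence", {
  # disrupting a gene linked to an AD disorder -> pathogenic
  sv <- sv_spec("translocation", chrom1 = "chr2", pos1 = 160001,
                chrom2 = "chr1", pos2 = 250001, sv_id = "t_path")
  expect_equal(classify_balanced(sv, hits_for(sv))$category, "pathogenic")

  # encompassing a pLI >= 0.9 gene with no disease link -> likely pathogenic
  inv <- sv_spec("inversion", chrom1 = "chr1", pos1 = 305001, pos2 = 340001,
                 sv_id = "inv_pli")
  cl <- classify_balanced(inv, hits_for(inv))
  expect_equal(cl$category, "likely_pathogenic")
  expect_match(cl$triggered_rules, "pli")

  # only an AR-linked gene affected -> likely benign
  ar <- sv_spec("translocation", chrom1 = "chr2", pos1 = 220001,
                chrom2 = "chr1", pos2 = 50001, sv_id = "t_ar")
  expect_equal(classify_balanced(ar, hits_for(ar))$category, "likely_benign")

  # no genes, no disorder-linked elements -> benign
  ben <- sv_spec("translocation", chrom1 = "chr1", pos1 = 50001,
                 chrom2 = "chr2", pos2 = 390001, sv_id = "t_ben")
  expect_equal(classify_balanced(ben, hits_for(ben))$category, "benign")

  # intergenic breakpoints near linked genes, no phenotype -> vus
  pe <- sv_spec("translocation", chrom1 = "chr1", pos1 = 150001,
                chrom2 = "chr2", pos2 = 50001, sv_id = "t_pe")
  expect_equal(classify_balanced(pe, hits_for(pe))$category, "vus")

  # CNVs are routed to the ACMG scorer instead
  del <- sv_spec("deletion", chrom1 = "chr1", span_start = 404001,
                 span_end = 455000)
  expect_error(classify_balanced(del, hits_for(del)), "ACMG")
})

test_that("position-effect arm needs TAD proximity, regulatory impact and phenotype", {
  pe <- sv_spec("translocation", chrom1 = "chr1", pos1 = 150001,
                chrom2 = "chr2", pos2 = 50001, sv_id = "t_pe")
  h <- hits_for(pe)
  # G_PE has its cluster severed and 3 loops broken by chr1:150000
  gpe <- h[h$gene_id == "G_PE", ]
  expect_true(gpe$cluster_disrupted)
  expect_equal(gpe$loops_disrupted, 3L)
  # with a supporting similarity triple the SV becomes likely pathogenic
  sim <- tibble::tibble(disease_id = "OMIM:600001", name = "Syndrome alpha",
                        phenssc = 2.64, maxssc = 4.01, p_value = 0.02,
                        n = 100L)
  cl <- classify_balanced(pe, h, similarity = sim)
  expect_equal(cl$category, "likely_pathogenic")
  expect_match(cl$triggered_rules, "position-effect")
  expect_equal(cl$phenssc, 2.64)
  # a weak triple does not fire the arm ...
  sim2 <- dplyr::mutate(sim, phenssc = 1.33, maxssc = 4.2, p_value = 0.3)
  expect_equal(classify_balanced(pe, h, similarity = sim2)$category, "vus")
  # ... unless the expert override is set
  expect_equal(classify_balanced(pe, h, similarity = sim2,
                                 force_phenotype_overlap = TRUE)$category,
               "likely_pathogenic")
})

test_that("sequencing prefilter applies size, frequency and gene conditions", {
  b <- fixture_bundle()
  mk <- function(sv_id, s, e) {
    tibble::tibble(sv_id = sv_id, sv_type = "deletion", chrom1 = "chr2",
                   pos1 = NA_real_, chrom2 = NA_character_, pos2 = NA_real_,
                   span_start = s, span_end = e, genome_build = "GRCh37",
                   tissue = "hESC")
  }
  # 900 bp deletion: too small
  small <- mk("small", 150000, 150900)
  # novel SV disrupting a LoF-sensitive gene (G_AD oe 0.12): kept
  lof <- mk("lof", 155000, 165000)
  # covers G_AR only (oe 0.70, AR link): fails the gene condition
  aronly <- mk("aronly", 205000, 235000)
  svs <- dplyr::bind_rows(small, lof, aronly)
  kept <- prefilter_sequencing_svs(svs, b$cnv_db, b$genes)
  expect_equal(kept$sv_id, "lof")

  # common database variant (frequency >= 1%) is excluded
  db <- tibble::tibble(chrom = "chr2", start = 155000, end = 165000,
                       cnv_type = "loss", classification = "benign",
                       frequency = 0.05, source_db = "dbA", record_id = "r1")
  expect_equal(nrow(prefilter_sequencing_svs(lof, db, b$genes)), 0)
  # same record at low frequency passes
  db$frequency <- 0.002
  expect_equal(nrow(prefilter_sequencing_svs(lof, db, b$genes)), 1)
})

test_that("consensus merging: majority wins, otherwise the median", {
  expect_equal(consensus_classification(c("likely_benign", "likely_benign", "vus")),
               "likely_benign")
  expect_equal(consensus_classification(c("benign", "vus", "pathogenic")), "vus")
  expect_equal(consensus_classification(c("benign", "likely_benign", "pathogenic")),
               "likely_benign")
  expect_error(consensus_classification(c("vus", "vus")), "three")
  expect_error(consensus_classification(c("vus", "vus", "nope")), "unknown category")
  # permutation invariance on a sample of triples
  set.seed(7)
  for (i in 1:50) {
    calls <- sample(sv_categories, 3, replace = TRUE)
    ref <- consensus_classification(calls)
    for (j in 1:3) {
      expect_equal(consensus_classification(sample(calls)), ref)
    }
  }
})
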