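mk_genes <- function(n, chrom = "chr1", start0 = 0, width = 1000, gap = 500,
                     biotype = "protein_coding", hi = FALSE, ts = FALSE) {
  starts <- start0 + (seq_len(n) - 1) * (width + gap)
  tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)),
                 symbol = sprintf("G%03d", seq_len(n)), chrom = chrom,
                 start = starts, end = starts + width, strand = "+",
                 biotype = biotype, pli = 0.1, oe_lof = 1,
                 haploinsufficient = hi, triplosensitive = ts,
                 has_expression_pattern = TRUE, disorders = "")
}

test_that("worked deletion case scores -0.90 and classifies likely benign", {
  b <- fixture_bundle()
  sv <- sv_spec("deletion", chrom1 = "chr1", span_start = 404001,
                span_end = 455000, sv_id = "case_ck")
  res <- acmg_score(sv, b$genes, b$cnv_db)
  expect_equal(res$final_score, -0.90)
  expect_equal(res$acmg_class, "likely_benign")
  expect_setequal(res$evidence$criterion_id, c("1A", "benign-overlap", "3A"))
  expect_equal(res$evidence$points[res$evidence$criterion_id == "benign-overlap"],
               -0.90)
  g <- glance(res)
  expect_equal(g$final_score, -0.90)
  expect_equal(nrow(tidy(res)), 3)
})

test_that("section 1 and dosage-sensitivity criteria fire as specified", {
  # deletion containing zero elements -> 1B only (plus gene count 3A)
  sv <- sv_spec("deletion", chrom1 = "chr1", span_start = 1, span_end = 10000)
  ev <- assign_evidence(sv, mk_genes(0))
  expect_equal(ev$criterion_id, c("1B", "3A"))
  expect_equal(final_score(ev), -0.60)

  # deletion fully containing a haploinsufficient gene -> includes 2A +1.00
  genes <- mk_genes(3, hi = c(FALSE, TRUE, FALSE))
  sv2 <- sv_spec("deletion", chrom1 = "chr1", span_start = 1, span_end = 5000)
  ev2 <- assign_evidence(sv2, genes)
  expect_true("2A" %in% ev2$criterion_id)
  expect_equal(ev2$points[ev2$criterion_id == "2A"], 1.00)

  # duplication mirrors with triplosensitive genes
  genes3 <- mk_genes(3, ts = c(TRUE, FALSE, FALSE))
  sv3 <- sv_spec("duplication", chrom1 = "chr1", span_start = 1, span_end = 5000)
  ev3 <- assign_evidence(sv3, genes3)
  expect_true("2A" %in% ev3$criterion_id)
  # but a deletion over the same genes ignores triplosensitivity
  ev4 <- assign_evidence(sv_spec("deletion", chrom1 = "chr1", span_start = 1,
                                 span_end = 5000), genes3)
  expect_false("2A" %in% ev4$criterion_id)
})

test_that("containment in an established benign region suppresses the overlap point", {
  db <- tibble::tibble(chrom = "chr1", start = c(0, 2000), end = c(50000, 12000),
                       cnv_type = "loss",
                       classification = c("benign", "likely_benign"),
                       frequency = c(0.02, 0.01),
                       source_db = "dbA", record_id = c("big", "exact"))
  sv <- sv_spec("deletion", chrom1 = "chr1", span_start = 2001, span_end = 12000)
  ev <- assign_evidence(sv, mk_genes(1, start0 = 3000), db)
  expect_true("2F" %in% ev$criterion_id)
  expect_false("benign-overlap" %in% ev$criterion_id)  # never co-fire
  # without the containing region, the 100% benign best hit scores -0.90
  ev2 <- assign_evidence(sv, mk_genes(1, start0 = 3000), db[2, ])
  expect_false("2F" %in% ev2$criterion_id)
  expect_true("benign-overlap" %in% ev2$criterion_id)
})

test_that("gene-count bins differ between losses and gains", {
  sv_of <- function(type) sv_spec(type, chrom1 = "chr1", span_start = 1,
                                  span_end = 100000)
  for (n in c(24, 25, 34, 35, 49, 50)) {
    genes <- mk_genes(n)
    loss <- assign_evidence(sv_of("deletion"), genes)
    gain <- assign_evidence(sv_of("duplication"), genes)
    loss_id <- loss$criterion_id[grepl("^3", loss$criterion_id)]
    gain_id <- gain$criterion_id[grepl("^3", gain$criterion_id)]
    expect_equal(loss_id, if (n < 25) "3A" else if (n < 35) "3B" else "3C")
    expect_equal(gain_id, if (n < 35) "3A" else if (n < 50) "3B" else "3C")
  }
})

test_that("score bands form a monotone total partition", {
  expect_equal(classify_score(0), "vus")
  expect_equal(classify_score(1.00), "pathogenic")
  expect_equal(classify_score(0.99), "pathogenic")
  expect_equal(classify_score(0.98), "likely_pathogenic")
  expect_equal(classify_score(0.90), "likely_pathogenic")
  expect_equal(classify_score(0.89), "vus")
  expect_equal(classify_score(-0.89), "vus")
  expect_equal(classify_score(-0.90), "likely_benign")
  expect_equal(classify_score(-0.98), "likely_benign")
  expect_equal(classify_score(-0.99), "benign")
  grid <- seq(-2, 2, by = 0.01)
  cls <- classify_score(grid)
  expect_true(all(cls %in% sv_categories))
  # monotone: class index never decreases as the score increases
  expect_true(all(diff(match(cls, sv_categories)) >= 0))
})

test_that("evidence is deterministic and mutually exclusive within sections", {
  b <- fixture_bundle()
  set.seed(23)
  for (i in 1:30) {
    len <- sample(2000:80000, 1)
    s <- sample(0:(600000 - len), 1)
    type <- sample(c("deletion", "duplication"), 1)
    sv <- sv_spec(type, chrom1 = "chr1", span_start = s + 1, span_end = s + len)
    ev1 <- assign_evidence(sv, b$genes, b$cnv_db)
    ev2 <- assign_evidence(sv, b$genes, b$cnv_db)
    expect_equal(ev1, ev2)
    expect_lte(sum(ev1$criterion_id %in% c("1A", "1B")), 1)
    expect_lte(sum(grepl("^3", ev1$criterion_id)), 1)
    expect_lte(sum(ev1$criterion_id %in% c("2F", "benign-overlap")), 1)
    expect_equal(final_score(ev1), round(sum(ev1$points), 2))
  }
})

test_that("manual evidence adds to the automated score", {
  sv <- sv_spec("deletion", chrom1 = "chr1", span_start = 1, span_end = 10000)
  ev <- assign_evidence(sv, mk_genes(0))
  expect_equal(final_score(ev, manual = c("5A" = 0.45)), -0.15)
})

test_that("balanced SVs are rejected by the ACMG scorer", {
  b <- fixture_bundle()
  tra <- sv_spec("translocation", chrom1 = "chr1", pos1 = 1, chrom2 = "chr2",
                 pos2 = 1)
  expect_error(assign_evidence(tra, b$genes), "deletions and duplications")
})
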