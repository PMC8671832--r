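region_of <- function(chrom, start, end, kind, bp_pos = NA_real_) {
  tibble::tibble(chrom = chrom, start = start, end = end, kind = kind,
                 offset = if (kind == "brTAD") 0L else NA_integer_,
                 tad_index = NA_integer_, note = NA_character_,
                 bp_chrom = if (is.na(bp_pos)) NA_character_ else chrom,
                 bp_pos = bp_pos, bp_label = NA_character_)
}

test_that("element filter keeps everything at breakpoints, filters elsewhere", {
  b <- fixture_bundle()
  # G_NF is non_functional without an expression pattern, in chr1 TAD2
  br <- collect_elements(region_of("chr1", 200000, 300000, "brTAD", 250000),
                         b$genes, b$clusters, b$loops)
  expect_true("G_NF" %in% br$gene_id)
  rem <- collect_elements(region_of("chr1", 200000, 300000, "remaining"),
                          b$genes, b$clusters, b$loops)
  expect_false("G_NF" %in% rem$gene_id)
  # monotonicity: remaining-rule hits are a subset of breakpoint-rule hits
  expect_true(all(rem$gene_id %in% br$gene_id))
  # empty region yields an empty hit table
  expect_equal(nrow(collect_elements(region_of("chr1", 0, 10, "brTAD", 5),
                                     b$genes)), 0)
})

test_that("gene disruption requires a strictly interior breakpoint", {
  expect_true(flag_gene_disruption(150, 100, 200))
  expect_false(flag_gene_disruption(100, 100, 200))  # at gene start
  expect_false(flag_gene_disruption(200, 100, 200))  # at gene end
  set.seed(5)
  for (i in 1:1000) {
    s <- sample(0:1e6, 1); e <- s + sample(1:1e5, 1)
    pos <- sample(0:1.2e6, 1)
    expect_identical(flag_gene_disruption(pos, s, e), s < pos && pos < e)
  }
})

test_that("loop disruption counts loops broken strictly between anchors", {
  b <- fixture_bundle()
  # planted position-effect gene: 3 of its 4 loops straddle chr1:150000
  lc <- count_disrupted_loops("chr1", 150000, "chr1", 160000, 180000, b$loops)
  expect_equal(lc$loops_disrupted, 3L)
  expect_equal(lc$loops_total, 4L)
  expect_lte(lc$loops_disrupted, lc$loops_total)
  # a breakpoint inside an anchor does not count as disrupting that loop
  loops <- tibble::tibble(chrom = "chr1", start_a = 100, end_a = 200,
                          start_b = 500, end_b = 600, tissue = "t")
  lc2 <- count_disrupted_loops("chr1", 150, "chr1", 80, 120, loops)
  expect_equal(lc2$loops_disrupted, 0L)
  expect_equal(lc2$loops_total, 1L)
  # no loops touching the gene
  lc3 <- count_disrupted_loops("chr1", 150, "chr1", 5000, 6000, loops)
  expect_equal(unlist(lc3), c(loops_disrupted = 0L, loops_total = 0L))
})

test_that("cluster disruption needs the hull plus elements on both sides", {
  cl <- tibble::tibble(chrom = "chr1",
                       element_start = c(100, 300, 900),
                       element_end = c(150, 350, 950))
  expect_true(flag_cluster_disruption("chr1", 500, cl))   # between enhancer and TSS
  expect_false(flag_cluster_disruption("chr1", 50, cl))   # left of all elements
  expect_false(flag_cluster_disruption("chr1", 1000, cl)) # right of all elements
  one <- cl[1, ]
  expect_false(flag_cluster_disruption("chr1", 120, one)) # inside the only element
  expect_false(flag_cluster_disruption("chr2", 500, cl))  # wrong chromosome
})

test_that("disruption flags match a brute-force re-derivation on random data", {
  set.seed(9)
  for (i in 1:50) {
    gs <- sample(0:5e5, 1); ge <- gs + sample(1000:2e4, 1)
    pos <- sample(0:6e5, 1)
    n <- sample(1:6, 1)
    la <- sort(sample(0:6e5, n)); wa <- sample(100:2000, n, replace = TRUE)
    lb <- la + wa + sample(5000:5e4, n, replace = TRUE)
    loops <- tibble::tibble(chrom = "chr1", start_a = la, end_a = la + wa,
                            start_b = lb, end_b = lb + wa, tissue = "t")
    lc <- count_disrupted_loops("chr1", pos, "chr1", gs, ge, loops)
    # brute force
    total <- 0L; disr <- 0L
    for (j in seq_len(n)) {
      touch <- (la[j] < ge && la[j] + wa[j] > gs) || (lb[j] < ge && lb[j] + wa[j] > gs)
      if (touch) {
        total <- total + 1L
        if (la[j] + wa[j] <= pos && pos < lb[j]) disr <- disr + 1L
      }
    }
    expect_equal(lc$loops_total, total)
    expect_equal(lc$loops_disrupted, disr)
  }
})

test_that("UCSC links embed the 1-based region deterministically", {
  u <- ucsc_session_url("chr10", 81603168, 81976925, "GRCh37")
  expect_match(u, "position=chr10:81603169-81976925", fixed = TRUE)
  expect_match(u, "db=GRCh37", fixed = TRUE)
  expect_identical(u, ucsc_session_url("chr10", 81603168, 81976925, "GRCh37"))
  expect_error(ucsc_session_url("chr1", 0, 10, ""), "non-empty")
})
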