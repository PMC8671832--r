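grid_tads <- function() {
  p <- tempfile()
  writeLines(sprintf("chr1\t%d\t%d", seq(0, 5) * 100000, seq(1, 6) * 100000), p)
  read_tads(p, tissue = "t")
}

test_that("brTAD resolution follows half-open containment", {
  tads <- grid_tads()
  r <- resolve_brtad("chr1", 150000, tads)
  expect_equal(r$tad_index, 1L)
  expect_equal(r$kind, "brTAD")
  expect_equal(r$offset, 0L)
  # boundary position belongs to the right-hand TAD
  expect_equal(resolve_brtad("chr1", 100000, tads)$tad_index, 1L)
  expect_equal(resolve_brtad("chr1", 0, tads)$tad_index, 0L)
  expect_error(resolve_brtad("chrZ", 10, tads), "absent from the TAD map")
})

test_that("breakpoints in inter-TAD gaps resolve to the gap interval", {
  p <- tempfile()
  writeLines(c("chr1\t0\t200000", "chr1\t260000\t400000"), p)
  tads <- read_tads(p)
  r <- resolve_brtad("chr1", 250000, tads)
  expect_equal(r$start, 200000)
  expect_equal(r$end, 260000)
  expect_equal(r$note, "boundary/gap")
  expect_equal(r$kind, "brTAD")
})

test_that("flanking TADs truncate at chromosome ends with ordered offsets", {
  tads <- grid_tads()
  fl <- flanking_tads("chr1", 150000, tads, k = 2)  # brTAD index 1
  expect_equal(sort(fl$offset), c(-1L, 1L, 2L))     # -2 truncated
  expect_equal(fl$tad_index[fl$offset == -1], 0L)
  expect_equal(fl$tad_index[fl$offset == 2], 3L)
  # offsets strictly increase with coordinates
  expect_equal(order(fl$start), order(fl$offset))

  expect_equal(nrow(flanking_tads("chr1", 150000, tads, k = 0)), 0)
  last <- flanking_tads("chr1", 550000, tads, k = 5)  # last TAD
  expect_true(all(last$offset < 0))
  expect_equal(nrow(last), 5)
  expect_error(flanking_tads("chr1", 150000, tads, k = 6), "0..5")
})

test_that("average-size fallback tiles the chromosome", {
  w <- chry_fallback_window("chrY", 1000000, 815000)
  expect_equal(w$start, 815000)
  expect_equal(w$end, 1630000)
  expect_equal(w$note, "average-size window")
  expect_equal(chry_fallback_window("chrY", 0, 815000)$start, 0)
  expect_equal(chry_fallback_window("chrY", 815000, 815000)$start, 815000)
  expect_error(chry_fallback_window("chrY", 0, -1), "positive")
  # adjacent positions one window apart give adjacent disjoint windows
  for (pos in c(0, 123456, 815000 * 3 + 17)) {
    a <- chry_fallback_window("chrY", pos, 815000)
    b <- chry_fallback_window("chrY", pos + 815000, 815000)
    expect_equal(a$end, b$start)
  }
  # fallback engages through resolve_brtad for absent chromosomes
  tads <- grid_tads()
  r <- resolve_brtad("chrY", 1000000, tads, avg_size = 815000)
  expect_equal(r$start, 815000)
})

test_that("regions_for_sv assembles brTADs, flanks and CNV interior", {
  tads <- grid_tads()
  del <- sv_spec("deletion", chrom1 = "chr1", span_start = 120001,
                 span_end = 310000)  # internal [120000, 310000)
  rg <- regions_for_sv(del, tads)
  br <- rg[rg$kind == "brTAD", ]
  expect_equal(sort(br$tad_index), c(1L, 3L))
  rem <- rg[rg$kind == "remaining", ]
  expect_equal(rem$start, 200000)
  expect_equal(rem$end, 300000)

  tra <- sv_spec("translocation", chrom1 = "chr1", pos1 = 150001,
                 chrom2 = "chr2", pos2 = 50001)
  b <- fixture_bundle()
  rg2 <- regions_for_sv(tra, b$tads, k = 1)
  expect_equal(sum(rg2$kind == "brTAD"), 2)
  expect_equal(sum(rg2$kind == "flankTAD"), 3)  # chr2 TAD0 has no left flank

  reg <- sv_spec("region", chrom1 = "chr1", span_start = 1, span_end = 10000)
  rg3 <- regions_for_sv(reg, tads)
  expect_equal(rg3$kind, "explicit")
  expect_equal(rg3$start, 0)
  expect_equal(rg3$end, 10000)
})

test_that("indexed brTAD lookup matches the linear-scan oracle", {
  b <- fixture_bundle()
  set.seed(11)
  for (i in 1:200) {
    chrom <- sample(c("chr1", "chr2"), 1)
    lim <- if (chrom == "chr1") 600000 else 400000
    pos <- sample(0:(lim - 1), 1)
    r <- resolve_brtad(chrom, pos, b$tads)
    o <- oracle_brtad(b$tads, chrom, pos)
    expect_equal(r$start, o$start)
    expect_equal(r$end, o$end)
    expect_equal(r$tad_index, o$index)
  }
})

test_that("SV validation enforces the paper-scale constraints", {
  expect_error(sv_spec("deletion", chrom1 = "chr1", span_start = 1,
                       span_end = 900), "larger than 1 kb")
  expect_error(sv_spec("translocation", chrom1 = "chr1", pos1 = 1,
                       chrom2 = "chr1", pos2 = 2), "different chromosomes")
  expect_error(sv_spec("inversion", chrom1 = "chr1", pos1 = 500, pos2 = 100),
               "ordered")
  expect_error(sv_spec("banana"), "unknown sv_type")
})
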