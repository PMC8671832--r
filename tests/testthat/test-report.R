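# Cytoband tables for the clinically reported strings (band intervals are
# inputs; breakpoints fall inside the named bands).
report_cytobands <- function() {
  tibble::tibble(
    chrom = c("chr10", "chr2", "chr2", "chr11", "chr2"),
    start = c(80300000, 117800000, 120800000, 85600000, 55000000),
    end = c(84200000, 120800000, 125000000, 88300000, 61100000),
    band = c("q22.3", "q14.2", "q14.3", "q14.2", "p16.1"),
    stain = "gneg")
}

test_that("ISCN strings cover the five SV grammars", {
  cb <- report_cytobands()
  del <- sv_spec("deletion", chrom1 = "chr10", span_start = 81603169,
                 span_end = 81976925, genome_build = "GRCh37")
  expect_equal(format_iscn(del, cb),
               "arr[GRCh37]10q22.3(81,603,169_81,976,925)x1")
  expect_equal(format_iscn(del, cb, style = "shorthand"), "del(10)(q22.3)")

  tra <- sv_spec("translocation", chrom1 = "chr2", pos1 = 118000000,
                 chrom2 = "chr11", pos2 = 86000000)
  expect_equal(format_iscn(tra, cb), "t(2;11)(q14.2;q14.2)")
  # chromosome order is normalised regardless of input order
  tra2 <- sv_spec("translocation", chrom1 = "chr11", pos1 = 86000000,
                  chrom2 = "chr2", pos2 = 118000000)
  expect_equal(format_iscn(tra2, cb), "t(2;11)(q14.2;q14.2)")

  inv <- sv_spec("inversion", chrom1 = "chr2", pos1 = 56000000,
                 pos2 = 121000000)
  expect_equal(format_iscn(inv, cb), "inv(2)(p16.1q14.3)")

  dup <- sv_spec("duplication", chrom1 = "chr2", span_start = 118000001,
                 span_end = 118589000)
  expect_equal(format_iscn(dup, cb, style = "shorthand"), "dup(2)(q14.2)")
  expect_match(format_iscn(dup, cb), "x3$")

  # breakpoint outside band coverage errors
  far <- sv_spec("inversion", chrom1 = "chr2", pos1 = 1000, pos2 = 56000000)
  expect_error(format_iscn(far, cb), "outside cytoband coverage")
})

test_that("sex chromosomes come first in translocation strings", {
  cb <- tibble::tibble(chrom = c("chrY", "chr3"), start = 0,
                       end = c(57227415, 198295559),
                       band = c("p11.2", "p12.3"), stain = "gneg")
  tra <- sv_spec("translocation", chrom1 = "chr3", pos1 = 1e6,
                 chrom2 = "chrY", pos2 = 1e6)
  expect_equal(format_iscn(tra, cb), "t(Y;3)(p11.2;p12.3)")
})

test_that("length labels round to kb below 1 Mb and 0.1 Mb above", {
  expect_equal(sv_length_label(81976925 - 81603169 + 1), "374 kb")
  expect_equal(sv_length_label(16527659 - 15416498 + 1), "1.1 Mb")
  expect_equal(sv_length_label(1000000), "1.0 Mb")
  expect_equal(sv_length_label(999499), "999 kb")
  expect_equal(sv_length_label(c(2000, 67300000)), c("2 kb", "67.3 Mb"))
})

test_that("run summary reproduces the published cohort statistics", {
  # 222 SVs: 127 originally VUS, 76 VUS after reanalysis, 139 concordant
  original <- c(rep("vus", 76), rep("benign", 63), rep("vus", 51),
                rep("likely_pathogenic", 32))
  reanalyzed <- c(rep("vus", 76), rep("benign", 63), rep("likely_benign", 51),
                  rep("pathogenic", 32))
  s <- summarize_run(original, reanalyzed)
  expect_equal(s$vus_reduction_percent, 40)
  expect_equal(s$original_vus_share_percent, 57.2)
  expect_equal(s$concordance_percent, 62.6)
  g <- glance(s)
  expect_equal(g$n, 222)
  expect_equal(sum(tidy(s)$original), 222)
  expect_equal(sum(tidy(s)$reanalyzed), 222)
})

test_that("run summary handles identity and degenerate inputs", {
  calls <- c("vus", "benign", "pathogenic")
  s <- summarize_run(calls, calls)
  expect_equal(s$concordance_percent, 100.0)
  expect_equal(s$vus_reduction_percent, 0)
  s2 <- summarize_run(c("benign", "benign"), c("vus", "benign"))
  expect_true(is.na(s2$vus_reduction_percent))  # no original VUS: no ratio
  expect_error(summarize_run(calls, calls[1:2]), "same length")
})

test_that("summary percentages recompute from the count vectors", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    o <- sample(sv_categories, n, replace = TRUE)
    r <- sample(sv_categories, n, replace = TRUE)
    s <- summarize_run(o, r)
    cnt <- s$counts
    v0 <- cnt$original[cnt$category == "vus"]
    v1 <- cnt$reanalyzed[cnt$category == "vus"]
    expect_equal(v0, sum(o == "vus"))
    if (v0 > 0) expect_equal(s$vus_reduction_percent, round(100 * (v0 - v1) / v0))
    expect_equal(s$concordance_percent, round(100 * mean(o == r), 1))
    expect_equal(s$original_vus_share_percent, round(100 * v0 / n, 1))
  }
})

test_that("outputs are written deterministically as TSV", {
  b <- fixture_bundle()
  v <- read_variants(file.path(fixture_dir(), "variants.tsv"))
  res <- interpret_batch(v[v$sv_id %in% c("sv_ck", "sv_benign"), ], b, seed = 1)
  d1 <- tempfile(); d2 <- tempfile()
  s <- summarize_run(res$classifications$category, res$classifications$category)
  write_outputs(res$rows, d1, summary = s, detailed_overlaps = res$overlaps)
  write_outputs(res$rows, d2, summary = s, detailed_overlaps = res$overlaps)
  for (suffix in c("_report.tsv", "_summary.tsv", "_overlaps.tsv")) {
    f1 <- paste0(d1, suffix); f2 <- paste0(d2, suffix)
    expect_true(file.exists(f1))
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
  expect_error(write_outputs(res$rows, tempfile(), formats = "xlsx"),
               "TSV")
  expect_error(write_outputs(NULL, tempfile()), "nothing to write")
  # summary-only run writes just the summary file
  p <- tempfile()
  out <- write_outputs(NULL, p, summary = s)
  expect_equal(out, paste0(p, "_summary.tsv"))
})
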