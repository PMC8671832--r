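# Reciprocal ("mutual") overlap search of a query CNV against curated
# database tables: the mutual overlap is the smaller of the two coverage
# fractions, and the best hit per database maximises it.

#' Mutual (reciprocal) overlap between two intervals
#'
#' `cov_a` is the percentage of interval A covered by the intersection,
#' `cov_b` likewise for B, and `mutual = min(cov_a, cov_b)`.  Intervals on
#' different chromosomes score zero.  Vectorised over B.
#'
#' @param a_chrom,a_start,a_end Query interval (0-based half-open).
#' @param b_chrom,b_start,b_end Subject interval(s).
#' @return Tibble `mutual, cov_a, cov_b` (percentages in \[0, 100\]).
#' @export
mutual_overlap <- function(a_chrom, a_start, a_end, b_chrom, b_start, b_end) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  ov[b_chrom != a_chrom] <- 0
  cov_a <- 100 * ov / (a_end - a_start)
  cov_b <- 100 * ov / (b_end - b_start)
  tibble(mutual = pmin(cov_a, cov_b), cov_a = cov_a, cov_b = cov_b)
}

cnv_candidates <- function(chrom, start, end, cnv_type, db, threshold) {
  if (length(threshold) != 1 || threshold <= 0 || threshold > 100) {
    abort("threshold must be in (0, 100]")
  }
  m <- mutual_overlap(chrom, start, end, db$chrom, db$start, db$end)
  out <- mutate(db, mutual_overlap = m$mutual, query_coverage = m$cov_a,
                record_coverage = m$cov_b)
  filter(out, .data$cnv_type == .env$cnv_type,
         .data$mutual_overlap >= .env$threshold)
}

#' All database hits above the mutual-overlap threshold
#'
#' @param chrom,start,end Query CNV interval (0-based half-open).
#' @param cnv_type `"loss"` or `"gain"`; only same-type records are
#'   candidates.
#' @param db CNV database tibble from [read_cnv_db()] (may pool several
#'   `source_db` values).
#' @param threshold Minimum mutual overlap percentage (default 70).
#' @return Tibble of passing records with `mutual_overlap`,
#'   `query_coverage`, `record_coverage`, sorted by decreasing mutual
#'   overlap (ties by record coverage, then record id).
#' @export
cnv_overlap_table <- function(chrom, start, end, cnv_type, db, threshold = 70) {
  cnv_candidates(chrom, start, end, cnv_type, db, threshold) |>
    arrange(desc(.data$mutual_overlap), desc(.data$record_coverage),
            .data$record_id)
}

#' Best database hit per source database
#'
#' The best hit maximises mutual overlap within each `source_db`; ties
#' are broken by higher record coverage, then lexicographic record id.
#' Databases without a passing hit are absent from the result.
#'
#' @inheritParams cnv_overlap_table
#' @return Tibble with one row per database that produced a hit.
#' @export
best_hits <- function(chrom, start, end, cnv_type, db, threshold = 70) {
  cnv_overlap_table(chrom, start, end, cnv_type, db, threshold) |>
    group_by(.data$source_db) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$source_db)
}
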