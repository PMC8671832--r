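# Element retrieval per resolved region with the breakpoint-vs-remaining
# filter, plus the disruption flags that signal gene disruption and
# potential position effects (severed regulatory clusters, broken
# chromatin loops).

remaining_biotypes <- c("protein_coding", "lincRNA", "lncRNA")

#' Is a gene disrupted by a breakpoint?
#'
#' A gene counts as disrupted only when the breakpoint lies strictly
#' inside its span; a breakpoint at an exact gene boundary flanks the gene
#' rather than disrupting it.
#'
#' @param pos Breakpoint position (0-based).
#' @param gene_start,gene_end Gene span (0-based half-open); vectorised.
#' @return Logical vector.
#' @export
flag_gene_disruption <- function(pos, gene_start, gene_end) {
  gene_start < pos & pos < gene_end
}

#' Chromatin loops of a gene broken by a breakpoint
#'
#' `loops_total` counts loops with either anchor overlapping the gene
#' span; a loop is disrupted when the breakpoint falls strictly between
#' its anchors (`end_a <= pos < start_b`).  Breakpoints inside an anchor
#' are ambiguous and not counted as disrupting.
#'
#' @param chrom,pos Breakpoint.
#' @param gene_chrom,gene_start,gene_end Gene span.
#' @param loops Loop tibble from [read_loops()].
#' @return List with `loops_disrupted` and `loops_total`.
#' @export
count_disrupted_loops <- function(chrom, pos, gene_chrom, gene_start, gene_end, loops) {
  gl <- loops[loops$chrom == gene_chrom &
                ((loops$start_a < gene_end & loops$end_a > gene_start) |
                   (loops$start_b < gene_end & loops$end_b > gene_start)), ,
              drop = FALSE]
  total <- nrow(gl)
  if (total == 0 || chrom != gene_chrom) {
    return(list(loops_disrupted = 0L, loops_total = total))
  }
  disrupted <- sum(gl$end_a <= pos & pos < gl$start_b)
  list(loops_disrupted = as.integer(disrupted), loops_total = total)
}

#' Is a regulatory-interaction cluster severed by a breakpoint?
#'
#' True when the breakpoint lies within the cluster hull (min element
#' start to max element end) and at least one element lies entirely on
#' each side — i.e. the break separates a regulator from its target.
#'
#' @param chrom,pos Breakpoint.
#' @param cluster Tibble of the cluster's elements (`chrom,
#'   element_start, element_end` rows for one target gene).
#' @return Logical scalar.
#' @export
flag_cluster_disruption <- function(chrom, pos, cluster) {
  if (nrow(cluster) == 0 || cluster$chrom[1] != chrom) return(FALSE)
  hull_lo <- min(cluster$element_start)
  hull_hi <- max(cluster$element_end)
  if (!(pos >= hull_lo && pos < hull_hi)) return(FALSE)
  any(cluster$element_end <= pos) && any(cluster$element_start >= pos)
}

#' Collect genomic elements within a resolved region
#'
#' From breakpoint TADs (`kind = "brTAD"`) every overlapping element is
#' retrieved; from the remaining regions of CNVs, flanking TADs and
#' explicit regions only protein-coding genes, lincRNAs, lncRNAs and
#' other elements with a tissue expression pattern are kept.  When the
#' region carries a source breakpoint, per-gene disruption flags are
#' computed: gene disruption, disrupted/total chromatin loops, and
#' regulatory-cluster severance; `intergenic_breakpoint` records whether
#' no gene body contains the breakpoint.
#'
#' @param region One-row region tibble (from [resolve_brtad()] /
#'   [regions_for_sv()]).
#' @param genes Gene tibble.
#' @param clusters Cluster tibble (may be empty/NULL).
#' @param loops Loop tibble (may be empty/NULL).
#' @return Tibble with one row per gene hit, carrying gene fields plus
#'   `region_kind`, `region_offset`, `disrupted_by_breakpoint`,
#'   `loops_disrupted`, `loops_total`, `cluster_disrupted`,
#'   `intergenic_breakpoint`.
#' @export
collect_elements <- function(region, genes, clusters = NULL, loops = NULL) {
  stopifnot(nrow(region) == 1)
  if (is.null(clusters)) clusters <- tibble(target_gene = character(),
                                            chrom = character(),
                                            element_start = numeric(),
                                            element_end = numeric())
  if (is.null(loops)) loops <- tibble(chrom = character(), start_a = numeric(),
                                      end_a = numeric(), start_b = numeric(),
                                      end_b = numeric(), tissue = character())
  hit <- genes[genes$chrom == region$chrom &
                 genes$start < region$end & genes$end > region$start, ,
               drop = FALSE]
  if (region$kind != "brTAD") {
    hit <- hit[hit$biotype %in% remaining_biotypes | hit$has_expression_pattern, ,
               drop = FALSE]
  }
  has_bp <- !is.na(region$bp_pos)
  bp_chrom <- region$bp_chrom
  bp_pos <- region$bp_pos
  n <- nrow(hit)
  if (n == 0) {
    out <- mutate(hit, disrupted_by_breakpoint = logical(0),
                  loops_disrupted = integer(0), loops_total = integer(0),
                  cluster_disrupted = logical(0),
                  intergenic_breakpoint = logical(0))
  } else {
    disrupted <- rep(FALSE, n)
    ld <- integer(n); lt <- integer(n); cd <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (has_bp && bp_chrom == hit$chrom[i]) {
        disrupted[i] <- flag_gene_disruption(bp_pos, hit$start[i], hit$end[i])
        lc <- count_disrupted_loops(bp_chrom, bp_pos, hit$chrom[i],
                                    hit$start[i], hit$end[i], loops)
        ld[i] <- lc$loops_disrupted; lt[i] <- lc$loops_total
        cl <- clusters[clusters$target_gene == hit$gene_id[i], , drop = FALSE]
        cd[i] <- flag_cluster_disruption(bp_chrom, bp_pos, cl)
      } else {
        lc <- count_disrupted_loops(hit$chrom[i], -1, hit$chrom[i],
                                    hit$start[i], hit$end[i], loops)
        lt[i] <- lc$loops_total
      }
    }
    out <- mutate(hit,
                  disrupted_by_breakpoint = disrupted,
                  loops_disrupted = ld, loops_total = lt,
                  cluster_disrupted = cd,
                  intergenic_breakpoint = has_bp && !any(disrupted))
  }
  mutate(out, region_kind = region$kind, region_offset = region$offset,
         region_start = region$start, region_end = region$end,
         bp_label = region$bp_label, .before = 1)
}

#' UCSC genome-browser URL for a region
#'
#' Deterministic link embedding the build and the 1-based inclusive
#' position of the region.
#'
#' @param chrom,start,end Region (0-based half-open).
#' @param build Genome build label (e.g. "GRCh37"); must be non-empty.
#' @return URL string.
#' @export
ucsc_session_url <- function(chrom, start, end, build) {
  if (!nzchar(build)) abort("genome build label must be non-empty")
  sprintf("https://genome.ucsc.edu/cgi-bin/hgTracks?db=%s&position=%s:%d-%d",
          build, chrom, as.integer(disp_start(start)), as.integer(disp_end(end)))
}
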