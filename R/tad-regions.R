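# Resolution of the genomic regions to analyse for an SV: the TAD hit by
# each breakpoint (brTAD), up to five flanking TADs per side, the interior
# "remaining" region of CNVs, explicit genomic-region mode, and an
# average-TAD-size fallback for chromosomes without called TADs (chrY).

sv_types <- c("translocation", "inversion", "deletion", "duplication",
              "insertion", "region")

#' Construct a structural-variant record
#'
#' Positions are user-facing 1-based coordinates (as printed in clinical
#' reports) and converted to the internal 0-based half-open convention.
#' `span_start`/`span_end` are 1-based inclusive.  Deletions and
#' duplications must be larger than 1 kb.
#'
#' @param sv_type One of `translocation`, `inversion`, `deletion`,
#'   `duplication`, `insertion`, `region`.
#' @param chrom1,pos1 First breakpoint (1-based).  For insertions this is
#'   the acceptor site.
#' @param chrom2,pos2 Second breakpoint (1-based) where applicable; for
#'   translocations this must be a different chromosome.
#' @param span_start,span_end CNV / donor / region span (1-based
#'   inclusive) where applicable.
#' @param sv_id Identifier used in report rows.
#' @param genome_build Build label embedded in ISCN strings and URLs.
#' @param tissue TAD/loop reference label.
#' @return A one-row tibble with internal 0-based coordinates.
#' @export
sv_spec <- function(sv_type, chrom1 = NA, pos1 = NA, chrom2 = NA, pos2 = NA,
                    span_start = NA, span_end = NA, sv_id = "sv1",
                    genome_build = "GRCh37", tissue = "hESC") {
  sv <- tibble(sv_id = sv_id, sv_type = sv_type,
               chrom1 = as.character(chrom1),
               pos1 = if (is.na(pos1)) NA_real_ else pos1 - 1,
               chrom2 = as.character(chrom2),
               pos2 = if (is.na(pos2)) NA_real_ else pos2 - 1,
               span_start = if (is.na(span_start)) NA_real_ else span_start - 1,
               span_end = if (is.na(span_end)) NA_real_ else as.numeric(span_end),
               genome_build = genome_build, tissue = tissue)
  validate_sv(sv)
  sv
}

# Validates one SV row (internal 0-based coordinates).
validate_sv <- function(sv) {
  stopifnot(nrow(sv) == 1)
  t <- sv$sv_type
  if (!t %in% sv_types) abort(sprintf("unknown sv_type '%s'", t))
  has_span <- !is.na(sv$span_start) && !is.na(sv$span_end)
  if (t %in% c("deletion", "duplication")) {
    if (!has_span) abort(sprintf("%s '%s' needs span_start/span_end", t, sv$sv_id))
    len <- sv$span_end - sv$span_start
    if (len <= 1000) {
      abort(sprintf("%s '%s' is %d bp; only SVs larger than 1 kb are analysed",
                    t, sv$sv_id, len))
    }
  }
  if (t == "region" && !has_span) abort(sprintf("region '%s' needs a span", sv$sv_id))
  if (t == "translocation") {
    if (is.na(sv$chrom1) || is.na(sv$chrom2) || is.na(sv$pos1) || is.na(sv$pos2)) {
      abort(sprintf("translocation '%s' needs two breakpoints", sv$sv_id))
    }
    if (sv$chrom1 == sv$chrom2) {
      abort(sprintf("translocation '%s' breakpoints must be on different chromosomes",
                    sv$sv_id))
    }
  }
  if (t == "inversion") {
    if (is.na(sv$pos1) || is.na(sv$pos2)) {
      abort(sprintf("inversion '%s' needs two breakpoints", sv$sv_id))
    }
    if (!is.na(sv$chrom2) && sv$chrom1 != sv$chrom2) {
      abort(sprintf("inversion '%s' breakpoints must share a chromosome", sv$sv_id))
    }
    if (sv$pos1 >= sv$pos2) {
      abort(sprintf("inversion '%s' breakpoints must be ordered", sv$sv_id))
    }
  }
  if (t == "insertion" && (is.na(sv$chrom1) || is.na(sv$pos1))) {
    abort(sprintf("insertion '%s' needs an acceptor breakpoint", sv$sv_id))
  }
  invisible(sv)
}

# Empty resolved-region tibble with the canonical schema.
empty_regions <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric(),
         kind = character(), offset = integer(), tad_index = integer(),
         note = character(), bp_chrom = character(), bp_pos = numeric(),
         bp_label = character())
}

region_row <- function(chrom, start, end, kind, offset, tad_index, note,
                       bp_chrom = NA_character_, bp_pos = NA_real_,
                       bp_label = NA_character_) {
  tibble(chrom = chrom, start = start, end = end, kind = kind,
         offset = as.integer(offset), tad_index = as.integer(tad_index),
         note = note, bp_chrom = bp_chrom, bp_pos = bp_pos, bp_label = bp_label)
}

#' Resolve the TAD containing a breakpoint (brTAD)
#'
#' Uses an indexed lookup (`findInterval` over the sorted TAD starts) on
#' the per-chromosome TAD map.  A breakpoint falling in an inter-TAD gap
#' resolves to the gap interval itself, flagged `"boundary/gap"` — TAD
#' boundaries restrict regulatory interactions and deserve explicit
#' surfacing rather than silently picking a side.  Positions before the
#' first or after the last TAD resolve to the flanking unbounded gap,
#' clipped to a zero-offset window of the neighbouring TAD's size.
#'
#' @param chrom,pos Breakpoint (internal 0-based position).
#' @param tads TAD tibble from [read_tads()].
#' @param avg_size Optional average TAD size: fallback window size used
#'   when `chrom` has no TADs in the map (the chrY case).
#' @param bp_label Free-text label carried into the result.
#' @return One-row region tibble: `chrom, start, end, kind ("brTAD"),
#'   offset (0), tad_index, note, bp_chrom, bp_pos, bp_label`.
#' @export
resolve_brtad <- function(chrom, pos, tads, avg_size = NULL, bp_label = NA_character_) {
  ct <- tads[tads$chrom == chrom, , drop = FALSE]
  if (nrow(ct) == 0) {
    if (!is.null(avg_size)) {
      return(chry_fallback_window(chrom, pos, avg_size, bp_label = bp_label))
    }
    abort(sprintf("chromosome '%s' absent from the TAD map and no average-size fallback configured",
                  chrom))
  }
  ct <- arrange(ct, .data$start)
  i <- findInterval(pos, ct$start)  # last TAD with start <= pos
  if (i >= 1 && pos < ct$end[i]) {
    return(region_row(chrom, ct$start[i], ct$end[i], "brTAD", 0L,
                      ct$index[i], NA_character_, chrom, pos, bp_label))
  }
  # in a gap: before the first TAD, between TADs, or after the last
  if (i == 0) {
    return(region_row(chrom, max(0, ct$start[1] - (ct$end[1] - ct$start[1])),
                      ct$start[1], "brTAD", 0L, NA_integer_,
                      "boundary/gap", chrom, pos, bp_label))
  }
  gap_end <- if (i < nrow(ct)) ct$start[i + 1] else {
    ct$end[i] + (ct$end[i] - ct$start[i])
  }
  note <- if (i < nrow(ct)) "boundary/gap" else "boundary/gap"
  region_row(chrom, ct$end[i], gap_end, "brTAD", 0L, NA_integer_,
             note, chrom, pos, bp_label)
}

#' Flanking TADs around a breakpoint
#'
#' Up to `k` TADs on each side of the brTAD in coordinate order, truncated
#' at the chromosome ends; offsets run -k..-1 (lower coordinates) and
#' +1..+k (higher coordinates).  Flank direction is genomic, not
#' transcriptional.
#'
#' @inheritParams resolve_brtad
#' @param k Number of flanking TADs per side, 0..5.
#' @return Region tibble with `kind = "flankTAD"`, possibly empty.
#' @export
flanking_tads <- function(chrom, pos, tads, k, avg_size = NULL,
                          bp_label = NA_character_) {
  if (length(k) != 1 || is.na(k) || k < 0 || k > 5) {
    abort("k must be an integer in 0..5")
  }
  k <- as.integer(k)
  if (k == 0) return(empty_regions())
  br <- resolve_brtad(chrom, pos, tads, avg_size = avg_size, bp_label = bp_label)
  ct <- tads[tads$chrom == chrom, , drop = FALSE]
  if (nrow(ct) == 0) {
    # average-size fallback: adjacent same-size windows
    w <- br$end - br$start
    offs <- setdiff(seq(-k, k), 0)
    rows <- purrr::map(offs, function(o) {
      s <- br$start + o * w
      if (s < 0) return(NULL)
      region_row(chrom, s, s + w, "flankTAD", o, NA_integer_,
                 "average-size window", chrom, pos, bp_label)
    })
    return(bind_rows(c(list(empty_regions()), rows)))
  }
  ct <- arrange(ct, .data$start)
  left <- ct[ct$end <= br$start, , drop = FALSE]
  right <- ct[ct$start >= br$end, , drop = FALSE]
  left <- utils::tail(left, k)
  right <- utils::head(right, k)
  rows <- list(empty_regions())
  if (nrow(left) > 0) {
    offs <- seq(-nrow(left), -1L)
    for (j in seq_len(nrow(left))) {
      rows[[length(rows) + 1]] <- region_row(chrom, left$start[j], left$end[j],
                                             "flankTAD", offs[j], left$index[j],
                                             NA_character_, chrom, pos, bp_label)
    }
  }
  if (nrow(right) > 0) {
    for (j in seq_len(nrow(right))) {
      rows[[length(rows) + 1]] <- region_row(chrom, right$start[j], right$end[j],
                                             "flankTAD", j, right$index[j],
                                             NA_character_, chrom, pos, bp_label)
    }
  }
  bind_rows(rows)
}

#' Average-TAD-size fallback window
#'
#' For chromosomes without called TADs (chromosome Y in most references),
#' the chromosome is tiled with windows of the reference's average TAD
#' size; the window containing the breakpoint plays the brTAD role.
#'
#' @inheritParams resolve_brtad
#' @param avg_size Window size in base pairs (> 0), e.g. 815000 for a
#'   lymphoblastoid reference.
#' @return One-row region tibble flagged `"average-size window"`.
#' @export
chry_fallback_window <- function(chrom, pos, avg_size, bp_label = NA_character_) {
  if (length(avg_size) != 1 || is.na(avg_size) || avg_size <= 0) {
    abort("avg_size must be a positive number of base pairs")
  }
  s <- floor(pos / avg_size) * avg_size
  region_row(chrom, s, s + avg_size, "brTAD", 0L, NA_integer_,
             "average-size window", chrom, pos, bp_label)
}

#' Resolve all regions to analyse for a structural variant
#'
#' * translocation / inversion / insertion: brTAD plus `k` flanking TADs
#'   per breakpoint (insertions contribute the acceptor site and, when a
#'   donor span is given, its two ends — three breakpoints in all);
#' * deletion / duplication: brTADs of both span ends, their flanks, plus
#'   the interior of the span not covered by the two brTADs as a
#'   `"remaining"` region;
#' * region mode: the explicit span, unmodified.
#'
#' @param sv One-row SV tibble from [sv_spec()] or [read_variants()].
#' @param tads TAD tibble.
#' @param k Flanking TADs per side (0..5).
#' @param avg_size Optional fallback window size for chromosomes missing
#'   from the TAD map.
#' @return Region tibble ordered by breakpoint then offset.
#' @export
regions_for_sv <- function(sv, tads, k = 0, avg_size = NULL) {
  validate_sv(sv)
  t <- sv$sv_type
  if (t == "region") {
    return(region_row(sv$chrom1, sv$span_start, sv$span_end, "explicit",
                      NA_integer_, NA_integer_, NA_character_))
  }
  bps <- list()
  if (t %in% c("translocation", "inversion")) {
    bps <- list(list(chrom = sv$chrom1, pos = sv$pos1, label = "bp1"),
                list(chrom = if (t == "inversion") sv$chrom1 else sv$chrom2,
                     pos = sv$pos2, label = "bp2"))
  } else if (t == "insertion") {
    bps <- list(list(chrom = sv$chrom1, pos = sv$pos1, label = "acceptor"))
    if (!is.na(sv$span_start) && !is.na(sv$span_end)) {
      dc <- if (!is.na(sv$chrom2)) sv$chrom2 else sv$chrom1
      bps <- c(bps, list(list(chrom = dc, pos = sv$span_start, label = "donor-start"),
                         list(chrom = dc, pos = sv$span_end, label = "donor-end")))
    }
  } else {  # deletion / duplication
    bps <- list(list(chrom = sv$chrom1, pos = sv$span_start, label = "span-start"),
                list(chrom = sv$chrom1, pos = sv$span_end, label = "span-end"))
  }
  out <- purrr::map(bps, function(b) {
    br <- resolve_brtad(b$chrom, b$pos, tads, avg_size = avg_size, bp_label = b$label)
    fl <- flanking_tads(b$chrom, b$pos, tads, k, avg_size = avg_size, bp_label = b$label)
    arrange(bind_rows(br, fl), .data$offset)
  })
  out <- bind_rows(out)
  if (t %in% c("deletion", "duplication")) {
    br <- out[out$kind == "brTAD", , drop = FALSE]
    inner_start <- min(br$end[br$bp_label == "span-start"], sv$span_end)
    inner_end <- max(br$start[br$bp_label == "span-end"], sv$span_start)
    if (inner_start < inner_end) {
      out <- bind_rows(out, region_row(sv$chrom1, inner_start, inner_end,
                                       "remaining", NA_integer_, NA_integer_,
                                       "CNV interior"))
    }
  }
  out
}
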