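# Minimal ISCN-style nomenclature: the grammar covering the five SV types
# (t, inv, arr, dup/del shorthand).  Full ISCN 2020 (complex karyotypes,
# uncertainty brackets) is out of scope.

#' Cytogenetic band containing a position
#'
#' @param cytobands Cytoband tibble from [read_cytobands()].
#' @param chrom Chromosome.
#' @param pos Position (0-based).
#' @return Band label (e.g. `"q22.3"`).
#' @export
band_at <- function(cytobands, chrom, pos) {
  hit <- cytobands[cytobands$chrom == chrom & cytobands$start <= pos &
                     pos < cytobands$end, , drop = FALSE]
  if (nrow(hit) == 0) {
    abort(sprintf("position %s:%s outside cytoband coverage", chrom, fmt_coord(pos)))
  }
  hit$band[1]
}

collapse_bands <- function(b1, b2) if (b1 == b2) b1 else paste0(b1, b2)

#' ISCN-style string for a structural variant
#'
#' Produces the minimal ISCN grammar used in clinical reports:
#' * translocation: `t(2;11)(q14.2;q14.2)` — sex chromosomes first, then
#'   ascending autosomes;
#' * inversion: `inv(2)(p16.1q14.3)` with bands in coordinate order;
#' * deletion/duplication: microarray-style
#'   `arr[GRCh37]10q22.3(81,603,169_81,976,925)x1` with comma-grouped
#'   1-based inclusive coordinates, same-band collapsing, and copy number
#'   1 (loss) or 3 (gain); shorthand `dup(2)(q21.1)` via
#'   `style = "shorthand"`;
#' * insertion: `ins(2)(q14.2)` at the acceptor band;
#' * region: `chrom:start-end` (1-based).
#'
#' @param sv One-row SV tibble.
#' @param cytobands Cytoband tibble covering the breakpoints.
#' @param build Genome build label for `arr[...]` strings (default the
#'   SV's `genome_build`).
#' @param style `"arr"` (default) or `"shorthand"` for CNVs.
#' @return ISCN-style string.
#' @export
format_iscn <- function(sv, cytobands, build = NULL, style = c("arr", "shorthand")) {
  style <- match.arg(style)
  validate_sv(sv)
  if (is.null(build)) build <- sv$genome_build
  t <- sv$sv_type
  if (t == "translocation") {
    k1 <- iscn_chrom_key(sv$chrom1); k2 <- iscn_chrom_key(sv$chrom2)
    b1 <- band_at(cytobands, sv$chrom1, sv$pos1)
    b2 <- band_at(cytobands, sv$chrom2, sv$pos2)
    if (k2 < k1) {
      tmp <- list(sv$chrom1, b1); c1 <- sv$chrom2; b1 <- b2
      c2 <- tmp[[1]]; b2 <- tmp[[2]]
    } else {
      c1 <- sv$chrom1; c2 <- sv$chrom2
    }
    return(sprintf("t(%s;%s)(%s;%s)", chrom_label(c1), chrom_label(c2), b1, b2))
  }
  if (t == "inversion") {
    b1 <- band_at(cytobands, sv$chrom1, sv$pos1)
    b2 <- band_at(cytobands, sv$chrom1, sv$pos2)
    return(sprintf("inv(%s)(%s%s)", chrom_label(sv$chrom1), b1, b2))
  }
  if (t %in% c("deletion", "duplication")) {
    b1 <- band_at(cytobands, sv$chrom1, sv$span_start)
    b2 <- band_at(cytobands, sv$chrom1, sv$span_end - 1)
    bands <- collapse_bands(b1, b2)
    if (style == "shorthand") {
      op <- if (t == "deletion") "del" else "dup"
      return(sprintf("%s(%s)(%s)", op, chrom_label(sv$chrom1), bands))
    }
    cn <- if (t == "deletion") 1L else 3L
    return(sprintf("arr[%s]%s%s(%s_%s)x%d", build, chrom_label(sv$chrom1),
                   bands, fmt_coord(disp_start(sv$span_start)),
                   fmt_coord(disp_end(sv$span_end)), cn))
  }
  if (t == "insertion") {
    b <- band_at(cytobands, sv$chrom1, sv$pos1)
    return(sprintf("ins(%s)(%s)", chrom_label(sv$chrom1), b))
  }
  sprintf("%s:%s-%s", sv$chrom1, fmt_coord(disp_start(sv$span_start)),
          fmt_coord(disp_end(sv$span_end)))
}

#' Human-readable SV length label
#'
#' Lengths under 1 Mb print as the nearest kilobase (`"374 kb"`); 1 Mb
#' and above as the nearest 0.1 Mb (`"1.1 Mb"`).
#'
#' @param length_bp Length in base pairs (the inclusive span length;
#'   for internal half-open intervals this is simply `end - start`).
#' @return Character label.
#' @export
sv_length_label <- function(length_bp) {
  vapply(length_bp, function(l) {
    if (l < 1e6) {
      sprintf("%d kb", as.integer(round(l / 1000)))
    } else {
      sprintf("%.1f Mb", round(l / 1e5) / 10)
    }
  }, character(1))
}
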