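# Automated ACMG/ClinGen dosage scoring for CNVs: the machine-determinable
# evidence criteria are assigned deterministically from the annotation,
# summed, and banded into the five-level classification.

acmg_rubric <- tibble::tribble(
  ~criterion_id,    ~min_points, ~max_points,
  "1A",             0,           0,
  "1B",             -0.60,       -0.60,
  "2A",             1.00,        1.00,
  "2F",             -1.00,       -1.00,
  "benign-overlap", -0.90,       -0.90,
  "3A",             0,           0,
  "3B",             0.45,        0.45,
  "3C",             0.90,        0.90
)

evidence_row <- function(id, points, rationale) {
  tibble(criterion_id = id, points = points, rationale = rationale)
}

#' Assign machine-determinable ACMG CNV evidence
#'
#' Loss rubric: 1A (0.00) when the CNV contains protein-coding or other
#' functional elements, else 1B (-0.60); 2A (+1.00) when an established
#' haploinsufficient gene is fully contained or disrupted by a span end;
#' 2F (-1.00) when the query is completely contained within a curated
#' benign region; a benign-overlap point (-0.90) when the best database
#' hit is a benign / likely-benign record at 100% mutual overlap and 2F
#' does not apply; gene-count bins 0-24 (3A, 0.00), 25-34 (3B, +0.45),
#' >= 35 (3C, +0.90) over protein-coding genes overlapping the span by at
#' least 1 bp.  The gain rubric mirrors this with triplosensitive genes
#' for 2A and bins 0-34 / 35-49 / >= 50.
#'
#' @param sv One-row SV tibble (deletion or duplication; balanced SVs are
#'   routed to the rule engine, not scored here).
#' @param genes Gene tibble.
#' @param cnv_db CNV database tibble (all sources pooled), or NULL.
#' @param threshold Mutual-overlap threshold for the database search.
#' @return Evidence tibble `criterion_id, points, rationale`.
#' @export
assign_evidence <- function(sv, genes, cnv_db = NULL, threshold = 70) {
  validate_sv(sv)
  if (!sv$sv_type %in% c("deletion", "duplication")) {
    abort("ACMG dosage scoring applies to deletions and duplications only")
  }
  loss <- sv$sv_type == "deletion"
  chrom <- sv$chrom1
  s <- sv$span_start; e <- sv$span_end
  ov <- genes[genes$chrom == chrom & genes$start < e & genes$end > s, , drop = FALSE]
  ev <- list()

  functional <- ov[ov$biotype != "non_functional", , drop = FALSE]
  if (nrow(functional) > 0) {
    ev[[length(ev) + 1]] <- evidence_row("1A", 0,
      sprintf("contains %d protein-coding/functional element(s)", nrow(functional)))
  } else {
    ev[[length(ev) + 1]] <- evidence_row("1B", -0.60,
      "contains no protein-coding or functional elements")
  }

  dosage_col <- if (loss) ov$haploinsufficient else ov$triplosensitive
  contained <- ov$start >= s & ov$end <= e
  disrupted <- flag_gene_disruption(s, ov$start, ov$end) |
    flag_gene_disruption(e, ov$start, ov$end)
  dosage_hit <- dosage_col & (contained | disrupted)
  if (any(dosage_hit)) {
    ev[[length(ev) + 1]] <- evidence_row("2A", 1.00,
      sprintf("established %s gene %s fully contained or disrupted",
              if (loss) "haploinsufficient" else "triplosensitive",
              paste(ov$symbol[dosage_hit], collapse = ",")))
  }

  fired_2f <- FALSE
  if (!is.null(cnv_db) && nrow(cnv_db) > 0) {
    type <- if (loss) "loss" else "gain"
    benign_regions <- cnv_db[cnv_db$classification == "benign" &
                               cnv_db$cnv_type == type &
                               cnv_db$chrom == chrom &
                               cnv_db$start <= s & cnv_db$end >= e, , drop = FALSE]
    if (nrow(benign_regions) > 0) {
      fired_2f <- TRUE
      ev[[length(ev) + 1]] <- evidence_row("2F", -1.00,
        sprintf("completely contained within established benign region %s",
                benign_regions$record_id[1]))
    }
    if (!fired_2f) {
      bh <- best_hits(chrom, s, e, type, cnv_db, threshold = threshold)
      bo <- bh[bh$classification %in% c("benign", "likely_benign") &
                 bh$mutual_overlap >= 100 - 1e-9, , drop = FALSE]
      if (nrow(bo) > 0) {
        ev[[length(ev) + 1]] <- evidence_row("benign-overlap", -0.90,
          sprintf("100%% mutual overlap with %s record %s (%s)",
                  bo$classification[1], bo$record_id[1], bo$source_db[1]))
      }
    }
  }

  n_pc <- sum(ov$biotype == "protein_coding")
  bins <- if (loss) c(25, 35) else c(35, 50)
  gc <- if (n_pc < bins[1]) {
    evidence_row("3A", 0, sprintf("%d protein-coding gene(s)", n_pc))
  } else if (n_pc < bins[2]) {
    evidence_row("3B", 0.45, sprintf("%d protein-coding gene(s)", n_pc))
  } else {
    evidence_row("3C", 0.90, sprintf("%d protein-coding gene(s)", n_pc))
  }
  ev[[length(ev) + 1]] <- gc
  bind_rows(ev)
}

#' Sum evidence points into a final ACMG score
#'
#' @param evidence Evidence tibble from [assign_evidence()].
#' @param manual Optional named numeric vector of manually asserted
#'   points for criteria outside the automated subset (e.g.
#'   `c("5A" = 0.45)`); added to the sum.
#' @return Score rounded to 2 decimals.
#' @export
final_score <- function(evidence, manual = NULL) {
  s <- sum(evidence$points)
  if (!is.null(manual)) s <- s + sum(manual)
  round(s, 2)
}

#' Map an ACMG score to its classification band
#'
#' Bands (inclusive edges, hundredth precision): `>= 0.99` pathogenic,
#' `0.90..0.98` likely pathogenic, `-0.89..0.89` VUS, `-0.98..-0.90`
#' likely benign, `<= -0.99` benign.
#'
#' @param score Numeric score(s).
#' @return Character vector of categories.
#' @export
classify_score <- function(score) {
  h <- round(score * 100)
  dplyr::case_when(
    h >= 99 ~ "pathogenic",
    h >= 90 ~ "likely_pathogenic",
    h >= -89 ~ "vus",
    h >= -98 ~ "likely_benign",
    TRUE ~ "benign"
  )
}

#' Score a CNV under the automated ACMG rubric
#'
#' Convenience wrapper combining [assign_evidence()], [final_score()] and
#' [classify_score()].
#'
#' @inheritParams assign_evidence
#' @param manual Optional named numeric vector of manual evidence points.
#' @return Object of class `tad_acmg`: list with `evidence`,
#'   `final_score`, `acmg_class`, `sv_id`.
#' @export
acmg_score <- function(sv, genes, cnv_db = NULL, threshold = 70, manual = NULL) {
  ev <- assign_evidence(sv, genes, cnv_db, threshold = threshold)
  fs <- final_score(ev, manual = manual)
  structure(list(evidence = ev, final_score = fs,
                 acmg_class = classify_score(fs), sv_id = sv$sv_id),
            class = "tad_acmg")
}

#' @export
print.tad_acmg <- function(x, ...) {
  cat(sprintf("<tad_acmg> %s: score %.2f -> %s\n", x$sv_id, x$final_score,
              x$acmg_class))
  for (i in seq_len(nrow(x$evidence))) {
    cat(sprintf("  %-14s %+.2f  %s\n", x$evidence$criterion_id[i],
                x$evidence$points[i], x$evidence$rationale[i]))
  }
  invisible(x)
}

#' @rdname acmg_score
#' @param x A `tad_acmg` object.
#' @param ... Unused.
#' @export
tidy.tad_acmg <- function(x, ...) x$evidence

#' @rdname acmg_score
#' @export
glance.tad_acmg <- function(x, ...) {
  tibble(sv_id = x$sv_id, final_score = x$final_score,
         acmg_class = x$acmg_class, n_criteria = nrow(x$evidence))
}
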