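# Run-level summary statistics and deterministic TSV output.

#' Summarise an original-vs-reanalysed classification run
#'
#' Compares two category calls per SV (e.g. the published classification
#' and the tool-based reevaluation) and reports the VUS reduction, the
#' share of SVs originally called VUS, and the concordance between the
#' two call sets.
#'
#' @param original,reanalyzed Tibbles `sv_id, category`, or plain
#'   category vectors of equal length (then matched positionally).
#' @return Object of class `tad_run_summary`: list with `counts` (per
#'   category, both call sets), `vus_reduction_percent` (nearest
#'   integer; `NA` when no original VUS), `original_vus_share_percent`
#'   and `concordance_percent` (1 decimal), and `n`.
#' @export
summarize_run <- function(original, reanalyzed) {
  as_calls <- function(x, label) {
    if (is.data.frame(x)) {
      require_cols(x, c("sv_id", "category"), label)
      x
    } else tibble(sv_id = as.character(seq_along(x)), category = as.character(x))
  }
  o <- as_calls(original, "original")
  r <- as_calls(reanalyzed, "reanalyzed")
  if (nrow(o) != nrow(r)) abort("call sets must have the same length")
  r <- r[match(o$sv_id, r$sv_id), , drop = FALSE]
  if (anyNA(r$sv_id)) abort("call sets must cover the same sv_ids")
  stopifnot(all(o$category %in% sv_categories), all(r$category %in% sv_categories))

  count_cats <- function(x) {
    unname(vapply(sv_categories, function(k) sum(x == k), integer(1)))
  }
  counts <- tibble(category = sv_categories,
                   original = count_cats(o$category),
                   reanalyzed = count_cats(r$category))
  v0 <- counts$original[counts$category == "vus"]
  v1 <- counts$reanalyzed[counts$category == "vus"]
  n <- nrow(o)
  structure(list(
    counts = counts,
    n = n,
    vus_reduction_percent = if (v0 == 0) NA_real_ else round(100 * (v0 - v1) / v0),
    original_vus_share_percent = round(100 * v0 / n, 1),
    concordance_percent = round(100 * sum(o$category == r$category) / n, 1)
  ), class = "tad_run_summary")
}

#' @export
print.tad_run_summary <- function(x, ...) {
  cat(sprintf("<tad_run_summary> %d SVs: VUS reduction %s%%, original-VUS share %.1f%%, concordance %.1f%%\n",
              x$n, ifelse(is.na(x$vus_reduction_percent), "-",
                          format(x$vus_reduction_percent)),
              x$original_vus_share_percent, x$concordance_percent))
  print(x$counts)
  invisible(x)
}

#' @rdname summarize_run
#' @param x A `tad_run_summary`.
#' @param ... Unused.
#' @export
tidy.tad_run_summary <- function(x, ...) x$counts

#' @rdname summarize_run
#' @export
glance.tad_run_summary <- function(x, ...) {
  tibble(n = x$n, vus_reduction_percent = x$vus_reduction_percent,
         original_vus_share_percent = x$original_vus_share_percent,
         concordance_percent = x$concordance_percent)
}

#' Write report tables to disk
#'
#' Writes the main report rows, the run summary and (optionally) the
#' detailed overlap table as tab-separated files with a fixed column
#' order, so two runs with the same inputs and seed are byte-identical.
#'
#' @param rows Report-row tibble from [interpret_batch()] (may be NULL
#'   with a summary-only run).
#' @param path_prefix Output path prefix; files are written as
#'   `<prefix>_report.tsv`, `<prefix>_summary.tsv`,
#'   `<prefix>_overlaps.tsv`.
#' @param summary Optional `tad_run_summary`.
#' @param detailed_overlaps Optional tibble of all passing database hits.
#' @param formats Output formats; only `"tsv"` is supported.
#' @return Character vector of the paths written, invisibly.
#' @export
write_outputs <- function(rows, path_prefix, summary = NULL,
                          detailed_overlaps = NULL, formats = "tsv") {
  if (!all(formats %in% "tsv")) {
    abort("only TSV output is supported (formats = \"tsv\")")
  }
  if (is.null(rows) && is.null(summary)) {
    abort("nothing to write: provide report rows or a summary")
  }
  written <- character()
  if (!is.null(rows)) {
    p <- paste0(path_prefix, "_report.tsv")
    readr::write_tsv(rows, p, progress = FALSE)
    written <- c(written, p)
  }
  if (!is.null(summary)) {
    p <- paste0(path_prefix, "_summary.tsv")
    readr::write_tsv(dplyr::cross_join(glance(summary),
                                       tidyr::pivot_wider(summary$counts,
                                                          names_from = "category",
                                                          values_from = c("original", "reanalyzed"))),
                     p, progress = FALSE)
    written <- c(written, p)
  }
  if (!is.null(detailed_overlaps)) {
    p <- paste0(path_prefix, "_overlaps.tsv")
    readr::write_tsv(detailed_overlaps, p, progress = FALSE)
    written <- c(written, p)
  }
  invisible(written)
}
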