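# Writers mirroring the readers; write-then-read round-trips field-for-field.

write_plain_tsv <- function(df, path, col_names) {
  readr::write_tsv(df, path, col_names = col_names, progress = FALSE)
  invisible(path)
}

num_chr <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) {
    if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE)
  }, ""))
}

#' Write annotation tables in their on-disk dialects
#'
#' Inverse of the corresponding readers: coordinates stay 0-based half-open
#' except [write_variants()], which re-emits 1-based inclusive positions.
#'
#' @param df Tibble as returned by the matching reader.
#' @param path Output path.
#' @return The path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_tads <- function(df, path) {
  write_plain_tsv(df[, c("chrom", "start", "end")], path, col_names = FALSE)
}

#' @rdname writers
#' @export
write_loops <- function(df, path) {
  out <- tibble(chrom1 = df$chrom, start1 = df$start_a, end1 = df$end_a,
                chrom2 = df$chrom, start2 = df$start_b, end2 = df$end_b)
  write_plain_tsv(out, path, col_names = FALSE)
}

#' @rdname writers
#' @export
write_genes <- function(df, path) {
  out <- df
  out$pli <- num_chr(out$pli)
  out$oe_lof <- num_chr(out$oe_lof)
  write_plain_tsv(out, path, col_names = TRUE)
}

#' @rdname writers
#' @export
write_clusters <- function(df, path) write_plain_tsv(df, path, col_names = TRUE)

#' @rdname writers
#' @export
write_cnv_db <- function(df, path) {
  out <- df
  out$frequency <- num_chr(out$frequency)
  write_plain_tsv(out, path, col_names = TRUE)
}

#' @rdname writers
#' @export
write_cytobands <- function(df, path) write_plain_tsv(df, path, col_names = FALSE)

#' @rdname writers
#' @export
write_variants <- function(df, path) {
  out <- df
  out$pos1 <- num_chr(df$pos1 + 1)
  out$pos2 <- num_chr(df$pos2 + 1)
  out$span_start <- num_chr(df$span_start + 1)
  out$span_end <- num_chr(df$span_end)
  out$chrom1 <- ifelse(is.na(out$chrom1), "", out$chrom1)
  out$chrom2 <- ifelse(is.na(out$chrom2), "", out$chrom2)
  write_plain_tsv(out, path, col_names = TRUE)
}

#' Write a disease-annotation table (HPOA-like)
#'
#' Columns `disease_id, disease_name, inheritance, term_id`, one term per
#' row.
#'
#' @param df Tibble with those four columns.
#' @param path Output path.
#' @export
write_annotations <- function(df, path) write_plain_tsv(df, path, col_names = TRUE)
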