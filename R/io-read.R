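# Readers for the local annotation-file dialects.
#
# Coordinate convention: every file except the variant table stores 0-based
# half-open intervals; the variant table (user-facing) is 1-based inclusive
# and converted on ingest.  All in-memory tibbles are 0-based half-open.

read_tsv_quiet <- function(path, col_names) {
  readr::read_tsv(path, col_names = col_names, col_types = readr::cols(.default = "c"),
                  na = character(), progress = FALSE)
}

parse_int_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) | out != floor(out))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: column '%s' is not an integer ('%s')",
                  path, bad[1], col, x[bad[1]]))
  }
  out
}

parse_num_col <- function(x, col, path, allow_na = TRUE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & nzchar(x) & x != "NA")
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: column '%s' is not numeric ('%s')",
                  path, bad[1], col, x[bad[1]]))
  }
  if (!allow_na && anyNA(out)) abort(sprintf("%s: column '%s' has missing values", path, col))
  out[x == "NA"] <- NA_real_
  out
}

parse_lgl_col <- function(x, col, path) {
  up <- toupper(x)
  ok <- up %in% c("TRUE", "FALSE", "T", "F", "0", "1")
  if (!all(ok)) {
    abort(sprintf("%s: line %d: column '%s' is not logical ('%s')",
                  path, which(!ok)[1], col, x[which(!ok)[1]]))
  }
  up %in% c("TRUE", "T", "1")
}

check_interval <- function(df, path) {
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: invalid interval [%s, %s) (need 0 <= start < end)",
                  path, bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  if (any(!nzchar(df$chrom))) abort(sprintf("%s: empty chromosome name", path))
  invisible(df)
}

require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing mandatory column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read a TAD interval file
#'
#' Tab-separated, headerless, columns `chrom`, `start`, `end` (0-based
#' half-open) and an optional name.  Records are sorted by `(chrom, start)`,
#' checked for overlap, and given a per-chromosome ordinal `index` starting
#' at 0.
#'
#' @param path Path to the TAD file.
#' @param tissue Label of the tissue or cell line the TAD map refers to.
#' @return A tibble with columns `chrom`, `start`, `end`, `tissue`, `index`.
#' @export
read_tads <- function(path, tissue = "unspecified") {
  raw <- read_tsv_quiet(path, col_names = FALSE)
  if (ncol(raw) < 3) abort(sprintf("%s: TAD file needs at least 3 columns", path))
  df <- tibble(chrom = raw[[1]],
               start = parse_int_col(raw[[2]], "start", path),
               end = parse_int_col(raw[[3]], "end", path))
  check_interval(df, path)
  df <- arrange(df, .data$chrom, .data$start)
  df <- mutate(group_by(df, .data$chrom), index = row_number() - 1L)
  df <- ungroup(df)
  ov <- df |>
    group_by(.data$chrom) |>
    filter(dplyr::lag(.data$end, default = -1) > .data$start) |>
    ungroup()
  if (nrow(ov) > 0) {
    prev <- df[df$chrom == ov$chrom[1] & df$index == ov$index[1] - 1L, ]
    abort(sprintf("%s: overlapping TADs on %s: [%d, %d) and [%d, %d)",
                  path, ov$chrom[1], prev$start[1], prev$end[1], ov$start[1], ov$end[1]))
  }
  mutate(df, tissue = tissue, .before = "index")
}

#' Read a chromatin-loop file
#'
#' BEDPE-style, headerless, columns `chrom1,start1,end1,chrom2,start2,end2`
#' (0-based half-open).  Both anchors must be on one chromosome and the left
#' anchor must end before the right anchor starts.
#'
#' @inheritParams read_tads
#' @return Tibble with columns `chrom`, `start_a`, `end_a`, `start_b`,
#'   `end_b`, `tissue`.
#' @export
read_loops <- function(path, tissue = "unspecified") {
  raw <- read_tsv_quiet(path, col_names = FALSE)
  if (ncol(raw) < 6) abort(sprintf("%s: loop file needs 6 columns", path))
  df <- tibble(chrom = raw[[1]],
               start_a = parse_int_col(raw[[2]], "start1", path),
               end_a = parse_int_col(raw[[3]], "end1", path),
               chrom2 = raw[[4]],
               start_b = parse_int_col(raw[[5]], "start2", path),
               end_b = parse_int_col(raw[[6]], "end2", path))
  bad <- which(df$chrom != df$chrom2)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: loop anchors on different chromosomes (%s vs %s)",
                  path, bad[1], df$chrom[bad[1]], df$chrom2[bad[1]]))
  }
  bad <- which(df$end_a > df$start_b)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: left anchor must precede right anchor", path, bad[1]))
  }
  df |> select(-"chrom2") |> mutate(tissue = tissue)
}

gene_biotypes <- c("protein_coding", "lincRNA", "lncRNA",
                   "other_functional", "non_functional")

#' Read a gene-model + metadata table
#'
#' Tab-separated with header: `gene_id, symbol, chrom, start, end, strand,
#' biotype, pli, oe_lof, haploinsufficient, triplosensitive,
#' has_expression_pattern, disorders`.  Coordinates are 0-based half-open.
#' `disorders` is a semicolon-joined list of `disease_id:inheritance` pairs
#' (may be empty).  `pli` must lie in \[0,1\] and `oe_lof` be non-negative
#' when present (empty or `NA` for absent).
#'
#' @param path Path to the gene table.
#' @return Tibble of validated gene records.
#' @export
read_genes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = character(), progress = FALSE)
  require_cols(df, c("gene_id", "symbol", "chrom", "start", "end", "strand",
                     "biotype", "pli", "oe_lof", "haploinsufficient",
                     "triplosensitive", "has_expression_pattern", "disorders"), path)
  out <- tibble(
    gene_id = df$gene_id,
    symbol = df$symbol,
    chrom = df$chrom,
    start = parse_int_col(df$start, "start", path),
    end = parse_int_col(df$end, "end", path),
    strand = df$strand,
    biotype = df$biotype,
    pli = parse_num_col(df$pli, "pli", path),
    oe_lof = parse_num_col(df$oe_lof, "oe_lof", path),
    haploinsufficient = parse_lgl_col(df$haploinsufficient, "haploinsufficient", path),
    triplosensitive = parse_lgl_col(df$triplosensitive, "triplosensitive", path),
    has_expression_pattern = parse_lgl_col(df$has_expression_pattern,
                                           "has_expression_pattern", path),
    disorders = df$disorders
  )
  out$pli[df$pli == ""] <- NA_real_
  out$oe_lof[df$oe_lof == ""] <- NA_real_
  check_interval(out, path)
  bad <- which(!is.na(out$pli) & (out$pli < 0 | out$pli > 1))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: pli = %s outside [0, 1]", path, bad[1], out$pli[bad[1]]))
  }
  bad <- which(!is.na(out$oe_lof) & out$oe_lof < 0)
  if (length(bad) > 0) abort(sprintf("%s: line %d: negative oe_lof", path, bad[1]))
  bad <- which(!out$biotype %in% gene_biotypes)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: unknown biotype '%s'", path, bad[1], out$biotype[bad[1]]))
  }
  bad <- which(!out$strand %in% c("+", "-"))
  if (length(bad) > 0) abort(sprintf("%s: line %d: strand must be + or -", path, bad[1]))
  out
}

#' Expand the per-gene disorder column into one row per link
#'
#' @param genes Gene tibble from [read_genes()].
#' @return Tibble `gene_id, disease_id, inheritance` (one row per link).
#' @export
gene_disorder_links <- function(genes) {
  rows <- purrr::map2(genes$gene_id, genes$disorders, function(gid, txt) {
    if (is.na(txt) || !nzchar(txt)) return(NULL)
    parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    tibble(gene_id = gid,
           disease_id = vapply(kv, function(p) paste(p[-length(p)], collapse = ":"), ""),
           inheritance = vapply(kv, function(p) p[length(p)], ""))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(), disease_id = character(),
                  inheritance = character())
  }
  out
}

#' Read a regulatory-interaction cluster table
#'
#' Tab-separated with header: `target_gene, chrom, element_start,
#' element_end`, one element (enhancer or TSS interval) per row, 0-based
#' half-open.  Each cluster (one `target_gene`) must have at least two
#' elements, all on one chromosome.
#'
#' @param path Path to the cluster table.
#' @return Tibble `target_gene, chrom, element_start, element_end`.
#' @export
read_clusters <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = character(), progress = FALSE)
  require_cols(df, c("target_gene", "chrom", "element_start", "element_end"), path)
  out <- tibble(target_gene = df$target_gene,
                chrom = df$chrom,
                element_start = parse_int_col(df$element_start, "element_start", path),
                element_end = parse_int_col(df$element_end, "element_end", path))
  counts <- table(out$target_gene)
  if (any(counts < 2)) {
    abort(sprintf("%s: cluster for '%s' has fewer than 2 elements",
                  path, names(counts)[counts < 2][1]))
  }
  nch <- tapply(out$chrom, out$target_gene, function(x) length(unique(x)))
  if (any(nch > 1)) {
    abort(sprintf("%s: cluster for '%s' spans multiple chromosomes",
                  path, names(nch)[nch > 1][1]))
  }
  out
}

cnv_classifications <- c("benign", "likely_benign", "vus",
                         "likely_pathogenic", "pathogenic", "unclassified")

#' Read a curated CNV database table
#'
#' Tab-separated with header: `chrom, start, end, cnv_type, classification,
#' frequency, source_db, record_id` (0-based half-open; frequency in \[0,1\]
#' or empty).  Unknown classification labels are coerced to `"unclassified"`
#' with a warning, never dropped.
#'
#' @param path Path to the CNV database table.
#' @return Tibble of validated CNV records.
#' @export
read_cnv_db <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = character(), progress = FALSE)
  require_cols(df, c("chrom", "start", "end", "cnv_type", "classification",
                     "frequency", "source_db", "record_id"), path)
  out <- tibble(chrom = df$chrom,
                start = parse_int_col(df$start, "start", path),
                end = parse_int_col(df$end, "end", path),
                cnv_type = df$cnv_type,
                classification = df$classification,
                frequency = parse_num_col(df$frequency, "frequency", path),
                source_db = df$source_db,
                record_id = df$record_id)
  out$frequency[df$frequency == ""] <- NA_real_
  check_interval(out, path)
  bad <- which(!out$cnv_type %in% c("loss", "gain"))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: cnv_type must be loss or gain", path, bad[1]))
  }
  unknown <- !out$classification %in% cnv_classifications
  if (any(unknown)) {
    warn(sprintf("%s: %d record(s) with unknown classification coerced to 'unclassified' (e.g. '%s')",
                 path, sum(unknown), out$classification[unknown][1]))
    out$classification[unknown] <- "unclassified"
  }
  bad <- which(!is.na(out$frequency) & (out$frequency < 0 | out$frequency > 1))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: frequency %s outside [0, 1]",
                  path, bad[1], out$frequency[bad[1]]))
  }
  out
}

#' Read a UCSC-style cytoband file
#'
#' Headerless, columns `chrom, start, end, band, stain` (0-based half-open).
#' Bands per chromosome must be sorted and tile the chromosome without
#' overlap or gaps.
#'
#' @param path Path to the cytoband file.
#' @return Tibble `chrom, start, end, band, stain`.
#' @export
read_cytobands <- function(path) {
  raw <- read_tsv_quiet(path, col_names = FALSE)
  if (ncol(raw) < 5) abort(sprintf("%s: cytoband file needs 5 columns", path))
  df <- tibble(chrom = raw[[1]],
               start = parse_int_col(raw[[2]], "start", path),
               end = parse_int_col(raw[[3]], "end", path),
               band = raw[[4]],
               stain = raw[[5]])
  check_interval(df, path)
  df <- arrange(df, .data$chrom, .data$start)
  bad <- df |>
    group_by(.data$chrom) |>
    filter(dplyr::lag(.data$end) != .data$start) |>
    ungroup()
  if (nrow(bad) > 0) {
    abort(sprintf("%s: bands on %s do not tile the chromosome near position %d",
                  path, bad$chrom[1], bad$start[1]))
  }
  df
}

#' Read a batch variant table
#'
#' Tab-separated with header: `sv_id, sv_type, chrom1, pos1, chrom2, pos2,
#' span_start, span_end, genome_build, tissue`.  Positions and spans are
#' user-facing 1-based inclusive and converted to the internal 0-based
#' half-open convention on ingest (empty fields for coordinates that do not
#' apply to the SV type).
#'
#' @param path Path to the variant table.
#' @return Tibble of SV records with 0-based `pos1`, `pos2`, `span_start`,
#'   `span_end` columns.
#' @export
read_variants <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = character(), progress = FALSE)
  require_cols(df, c("sv_id", "sv_type", "chrom1", "pos1", "chrom2", "pos2",
                     "span_start", "span_end", "genome_build", "tissue"), path)
  to0 <- function(x, col, off) {
    out <- rep(NA_real_, length(x))
    has <- nzchar(x) & x != "NA"
    out[has] <- parse_int_col(x[has], col, path) - off
    out
  }
  out <- tibble(sv_id = df$sv_id,
                sv_type = df$sv_type,
                chrom1 = ifelse(nzchar(df$chrom1), df$chrom1, NA_character_),
                pos1 = to0(df$pos1, "pos1", 1),
                chrom2 = ifelse(nzchar(df$chrom2), df$chrom2, NA_character_),
                pos2 = to0(df$pos2, "pos2", 1),
                span_start = to0(df$span_start, "span_start", 1),
                span_end = to0(df$span_end, "span_end", 0),
                genome_build = df$genome_build,
                tissue = df$tissue)
  bad <- which(!out$sv_type %in% c("translocation", "inversion", "deletion",
                                   "duplication", "insertion", "region"))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: unknown sv_type '%s'", path, bad[1], out$sv_type[bad[1]]))
  }
  for (i in seq_len(nrow(out))) validate_sv(out[i, ])
  out
}
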