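# Seeded synthetic-data generator: a complete miniature input universe
# (TADs, loops, genes, regulatory clusters, cytobands, CNV databases,
# ontology + disease annotations, variants) with planted truths that are
# re-derived by independent brute-force code before anything is written.

toy_tads <- function() {
  bind_rows(
    tibble(chrom = "chr1", start = seq(0, 5) * 100000, end = seq(1, 6) * 100000),
    tibble(chrom = "chr2", start = seq(0, 3) * 100000, end = seq(1, 4) * 100000)
  )
}

toy_genes <- function(seed) {
  planted <- tibble::tribble(
    ~gene_id, ~symbol, ~chrom, ~start, ~end, ~strand, ~biotype, ~pli, ~oe_lof,
    ~haploinsufficient, ~triplosensitive, ~has_expression_pattern, ~disorders,
    "G_PE",  "PEGA",  "chr1", 160000, 180000, "+", "protein_coding", 0.99, 0.10, FALSE, FALSE, TRUE,  "OMIM:600001:AD",
    "G_CK1", "CKA1",  "chr1", 405000, 408000, "+", "protein_coding", 0.01, 1.10, FALSE, FALSE, TRUE,  "",
    "G_CK2", "CKA2",  "chr1", 412000, 416000, "-", "protein_coding", 0.05, 0.95, FALSE, FALSE, TRUE,  "",
    "G_CK3", "CKA3",  "chr1", 420000, 425000, "+", "protein_coding", 0.10, 0.80, FALSE, FALSE, FALSE, "",
    "G_CK4", "CKA4",  "chr1", 430000, 436000, "-", "protein_coding", 0.22, 1.25, FALSE, FALSE, TRUE,  "",
    "G_CK5", "CKA5",  "chr1", 440000, 445000, "+", "protein_coding", 0.30, 0.90, FALSE, FALSE, TRUE,  "",
    "G_PLI", "PLIA",  "chr1", 310000, 330000, "+", "protein_coding", 0.95, 0.20, FALSE, FALSE, TRUE,  "",
    "G_NF",  "NFE1",  "chr1", 205000, 206000, "+", "non_functional", NA,   NA,   FALSE, FALSE, FALSE, "",
    "G_HI",  "HIG1",  "chr2", 50000,  60000,  "+", "protein_coding", 0.99, 0.05, TRUE,  FALSE, TRUE,  "OMIM:600002:AD",
    "G_AD",  "ADG1",  "chr2", 150000, 170000, "+", "protein_coding", 0.97, 0.12, FALSE, FALSE, TRUE,  "OMIM:600002:AD",
    "G_AR",  "ARG1",  "chr2", 210000, 230000, "-", "protein_coding", 0.10, 0.70, FALSE, FALSE, TRUE,  "OMIM:600003:AR",
    "G_TS",  "TSG1",  "chr2", 310000, 320000, "+", "protein_coding", 0.50, 0.40, FALSE, TRUE,  TRUE,  ""
  )
  filler <- with_local_seed(derive_seed(seed, "filler-genes"), {
    n <- 6
    starts <- sort(sample(seq(505000, 590000, by = 1000), n))
    tibble(gene_id = sprintf("G_F%02d", seq_len(n)),
           symbol = sprintf("FIL%02d", seq_len(n)),
           chrom = "chr1", start = starts, end = starts + 2000,
           strand = sample(c("+", "-"), n, replace = TRUE),
           biotype = sample(c("lincRNA", "lncRNA", "other_functional"), n,
                            replace = TRUE),
           pli = round(stats::runif(n), 2), oe_lof = round(stats::runif(n, 0, 2), 2),
           haploinsufficient = FALSE, triplosensitive = FALSE,
           has_expression_pattern = sample(c(TRUE, FALSE), n, replace = TRUE),
           disorders = "")
  })
  bind_rows(planted, filler)
}

toy_loops <- function() {
  tibble::tribble(
    ~chrom, ~start_a, ~end_a, ~start_b, ~end_b,
    "chr1", 108000, 110000, 158000, 161000,
    "chr1", 100000, 102000, 165000, 167000,
    "chr1", 130000, 132000, 170000, 172000,
    "chr1", 162000, 164000, 185000, 187000,
    "chr2", 140000, 142000, 175000, 177000
  ) |> mutate(tissue = "hESC")
}

toy_clusters <- function() {
  tibble(target_gene = "G_PE", chrom = "chr1",
         element_start = c(110000, 120000, 160000),
         element_end = c(112000, 122000, 161000))
}

toy_cytobands <- function() {
  tibble::tribble(
    ~chrom, ~start, ~end, ~band, ~stain,
    "chr1", 0,      150000, "p12",   "gneg",
    "chr1", 150000, 300000, "p11",   "gpos50",
    "chr1", 300000, 450000, "q11",   "gneg",
    "chr1", 450000, 600000, "q12",   "gpos25",
    "chr2", 0,      200000, "p11",   "gneg",
    "chr2", 200000, 300000, "q11",   "gpos50",
    "chr2", 300000, 400000, "q21.1", "gneg"
  )
}

toy_cnv_db <- function(seed) {
  planted <- tibble::tribble(
    ~chrom, ~start, ~end, ~cnv_type, ~classification, ~frequency, ~source_db, ~record_id,
    "chr1", 404000, 455000, "loss", "likely_benign", 0.002, "clingen_syn", "nsvS0001",
    "chr2", 200000, 300000, "loss", "benign",        0.050, "clingen_syn", "nsvS0002",
    "chr1", 404000, 455000, "loss", "likely_benign", 0.010, "dgv_syn",     "dgvS0003",
    "chr1", 100000, 200000, "loss", "vus",           NA,    "dgv_syn",     "dgvS0004",
    "chr2", 300000, 330000, "gain", "likely_benign", 0.001, "clingen_syn", "nsvS0005"
  )
  extra <- with_local_seed(derive_seed(seed, "cnv-db"), {
    n <- 40
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    lim <- ifelse(chrom == "chr1", 600000, 400000)
    start <- floor(stats::runif(n, 0, lim - 30000))
    len <- floor(stats::runif(n, 2000, 60000))
    tibble(chrom = chrom, start = start, end = pmin(start + len, lim),
           cnv_type = sample(c("loss", "gain"), n, replace = TRUE),
           classification = sample(cnv_classifications, n, replace = TRUE),
           frequency = round(stats::runif(n, 0, 0.05), 4),
           source_db = sample(c("clingen_syn", "dgv_syn", "decipher_syn"),
                              n, replace = TRUE),
           record_id = sprintf("rnd%04d", seq_len(n)))
  })
  # the planted worked-case deletion is specified to have no containing
  # established benign region; drop any random record that would create one
  extra <- extra[!(extra$chrom == "chr1" & extra$cnv_type == "loss" &
                     extra$classification == "benign" &
                     extra$start <= 404000 & extra$end >= 455000), ]
  bind_rows(planted, extra)
}

toy_obo_lines <- function() {
  term <- function(id, name, parents = NULL) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      if (!is.null(parents)) paste0("is_a: ", parents), "")
  }
  c("format-version: 1.2", "ontology: toy-phenotype", "",
    term("HP:0000001", "Phenotypic abnormality"),
    term("HP:0000100", "Branch A", "HP:0000001"),
    term("HP:0000200", "Branch B", "HP:0000001"),
    term("HP:0000300", "Branch C", "HP:0000001"),
    term("HP:0000101", "Leaf a1", "HP:0000100"),
    term("HP:0000102", "Leaf a2", "HP:0000100"),
    term("HP:0000103", "Leaf a3", "HP:0000100"),
    term("HP:0000201", "Leaf b1", "HP:0000200"),
    term("HP:0000202", "Leaf b2", "HP:0000200"),
    term("HP:0000203", "Leaf b3", "HP:0000200"),
    term("HP:0000301", "Leaf c1", "HP:0000300"),
    term("HP:0000302", "Leaf c2", "HP:0000300"))
}

toy_annotations <- function() {
  tibble::tribble(
    ~disease_id, ~disease_name, ~inheritance, ~term_id,
    "OMIM:600001", "Syndrome alpha", "AD", "HP:0000101",
    "OMIM:600001", "Syndrome alpha", "AD", "HP:0000102",
    "OMIM:600002", "Syndrome beta",  "AD", "HP:0000101",
    "OMIM:600002", "Syndrome beta",  "AD", "HP:0000201",
    "OMIM:600003", "Syndrome gamma", "AR", "HP:0000202",
    "OMIM:600004", "Syndrome delta", "AR", "HP:0000201",
    "OMIM:600004", "Syndrome delta", "AR", "HP:0000202"
  )
}

toy_variants <- function() {
  v <- function(sv_id, sv_type, chrom1 = NA, pos1 = NA, chrom2 = NA, pos2 = NA,
                span_start = NA, span_end = NA) {
    tibble(sv_id = sv_id, sv_type = sv_type, chrom1 = chrom1,
           pos1 = as.numeric(pos1), chrom2 = chrom2, pos2 = as.numeric(pos2),
           span_start = as.numeric(span_start), span_end = as.numeric(span_end),
           genome_build = "GRCh37", tissue = "hESC")
  }
  # 0-based internal coordinates here (this tibble mirrors read_variants())
  bind_rows(
    v("sv_pe",     "translocation", "chr1", 150000, "chr2", 50000),
    v("sv_ck",     "deletion",      "chr1", NA, NA, NA, 404000, 455000),
    v("sv_path",   "translocation", "chr2", 160000, "chr1", 250000),
    v("sv_inv",    "inversion",     "chr1", 305000, "chr1", 340000),
    v("sv_benign", "translocation", "chr1", 50000, "chr2", 390000),
    v("sv_dup",    "duplication",   "chr2", NA, NA, NA, 300000, 330000),
    v("sv_ins",    "insertion",     "chr2", 105000, "chr1", NA, 405000, 406000),
    v("sv_region", "region",        "chr1", NA, NA, NA, 0, 10000)
  )
}

# ---- independent brute-force truth derivation (plain loops, no package
# lookup paths) ---------------------------------------------------------------

bf_brtad_index <- function(tads, chrom, pos) {
  idx <- NA_integer_
  for (i in seq_len(nrow(tads))) {
    if (tads$chrom[i] == chrom && tads$start[i] <= pos && pos < tads$end[i]) {
      idx <- tads$index[i]
    }
  }
  idx
}

bf_ck_score <- function(genes, cnv_db, span_chrom, span_start, span_end) {
  score <- 0
  ov <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom == span_chrom && g$start < span_end && g$end > span_start) {
      ov[[length(ov) + 1]] <- g
    }
  }
  n_func <- sum(vapply(ov, function(g) g$biotype != "non_functional", TRUE))
  if (n_func == 0) score <- score - 0.60
  hi <- any(vapply(ov, function(g) {
    g$haploinsufficient && ((g$start >= span_start && g$end <= span_end) ||
      (g$start < span_start && span_start < g$end) ||
      (g$start < span_end && span_end < g$end))
  }, TRUE))
  if (hi) score <- score + 1.00
  contained_benign <- FALSE
  best100_benign <- FALSE
  for (i in seq_len(nrow(cnv_db))) {
    r <- cnv_db[i, ]
    if (r$chrom != span_chrom || r$cnv_type != "loss") next
    if (r$classification == "benign" && r$start <= span_start && r$end >= span_end) {
      contained_benign <- TRUE
    }
    if (r$start == span_start && r$end == span_end &&
        r$classification %in% c("benign", "likely_benign")) {
      best100_benign <- TRUE
    }
  }
  if (contained_benign) score <- score - 1.00
  else if (best100_benign) score <- score - 0.90
  n_pc <- sum(vapply(ov, function(g) g$biotype == "protein_coding", TRUE))
  if (n_pc >= 35) score <- score + 0.90 else if (n_pc >= 25) score <- score + 0.45
  round(score, 2)
}

bf_pe_loops <- function(loops, gene_start, gene_end, chrom, pos) {
  total <- 0L; disrupted <- 0L
  for (i in seq_len(nrow(loops))) {
    l <- loops[i, ]
    if (l$chrom != chrom) next
    touches <- (l$start_a < gene_end && l$end_a > gene_start) ||
      (l$start_b < gene_end && l$end_b > gene_start)
    if (!touches) next
    total <- total + 1L
    if (l$end_a <= pos && pos < l$start_b) disrupted <- disrupted + 1L
  }
  c(disrupted = disrupted, total = total)
}

#' Generate the toy annotation universe
#'
#' Writes every file dialect the package reads into `dir`: TADs (6 on
#' chr1, 4 on chr2), chromatin loops, genes with dosage and disease
#' metadata, a regulatory cluster, cytobands, CNV databases, a 12-term
#' ontology with 4 annotated diseases, and a planted variant table.  Two
#' analogues of published worked cases are planted: a deletion spanning
#' five non-dosage-sensitive genes with a 100%-mutual-overlap
#' likely-benign database record (expected automated ACMG score -0.90),
#' and a position-effect gene whose regulatory cluster and 3 of 4
#' chromatin loops straddle a planted breakpoint.  Planted truths are
#' re-derived with independent brute-force code at generation time;
#' generation fails if they disagree.  Regeneration with the same seed
#' is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the randomised filler records.
#' @return The fixture manifest (list), invisibly: per-file record
#'   counts and the planted truths.
#' @export
make_toy_genome <- function(dir, seed = 7L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tads <- toy_tads()
  tads <- tads |> group_by(.data$chrom) |>
    mutate(index = row_number() - 1L) |> ungroup() |>
    mutate(tissue = "hESC", .before = "index")
  genes <- toy_genes(seed)
  loops <- toy_loops()
  clusters <- toy_clusters()
  cyto <- toy_cytobands()
  cnv <- toy_cnv_db(seed)
  ann <- toy_annotations()
  variants <- toy_variants()

  truths <- list(
    brtad_chr1_150k = 1L,
    ck_span = c(404000, 455000),
    ck_score = -0.90,
    ck_class = "likely_benign",
    pe_gene = "G_PE",
    pe_breakpoint = c("chr1", 150000),
    pe_loops = c(disrupted = 3L, total = 4L),
    pe_cluster_disrupted = TRUE
  )
  # validate planted truths with independent brute force before writing
  stopifnot(identical(bf_brtad_index(tads, "chr1", 150000), truths$brtad_chr1_150k))
  stopifnot(isTRUE(all.equal(bf_ck_score(genes, cnv, "chr1", 404000, 455000),
                             truths$ck_score)))
  lp <- bf_pe_loops(loops, 160000, 180000, "chr1", 150000)
  stopifnot(identical(lp, truths$pe_loops))
  el <- clusters[clusters$target_gene == "G_PE", ]
  stopifnot(any(el$element_end <= 150000) && any(el$element_start >= 150000) &&
              min(el$element_start) <= 150000 && 150000 < max(el$element_end))

  write_tads(tads, file.path(dir, "tads.tsv"))
  write_loops(loops, file.path(dir, "loops.tsv"))
  write_genes(genes, file.path(dir, "genes.tsv"))
  write_clusters(clusters, file.path(dir, "clusters.tsv"))
  write_cytobands(cyto, file.path(dir, "cytobands.tsv"))
  write_cnv_db(cnv, file.path(dir, "cnv_db.tsv"))
  writeLines(toy_obo_lines(), file.path(dir, "ontology.obo"))
  write_annotations(ann, file.path(dir, "annotations.tsv"))
  write_variants(variants, file.path(dir, "variants.tsv"))

  manifest <- list(
    seed = as.integer(seed),
    counts = list(tads_chr1 = sum(tads$chrom == "chr1"),
                  tads_chr2 = sum(tads$chrom == "chr2"),
                  genes = nrow(genes), loops = nrow(loops),
                  cluster_elements = nrow(clusters),
                  cytobands = nrow(cyto), cnv_records = nrow(cnv),
                  ontology_terms = 12L, diseases = 4L,
                  variants = nrow(variants)),
    truths = truths
  )
  invisible(manifest)
}

#' Generate a random SV suite with brute-force expected results
#'
#' Emits `variants_random.tsv` (batch-mode dialect) and
#' `expected_random.tsv` carrying, for each SV, the brTAD interval of
#' its first breakpoint derived by an independent linear scan, the best
#' database hit per full scan, and the expected five-level category
#' derived by straight-line application of the classification rules.
#' The first five SVs are fixed archetypes covering all five categories;
#' the rest are random.
#'
#' @param dir Directory already populated by [make_toy_genome()].
#' @param seed Integer seed.
#' @param n_svs Number of SVs (>= 1).
#' @return Invisibly, the expected-result tibble.
#' @export
make_random_suite <- function(dir, seed = 1L, n_svs = 50L) {
  if (n_svs < 1) abort("n_svs must be >= 1")
  tads <- read_tads(file.path(dir, "tads.tsv"), tissue = "hESC")
  lims <- c(chr1 = 600000, chr2 = 400000)

  archetypes <- toy_variants()[c("sv_benign", "sv_path", "sv_inv", "sv_ck",
                                 "sv_pe") |> match(toy_variants()$sv_id), ]
  rows <- with_local_seed(derive_seed(seed, "random-suite"), {
    purrr::map(seq_len(n_svs), function(i) {
      if (i <= nrow(archetypes)) {
        out <- archetypes[i, ]
        out$sv_id <- sprintf("rsv%04d", i)
        return(out)
      }
      type <- sample(c("translocation", "inversion", "deletion",
                       "duplication", "insertion"), 1)
      chrom <- sample(names(lims), 1)
      lim <- lims[[chrom]]
      base <- tibble(sv_id = sprintf("rsv%04d", i), sv_type = type,
                     chrom1 = NA_character_, pos1 = NA_real_,
                     chrom2 = NA_character_, pos2 = NA_real_,
                     span_start = NA_real_, span_end = NA_real_,
                     genome_build = "GRCh37", tissue = "hESC")
      if (type == "translocation") {
        other <- setdiff(names(lims), chrom)
        base$chrom1 <- chrom; base$pos1 <- floor(stats::runif(1, 0, lim))
        base$chrom2 <- other; base$pos2 <- floor(stats::runif(1, 0, lims[[other]]))
      } else if (type == "inversion") {
        ps <- sort(floor(stats::runif(2, 0, lim)))
        if (ps[1] == ps[2]) ps[2] <- ps[2] + 1000
        base$chrom1 <- chrom; base$pos1 <- ps[1]; base$pos2 <- min(ps[2], lim - 1)
      } else if (type %in% c("deletion", "duplication")) {
        len <- floor(stats::runif(1, 2000, 80000))
        s <- floor(stats::runif(1, 0, lim - len))
        base$chrom1 <- chrom; base$span_start <- s; base$span_end <- s + len
      } else {
        base$chrom1 <- chrom; base$pos1 <- floor(stats::runif(1, 0, lim))
        other <- setdiff(names(lims), chrom)
        len <- floor(stats::runif(1, 1000, 5000))
        s <- floor(stats::runif(1, 0, lims[[other]] - len))
        base$chrom2 <- other; base$span_start <- s; base$span_end <- s + len
      }
      base
    })
  })
  variants <- bind_rows(rows)
  genes <- read_genes(file.path(dir, "genes.tsv"))
  loops <- read_loops(file.path(dir, "loops.tsv"), tissue = "hESC")
  clusters <- read_clusters(file.path(dir, "clusters.tsv"))
  cnv <- read_cnv_db(file.path(dir, "cnv_db.tsv"))

  expected <- bind_rows(purrr::map(seq_len(nrow(variants)), function(i) {
    sv <- variants[i, ]
    bp_chrom <- sv$chrom1
    bp_pos <- if (!is.na(sv$pos1)) sv$pos1 else sv$span_start
    ct <- tads[tads$chrom == bp_chrom, ]
    br_s <- NA_real_; br_e <- NA_real_
    for (j in seq_len(nrow(ct))) {
      if (ct$start[j] <= bp_pos && bp_pos < ct$end[j]) {
        br_s <- ct$start[j]; br_e <- ct$end[j]
      }
    }
    best_id <- NA_character_
    if (sv$sv_type %in% c("deletion", "duplication")) {
      type <- if (sv$sv_type == "deletion") "loss" else "gain"
      best_m <- -1; best_cov <- -1
      for (j in seq_len(nrow(cnv))) {
        r <- cnv[j, ]
        if (r$chrom != sv$chrom1 || r$cnv_type != type) next
        ov <- max(0, min(sv$span_end, r$end) - max(sv$span_start, r$start))
        ca <- 100 * ov / (sv$span_end - sv$span_start)
        cb <- 100 * ov / (r$end - r$start)
        m <- min(ca, cb)
        if (m < 70) next
        if (m > best_m || (m == best_m && (cb > best_cov ||
            (cb == best_cov && r$record_id < best_id)))) {
          best_m <- m; best_cov <- cb; best_id <- r$record_id
        }
      }
    }
    tibble(sv_id = sv$sv_id, sv_type = sv$sv_type,
           brtad_chrom = bp_chrom, brtad_start = br_s, brtad_end = br_e,
           best_record_id = best_id,
           category = bf_category(sv, tads, genes, loops, clusters, cnv))
  }))

  write_variants(variants, file.path(dir, "variants_random.tsv"))
  readr::write_tsv(expected, file.path(dir, "expected_random.tsv"), progress = FALSE)
  invisible(expected)
}

# Straight-line expected category (no phenotype input): CNVs via direct
# rubric arithmetic, balanced SVs via direct rule checks on raw coordinates.
bf_category <- function(sv, tads, genes, loops, clusters, cnv) {
  if (sv$sv_type %in% c("deletion", "duplication")) {
    score <- if (sv$sv_type == "deletion") {
      bf_ck_score(genes, cnv, sv$chrom1, sv$span_start, sv$span_end)
    } else {
      bf_gain_score(genes, cnv, sv$chrom1, sv$span_start, sv$span_end)
    }
    h <- round(score * 100)
    return(if (h >= 99) "pathogenic" else if (h >= 90) "likely_pathogenic"
           else if (h >= -89) "vus" else if (h >= -98) "likely_benign"
           else "benign")
  }
  if (sv$sv_type == "region") return("vus")
  bps <- list()
  if (sv$sv_type == "translocation") {
    bps <- list(c(sv$chrom1, sv$pos1), c(sv$chrom2, sv$pos2))
  } else if (sv$sv_type == "inversion") {
    bps <- list(c(sv$chrom1, sv$pos1), c(sv$chrom1, sv$pos2))
  } else {
    bps <- list(c(sv$chrom1, sv$pos1))
    if (!is.na(sv$span_start)) {
      dc <- if (!is.na(sv$chrom2)) sv$chrom2 else sv$chrom1
      bps <- c(bps, list(c(dc, sv$span_start), c(dc, sv$span_end)))
    }
  }
  # gene hits in each brTAD (or gap) of each breakpoint
  hit_rows <- list()
  for (b in bps) {
    chrom <- b[1]; pos <- as.numeric(b[2])
    ct <- tads[tads$chrom == chrom, ]
    ct <- ct[order(ct$start), ]
    rs <- NA; re <- NA
    for (j in seq_len(nrow(ct))) {
      if (ct$start[j] <= pos && pos < ct$end[j]) { rs <- ct$start[j]; re <- ct$end[j] }
    }
    if (is.na(rs)) {  # gap
      prev_end <- suppressWarnings(max(ct$end[ct$end <= pos]))
      nxt_start <- suppressWarnings(min(ct$start[ct$start > pos]))
      rs <- if (is.finite(prev_end)) prev_end else 0
      re <- if (is.finite(nxt_start)) nxt_start else pos + 1
    }
    for (g in seq_len(nrow(genes))) {
      gg <- genes[g, ]
      if (gg$chrom == chrom && gg$start < re && gg$end > rs) {
        hit_rows[[length(hit_rows) + 1]] <-
          mutate(gg, bp_pos = pos, bp_chrom = chrom)
      }
    }
  }
  if (length(hit_rows) == 0) return("benign")
  hits <- bind_rows(hit_rows)
  ad <- grepl(":AD", hits$disorders)
  arln <- grepl(":AR", hits$disorders)
  has_link <- nzchar(hits$disorders)
  ar_only <- has_link & arln & !grepl(":(AD|XL|other)", hits$disorders)
  disrupted <- hits$start < hits$bp_pos & hits$bp_pos < hits$end &
    hits$chrom == hits$bp_chrom
  encompassed <- rep(FALSE, nrow(hits))
  if (sv$sv_type == "inversion") {
    encompassed <- hits$chrom == sv$chrom1 & hits$start >= sv$pos1 &
      hits$end <= sv$pos2
  } else if (sv$sv_type == "insertion" && !is.na(sv$span_start)) {
    dc <- if (!is.na(sv$chrom2)) sv$chrom2 else sv$chrom1
    encompassed <- hits$chrom == dc & hits$start >= sv$span_start &
      hits$end <= sv$span_end
  }
  affected <- disrupted | encompassed
  if (any(affected & ad)) return("pathogenic")
  if (any(affected & !has_link & !is.na(hits$pli) & hits$pli >= 0.9)) {
    return("likely_pathogenic")
  }
  # no phenotype input, so the position-effect arm cannot fire
  if (any(affected) && all(ar_only[affected])) return("likely_benign")
  if (!any(affected) && !any(has_link)) return("benign")
  "vus"
}

bf_gain_score <- function(genes, cnv_db, span_chrom, span_start, span_end) {
  score <- 0
  ov <- genes[genes$chrom == span_chrom & genes$start < span_end &
                genes$end > span_start, ]
  if (sum(ov$biotype != "non_functional") == 0) score <- score - 0.60
  ts <- any(ov$triplosensitive &
              ((ov$start >= span_start & ov$end <= span_end) |
                 (ov$start < span_start & span_start < ov$end) |
                 (ov$start < span_end & span_end < ov$end)))
  if (ts) score <- score + 1.00
  contained_benign <- any(cnv_db$chrom == span_chrom & cnv_db$cnv_type == "gain" &
                            cnv_db$classification == "benign" &
                            cnv_db$start <= span_start & cnv_db$end >= span_end)
  best100 <- any(cnv_db$chrom == span_chrom & cnv_db$cnv_type == "gain" &
                   cnv_db$start == span_start & cnv_db$end == span_end &
                   cnv_db$classification %in% c("benign", "likely_benign"))
  if (contained_benign) score <- score - 1.00 else if (best100) score <- score - 0.90
  n_pc <- sum(ov$biotype == "protein_coding")
  if (n_pc >= 50) score <- score + 0.90 else if (n_pc >= 35) score <- score + 0.45
  round(score, 2)
}
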