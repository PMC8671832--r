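# End-to-end interpretation pipeline: resolve regions, collect elements,
# score phenotype similarity, match CNV databases, score/classify, and
# assemble report rows.

#' Load a directory of annotation files into one bundle
#'
#' Expects the file names emitted by [make_toy_genome()] (`tads.tsv`,
#' `loops.tsv`, `genes.tsv`, `clusters.tsv`, `cytobands.tsv`,
#' `cnv_db.tsv`, `ontology.obo`, `annotations.tsv`); individual paths
#' can be overridden.  Chromosome-name styles must agree across files.
#'
#' @param dir Directory containing the annotation files.
#' @param tissue TAD/loop tissue label.
#' @param tads,loops,genes,clusters,cytobands,cnv_db,obo,annotations
#'   Optional path overrides; `NA` skips an optional file.
#' @return A list bundle consumed by [interpret_sv()].
#' @export
load_annotations <- function(dir, tissue = "hESC",
                             tads = file.path(dir, "tads.tsv"),
                             loops = file.path(dir, "loops.tsv"),
                             genes = file.path(dir, "genes.tsv"),
                             clusters = file.path(dir, "clusters.tsv"),
                             cytobands = file.path(dir, "cytobands.tsv"),
                             cnv_db = file.path(dir, "cnv_db.tsv"),
                             obo = file.path(dir, "ontology.obo"),
                             annotations = file.path(dir, "annotations.tsv")) {
  opt <- function(path, reader, ...) {
    if (length(path) == 1 && (is.na(path) || !file.exists(path))) NULL
    else reader(path, ...)
  }
  bundle <- list(
    tads = read_tads(tads, tissue = tissue),
    loops = opt(loops, read_loops, tissue = tissue),
    genes = read_genes(genes),
    clusters = opt(clusters, read_clusters),
    cytobands = opt(cytobands, read_cytobands),
    cnv_db = opt(cnv_db, read_cnv_db),
    ontology = if (!is.na(obo) && file.exists(obo) &&
                   !is.na(annotations) && file.exists(annotations)) {
      read_ontology(obo, annotations)
    } else NULL,
    tissue = tissue
  )
  check_chrom_styles(bundle$tads$chrom, bundle$genes$chrom,
                     if (!is.null(bundle$loops)) bundle$loops$chrom,
                     if (!is.null(bundle$clusters)) bundle$clusters$chrom,
                     if (!is.null(bundle$cytobands)) bundle$cytobands$chrom,
                     if (!is.null(bundle$cnv_db)) bundle$cnv_db$chrom)
  bundle
}

#' Interpret a single structural variant
#'
#' Runs the full pipeline: region resolution (brTAD + flanks, CNV
#' interior, or explicit region), element collection with disruption
#' flags, optional phenotype-similarity scoring of every disorder linked
#' to a collected gene, CNV database matching and automated ACMG scoring
#' (unbalanced SVs) or rule-engine classification (balanced SVs and
#' insertions), and report-row assembly.
#'
#' @param sv One-row SV tibble from [sv_spec()] / [read_variants()].
#' @param bundle Annotation bundle from [load_annotations()].
#' @param k Flanking TADs per side (0..5).
#' @param phenotype Optional character vector of phenotype term ids.
#' @param overlap_threshold Minimum mutual overlap percentage.
#' @param perm_n Permutation count for p-values.
#' @param seed Seed governing all randomness in the run.
#' @param avg_size Average-TAD-size fallback for chromosomes without
#'   TADs.
#' @param r,alpha,force_phenotype_overlap Rule-engine phenotype
#'   thresholds (see [phenotype_overlap_flag()]).
#' @return List of class `tad_interpretation`: `sv`, `regions`, `hits`,
#'   `similarity`, `overlaps` (detailed hit table), `best_hits`, `acmg`
#'   (for CNVs), `classification` (one-row tibble), `rows` (report
#'   rows).
#' @export
interpret_sv <- function(sv, bundle, k = 0, phenotype = NULL,
                         overlap_threshold = 70, perm_n = 100, seed = 1L,
                         avg_size = NULL, r = 0.5, alpha = 0.05,
                         force_phenotype_overlap = FALSE) {
  validate_sv(sv)
  regions <- regions_for_sv(sv, bundle$tads, k = k, avg_size = avg_size)
  hits <- bind_rows(purrr::map(seq_len(nrow(regions)), function(i) {
    collect_elements(regions[i, ], bundle$genes, bundle$clusters, bundle$loops)
  }))

  similarity <- NULL
  if (!is.null(phenotype) && !is.null(bundle$ontology) && nrow(hits) > 0) {
    links <- gene_disorder_links(hits)
    dis <- intersect(unique(links$disease_id),
                     bundle$ontology$diseases$disease_id)
    if (length(dis) > 0) {
      similarity <- phenosim(bundle$ontology, phenotype, diseases = dis,
                             n = perm_n, seed = seed)
    }
  }

  overlaps <- NULL; bh <- NULL; acmg <- NULL
  is_cnv <- sv$sv_type %in% c("deletion", "duplication")
  if (is_cnv && !is.null(bundle$cnv_db)) {
    type <- if (sv$sv_type == "deletion") "loss" else "gain"
    overlaps <- cnv_overlap_table(sv$chrom1, sv$span_start, sv$span_end, type,
                                  bundle$cnv_db, threshold = overlap_threshold)
    overlaps <- mutate(overlaps, sv_id = sv$sv_id, .before = 1)
    bh <- best_hits(sv$chrom1, sv$span_start, sv$span_end, type,
                    bundle$cnv_db, threshold = overlap_threshold)
  }
  if (is_cnv) {
    acmg <- acmg_score(sv, bundle$genes, bundle$cnv_db,
                       threshold = overlap_threshold)
    classification <- tibble(sv_id = sv$sv_id, category = acmg$acmg_class,
                             triggered_rules = paste(
                               sprintf("%s=%+.2f", acmg$evidence$criterion_id,
                                       acmg$evidence$points), collapse = ";"),
                             phenssc = NA_real_, maxssc = NA_real_,
                             p_value = NA_real_)
  } else if (sv$sv_type == "region") {
    classification <- tibble(sv_id = sv$sv_id, category = "vus",
                             triggered_rules = "region-mode-no-classification",
                             phenssc = NA_real_, maxssc = NA_real_,
                             p_value = NA_real_)
  } else {
    classification <- classify_balanced(sv, hits, similarity, r = r,
                                        alpha = alpha,
                                        force_phenotype_overlap = force_phenotype_overlap)
  }

  rows <- assemble_report_rows(sv, regions, hits, similarity, bh, acmg,
                               classification, bundle)
  structure(list(sv = sv, regions = regions, hits = hits,
                 similarity = similarity, overlaps = overlaps,
                 best_hits = bh, acmg = acmg,
                 classification = classification, rows = rows),
            class = "tad_interpretation")
}

#' @export
print.tad_interpretation <- function(x, ...) {
  cat(sprintf("<tad_interpretation> %s (%s): %s [%s]\n", x$sv$sv_id,
              x$sv$sv_type, x$classification$category,
              x$classification$triggered_rules))
  cat(sprintf("  %d region(s), %d element hit(s)\n", nrow(x$regions), nrow(x$hits)))
  invisible(x)
}

# One report row per (region, element); region-only rows for regions
# without elements so every classified SV yields >= 1 row.
assemble_report_rows <- function(sv, regions, hits, similarity, bh, acmg,
                                 classification, bundle) {
  iscn <- tryCatch(
    if (!is.null(bundle$cytobands)) format_iscn(sv, bundle$cytobands)
    else NA_character_,
    error = function(e) NA_character_)
  len <- if (!is.na(sv$span_start)) sv$span_end - sv$span_start else NA_real_
  base <- tibble(sv_id = sv$sv_id, sv_type = sv$sv_type, iscn = iscn,
                 length_label = if (is.na(len)) NA_character_ else sv_length_label(len),
                 category = classification$category,
                 triggered_rules = classification$triggered_rules,
                 acmg_score = if (!is.null(acmg)) acmg$final_score else NA_real_,
                 acmg_class = if (!is.null(acmg)) acmg$acmg_class else NA_character_)
  best_txt <- if (!is.null(bh) && nrow(bh) > 0) {
    paste(sprintf("%s:%s(%s,%.1f%%)", bh$source_db, bh$record_id,
                  bh$classification, bh$mutual_overlap), collapse = ";")
  } else NA_character_

  sim_for_gene <- function(gid) {
    if (is.null(similarity)) return(NA_character_)
    links <- gene_disorder_links(hits[hits$gene_id == gid, , drop = FALSE])
    s <- similarity[similarity$disease_id %in% links$disease_id, , drop = FALSE]
    if (nrow(s) == 0) return(NA_character_)
    paste(sprintf("%s:PhenSSc=%.2f,MaxSSc=%.2f,p=%.2f", s$disease_id,
                  s$phenssc, s$maxssc, s$p_value), collapse = ";")
  }

  rows <- purrr::map(seq_len(nrow(regions)), function(i) {
    rg <- regions[i, ]
    h <- hits[!is.na(hits$region_start) & hits$region_start == rg$start &
                hits$region_end == rg$end & hits$region_kind == rg$kind &
                (is.na(rg$bp_label) | (!is.na(hits$bp_label) & hits$bp_label == rg$bp_label)), ,
              drop = FALSE]
    url <- ucsc_session_url(rg$chrom, rg$start, rg$end, sv$genome_build)
    reg <- tibble(region_kind = rg$kind, region_offset = rg$offset,
                  region_chrom = rg$chrom,
                  region_start = disp_start(rg$start),
                  region_end = disp_end(rg$end),
                  region_note = rg$note, ucsc_url = url)
    if (nrow(h) == 0) {
      return(dplyr::cross_join(base, mutate(reg,
        gene_id = NA_character_, symbol = NA_character_,
        biotype = NA_character_, pli = NA_real_,
        disrupted_by_breakpoint = NA, loops_disrupted = NA_integer_,
        loops_total = NA_integer_, cluster_disrupted = NA,
        intergenic_breakpoint = NA, similarity = NA_character_,
        best_hit = best_txt)))
    }
    dplyr::cross_join(base, mutate(reg,
      gene_id = list(h$gene_id), symbol = list(h$symbol),
      biotype = list(h$biotype), pli = list(h$pli),
      disrupted_by_breakpoint = list(h$disrupted_by_breakpoint),
      loops_disrupted = list(h$loops_disrupted),
      loops_total = list(h$loops_total),
      cluster_disrupted = list(h$cluster_disrupted),
      intergenic_breakpoint = list(h$intergenic_breakpoint),
      similarity = list(vapply(h$gene_id, sim_for_gene, character(1))),
      best_hit = best_txt)) |>
      tidyr::unnest(cols = c("gene_id", "symbol", "biotype", "pli",
                             "disrupted_by_breakpoint", "loops_disrupted",
                             "loops_total", "cluster_disrupted",
                             "intergenic_breakpoint", "similarity"))
  })
  bind_rows(rows)
}

#' Interpret a batch of structural variants
#'
#' @param variants Variant tibble from [read_variants()].
#' @param bundle Annotation bundle.
#' @param ... Passed to [interpret_sv()].
#' @return List with `rows` (report rows for all SVs), `classifications`
#'   (one row per SV) and `overlaps` (detailed overlap table).
#' @export
interpret_batch <- function(variants, bundle, ...) {
  res <- purrr::map(seq_len(nrow(variants)), function(i) {
    interpret_sv(variants[i, ], bundle, ...)
  })
  list(rows = bind_rows(purrr::map(res, "rows")),
       classifications = bind_rows(purrr::map(res, "classification")),
       overlaps = bind_rows(purrr::map(res, "overlaps")))
}
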