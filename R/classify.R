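# Rule engines: five-level classification of balanced SVs and insertions,
# prefilters for sequencing-derived SV triage, and the three-evaluator
# consensus merge.

#' Phenotype-overlap flag from a similarity triple
#'
#' A disorder "supports" the phenotype when PhenSSc is close to MaxSSc
#' (ratio at least `r`) and the permutation p-value is at most `alpha`.
#' Both thresholds are configurable; with `force = TRUE` the flag is
#' always raised (expert override).
#'
#' @param phenssc,maxssc,p_value Similarity triple (vectorised).
#' @param r Minimum PhenSSc/MaxSSc ratio (default 0.5).
#' @param alpha Maximum p-value (default 0.05).
#' @param force Expert override: treat overlap as significant regardless.
#' @return Logical vector.
#' @export
phenotype_overlap_flag <- function(phenssc, maxssc, p_value, r = 0.5,
                                   alpha = 0.05, force = FALSE) {
  if (force) return(rep(TRUE, length(phenssc)))
  zero <- !is.na(maxssc) & maxssc == 0
  if (any(zero)) warn("maxssc of 0: phenotype-overlap flag set to FALSE")
  out <- !is.na(phenssc) & !is.na(maxssc) & !is.na(p_value) &
    maxssc > 0 & phenssc / maxssc >= r & p_value <= alpha
  out
}

# Per-gene disorder summary used by the rule engine.
gene_rule_facts <- function(hits) {
  links <- gene_disorder_links(hits)
  link_sum <- links |>
    group_by(.data$gene_id) |>
    summarise(has_link = n() > 0,
              ad_link = any(.data$inheritance == "AD"),
              ar_only = all(.data$inheritance == "AR"), .groups = "drop")
  hits |>
    left_join(link_sum, by = "gene_id") |>
    mutate(has_link = !is.na(.data$has_link) & .data$has_link,
           ad_link = !is.na(.data$ad_link) & .data$ad_link,
           ar_only = .data$has_link & !is.na(.data$ar_only) & .data$ar_only)
}

#' Classify a balanced SV or insertion with the five-level rule engine
#'
#' Rules, applied in precedence order (first match wins; clinical
#' conservatism resolves conflicts towards the more severe call):
#'
#' 1. *Pathogenic* — the variant affects (disrupts) or encompasses a gene
#'    linked to an autosomal-dominant disorder.
#' 2. *Likely pathogenic* — an affected gene with pLI >= 0.9 and no
#'    disease association; **or** the position-effect arm: a candidate
#'    gene with an AD disorder link lies in a breakpoint or flanking TAD,
#'    its long-range regulatory interactions are predicted to be impacted
#'    (regulatory cluster severed or at least one chromatin loop broken),
#'    and the proband shows significant phenotype overlap with the
#'    disorder ([phenotype_overlap_flag()]).
#' 3. *Likely benign* — affected genes exist but all are linked only to
#'    autosomal-recessive disorders, with no phenotype support.
#' 4. *Benign* — no gene affected or encompassed and no disorder-linked
#'    element in the disrupted TADs, with no phenotype support.
#' 5. otherwise *VUS*.
#'
#' "Affected or encompassed" means disrupted by a breakpoint, or (when
#' the SV carries a span, e.g. an inversion) lying fully inside it.
#'
#' @param sv One-row SV tibble (translocation, inversion or insertion).
#' @param hits Element-hit tibble from [collect_elements()] over the SV's
#'   resolved regions (bind the per-region results).
#' @param similarity Optional `tad_phenosim` tibble for the proband's
#'   phenotype.
#' @param r,alpha,force_phenotype_overlap Passed to
#'   [phenotype_overlap_flag()].
#' @return One-row tibble `sv_id, category, triggered_rules, phenssc,
#'   maxssc, p_value` (the triple of the best supporting disorder when
#'   phenotype evidence was used, else `NA`).
#' @export
classify_balanced <- function(sv, hits, similarity = NULL, r = 0.5,
                              alpha = 0.05, force_phenotype_overlap = FALSE) {
  validate_sv(sv)
  if (sv$sv_type %in% c("deletion", "duplication")) {
    abort("unbalanced CNVs are scored with the ACMG rubric, not this rule engine")
  }
  out <- function(category, rules, trip = NULL) {
    tibble(sv_id = sv$sv_id, category = category,
           triggered_rules = paste(rules, collapse = ";"),
           phenssc = if (is.null(trip)) NA_real_ else trip$phenssc,
           maxssc = if (is.null(trip)) NA_real_ else trip$maxssc,
           p_value = if (is.null(trip)) NA_real_ else trip$p_value)
  }
  if (nrow(hits) == 0) return(out("benign", "no-genes"))

  facts <- gene_rule_facts(hits)
  has_span <- !is.na(sv$span_start) && !is.na(sv$span_end)
  span_chrom <- if (sv$sv_type == "insertion" && !is.na(sv$chrom2)) {
    sv$chrom2  # donor span lives on the second chromosome
  } else sv$chrom1
  encompassed <- if (has_span) {
    facts$chrom == span_chrom & facts$start >= sv$span_start &
      facts$end <= sv$span_end
  } else if (sv$sv_type == "inversion") {
    facts$chrom == sv$chrom1 & facts$start >= sv$pos1 & facts$end <= sv$pos2
  } else rep(FALSE, nrow(facts))
  affected <- facts$disrupted_by_breakpoint | encompassed

  # Phenotype support per gene: any linked disorder passing the flag.
  pheno_gene <- rep(FALSE, nrow(facts))
  best_trip <- NULL
  if (force_phenotype_overlap) {
    pheno_gene <- rep(TRUE, nrow(facts))
  } else if (!is.null(similarity) && nrow(similarity) > 0) {
    links <- gene_disorder_links(facts)
    sim <- similarity |>
      mutate(flag = phenotype_overlap_flag(.data$phenssc, .data$maxssc,
                                           .data$p_value, r = r, alpha = alpha))
    flagged <- sim$disease_id[sim$flag]
    pheno_gene <- vapply(facts$gene_id, function(g) {
      any(links$disease_id[links$gene_id == g] %in% flagged)
    }, logical(1))
    if (any(pheno_gene)) {
      dd <- links$disease_id[links$gene_id %in% facts$gene_id[pheno_gene]]
      cand <- sim[sim$flag & sim$disease_id %in% dd, , drop = FALSE]
      if (nrow(cand) > 0) best_trip <- cand[1, ]
    }
  }
  any_pheno_support <- any(pheno_gene)

  if (any(affected & facts$ad_link)) {
    return(out("pathogenic", "affected-AD-gene"))
  }
  lp_pli <- affected & !facts$has_link & !is.na(facts$pli) & facts$pli >= 0.9
  in_tad <- facts$region_kind %in% c("brTAD", "flankTAD")
  regulatory_hit <- facts$cluster_disrupted | facts$loops_disrupted >= 1
  lp_pe <- in_tad & facts$ad_link & regulatory_hit & pheno_gene
  if (any(lp_pli) || any(lp_pe)) {
    rules <- c(if (any(lp_pli)) "affected-pli>=0.9-no-disease",
               if (any(lp_pe)) "position-effect-candidate")
    trip <- if (any(lp_pe)) best_trip else NULL
    return(out("likely_pathogenic", rules, trip))
  }
  if (any(affected) && all(facts$ar_only[affected]) && !any_pheno_support) {
    return(out("likely_benign", "affected-AR-only"))
  }
  brtad_linked <- facts$has_link & facts$region_kind == "brTAD"
  if (!any(affected) && !any(brtad_linked) && !any_pheno_support) {
    return(out("benign", "no-affected-genes-no-linked-elements"))
  }
  out("vus", "no-rule-matched")
}

#' Prefilter sequencing-derived SVs for clinical evaluation
#'
#' Keeps an SV when it is larger than 1 kb, is novel or matches database
#' records only at low population frequency (best-hit frequency below
#' `max_freq`), and overlaps or disrupts a loss-of-function-sensitive
#' gene (`oe_lof < oe_cut`) or a gene linked to an autosomal-dominant
#' disorder.
#'
#' @param svs Variant tibble (rows with spans; from [read_variants()]).
#' @param cnv_db Pooled CNV database tibble (may be NULL: all SVs novel).
#' @param genes Gene tibble.
#' @param oe_cut LoF observed/expected cutoff (default 0.35).
#' @param max_freq Maximum database frequency (default 0.01).
#' @param threshold Mutual-overlap threshold for the database match.
#' @return The kept subset of `svs`, with a `prefilter_reason` column for
#'   the excluded rows dropped.
#' @export
prefilter_sequencing_svs <- function(svs, cnv_db = NULL, genes,
                                     oe_cut = 0.35, max_freq = 0.01,
                                     threshold = 70) {
  keep <- vapply(seq_len(nrow(svs)), function(i) {
    sv <- svs[i, ]
    s <- sv$span_start; e <- sv$span_end
    if (is.na(s) || is.na(e)) {
      # balanced SV: use breakpoints for the gene condition, no size filter
      s <- min(sv$pos1, sv$pos2, na.rm = TRUE)
      e <- max(sv$pos1, sv$pos2, na.rm = TRUE) + 1
    } else {
      if (e - s <= 1000) return(FALSE)
      if (!is.null(cnv_db) && sv$sv_type %in% c("deletion", "duplication")) {
        type <- if (sv$sv_type == "deletion") "loss" else "gain"
        bh <- best_hits(sv$chrom1, s, e, type, cnv_db, threshold = threshold)
        if (nrow(bh) > 0 && !all(is.na(bh$frequency)) &&
            max(bh$frequency, na.rm = TRUE) >= max_freq) return(FALSE)
      }
    }
    ov <- genes[genes$chrom == sv$chrom1 & genes$start < e & genes$end > s, ,
                drop = FALSE]
    if (nrow(ov) == 0) return(FALSE)
    lof <- any(!is.na(ov$oe_lof) & ov$oe_lof < oe_cut)
    links <- gene_disorder_links(ov)
    ad <- any(links$inheritance == "AD")
    lof || ad
  }, logical(1))
  svs[keep, , drop = FALSE]
}

#' Merge three evaluators' calls into a consensus classification
#'
#' If at least two of the three calls agree, that call wins; otherwise
#' the median on the ordered five-level scale is taken.
#'
#' @param calls Character vector of exactly three categories from
#'   [sv_categories].
#' @return A single category.
#' @export
consensus_classification <- function(calls) {
  if (length(calls) != 3) abort("exactly three evaluator calls are required")
  if (!all(calls %in% sv_categories)) {
    abort(sprintf("unknown category '%s'", setdiff(calls, sv_categories)[1]))
  }
  tab <- table(calls)
  if (max(tab) >= 2) return(names(tab)[which.max(tab)])
  sv_categories[sort(match(calls, sv_categories))[2]]
}
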