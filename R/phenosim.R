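# Information-content phenotype similarity: per-term IC, pairwise
# most-informative-common-ancestor (MICA) similarity, symmetric best-match
# list similarity, PhenSSc/MaxSSc, and a permutation p-value.

#' Information content of ontology terms
#'
#' `IC(t) = -ln(|ann(t)| / N)` where `ann(t)` is the set of diseases
#' annotated to `t` or any of its descendants and `N` the total number of
#' annotated diseases.  The root, annotating every disease, has IC 0.
#' Terms with more annotated diseases are less specific and score lower.
#'
#' @param ontology A `tad_ontology` from [read_ontology()].
#' @param terms Character vector of term ids.
#' @param strict Error on terms with zero propagated annotations (their IC
#'   is undefined); with `strict = FALSE` they yield `NA`.
#' @return Numeric vector of IC values (natural log).
#' @export
information_content <- function(ontology, terms, strict = TRUE) {
  counts <- vapply(terms, function(t) {
    if (!t %in% ontology$terms) {
      if (strict) abort(sprintf("unknown term '%s'", t)) else return(NA_integer_)
    }
    length(ontology$ann[[t]])
  }, integer(1))
  if (strict && any(counts == 0, na.rm = TRUE)) {
    abort(sprintf("IC undefined for term '%s' (no annotated diseases)",
                  terms[which(counts == 0)[1]]))
  }
  ic <- -log(counts / ontology$n_diseases)
  ic[is.na(counts) | counts == 0] <- NA_real_
  unname(ic)
}

#' Pairwise term similarity (IC of the most informative common ancestor)
#'
#' Both terms count among their own ancestors, so `pairwise_sim(t, t)`
#' equals `IC(t)`, and terms sharing only the root score 0.
#'
#' @inheritParams information_content
#' @param t1,t2 Term ids.
#' @return Non-negative similarity value; symmetric in its arguments.
#' @export
pairwise_sim <- function(ontology, t1, t2) {
  common <- intersect(ontology$ancestors[[t1]], ontology$ancestors[[t2]])
  if (length(common) == 0) return(0)
  max(information_content(ontology, common, strict = FALSE), na.rm = FALSE)
}

# Drop terms with undefined IC (unknown or unannotated), warning once.
scoreable_terms <- function(ontology, terms, what) {
  ok <- vapply(terms, function(t) {
    t %in% ontology$terms && length(ontology$ann[[t]]) > 0
  }, logical(1))
  if (any(!ok)) {
    warn(sprintf("dropping %d %s term(s) with undefined IC: %s",
                 sum(!ok), what, paste(terms[!ok], collapse = ", ")))
  }
  terms[ok]
}

#' Similarity between two term sets (symmetric best-match average)
#'
#' For each term in one set, the best pairwise MICA similarity against the
#' other set is taken; the score is the mean of these maxima, averaged in
#' both directions.  This makes a set's self-similarity equal to the mean
#' IC of its terms.
#'
#' @inheritParams information_content
#' @param a,b Character vectors of term ids (non-empty after dropping
#'   terms with undefined IC).
#' @return Non-negative score; symmetric in `a` and `b`.
#' @export
list_sim <- function(ontology, a, b) {
  a <- scoreable_terms(ontology, unique(a), "query")
  b <- scoreable_terms(ontology, unique(b), "target")
  if (length(a) == 0 || length(b) == 0) {
    abort("list_sim needs non-empty term sets with defined IC on both sides")
  }
  simmat <- outer(seq_along(a), seq_along(b),
                  Vectorize(function(i, j) pairwise_sim(ontology, a[i], b[j])))
  (mean(apply(simmat, 1, max)) + mean(apply(simmat, 2, max))) / 2
}

#' Phenotype similarity score against a disorder (PhenSSc)
#'
#' @inheritParams information_content
#' @param query Character vector of term ids describing the proband.
#' @param disease Disease id known to the ontology, or a character vector
#'   of term ids.
#' @return The list similarity between query and disorder term sets.
#' @export
phenssc <- function(ontology, query, disease) {
  terms <- if (length(disease) == 1 &&
               disease %in% ontology$diseases$disease_id) {
    disease_terms(ontology, disease)
  } else disease
  list_sim(ontology, query, terms)
}

#' Maximum similarity score of a query (MaxSSc)
#'
#' The query compared with itself: the mean IC of the inputted terms, the
#' upper bound any PhenSSc can reach for this query.
#'
#' @inheritParams phenssc
#' @return Mean IC of the scoreable query terms.
#' @export
maxssc <- function(ontology, query) {
  list_sim(ontology, query, query)
}

#' Permutation p-value for a PhenSSc
#'
#' Draws `n` random term sets of the same size as the query (uniformly,
#' without replacement, from the pool of directly disease-annotated
#' terms), scores each against the disorder, and reports the fraction of
#' simulated scores greater than or equal to the observed score.
#' Reported p-values therefore lie on the grid `0, 1/n, ..., 1`.
#'
#' @inheritParams information_content
#' @param query_size Number of terms in the query.
#' @param disease Disease id or term-id vector (as in [phenssc()]).
#' @param observed The observed PhenSSc.
#' @param n Number of permutations (default 100).
#' @param seed Integer seed; the same seed reproduces the same p-value.
#' @return p-value in \[0, 1\].
#' @export
permutation_p <- function(ontology, query_size, disease, observed,
                          n = 100, seed = 1L) {
  terms <- if (length(disease) == 1 &&
               disease %in% ontology$diseases$disease_id) {
    disease_terms(ontology, disease)
  } else disease
  pool <- ontology$direct_terms
  if (query_size < 1) abort("query_size must be >= 1")
  if (length(pool) < query_size) {
    abort(sprintf("annotated-term pool (%d) smaller than query size (%d)",
                  length(pool), query_size))
  }
  sims <- with_local_seed(seed, {
    vapply(seq_len(n), function(i) {
      list_sim(ontology, sample(pool, query_size), terms)
    }, numeric(1))
  })
  # >= with a float guard so arithmetic ties count against significance
  mean(sims >= observed - 1e-9)
}

#' Phenotype similarity of a query against a set of disorders
#'
#' Computes PhenSSc, MaxSSc and the permutation p-value for each disorder.
#' Per-disorder permutation streams are derived deterministically from
#' `(seed, disease_id)`, so the whole table reproduces under one seed.
#'
#' @inheritParams permutation_p
#' @param query Character vector of term ids.
#' @param diseases Disease ids to score; default all diseases known to the
#'   ontology.
#' @return A tibble `disease_id, name, phenssc, maxssc, p_value, n`,
#'   sorted by decreasing PhenSSc, of class `tad_phenosim`.
#' @export
phenosim <- function(ontology, query, diseases = NULL, n = 100, seed = 1L) {
  if (is.null(diseases)) diseases <- ontology$diseases$disease_id
  query <- scoreable_terms(ontology, unique(query), "query")
  if (length(query) == 0) abort("no query terms with defined IC remain")
  mx <- maxssc(ontology, query)
  rows <- purrr::map(diseases, function(d) {
    ph <- phenssc(ontology, query, d)
    p <- permutation_p(ontology, length(query), d, ph, n = n,
                       seed = derive_seed(seed, d))
    tibble(disease_id = d,
           name = ontology$diseases$name[match(d, ontology$diseases$disease_id)],
           phenssc = ph, maxssc = mx, p_value = p, n = as.integer(n))
  })
  out <- arrange(bind_rows(rows), desc(.data$phenssc), .data$disease_id)
  class(out) <- c("tad_phenosim", class(out))
  out
}
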