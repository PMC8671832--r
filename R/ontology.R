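# Phenotype-ontology container: a rooted DAG of terms with disease
# annotations propagated to ancestors, backing the information-content
# similarity scores.

parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NULL, name = NA_character_, is_a = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^name:", ln)) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      cur$is_a <- c(cur$is_a, trimws(sub("^is_a:", "", ln)))
    }
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0) abort(sprintf("%s: no [Term] stanzas found", path))
  if (anyDuplicated(names(terms))) abort(sprintf("%s: duplicate term ids", path))
  terms
}

# Depth-first cycle detection; returns one cycle as a term vector or NULL.
find_cycle <- function(parents) {
  state <- setNames(rep(0L, length(parents)), names(parents))  # 0 new, 1 open, 2 done
  stack <- character()
  cycle <- NULL
  visit <- function(t) {
    if (!is.null(cycle)) return()
    if (state[[t]] == 1L) {
      i <- match(t, stack)
      cycle <<- c(stack[i:length(stack)], t)
      return()
    }
    if (state[[t]] == 2L) return()
    state[[t]] <<- 1L
    stack <<- c(stack, t)
    for (p in parents[[t]]) if (p %in% names(parents)) visit(p)
    stack <<- stack[-length(stack)]
    state[[t]] <<- 2L
  }
  for (t in names(parents)) {
    visit(t)
    if (!is.null(cycle)) return(cycle)
  }
  NULL
}

# Ancestor closure (every term is its own ancestor), memoised bottom-up.
ancestor_closure <- function(parents) {
  anc <- list()
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    res <- t
    for (p in parents[[t]]) res <- union(res, get_anc(p))
    anc[[t]] <<- res
    res
  }
  for (t in names(parents)) get_anc(t)
  anc
}

#' Read a phenotype ontology and its disease annotations
#'
#' Parses a minimal OBO file (`id`, `name`, `is_a` stanzas) and an
#' HPOA-like annotation table (`disease_id, disease_name, inheritance,
#' term_id`, one term per row).  The `is_a` edges must form a DAG with a
#' single root; annotations to unknown terms are an error.  Disease
#' annotations are propagated to all ancestors, so each term carries the
#' set of diseases annotated to it or to any descendant.
#'
#' @param obo_path Path to the OBO file.
#' @param annotations_path Path to the disease-annotation table.
#' @return An object of class `tad_ontology`: a list with `terms`,
#'   `parents`, `ancestors`, `ann` (propagated term -> disease-id sets),
#'   `direct_terms` (terms with a direct annotation), `diseases` (tibble
#'   with a `terms` list-column), `n_diseases`, and `root`.
#' @export
read_ontology <- function(obo_path, annotations_path) {
  stanzas <- parse_obo(obo_path)
  ids <- names(stanzas)
  parents <- lapply(stanzas, function(s) intersect(s$is_a, ids))
  unknown_parent <- unlist(lapply(stanzas, function(s) setdiff(s$is_a, ids)))
  if (length(unknown_parent) > 0) {
    abort(sprintf("%s: is_a reference to unknown term %s", obo_path, unknown_parent[1]))
  }
  cyc <- find_cycle(parents)
  if (!is.null(cyc)) {
    abort(sprintf("%s: is_a edges contain a cycle: %s",
                  obo_path, paste(cyc, collapse = " -> ")))
  }
  roots <- ids[vapply(parents, length, 1L) == 0]
  if (length(roots) != 1) {
    abort(sprintf("%s: ontology must have exactly one root, found %d (%s)",
                  obo_path, length(roots), paste(roots, collapse = ", ")))
  }
  anc <- ancestor_closure(parents)

  adf <- readr::read_tsv(annotations_path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  require_cols(adf, c("disease_id", "disease_name", "inheritance", "term_id"),
               annotations_path)
  unknown <- setdiff(unique(adf$term_id), ids)
  if (length(unknown) > 0) {
    abort(sprintf("%s: annotation to unknown term %s", annotations_path, unknown[1]))
  }

  ann <- setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(adf))) {
    for (t in anc[[adf$term_id[i]]]) ann[[t]] <- union(ann[[t]], adf$disease_id[i])
  }
  diseases <- adf |>
    group_by(.data$disease_id) |>
    summarise(name = .data$disease_name[1],
              inheritance = .data$inheritance[1],
              terms = list(unique(.data$term_id)), .groups = "drop")

  structure(list(
    terms = ids,
    names = setNames(vapply(stanzas, function(s) s$name, ""), ids),
    parents = parents,
    ancestors = anc,
    ann = ann,
    direct_terms = sort(unique(adf$term_id)),
    diseases = diseases,
    n_diseases = nrow(diseases),
    root = roots,
    annotation_rows = adf
  ), class = "tad_ontology")
}

#' @export
print.tad_ontology <- function(x, ...) {
  cat(sprintf("<tad_ontology> %d terms, %d annotated diseases, root %s\n",
              length(x$terms), x$n_diseases, x$root))
  invisible(x)
}

#' Edge list of an ontology
#'
#' @param ontology A `tad_ontology`.
#' @return Tibble `child, parent`, one row per `is_a` edge.
#' @export
ontology_edges <- function(ontology) {
  bind_rows(purrr::imap(ontology$parents, function(ps, child) {
    if (length(ps) == 0) return(NULL)
    tibble(child = child, parent = ps)
  }))
}

#' Term sets of the diseases known to an ontology
#'
#' @param ontology A `tad_ontology`.
#' @param disease_id Disease identifier.
#' @return Character vector of term ids annotated to the disease.
#' @export
disease_terms <- function(ontology, disease_id) {
  i <- match(disease_id, ontology$diseases$disease_id)
  if (is.na(i)) abort(sprintf("unknown disease '%s'", disease_id))
  ontology$diseases$terms[[i]]
}
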