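# Shared fixtures: the toy annotation universe is generated once per test
# run and cached; a larger random ontology backs the property suites.

fixture_dir <- function() {
  d <- file.path(tempdir(), "tadsv-fixtures")
  if (!file.exists(file.path(d, "tads.tsv"))) make_toy_genome(d, seed = 7)
  d
}

.bundle_cache <- new.env(parent = emptyenv())

fixture_bundle <- function() {
  if (is.null(.bundle_cache$bundle)) {
    .bundle_cache$bundle <- load_annotations(fixture_dir())
  }
  .bundle_cache$bundle
}

# Random rooted DAG ontology with annotated diseases, written in the OBO +
# annotation-TSV dialects and read back through the package readers.
random_ontology <- function(seed, n_terms = 200, n_diseases = 50) {
  key <- sprintf("ont_%d_%d_%d", seed, n_terms, n_diseases)
  if (!is.null(.bundle_cache[[key]])) return(.bundle_cache[[key]])
  set.seed(seed)
  ids <- sprintf("HP:%07d", seq_len(n_terms))
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(n_terms)) {
    parents <- if (i == 1) character() else {
      unique(ids[sample(seq_len(i - 1), min(i - 1, sample(1:2, 1)))])
    }
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: term ", i),
               if (length(parents)) paste0("is_a: ", parents), "")
  }
  ann <- do.call(rbind, lapply(seq_len(n_diseases), function(d) {
    terms <- sample(ids[-1], sample(3:8, 1))
    data.frame(disease_id = sprintf("OMIM:%06d", d),
               disease_name = sprintf("disease %d", d),
               inheritance = sample(c("AD", "AR"), 1),
               term_id = terms)
  }))
  obo <- tempfile(fileext = ".obo")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(lines, obo)
  readr::write_tsv(ann, tsv, progress = FALSE)
  .bundle_cache[[key]] <- read_ontology(obo, tsv)
  .bundle_cache[[key]]
}

# Independent linear-scan oracle for brTAD containment.
oracle_brtad <- function(tads, chrom, pos) {
  out <- NULL
  for (i in seq_len(nrow(tads))) {
    if (tads$chrom[i] == chrom && tads$start[i] <= pos && pos < tads$end[i]) {
      out <- tads[i, ]
    }
  }
  out
}
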