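#' Read a gene-to-GO annotation map
#'
#' Two-column tab-separated input (`gene`, `term`), one direct annotation
#' per line.  An optional ontology supplies parent relations for true-path
#' propagation.
#'
#' @param path annotation TSV.
#' @param ontology optional ontology: named list mapping term to character
#'   vector of parents (e.g. from [read_obo()]).
#' @return an `annotation_map`: list with `ann` (named list term → genes)
#'   and `parents` (named list term → parent terms, possibly empty).
#' @export
read_go_annotations <- function(path, ontology = NULL) {
  df <- read.delim(path, header = FALSE, col.names = c("gene", "term"),
                   colClasses = "character")
  annotation_map(df, ontology)
}

#' Build an annotation map from a data frame
#'
#' @param df data frame with columns `gene` and `term`.
#' @param ontology optional named list term → parent terms (must be
#'   acyclic).
#' @rdname read_go_annotations
#' @export
annotation_map <- function(df, ontology = NULL) {
  ann <- lapply(split(df$gene, df$term), unique)
  structure(list(ann = ann,
                 parents = if (is.null(ontology)) list() else ontology),
            class = "annotation_map")
}

#' Minimal OBO ontology reader
#'
#' Parses `[Term]` stanzas of an OBO file, keeping `id`, `name` and `is_a`
#' relations; obsolete terms are skipped.  Other relationship types and
#' header fields are ignored.
#'
#' @param path OBO file.
#' @return named list mapping each term id to the character vector of its
#'   `is_a` parents (terms without parents map to `character(0)`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  parents <- list()
  cur <- NULL
  in_term <- FALSE
  obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete && !cur %in% names(parents))
      parents[[cur]] <<- character(0)
  }
  for (ln in lines) {
    if (ln == "[Term]") { flush(); cur <- NULL; in_term <- TRUE; obsolete <- FALSE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term) next
    if (grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
      if (!cur %in% names(parents)) parents[[cur]] <- character(0)
    } else if (grepl("^is_a:", ln) && !is.null(cur)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      parents[[cur]] <- c(parents[[cur]], p)
    } else if (grepl("^is_obsolete: *true", ln) && !is.null(cur)) {
      parents[[cur]] <- NULL
      obsolete <- TRUE
    }
  }
  parents
}

# Topological order of the parent DAG; errors on cycles.
topo_order <- function(parents) {
  terms <- unique(c(names(parents), unlist(parents, use.names = FALSE)))
  state <- setNames(rep(0L, length(terms)), terms)  # 0 new, 1 open, 2 done
  order <- character(0)
  visit <- function(t) {
    if (state[[t]] == 1L) stopf("ontology parent relation contains a cycle at %s", t)
    if (state[[t]] == 2L) return(invisible())
    state[[t]] <<- 1L
    for (p in parents[[t]]) visit(p)
    state[[t]] <<- 2L
    order <<- c(order, t)
  }
  for (t in terms) visit(t)
  order
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Every gene annotated to a term becomes annotated to all of the term's
#' ancestors.  Idempotent; a cycle in the parent relation is an error.
#'
#' @param map an `annotation_map`.
#' @return the map with propagated annotations.
#' @export
propagate_annotations <- function(map) {
  stopifnot(inherits(map, "annotation_map"))
  parents <- map$parents
  if (!length(parents)) return(map)
  ord <- topo_order(parents)
  ann <- map$ann
  # topo_order emits ancestors first; walk it in reverse so each term's
  # genes reach direct parents before those parents are processed
  for (t in rev(ord)) {
    g <- ann[[t]]
    if (is.null(g)) next
    for (p in parents[[t]]) ann[[p]] <- unique(c(ann[[p]], g))
  }
  map$ann <- ann
  map
}

#' Term-for-term GO overrepresentation test
#'
#' For every term annotating at least one study gene, the hypergeometric
#' upper tail `P(X >= study_count)` with population size `N`, `K` genes of
#' the population annotated to the term and a study of size `n` is
#' computed, then Bonferroni-corrected by the number of tested terms
#' (terms with zero study genes are not tested and do not contribute to
#' the correction factor).
#'
#' @param study character vector of study gene ids (must be a subset of
#'   the population).
#' @param population character vector of population gene ids.
#' @param map an `annotation_map` (propagate first if ontology semantics
#'   are wanted).
#' @param cfg a [pipeline_config()] (`enrich_p_threshold`).
#' @return data frame sorted by `p_raw`: `term`, `study_count`,
#'   `study_size`, `pop_count`, `pop_size`, `p_raw`, `p_adj`,
#'   `significant`.
#' @examples
#' df <- data.frame(gene = paste0("g", 1:5), term = "T")
#' m <- annotation_map(df)
#' term_for_term(paste0("g", c(1, 2, 3, 6, 7)), paste0("g", 1:20), m)$p_raw
#' # 1126/15504
#' @export
term_for_term <- function(study, population, map, cfg = pipeline_config()) {
  stopifnot(inherits(map, "annotation_map"))
  study <- unique(study)
  population <- unique(population)
  if (!all(study %in% population))
    stopf("study set must be a subset of the population")
  N <- length(population)
  n <- length(study)
  rows <- lapply(names(map$ann), function(term) {
    genes <- intersect(map$ann[[term]], population)
    sc <- length(intersect(genes, study))
    if (sc == 0) return(NULL)
    K <- length(genes)
    data.frame(term = term, study_count = sc, study_size = n,
               pop_count = K, pop_size = N,
               p_raw = stats::phyper(sc - 1, K, N - K, n, lower.tail = FALSE))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(term = character(), study_count = integer(),
                      study_size = integer(), pop_count = integer(),
                      pop_size = integer(), p_raw = numeric(),
                      p_adj = numeric(), significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * nrow(out))
  out$significant <- out$p_adj <= cfg$enrich_p_threshold
  out <- out[order(out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
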