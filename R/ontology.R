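# Ontology handling: OBO parsing, true-path annotation propagation,
# hypergeometric term enrichment, and the ancestor/offspring local
# redundancy rule.

#' Construct an ontology DAG
#'
#' @param terms Data frame with columns `id`, `name`, `namespace`.
#' @param edges Data frame with columns `child`, `parent` (is_a edges).
#' @return An object of class `OntologyDAG`: list with `terms`,
#'   `parents` / `children` adjacency (named lists), `roots`, and a
#'   topological order `topo` (parents before children).
#' @export
ontology_dag <- function(terms, edges) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(terms))) abort_config("'terms' needs id and name columns")
  if (is.null(terms$namespace)) terms$namespace <- "biological_process"
  if (anyDuplicated(terms$id)) abort_config("duplicate term ids")
  ids <- terms$id
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$child, edges$parent), ids)
    if (length(unknown)) {
      abort_format("is_a edges reference unknown term(s): ",
                   paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  parents <- lapply(setNames(ids, ids), function(i) character())
  children <- parents
  for (k in seq_len(nrow(edges))) {
    ch <- edges$child[k]; pa <- edges$parent[k]
    parents[[ch]] <- union(parents[[ch]], pa)
    children[[pa]] <- union(children[[pa]], ch)
  }
  # Kahn topological sort; detects cycles and yields a parent-first order
  indeg <- vapply(parents, length, integer(1))
  queue <- sort(ids[indeg == 0L])
  topo <- character(0)
  indeg_work <- indeg
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      indeg_work[ch] <- indeg_work[ch] - 1L
      if (indeg_work[ch] == 0L) queue <- sort(c(queue, ch))
    }
  }
  if (length(topo) != length(ids)) {
    cyc <- setdiff(ids, topo)
    abort_format("cycle detected among term(s): ",
                 paste(utils::head(sort(cyc), 10L), collapse = " -> "))
  }
  roots <- sort(ids[indeg == 0L])
  if (length(roots) == 0L) abort_format("ontology has no root term")
  structure(list(terms = terms, parents = parents, children = children,
                 roots = roots, topo = topo),
            class = "OntologyDAG")
}

#' @export
print.OntologyDAG <- function(x, ...) {
  cat(sprintf("OntologyDAG: %d terms, %d is_a edges, root(s): %s\n",
              nrow(x$terms), sum(vapply(x$parents, length, integer(1))),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' Parse an OBO 1.2 file into an ontology DAG
#'
#' Reads `[Term]` stanzas, honouring `id`, `name`, `namespace`, `is_a`
#' and `is_obsolete`.  Obsolete terms are dropped (together with edges
#' touching them); unrecognised tags are counted and ignored.
#'
#' @param path Path to an OBO file.
#' @return An [ontology_dag()], with attribute `ignored_tags` giving the
#'   count of unrecognised tag lines.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  ignored <- 0L
  flush <- function(cur) {
    if (is.null(cur)) return(invisible())
    if (is.null(cur$id)) {
      abort_format(sprintf("[Term] stanza ending near line %d has no id", cur$line))
    }
    stanzas[[length(stanzas) + 1L]] <<- cur
  }
  for (i in seq_along(lines)) {
    line <- sub("\\s*!.*$", "", trimws(lines[i]))
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush(cur)
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) cur <- list(line = i, is_a = character(), obsolete = FALSE)
      next
    }
    if (!in_term) next
    tag <- sub(":.*$", "", line)
    value <- trimws(sub("^[^:]+:", "", line))
    if (tag == "id") cur$id <- value
    else if (tag == "name") cur$name <- value
    else if (tag == "namespace") cur$namespace <- value
    else if (tag == "is_a") cur$is_a <- c(cur$is_a, trimws(sub("\\s*\\{.*$", "", value)))
    else if (tag == "is_obsolete") cur$obsolete <- tolower(value) == "true"
    else ignored <- ignored + 1L
  }
  flush(cur)
  if (!length(stanzas)) abort_format("no [Term] stanzas found in ", path)
  keep <- !vapply(stanzas, function(s) isTRUE(s$obsolete), logical(1))
  stanzas <- stanzas[keep]
  ids <- vapply(stanzas, `[[`, character(1), "id")
  terms <- data.frame(
    id = ids,
    name = vapply(stanzas, function(s) s$name %||% s$id, character(1)),
    namespace = vapply(stanzas, function(s) s$namespace %||% "biological_process",
                       character(1)),
    stringsAsFactors = FALSE)
  edge_list <- lapply(stanzas, function(s) {
    pa <- intersect(s$is_a, ids)  # edges to obsolete/unknown parents dropped
    if (length(pa)) data.frame(child = s$id, parent = pa, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_list)
  if (is.null(edges)) edges <- data.frame(child = character(), parent = character())
  dag <- ontology_dag(terms, edges)
  attr(dag, "ignored_tags") <- ignored
  dag
}

#' Write an ontology DAG as OBO 1.2
#'
#' @param dag An [ontology_dag()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "OntologyDAG"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i]),
                 if (length(dag$parents[[id]]))
                   paste0("is_a: ", sort(dag$parents[[id]])),
                 ""), con)
  }
  invisible(path)
}

#' Ancestors / descendants of a term
#'
#' `term_ancestors()` walks is_a edges upwards, `term_descendants()`
#' downwards; neither includes the query term itself.
#'
#' @param dag An [ontology_dag()].
#' @param id Term identifier present in `dag`.
#' @return Character vector of term ids (sorted).
#' @export
term_ancestors <- function(dag, id) .reachable(dag, id, "parents")

#' @rdname term_ancestors
#' @export
term_descendants <- function(dag, id) .reachable(dag, id, "children")

.reachable <- function(dag, id, field) {
  stopifnot(inherits(dag, "OntologyDAG"))
  if (!id %in% dag$terms$id) abort_config("term not in ontology: ", id)
  seen <- character(0)
  frontier <- dag[[field]][[id]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag[[field]][frontier], use.names = FALSE)), seen)
  }
  sort(seen)
}

#' Construct an annotation map
#'
#' @param term2genes Named list, term id -> character vector of genes.
#' @param universe Background gene universe (defaults to the union of all
#'   annotated genes).
#' @return An object of class `AnnotationMap`.
#' @export
annotation_map <- function(term2genes, universe = NULL) {
  if (!is.list(term2genes) || is.null(names(term2genes))) {
    abort_config("'term2genes' must be a named list of gene vectors")
  }
  term2genes <- lapply(term2genes, function(g) sort(unique(as.character(g))))
  all_genes <- sort(unique(unlist(term2genes, use.names = FALSE)))
  universe <- if (is.null(universe)) all_genes else sort(unique(as.character(universe)))
  stray <- setdiff(all_genes, universe)
  if (length(stray)) {
    abort_config("annotated gene(s) outside the universe: ",
                 paste(utils::head(stray, 5L), collapse = ", "))
  }
  structure(list(term2genes = term2genes, universe = universe),
            class = "AnnotationMap")
}

#' @export
print.AnnotationMap <- function(x, ...) {
  cat(sprintf("AnnotationMap: %d terms, %d genes in universe\n",
              length(x$term2genes), length(x$universe)))
  invisible(x)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor
#' of that term; enrichment assumes this closure.  The operation is
#' idempotent.
#'
#' @param raw Named list, term id -> genes (direct annotations), or an
#'   `AnnotationMap`.
#' @param dag An [ontology_dag()]; every annotated term must be in it.
#' @param universe Optional background universe passed through to
#'   [annotation_map()].
#' @return An [annotation_map()] whose gene sets are closed under
#'   ancestor propagation.
#' @export
propagate_annotations <- function(raw, dag, universe = NULL) {
  stopifnot(inherits(dag, "OntologyDAG"))
  if (inherits(raw, "AnnotationMap")) {
    if (is.null(universe)) universe <- raw$universe
    raw <- raw$term2genes
  }
  unknown <- setdiff(names(raw), dag$terms$id)
  if (length(unknown)) {
    abort_config("annotated term(s) not in ontology: ",
                 paste(utils::head(unknown, 5L), collapse = ", "))
  }
  sets <- lapply(setNames(dag$terms$id, dag$terms$id), function(i) character())
  for (t in names(raw)) sets[[t]] <- unique(as.character(raw[[t]]))
  # children-first order: reverse of the parent-first topological order
  for (t in rev(dag$topo)) {
    if (!length(sets[[t]])) next
    for (pa in dag$parents[[t]]) sets[[pa]] <- union(sets[[pa]], sets[[t]])
  }
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  annotation_map(sets, universe)
}

#' Hypergeometric enrichment of one term
#'
#' Tests over-representation of `gene_list` in the term's gene set:
#' upper-tail hypergeometric probability of drawing at least the observed
#' number of term genes when `list_size` genes are drawn from the
#' universe.
#'
#' @param gene_list Character vector of query genes (must lie in the
#'   universe of `ann`), or a `DEGeneList`.
#' @param ann An [annotation_map()].
#' @param term Term identifier annotated in `ann`.
#' @return One-row data frame: `term_id`, `hit_count`, `term_size`,
#'   `universe_size`, `list_size`, `p_value`, `testable` (FALSE for an
#'   empty term, with `p_value` NA).
#' @export
term_enrichment <- function(gene_list, ann, term) {
  stopifnot(inherits(ann, "AnnotationMap"))
  genes <- unique(.gene_set(gene_list))
  outside <- setdiff(genes, ann$universe)
  if (length(outside)) {
    abort_domain("query gene(s) outside the universe: ",
                 paste(utils::head(outside, 5L), collapse = ", "))
  }
  term_genes <- ann$term2genes[[term]]
  if (is.null(term_genes)) abort_config("term not annotated: ", term)
  K <- length(term_genes)
  N <- length(ann$universe)
  n <- length(genes)
  k <- length(intersect(genes, term_genes))
  data.frame(term_id = term, hit_count = k, term_size = K,
             universe_size = N, list_size = n,
             p_value = if (K > 0) hypergeometric_tail(k, N, K, n) else NA_real_,
             testable = K > 0, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment; a thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    abort_domain("p-values must be numeric in [0, 1] with no missing values")
  }
  p.adjust(p_values, method = "BH")
}

#' Enrichment scan with ancestor/offspring redundancy pruning
#'
#' Tests every testable term for enrichment with the query list
#' (hypergeometric upper tail), adjusts with Benjamini-Hochberg, and then
#' applies the local redundancy rule: when an ancestor and one or more of
#' its offspring are both significant, the ancestor is kept only if the
#' remaining genes still carry evidence — concretely, the ancestor is
#' re-tested after removing all genes belonging to its significant
#' offspring terms (from the ancestor's gene set, the query list and the
#' universe alike), and retained iff the re-test p-value does not exceed
#' the largest raw p-value that was BH-significant in the original scan.
#' Terms are processed children first, so offspring retention is settled
#' before their ancestors are examined.  Both terms may survive, or only
#' the offspring.
#'
#' @inheritParams term_enrichment
#' @param dag The [ontology_dag()] the annotations live on.
#' @param fdr_threshold BH FDR level in `(0, 1)`; the study default is 0.01.
#' @param min_term_size,max_term_size Term-size bounds for testability.
#' @param terms Optional subset of term ids to scan (used by
#'   [stimulus_functions()]); defaults to all annotated terms.
#' @return Data frame with one row per tested term: `term_id`, `name`,
#'   `hit_count`, `term_size`, `universe_size`, `list_size`, `p_value`,
#'   `fdr`, `significant`, `p_retest` (NA where no re-test was needed)
#'   and `retained`.  `retained` implies `significant`.
#' @export
select_significant_terms <- function(gene_list, ann, dag, fdr_threshold = 0.01,
                                     min_term_size = 5L, max_term_size = 2000L,
                                     terms = NULL) {
  stopifnot(inherits(ann, "AnnotationMap"), inherits(dag, "OntologyDAG"))
  if (fdr_threshold <= 0 || fdr_threshold >= 1) abort_config("'fdr_threshold' must be in (0, 1)")
  genes <- unique(.gene_set(gene_list))
  candidates <- intersect(names(ann$term2genes), dag$terms$id)
  if (!is.null(terms)) candidates <- intersect(candidates, as.character(terms))
  sizes <- vapply(ann$term2genes[candidates], length, integer(1))
  candidates <- candidates[sizes >= min_term_size & sizes <= max_term_size]
  candidates <- sort(candidates)
  if (!length(candidates)) {
    return(data.frame(term_id = character(), name = character(),
                      hit_count = integer(), term_size = integer(),
                      universe_size = integer(), list_size = integer(),
                      p_value = numeric(), fdr = numeric(),
                      significant = logical(), p_retest = numeric(),
                      retained = logical(), stringsAsFactors = FALSE))
  }
  rows <- do.call(rbind, lapply(candidates, function(t)
    term_enrichment(genes, ann, t)))
  rows$fdr <- benjamini_hochberg(rows$p_value)
  rows$significant <- rows$fdr <= fdr_threshold
  rows$p_retest <- NA_real_
  rows$retained <- rows$significant
  sig <- rows$term_id[rows$significant]
  if (length(sig) > 1L) {
    # raw-p cutoff corresponding to the BH decision boundary
    p_cut <- max(rows$p_value[rows$significant])
    # children before parents: reverse topological order restricted to sig
    order_sig <- rev(dag$topo)[rev(dag$topo) %in% sig]
    for (t in order_sig) {
      off_sig <- intersect(term_descendants(dag, t), sig)
      if (!length(off_sig)) next
      drop_genes <- unique(unlist(ann$term2genes[off_sig], use.names = FALSE))
      term_rest <- setdiff(ann$term2genes[[t]], drop_genes)
      list_rest <- setdiff(genes, drop_genes)
      univ_rest <- setdiff(ann$universe, drop_genes)
      k <- length(intersect(list_rest, term_rest))
      i <- match(t, rows$term_id)
      p_new <- if (length(term_rest) == 0L || k == 0L) 1 else
        hypergeometric_tail(k, length(univ_rest), length(term_rest),
                            length(list_rest))
      rows$p_retest[i] <- p_new
      rows$retained[i] <- p_new <= p_cut
    }
  }
  idx <- match(rows$term_id, dag$terms$id)
  rows <- cbind(term_id = rows$term_id, name = dag$terms$name[idx],
                rows[, setdiff(names(rows), "term_id"), drop = FALSE])
  rows$name <- as.character(rows$name)
  rownames(rows) <- NULL
  rows
}

#' Stimulus-response functions enriched with a disease DE list
#'
#' Restricts the redundancy-pruned enrichment scan to the subtree rooted
#' at a designated "response to stimulus" term: only that term and its
#' descendants are tested (and BH-adjusted among themselves).
#'
#' @inheritParams select_significant_terms
#' @param de_list `DEGeneList` or character vector of query genes.
#' @param stimulus_root Term id of the subtree root; must be in `dag`.
#' @return As [select_significant_terms()], restricted to the subtree.
#' @export
stimulus_functions <- function(de_list, ann, dag, fdr_threshold = 0.01,
                               stimulus_root, min_term_size = 5L,
                               max_term_size = 2000L) {
  stopifnot(inherits(dag, "OntologyDAG"))
  if (!stimulus_root %in% dag$terms$id) {
    abort_config("stimulus root not in ontology: ", stimulus_root)
  }
  subtree <- c(stimulus_root, term_descendants(dag, stimulus_root))
  select_significant_terms(de_list, ann, dag, fdr_threshold = fdr_threshold,
                           min_term_size = min_term_size,
                           max_term_size = max_term_size, terms = subtree)
}

#' Export retained terms of an enrichment scan as DOT
#'
#' Writes a Graphviz DOT file of the is_a relationships among the
#' retained terms (plus the ontology root for orientation), one node per
#' term labelled with its name.
#'
#' @param scan Result of [select_significant_terms()].
#' @param dag The [ontology_dag()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dag_dot <- function(scan, dag, path) {
  retained <- scan$term_id[scan$retained]
  lines <- c("digraph retained_terms {", "  rankdir=BT;")
  for (t in retained) {
    i <- match(t, dag$terms$id)
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"];", t, dag$terms$name[i]))
  }
  for (t in retained) {
    anc <- intersect(term_ancestors(dag, t), retained)
    for (a in anc) lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", t, a))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
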