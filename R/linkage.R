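# Transcriptional regulatory linkage: do DE transcription factors in a
# stimulus-response function F1 target disease-consistent DE genes in a
# disease-related function F2 more often than chance?

#' Construct a TF-target network
#'
#' @param edges Data frame with character columns `tf` and `target`.
#'   Duplicate edges are collapsed; self-loops (tf == target) are dropped
#'   with their count recorded in attribute `n_self_loops`.
#' @return An object of class `TFNetwork` wrapping the deduplicated edge
#'   data frame (any extra columns are kept, first value per edge).
#' @export
tf_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("tf", "target") %in% names(edges))) {
    abort_config("'edges' needs 'tf' and 'target' columns")
  }
  edges$tf <- as.character(edges$tf)
  edges$target <- as.character(edges$target)
  self <- edges$tf == edges$target
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  key <- paste(edges$tf, edges$target, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "TFNetwork",
            n_self_loops = n_self)
}

#' @export
print.TFNetwork <- function(x, ...) {
  cat(sprintf("TFNetwork: %d edges, %d TFs, %d targets\n",
              nrow(x$edges), length(unique(x$edges$tf)),
              length(unique(x$edges$target))))
  invisible(x)
}

#' Upper tail of the hypergeometric distribution
#'
#' Exact `P(X >= m)` for `X ~ Hypergeometric(N, M, n)`: drawing `n`
#' objects without replacement from `N` of which `M` are marked.
#' Computed in log space, stable to `N` of order 1e6.
#'
#' @param m Observed marked draws, `0 <= m <= n` and `m <= M`.
#' @param N Population size.
#' @param M Number of marked objects, `M <= N`.
#' @param n Number of draws, `n <= N`.
#' @return `P(X >= m)`.
#' @examples
#' hypergeometric_tail(4, 10, 5, 4)  # choose(5,4)/choose(10,4) = 5/210
#' @export
hypergeometric_tail <- function(m, N, M, n) {
  vals <- c(m = m, N = N, M = M, n = n)
  if (!all(vapply(vals, function(v) is.numeric(v) && length(v) == 1L &&
                    !is.na(v) && v == round(v), logical(1)))) {
    abort_domain("m, N, M, n must be single integers")
  }
  if (m < 0 || n < 0 || N < 0 || M < 0 || m > n || n > N || M > N || m > M) {
    abort_domain(sprintf("invalid hypergeometric bounds: m=%d, N=%d, M=%d, n=%d",
                         m, N, M, n))
  }
  phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Count TF-target pairs between two functions
#'
#' Computes the four margins of the linkage test for a function pair
#' (F1, F2).  Genes shared by F1 and F2 are removed from both sets before
#' counting.  Then `N` is the total number of network edges, `M` the
#' number of edges whose TF and target are both DE in disease A, `n` the
#' number of edges from an F1 TF to an F2 target, and `m` the subset of
#' those `n` edges whose TF is DE in disease A and whose target is a
#' cross-disease direction-consistent DE gene.
#'
#' @param f1_genes,f2_genes Character vectors: gene membership of the two
#'   functions.
#' @param network A [tf_network()].
#' @param de_a `DEGeneList` (or character vector) of disease-A DE genes.
#' @param consistent [classify_cross_disease()] result (or character
#'   vector of direction-consistent genes).
#' @return Named list `N`, `M`, `n`, `m`.
#' @export
count_tf_target_pairs <- function(f1_genes, f2_genes, network, de_a, consistent) {
  stopifnot(inherits(network, "TFNetwork"))
  f1 <- unique(as.character(f1_genes))
  f2 <- unique(as.character(f2_genes))
  if (!length(f1) || !length(f2)) abort_config("'f1_genes' and 'f2_genes' must be nonempty")
  if (!nrow(network$edges)) abort_config("'network' has no edges")
  de <- .gene_set(de_a)
  cons <- if (inherits(consistent, "CrossDiseaseClassification"))
    consistent$consistent$gene else as.character(consistent)
  # consistent genes are DE in both diseases by definition; intersecting
  # guards degenerate inputs and guarantees m <= M
  cons <- intersect(cons, de)
  overlap <- intersect(f1, f2)
  f1 <- setdiff(f1, overlap)
  f2 <- setdiff(f2, overlap)
  E <- network$edges
  tf_de <- E$tf %in% de
  tg_de <- E$target %in% de
  in_pair <- E$tf %in% f1 & E$target %in% f2
  list(N = nrow(E),
       M = sum(tf_de & tg_de),
       n = sum(in_pair),
       m = sum(in_pair & tf_de & E$target %in% cons))
}

#' Scan all function pairs for regulatory linkage
#'
#' Tests every (stimulus function F1) x (disease function F2) pair with
#' at least one F1-TF to F2-target edge, using the hypergeometric upper
#' tail on the margins of [count_tf_target_pairs()], and adjusts across
#' the tested pairs with Benjamini-Hochberg.  Pairs with `n = 0` are
#' reported untestable with `p_value` NA and excluded from the
#' adjustment.
#'
#' @param stimulus_terms,disease_terms Character vectors of term ids
#'   (the F1 and F2 candidates); both nonempty.
#' @param ann [annotation_map()] giving each term's gene set.
#' @param network A [tf_network()].
#' @inheritParams count_tf_target_pairs
#' @param fdr_threshold Level for the `significant` flag; the study
#'   default is 0.10.
#' @return Data frame, one row per pair: `f1`, `f2`, `N`, `M`, `n`, `m`,
#'   `p_value`, `fdr`, `testable`, `significant`; rows ordered by
#'   `(f1, f2)` so results do not depend on input ordering.
#' @export
linkage_scan <- function(stimulus_terms, disease_terms, ann, network, de_a,
                         consistent, fdr_threshold = 0.10) {
  stopifnot(inherits(ann, "AnnotationMap"))
  stimulus_terms <- sort(unique(as.character(stimulus_terms)))
  disease_terms <- sort(unique(as.character(disease_terms)))
  if (!length(stimulus_terms) || !length(disease_terms)) {
    abort_config("term lists must be nonempty")
  }
  missing <- setdiff(c(stimulus_terms, disease_terms), names(ann$term2genes))
  if (length(missing)) {
    abort_config("terms not in annotation map: ",
                 paste(utils::head(missing, 5L), collapse = ", "))
  }
  rows <- list()
  for (f1 in stimulus_terms) {
    for (f2 in disease_terms) {
      cnt <- count_tf_target_pairs(ann$term2genes[[f1]], ann$term2genes[[f2]],
                                   network, de_a, consistent)
      rows[[length(rows) + 1L]] <- data.frame(
        f1 = f1, f2 = f2, N = cnt$N, M = cnt$M, n = cnt$n, m = cnt$m,
        p_value = if (cnt$n >= 1L)
          hypergeometric_tail(cnt$m, cnt$N, cnt$M, cnt$n) else NA_real_,
        testable = cnt$n >= 1L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  if (any(out$testable)) {
    out$fdr[out$testable] <- benjamini_hochberg(out$p_value[out$testable])
  }
  out$significant <- !is.na(out$fdr) & out$fdr <= fdr_threshold
  rownames(out) <- NULL
  out
}

#' Export significant linkage results as DOT
#'
#' Writes a Graphviz DOT file with one edge per significant F1 -> F2
#' pair, edge thickness proportional to `-log10(p)`.
#'
#' @param scan Result of [linkage_scan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_linkage_dot <- function(scan, path) {
  sig <- scan[scan$significant, , drop = FALSE]
  lines <- c("digraph linkage {", "  rankdir=LR;")
  for (i in seq_len(nrow(sig))) {
    w <- -log10(max(sig$p_value[i], 1e-300))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [penwidth=%.2f];",
                              sig$f1[i], sig$f2[i], max(0.5, w)))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a TF-target edge list
#'
#' Two-column tab-separated format with header `tf<TAB>target`.
#'
#' @param path File path.
#' @return `read_tf_network()` returns a [tf_network()];
#'   `write_tf_network()` returns `path` invisibly.
#' @export
read_tf_network <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "target") %in% names(df))) {
    abort_format("TF network file needs 'tf' and 'target' columns: ", path)
  }
  tf_network(df[, c("tf", "target")])
}

#' @rdname read_tf_network
#' @param network A [tf_network()].
#' @export
write_tf_network <- function(network, path) {
  stopifnot(inherits(network, "TFNetwork"))
  write.table(network$edges[, c("tf", "target")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
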