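# Independent oracles (direct mass summation, brute-force walks) and
# small fixture builders shared across the test files.

# Direct log-space summation of the binomial upper tail, independent of
# stats::pbinom.
bf_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}

# Direct summation of the hypergeometric upper tail P(X >= m) for
# drawing n from N with M marked, independent of stats::phyper.
bf_hyper_tail <- function(m, N, M, n) {
  if (m <= 0) return(1)
  hi <- min(n, M)
  if (m > hi) return(0)
  k <- m:hi
  sum(exp(lchoose(M, k) + lchoose(N - M, n - k) - lchoose(N, n)))
}

# Manual Benjamini-Hochberg step-up, independent of stats::p.adjust.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Tiny two-group dataset from explicit per-gene values.
make_dataset <- function(disease, normal, id = "t",
                         genes = sprintf("g%d", seq_len(nrow(disease)))) {
  x <- cbind(disease, normal)
  rownames(x) <- genes
  expression_dataset(x, rep(c("disease", "normal"),
                            c(ncol(disease), ncol(normal))), id)
}

# Fabricate a DEResult with fully controlled calls (the documented
# structure of call_de_genes output).
make_de_result <- function(genes, direction, is_de = rep(TRUE, length(genes)),
                           id = "fake", d = direction * 5, q = ifelse(is_de, 0, 1)) {
  structure(list(dataset_id = id, s0 = 0.1, fdr_threshold = 0.01,
                 table = data.frame(gene = genes, d = d, q = q,
                                    direction = as.integer(direction),
                                    is_de = is_de, stringsAsFactors = FALSE)),
            class = "DEResult")
}

# Fabricate a DEGeneList directly.
make_gene_list <- function(genes, direction, disease_id = "X") {
  structure(list(disease_id = disease_id,
                 table = data.frame(gene = genes,
                                    direction = as.integer(direction),
                                    n_datasets = 1L, datasets = "ds1",
                                    stringsAsFactors = FALSE),
                 excluded = character()),
            class = "DEGeneList")
}

# Two-level fixture for the redundancy rule: universe of 1000 genes,
# parent P with child C.  C holds 50 genes, 40 of them in the query.
# `parent_own_hits` controls whether P has evidence of its own.
prune_fixture <- function(parent_own_hits) {
  universe <- sprintf("g%04d", 1:1000)
  dag <- ontology_dag(
    data.frame(id = c("R", "P", "C"), name = c("root", "parent", "child"),
               namespace = "biological_process"),
    data.frame(child = c("P", "C"), parent = c("R", "P")))
  child_genes <- universe[1:50]
  parent_own <- universe[51:100]
  raw <- list(C = child_genes, P = c(child_genes, parent_own))
  ann <- propagate_annotations(raw, dag, universe = universe)
  query <- c(universe[1:40],                                  # child hits
             if (parent_own_hits > 0) parent_own[seq_len(parent_own_hits)],
             universe[900:949])                               # background noise
  list(ann = ann, dag = dag, query = unique(query))
}

# Minimal chain ontology root -> A -> B.
chain_dag <- function() {
  ontology_dag(
    data.frame(id = c("R", "A", "B"), name = c("root", "mid", "leaf"),
               namespace = "biological_process"),
    data.frame(child = c("A", "B"), parent = c("R", "A")))
}
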