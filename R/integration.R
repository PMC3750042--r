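# Cross-dataset consistency, multi-dataset integration, and two-disease
# direction classification with function-level concordance testing.

#' Upper tail of the binomial distribution
#'
#' Exact one-sided probability `P(X >= k)` for `X ~ Binomial(n, p)`,
#' computed in a numerically stable way for large `n`.  This is the test
#' used throughout for direction-consistency questions: under the null
#' that two direction calls agree by coin flip, `p = 0.5`.
#'
#' @param k Observed success count, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param p Success probability in `(0, 1)`.
#' @return `P(X >= k)` (a single number; may underflow to 0 for extreme
#'   counts, in which case the true value is below ~1e-308).
#' @examples
#' binomial_tail(3, 3, 0.5)      # 0.125
#' binomial_tail(4061, 4121, 0.5) # far below 1e-16
#' @export
binomial_tail <- function(k, n, p) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort_domain("'n' must be a single integer >= 1")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > n || k != round(k)) {
    abort_domain("'k' must be an integer with 0 <= k <= n")
  }
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    abort_domain("'p' must be in (0, 1)")
  }
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

.consistency_report <- function(pair, common_a, common_b) {
  # common_a/common_b: named direction vectors over the same gene set
  genes <- intersect(names(common_a), names(common_b))
  # direction ties (0) cannot occur among DE genes, but guard anyway
  genes <- genes[common_a[genes] != 0L & common_b[genes] != 0L]
  n_common <- length(genes)
  n_consistent <- sum(common_a[genes] == common_b[genes])
  structure(list(
    dataset_pair = pair,
    n_common = n_common,
    n_consistent = n_consistent,
    percent_consistent = if (n_common > 0) 100 * n_consistent / n_common else NA_real_,
    p_value = if (n_common > 0) binomial_tail(n_consistent, n_common, 0.5) else NA_real_,
    undefined = n_common == 0
  ), class = "ConsistencyReport")
}

#' Direction consistency of two DE results for the same disease
#'
#' Restricts to genes called DE in both datasets and asks how often the
#' dysregulation direction agrees.  Under the null of independent
#' direction calls the agreement count is Binomial(n, 0.5); the reported
#' p-value is the one-sided upper tail.
#'
#' @param a,b `DEResult` objects (from [call_de_genes()]) for two datasets
#'   of the same disease, with comparable gene identifiers.
#' @return A `ConsistencyReport`: list with `dataset_pair`, `n_common`,
#'   `n_consistent`, `percent_consistent` (0-100), `p_value`, and an
#'   `undefined` flag set when no gene is DE in both (then the percentage
#'   and p-value are `NA` rather than an error).
#' @export
pairwise_consistency <- function(a, b) {
  stopifnot(inherits(a, "DEResult"), inherits(b, "DEResult"))
  .consistency_report(c(a$dataset_id, b$dataset_id),
                      .de_directions(a), .de_directions(b))
}

#' Direction consistency of two conditions against a shared reference
#'
#' Identical computation to [pairwise_consistency()], exposed as a named
#' entry point for the design where two disease subtypes are each
#' contrasted against the same background group (rather than against
#' normal controls), and their DE calls are compared for direction
#' agreement.
#'
#' @param a_vs_ref,b_vs_ref `DEResult` objects computed against the same
#'   reference group.
#' @return A `ConsistencyReport`; see [pairwise_consistency()].
#' @export
subtype_similarity <- function(a_vs_ref, b_vs_ref) {
  pairwise_consistency(a_vs_ref, b_vs_ref)
}

#' @export
print.ConsistencyReport <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("ConsistencyReport %s vs %s: no common DE genes\n",
                x$dataset_pair[1], x$dataset_pair[2]))
  } else {
    cat(sprintf("ConsistencyReport %s vs %s: %.2f%% (%d/%d), binomial P = %.3g\n",
                x$dataset_pair[1], x$dataset_pair[2], x$percent_consistent,
                x$n_consistent, x$n_common, x$p_value))
  }
  invisible(x)
}

#' Integrate per-dataset DE calls into one list per disease
#'
#' A gene enters the disease list if it was DE in at least one dataset;
#' genes DE in two or more datasets with conflicting directions are
#' excluded.  Surviving genes keep their unanimous direction, with
#' provenance recording the datasets that called them.
#'
#' @param results List of `DEResult` objects for one disease.
#' @param disease_id Single string naming the disease.
#' @return An object of class `DEGeneList`: list with `disease_id`, a
#'   data frame `table` (columns `gene`, `direction`, `n_datasets`,
#'   `datasets`, sorted by gene), and `excluded` (genes dropped for
#'   conflicting directions).
#' @export
integrate_de_lists <- function(results, disease_id) {
  if (length(results) < 1L) abort_config("need at least one DEResult")
  for (r in results) stopifnot(inherits(r, "DEResult"))
  calls <- do.call(rbind, lapply(results, function(r) {
    tab <- r$table[r$table$is_de, c("gene", "direction"), drop = FALSE]
    if (nrow(tab)) tab$dataset <- r$dataset_id
    tab
  }))
  if (is.null(calls) || nrow(calls) == 0L) {
    tab <- data.frame(gene = character(), direction = integer(),
                      n_datasets = integer(), datasets = character(),
                      stringsAsFactors = FALSE)
    return(structure(list(disease_id = disease_id, table = tab,
                          excluded = character()), class = "DEGeneList"))
  }
  calls <- calls[order(calls$gene, calls$dataset), , drop = FALSE]
  by_gene <- split(calls, calls$gene)
  dirs <- vapply(by_gene, function(g) {
    if (length(unique(g$direction)) == 1L) g$direction[1] else NA_integer_
  }, integer(1))
  excluded <- names(dirs)[is.na(dirs)]
  keep <- !is.na(dirs)
  tab <- data.frame(
    gene = names(dirs)[keep],
    direction = unname(dirs[keep]),
    n_datasets = vapply(by_gene[keep], nrow, integer(1), USE.NAMES = FALSE),
    datasets = vapply(by_gene[keep], function(g) paste(g$dataset, collapse = ";"),
                      character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(disease_id = disease_id, table = tab, excluded = sort(excluded)),
            class = "DEGeneList")
}

#' @export
print.DEGeneList <- function(x, ...) {
  cat(sprintf("DEGeneList '%s': %d genes (%d up, %d down), %d excluded for conflicting directions\n",
              x$disease_id, nrow(x$table), sum(x$table$direction > 0),
              sum(x$table$direction < 0), length(x$excluded)))
  invisible(x)
}

# Named direction vector from a DEGeneList or a bare named vector.
.list_directions <- function(x) {
  if (inherits(x, "DEGeneList")) setNames(x$table$direction, x$table$gene)
  else if (is.numeric(x) && !is.null(names(x))) x
  else abort_config("expected a DEGeneList or a named direction vector")
}

# Gene identifiers from a DEGeneList or a character vector.
.gene_set <- function(x) {
  if (inherits(x, "DEGeneList")) x$table$gene
  else if (inherits(x, "CrossDiseaseClassification")) x$consistent$gene
  else as.character(x)
}

#' Classify genes DE in both diseases by direction agreement
#'
#' Partitions the intersection of two integrated DE gene lists into
#' direction-consistent genes (same sign in both diseases) and
#' direction-inconsistent genes (opposite signs), with a one-sided
#' binomial test of the consistent fraction against a null of 0.5.
#'
#' @param list_a,list_b `DEGeneList` objects for the two diseases.
#' @return An object of class `CrossDiseaseClassification`: list with
#'   `disease_a`, `disease_b`, data frames `consistent` (gene, direction)
#'   and `inconsistent` (gene, direction_a, direction_b), `overlap_size`,
#'   `consistent_fraction`, `p_value` and an `undefined` flag for an
#'   empty overlap.
#' @export
classify_cross_disease <- function(list_a, list_b) {
  dir_a <- .list_directions(list_a)
  dir_b <- .list_directions(list_b)
  genes <- sort(intersect(names(dir_a), names(dir_b)))
  agree <- dir_a[genes] == dir_b[genes]
  consistent <- data.frame(gene = genes[agree],
                           direction = unname(dir_a[genes[agree]]),
                           stringsAsFactors = FALSE)
  inconsistent <- data.frame(gene = genes[!agree],
                             direction_a = unname(dir_a[genes[!agree]]),
                             direction_b = unname(dir_b[genes[!agree]]),
                             stringsAsFactors = FALSE)
  n <- length(genes)
  structure(list(
    disease_a = if (inherits(list_a, "DEGeneList")) list_a$disease_id else "A",
    disease_b = if (inherits(list_b, "DEGeneList")) list_b$disease_id else "B",
    consistent = consistent,
    inconsistent = inconsistent,
    overlap_size = n,
    consistent_fraction = if (n > 0) nrow(consistent) / n else NA_real_,
    p_value = if (n > 0) binomial_tail(nrow(consistent), n, 0.5) else NA_real_,
    undefined = n == 0
  ), class = "CrossDiseaseClassification")
}

#' @export
print.CrossDiseaseClassification <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("CrossDiseaseClassification %s vs %s: empty overlap\n",
                x$disease_a, x$disease_b))
  } else {
    cat(sprintf("CrossDiseaseClassification %s vs %s: %d overlap, %.2f%% consistent (P = %.3g)\n",
                x$disease_a, x$disease_b, x$overlap_size,
                100 * x$consistent_fraction, x$p_value))
  }
  invisible(x)
}

#' Per-function direction concordance
#'
#' For each supplied ontology term, restricts the cross-disease overlap
#' genes to those annotated to the term and tests whether the fraction
#' with consistent dysregulation directions exceeds the coin-flip null of
#' 0.5 (one-sided binomial), with Benjamini-Hochberg adjustment across
#' the testable terms.
#'
#' @param cls A [classify_cross_disease()] result.
#' @param ann An [annotation_map()].
#' @param term_ids Terms to test; each must be annotated in `ann`.
#' @param fdr_threshold Level used for the `significant` flag (default 0.05).
#' @return Data frame with one row per term: `term_id`, `n_overlap`,
#'   `n_consistent`, `frequency`, `p_value`, `fdr`, `testable`,
#'   `significant`.  Terms with no overlap genes are flagged untestable
#'   and excluded from the BH adjustment.
#' @export
function_concordance <- function(cls, ann, term_ids, fdr_threshold = 0.05) {
  stopifnot(inherits(cls, "CrossDiseaseClassification"))
  stopifnot(inherits(ann, "AnnotationMap"))
  term_ids <- as.character(term_ids)
  missing <- setdiff(term_ids, names(ann$term2genes))
  if (length(missing)) {
    abort_config("terms not in annotation map: ",
                 paste(utils::head(missing, 5L), collapse = ", "))
  }
  cons <- cls$consistent$gene
  overlap <- c(cons, cls$inconsistent$gene)
  rows <- lapply(term_ids, function(t) {
    genes_t <- intersect(ann$term2genes[[t]], overlap)
    n <- length(genes_t)
    k <- sum(genes_t %in% cons)
    data.frame(term_id = t, n_overlap = n, n_consistent = k,
               frequency = if (n > 0) k / n else NA_real_,
               p_value = if (n > 0) binomial_tail(k, n, 0.5) else NA_real_,
               testable = n > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  if (any(out$testable)) {
    out$fdr[out$testable] <- benjamini_hochberg(out$p_value[out$testable])
  }
  out$significant <- !is.na(out$fdr) & out$fdr <= fdr_threshold
  out
}

#' Collapse probe-level rows to one row per gene
#'
#' Utility for real platform data where several probes map to one gene:
#' keeps, for each gene, the probe with the highest mean expression.
#' Synthetic data is already gene-level, so this is not part of the
#' tested analysis core.
#'
#' @param exprs Numeric matrix, probes in rows.
#' @param probe2gene Named character vector mapping probe id (names) to
#'   gene id.
#' @return Matrix with one row per gene.
#' @export
collapse_probes <- function(exprs, probe2gene) {
  if (is.null(rownames(exprs))) abort_config("'exprs' needs probe row names")
  probes <- intersect(rownames(exprs), names(probe2gene))
  exprs <- exprs[probes, , drop = FALSE]
  genes <- probe2gene[probes]
  means <- rowMeans(exprs)
  keep <- unlist(lapply(split(seq_along(genes), genes), function(i) i[which.max(means[i])]),
                 use.names = FALSE)
  out <- exprs[keep, , drop = FALSE]
  rownames(out) <- genes[keep]
  out[order(rownames(out)), , drop = FALSE]
}

#' Consistency matrix in percent (k/n) form
#'
#' Builds the classical all-pairs consistency matrix for one disease:
#' cells read `"98.54% (4061/4121)"` on the off-diagonal and `"100%
#' (k/k)"` on the diagonal (a dataset compared to itself).
#'
#' @param results List of `DEResult` objects for one disease.
#' @return List with `formatted` (character matrix) and `numeric` (data
#'   frame of the pairwise counts and p-values).
#' @export
consistency_matrix <- function(results) {
  ids <- vapply(results, function(r) r$dataset_id, character(1))
  n <- length(results)
  fmt <- matrix("", n, n, dimnames = list(ids, ids))
  num <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      rep_ij <- pairwise_consistency(results[[i]], results[[j]])
      fmt[i, j] <- if (rep_ij$undefined) "NA (0/0)" else
        sprintf("%.2f%% (%d/%d)", rep_ij$percent_consistent,
                rep_ij$n_consistent, rep_ij$n_common)
      if (i < j) {
        num[[length(num) + 1L]] <- data.frame(
          dataset_a = ids[i], dataset_b = ids[j],
          n_common = rep_ij$n_common, n_consistent = rep_ij$n_consistent,
          percent_consistent = rep_ij$percent_consistent,
          p_value = rep_ij$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  list(formatted = fmt,
       numeric = if (length(num)) do.call(rbind, num) else
         data.frame(dataset_a = character(), dataset_b = character(),
                    n_common = integer(), n_consistent = integer(),
                    percent_consistent = numeric(), p_value = numeric()))
}
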