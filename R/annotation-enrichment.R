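# Category enrichment of direction-reversed genes (immune categories,
# cell-type-specific sets) and binomial alteration-burden tests against
# fixed background rates.

#' Hypergeometric enrichment of a gene set in a category
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and a category gene set within a common universe.
#'
#' @param query,category Character vectors of genes, both subsets of
#'   `universe`.
#' @param universe Nonempty background gene set.
#' @return The enrichment p-value `P(X >= |query & category|)`.
#' @export
category_enrichment <- function(query, category, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) abort_domain("'universe' must be nonempty")
  query <- unique(as.character(query))
  category <- unique(as.character(category))
  stray <- c(setdiff(query, universe), setdiff(category, universe))
  if (length(stray)) {
    abort_domain("gene(s) outside the universe: ",
                 paste(utils::head(stray, 5L), collapse = ", "))
  }
  m <- length(intersect(query, category))
  hypergeometric_tail(m, length(universe), length(category), length(query))
}

#' Enrichment of a query set across a list of categories
#'
#' @inheritParams category_enrichment
#' @param categories Named list of gene sets (e.g. read with [read_gmt()]).
#' @param fdr_threshold Level for the `significant` flag.
#' @return Data frame: `category`, `category_size`, `query_size`,
#'   `overlap`, `p_value`, `fdr`, `significant`.
#' @export
category_enrichment_table <- function(query, categories, universe,
                                      fdr_threshold = 0.05) {
  if (!is.list(categories) || is.null(names(categories))) {
    abort_config("'categories' must be a named list of gene sets")
  }
  if (anyDuplicated(names(categories))) abort_config("category names must be unique")
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(unique(as.character(categories[[nm]])), universe)
    data.frame(category = nm,
               category_size = length(cat_genes),
               query_size = length(unique(query)),
               overlap = length(intersect(query, cat_genes)),
               p_value = category_enrichment(query, cat_genes, universe),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p_value)
  out$significant <- out$fdr <= fdr_threshold
  out
}

.check_alteration_table <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  need <- c("gene", "cohort_size")
  if (!all(need %in% names(table))) {
    abort_config("alteration table needs columns: ", paste(need, collapse = ", "))
  }
  for (col in intersect(c("n_mutated", "n_deleted"), names(table))) {
    if (any(table[[col]] > table$cohort_size)) {
      abort_config("'", col, "' exceeds cohort_size for some gene")
    }
  }
  table
}

#' Binomial test of per-gene mutation burden
#'
#' Converts a per-base, per-sample background mutation rate into a
#' per-gene probability `p_g = 1 - (1 - rate)^length` and tests whether
#' each gene is mutated in more cohort samples than that background
#' predicts (one-sided binomial, BH-adjusted across genes).
#'
#' @param table Data frame with columns `gene`, `n_mutated`,
#'   `cohort_size` and optionally `gene_length` (bases).
#' @param background_rate Per-base, per-sample mutation probability in
#'   `(0, 1)`; the study value is 1.2e-6.
#' @param fdr_threshold Level for the `significant` flag; default 0.01.
#' @param default_gene_length Length used for genes without a
#'   `gene_length`; required if the column is absent.
#' @return `table` with added columns `p_gene` (per-sample probability),
#'   `p_value`, `fdr`, `significant`.
#' @export
mutation_enrichment <- function(table, background_rate = 1.2e-6,
                                fdr_threshold = 0.01,
                                default_gene_length = 1500) {
  table <- .check_alteration_table(table)
  if (!"n_mutated" %in% names(table)) abort_config("missing 'n_mutated' column")
  if (background_rate <= 0 || background_rate >= 1) {
    abort_config("'background_rate' must be in (0, 1)")
  }
  len <- table$gene_length
  if (is.null(len)) {
    if (is.null(default_gene_length)) {
      abort_config("no 'gene_length' column and no 'default_gene_length' given")
    }
    len <- rep(default_gene_length, nrow(table))
  }
  len[is.na(len)] <- default_gene_length
  p_gene <- 1 - (1 - background_rate)^len
  p <- vapply(seq_len(nrow(table)), function(i) {
    binomial_tail(table$n_mutated[i], table$cohort_size[i], p_gene[i])
  }, numeric(1))
  table$p_gene <- p_gene
  table$p_value <- p
  table$fdr <- benjamini_hochberg(p)
  table$significant <- table$fdr <= fdr_threshold
  table
}

#' Binomial test of per-gene copy-number deletion burden
#'
#' The background copy-number alteration rate is treated as a per-gene,
#' per-sample probability directly (no length scaling); each gene's
#' deleted-sample count is tested against it one-sided, BH-adjusted
#' across genes.
#'
#' @param table Data frame with columns `gene`, `n_deleted`, `cohort_size`.
#' @param background_rate Per-gene, per-sample deletion probability in
#'   `(0, 1)`; the study value is 1.2e-2.
#' @inheritParams mutation_enrichment
#' @return `table` with added columns `p_value`, `fdr`, `significant`.
#' @export
cnv_enrichment <- function(table, background_rate = 1.2e-2,
                           fdr_threshold = 0.01) {
  table <- .check_alteration_table(table)
  if (!"n_deleted" %in% names(table)) abort_config("missing 'n_deleted' column")
  if (background_rate <= 0 || background_rate >= 1) {
    abort_config("'background_rate' must be in (0, 1)")
  }
  p <- vapply(seq_len(nrow(table)), function(i) {
    binomial_tail(table$n_deleted[i], table$cohort_size[i], background_rate)
  }, numeric(1))
  table$p_value <- p
  table$fdr <- benjamini_hochberg(p)
  table$significant <- table$fdr <= fdr_threshold
  table
}

#' Four-way direction breakdown of a gene set
#'
#' Tallies, for genes classified by [classify_cross_disease()], the four
#' direction patterns (up/up, down/down, up in A & down in B, down in A &
#' up in B); genes outside the classified overlap are counted as
#' unclassified.
#'
#' @param genes Character vector of genes to tally.
#' @param cls A [classify_cross_disease()] result.
#' @return Named integer vector with elements `up_up`, `down_down`,
#'   `upA_downB`, `downA_upB`, `unclassified`; sums to `length(unique(genes))`.
#' @export
direction_breakdown <- function(genes, cls) {
  stopifnot(inherits(cls, "CrossDiseaseClassification"))
  genes <- unique(as.character(genes))
  cons <- setNames(cls$consistent$direction, cls$consistent$gene)
  inc_a <- setNames(cls$inconsistent$direction_a, cls$inconsistent$gene)
  out <- c(up_up = 0L, down_down = 0L, upA_downB = 0L, downA_upB = 0L,
           unclassified = 0L)
  for (g in genes) {
    if (g %in% names(cons)) {
      if (cons[[g]] > 0) out["up_up"] <- out["up_up"] + 1L
      else out["down_down"] <- out["down_down"] + 1L
    } else if (g %in% names(inc_a)) {
      if (inc_a[[g]] > 0) out["upA_downB"] <- out["upA_downB"] + 1L
      else out["downA_upB"] <- out["downA_upB"] + 1L
    } else {
      out["unclassified"] <- out["unclassified"] + 1L
    }
  }
  out
}
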