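# Per-dataset differential expression: SAM-style moderated t statistic
# with a variance-stabilising fudge factor s0 and permutation-based FDR.

#' Construct an expression dataset
#'
#' Bundles one study's log2-scale expression matrix with its sample group
#' labels.  The matrix is expected to hold preprocessed (e.g. RMA-style)
#' log intensities; missing values are rejected rather than imputed.
#'
#' @param exprs Numeric matrix, genes in rows, samples in columns.
#' @param groups Character vector, one entry per column of `exprs`, each
#'   either `"disease"` or `"normal"`; at least two samples per group.
#' @param dataset_id Single string identifying the dataset.
#' @param gene_ids Unique gene identifiers, one per row; defaults to the
#'   row names of `exprs`.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `dataset_id`, `exprs`, `groups` and `gene_ids`.
#' @examples
#' x <- matrix(rnorm(40), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' ds <- expression_dataset(x, c("disease", "disease", "normal", "normal"), "demo")
#' @export
expression_dataset <- function(exprs, groups, dataset_id,
                               gene_ids = rownames(exprs)) {
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    abort_config("'exprs' must be a numeric matrix (genes x samples)")
  }
  if (anyNA(exprs)) {
    abort_config("'exprs' contains missing values; imputation is not supported")
  }
  if (is.null(gene_ids)) abort_config("'gene_ids' are required (or row names on 'exprs')")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(exprs)) abort_config("'gene_ids' length must match nrow(exprs)")
  if (anyDuplicated(gene_ids)) abort_config("'gene_ids' must be unique")
  groups <- as.character(groups)
  if (length(groups) != ncol(exprs)) abort_config("'groups' length must match ncol(exprs)")
  if (!all(groups %in% c("disease", "normal"))) {
    abort_config("'groups' entries must be 'disease' or 'normal'")
  }
  if (sum(groups == "disease") < 2L || sum(groups == "normal") < 2L) {
    abort_config("each group needs at least 2 samples")
  }
  rownames(exprs) <- gene_ids
  structure(list(dataset_id = as.character(dataset_id), exprs = exprs,
                 groups = groups, gene_ids = gene_ids),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d genes, %d disease vs %d normal samples\n",
              x$dataset_id, nrow(x$exprs),
              sum(x$groups == "disease"), sum(x$groups == "normal")))
  invisible(x)
}

# Per-gene mean difference r and pooled standard error s for a given
# assignment of columns to the disease group.
.sam_parts <- function(X, disease_idx) {
  n <- ncol(X)
  idx_d <- disease_idx
  idx_n <- setdiff(seq_len(n), idx_d)
  n1 <- length(idx_d)
  n2 <- length(idx_n)
  Xd <- X[, idx_d, drop = FALSE]
  Xn <- X[, idx_n, drop = FALSE]
  m1 <- rowMeans(Xd)
  m2 <- rowMeans(Xn)
  ss1 <- rowSums((Xd - m1)^2)
  ss2 <- rowSums((Xn - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(r = m1 - m2, s = s)
}

.d_from_parts <- function(parts, s0, gene_ids = names(parts$r)) {
  denom <- parts$s + s0
  bad <- denom == 0 & parts$r != 0
  if (any(bad)) {
    abort_compute("s + s0 = 0 with nonzero mean difference for gene(s): ",
                  paste(utils::head(gene_ids[bad], 5L), collapse = ", "))
  }
  d <- ifelse(denom == 0, 0, parts$r / denom)
  names(d) <- gene_ids
  d
}

#' SAM moderated t statistic
#'
#' Computes, per gene, `d = (mean_disease - mean_normal) / (s + s0)` where
#' `s` is the pooled gene-specific standard error of the mean difference
#' and `s0` a nonnegative fudge factor that damps the statistic for genes
#' with tiny variance.  Swapping the two group labels negates every `d`.
#'
#' @param dataset An [expression_dataset()].
#' @param s0 Nonnegative fudge factor; see [choose_s0()] for an automatic
#'   choice.  With `s0 = 0` every gene must have positive pooled `s`.
#' @return Named numeric vector of `d` values, one per gene.  Genes whose
#'   values are identical across all samples get `d = 0`.
#' @seealso [choose_s0()], [permutation_fdr()], [call_de_genes()]
#' @export
sam_statistic <- function(dataset, s0) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!is.numeric(s0) || length(s0) != 1L || is.na(s0) || s0 < 0) {
    abort_config("'s0' must be a single nonnegative number")
  }
  parts <- .sam_parts(dataset$exprs, which(dataset$groups == "disease"))
  .d_from_parts(parts, s0, dataset$gene_ids)
}

#' Choose the SAM fudge factor s0
#'
#' Percentile rule: candidate values of `s0` are percentiles of the
#' distribution of pooled standard errors `s`; for each candidate the
#' genes are binned into `s`-quantile windows and the coefficient of
#' variation of the median absolute deviation of `d` across windows is
#' computed.  The candidate minimising that coefficient of variation is
#' returned, making the spread of `d` approximately independent of `s`.
#'
#' @param x An [expression_dataset()], or a list with numeric components
#'   `r` (per-gene mean differences) and `s` (pooled standard errors).
#' @param alphas Candidate percentiles, in `[0, 1]`.
#' @return The selected `s0` (a single nonnegative number).  A value of 0
#'   is never chosen automatically; pass `s0 = 0` to [call_de_genes()]
#'   explicitly if an unmoderated statistic is wanted.
#' @export
choose_s0 <- function(x, alphas = seq(0, 1, by = 0.05)) {
  if (inherits(x, "ExpressionDataset")) {
    parts <- .sam_parts(x$exprs, which(x$groups == "disease"))
  } else if (is.list(x) && all(c("r", "s") %in% names(x))) {
    parts <- x
  } else {
    abort_config("'x' must be an ExpressionDataset or a list with 'r' and 's'")
  }
  G <- length(parts$s)
  if (G < 10L) abort_config("choose_s0 needs at least 10 genes, got ", G)
  s <- parts$s
  r <- parts$r
  cand <- vapply(alphas, function(a) as.numeric(quantile(s, a, names = FALSE)),
                 numeric(1))
  keep <- cand > 0
  if (!any(keep)) {
    abort_compute("all candidate s0 values are zero (every gene has zero pooled s)")
  }
  alphas <- alphas[keep]
  cand <- cand[keep]
  nbins <- max(2L, min(100L, G %/% 10L))
  bin <- cut(rank(s, ties.method = "first"), breaks = nbins, labels = FALSE)
  cv <- vapply(seq_along(cand), function(i) {
    d <- r / (s + cand[i])
    mads <- tapply(abs(d), bin, stats::mad)
    mads <- mads[is.finite(mads)]
    mu <- mean(mads)
    if (mu == 0) 0 else stats::sd(mads) / mu
  }, numeric(1))
  cand[which.min(cv)]
}

# Enumerate or sample assignments of columns to the disease group.
# Returns a list of integer vectors (disease column indices), the first
# being the observed assignment when exhaustive enumeration is used.
.permutation_set <- function(n, n1, n_permutations, seed) {
  n_arrangements <- choose(n, n1)
  if (n_arrangements <= n_permutations) {
    cols <- combn(n, n1)
    lapply(seq_len(ncol(cols)), function(j) cols[, j])
  } else {
    with_seed(seed, {
      lapply(seq_len(n_permutations), function(b) sort(sample.int(n, n1)))
    })
  }
}

#' Permutation-based false discovery rate for SAM statistics
#'
#' Estimates, for each gene, the plug-in FDR of calling every gene with an
#' absolute statistic at least as large: the median over label
#' permutations of the number of permuted `|d|` values exceeding the
#' gene's `|d|`, scaled by `pi0` and divided by the observed exceedance
#' count, clipped to `[0, 1]` and made monotone non-increasing in `|d|`.
#' When the number of distinct group-label arrangements does not exceed
#' `n_permutations` the full arrangement set is enumerated, otherwise
#' `n_permutations` arrangements are sampled with replacement.
#'
#' @inheritParams sam_statistic
#' @param n_permutations Number of label permutations (at least 50 unless
#'   exhaustive enumeration is smaller).
#' @param seed Integer seed for permutation sampling.
#' @param pi0 Assumed proportion of null genes; 1 (conservative) by default.
#' @return Named numeric vector of q-values in `[0, 1]`.
#' @export
permutation_fdr <- function(dataset, s0, n_permutations = 200L, seed = 1L,
                            pi0 = 1) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  n1 <- sum(dataset$groups == "disease")
  n2 <- sum(dataset$groups == "normal")
  if (n1 == 1L && n2 == 1L) abort_config("cannot permute with one sample per group")
  n_permutations <- .check_count(n_permutations, "n_permutations", min = 1L)
  n_arrangements <- choose(n1 + n2, n1)
  if (n_permutations < 50L && n_arrangements > n_permutations) {
    abort_config("'n_permutations' must be >= 50 unless exhaustive enumeration is smaller")
  }
  if (!is.numeric(pi0) || pi0 < 0 || pi0 > 1) abort_config("'pi0' must be in [0, 1]")

  X <- dataset$exprs
  obs_idx <- which(dataset$groups == "disease")
  d_obs <- .d_from_parts(.sam_parts(X, obs_idx), s0, dataset$gene_ids)
  absd <- abs(d_obs)
  sorted_abs <- sort(absd)
  G <- length(absd)
  # observed count of |d| >= |d_g|, ties counted (>=)
  n_below <- findInterval(absd, sorted_abs, left.open = TRUE)
  denom <- G - n_below

  perms <- .permutation_set(n1 + n2, n1, n_permutations, seed)
  counts <- vapply(perms, function(idx) {
    dstar <- abs(.d_from_parts(.sam_parts(X, idx), s0, dataset$gene_ids))
    sstar <- sort(dstar)
    G - findInterval(absd, sstar, left.open = TRUE)
  }, numeric(G))
  num <- apply(counts, 1L, median)

  q <- pmin(1, pmax(0, pi0 * num / denom))
  # enforce monotone non-increasing q in |d| (conservative direction)
  ord <- order(absd, decreasing = TRUE)
  q[ord] <- cummax(q[ord])
  names(q) <- dataset$gene_ids
  q
}

#' Call differentially expressed genes in one dataset
#'
#' Runs the SAM statistic with an automatically chosen (or supplied) `s0`,
#' estimates permutation q-values, and flags genes with `q <= fdr_threshold`.
#' The dysregulation direction is the sign of the disease-minus-normal
#' mean difference; genes with exactly zero mean difference (including
#' genes constant across all samples) are never called DE.
#'
#' @inheritParams permutation_fdr
#' @param fdr_threshold FDR level in `(0, 1]`; the study default is 0.01.
#' @param s0 Either `"auto"` (percentile rule via [choose_s0()]) or a
#'   fixed nonnegative value.
#' @return An object of class `DEResult`: list with `dataset_id`, `s0`,
#'   `fdr_threshold` and a data frame `table` with columns `gene`, `d`,
#'   `q`, `direction` (+1 / -1 / 0) and `is_de`.
#' @examples
#' cfg <- simulation_config(n_genes = 200, samples_per_group = 8, seed = 3)
#' sim <- generate_expression(cfg, "demo")
#' res <- call_de_genes(sim$datasets[[1]], fdr_threshold = 0.01, seed = 1)
#' table(res$table$is_de)
#' @export
call_de_genes <- function(dataset, fdr_threshold = 0.01, seed = 1L,
                          s0 = "auto", n_permutations = 200L, pi0 = 1) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!is.numeric(fdr_threshold) || length(fdr_threshold) != 1L ||
      fdr_threshold <= 0 || fdr_threshold > 1) {
    abort_config("'fdr_threshold' must be in (0, 1]")
  }
  s0_value <- if (identical(s0, "auto")) choose_s0(dataset) else {
    if (!is.numeric(s0) || length(s0) != 1L || s0 < 0) {
      abort_config("'s0' must be \"auto\" or a single nonnegative number")
    }
    as.numeric(s0)
  }
  parts <- .sam_parts(dataset$exprs, which(dataset$groups == "disease"))
  d <- .d_from_parts(parts, s0_value, dataset$gene_ids)
  q <- permutation_fdr(dataset, s0_value, n_permutations = n_permutations,
                       seed = seed, pi0 = pi0)
  direction <- as.integer(sign(parts$r))
  constant <- parts$s == 0 & parts$r == 0
  q[constant] <- 1
  is_de <- q <= fdr_threshold & direction != 0L
  structure(list(
    dataset_id = dataset$dataset_id,
    s0 = s0_value,
    fdr_threshold = fdr_threshold,
    table = data.frame(gene = dataset$gene_ids, d = unname(d), q = unname(q),
                       direction = direction, is_de = unname(is_de),
                       stringsAsFactors = FALSE)
  ), class = "DEResult")
}

#' @export
print.DEResult <- function(x, ...) {
  cat(sprintf("DEResult '%s': %d genes, %d DE at FDR <= %g (s0 = %.4g)\n",
              x$dataset_id, nrow(x$table), sum(x$table$is_de),
              x$fdr_threshold, x$s0))
  invisible(x)
}

# Genes flagged DE, as a named direction vector.
.de_directions <- function(result) {
  stopifnot(inherits(result, "DEResult"))
  tab <- result$table[result$table$is_de, , drop = FALSE]
  setNames(tab$direction, tab$gene)
}

#' Write a DE result table to TSV
#'
#' @param result A `DEResult` from [call_de_genes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(result, path) {
  stopifnot(inherits(result, "DEResult"))
  write.table(result$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
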