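# Plain-text readers/writers for the pipeline's interchange formats:
# expression TSV + sample sheet, GMT gene sets, alteration tables, and
# ground-truth tables.

#' Write / read an expression dataset as TSV
#'
#' The expression file has genes as rows, a first column `gene` and one
#' column per sample; the sample sheet has columns `sample_id` and
#' `group` (`disease` or `normal`).
#'
#' @param dataset An [expression_dataset()].
#' @param expr_path,samples_path File paths for the matrix and the sheet.
#' @return `write_expression_tsv()` returns `expr_path` invisibly;
#'   `read_expression_dataset()` returns an [expression_dataset()].
#' @export
write_expression_tsv <- function(dataset, expr_path, samples_path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  df <- data.frame(gene = dataset$gene_ids, dataset$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = colnames(dataset$exprs),
                      group = dataset$groups, stringsAsFactors = FALSE)
  write.table(sheet, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr_path)
}

#' @rdname write_expression_tsv
#' @param dataset_id Identifier for the loaded dataset.
#' @export
read_expression_dataset <- function(expr_path, samples_path, dataset_id) {
  df <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") abort_format("first column of ", expr_path, " must be 'gene'")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) abort_format("non-numeric expression values in ", expr_path)
  sheet <- read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    abort_format("sample sheet needs 'sample_id' and 'group' columns: ", samples_path)
  }
  missing <- setdiff(colnames(mat), sheet$sample_id)
  if (length(missing)) {
    abort_format("samples missing from sheet: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  groups <- sheet$group[match(colnames(mat), sheet$sample_id)]
  expression_dataset(mat, groups, dataset_id, gene_ids = genes)
}

#' Write / read gene sets in GMT format
#'
#' One line per set: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets Named list of character gene vectors.
#' @param path File path.
#' @param descriptions Optional named character vector of descriptions.
#' @return `write_gmt()` returns `path` invisibly; `read_gmt()` returns a
#'   named list of gene vectors with a `descriptions` attribute.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets))) abort_config("'sets' must be a named list")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) abort_format("GMT line(s) with fewer than 3 fields in ", path)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, character(1), 2L),
                                         names(sets))
  sets
}

#' Write / read a per-gene alteration table
#'
#' Tab-separated with columns `gene`, `n_mutated`, `n_deleted`,
#' `cohort_size` and optionally `gene_length`.
#'
#' @param table Data frame as produced by [generate_alteration_table()].
#' @param path File path.
#' @return `write_alteration_table()` returns `path` invisibly;
#'   `read_alteration_table()` returns the data frame.
#' @export
write_alteration_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alteration_table
#' @export
read_alteration_table <- function(path) {
  .check_alteration_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read a ground-truth table
#'
#' Long-format TSV with columns `gene`, `disease`, `status`.
#'
#' @param truth A `GroundTruth`.
#' @param path File path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns a `GroundTruth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "GroundTruth"))
  long <- do.call(rbind, lapply(truth$diseases, function(d) {
    data.frame(gene = truth$genes, disease = d, status = truth$status[, d],
               stringsAsFactors = FALSE)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "disease", "status") %in% names(long))) {
    abort_format("ground-truth file needs gene, disease, status columns: ", path)
  }
  diseases <- unique(long$disease)
  genes <- unique(long$gene)
  status <- matrix("null", nrow = length(genes), ncol = length(diseases),
                   dimnames = list(genes, diseases))
  for (d in diseases) {
    sub <- long[long$disease == d, , drop = FALSE]
    status[sub$gene, d] <- sub$status
  }
  structure(list(genes = genes, diseases = diseases, status = status,
                 consistent_fraction = NA_real_),
            class = "GroundTruth")
}
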