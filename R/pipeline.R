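# End-to-end orchestration: simulate a study to disk, run every analysis
# stage from files to files, and render a plain-text report.

#' Pipeline configuration
#'
#' Collects the input paths and per-stage parameters of a full run.  The
#' default FDR levels per stage are 1% for DE calling and function
#' enrichment, 5% for function concordance and 10% for regulatory
#' linkage.
#'
#' @param datasets_a,datasets_b Lists of `list(expr =, samples =)` path
#'   pairs, one per dataset, for disease A (the stimulus-driven disease)
#'   and disease B (the disease whose related functions are scanned).
#' @param disease_a,disease_b Disease labels.
#' @param obo Path to the ontology in OBO format.
#' @param annotations Path to term -> gene annotations in GMT format.
#' @param tf_network Path to the TF-target edge list TSV.
#' @param stimulus_root Term id rooting the stimulus-response subtree.
#' @param out_dir Output directory (created if needed).
#' @param categories Optional GMT of gene categories (immune sets etc.).
#' @param alterations Optional per-gene alteration table TSV.
#' @param fdr_de,fdr_functions,fdr_concordance,fdr_linkage,fdr_alteration
#'   Per-stage FDR levels, each in (0, 1).
#' @param s0 SAM fudge-factor policy: `"auto"` or a fixed value.
#' @param n_permutations Permutations per dataset for the DE q-values.
#' @param seed Master seed; every stage derives its stream from it.
#' @param min_term_size,max_term_size Term-size bounds for enrichment.
#' @param mutation_rate,cnv_rate Background alteration rates.
#' @param default_gene_length Fallback length for the mutation model.
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(datasets_a, datasets_b,
                            disease_a = "diseaseA", disease_b = "diseaseB",
                            obo, annotations, tf_network, stimulus_root,
                            out_dir, categories = NULL, alterations = NULL,
                            fdr_de = 0.01, fdr_functions = 0.01,
                            fdr_concordance = 0.05, fdr_linkage = 0.10,
                            fdr_alteration = 0.01,
                            s0 = "auto", n_permutations = 200L, seed = 1L,
                            min_term_size = 5L, max_term_size = 2000L,
                            mutation_rate = 1.2e-6, cnv_rate = 1.2e-2,
                            default_gene_length = 1500) {
  check_sets <- function(x, name) {
    if (!is.list(x) || !length(x)) abort_config("'", name, "' must be a nonempty list")
    for (d in x) {
      if (!all(c("expr", "samples") %in% names(d))) {
        abort_config("each entry of '", name, "' needs 'expr' and 'samples' paths")
      }
      for (p in c(d$expr, d$samples)) {
        if (!file.exists(p)) abort_config("missing input file: ", p)
      }
    }
    x
  }
  for (p in c(obo, annotations, tf_network, categories, alterations)) {
    if (!is.null(p) && !file.exists(p)) abort_config("missing input file: ", p)
  }
  for (f in c("fdr_de", "fdr_functions", "fdr_concordance", "fdr_linkage",
              "fdr_alteration")) {
    v <- get(f)
    if (!is.numeric(v) || v <= 0 || v >= 1) abort_config("'", f, "' must be in (0, 1)")
  }
  structure(list(
    datasets_a = check_sets(datasets_a, "datasets_a"),
    datasets_b = check_sets(datasets_b, "datasets_b"),
    disease_a = disease_a, disease_b = disease_b,
    obo = obo, annotations = annotations, tf_network = tf_network,
    stimulus_root = stimulus_root, out_dir = out_dir,
    categories = categories, alterations = alterations,
    fdr_de = fdr_de, fdr_functions = fdr_functions,
    fdr_concordance = fdr_concordance, fdr_linkage = fdr_linkage,
    fdr_alteration = fdr_alteration,
    s0 = s0, n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    min_term_size = as.integer(min_term_size),
    max_term_size = as.integer(max_term_size),
    mutation_rate = mutation_rate, cnv_rate = cnv_rate,
    default_gene_length = default_gene_length
  ), class = "PipelineConfig")
}

# Flat, deterministic text rendering of a config (for the manifest).
.config_lines <- function(config) {
  flat <- function(x) paste(unlist(x), collapse = ";")
  nm <- sort(names(config))
  vapply(nm, function(k) sprintf("%s: %s", k, flat(config[[k]])), character(1))
}

#' Simulate a complete synthetic study to disk
#'
#' Generates a two-disease ground truth, expression datasets for both
#' diseases, an ontology with planted enriched terms, a TF network with
#' one planted linked function pair (from a planted stimulus-subtree term
#' to a planted disease-side term), gene categories and an alteration
#' table, writes everything under `dir` in the pipeline's plain-text
#' formats, and returns a ready [pipeline_config()] plus the ground
#' truth.
#'
#' @param config A [simulation_config()].
#' @param dir Directory to write inputs into (created if needed).
#' @param diseases Two disease labels.
#' @param linked_extra Number of planted TF-target edges for the linked
#'   function pair (0 disables planting).
#' @return List with `config` (a `PipelineConfig` whose `out_dir` is
#'   `dir/out`), `truth`, `ontology` (the generator output) and
#'   `linked_pair` (the planted F1/F2 term ids, or NULL).
#' @export
simulate_study <- function(config, dir, diseases = c("diseaseA", "diseaseB"),
                           linked_extra = 60L) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_two_disease_truth(config, diseases)
  onto <- generate_ontology(config, truth)

  linked <- NULL
  linked_pair <- NULL
  pl <- onto$planted
  f1_cand <- pl$term_id[pl$planted & pl$in_stimulus_subtree]
  f2_cand <- pl$term_id[pl$planted & !pl$in_stimulus_subtree]
  if (linked_extra > 0L && length(f1_cand) && length(f2_cand)) {
    linked_pair <- c(f1 = f1_cand[1L], f2 = f2_cand[1L])
    linked <- list(f1 = onto$annotations$term2genes[[f1_cand[1L]]],
                   f2 = onto$annotations$term2genes[[f2_cand[1L]]],
                   n_extra = linked_extra)
  }
  network <- generate_tf_network(config, truth, linked = linked)

  paths <- list()
  for (d in diseases) {
    sim <- generate_expression(config, d, truth)
    paths[[d]] <- lapply(seq_along(sim$datasets), function(k) {
      ds <- sim$datasets[[k]]
      expr <- file.path(dir, sprintf("expr_%s.tsv", ds$dataset_id))
      samp <- file.path(dir, sprintf("samples_%s.tsv", ds$dataset_id))
      write_expression_tsv(ds, expr, samp)
      list(expr = expr, samples = samp)
    })
  }
  obo_path <- file.path(dir, "ontology.obo")
  write_obo(onto$dag, obo_path)
  gmt_path <- file.path(dir, "annotations.gmt")
  write_gmt(onto$annotations$term2genes, gmt_path)
  net_path <- file.path(dir, "tf_network.tsv")
  write_tf_network(network, net_path)
  truth_path <- file.path(dir, "ground_truth.tsv")
  write_ground_truth(truth, truth_path)

  # categories: one set concentrated in direction-reversed genes, one in
  # consistent genes, one arbitrary background set (deterministic picks)
  de_a <- truth$status[, 1L] != "null"
  de_b <- truth$status[, 2L] != "null"
  incons <- truth$genes[de_a & de_b & truth$status[, 1L] != truth$status[, 2L]]
  cons <- truth_consistent_genes(truth)
  cats <- list(
    reversed_set = utils::head(incons, 25L),
    consistent_set = utils::head(cons, 25L),
    background_set = utils::head(truth$genes, 25L)
  )
  cats <- cats[vapply(cats, length, integer(1)) > 0L]
  cat_path <- file.path(dir, "categories.gmt")
  write_gmt(cats, cat_path)

  alt_path <- file.path(dir, "alterations.tsv")
  alt <- generate_alteration_table(config, truth$genes,
                                   elevated = utils::head(sort(incons), 10L))
  write_alteration_table(alt, alt_path)

  cfg <- pipeline_config(
    datasets_a = paths[[diseases[1L]]], datasets_b = paths[[diseases[2L]]],
    disease_a = diseases[1L], disease_b = diseases[2L],
    obo = obo_path, annotations = gmt_path, tf_network = net_path,
    stimulus_root = onto$stimulus_root,
    out_dir = file.path(dir, "out"),
    categories = cat_path, alterations = alt_path,
    seed = config$seed)
  list(config = cfg, truth = truth, ontology = onto, linked_pair = linked_pair)
}

.write_tsv <- function(df, path, rownames = FALSE) {
  if (rownames) {
    write.table(df, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Run the full concordance pipeline
#'
#' Executes every stage in dependency order: per-dataset DE calling,
#' within-disease pairwise consistency, per-disease integration,
#' cross-disease classification, disease-related function enrichment
#' (redundancy-pruned), per-function concordance, stimulus-function
#' enrichment, the TF-target linkage scan, and (when configured) category
#' and alteration enrichment.  All stage outputs are written as TSV under
#' `config$out_dir` together with a manifest recording the configuration,
#' a config hash, derived seeds and per-stage row counts.  Reruns with an
#' identical configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's in-memory result and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  incomplete <- file.path(out, "INCOMPLETE")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(name, incomplete)
      abort_compute("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  if (file.exists(incomplete)) file.remove(incomplete)
  counts <- list()

  diseases <- c(config$disease_a, config$disease_b)
  sets <- list(config$datasets_a, config$datasets_b)
  de <- list()
  idx <- 0L
  for (i in 1:2) {
    d <- diseases[i]
    de[[d]] <- stage(paste0("de_", d), lapply(seq_along(sets[[i]]), function(k) {
      ds <- read_expression_dataset(sets[[i]][[k]]$expr, sets[[i]][[k]]$samples,
                                    sprintf("%s_ds%d", d, k))
      res <- call_de_genes(ds, fdr_threshold = config$fdr_de,
                           seed = derive_seed(config$seed, 200L + idx + k),
                           s0 = config$s0,
                           n_permutations = config$n_permutations)
      write_de_result(res, file.path(out, sprintf("de_%s.tsv", res$dataset_id)))
      res
    }))
    idx <- idx + length(sets[[i]])
    counts[[paste0("de_genes_", d)]] <-
      sum(vapply(de[[d]], function(r) sum(r$table$is_de), integer(1)))
  }

  cons_mat <- list()
  for (d in diseases) {
    cons_mat[[d]] <- stage(paste0("consistency_", d), {
      cm <- consistency_matrix(de[[d]])
      .write_tsv(as.data.frame(cm$formatted),
                 file.path(out, sprintf("consistency_matrix_%s.tsv", d)),
                 rownames = TRUE)
      .write_tsv(cm$numeric, file.path(out, sprintf("consistency_pairs_%s.tsv", d)))
      cm
    })
  }

  lists <- list()
  for (i in 1:2) {
    d <- diseases[i]
    lists[[d]] <- stage(paste0("integrate_", d), {
      dl <- integrate_de_lists(de[[d]], d)
      .write_tsv(dl$table, file.path(out, sprintf("de_list_%s.tsv", d)))
      dl
    })
    counts[[paste0("integrated_", d)]] <- nrow(lists[[d]]$table)
  }

  cls <- stage("classify", {
    x <- classify_cross_disease(lists[[config$disease_a]], lists[[config$disease_b]])
    .write_tsv(x$consistent, file.path(out, "consistent_genes.tsv"))
    .write_tsv(x$inconsistent, file.path(out, "inconsistent_genes.tsv"))
    .write_tsv(data.frame(overlap_size = x$overlap_size,
                          consistent_fraction = x$consistent_fraction,
                          p_value = x$p_value),
               file.path(out, "classification_summary.tsv"))
    x
  })
  counts$overlap <- cls$overlap_size

  onto <- stage("ontology", {
    dag <- parse_obo(config$obo)
    raw <- read_gmt(config$annotations)
    universe <- sort(unique(unlist(lapply(unlist(sets, recursive = FALSE),
                                          function(p) {
      as.character(read.delim(p$expr, check.names = FALSE,
                              stringsAsFactors = FALSE)[[1]])
    }))))
    raw <- lapply(raw, function(g) intersect(g, universe))
    raw <- raw[vapply(raw, length, integer(1)) > 0L]
    ann <- propagate_annotations(raw, dag, universe = universe)
    list(dag = dag, ann = ann)
  })

  functions_b <- stage("functions", {
    x <- select_significant_terms(lists[[config$disease_b]], onto$ann, onto$dag,
                                  fdr_threshold = config$fdr_functions,
                                  min_term_size = config$min_term_size,
                                  max_term_size = config$max_term_size)
    .write_tsv(x, file.path(out, sprintf("functions_%s.tsv", config$disease_b)))
    write_dag_dot(x, onto$dag, file.path(out, "functions_dag.dot"))
    x
  })
  counts$functions_retained <- sum(functions_b$retained)

  concord <- stage("concordance", {
    terms <- functions_b$term_id[functions_b$retained]
    x <- if (length(terms)) {
      function_concordance(cls, onto$ann, terms,
                           fdr_threshold = config$fdr_concordance)
    } else {
      data.frame(term_id = character(), n_overlap = integer(),
                 n_consistent = integer(), frequency = numeric(),
                 p_value = numeric(), testable = logical(), fdr = numeric(),
                 significant = logical())
    }
    .write_tsv(x, file.path(out, "concordance.tsv"))
    x
  })

  stim <- stage("stimulus_functions", {
    x <- stimulus_functions(lists[[config$disease_a]], onto$ann, onto$dag,
                            fdr_threshold = config$fdr_functions,
                            stimulus_root = config$stimulus_root,
                            min_term_size = config$min_term_size,
                            max_term_size = config$max_term_size)
    .write_tsv(x, file.path(out, sprintf("stimulus_functions_%s.tsv",
                                         config$disease_a)))
    x
  })
  counts$stimulus_retained <- sum(stim$retained)

  linkage <- stage("linkage", {
    network <- read_tf_network(config$tf_network)
    f1 <- stim$term_id[stim$retained]
    f2 <- functions_b$term_id[functions_b$retained]
    x <- if (length(f1) && length(f2)) {
      linkage_scan(f1, f2, onto$ann, network, lists[[config$disease_a]], cls,
                   fdr_threshold = config$fdr_linkage)
    } else {
      data.frame(f1 = character(), f2 = character(), N = integer(),
                 M = integer(), n = integer(), m = integer(),
                 p_value = numeric(), testable = logical(), fdr = numeric(),
                 significant = logical())
    }
    .write_tsv(x, file.path(out, "linkage.tsv"))
    write_linkage_dot(x, file.path(out, "linkage.dot"))
    x
  })
  counts$linkage_significant <- sum(linkage$significant)

  categories <- NULL
  if (!is.null(config$categories)) {
    categories <- stage("categories", {
      cats <- read_gmt(config$categories)
      query <- intersect(cls$inconsistent$gene, onto$ann$universe)
      cats <- lapply(cats, function(g) intersect(g, onto$ann$universe))
      cats <- cats[vapply(cats, length, integer(1)) > 0L]
      enr <- category_enrichment_table(query, cats, onto$ann$universe)
      bd <- do.call(rbind, lapply(names(cats), function(nm) {
        data.frame(category = nm, t(as.matrix(direction_breakdown(cats[[nm]], cls))),
                   stringsAsFactors = FALSE)
      }))
      .write_tsv(enr, file.path(out, "category_enrichment.tsv"))
      .write_tsv(bd, file.path(out, "category_directions.tsv"))
      list(enrichment = enr, directions = bd)
    })
  }

  alterations <- NULL
  if (!is.null(config$alterations)) {
    alterations <- stage("alterations", {
      tab <- read_alteration_table(config$alterations)
      mut <- mutation_enrichment(tab, background_rate = config$mutation_rate,
                                 fdr_threshold = config$fdr_alteration,
                                 default_gene_length = config$default_gene_length)
      cnv <- cnv_enrichment(tab, background_rate = config$cnv_rate,
                            fdr_threshold = config$fdr_alteration)
      .write_tsv(mut, file.path(out, "mutation_enrichment.tsv"))
      .write_tsv(cnv, file.path(out, "cnv_enrichment.tsv"))
      list(mutation = mut, cnv = cnv)
    })
  }

  stage("manifest", {
    cfg_lines <- .config_lines(config)
    lines <- c(sprintf("concordis_version: %s", as.character(packageVersion("concordis"))),
               sprintf("config_hash: %s", .text_hash(cfg_lines)),
               cfg_lines,
               vapply(sort(names(counts)),
                      function(k) sprintf("rows_%s: %d", k, counts[[k]]),
                      character(1)))
    writeLines(lines, file.path(out, "manifest.txt"))
  })
  make_report(out)

  invisible(list(out_dir = out, de = de, consistency = cons_mat,
                 de_lists = lists, classification = cls,
                 functions = functions_b, concordance = concord,
                 stimulus_functions = stim, linkage = linkage,
                 categories = categories, alterations = alterations))
}

#' Render a plain-text summary report from pipeline outputs
#'
#' Reads the stage TSVs under `out_dir` and writes `report.txt` with the
#' consistency matrices in `percent (k/n)` form, the cross-disease
#' classification summary, the function-concordance table and the
#' significant regulatory links.  Missing stage outputs are listed as
#' absent rather than failing; regeneration is idempotent.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @return The report path, invisibly.
#' @export
make_report <- function(out_dir) {
  lines <- c("concordis pipeline report", "=========================", "")
  mats <- sort(list.files(out_dir, pattern = "^consistency_matrix_.*\\.tsv$"))
  if (length(mats)) {
    for (mfile in mats) {
      d <- sub("^consistency_matrix_(.*)\\.tsv$", "\\1", mfile)
      m <- read.delim(file.path(out_dir, mfile), check.names = FALSE,
                      row.names = 1)
      lines <- c(lines, sprintf("Within-disease consistency: %s", d),
                 paste(c("", colnames(m)), collapse = "\t"),
                 vapply(rownames(m), function(r)
                   paste(c(r, unlist(m[r, ])), collapse = "\t"), character(1)),
                 "")
    }
  } else {
    lines <- c(lines, "[absent] consistency matrices", "")
  }
  cls_file <- file.path(out_dir, "classification_summary.tsv")
  if (file.exists(cls_file)) {
    s <- read.delim(cls_file)
    lines <- c(lines, "Cross-disease classification",
               sprintf("  overlap: %d genes, %.2f%% consistent (binomial P = %.3g)",
                       s$overlap_size, 100 * s$consistent_fraction, s$p_value), "")
  } else {
    lines <- c(lines, "[absent] classification summary", "")
  }
  conc_file <- file.path(out_dir, "concordance.tsv")
  if (file.exists(conc_file)) {
    co <- read.delim(conc_file)
    lines <- c(lines, "Function concordance (consistent frequency per function)")
    if (nrow(co)) {
      lines <- c(lines, vapply(seq_len(nrow(co)), function(i) {
        if (!isTRUE(co$testable[i]) || is.na(co$fdr[i])) {
          sprintf("  %s: untestable (no overlap genes annotated)", co$term_id[i])
        } else {
          sprintf("  %s: %d/%d consistent (%.1f%%), FDR = %.3g%s",
                  co$term_id[i], co$n_consistent[i], co$n_overlap[i],
                  100 * co$frequency[i], co$fdr[i],
                  if (isTRUE(co$significant[i])) " *" else "")
        }
      }, character(1)))
    } else {
      lines <- c(lines, "  no testable functions")
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "[absent] concordance table", "")
  }
  link_file <- file.path(out_dir, "linkage.tsv")
  if (file.exists(link_file)) {
    li <- read.delim(link_file)
    sig <- li[li$significant %in% TRUE, , drop = FALSE]
    lines <- c(lines, "Regulatory linkage (stimulus function -> disease function)")
    if (nrow(sig)) {
      lines <- c(lines, vapply(seq_len(nrow(sig)), function(i)
        sprintf("  %s -> %s: m=%d of n=%d edges, P = %.3g, FDR = %.3g",
                sig$f1[i], sig$f2[i], sig$m[i], sig$n[i], sig$p_value[i],
                sig$fdr[i]), character(1)))
    } else {
      lines <- c(lines, "  no significant links")
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "[absent] linkage table", "")
  }
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
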