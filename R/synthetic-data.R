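# Synthetic study generator: expression datasets with planted DE genes,
# a two-disease ground truth with a controllable direction-agreement
# fraction, an ontology DAG with planted enriched terms, a TF network
# with optional planted function-pair linkage, and alteration tables.
#
# Every generator derives its RNG stream from the config seed plus a
# fixed offset, so component outputs do not depend on call order and the
# same config reproduces every byte.

#' Simulation configuration
#'
#' Defines one synthetic study.  Defaults emulate the data regime of a
#' multi-dataset microarray meta-analysis on the log2 scale: a few
#' datasets per disease with moderate group sizes, a planted DE fraction
#' per disease, an additive log2 group effect against homoscedastic
#' Gaussian noise, and a direction-agreement fraction of 0.7233 among
#' genes DE in both diseases.
#'
#' @param n_genes Number of genes.
#' @param n_datasets_per_disease Datasets generated per disease.
#' @param samples_per_group Samples per group (disease and normal) in
#'   each dataset.
#' @param de_fraction Fraction of genes planted DE per disease.
#' @param effect_size Mean log2 shift magnitude for planted DE genes
#'   (> 0; sign follows the planted direction).
#' @param noise_sd Per-gene residual standard deviation (> 0).
#' @param consistent_fraction Probability that a gene planted DE in both
#'   diseases agrees in direction.
#' @param n_terms Ontology term count (>= 3).
#' @param term_size_range Length-2 integer vector, min/max genes directly
#'   annotated per term.
#' @param n_tfs Number of transcription factors in the synthetic network.
#' @param targets_per_tf_range Length-2 integer vector, min/max targets
#'   per TF.
#' @param seed Integer random seed; identical configs (including the
#'   seed) give bit-identical outputs.
#' @return An object of class `SimulationConfig` (a validated list).
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_datasets_per_disease = 3L,
                              samples_per_group = 20L,
                              de_fraction = 0.2,
                              effect_size = 1.5,
                              noise_sd = 0.5,
                              consistent_fraction = 0.7233,
                              n_terms = 60L,
                              term_size_range = c(10L, 80L),
                              n_tfs = 40L,
                              targets_per_tf_range = c(10L, 40L),
                              seed = 1L) {
  cfg <- list(
    n_genes = .check_count(n_genes, "n_genes"),
    n_datasets_per_disease = .check_count(n_datasets_per_disease, "n_datasets_per_disease"),
    samples_per_group = .check_count(samples_per_group, "samples_per_group", min = 2L),
    de_fraction = .check_prob(de_fraction, "de_fraction"),
    effect_size = if (effect_size == 0) 0 else .check_pos(effect_size, "effect_size"),
    noise_sd = .check_pos(noise_sd, "noise_sd"),
    consistent_fraction = .check_prob(consistent_fraction, "consistent_fraction"),
    n_terms = .check_count(n_terms, "n_terms", min = 3L),
    term_size_range = term_size_range,
    n_tfs = .check_count(n_tfs, "n_tfs"),
    targets_per_tf_range = targets_per_tf_range,
    seed = .check_count(seed, "seed", min = 0L)
  )
  for (fld in c("term_size_range", "targets_per_tf_range")) {
    r <- cfg[[fld]]
    if (length(r) != 2L || !is.numeric(r) || any(r < 1) || r[1] > r[2] ||
        any(r != round(r))) {
      abort_config(sprintf("'%s' must be an increasing pair of positive integers", fld))
    }
    cfg[[fld]] <- as.integer(r)
  }
  if (cfg$term_size_range[2] > cfg$n_genes) {
    abort_config("'term_size_range' exceeds 'n_genes'")
  }
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

.sim_genes <- function(config) sprintf("g%05d", seq_len(config$n_genes))

#' Planted two-disease ground truth
#'
#' Assigns each gene a status (`up`, `down`, `null`) per disease: each
#' disease independently gets exactly `round(n_genes * de_fraction)`
#' planted DE genes, and among genes DE in both diseases the two
#' directions agree with probability `consistent_fraction`.
#'
#' @param config A [simulation_config()].
#' @param diseases Character vector of two disease labels.
#' @return An object of class `GroundTruth`: list with `genes`,
#'   `diseases`, a character `status` matrix (genes x diseases) and the
#'   configured `consistent_fraction`.
#' @export
generate_two_disease_truth <- function(config,
                                       diseases = c("diseaseA", "diseaseB")) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (length(diseases) != 2L || anyDuplicated(diseases)) {
    abort_config("'diseases' must be two distinct labels")
  }
  genes <- .sim_genes(config)
  n_de <- round(config$n_genes * config$de_fraction)
  status <- matrix("null", nrow = config$n_genes, ncol = 2L,
                   dimnames = list(genes, diseases))
  with_seed(derive_seed(config$seed, 11L), {
    de_a <- sort(sample.int(config$n_genes, n_de))
    de_b <- sort(sample.int(config$n_genes, n_de))
    dir_a <- sample(c("up", "down"), n_de, replace = TRUE)
    status[de_a, 1L] <- dir_a
    both <- intersect(de_a, de_b)
    b_only <- setdiff(de_b, de_a)
    if (length(both)) {
      agree <- runif(length(both)) < config$consistent_fraction
      a_dir <- status[both, 1L]
      status[both, 2L] <- ifelse(agree, a_dir,
                                 ifelse(a_dir == "up", "down", "up"))
    }
    if (length(b_only)) {
      status[b_only, 2L] <- sample(c("up", "down"), length(b_only), replace = TRUE)
    }
  })
  structure(list(genes = genes, diseases = diseases, status = status,
                 consistent_fraction = config$consistent_fraction),
            class = "GroundTruth")
}

# Single-disease truth: one column of the two-disease machinery.
.single_disease_truth <- function(config, disease_id) {
  genes <- .sim_genes(config)
  n_de <- round(config$n_genes * config$de_fraction)
  status <- matrix("null", nrow = config$n_genes, ncol = 1L,
                   dimnames = list(genes, disease_id))
  with_seed(derive_seed(config$seed, 11L + .id_offset(disease_id)), {
    de <- sort(sample.int(config$n_genes, n_de))
    status[de, 1L] <- sample(c("up", "down"), n_de, replace = TRUE)
  })
  structure(list(genes = genes, diseases = disease_id, status = status,
                 consistent_fraction = config$consistent_fraction),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d genes, disease(s): %s\n",
              length(x$genes), paste(x$diseases, collapse = ", ")))
  for (d in x$diseases) {
    cat(sprintf("  %s: %d up, %d down, %d null\n", d,
                sum(x$status[, d] == "up"), sum(x$status[, d] == "down"),
                sum(x$status[, d] == "null")))
  }
  invisible(x)
}

#' Planted DE genes of a ground truth
#'
#' @param truth A `GroundTruth`.
#' @param disease_id One of `truth$diseases`.
#' @return Named integer vector of directions (+1 up / -1 down) over the
#'   planted DE genes.
#' @export
truth_de_genes <- function(truth, disease_id) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (!disease_id %in% truth$diseases) abort_config("unknown disease: ", disease_id)
  st <- truth$status[, disease_id]
  de <- st != "null"
  setNames(ifelse(st[de] == "up", 1L, -1L), truth$genes[de])
}

#' Cross-disease consistent genes of a ground truth
#'
#' @param truth A two-disease `GroundTruth`.
#' @return Character vector of genes planted DE in both diseases with
#'   agreeing directions.
#' @export
truth_consistent_genes <- function(truth) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (length(truth$diseases) != 2L) abort_config("need a two-disease GroundTruth")
  a <- truth$status[, 1L]
  b <- truth$status[, 2L]
  truth$genes[a != "null" & b != "null" & a == b]
}

#' Generate expression datasets for one disease
#'
#' Produces `n_datasets_per_disease` datasets sharing one planted DE gene
#' set: per-gene baselines are drawn once on the log2 scale (normal with
#' mean 7, sd 1.5, the typical range of RMA-processed intensities) and
#' shared across the disease's datasets; planted genes shift the disease
#' group mean by `effect_size` with the planted sign; noise is Gaussian
#' with sd `noise_sd`, independent per dataset.
#'
#' @param config A [simulation_config()].
#' @param disease_id Disease label.
#' @param truth Optional `GroundTruth` containing `disease_id` (e.g. from
#'   [generate_two_disease_truth()]); if missing, a single-disease truth
#'   is generated from the config seed.
#' @return List with `datasets` (list of [expression_dataset()]) and
#'   `truth`.
#' @export
generate_expression <- function(config, disease_id, truth = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(truth)) truth <- .single_disease_truth(config, disease_id)
  stopifnot(inherits(truth, "GroundTruth"))
  if (!disease_id %in% truth$diseases) {
    abort_config("'truth' does not contain disease: ", disease_id)
  }
  genes <- truth$genes
  G <- length(genes)
  st <- truth$status[, disease_id]
  delta <- ifelse(st == "up", config$effect_size,
                  ifelse(st == "down", -config$effect_size, 0))
  spg <- config$samples_per_group
  datasets <- with_seed(derive_seed(config$seed, 101L + .id_offset(disease_id)), {
    baseline <- rnorm(G, mean = 7, sd = 1.5)
    lapply(seq_len(config$n_datasets_per_disease), function(k) {
      noise <- matrix(rnorm(G * 2L * spg, sd = config$noise_sd), nrow = G)
      mat <- baseline + noise
      mat[, seq_len(spg)] <- mat[, seq_len(spg)] + delta
      colnames(mat) <- c(sprintf("%s_ds%d_dis%02d", disease_id, k, seq_len(spg)),
                         sprintf("%s_ds%d_nor%02d", disease_id, k, seq_len(spg)))
      expression_dataset(mat,
                         rep(c("disease", "normal"), each = spg),
                         sprintf("%s_ds%d", disease_id, k),
                         gene_ids = genes)
    })
  })
  list(datasets = datasets, truth = truth)
}

#' Generate a synthetic ontology with planted enriched terms
#'
#' Builds a rooted is_a DAG with a designated "response to stimulus"-role
#' subtree.  A subset of terms is planted enriched: their direct gene
#' sets draw a share `enriched_de_share` of members from the planted DE
#' genes (disease A genes for terms inside the stimulus subtree, disease
#' B genes outside), against a uniform draw for unplanted terms.  At
#' least one planted parent/child pair is created so the redundancy
#' pruning rule is exercised.  Annotations are returned true-path
#' propagated over the full gene universe.
#'
#' @param config A [simulation_config()].
#' @param truth A `GroundTruth` (two-disease for the A/B split; with a
#'   single disease all planted terms draw from it).
#' @param enriched_fraction Fraction of non-root terms planted enriched.
#' @param enriched_de_share Share of a planted term's direct genes drawn
#'   from DE genes.
#' @return List with `dag` ([ontology_dag()]), `annotations`
#'   ([annotation_map()], propagated, universe = all genes), `planted`
#'   (data frame: `term_id`, `planted`, `in_stimulus_subtree`) and
#'   `stimulus_root`.
#' @export
generate_ontology <- function(config, truth, enriched_fraction = 0.15,
                              enriched_de_share = 0.8) {
  stopifnot(inherits(config, "SimulationConfig"), inherits(truth, "GroundTruth"))
  if (config$n_terms < 3L) abort_config("'n_terms' must be >= 3")
  genes <- truth$genes
  disease_a <- truth$diseases[1L]
  disease_b <- truth$diseases[min(2L, length(truth$diseases))]
  de_a <- names(truth_de_genes(truth, disease_a))
  de_b <- names(truth_de_genes(truth, disease_b))
  n_terms <- config$n_terms
  ids <- sprintf("T:%04d", seq_len(n_terms))
  root <- ids[1L]
  stim_root <- ids[2L]

  res <- with_seed(derive_seed(config$seed, 31L), {
    parent <- character(n_terms)
    in_stim <- logical(n_terms)
    parent[2L] <- root
    in_stim[2L] <- TRUE
    for (i in seq_len(n_terms)[-(1:2)]) {
      stim_side <- runif(1) < 0.4
      pool <- if (stim_side) which(in_stim[seq_len(i - 1L)]) else
        c(1L, which(!in_stim[seq_len(i - 1L)] & seq_len(i - 1L) > 2L))
      p <- .resample(pool, 1L)
      parent[i] <- ids[p]
      in_stim[i] <- stim_side
    }
    candidates <- seq_len(n_terms)[-(1:2)]
    n_enr <- max(2L, round(enriched_fraction * length(candidates)))
    planted <- sort(sample(candidates, min(n_enr, length(candidates))))
    # ensure coverage of both sides of the tree
    if (!any(in_stim[planted]) && any(in_stim[candidates])) {
      planted <- sort(c(planted[-1L], .resample(candidates[in_stim[candidates]], 1L)))
    }
    if (all(in_stim[planted]) && any(!in_stim[candidates])) {
      planted <- sort(c(planted[-1L], .resample(candidates[!in_stim[candidates]], 1L)))
    }
    # ensure a planted ancestor/offspring pair for the pruning rule
    pair_child <- planted[match(TRUE, !ids[planted] %in% c(root, stim_root) &
                                  !parent[planted] %in% c(root, stim_root))]
    if (is.na(pair_child)) {
      deep <- candidates[!parent[candidates] %in% c(root, stim_root)]
      if (length(deep)) {
        pair_child <- deep[1L]
        planted <- sort(unique(c(planted, pair_child)))
      }
    }
    if (!is.na(pair_child)) {
      planted <- sort(unique(c(planted, match(parent[pair_child], ids))))
      planted <- setdiff(planted, 1:2)
    }
    sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                    n_terms, replace = TRUE)
    raw <- list()
    for (i in seq_len(n_terms)[-1L]) {
      sz <- sizes[i]
      if (i %in% planted) {
        pool <- if (in_stim[i]) de_a else de_b
        n_from_pool <- min(length(pool), round(enriched_de_share * sz))
        rest_pool <- setdiff(genes, pool)
        picked <- c(.resample(pool, n_from_pool),
                    .resample(rest_pool, min(length(rest_pool), sz - n_from_pool)))
      } else {
        picked <- .resample(genes, sz)
      }
      raw[[ids[i]]] <- sort(picked)
    }
    list(parent = parent, in_stim = in_stim, planted = planted, raw = raw)
  })

  names <- c("biological process root", "response to stimulus",
             sprintf("%s process %04d",
                     ifelse(res$in_stim[-(1:2)], "stimulus response", "cellular"),
                     seq_len(n_terms)[-(1:2)]))
  terms <- data.frame(id = ids, name = names,
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = ids[-1L], parent = res$parent[-1L],
                      stringsAsFactors = FALSE)
  dag <- ontology_dag(terms, edges)
  ann <- propagate_annotations(res$raw, dag, universe = genes)
  planted_df <- data.frame(term_id = ids,
                           planted = seq_len(n_terms) %in% res$planted,
                           in_stimulus_subtree = res$in_stim,
                           stringsAsFactors = FALSE)
  list(dag = dag, annotations = ann, planted = planted_df,
       stimulus_root = stim_root)
}

#' Generate a synthetic TF-target network
#'
#' Wires each of `n_tfs` transcription factors (sampled from the gene
#' universe) to a random number of targets.  Optionally plants a linked
#' function pair: extra edges from disease-A DE TFs in `linked$f1` to
#' cross-disease-consistent DE targets in `linked$f2` (genes shared by
#' the two sets are avoided, matching the counting rule of
#' [count_tf_target_pairs()]).
#'
#' @param config A [simulation_config()].
#' @param truth A `GroundTruth`.
#' @param linked Optional list with `f1`, `f2` (character gene sets) and
#'   `n_extra` (count of planted edges).
#' @return A [tf_network()]; the edge table carries a logical `planted`
#'   column.
#' @export
generate_tf_network <- function(config, truth, linked = NULL) {
  stopifnot(inherits(config, "SimulationConfig"), inherits(truth, "GroundTruth"))
  genes <- truth$genes
  rng <- config$targets_per_tf_range
  edges <- with_seed(derive_seed(config$seed, 41L), {
    tfs <- .resample(genes, min(config$n_tfs, length(genes)))
    ks <- pmin(.resample(seq(rng[1], rng[2]), length(tfs), replace = TRUE),
               length(genes) - 1L)
    # drawing k+1 without replacement leaves exactly k after removing a
    # possible self-loop, so every TF gets its drawn target count
    targets <- lapply(seq_along(tfs), function(i) {
      cand <- .resample(genes, ks[i] + 1L)
      cand[cand != tfs[i]][seq_len(ks[i])]
    })
    base <- data.frame(tf = rep(tfs, ks),
                       target = unlist(targets, use.names = FALSE),
                       planted = FALSE, stringsAsFactors = FALSE)
    if (!is.null(linked)) {
      if (!all(c("f1", "f2", "n_extra") %in% names(linked))) {
        abort_config("'linked' needs elements f1, f2, n_extra")
      }
      overlap <- intersect(linked$f1, linked$f2)
      de_a <- names(truth_de_genes(truth, truth$diseases[1L]))
      cons <- if (length(truth$diseases) == 2L) truth_consistent_genes(truth) else de_a
      src <- setdiff(intersect(linked$f1, de_a), overlap)
      dst <- setdiff(intersect(linked$f2, cons), overlap)
      if (length(src) && length(dst)) {
        extra <- data.frame(
          tf = .resample(src, linked$n_extra, replace = TRUE),
          target = .resample(dst, linked$n_extra, replace = TRUE),
          planted = TRUE, stringsAsFactors = FALSE)
        base <- rbind(base, extra[extra$tf != extra$target, , drop = FALSE])
      }
    }
    base
  })
  # planted edges win over duplicate background edges
  edges <- edges[order(edges$tf, edges$target, !edges$planted), , drop = FALSE]
  tf_network(edges)
}

#' Generate a synthetic per-gene alteration table
#'
#' Draws mutated-sample and deleted-sample counts per gene from binomials
#' at configurable per-gene probabilities over a cohort, emulating a
#' tumour-cohort alteration summary.  Background genes use the per-base
#' mutation rate scaled by gene length and the per-gene deletion rate;
#' `elevated` genes use the elevated probabilities for both.
#'
#' @param config A [simulation_config()] (provides the seed).
#' @param genes Nonempty character vector of genes.
#' @param cohort_size Number of cohort samples (default 208).
#' @param gene_length Gene length in bases for the mutation model.
#' @param mutation_rate Background per-base, per-sample mutation rate.
#' @param deletion_rate Background per-gene, per-sample deletion rate.
#' @param elevated Subset of `genes` planted with elevated alteration
#'   probabilities.
#' @param elevated_mutation_p,elevated_deletion_p Per-sample
#'   probabilities for the elevated genes.
#' @return Data frame: `gene`, `n_mutated`, `n_deleted`, `cohort_size`,
#'   `gene_length`.
#' @export
generate_alteration_table <- function(config, genes, cohort_size = 208L,
                                      gene_length = 1500L,
                                      mutation_rate = 1.2e-6,
                                      deletion_rate = 1.2e-2,
                                      elevated = character(0),
                                      elevated_mutation_p = 0.2,
                                      elevated_deletion_p = 0.2) {
  stopifnot(inherits(config, "SimulationConfig"))
  genes <- as.character(genes)
  if (!length(genes)) abort_config("'genes' must be nonempty")
  p_mut <- rep(1 - (1 - mutation_rate)^gene_length, length(genes))
  p_del <- rep(deletion_rate, length(genes))
  p_mut[genes %in% elevated] <- elevated_mutation_p
  p_del[genes %in% elevated] <- elevated_deletion_p
  with_seed(derive_seed(config$seed, 51L), {
    data.frame(gene = genes,
               n_mutated = rbinom(length(genes), cohort_size, p_mut),
               n_deleted = rbinom(length(genes), cohort_size, p_del),
               cohort_size = cohort_size,
               gene_length = gene_length,
               stringsAsFactors = FALSE)
  })
}
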