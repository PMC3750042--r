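test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(n_genes = 0), "n_genes",
               class = "concordis_config_error")
  expect_error(simulation_config(de_fraction = 1.2), "de_fraction",
               class = "concordis_config_error")
  expect_error(simulation_config(noise_sd = 0), "noise_sd",
               class = "concordis_config_error")
  expect_error(simulation_config(effect_size = -1), "effect_size",
               class = "concordis_config_error")
  expect_error(simulation_config(term_size_range = c(50, 10)), "term_size_range",
               class = "concordis_config_error")
  expect_error(simulation_config(n_genes = 100, term_size_range = c(10, 500)),
               "term_size_range", class = "concordis_config_error")
})

test_that("identical configs give bit-identical outputs and call order does not matter", {
  cfg <- simulation_config(n_genes = 150, n_datasets_per_disease = 2,
                           samples_per_group = 4, n_terms = 12,
                           term_size_range = c(5, 20), n_tfs = 8,
                           targets_per_tf_range = c(3, 6), seed = 99)
  t1 <- generate_two_disease_truth(cfg)
  e1 <- generate_expression(cfg, "diseaseA", t1)
  o1 <- generate_ontology(cfg, t1)
  n1 <- generate_tf_network(cfg, t1)
  # regenerate in a different order
  n2 <- generate_tf_network(cfg, generate_two_disease_truth(cfg))
  o2 <- generate_ontology(cfg, generate_two_disease_truth(cfg))
  e2 <- generate_expression(cfg, "diseaseA", generate_two_disease_truth(cfg))
  t2 <- generate_two_disease_truth(cfg)
  expect_identical(t1$status, t2$status)
  expect_identical(e1$datasets[[1]]$exprs, e2$datasets[[1]]$exprs)
  expect_identical(o1$annotations$term2genes, o2$annotations$term2genes)
  expect_identical(n1$edges, n2$edges)
})

test_that("planted DE counts are exact and shared across a disease's datasets", {
  cfg <- simulation_config(n_genes = 1000, de_fraction = 0.2, seed = 7,
                           n_datasets_per_disease = 3, samples_per_group = 3)
  tr <- generate_two_disease_truth(cfg)
  for (d in tr$diseases) {
    expect_identical(sum(tr$status[, d] != "null"), 200L)
  }
  sim <- generate_expression(cfg, "diseaseA", tr)
  expect_length(sim$datasets, 3L)
  # all datasets derive from the same truth object, hence one planted set
  expect_identical(sim$truth$status, tr$status)
  # disease-group means shift by +/- effect size for planted genes
  ds <- sim$datasets[[1]]
  shift <- rowMeans(ds$exprs[, ds$groups == "disease"]) -
    rowMeans(ds$exprs[, ds$groups == "normal"])
  up <- tr$status[, "diseaseA"] == "up"
  dn <- tr$status[, "diseaseA"] == "down"
  expect_gt(mean(shift[up]), 1.0)
  expect_lt(mean(shift[dn]), -1.0)
})

test_that("direction agreement among doubly-DE genes follows consistent_fraction", {
  cfg1 <- simulation_config(n_genes = 3000, de_fraction = 0.5,
                            consistent_fraction = 1, seed = 3)
  tr1 <- generate_two_disease_truth(cfg1)
  both <- tr1$status[, 1] != "null" & tr1$status[, 2] != "null"
  expect_true(all(tr1$status[both, 1] == tr1$status[both, 2]))

  cfg5 <- simulation_config(n_genes = 3000, de_fraction = 0.5,
                            consistent_fraction = 0.5, seed = 3)
  tr5 <- generate_two_disease_truth(cfg5)
  both <- tr5$status[, 1] != "null" & tr5$status[, 2] != "null"
  agree <- mean(tr5$status[both, 1] == tr5$status[both, 2])
  expect_lt(abs(agree - 0.5), 3 * sqrt(0.25 / sum(both)))
})

test_that("mean recovered agreement over many seeds matches a 0.72 target", {
  fr <- vapply(1:200, function(s) {
    cfg <- simulation_config(n_genes = 10000, de_fraction = 0.65,
                             consistent_fraction = 0.72, seed = s)
    tr <- generate_two_disease_truth(cfg)
    both <- tr$status[, 1] != "null" & tr$status[, 2] != "null"
    expect_gte(sum(both), 4000)
    mean(tr$status[both, 1] == tr$status[both, 2])
  }, numeric(1))
  expect_gte(mean(fr), 0.70)
  expect_lte(mean(fr), 0.74)
})

test_that("the generated ontology is a rooted DAG with true-path annotations", {
  cfg <- simulation_config(n_genes = 800, de_fraction = 0.2, n_terms = 25,
                           term_size_range = c(10, 40), seed = 13)
  tr <- generate_two_disease_truth(cfg)
  onto <- generate_ontology(cfg, tr)
  dag <- onto$dag
  expect_s3_class(dag, "OntologyDAG")
  expect_identical(dag$roots, "T:0001")
  # true-path: every term's propagated genes are contained in each parent's
  for (t in names(onto$annotations$term2genes)) {
    for (pa in dag$parents[[t]]) {
      if (pa %in% names(onto$annotations$term2genes)) {
        expect_true(all(onto$annotations$term2genes[[t]] %in%
                          onto$annotations$term2genes[[pa]]))
      }
    }
  }
  # a planted parent/child pair exists to exercise redundancy pruning
  planted <- onto$planted$term_id[onto$planted$planted]
  has_pair <- any(vapply(planted, function(t)
    length(intersect(term_ancestors(dag, t), planted)) > 0, logical(1)))
  expect_true(has_pair)
})

test_that("planted enriched terms are strongly enriched for planted DE genes", {
  cfg <- simulation_config(n_genes = 2000, de_fraction = 0.2, n_terms = 40,
                           term_size_range = c(40, 60), seed = 21)
  tr <- generate_two_disease_truth(cfg)
  onto <- generate_ontology(cfg, tr)
  pl <- onto$planted
  t_stim <- pl$term_id[pl$planted & pl$in_stimulus_subtree][1]
  skip_if(is.na(t_stim), "no planted stimulus term at this seed")
  de_a <- names(truth_de_genes(tr, tr$diseases[1]))
  row <- term_enrichment(de_a, onto$annotations, t_stim)
  expect_lt(row$p_value, 1e-6)
})

test_that("a minimal three-term chain survives an OBO round trip", {
  cfg <- simulation_config(n_genes = 50, n_terms = 3, term_size_range = c(5, 10),
                           seed = 2)
  tr <- generate_two_disease_truth(cfg)
  onto <- generate_ontology(cfg, tr)
  path <- tempfile(fileext = ".obo")
  write_obo(onto$dag, path)
  dag2 <- parse_obo(path)
  expect_identical(dag2$terms[order(dag2$terms$id), ],
                   onto$dag$terms[order(onto$dag$terms$id), ])
  expect_identical(lapply(dag2$parents, sort), lapply(onto$dag$parents, sort))
})

test_that("the TF network has the configured shape and no self-loops", {
  cfg <- simulation_config(n_genes = 200, n_tfs = 1,
                           targets_per_tf_range = c(5, 5), seed = 31)
  tr <- generate_two_disease_truth(cfg)
  net <- generate_tf_network(cfg, tr)
  expect_identical(nrow(net$edges), 5L)
  expect_identical(length(unique(net$edges$tf)), 1L)
  expect_true(all(net$edges$tf != net$edges$target))
  expect_false(any(duplicated(net$edges[, c("tf", "target")])))
})

test_that("planted linked edges connect DE TFs in F1 to consistent targets in F2", {
  cfg <- simulation_config(n_genes = 500, de_fraction = 0.4,
                           consistent_fraction = 0.9, n_tfs = 10,
                           targets_per_tf_range = c(3, 8), seed = 17)
  tr <- generate_two_disease_truth(cfg)
  de_a <- names(truth_de_genes(tr, "diseaseA"))
  cons <- truth_consistent_genes(tr)
  f1 <- tr$genes[1:200]
  f2 <- tr$genes[201:400]
  net <- generate_tf_network(cfg, tr, linked = list(f1 = f1, f2 = f2, n_extra = 20))
  pl <- net$edges[net$edges$planted, ]
  expect_gt(nrow(pl), 0)
  expect_true(all(pl$tf %in% intersect(f1, de_a)))
  expect_true(all(pl$target %in% intersect(f2, cons)))
})

test_that("alteration tables follow the configured binomial regime", {
  cfg <- simulation_config(n_genes = 100, seed = 5)
  genes <- sprintf("g%05d", 1:100)
  # zero rates give zero counts
  tab0 <- generate_alteration_table(cfg, genes, mutation_rate = 1e-12,
                                    deletion_rate = 1e-12)
  expect_true(all(tab0$n_mutated %in% 0:1))  # 208 * ~1.5e-9 chance
  expect_lte(sum(tab0$n_deleted), 1)
  # elevated genes sit near cohort * p
  tab <- generate_alteration_table(cfg, genes, elevated = genes[1:5],
                                   elevated_mutation_p = 0.2,
                                   elevated_deletion_p = 0.2)
  expect_true(all(tab$n_mutated[1:5] >= qbinom(1e-6, 208, 0.2)))
  expect_true(all(tab$n_mutated[1:5] <= qbinom(1 - 1e-6, 208, 0.2)))
  expect_true(all(tab$n_mutated <= tab$cohort_size))
  expect_error(generate_alteration_table(cfg, character()),
               class = "concordis_config_error")
})
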