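obo_fixture <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

test_that("parse_obo reads term stanzas, skips obsolete terms, flags format errors", {
  path <- obo_fixture(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: T:2", "name: mid", "is_a: T:1 ! root", "xref: X:1", "",
    "[Term]", "id: T:3", "name: leaf", "is_a: T:2", "",
    "[Term]", "id: T:9", "name: dead", "is_a: T:1", "is_obsolete: true", ""))
  dag <- parse_obo(path)
  expect_identical(sort(dag$terms$id), c("T:1", "T:2", "T:3"))
  expect_identical(sum(vapply(dag$parents, length, integer(1))), 2L)
  expect_false("T:9" %in% dag$terms$id)
  expect_identical(attr(dag, "ignored_tags"), 1L)

  no_id <- obo_fixture(c("[Term]", "name: anonymous", ""))
  expect_error(parse_obo(no_id), "no id", class = "concordis_format_error")

  cyc <- obo_fixture(c("[Term]", "id: A", "name: a", "is_a: B", "",
                       "[Term]", "id: B", "name: b", "is_a: A", ""))
  expect_error(parse_obo(cyc), "cycle", class = "concordis_format_error")
})

test_that("annotation propagation is the ancestor closure and is idempotent", {
  dag <- chain_dag()
  ann <- propagate_annotations(list(B = c("g1", "g2"), A = "g3"), dag)
  expect_identical(ann$term2genes$R, c("g1", "g2", "g3"))
  expect_identical(ann$term2genes$A, c("g1", "g2", "g3"))
  expect_identical(ann$term2genes$B, c("g1", "g2"))
  twice <- propagate_annotations(ann, dag)
  expect_identical(twice$term2genes, ann$term2genes)
  expect_error(propagate_annotations(list(Z = "g1"), dag), "Z",
               class = "concordis_config_error")
})

test_that("propagation equals a brute-force per-gene ancestor walk on a random DAG", {
  set.seed(5)
  n <- 25
  ids <- sprintf("N%02d", 1:n)
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), numeric(1)))
  dag <- ontology_dag(
    data.frame(id = ids, name = ids, namespace = "biological_process"),
    data.frame(child = ids[-1], parent = ids[parent[-1]]))
  raw <- lapply(setNames(ids, ids), function(i)
    sprintf("g%02d", sample(40, sample(3:8, 1))))
  ann <- propagate_annotations(raw, dag)
  # brute force: gene belongs to term iff directly annotated to it or to a
  # term whose ancestors include it
  for (t in ids) {
    expected <- sort(unique(unlist(
      raw[c(t, names(raw)[vapply(names(raw), function(s)
        t %in% term_ancestors(dag, s), logical(1))])])))
    expect_identical(ann$term2genes[[t]], expected)
  }
})

test_that("term enrichment matches the hypergeometric closed form and oracle", {
  universe <- sprintf("u%02d", 1:20)
  ann <- annotation_map(list(tA = universe[1:5]), universe = universe)
  row <- term_enrichment(universe[1:5], ann, "tA")
  expect_equal(row$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # zero hits give p = 1
  row0 <- term_enrichment(universe[6:10], ann, "tA")
  expect_equal(row0$p_value, 1)
  # random-fixture oracle
  set.seed(9)
  big <- sprintf("u%03d", 1:50)
  ann2 <- annotation_map(list(t1 = big[1:10]), universe = big)
  q <- sample(big, 12)
  row2 <- term_enrichment(q, ann2, "t1")
  expect_equal(row2$p_value,
               bf_hyper_tail(row2$hit_count, 50, 10, 12), tolerance = 1e-10)
  expect_error(term_enrichment("not_in_universe", ann, "tA"),
               class = "concordis_domain_error")
})

test_that("benjamini_hochberg matches a manual step-up implementation", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  set.seed(4)
  p <- runif(100)
  expect_equal(benjamini_hochberg(p), bf_bh(p), tolerance = 1e-12)
  # order equivariance
  o <- sample(100)
  expect_equal(benjamini_hochberg(p[o]), benjamini_hochberg(p)[o])
  expect_error(benjamini_hochberg(c(0.1, 1.2)), class = "concordis_domain_error")
})

test_that("an ancestor significant only through its offspring is pruned", {
  fx <- prune_fixture(parent_own_hits = 0)
  out <- select_significant_terms(fx$query, fx$ann, fx$dag, fdr_threshold = 0.01,
                                  min_term_size = 5, max_term_size = 900)
  expect_true(out$significant[out$term_id == "P"])   # significant pre-pruning
  expect_true(out$retained[out$term_id == "C"])
  expect_false(out$retained[out$term_id == "P"])     # all evidence was C's
  expect_equal(out$p_retest[out$term_id == "P"], 1)
})

test_that("an ancestor with independent evidence is retained beside its offspring", {
  fx <- prune_fixture(parent_own_hits = 40)
  out <- select_significant_terms(fx$query, fx$ann, fx$dag, fdr_threshold = 0.01,
                                  min_term_size = 5, max_term_size = 900)
  expect_true(out$retained[out$term_id == "C"])
  expect_true(out$retained[out$term_id == "P"])
  expect_lt(out$p_retest[out$term_id == "P"],
            max(out$p_value[out$significant]) + 1e-15)
})

test_that("pruning is sound: every retained term was significant, no empty scans break", {
  cfg <- simulation_config(n_genes = 1000, de_fraction = 0.25, n_terms = 30,
                           term_size_range = c(10, 60), seed = 19)
  tr <- generate_two_disease_truth(cfg)
  onto <- generate_ontology(cfg, tr)
  de_b <- names(truth_de_genes(tr, "diseaseB"))
  out <- select_significant_terms(de_b, onto$annotations, onto$dag,
                                  fdr_threshold = 0.01)
  expect_true(all(out$significant[out$retained]))
  expect_true(all(out$fdr >= out$p_value - 1e-15))
  # a query with no enrichment anywhere yields no retained terms
  none <- select_significant_terms(tr$genes[1:10], onto$annotations, onto$dag,
                                   fdr_threshold = 1e-6)
  expect_identical(sum(none$retained), 0L)
})

test_that("stimulus functions are restricted to the designated subtree", {
  universe <- sprintf("g%04d", 1:500)
  dag <- ontology_dag(
    data.frame(id = c("R", "S", "S1", "X"),
               name = c("root", "stimulus", "stim leaf", "outside"),
               namespace = "biological_process"),
    data.frame(child = c("S", "S1", "X"), parent = c("R", "S", "R")))
  raw <- list(S1 = universe[1:40], X = universe[1:40])  # equally enriched
  ann <- propagate_annotations(raw, dag, universe = universe)
  query <- universe[1:35]
  out <- stimulus_functions(query, ann, dag, fdr_threshold = 0.05,
                            stimulus_root = "S", min_term_size = 5,
                            max_term_size = 400)
  expect_true(all(out$term_id %in% c("S", "S1")))
  expect_true(out$retained[out$term_id == "S1"])
  expect_false("X" %in% out$term_id)                 # enriched but outside
  expect_error(stimulus_functions(query, ann, dag, stimulus_root = "nope"),
               class = "concordis_config_error")
  # a leaf root with no annotated descendants yields an empty scan
  leaf <- stimulus_functions(query, ann, dag, stimulus_root = "X",
                             min_term_size = 100, max_term_size = 400)
  expect_identical(nrow(leaf), 0L)
})
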