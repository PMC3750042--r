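test_that("SAM statistic matches the pooled-standard-error formula", {
  # zero within-group variance: d = diff / s0
  ds <- make_dataset(matrix(3, 2, 2), matrix(1, 2, 2))
  expect_equal(unname(sam_statistic(ds, 1)), c(2, 2))

  # identical group means give d = 0
  ds0 <- make_dataset(matrix(c(1, 2, 3, 2), 2), matrix(c(2, 3, 2, 1), 2))
  expect_equal(unname(sam_statistic(ds0, 0.5)), c(0, 0))

  # hand-computed oracle for unequal variances
  dis <- c(2.0, 2.5, 3.0); nor <- c(1.0, 1.2, 1.1)
  s_hand <- sqrt((1/3 + 1/3) *
                 (sum((dis - mean(dis))^2) + sum((nor - mean(nor))^2)) / 4)
  d_hand <- (mean(dis) - mean(nor)) / (s_hand + 0.1)
  expect_equal(d_hand, 3.5497674839, tolerance = 1e-10)
  ds2 <- make_dataset(matrix(dis, 1), matrix(nor, 1), genes = "gX")
  expect_equal(unname(sam_statistic(ds2, 0.1)), d_hand, tolerance = 1e-12)
})

test_that("zero pooled spread with nonzero difference is an error naming the gene", {
  ds <- make_dataset(matrix(3, 1, 2), matrix(1, 1, 2), genes = "gBad")
  expect_error(sam_statistic(ds, 0), "gBad", class = "concordis_compute_error")
})

test_that("label swap negates d, flips directions, and keeps the DE set", {
  cfg <- simulation_config(n_genes = 300, samples_per_group = 6, seed = 8)
  ds <- generate_expression(cfg, "swap")$datasets[[1]]
  swapped <- expression_dataset(ds$exprs,
                                ifelse(ds$groups == "disease", "normal", "disease"),
                                "swapped")
  expect_equal(sam_statistic(swapped, 0.2), -sam_statistic(ds, 0.2))
  a <- call_de_genes(ds, seed = 1, s0 = 0.2, n_permutations = 100)
  b <- call_de_genes(swapped, seed = 1, s0 = 0.2, n_permutations = 100)
  expect_equal(a$table$is_de, b$table$is_de)
  expect_equal(a$table$direction, -b$table$direction)
})

test_that("results are invariant to gene order", {
  cfg <- simulation_config(n_genes = 200, samples_per_group = 5, seed = 11)
  ds <- generate_expression(cfg, "ord")$datasets[[1]]
  set.seed(42)
  perm <- sample(nrow(ds$exprs))
  ds_p <- expression_dataset(ds$exprs[perm, ], ds$groups, "perm")
  a <- call_de_genes(ds, seed = 3, s0 = 0.2, n_permutations = 60)
  b <- call_de_genes(ds_p, seed = 3, s0 = 0.2, n_permutations = 60)
  bt <- b$table[match(a$table$gene, b$table$gene), ]
  expect_equal(a$table$d, bt$d)
  expect_equal(a$table$q, bt$q)
  expect_equal(a$table$is_de, bt$is_de)
})

test_that("choose_s0 follows the percentile rule", {
  # degenerate: all genes share the same pooled s -> s0 equals it
  r <- rnorm(50)
  expect_equal(choose_s0(list(r = r, s = rep(0.7, 50))), 0.7)
  expect_error(choose_s0(list(r = 1:5, s = rep(1, 5))),
               class = "concordis_config_error")
  # explicit override is passed through unchanged
  cfg <- simulation_config(n_genes = 100, samples_per_group = 4, seed = 2)
  ds <- generate_expression(cfg, "ovr")$datasets[[1]]
  expect_equal(call_de_genes(ds, seed = 1, s0 = 0.5, n_permutations = 60)$s0, 0.5)
})

test_that("the chosen s0 stabilises d across s-quantile windows at least as well as s0 = 0", {
  cv_of <- function(parts, s0, nbins = 10) {
    d <- parts$r / (parts$s + s0)
    bin <- cut(rank(parts$s, ties.method = "first"), breaks = nbins, labels = FALSE)
    mads <- tapply(abs(d), bin, mad)
    sd(mads) / mean(mads)
  }
  for (seed in c(1, 5, 9)) {
    cfg <- simulation_config(n_genes = 2000, samples_per_group = 10, seed = seed)
    ds <- generate_expression(cfg, "cv")$datasets[[1]]
    parts <- list(r = sam_statistic(ds, 0) * 0, s = NULL)  # placeholder
    m <- ds$exprs
    idx <- which(ds$groups == "disease")
    m1 <- rowMeans(m[, idx]); m2 <- rowMeans(m[, -idx])
    ss1 <- rowSums((m[, idx] - m1)^2); ss2 <- rowSums((m[, -idx] - m2)^2)
    parts <- list(r = m1 - m2,
                  s = sqrt((1/length(idx) + 1/(ncol(m) - length(idx))) *
                           (ss1 + ss2) / (ncol(m) - 2)))
    s0 <- choose_s0(ds)
    expect_lte(cv_of(parts, s0), cv_of(parts, 0))
  }
})

test_that("sampled permutation q-values agree with the exhaustive null", {
  cfg <- simulation_config(n_genes = 100, samples_per_group = 3, seed = 5)
  ds <- generate_expression(cfg, "tiny")$datasets[[1]]
  # 3v3 has choose(6,3) = 20 arrangements: exhaustive whenever allowed
  q_ex <- permutation_fdr(ds, 0.2, n_permutations = 20, seed = 1)
  q_ex2 <- permutation_fdr(ds, 0.2, n_permutations = 20, seed = 99)
  expect_identical(q_ex, q_ex2)  # exhaustive is seed-independent
  q_s <- permutation_fdr(ds, 0.2, n_permutations = 10000, seed = 2)
  expect_lte(max(abs(q_ex - q_s)), 0.01)
  expect_true(all(q_ex >= 0 & q_ex <= 1))
})

test_that("q-values are monotone non-increasing in |d| and extreme genes reach q = 0", {
  cfg <- simulation_config(n_genes = 100, samples_per_group = 5, effect_size = 0,
                           noise_sd = 0.3, seed = 2)
  ds <- generate_expression(cfg, "mono")$datasets[[1]]
  ds$exprs[1, 1:5] <- ds$exprs[1, 1:5] + 50  # one gene far beyond any permuted d
  d <- abs(sam_statistic(ds, 0.1))
  q <- permutation_fdr(ds, 0.1, n_permutations = 100, seed = 1)
  ord <- order(d, decreasing = TRUE)
  expect_true(all(diff(q[ord]) >= 0))
  expect_equal(unname(q[which.max(d)]), 0)
})

test_that("permutation preconditions are enforced", {
  set.seed(1)
  ds <- make_dataset(matrix(rnorm(60), 10), matrix(rnorm(60), 10))
  # 6v6 has 924 arrangements, so fewer than 50 sampled permutations is refused
  expect_error(permutation_fdr(ds, 0.1, n_permutations = 10, seed = 1),
               class = "concordis_config_error")
})

test_that("constant genes are never DE and fdr_threshold = 1 flags every changed gene", {
  cfg <- simulation_config(n_genes = 80, samples_per_group = 4, seed = 4)
  ds <- generate_expression(cfg, "const")$datasets[[1]]
  ds$exprs[1, ] <- 5  # identical in all samples
  res <- call_de_genes(ds, fdr_threshold = 1, seed = 1, s0 = 0.2,
                       n_permutations = 60)
  tab <- res$table
  expect_equal(tab$d[tab$gene == "g00001"], 0)
  expect_equal(tab$q[tab$gene == "g00001"], 1)
  expect_false(tab$is_de[tab$gene == "g00001"])
  expect_true(all(tab$is_de[tab$direction != 0]))
})

test_that("raising a gene's disease samples never decreases its d", {
  cfg <- simulation_config(n_genes = 50, samples_per_group = 5, seed = 6,
                           term_size_range = c(5, 20))
  ds <- generate_expression(cfg, "monot")$datasets[[1]]
  d0 <- sam_statistic(ds, 0.2)
  shifted <- ds
  shifted$exprs[3, shifted$groups == "disease"] <-
    shifted$exprs[3, shifted$groups == "disease"] + 1
  d1 <- sam_statistic(shifted, 0.2)
  expect_gte(d1[3], d0[3])
  expect_equal(d1[-3], d0[-3])
})

test_that("planted DE genes are recovered with correct directions at FDR 1%", {
  cfg <- simulation_config(n_genes = 2000, samples_per_group = 20,
                           effect_size = 1.5, noise_sd = 0.5, seed = 1)
  sim <- generate_expression(cfg, "recov")
  res <- call_de_genes(sim$datasets[[1]], fdr_threshold = 0.01, seed = 1)
  planted <- truth_de_genes(sim$truth, "recov")
  tab <- res$table[res$table$is_de, ]
  hit <- intersect(names(planted), tab$gene)
  correct <- sum(tab$direction[match(hit, tab$gene)] == planted[hit])
  expect_gte(correct / length(planted), 0.9)
})
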