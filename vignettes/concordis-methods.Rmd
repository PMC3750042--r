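---
title: "Cross-disease transcriptome concordance: models and methods"
author: "concordis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-disease transcriptome concordance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordis)
```

## The scientific question

Two related diseases — for instance a chronic inflammatory bowel condition
and the colorectal carcinoma it predisposes to — can dysregulate largely
the same genes. What matters for understanding the transition between
them is not only *which* genes respond in both, but whether they respond
in the *same direction* relative to normal controls, and whether the
agreement concentrates in particular biological functions. `concordis`
implements that comparison as a reusable pipeline:

1. call differentially expressed (DE) genes per dataset against normal
   controls, with direction;
2. check that independent datasets for one disease agree in direction far
   beyond chance;
3. merge the per-dataset calls into one direction-annotated list per
   disease;
4. split the genes DE in both diseases into direction-consistent and
   direction-reversed sets;
5. find the second disease's related functions by redundancy-pruned
   ontology enrichment and test per-function direction concordance;
6. ask whether DE transcription factors (TFs) in stimulus-response
   functions of the first disease preferentially target consistent DE
   genes in the second disease's functions.

Every stage can be exercised on synthetic data with known ground truth;
no external downloads are required.

## Per-dataset DE calling

For gene $g$ with disease/normal group means $\bar x_1, \bar x_2$ and
pooled standard error $s_g$ of the difference, the moderated statistic is

$$ d_g = \frac{\bar x_{1g} - \bar x_{2g}}{s_g + s_0}. $$

The fudge factor $s_0 \ge 0$ damps the statistic for genes whose tiny
variance would otherwise dominate the tails. `choose_s0()` picks $s_0$
by the percentile rule: candidates are percentiles of the $s_g$
distribution (steps of 0.05); for each candidate, genes are binned into
$s$-quantile windows (up to 100, at least 10 genes each) and the
coefficient of variation of the windowed median absolute deviation of
$|d|$ is computed; the candidate minimising it is selected, making the
spread of $d$ approximately independent of $s$. A value of 0 is never
chosen automatically. Passing `s0 =` a number to `call_de_genes()`
overrides the rule, which keeps pipelines deterministic across platforms
if desired.

False discovery rates come from group-label permutations. When the
number of distinct label arrangements is no larger than the requested
permutation count the full arrangement set is enumerated (for example
3 vs 3 samples has only 20), otherwise arrangements are sampled with
replacement (at least 50). The q-value of gene $g$ is the plug-in
estimate

$$ q_g = \pi_0 \cdot
   \frac{\mathrm{median}_b \,\#\{g' : |d^{*(b)}_{g'}| \ge |d_g|\}}
        {\#\{g' : |d_{g'}| \ge |d_g|\}}, $$

clipped to $[0,1]$ and made monotone non-increasing in $|d|$ (by a
running maximum from the largest $|d|$ downward — the conservative
direction). $\pi_0$ is fixed at 1 by default, which over- rather than
under-estimates the FDR. Ties are counted with $\ge$ on both sides.
Genes with identical values in all samples receive $d = 0$, $q = 1$;
genes with exactly zero mean difference are never called DE, whatever
their $q$. The study-level default threshold is $q \le 0.01$.

## Consistency, integration and classification

All direction questions use the same exact one-sided binomial test: if
two independent mechanisms assigned directions by coin flip, the number
of agreements among $n$ shared DE genes would be Binomial($n$, 0.5);
`binomial_tail()` returns $P(X \ge k)$. This is applied to every pair of
datasets within a disease (`pairwise_consistency()`, reported in the
classical "98.5% (4061/4121)"-style matrix), to two conditions contrasted
against a shared reference (`subtype_similarity()`), to the cross-disease
overlap (`classify_cross_disease()`, null 0.5), and per ontology function
(`function_concordance()`, BH-adjusted across functions at FDR 5% by
default).

Integration follows the published rule verbatim: a gene enters a
disease's list if DE in at least one dataset, unless it was DE in two or
more datasets with conflicting directions, in which case it is excluded
outright. Genes with exactly zero fold change are excluded from
consistency counts (they cannot carry a direction); the package logs
them rather than guessing.

## Ontology enrichment and the local-redundancy rule

Annotations are propagated by the true-path rule (a gene annotated to a
term belongs to all its ancestors) before any testing; `parse_obo()`
reads the OBO 1.2 dialect (id, name, namespace, is_a, is_obsolete) and
rejects cyclic input. Term enrichment is the hypergeometric upper tail
with population = the gene universe, marked = the term's genes, draws =
the query list. The default universe is the set of genes present on the
expression platform; this choice is recorded in the run manifest because
published analyses rarely state it. Term-size bounds (default 5–2000)
keep untestably small or uninformatively large terms out of the scan.

When an ancestor and its offspring are both BH-significant, the
ancestor may owe its significance entirely to the offspring's genes. The
local-redundancy rule re-tests each significant ancestor after removing
the genes of its significant offspring terms — from the ancestor's gene
set, from the query list, and from the universe, so the re-test is a
coherent conditional 2-by-2 on the remaining genes. The ancestor is
retained iff the re-test p-value still clears the largest raw p-value
that was BH-significant in the original scan (the raw-scale image of the
BH cutoff). Terms are processed children-first so offspring retention is
settled before ancestors are examined. Both outcomes occur in practice:
an ancestor with independent evidence survives beside its offspring; an
ancestor carried by its offspring is dropped and only the offspring kept.
Whether the original method used raw or adjusted thresholds in this
re-test is not documented anywhere we could verify, so the rule above is
stated explicitly rather than guessed differently.

`stimulus_functions()` is the same scan restricted to the subtree rooted
at a designated "response to stimulus" term, with BH adjustment among
the subtree's terms only.

## The TF-target linkage model

For a stimulus function $F_1$ and a disease function $F_2$ (genes shared
by both removed first), the margins are

* $N$ — all TF→target edges in the network,
* $M$ — edges whose TF and target are both DE in disease A,
* $n$ — edges from an $F_1$ TF to an $F_2$ target,
* $m$ — those $n$ edges whose TF is DE in disease A and whose target is
  a cross-disease direction-consistent DE gene,

and the p-value is the hypergeometric upper tail $P(X \ge m)$ for
drawing $n$ from $N$ with $M$ marked, BH-adjusted across all testable
pairs (default FDR 10%). Self-loops are dropped at load; duplicate edges
are collapsed. Direction of regulation (activation vs repression) is not
modelled; the counts are direction-agnostic.

Two statistical properties of this construction are worth knowing.
First, the marked class counted by $m$ (consistent targets) is a subset
of the class counted by $M$ (disease-A DE targets), so whenever
consistency is imperfect the test is **conservative**: true p-values are
stochastically larger than uniform. Second, edges sharing a hub TF rise
and fall together, so with few TFs and many targets per TF the count
$m$ is **overdispersed** relative to the hypergeometric reference. The
calibration test therefore checks uniformity under the exchangeable null
where the reference is exact — one target per TF (edges share no genes),
function membership and DE status assigned per gene independently of the
wiring, and the marked class matched between the global and local
margins — and the package documents, rather than hides, that in hubby
networks the test errs on the conservative side for detecting excess
linkage.

## Category and alteration-burden tests

Direction-reversed genes are profiled against named gene categories
(immune classes, cell-type-specific sets) with the same hypergeometric
upper tail, and `direction_breakdown()` tallies the four direction
patterns exhaustively. Alteration burden uses one-sided binomial tests:
for mutations the per-base background rate $r$ (study value
$1.2\times10^{-6}$) is converted to a per-gene, per-sample probability
$p_g = 1-(1-r)^{L}$ with $L$ the gene length (default 1500 coding
bases — the published analysis does not state how the per-base rate was
gene-scaled, so the simplest length-scaling model is used and recorded);
for copy-number deletions the rate (study value $1.2\times10^{-2}$) is
already per gene and is used directly. Hypermethylation is reported
descriptively only, since no background rate is available to test
against.

## The synthetic-data generator

`simulation_config()` fixes the study conditions; every generator
derives its RNG stream from the config seed plus a fixed offset, so
identical configs give bit-identical outputs regardless of call order.

* **Expression**: per-gene baselines on the log2 scale, $N(7, 1.5)$ —
  the typical range of RMA-processed intensities — shared across a
  disease's datasets; planted genes shift the disease-group mean by
  $\pm$`effect_size` (default 1.5); homoscedastic Gaussian noise
  (`noise_sd`, default 0.5), independent per dataset. Defaults of 20
  samples per group and 3 datasets per disease mirror the sample-size
  regime of multi-dataset microarray meta-analyses.
* **Truth**: exactly `round(n_genes * de_fraction)` genes DE per
  disease; among genes DE in both, directions agree with probability
  `consistent_fraction` (default 0.7233, the agreement level the
  analysis is designed to detect).
* **Ontology**: a rooted is_a DAG with a designated stimulus-response
  subtree; planted enriched terms draw 80% of their direct genes from
  the planted DE genes (disease A inside the subtree, disease B
  outside); at least one planted parent/child pair exists so the
  redundancy rule is exercised; annotations are emitted true-path
  propagated.
* **TF network**: TFs sampled from the gene universe with a random
  target count per TF; an optional planted linked pair adds edges from
  disease-A DE TFs in $F_1$ to consistent targets in $F_2$.
* **Alterations**: binomial counts over a cohort (default 208 samples)
  at background or planted-elevated per-gene probabilities.

What the generator does **not** emulate: probe-level artefacts, batch
effects, correlated gene modules, heavy-tailed noise, and annotation
bias. Passing tests on this generator therefore demonstrates the
correctness and calibration of the statistical machinery under its
stated model, not robustness to every pathology of real microarray data.

## Numerical and design choices

* Binomial and hypergeometric tails are computed in log space via R's
  `pbinom`/`phyper`; extreme counts may underflow to 0, which is
  reported as 0 rather than clamped.
* BH adjustment is `stats::p.adjust(method = "BH")`; untestable rows
  (empty terms, zero-overlap functions, zero-edge pairs) are flagged and
  excluded from the adjustment rather than given placeholder p-values.
* Exhaustive permutation enumeration includes the observed labelling,
  and sampled permutation sets draw with replacement; both choices make
  the q-values reproducible for a fixed seed and exactly equal to the
  exhaustive null when enumeration is active.
* Direction ties (zero mean difference) are excluded from every
  consistency count.
* Gene identifiers are opaque, case-sensitive strings throughout; a
  probe-collapse utility (`collapse_probes()`, highest-mean probe per
  gene) is provided for real platform data but sits outside the tested
  core.
* Problem sizes in the test suite (up to 20,000 genes for calibration,
  1,500-gene demo pipelines, 100-seed Monte-Carlo loops) were chosen so
  the whole suite completes in a couple of minutes on one CPU while
  keeping binomial standard errors well inside the asserted bounds.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_genes = 1500, n_datasets_per_disease = 2,
                         samples_per_group = 10, de_fraction = 0.3,
                         effect_size = 1.5, noise_sd = 0.5,
                         consistent_fraction = 0.9, n_terms = 40,
                         term_size_range = c(10, 60), n_tfs = 40,
                         targets_per_tf_range = c(10, 40), seed = 42)
study <- simulate_study(cfg, tempfile(), linked_extra = 150)
res <- run_pipeline(study$config)
res$classification
head(res$linkage[res$linkage$significant, ])
```

The written outputs (one TSV per stage, a DOT export of the retained
function DAG and of the significant linkage graph, a manifest with the
config hash and per-stage row counts, and `report.txt`) land in
`study$config$out_dir` and are byte-identical across reruns of the same
configuration.

## Known limitations

* $\pi_0 = 1$ makes the permutation FDR conservative; a $\pi_0$
  estimator is a natural extension point.
* The linkage test inherits the conservatism and hub-overdispersion
  discussed above; edge-level resampling nulls would be the stricter
  alternative.
* Effect-size meta-analysis (random-effects integration) and paired or
  multi-class designs are out of scope; the integration rule is purely
  direction-based.
* The OBO reader covers the subset of OBO 1.2 the pipeline needs (is_a,
  obsolete flags); relationship types such as part_of are ignored.
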