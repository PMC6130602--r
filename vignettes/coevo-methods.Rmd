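---
title: "Methods: correlated evolution of phylogenetic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlated evolution of phylogenetic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevo)
```

This vignette documents the statistical model, the numerical choices, and
the evaluation methodology implemented in `coevo`, together with the
reasoning behind defaults and the known limitations.

## 1. The model

### Independent model (null)

Each binary profile evolves along the rooted reference tree as a two-state
continuous-time Markov chain with gain rate α (0 → 1) and loss rate β
(1 → 0). Two profiles X and Y evolve independently, giving four free
parameters (α₁, β₁, α₂, β₂). The joint log-likelihood factorises into the
two single-trait log-likelihoods, and the package fits each trait
separately — the factorisation is exact, not an approximation.

### Dependent model (alternative)

The pair (X, Y) evolves as one four-state chain over
S1 = (0,0), S2 = (0,1), S3 = (1,0), S4 = (1,1), with eight free transition
rates between states differing in exactly one trait. Transitions changing
both traits at once (S1↔S4, S2↔S3) have rate zero: a simultaneous double
event has probability o(dt) in a continuous-time model. The eight rates
let each trait's gain/loss rate depend on the current state of the other
trait, which is the definition of correlated evolution in this framework.

### The test

Both models are fitted by maximum likelihood and compared with

$$\mathrm{LR} = 2(\ln L_{\text{dep}} - \ln L_{\text{indep}}),$$

asymptotically $\chi^2_4$ under the null (8 − 4 = 4 degrees of freedom).
The independent model is nested in the dependent one (constrain each
trait's rates to ignore the other trait's state), so LR ≥ 0 up to
optimiser error; the implementation enforces this by warm-starting the
dependent fit at the mapped independent optimum and clamping small
negative LR values (tolerance 10⁻³, after automatic refitting with extra
restarts) to zero.

Likelihoods are computed with Felsenstein's pruning algorithm in compiled
code. Tip states are observed exactly (no observation-error layer); a
profile's root prior is uniform over states, which keeps the test
symmetric in presence/absence and avoids estimating extra parameters —
stationary priors are available for the simulator where the sampling
distribution matters.

## 2. Numerical choices

- **Tree rescaling.** Before fitting, the tree is rescaled to mean
  root-to-tip depth 1 and fitted rates are scaled back. The LR statistic
  is invariant to this joint rescaling, but it makes one fixed rate box
  ([10⁻⁷, 10³]) appropriate for any input tree.
- **Log-rate optimisation.** Rates are optimised on the log scale with
  L-BFGS-B (`factr = 1e8`), so positivity is structural and the box is
  symmetric in orders of magnitude.
- **Multi-start.** The likelihood surface is multimodal for small trees
  and near-boundary rates. Each fit uses one fixed start (all rates 1) plus
  `restarts` random starts; the dependent fit additionally starts from the
  mapped independent optimum (the nesting warm start). The default
  `restarts = 10` is conservative for single analyses; simulation studies
  embedded in the test suite use `restarts = 2`, which pilot runs showed
  sufficient for calibration-level accuracy at 74 tips.
- **Deterministic per-pair seeds.** `all_pairs_lrt()` derives each pair's
  optimiser seed from the global seed and the pair indices, so results are
  identical however the pair list is chunked across jobs, and checkpoint
  resumes are bit-identical (checkpoint TSVs store 17 significant digits).
- **Transition probabilities.** The 2-state P(t) uses its closed form. The
  4-state P(t) uses the eigendecomposition of the (generally
  non-symmetric) generator, with a condition-number check that falls back
  to a dense matrix exponential when the eigenbasis is ill-conditioned.
  Per-edge partial-likelihood rescaling prevents underflow on large trees.

## 3. Rooting

Pagel's model is defined on a rooted tree, but reference phylogenies are
often published unrooted or rooted by convention. The package implements
midpoint rooting and MAD (minimal ancestor deviation) rooting, which
roots at the branch position minimising the root-mean-square relative
deviation of induced ancestor–descendant distances over all tip pairs.
`rooting_robustness()` quantifies the practical impact: it recomputes all
pairwise LR statistics under the original, MAD and midpoint rootings with
identical optimiser settings and reports the Pearson correlations between
the LR vectors. On simulated data these correlations exceed 0.9 (the
packaged acceptance script reproduces this), supporting the use of the
statistics when the true root is uncertain.

## 4. From homology hits to profiles

`read_hits()` parses tabular homology-search output; `build_profiles()`
thresholds hits at an E-value cutoff (default 10⁻²⁰, inclusive) to build
the presence/absence matrix over a genome list. The stringent default
trades sensitivity for precision: profile methods are damaged more by
spurious presences than by missed remote homologs. Identical profiles are
collapsed by `deduplicate_profiles()` (keeping multiplicities and the
member lists), since duplicate columns carry no extra information for the
pairwise test and would quadratically inflate the pair count. Constant
profiles are uninformative for the LRT and are dropped with a message.
`flag_unexpected_hits()` (strict inequality, with rank filtering via
`add_ranks()`) supports screening for candidate lateral-transfer genes,
whose patchy profiles are exactly the signal the tree-aware test can
separate from vertical descent.

## 5. Clustering

Pairwise LR values are converted to distances d = LR_max − LR
(`lr_to_distance()`; shift-invariant by construction) and clustered with
UPGMA via `stats::hclust(method = "average")` after lexical leaf
pre-ordering, which makes the dendrogram invariant to input column order.
`cut_clusters(dend, h)` keeps merges at height ≤ h. The choice of h is a
resolution parameter, not an estimate; the GO-based scores below are the
intended tool for comparing cuts. LR values are not metric distances —
UPGMA is used as a heuristic grouping device, as in the underlying method,
not as an estimator of a tree over genes.

## 6. GO-based evaluation

- **Semantic similarity.** Wang's measure (G-SESAME): each term's
  S-values decay along the DAG (weight 0.8 for `is_a`, 0.6 for `part_of`
  edges); term similarity is the normalised sum of shared-ancestor
  S-values; gene similarity is the best-match average over the genes'
  term sets; a clustering's score averages gene pairs within clusters,
  weighting clusters by annotated size. `relabel_null()` gives a
  permutation reference distribution for the score.
- **Enrichment.** For each term with at least `min_freq = 5` annotated
  genes, X² compares observed per-cluster counts with expectations
  proportional to cluster sizes; the p-value comes from resampling
  gene-to-cluster assignments (default 100,000 draws, with the +1
  correction so p > 0), and Benjamini–Hochberg adjustment controls FDR.
  Resampling avoids the χ² asymptotics that fail for small clusters and
  rare terms.
- **Overrepresentation.** An exact binomial tail
  P(K ≥ k | n, p₀) with p₀ the global flagged-gene fraction, for
  flag-type analyses (e.g. candidate transferred genes per cluster).

## 7. The simulator

`simulate_tree()` wraps a birth–death process conditioned on the tip
count (defaults: birth 1, death 0.5, 74 tips in examples) and rescales to
depth 1; `jitter_sd` applies mean-1 lognormal branch jitter to break the
clock when exercising rooting code. Traits are simulated by exact CTMC
realisation (exponential waiting times), not by matrix-exponential
sampling at nodes, so arbitrarily short branches are handled exactly.
`simulate_profile_set()` plants correlated blocks: each block has one
latent 2-state trait, and members copy it with independent per-tip noise
flips (default 0.05). This latent-block construction is a validation
harness — it is *not* the dependent model, which makes it a fair,
model-misspecified test of block recovery. Its limits: real profiles
feature rate heterogeneity across gene families, genome-level biases
(reduced genomes), and annotation error, none of which are modelled.
Constant columns are redrawn by default (`ensure_informative`), because
the pairwise test is undefined for them.

Taxon count matters a great deal: in development pilots, planted blocks
(noise 0.05, two blocks of five) were recovered almost perfectly on
74-tip trees but only about half the time on 40-tip trees with identical
settings — a binary profile on few genomes simply witnesses too few gain
and loss events for a decisive likelihood ratio. Users with small genome
panels should expect sharply reduced power.

Problem sizes used in the packaged tests (74 tips, 20 profiles, blocks of
5, 500 null pairs, 20 recovery seeds) are this package's choices for
desk-scale validation; they balance statistical resolution against the
test-suite time budget and are not claims about any particular dataset.

## 8. Pipeline and reproducibility

`run_pipeline()` executes profiles → rooting → Pagel → clustering → GO
evaluation from a single config, writing each stage's output with a
provenance header (config hash, seed, package version) and a manifest.
Every stochastic step takes an explicit seed; reruns with identical
config are bit-identical. The `pagel` stage checkpoints pair results and
resumes. The CLI (`inst/cli/coevo.R`) exposes each stage as a subcommand.

## 9. Limitations

- The $\chi^2_4$ reference distribution is asymptotic; for small trees or
  boundary rate estimates the null can deviate (boundary fits are
  flagged). The packaged calibration test checks the 74-tip case only.
- The test assumes the reference tree (topology and branch lengths) is
  known without error, a single rate regime per trait across the tree,
  and independence across pairs when clustering — shared tree structure
  induces dependence between pair statistics that the clustering step
  ignores.
- UPGMA on LR-derived distances has no consistency guarantee; it is an
  exploratory grouping tool evaluated post hoc with GO scores.
- Wang similarity depends on the ontology snapshot; scores are comparable
  only within one ontology release.
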