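---
title: "From single-cell counts to regulatory networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-cell counts to regulatory networks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery inside `scgrnet`, the
assumptions behind each stage, the parameters a user may want to move, and
the choices we made where the methodology is genuinely open. The package
runs a four-stage chain — representative cells, weighted co-expression
modules, a motif-validated regulatory network, and a drug overlay — plus a
synthetic-data generator that makes every stage testable offline.

## Representative cells

Single-cell counts are sparse and high-resolution: a cell type is
represented by hundreds to thousands of noisy profiles. We collapse each
cell group (any categorical metadata column; cell type is the common
choice) into exactly *N* representative cells: the group is sub-clustered
into *N* sub-clusters and each sub-cluster is averaged per gene.

The sub-clustering algorithm is a genuinely open choice — any partitioner
of "neighboring cells" would do. We use k-means (k-means++ seeding, fixed
seed, up to 5 re-seeded retries if a cluster comes back empty) on the top
50 principal components (capped at group size − 1) of the group's z-scored
expression. This is deterministic given a seed, fast at 10^5 cells, and
standard. A graph-based (kNN/metacell) aggregator would respect manifold
structure better at extreme sparsity; it is deliberately out of scope.

Properties the implementation guarantees, and the tests assert:

* **Conservation** — per gene, the size-weighted sum over representative
  cells equals the sum over the original cells (relative error ≤ 1e-9);
  averaging loses no mass.
* **Equal representation** — every retained group yields exactly *N*
  representative cells; groups with fewer than *N* cells are dropped with
  a warning rather than silently represented at lower resolution.
* **Determinism** — identical input and seed give identical assignments.

*N* has no default: the right value depends on the depth and redundancy
of the data, so it is a required argument. Averaging happens on whatever
scale the input is on; the pipeline default normalizes counts to 10^4 per
cell and applies `log1p` first, since averaging raw counts lets deep cells
dominate.

## The weighted co-expression network

Gene–gene similarity is correlation across representative cells. The
default is the biweight midcorrelation: with `u_i = (x_i − med x)/(9 mad
x)` (`mad` unscaled), weights `w_i = (1 − u_i²)² · 1[|u_i| < 1]`, and
`x̃_i = (x_i − med x) w_i`, it is the inner product of the normalized
`x̃`. Median-based weighting makes it robust to the occasional extreme
representative cell; genes whose `mad` is zero (more than half their
values tied) have no robust scale and fall back to Pearson for all their
pairs. Spearman and Pearson are available.

Correlations become a **signed adjacency** `a_ij = ((1 + cor)/2)^β`
(default; `unsigned` and `signed_hybrid` variants are provided — the
hybrid zeroes all negative correlations). β is picked as the smallest
power in 1..20 whose scale-free fit index reaches 0.85 — the published
convention for this model family. The fit index is the R² of an OLS fit
of `log10 p(k)` on `log10 k` over 10 equal-width connectivity bins,
signed by the negated slope so that only decreasing degree distributions
score well. With few, strongly modular samples — exactly the
representative-cell regime — the connectivity distribution is often not
scale-free at any power, and we found the "pick the power with the best
fit" fallback then degenerates into noise-chasing: across simulation
seeds it would land anywhere from β = 4 (under-thresholding, background
genes absorbed into modules) to β = 19, purely on fit-index jitter. When
no power reaches the cut and the sample count is known, we therefore fall
back to the conventional sample-size-based default of this network family
(signed: 18/16/14/12 for < 20, < 30, < 40, ≥ 40 samples; half that,
roughly, for unsigned), with a warning; the per-power diagnostic table is
always returned so the choice can be inspected.

Adjacency is then converted to the **topological overlap matrix**,
`TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij)`, which
rewards shared neighborhoods and denoises weak direct links. Modules are
branches of average-linkage hierarchical clustering on `1 − TOM`.

The cited workflow family uses dynamic hybrid tree cutting. We implement
a **static cut** (default 0.995 × the tallest merge) plus a minimum
module size (30) and an eigengene-merge step (closest pair first, merging
while eigengene correlation ≥ 0.75): the static variant is deterministic
and fully testable, at the cost of less adaptive branch sensitivity on
real data; the cutter is a single internal function and can be swapped.
Clusters below the size cut join the unassigned (grey, label 0) pool.
With tied dissimilarities average linkage can produce floating-point
non-monotone merge heights; heights are clamped with a running maximum
before cutting.

Module summaries follow the standard definitions: the **eigengene** is the
unit-normalized first principal-component score of the module's z-scored
expression, sign-oriented so its mean correlation with members is ≥ 0
(a single-gene module uses that gene's z-score); `var_explained` is the
leading eigenvalue over the total. **kIM** is the within-module adjacency
sum (self excluded), **kME** the correlation of a gene with its own
eigengene (same correlation method as the network). **Hubs** are the
intersection of the top-10% rankings by kIM and by kME, ties broken
lexicographically — the two rankings measure different things (local edge
mass vs. alignment with the module profile) and their intersection is the
conservative reading of a "top 10% most connected" rule. Module–trait
association uses Spearman correlation of eigengenes against numeric
traits and one-hot expansions of categorical ones, with asymptotic
p-values and Benjamini–Hochberg adjustment across the whole matrix;
constant traits are reported as 0 and flagged rather than dropped, so the
output shape is predictable. Mean module expression is a defensible
alternative summary; we use eigengenes, the convention of this model
family.

## From module to regulatory network

Within a selected module, regulators are the module genes present in a
user-supplied TF list (exact, case-sensitive symbol match). Each module
gene is regressed on the TFs (minus itself) with stochastic
gradient-boosted regression trees: depth-3 trees, learning rate 0.01, 90%
row subsampling, a √p feature subset per tree, at most 500 rounds, and
early stopping when the mean out-of-bag improvement over the last 25
rounds is non-positive. These are the cited defaults of the boosting GRN
literature; the paper-scale alternatives (full GENIE3 random forests) are
slower without accuracy gain at module scale. A TF's importance for a
target is its total impurity (sum-of-squares) reduction across the
ensemble; pairs with positive importance become candidate edges, capped
at the 50 strongest per TF so the motif stage tests a bounded set.

The motif screen mirrors the cisTarget recovery-curve construction. A
motif database is a motifs × genes matrix of ranks (each row a
permutation of 1..G; rank 1 = best) plus a motif→TF annotation. For a
TF's candidate target set S, a motif's **recovery AUC** over the top `T =
⌈0.05·G⌉` ranks is `Σ_{r≤T} c(r) / (T·|S|)` with `c(r)` the members of S
ranked ≤ r; the **NES** standardizes that AUC against all motifs in the
database for the same S. Motifs annotated to the TF with NES ≥ 3 (the
conventional cut; "significant enrichment" is otherwise unquantified) are
enriched, and an edge survives only if its target lies in the **leading
edge** (the members of S inside the top-T region) of some enriched motif;
the best-NES supporting motif is attached to the edge. TFs with no motif
annotation lose all their edges and are flagged — passing them through
unvalidated would silently change the meaning of the output (an override
is available). Note the NES denominator includes the enriched motifs
themselves, so with few motifs (or a tiny gene universe, where the AUC is
coarse) the achievable NES is bounded; databases of ≥ ~20 motifs and a
few hundred genes behave well.

## Drug overlay

Drug–target links come from a local versioned snapshot TSV (columns
drug_id, drug_name, gene_symbol, action, source; a `# provenance:` header
line is echoed into outputs). Live drug databases update weekly, which is
exactly the reproducibility hazard a snapshot avoids. Mapping is an exact
symbol join against any gene set — whole module, hubs, or GRN nodes (the
workflow's figures use both module-level and GRN-level overlays, so both
entry points exist). The combined graph types every node (`gene`, `tf`,
`drug`; drug ids are prefixed `drug:` to keep the namespace unique),
keeps regulatory edges directed with their importance and supporting
motif, and represents drug–target links as `drug_target` edges
(semantically undirected). No interactome expansion or id conversion is
attempted: that is the job of dedicated services, and doing it half-way
here would be worse than not doing it.

## The synthetic generator

`simulate_counts` draws negative-binomial counts (`variance = μ + 0.5 μ²`
at the default dispersion) over a log-scale latent-factor model: each of
5 modules of 60 genes has a per-cell activity `z_m ~ Normal(μ_bm, 1)`
with blob-specific shifts `μ_bm ~ Normal(0, 1)` (5 blobs per group, 2
groups × 300 cells), gene log-means are uniform on [0.5, 3.0], module
genes load at 0.8 on their factor and each module's designated driver TF
at 1.0. These defaults are the package's reference study conditions: 600
cells and 1000 genes keep every test run in seconds-to-minutes while
leaving the module signal realistic rather than trivial (within-module
log-count correlations around 0.4–0.6).

The generator emulates the features the pipeline consumes — overdispersed
counts, modular correlation, sub-population structure, motif rankings
consistent with the planted regulons (`simulate_motif_db` places 90% of a
regulon in the top 5% of its true motif's ranking; decoy motifs are
uniform permutations, two of them annotated per TF), and a toy drug
table. It does **not** emulate dropout zero-inflation beyond the NB's own
zeros, batch effects, doublets, or gene-length/GC biases. Passing tests
therefore demonstrate algorithmic correctness and statistical power under
a clean generative model, not robustness to every artifact of real
droplet data.

One fixture pair under `inst/extdata/` (filenames prefixed `synthetic_`)
is hand-constructed rather than simulated: a 40-gene network and a drug
table whose join yields exactly 20 distinct drugs over 8 targeted genes,
pinning the summary-counting path to known values.

## Numerical notes and limitations

* Correlations are clamped to [−1, 1], symmetrized, and given an exact
  unit diagonal before any power transform.
* The linear-regulation benchmark (10 TFs, 5 targets at `3·TF1 + ε`,
  n = 200, 20 seeds) recovers the planted regulator as top-importance in
  ~100% of target×seed pairs, with candidate AUPR about 10× the planted
  density; the boosting is nevertheless a marginal-association method and
  will split credit between strongly collinear TFs.
* With only N representative cells per group the sample size for
  correlation is small; bicor needs ≥ 3 samples and benefits from N ≥ 10.
* Problem sizes in the test-suite and acceptance runs (600×1000 default
  scenario, 90–150-gene pipeline fixtures, 20-seed replicates) were
  chosen to exercise every code path at full statistical strength while
  keeping a complete run in minutes on one core.
* `run_pipeline` selects the GRN module either by explicit id or as the
  module with the largest |Spearman correlation| with a named trait — the
  same rule the case studies of this workflow family use to pick their
  condition-associated module.
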