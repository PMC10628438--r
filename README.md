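# scgrnet

Single-cell gene co-expression modules, motif-validated regulatory
networks, and drug-target overlays — one offline, fully testable R
workflow.

## The problem

Single-cell RNA-seq profiles thousands of cells per cell type, each a
sparse, noisy draw of transcript counts. Module-level co-expression
analysis (the WGCNA family) was designed for bulk samples and does not
transfer directly to this regime. `scgrnet` implements the workflow that
bridges the gap, for computational biologists who want to go from a count
matrix to testable regulatory hypotheses and drug repurposing candidates:

1. **Representative cells** — cells of each group (e.g. cell type) are
   sub-clustered into *N* sub-clusters (k-means on a PCA embedding of
   z-scored expression) and each sub-cluster is averaged into one
   representative cell, taming sparsity while giving every group the same
   number of samples.
2. **Weighted co-expression network** — pairwise gene correlation
   (biweight midcorrelation by default) is soft-thresholded into an
   adjacency `a_ij = ((1 + cor_ij)/2)^β` (signed network, default), with β
   chosen as the smallest power whose scale-free fit index `R²` reaches
   0.85. Modules are branches of average-linkage clustering on the
   topological overlap dissimilarity `1 − TOM`, summarized by eigengenes
   (first principal component), correlated with cell metadata (Spearman),
   and mined for hub genes (intersection of the top-10% kIM and kME
   rankings).
3. **Regulatory network** — for a module of interest, each gene is
   regressed on the module's transcription factors with stochastic
   gradient-boosted trees (GRNBoost2-style); TF importances define
   candidate edges. A cisTarget-style motif screen then keeps only edges
   whose target is recovered in the top 5% of an enriched motif's
   genome-wide ranking (recovery AUC standardized to NES ≥ 3), discarding
   correlated-but-unbound false positives.
4. **Drug overlay** — a local drug-target snapshot table is joined onto
   the network's genes and everything is exported as one typed
   gene/TF/drug graph (GraphML/TSV).

A negative-binomial synthetic-data generator with planted modules, driver
TFs, consistent motif rankings and a toy drug table makes the entire chain
verifiable without any external download.

## Worked example

```r
library(scgrnet)

sim  <- simulate_counts(seed = 1)            # 600 cells x 1000 genes, 5 planted modules
expr <- normalize_counts(sim$expr)           # counts per 1e4, log1p
pc   <- make_representative_cells(expr, "group", n_subclusters = 10, seed = 1)
pc
#> pseudocells: 20 representative cells (10 per group) from 600 cells

gcn <- fit_gcn(pc$expr)                      # bicor + signed network, auto power
gcn
#> gcn_fit: bicor/signed network, power 16; 5 modules, 0 genes unassigned
#> scale-free fit index: 0.150
summary(gcn)
#>    module size var_explained n_hubs
#> M1     M1  696     0.4941838     64
#> M2     M2  122     0.6548348      1
#> M3     M3   62     0.9300094      4
#> M4     M4   60     0.9650894      3
#> M5     M5   60     0.9503162      5
```

The five planted 60-gene modules are recovered — three cleanly (M3–M5,
eigengenes explaining ~95% of their variance), two merged into M2 because
their latent activities happened to correlate across these 20
representative cells — while the weakly correlated background genes pool
into M1 (adjusted Rand index vs. the planted labels: 0.97). With no power
reaching the scale-free cut on 20 samples, the fit falls back to the
conventional sample-size default β = 16 (flagged in a warning). Converting
one module into a motif-validated regulatory network and overlaying drugs:

```r
db  <- simulate_motif_db(sim$truth, seed = 2)
mod <- names(gcn$modules$labels)[gcn$modules$labels == 2]
grn <- fit_grn(expr, mod, unname(sim$truth$driver_tf), db, seed = 1)
grn
#> grn_fit: 84 motif-supported edges (from 100 candidates), 2 TFs

drugs <- simulate_drug_table(sim$expr$gene_ids, seed = 3)
dm    <- map_drugs(unique(c(grn$edges$tf, grn$edges$target)), drugs)
graph <- build_combined_network(grn, dm)
write_graphml(graph, "combined_network.graphml")
```

The whole chain also runs from files through one call,
`run_pipeline("config.yaml", "out/")`, or from a shell via
`inst/cli/scgrnet.R`; it writes per-stage TSV tables, a combined GraphML
network, and a JSON run report with all parameters, seeds and counts.

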