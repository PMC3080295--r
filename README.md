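# iknn — integrated k-nearest-neighbour discovery of gene biosignatures

`iknn` is an R package for query-driven gene signature discovery in
small two-condition expression studies (think half a dozen treated vs
half a dozen untreated samples). Purely data-driven signature hunting is
fragile at that scale, so `iknn` expands a short list of *query genes* —
expert picks, or the top differential-expression hits — into ranked
**neighbourhoods** of genes related to each query under two independent
kinds of evidence at once:

* **functional similarity** from curated Gene Ontology annotation:
  Lin's information-content measure
  `sim(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))` with `IC(t) = -log p(t)`,
  aggregated over the genes' annotation sets (highest-pair by default,
  best-match-average as an alternative), on non-IEA annotations;
* **co-expression**: the absolute Pearson correlation `|r|` of the two
  genes' standardized profiles across all samples.

Each candidate is ranked by the fused score `s = (SIM + |r|) / 2` and
the top *k* per query form its neighbourhood. Query genes plus
neighbourhoods define a **biosignature**, encoded either as one feature
per gene or as one feature per query (the mean expression of the query
and its neighbours), and evaluated as a treated-vs-untreated classifier
with a linear SVM (C = 100) under leave-one-out cross-validation,
summarized by the ROC AUC.

The package also provides: readers/writers for expression TSV, OBO,
GAF 2.x, edge lists, SIF and GraphML; a SAM-style moderated
*d*-statistic with permutation FDR for selecting data-driven queries; a
PPI partner-set baseline and neighbourhood-overlap statistics; a seeded
synthetic-cohort generator with planted co-expressed, functionally
coherent, treatment-responsive modules; and an end-to-end pipeline with
manifest and stage caching (`run_pipeline()`, plus a thin CLI at
`inst/scripts/iknn.R`).

## Worked example

Everything below runs on a simulated cohort, so it is fully
reproducible offline:

```r
library(iknn)

cfg <- sim_config(n_genes = 300, n_modules = 3, module_size = 10, seed = 42)
ds  <- simulate_dataset(cfg)   # expression + labels, ontology, annotations
fit <- iknn(ds$expr, ds$model, cfg$queries, k = 10)
summary(fit)
#>  query n_neighbors top_neighbor top_fused mean_fused
#>  G0001          10        G0002     0.978      0.934
#>  G0012          10        G0016     0.979      0.939
#>  G0023          10        G0030     0.980      0.941
```

Each of the three queries retrieved 10 neighbours with fused scores
near 1 — the planted module members, which share a deep ontology term
(SIM = 1) and a latent expression factor (|r| ≈ 0.8 plus the treatment
shift). Now compare signature encodings as classifiers:

```r
models <- list(
  biosignature(cfg$queries, "individual_gene",         name = "queries"),
  biosignature(fit,         "integrated_neighborhood", name = "queries+10NN"),
  biosignature(fit,         "individual_gene",         name = "all-genes"))
compare_models(models, ds$expr)
#>          name          representation n_features   auc
#>     all-genes         individual_gene         33 1.000
#>  queries+10NN integrated_neighborhood          3 1.000
#>       queries         individual_gene          3 0.972
```

The neighbourhood representation reaches AUC 1.0 with only 3 classifier
inputs — the averaged neighbourhood expression per query — where the
query-only model pays for its single noisy feature per query (0.972),
and matching the 33-gene model's performance at a tenth of its inputs.
Data-driven queries come from the SAM-style selector:

```r
de <- sam_de(ds$expr, n_perm = 500, seed = 42)
head(select_queries(de, fold_change_min = 1.7, fdr_max = 0.01))
#> [1] "G0014" "G0019" "G0023" "G0017" "G0033" "G0015"
```

— all planted module genes (fold-change ≥ 1.7 and q ≤ 0.01), ordered by
decreasing |d|. `auc_by_k()` sweeps k = 1..20, `neighborhood_overlap()`
compares kNN neighbourhoods with PPI partner sets, and
`export_network()` writes the fitted weighted networks as SIF/GraphML.

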