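---
title: "Integrated kNN gene biosignatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated kNN gene biosignatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iknn)
```

## The problem

Small two-condition expression studies — a handful of treated and
untreated samples on a microarray-scale gene set — are too underpowered
for purely data-driven signature discovery: thousands of genes, a dozen
samples, and an abundance of chance correlations. `iknn` implements a
query-driven alternative: start from a short list of genes a biologist
already suspects matter (or from the strongest differential-expression
hits), and expand each query into a *neighbourhood* of genes that are
related to it under two complementary kinds of evidence at once —
curated functional annotation and observed co-expression. The query
genes plus their neighbourhoods form a *biosignature*, whose ability to
separate treated from untreated samples is then estimated honestly with
leave-one-out cross-validation.

## The integrated score

For a query gene $g_i$ and a candidate $g_j$ the package computes two
unit-interval components and averages them:

$$ s(g_i, g_j) = \frac{SIM(g_i, g_j) + |r_{ij}|}{2}. $$

**Functional similarity.** Each gene carries a set of Gene Ontology
annotations $A_i$ (evidence-filtered; electronically inferred `IEA`
records are excluded by default so the corpus reflects curation).
Term-to-term similarity is Lin's information-content measure,

$$ sim(t_1, t_2) = \frac{2\,IC(\mathrm{MICA})}{IC(t_1) + IC(t_2)}, \qquad
   IC(t) = -\log p(t), $$

where $p(t)$ is the fraction of annotated genes in the namespace that
are annotated to $t$ or any of its descendants (propagation runs over
both `is_a` and `part_of` edges, since both express the hierarchy), and
the MICA is the common ancestor with maximal information content. The
logarithm base is natural; it cancels in Lin's ratio and only affects
reported raw IC values. A pair whose shared information is zero — in
particular two copies of the root, or two terms whose only common
ancestor is the root — scores 0, not 1: zero shared information content
is no similarity.

Gene-level similarity aggregates the term-pair matrix over
$A_i \times A_j$. The default, `max_pair`, takes the single highest
between-term similarity, the "highest between-term similarity"
aggregation; `best_match_average` (the common BMA variant) averages each
term's best match in the other set. Both are symmetric and bounded in
$[0, 1]$, and both are exposed because the field uses both; `max_pair`
is the default as the more conservative claim — two genes are as similar
as their most similar pair of annotations. A gene with no scoreable
annotation in the namespace has *undefined* similarity and is excluded
from the candidate pool rather than scored 0; namespaces are never
fused (BP and MF models are built and used independently, and a
signature that looks strong under BP may be unscoreable under MF simply
because curated MF annotations are sparser).

**Co-expression.** Pearson correlation between the two genes' profiles
across *all* samples, treated and untreated pooled — with a dozen
samples, conditioning the correlation on condition would halve an
already small $n$; the pooling choice is deliberate and documented
here because it is a genuine judgement call. The correlation is mapped
to $[0, 1]$ by the absolute value: strong negative co-regulation is
strong association. No further min–max rescaling is applied to either
component — the Lin-based similarity is already unit-interval by
construction and the absolute value *is* the normalization of the
correlation.

**Fusion.** The arithmetic mean, weighting the two sources equally.
There is no evidence-based reason to prefer one source a priori, and
the equal-weight mean keeps the score interpretable; alternative
weighting schemes are out of scope. If either component is undefined
(constant expression vector, no scoreable annotation), the pair is
excluded from ranking rather than imputed.

## Retrieval

`iknn()` standardizes every gene row to mean 0, sd 1 (sample sd;
zero-variance rows cannot be standardized, carry no correlation signal,
and are excluded with a warning), scores every query against the
eligible pool, and returns the top $k$ per query. Ranking is fully
deterministic: fused score descending, ties broken by ascending gene id
in the C locale. The neighbourhood at $k$ is exactly the $k$-prefix of
the full descending sort, so raising $k$ only ever appends members, and
`auc_by_k()` can sweep $k$ without re-scoring. The query itself is never
its own neighbour; *other* query genes remain eligible, because
signatures sharing genes across neighbourhoods are biologically
meaningful rather than an artefact to suppress.

## Classification

Two input representations turn a signature into a feature matrix:

* **integrated neighbourhood** — one feature per query: the per-sample
  mean of the standardized expression of the query and its neighbours.
  A 6-query signature presents exactly 6 classifier inputs regardless
  of $k$.
* **individual gene** — one feature per distinct gene in the signature.

Models are linear support vector machines (libsvm via `e1071`,
C-classification, linear kernel, complexity constant $C = 100$, no
internal rescaling — features are already standardized), evaluated by
leave-one-out cross-validation. The held-out decision score is the
sample's projection onto the *unit normal* of the training fold's
separating hyperplane, deliberately omitting the fold's intercept.
This is the one place the package departs from the most literal
"signed distance to the hyperplane": every leave-one-out training fold
is class-imbalanced by exactly one sample, the intercept absorbs that
imbalance, and pooling intercept-bearing scores across folds biases
the null AUC far below 0.5 (measured means 0.24–0.42 on permuted
labels). The normal projection differs from the signed distance only
by a per-fold constant, is exchangeable under label permutation
(measured null means 0.47–0.49), and leaves separable data at AUC 1.

Standardization is a single global pre-processing step, not re-done
inside each fold, mirroring the pipeline order in which the method is
used in practice. This leaks a small amount of held-out information
(the held-out sample participated in the row means and sds); with
$n = 12$ the effect is minor, but AUCs should be read as estimates
under that convention.

AUC is computed by the Mann–Whitney pairwise formula (concordant plus
half of tied pairs over $n_{pos} n_{neg}$, via midranks); the ROC
points returned by `roc_auc()` come from a threshold sweep, and the
trapezoidal area under them equals the pairwise value to within 1e-9 —
the two routes are checked against each other and against an
independent implementation in the test suite.

## Data-driven queries

`sam_de()` scores each gene with a moderated difference statistic
$d = (\bar{x}_t - \bar{x}_c)/(s + s_0)$, where $s$ is the pooled
standard error of the mean difference and $s_0$ a fudge constant that
stops near-zero-variance genes from dominating. $s_0$ defaults to the
median of the per-gene pooled standard errors — a deliberate
simplification of the original percentile-search calibration, chosen
because it is transparent, parameter-free and configurable; users who
need the original tuning can pass any $s_0 \ge 0$. False discovery
rates come from label permutations (exhaustive when the requested
number covers all distinct assignments, sampled under an explicit seed
otherwise): $q$ is the median permutation count of null $|d^*|$
exceeding the gene's $|d|$, divided by the observed count of genes at
least as extreme, clipped to $[0,1]$ and made monotone non-increasing
in $|d|$ by a step-up pass. Query selection applies a two-sided
anti-logged fold-change filter (ratio of group means on the raw
intensity scale, $\ge \tau$ or $\le 1/\tau$; intensities are treated as
log2, the usual microarray convention) together with a $q$ threshold,
defaults $\tau = 1.7$ and $q \le 0.01$.

Two behaviours of this estimator are worth knowing. First, it is
conservative when many strong effects are present: the shifted genes
themselves contaminate the permutation null, so the weakest member of
a planted set can receive a visibly non-zero $q$ even at a 3-sd shift.
Second, the median-count numerator is discrete — $q$ jumps from 0 to
$1/R$ (with $R$ genes called) the moment the median exceedance count
reaches 1. Both are properties of SAM-style permutation FDRs generally,
not quirks of this implementation; the test suite asserts the
realistically attainable versions (perfect selection precision,
near-complete recall) rather than idealized exact recovery.

## The synthetic cohort generator

`simulate_dataset()` emulates the study design every other module is
tested against: a 6 vs 6 two-condition cohort of log2-scale
intensities over 500 genes (defaults chosen to mirror a small
two-colour microarray experiment while keeping simulations fast), with
planted modules. Each module is a query plus 15 members that

* share a latent factor: $x = \sqrt{\rho}\, f_s + \sqrt{1-\rho}\,
  \varepsilon$, giving unit marginal variance and expected pairwise
  correlation exactly $\rho$ (default 0.7 — tight but realistic
  within-module co-expression). The latent-factor form was chosen over
  an explicit covariance matrix for $O(n)$ generation and exact control
  of the expected correlation;
* shift by $\delta$ sd units in treated samples (default 2, a strong
  but not degenerate treatment response; on the log2 scale this is a
  4-fold change);
* share a deep, high-IC term in a toy BP ontology (each module gets its
  own chain of depth 4 under the root; unrelated genes are annotated to
  shallow root children; occasional cross-edges make the graph a true
  DAG; every gene carries at least one curated annotation and a random
  fifth also carry an `IEA` record so evidence filtering is
  exercised).

`simulate_ppi()` adds an interaction network whose `fidelity` parameter
interpolates between perfectly informative (every member adjacent to
its query) and pure noise, which is what the neighbourhood-overlap
baseline comparisons need. All generators take explicit seeds and
restore the caller's RNG state.

What the generator does **not** emulate: probe-level artefacts, dye
bias, intensity-dependent variance, realistic GO topology (tens of
thousands of terms, multiple inheritance depth, annotation bias toward
well-studied genes), or correlated noise between unrelated genes.
Passing tests therefore demonstrate that the machinery is correct and
well-calibrated under a clean planted-signal model — not that the
method will rank biologically true neighbours above false ones on any
particular real dataset.

One structural property of the generator deserves emphasis because it
bounds what neighbourhood averaging can achieve: the module's shared
factor $f_s$ is common to the query's feature and to the
neighbourhood-mean feature, so averaging members reduces only the
idiosyncratic noise ($\sqrt{1-\rho}$ component) and cannot touch the
factor's variance. At $\rho = 0.7$ the neighbourhood feature's residual
sd is still $\approx \sqrt{0.7}$ of the query's, so with a strong
treatment effect both models operate near the AUC ceiling and the
neighbourhood model's advantage, while real on average, is overtaken by
12-sample AUC noise in roughly one replicate in ten. The package
reports this comparison as measured.

## Numerical and degenerate-input choices

* Duplicate expression rows for one gene id are averaged (replicate
  probes); disagreement beyond 1e-9 additionally warns.
* Missing values are rejected by default; per-gene mean imputation is
  an explicit opt-in, because the correlation step assumes complete
  vectors.
* Gene identifiers are case-sensitive strings used as-is; no silent
  aliasing between expression, annotation and network namespaces.
  `alt_id` aliases inside the ontology itself are resolved to canonical
  term ids.
* Constant vectors make correlation undefined (`NA`), never 0 or 1.
* The one-sample overlap t-test returns $t = 0, p = 1$ when all
  per-query counts are zero (the disjoint limit) rather than failing on
  a zero standard deviation.
* A degenerate SVM training fold (all-constant features) contributes a
  decision score of 0, which under midrank tie handling yields AUC 0.5.

## Problem sizes

The test suite and the acceptance script run on deliberately small
instances: cohorts of 40–500 genes at 6 vs 6 samples, ontologies of
10–50 terms for oracle comparisons, 50–100 simulation replicates for
recovery and power properties, 200 label permutations for null
calibration, and 300–500 permutations for FDR checks. These sizes were
chosen as the package's own trade-off between Monte-Carlo resolution
and a test suite that runs in well under a minute per file; all of the
properties they check are size-stable.

## Known limitations

* The exact aggregation form used by older similarity tools is not
  always documented; both `max_pair` and `best_match_average` are
  provided, and results should state which was used.
* LOOCV on 12 samples has coarse AUC granularity (multiples of 1/36);
  differences smaller than that are not meaningful.
* The permutation FDR is conservative in dense-signal regimes (see
  above).
* Global standardization before cross-validation is a documented,
  mild information leak.
* PPI baseline neighbourhoods are unranked; overlap comparisons against
  ranked kNN neighbourhoods use the whole partner set at every $k$.
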