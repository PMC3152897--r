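---
title: "Network-driven discovery of prognostic biomarkers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-driven discovery of prognostic biomarkers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmarker)
```

## The problem

After a myocardial infarction (MI), some patients preserve left-ventricular
function (ejection fraction, EF, above 40%) while others progress toward
heart failure (EF at or below 40%). Individual inflammation markers such as
CRP discriminate these outcomes poorly. netmarker implements a
systems-level alternative: start from a protein--protein interaction (PPI)
network of inflammation-related proteins, find its topologically critical
components, and test whether the genes behind those components separate
good from poor outcome in blood transcriptomes — ending in small, explicit
gene panels whose prognostic value is quantified by cross-validated AUC.

The pipeline has seven stages, each usable on its own:

1. **Network ingestion** (`read_network`, `largest_component`) — edge-list
   or SIF files are cleaned to a simple undirected graph (self-loops
   dropped, duplicate edges collapsed) and the analysis proceeds on the
   giant connected component.
2. **Topology** (`node_topology`, `rank_bottlenecks`) — node degree and
   *traffic* (betweenness centrality): for a node $v$,
   $$T(v) = \sum_{\{s,t\}:\, s \ne v \ne t} \frac{\sigma_{st}(v)}{\sigma_{st}},$$
   where $\sigma_{st}$ counts shortest $s$--$t$ paths and $\sigma_{st}(v)$
   those through $v$. High-traffic nodes are *bottlenecks*, the
   coordination points of the network.
3. **Module detection** (`greedy_modules`) — agglomerative modularity
   maximization over
   $$Q = \sum_c \left[\frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2\right],$$
   with $e_c$ the intra-module edge count, $d_c$ the module degree sum and
   $m$ the edge total: the observed in-module edge fraction minus its
   expectation when the module's proteins are paired at random with
   degrees preserved.
4. **Module characterization** (`enrich_modules`) — two-tailed Fisher
   exact tests of module membership against annotation gene sets (GO
   BP/CC, miRNA target sets, GMT format), Benjamini–Hochberg corrected,
   significance called at corrected $p < 0.01$.
5. **Differential expression** (`gene_de_scan`, `module_de`) — two-sided
   Mann–Whitney tests between outcome classes, per gene and per module
   mean-expression profile.
6. **Panel evaluation** (`loocv_evaluate`) — ridge-penalized logistic
   regression with leave-one-out cross-validation, summarized by the
   Mann–Whitney formulation of the AUC.
7. **qPCR support** (`pcr_normalize`) — relative expression
   $2^{\,\mathrm{Ct_{ref}} - \mathrm{Ct_{gene}}}$ against a housekeeping
   reference, for follow-up verification assays.

`run_pipeline()` chains the stages; every stage with missing inputs is
skipped, so network-only runs are supported.

## Conventions and parameters that matter

**Traffic convention.** Undirected, unordered source–target pairs,
fractional dependencies for tied shortest paths, endpoints excluded, no
normalization (Brandes accumulation, compiled). Published traffic tables
for this kind of analysis often use tool-specific scalings; absolute
traffic values therefore depend on the convention, but *ranks* — the
quantity the discovery step consumes — do not. Node pairs in different
components contribute nothing, so disconnected inputs are legal.

**Ranking ties.** Bottleneck ranks sort by traffic descending, then degree
descending, then identifier ascending; pipelines are reproducible without
a seed.

**Modularity null.** The "random pairing" expectation in $Q$ is realized
as the configuration-model term $(d_c/2m)^2$ — standard Newman–Girvan
modularity. The greedy merge considers connected module pairs only
(merging disconnected modules can never increase $Q$), breaks $\Delta Q$
ties toward the lexicographically smallest module-id pair, stops when no
merge improves $Q$, and returns the partition at the maximal $Q$
encountered. `min_size` (default 3, the smallest module size worth
reporting) only flags small modules; it never deletes them. The exact
number of modules produced on a given network is a property of the greedy
variant, not a contract of the method; `exhaustive_modularity()` provides
a brute-force global optimum for graphs up to 12 nodes as an independent
reference.

**Module statistics.** Per module we report NP (proteins), IntraMI
(internal edges), InterMI (edges leaving the module), TotInt =
IntraMI + InterMI, and MTraffic. Published module tables do not pin down a
single MTraffic formula, so this package defines it explicitly: the sum of
betweenness traffic over the module's nodes computed on the module's
induced subgraph. The counting identities (TotInt decomposition; intra
plus half of inter summing to the global edge count) are enforced by
tests.

**Enrichment background.** The universe defaults to the intersection of
the clustered network's genes with the annotation collection's universe —
the conservative choice when the analysis is confined to a curated
network; an explicit background can be supplied. Correction is applied
across all (module, term) pairs within one namespace. The two-sided
Fisher p uses the minimum-likelihood rule (sum of all hypergeometric
outcomes no more probable than the observed table); no mid-p. Enrichment
results on real annotation snapshots are inherently release-dependent.

**Mann–Whitney modes.** Exact enumeration-based p for $n_1 + n_2 \le 20$
without ties, otherwise the normal approximation with tie and continuity
corrections. A constant gene yields $p = 1$ (all ties). Direction is
reported separately as the sign of (median poor − median good); tests are
two-sided throughout.

**Module-level statistic.** Gene-set differential expression is defined
here as the Mann–Whitney test on the per-sample *module mean-expression
profile* (unweighted mean over module genes with data; missing genes are
dropped and counted). Published analyses of this design used a gene-set
scoring tool whose precise statistic is not reproducible from the
description; the module mean matches how module signals are fed to the
classifiers and is the package's fixed, documented choice.

**Classifier.** Ridge logistic regression maximizes
$\ell(\beta_0, \beta) - \lambda \lVert\beta\rVert_2^2$ with the intercept
unpenalized; the default $\lambda = 10^{-8}$ reproduces the
near-unpenalized setting used with standard machine-learning toolkits
while keeping the optimum finite on separable folds. Fitting is by
iteratively reweighted least squares with step halving; convergence when
the largest parameter change or the relative penalized-deviance change
falls below `tol` ($10^{-8}$). Inputs are standardized to mean 0,
variance 1 (population convention). `scaler_scope = "fold"` (default)
takes scaling statistics from each training fold only — the leakage-free
choice; `"global"` reproduces whole-dataset scaling for comparability with
analyses that scaled before cross-validating. "Poor" outcome is the
positive class and scores are predicted probabilities.

**LOOCV behavior worth knowing.** With balanced classes, leaving one
sample out tilts the training prevalence against the held-out sample's
class; an uninformative feature therefore scores *below* 0.5 AUC on
average (anti-learning), which the test suite asserts. AUC uses the
rank/pair formulation with ties counted 0.5.

**Panel assembly rules.** Three families mirror how candidate models are
built from the network: (1) mean profiles of modules with corrected
differential-expression $p \le 0.05$; (2) the individual genes of those
modules; (3) the union of nominally DE ($p \le 0.02$) top-`top_k`
bottleneck genes and DE genes from the selected modules. The two
thresholds are the levels at which reported hits of this design pass and
are configurable.

## What the synthetic generators emulate

The generators make every stage testable without downloads, under a fixed
RNG (Mersenne–Twister, inversion normals), so outputs are identical across
platforms for a given seed.

* `synth_network` — planted-partition graphs: ground-truth modules with
  within-block probability `p_in` and between-block `p_out`.
* `synth_expression` — a balanced 16/16 good/poor cohort (the size of the
  post-MI microarray cohort this design targets) on a log-intensity-like
  scale: baseline + Gaussian noise, with chosen genes shifted in the poor
  class by effects expressed in noise-sd units, so power statements are
  scale-free. EF values are drawn consistently with the 40% rule (good:
  uniform 45–73; poor: uniform 20–40, the printed cohort ranges).
* `synth_annotations` — random gene sets of size 5–50 plus planted terms
  included verbatim.
* `synth_ct` — small qPCR tables in a plausible 15–35 cycle range with a
  low-variance housekeeping gene.

`synth_study_preset()` bundles the study-shaped conditions used by the
end-to-end demo and the acceptance script: ~2500 nodes as one 5-node block
(the planted prognostic module, sized like the small informative modules
of curated inflammation interactomes) plus 166 blocks of 15, `p_in = 0.30`
and `p_out` set for an expected between-block degree of 0.5 (overall mean
degree ≈ 4.7, matching a sparse curated PPI network); +1.5 sd effects on
the module's 5 genes and on the giant component's three top-traffic
bottlenecks; a planted annotation term equal to the module's genes; an
11-sample Ct table. Problem sizes throughout the tests (e.g. 200-gene null
matrices, 100-seed calibration loops, exhaustive searches up to 10–12
nodes) were chosen so the whole suite completes in about a minute while
keeping every estimate's Monte-Carlo error far below the asserted margins.

What the generators do **not** emulate: probe-level microarray artefacts,
correlated co-expression within modules, miRNA expression, hub-dominated
degree distributions, or survival outcomes. Two consequences seen in the
shipped results should be read accordingly. First, planted-partition
degrees are narrowly distributed, so the degree–traffic Spearman
correlation on synthetic networks (≈ 0.6) is weaker than on real scale-free
PPI networks (≈ 0.9). Second, greedy modularity maximization has the
well-known resolution limit: single bridging edges can merge small blocks
into super-modules, so the preset's 5-gene module is often absorbed into a
larger community — its mean-profile signal dilutes and module-level DE may
stay non-significant even though the enrichment stage pinpoints the
planted term and the gene-level and panel stages recover the prognostic
signal. Passing tests certify the statistical machinery, not microarray
realism.

## Numerical choices and degenerate inputs

* Empty networks error on component extraction; edgeless networks error
  on modularity. An empty graph reports mean degree 0. Mean degree is
  always $2m/n$; summaries of curated networks occasionally print other
  ratios, and this package does not attempt to match them.
* Fisher tables with an empty margin give $p = 1$; the enumeration uses a
  relative tolerance of $10^{-7}$ when comparing table probabilities.
* Benjamini–Hochberg is the standard step-up procedure (via
  `stats::p.adjust`), validated against the direct formula in tests.
* Constant classifier features pass through standardization as zeros with
  a warning rather than dividing by zero.
* The degree–traffic correlation p-value uses a label-permutation null
  with the add-one estimator $(1 + k)/(1 + B)$, so it is never exactly 0;
  $B = 10{,}000$ by default, matching the resolution at which such
  correlations are conventionally reported. An asymptotic t-approximation
  is available.
* Missing expression values fail fast; no imputation policy is assumed.

## Known limitations

* Identifiers are opaque case-sensitive strings; mapping between probe,
  gene and protein namespaces is upstream curation.
* The greedy clusterer is the classic agglomerative variant; Louvain,
  Leiden and overlapping methods are out of scope, as are GO-graph
  propagation and annotation-bias corrections.
* Cross-platform verification (fit on one expression dataset, score
  measurements from another) is supported as a generic operation
  (`train_test_evaluate`); reproducing any particular published
  cross-platform AUC requires the original measurement tables.
* Headline AUCs of the motivating study depend on its cohort data (GEO
  GSE11947) and unpublished qPCR values; the package reproduces the
  method, and its shipped numbers come from the synthetic study-shaped
  conditions above.

## A short worked run

```{r demo, eval = FALSE}
pre <- synth_study_preset(seed = 1)
cfg <- pipeline_config(network = pre$network, expression = pre$expression,
                       annotations = pre$annotations, ct = pre$ct,
                       n_perm = 2000, seed = 1)
report <- run_pipeline(cfg)
report$network_summary
head(report$bottlenecks)
min(report$enrichment$p_adj)
report$evaluations[[1]]
```

See the README for the concrete numbers this run prints and
`scripts/acceptance.R` for the full recomputation of the package's
headline quantities.
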