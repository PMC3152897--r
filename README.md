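# netmarker

Network-driven discovery of prognostic gene-expression biomarkers from
protein–protein interaction (PPI) data, built around outcome prediction
after myocardial infarction (MI) from blood transcriptomes.

## Who this is for

Translational bioinformaticians who have (a) a curated PPI network for a
disease context, (b) a two-class gene-expression cohort (here: good vs
poor post-MI outcome, defined by left-ventricular ejection fraction above
vs at-or-below 40%), and optionally (c) annotation gene sets (GO, miRNA
targets) and qPCR Ct tables — and who want to go from network topology to
small, evaluated biomarker panels in one reproducible pipeline.

## What it computes

Individual inflammation markers (CRP, IL6, TNF) discriminate post-MI
outcomes poorly; the premise of this workflow is that the network's
*structurally critical* genes do better. The stages:

1. **Network ingestion** — edge-list/SIF files cleaned to a simple
   undirected graph; analysis on the giant connected component.
2. **Bottleneck ranking** — node degree and traffic (betweenness
   centrality): `T(v) = Σ_{s,t} σ_st(v)/σ_st`, shortest-path flow through
   each node; ranked descending with deterministic tie-breaks, plus a
   permutation-tested Spearman correlation between degree and traffic.
3. **Module detection** — greedy agglomerative maximization of
   Newman–Girvan modularity `Q = Σ_c [e_c/m − (d_c/2m)²]` (observed
   in-module edge fraction minus its degree-preserving random
   expectation), with per-module statistics (NP, IntraMI, InterMI,
   TotInt, MTraffic).
4. **Module enrichment** — two-tailed Fisher exact tests against GMT
   gene-set collections, Benjamini–Hochberg corrected (significance at
   corrected p < 0.01).
5. **Differential expression** — two-sided Mann–Whitney tests between
   outcome classes, per gene and per module mean-expression profile.
6. **Panel evaluation** — ridge-penalized logistic regression
   (λ = 1e-8, intercept unpenalized, fold-scoped standardization) under
   leave-one-out cross-validation, summarized by AUC (rank formulation,
   ties 0.5).
7. **qPCR normalization** — relative expression
   `2^(Ct_reference − Ct_gene)` against a housekeeping gene.

Seeded generators (`synth_network`, `synth_expression`,
`synth_annotations`, `synth_ct`, `synth_study_preset`) produce
planted-truth inputs with the statistical structure the analysis assumes,
so every stage is testable offline.

## Worked example

```r
library(netmarker)

pre <- synth_study_preset(seed = 1)   # study-shaped synthetic inputs
cfg <- pipeline_config(network = pre$network, expression = pre$expression,
                       annotations = pre$annotations, ct = pre$ct,
                       n_perm = 2000, seed = 1)
report <- run_pipeline(cfg)

report$network_summary
#>   n_nodes n_edges mean_degree n_components giant_size giant_edges
#> 1    2495    5764    4.620441           10       2485        5763

head(report$bottlenecks, 3)
#>   protein degree  traffic traffic_rank
#> 1   G2230     10 98826.60            1
#> 2   G2106      9 88359.15            2
#> 3   G1103      7 81706.15            3

min(report$enrichment$p_adj)
#> [1] 0.000584955

report$evaluations[[1]]
#> panel_evaluation 'bottleneck_module_union': LOOCV AUC = 0.914 (n = 32)
```

Reading the numbers: the generated interactome has ~2500 proteins at mean
degree ≈ 4.6 with a giant component of 2485 nodes. The bottleneck table
ranks nodes by shortest-path traffic; the preset plants +1.5 sd
poor-outcome expression shifts on the top three bottlenecks and on a
5-gene module, emulating the empirical pattern that both carry prognostic
signal. The planted annotation term is recovered by module enrichment at
corrected p ≈ 6e-4, and the assembled panel of differentially expressed
bottleneck genes separates good from poor outcome with leave-one-out AUC
0.914 on the 16/16 cohort.

A thin command-line front end is included:

```sh
Rscript inst/scripts/netmarker-cli.R simulate --seed 1 --out-dir sim/
Rscript inst/scripts/netmarker-cli.R run-all --network sim/network.tsv \
    --expression sim/expression.tsv --phenotype sim/phenotype.tsv \
    --annotations sim/annotations.gmt --seed 1 --out-dir results/
```

## Documentation

The methods vignette
(`vignettes/network-biomarker-discovery.Rmd`) documents the model
conventions (betweenness and modularity definitions, enrichment
background, the module-mean differential-expression statistic, classifier
and scaling choices), what the synthetic generators do and do not
emulate, numerical edge cases, and known limitations.
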