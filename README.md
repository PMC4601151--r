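# gutdyn

Ecological time-series analysis of gut bacterial communities: who is
interacting with whom, in which direction, and what that implies about
community structure.

Dense longitudinal 16S profiles (daily stool samples over hundreds of
days) allow a stronger claim than co-occurrence: if today's abundance of
genus *j* predicts tomorrow's **change** in genus *i*, the data support a
directed biotic interaction *j* → *i*. For every ordered genus pair,
`gutdyn` fits the first-difference regression

    x[i, t+1] − x[i, t] = α(i,j) + β(i,j) · x[j, t]

on natural-log relative abundances, calling the slope significant at the
99 % confidence level (p ≤ 0.01). On top of the resulting n² interaction
matrix the package provides:

- **Preprocessing** — the standard cascade: per-day deduplication,
  singleton removal, 20,000-read library floor, common scaling (the
  expectation-preserving alternative to rarefying), genus-level
  collapsing, 0.01 % mean-abundance floor, log transform with explicit
  missingness for zero counts.
- **Network ecology** — pair categories (cooperation +/+, competition
  −/−, exploitation +/−, commensalism +/0, amensalism −/0), PI/PD/NI/ND
  connectedness per genus, phylum summaries normalized per genus and per
  unit abundance (the keystone/foundation diagnostics), Shannon-diversity
  versus phylum-abundance models.
- **Hypothesis tests** — limiting similarity (are within-phylum
  interactions more negative than between-phylum ones?), with the same
  test on precomputed reverse-ecology competition/complementarity
  indices; co-occurrence (Spearman) versus regression slopes, with a
  3-df spline fit for non-linear relationships.
- **Robustness** — the subsampling protocol: thin every model to a
  ladder of maximal point counts (250…25), 100 replicates per level,
  reporting coefficient correlation with the full model and power of
  detection.
- **Temporal enterotyping** — sqrt-Jensen–Shannon distances, PAM
  clustering, silhouette/Calinski–Harabasz cluster-number selection,
  PCoA, and a Wald–Wolfowitz runs test for temporal clustering of
  enterotype labels.
- **A synthetic community simulator** — latent log-abundance dynamics
  with a known interaction matrix, observed through softmax fractions
  and multinomial sequencing counts, so every stage is testable without
  external data (`make_benchmark()` regimes: `null`, `sparse`, `dense`,
  `enterotype-switch`).

## Worked example

```r
library(gutdyn)

ds  <- make_benchmark("sparse", seed = 42, n_taxa = 10, n_days = 300)
pre <- run_preprocess(ds$table, ds$taxonomy)
net <- infer_network(pre)
net
#> interaction_network: 10 taxa, 29 significant of 100 possible (29.0%), neg:pos 1.07

category_prevalence(classify_pairs(net))$fractions
#>  cooperation  competition exploitation commensalism   amensalism
#>    0.3571429    0.0000000    0.0000000    0.2857143    0.3571429

conn <- connectedness(net, pre$taxonomy)
head(conn[order(-conn$total), ], 3)
#>      taxon PI PD NI ND total         phylum
#> 3 Genus_01  6  8  0  0    14  Bacteroidetes
#> 6 Genus_08  1  0  3  0     4     Firmicutes
#> 7 Genus_04  1  1  0  2     4 Proteobacteria

enterotype_pipeline(pre)
#> enterotype_result: k = 2 (weak clustering), mean silhouette 0.234
```

Reading these numbers: all 10 intra-genus (diagonal) models are
significant and negative — the planted density-dependent self-limitation
— and 19 off-diagonal interactions are found, a mix of the planted links
and compositional common-mode associations (see the vignette). The
dominant, Bacteroidetes-like `Genus_01` is the most connected genus and
almost exclusively through positive interactions, the foundation-taxon
signature. The single-regime simulation earns a *weak clustering*
verdict from the enterotyping module (best mean silhouette 0.234 < 0.25),
so no enterotype-switching analysis is reported for it.

The full workflow, writing every artefact (β/p/n matrices, significance
mask, connectedness, categories, phylum summaries, co-occurrence,
enterotype series, test results, manifest and frozen config) into a
directory:

```r
res <- run_all(ds$table, ds$taxonomy, "out/", default_run_config())
report(res)
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/gutdyn.R`
(`Rscript gutdyn.R simulate|preprocess|infer|run-all|report ...`).

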