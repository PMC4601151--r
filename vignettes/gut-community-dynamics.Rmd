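---
title: "Inferring biotic interactions from gut community time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring biotic interactions from gut community time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutdyn)
```

## The problem

Cross-sectional microbiome surveys can tell us which taxa co-occur, but
co-occurrence is a weak proxy for interaction: two taxa may covary because
one feeds the other, because they compete for the same niche, or merely
because both respond to the same environment. Dense longitudinal sampling
of a single ecosystem — here, daily stool profiles of individual human
guts over hundreds of days — permits a stronger claim: if today's
abundance of genus *j* systematically predicts tomorrow's *change* in
genus *i*, the data support a directed biotic interaction from *j* to
*i*. `gutdyn` implements that inference, the ecological characterization
of the resulting interaction network (who cooperates, who competes, which
taxa are keystone- or foundation-like), and the temporal enterotyping of
the same series.

## The interaction model

For every ordered pair of genera $(i, j)$ the package fits

$$x_{i,t+1} - x_{i,t} = \alpha_{i,j} + \beta_{i,j}\, x_{j,t} + \varepsilon$$

where $x_{i,t}$ is the natural-log relative abundance of genus $i$ on day
$t$. The slope $\beta_{i,j}$ measures the effect of $j$ (the independent,
acting taxon) on the dynamics of $i$ (the dependent, acted-upon taxon).
The diagonal model $i = j$ captures intra-genus density dependence and is
expected to be strongly negative: a genus far above its typical abundance
tends to fall back. With $n$ modelled genera the system has $n^2$
equations. This is a linear, first-order, pairwise approximation: strongly
non-linear relationships, higher-order (three-way) effects and
environment-mediated interactions are outside its scope, and slopes on
relative abundances are not identical to interactions between absolute
populations (see *Compositionality* below).

A model is retained when its slope's two-sided $t$-test reaches
$p \le 0.01$ (a 99 % confidence level). Deliberately, no multiple-testing
correction is applied across the $n^2$ models — the per-model confidence
level is the convention this analysis follows; a Benjamini–Hochberg
adjustment can be layered on the returned $p$ matrix by the user if
desired.

### Data preparation

Six steps precede modelling, in a fixed order:

1. one sample per day (largest library kept; ties resolved to the first
   occurrence, deterministically);
2. singleton taxa removed (total count of one across the whole study);
3. samples under 20,000 reads removed (strict less-than);
4. *common scaling*: every count multiplied by (smallest library /
   sample library), the expectation-preserving alternative to rarefying —
   scaled counts are kept as reals;
5. collapse to genus level by summing counts over identical lineage
   paths; taxa with no genus label are grouped at their finest named rank
   as `unclassified-<rank>-<name>`;
6. taxa under 0.01 % mean relative abundance removed (per-sample
   fractions averaged unweighted over samples).

Because common scaling is a per-sample multiplication it cancels in
relative abundances; it matters only for count-level operations. The mean
relative abundance in step 6 is computed from the scaled table, which is
equivalent to unweighted averaging of per-sample fractions.

For the regressions themselves, a sample is usable as a time-$t$ point
only when a sample exists on the day directly after it; the successor
supplies $x_{t+1}$ even if it is not itself usable as a time-$t$ point.
Genera present in fewer than half of the usable samples are excluded
(a taxon at exactly 50 % is retained). Log zero is undefined, so a
transition enters the pair dataset only when all three of $x_{i,t}$,
$x_{i,t+1}$ and $x_{j,t}$ come from non-zero counts; models with fewer
than 50 such points are excluded rather than fitted.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_reads` | 20000 reads | library-size floor (step 3) |
| `min_mean_frac` | 1e-4 | mean relative-abundance floor (step 6) |
| `min_prev` | 0.5 | prevalence floor for modelled taxa |
| `min_points` | 50 points | minimum non-zero points per model |
| `alpha_level` | 0.01 | per-model significance level |
| `subsample_levels` | 250…25 | robustness ladder (points per model) |
| `subsample_reps` | 100 | replicates per ladder level |
| `sil_threshold` | 0.25 | weak-clustering silhouette verdict |

All defaults live in `default_run_config()` and a frozen copy of the
resolved configuration is written with every `run_all()` output.

## Network characterization

Each unordered pair is classified from the signs of its two directed
slopes, a non-significant direction counting as 0: cooperation (+/+),
competition (−/−), exploitation (+/−), commensalism (+/0), amensalism
(−/0). Per-taxon connectedness counts significant off-diagonal
interactions by sign and role — positive/negative × dependent (row) /
independent (column), the PI/PD/NI/ND scheme; their sum is the degree of
connectedness. Phylum summaries divide these counts by the number of
observed genera (mean connectedness) and by the phylum's mean relative
abundance. The abundance normalization is counts divided by the mean
abundance *fraction* — a phylum at 1 % abundance with the same
interaction count as one at 50 % scores fifty-fold higher — which is the
operational signature of a keystone-like group (rare but influential),
whereas a foundation-like group is abundant, highly connected and
disproportionately positive.

Two regression diagnostics accompany the counts: the positive *fraction*
of a genus's interactions regressed on its total degree (a zero slope is
the proportional null; a positive slope means hubs are disproportionately
cooperative), and a one-way ANOVA of per-genus positive counts on phylum.
The diversity link is assessed by regressing the Shannon index (natural
log, so in nats, consistent with the package-wide log convention) on the
log relative abundance of a focal phylum — across individuals using
per-individual means, or within an individual across samples. The
between-individual mode needs at least three individuals, the
within-individual mode at least 30 samples with the phylum present.

## Limiting similarity and reverse ecology

The limiting-similarity hypothesis predicts stronger competition between
more closely related taxa. The test pools slopes of significant models for
within-phylum pairs and between-phylum pairs and compares the pools with
a Wilcoxon rank-sum test. Intra-genus (diagonal) slopes are always
strongly negative and always within-phylum, so the test is run both with
and without them. Both the two-sided p and the directional
("within more negative") one-sided p are reported, since the hypothesis
is directional but the test itself is not.

The same comparison applies to genome-derived reverse-ecology indices:
for every ordered species pair the difference
(complementarity − competition) is formed, the diagonal excluded, and
within- versus between-phylum values compared. The index table is
consumed pre-computed; no metabolic-network reconstruction happens here.
The species set can first be restricted to the phyla present in the
time-series data.

## Robustness and co-occurrence

`subsample_robustness()` re-runs the whole fitting protocol after
randomly thinning every pair's points to a ladder of maxima (default
250, 200, 150, 125, 100, 75, 50, 25), 100 replicates per level. Two
metrics are averaged: the Pearson correlation between reduced and full
slopes — computed over off-diagonal pairs fitted in *both* runs, since
thinned models can fall under the point floor — and the power of
detection, significant off-diagonal models relative to the $n^2$ possible
interactions. The model-size floor drops from 50 to 25 at the 25-point
level, otherwise no model could survive there. The diagonal is omitted
from both metrics. All replicates flow from one seed and are
bit-reproducible.

`cooccurrence_matrix()` computes contemporaneous Spearman correlations
between relative-abundance series (zeros included — Spearman is invariant
to the log transform elsewhere, so only the zeros distinguish the two
scales), over exactly the modelled taxa. `cooccurrence_vs_beta()` relates
co-occurrence to the inferred slopes by Spearman correlation over
significant models (an `all_models` switch includes every fitted pair)
plus a natural cubic spline regression with 3 degrees of freedom whose
F-test accommodates non-linear relationships; a full penalized GAM is
deliberately not used, as 3 fixed degrees of freedom inside ordinary
least squares reproduce the intended test transparently.

## Enterotyping

Community profiles are compared with the square root of the
Jensen–Shannon divergence (natural log, $0\log 0 = 0$, no pseudocounts),
which is a proper metric with maximum $\sqrt{\ln 2}$ for disjoint
supports. Clustering is partitioning around medoids on the full
genus-level profile — the four classic driver groups (*Bacteroides*,
*Prevotella*, *Ruminococcus*, *Blautia*) are reported per cluster for
interpretation but are not the clustering input, so that cluster
discovery is not biased toward the expected drivers. The number of
clusters is scored over k = 2…10 by mean silhouette width and by the
Calinski–Harabasz index computed on PCoA coordinates (the distance is
non-Euclidean, so CH needs a Euclidean embedding; all
positive-eigenvalue axes are retained and negative eigenvalues are
reported). The two criteria often disagree on weakly structured data;
when even the best mean silhouette stays below 0.25 the verdict is "no
strong clustering" and no switching analysis is reported. The 0.25
threshold is a configurable default chosen so that silhouettes in the
low-0.2 range — conventionally read as weak structure — do not trigger a
switching report; it is not a universal constant.

Temporal clustering of the two-state label series is tested with the
Wald–Wolfowitz runs test: few runs means the states form blocks in time.
The exact run-count distribution (a hypergeometric-type closed form) is
used up to n = 20, the normal approximation with continuity correction
beyond. The binary runs test on the chronological label sequence is the
classic form of the statistic; it is only defined for two states, hence
it is reported exactly when two enterotypes are found.

## The synthetic community simulator

Because the original sequencing datasets are external, the package ships
a generative model that mirrors the estimation model: latent unnormalized
log abundances follow
$y_{t+1} = y_t + \alpha + B\,y_t + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$, initialized at the deterministic fixed
point and run 100 burn-in steps; stationarity requires the spectral
radius of $I + B$ below 1 and is checked before simulation. Observation
is compositional: daily fractions are the softmax of $y_t$, library
sizes are log-normal around 25,000 reads, counts are multinomial, and
days can be dropped or duplicated to emulate real sampling schedules.
Default communities are heavy-tailed (power-law target fractions) over
six phyla with the first phylum holding about half the community, and
self-interactions of −0.5 throughout.

Benchmark regimes: `null` (diagonal-only $B$), `sparse` (5 % of
off-diagonal entries at $|B| = 0.3$), `dense` (20 % at 0.15), and
`enterotype-switch` (two drift regimes alternated in time blocks, with a
strong positive effect of a Bacteroides-like genus on a Prevotella-like
genus and a weaker positive reciprocal, the configuration associated with
switching).

### Compositionality, and what the simulator does and does not emulate

The softmax observation deliberately breaks exact identifiability:
regressions see relative, not absolute, abundances, so every observed
series carries a shared renormalization term. Two measured consequences
(all numbers below are computed by the test suite at the stated sizes,
not assumed):

- *Attenuation and common-mode coupling.* Planted links are recovered
  with correct sign but shrunken magnitude, and independent latent taxa
  show spurious off-diagonal significance at rates well above the nominal
  level (about 9 % at 20 taxa / 300 days with a strongly dominant taxon).
  This is the classic spurious-correlation problem of compositional data,
  and it affects the real analysis equally; it is a property of the
  data-generating process, not a software defect.
- *Calibration of the test itself.* On Gaussian white-noise log-abundance
  series — a true null with serially independent regressors — the
  empirical off-diagonal significance rate at $p \le 0.01$ is close to
  nominal (measured ≈ 0.010–0.011 over 100 replicates of 20 taxa × 300
  days). On latent AR(1) null series the test is conservative (rate
  ≈ 0.001), because first-differencing induces negative error
  autocorrelation while the regressor is positively autocorrelated.
  The type-I calibration check therefore uses the white-noise null, where
  the null hypothesis actually holds at the observation level.

Parameter-recovery checks consequently target the *signs* and *relative
magnitudes* of $\beta$ on planted links (sign agreement of significant
recovered links, Spearman rank agreement over planted links), never
$\alpha$ or absolute $\beta$ magnitudes.

The simulator does not emulate: day-of-week or dietary covariates,
overdispersion beyond multinomial sampling (no Dirichlet-multinomial
observation layer), taxon birth/extinction, non-Gaussian process noise,
or strain-level dynamics. Passing recovery tests on simulated data
therefore demonstrates internal consistency of the pipeline under its own
model class, not that real gut series satisfy that model.

## Numerical choices and degenerate inputs

- Pairwise OLS is closed-form (centered sums of squares) with the
  two-sided slope $t$-test; it agrees with a normal-equations oracle to
  1e-8 over 1,000 random datasets in the test suite.
- Excluded pairs (too few points, constant predictor) are `NA` in all
  matrices and are distinguishable from fitted-but-non-significant pairs.
- Wilcoxon tests are exact when tie-free and the smaller sample has at
  most 8 observations; otherwise the normal approximation with midrank
  tie and continuity corrections is used.
- PAM uses the BUILD+SWAP implementation of the `cluster` package in
  dissimilarity mode; results are deterministic for a fixed distance
  matrix. Samples in singleton clusters get silhouette 0.
- PCoA drops negative-eigenvalue axes (reporting the eigenvalues); on
  Euclidean input it reproduces distances to 1e-8.
- A day with several samples keeps the largest library; exact ties keep
  the first occurrence, so re-running is deterministic.
- All stochastic procedures (simulation, subsampling) consume one seed
  and are bit-reproducible.

## Problem sizes used in the shipped checks

The test suite and the acceptance script validate the pipeline at desk
scale: 10–20 taxa, 150–300 days, 20 recovery seeds, 50–100 replicates for
calibration and robustness, 100-sample enterotype mixtures. These sizes
were chosen so that every property is measurable with tight Monte-Carlo
error while the whole suite completes in about a minute; the pipeline
itself has no hard-coded size limits and scales as $n^2$ models times the
series length.

## Known limitations

- Pairwise regressions ignore confounding by third taxa; a significant
  slope is evidence of association in dynamics, not proof of a direct
  mechanistic interaction.
- Relative-abundance compositionality induces common-mode associations
  (measured above) that no per-pair test can remove; absolute-abundance
  inference would require spike-ins or flow-cytometric scaling, out of
  scope here.
- The per-model 99 % confidence convention controls no family-wise error
  across $n^2$ models.
- Enterotype labels from PAM are forced partitions; the weak-clustering
  verdict, not the labels, should be consulted first on unstructured
  data.
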