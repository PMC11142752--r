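---
title: "Methods: splicing heterogeneity analysis with spliceHet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing heterogeneity analysis with spliceHet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceHet)
```

## Scope and model overview

spliceHet implements a reusable pipeline for studying alternative-splicing
(AS) heterogeneity across tumor cohorts, of the kind used to dissect adult
glioma: percent-spliced-in (PSI) quantification from junction counts,
variability-based event filtering, consensus subtype discovery, a
random-forest splicing signature with a survival-directed AS score,
single-cell pseudobulk splicing, an RNA-binding-protein (RBP) correlation
screen, and splice-site sequence features. Every stage is exercised
end-to-end on a synthetic-data generator with known ground truth, so each
claim a test makes is a claim about recoverable, planted structure.

## PSI estimation

For a two-isoform skipped-exon-style event with inclusion reads $I$,
skipping reads $S$ and effective lengths $l_I$, $l_S$ (distinct read
positions supporting each isoform), the point estimate is the
length-normalized plug-in value

$$\hat\psi = \frac{I\,l_S}{I\,l_S + S\,l_I},$$

the same form rMATS-style counters report. For uncertainty we model reads in
*read space*: $I \sim \mathrm{Bin}(I+S,\theta)$ with
$\theta = \psi l_I / (\psi l_I + (1-\psi) l_S)$. A uniform prior on
$\theta$ yields the closed-form posterior $\theta \sim \mathrm{Beta}(I+1,
S+1)$, and PSI quantiles follow exactly through the strictly increasing map
$\psi = \theta l_S/(\theta l_S + (1-\theta) l_I)$. This is a deliberate,
documented deviation from MISO's isoform-space prior: it buys an exact
closed form (no MCMC) while keeping concordance statistical rather than
bit-exact. The posterior mean is reported separately from the plug-in MLE
so both MISO-style and rMATS-style summaries are available.

Numerical conventions:

* The 95% interval is equal-tailed, except at count boundaries: $I=0$
  yields the one-sided $[0, q_{95}]$ and $S=0$ yields $[q_{05}, 1]$. The
  posterior is unchanged; this is a reporting convention so that boundary
  estimates carry boundary intervals.
* Entries with fewer than `min_reads = 10` informative reads are
  undetected; the cutoff is unspecified upstream and exposed in the API.
* Frequentist coverage of the interval (checked on 10,000 simulated events
  with $\psi \sim U(0,1)$, $n = 50$) sits in the 93.5–96.5% band; the only
  slack comes from count discreteness.

## Event filtering and sample QC

Samples with more than 40% undetected events are dropped. An event is kept
iff, over its detected entries: range $> 0.6$, SD $> 0.1$ (with the $n-1$
denominator), and the 95% CI width is $< 0.5$ in more than 80% of samples.
Inequalities are strict exactly as written. Two decisions the upstream
description leaves open: criterion (c)'s denominator counts *detected*
samples only, and events must additionally be detected in at least half the
QC-passed samples (prevents two-sample "high variance" artifacts); both are
configurable.

## Consensus subtype discovery

Consensus k-means: each of `n_iter` iterations subsamples 80% of samples,
z-scores each event row, standardizes each sample profile (which makes
Euclidean k-means equivalent to Pearson-correlation geometry), and runs
k-means with 10 restarts. The consensus matrix is the co-clustering
frequency among co-sampled pairs; final labels cut an average-linkage tree
of `1 - M` at `k = 2` (a CDF delta-area report for k = 2..6 is available
for transparency). Missing PSI values are median-imputed per event before
clustering. Representative samples are the global top-N by silhouette width
on `1 - M`, positive widths only; singleton-cluster silhouettes are defined
as 0. Whether representative selection should be balanced across clusters
is unknown upstream; global top-N is used.

A caveat the tests made explicit: when clusters are well separated, the
consensus matrix is *exactly* binary — no sample ever flips across
iterations — so every silhouette equals 1 and selection among ties is
arbitrary. Silhouette-based exclusion of boundary samples is therefore only
observable (and only tested) in regimes where clusters genuinely overlap.

## Random-forest signature and AS score

Events are ranked by Mean Decrease Gini (MDG) from a bootstrap CART forest
classifying the discovered cluster labels (Rcpp implementation; no suitable
forest package is assumed present). Two defaults deviate from the classical
`randomForest`-era settings, for measured reasons:

* **`n_trees = 2000`, not 500.** With ~1,300 candidate events, 500 trees
  leave the importance ranking unconverged: top-200 precision against
  planted truth was 0.87–0.92 for both this implementation and
  scikit-learn's forest on identical inputs, rising to 0.95–0.98 for both
  at 2,000 trees. Trees are cheap (~2 s); ranking stability is not.
* **`min_node = 10` (minimum leaf size), not 1.** Leaf-size-1 trees memorize
  stray samples from the latent overlap region in tiny leaves, leaking Gini
  importance onto uninformative events; the reference implementation shows
  the identical effect. A moderate leaf floor keeps the ranking on
  reproducible structure.

`mtry` stays at $\lfloor\sqrt{p}\rfloor$ and no class weighting is applied.

Groups: the worse-survival cluster is the one with lower median
Kaplan-Meier survival (log-rank recorded; exact ties require an explicit
override). An event joins group 1 if its mean detected PSI is higher in the
worse cluster, else group 2; the top 20 by MDG are kept per group. The
upstream direction rule is ambiguous between cluster-based and
survival-continuous readings; the cluster rule is the default with
`direction_by = "survival"` as the alternative. The AS score is the mean
detected group-1 PSI minus the mean detected group-2 PSI, `NA` unless each
group has `min_detected = 10` detected events. Scoring never refits:
frozen groups transfer across datasets, with absent events simply reducing
support.

## Survival layer

Thin plumbing over the `survival` package: median-split Kaplan-Meier with
log-rank, and a multivariable Cox fit (`ties = "efron"`) for hazard ratios
per unit score with 95% CIs. Categorical covariates are treated as factors;
constant or duplicated covariates are rejected; non-convergence warnings
propagate.

## Single-cell pseudobulk

Junction counts are *summed* over cells sharing a (patient, cellular-state)
label before PSI estimation — never averaged per cell — which is what
rescues detection at sparse per-cell coverage. Filters mirror the reference
thresholds (pseudobulks with < 50 detected signature events dropped, events
detected in < 100 pseudobulks dropped) with fraction-valued alternatives
for small simulations, because insisting on the absolute numbers at toy
scale would be dishonest. Hierarchical clustering follows Cluster 3.0:
uncentered correlation $u(x,y)=\sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$
over pairwise-complete entries, distance $1-u$, centroid linkage with
distances recomputed between merged centroids, lowest-index tie-breaking
and input-order leaves for determinism.

## RBP screen

Spearman correlation of each RBP's expression with the AS score per
dataset, BH-adjusted within dataset; an RBP is "consistent" iff $q <
0.05$ with the same sign in *every* dataset (the upstream description
states the outcome, not the rule; both the adjustment and $\alpha$ are
exposed). At single-cell resolution, events detected in more than 200
cells are correlated with RBP expression over the cells where the event is
detected, and the correlation matrix is clustered with the Cluster-3.0
routine.

## Sequence features

GC content is profiled over the window (default 100 nt) immediately
upstream of the 3' splice site and compared between sets by rank-sum test.
Splice-site strength uses three log-odds models over MaxEntScan-convention
windows (5'SS 9-mer, 3'SS 23-mer): a position weight matrix (WMM), a
first-order inhomogeneous Markov model (MM1), and a dinucleotide
composition model (DINUC), each trained with 0.5 pseudocounts. The
identity of the three models used upstream is not public; these are
declared stand-ins. Motif enrichment uses per-sequence presence/absence of
IUPAC matches (U≡T both ways) — not occurrence counts, to avoid length
confounding — with Fisher's exact test and Haldane-corrected odds ratios;
de novo k-mer scanning ranks by BH q then odds ratio.

## The synthetic world

`sim_config()` states the world once; tests never tune it after the fact:

* Latent score $s_i$: equal-weight mixture of two Betas with modes 0.25 and
  0.75 (the observed continuum with two cluster modes). The shared
  concentration is not stated upstream and is explicitly delegated to
  testability: the default (40) keeps a graded continuum while leaving
  component overlap below 0.1%, so cluster-recovery tests measure the
  pipeline rather than mixture overlap (an earlier guess of 18 put ~3% of
  samples across the midpoint and capped the best achievable ARI at
  ~0.88–0.92 for any method).
* Informative events: logit-scale slopes $\pm 6$ acting on $s_i - 1/2$,
  intercepts uniform on logit [0.15, 0.85] (centering keeps both modes
  visible instead of saturating); realized PSI is Beta with concentration
  100; reads are negative-binomial (mean 100, size 10) with binomial
  inclusion counts in read space; effective lengths default to $l_I = 2$,
  $l_S = 1$.
* Survival: exponential with hazard $\propto \exp(\beta \cdot AS_i^{true})$,
  $\beta = \log 3$, under uniform administrative censoring whose horizon is
  solved (uniroot) so the expected censored fraction equals the target 30%.
* RBPs: 29 of 276 coupled at target Spearman 0.8 (normal-rank mixing at the
  Pearson level $2\sin(\pi\rho_S/6)$, then a monotone log-normal transform),
  half positive, half negative.
* Single cell: patients carry latent scores; states carry scores on a
  [0.1, 0.9] grid; the pseudo-population latent value is their mean;
  per-cell coverage is Poisson (default mean 2 — sparse, mostly zeros).
* Sequences: i.i.d. background at GC 0.45, planted degenerate motifs
  (CYCUCY / CUBCCY upstream/downstream of excluded exons, CYUCWKC in
  included exons) and a −0.1 GC offset in the included-set 3'SS-upstream
  window.

What a green test establishes — and what it does not: the generator plants
exactly the structure the analysis assumes (monotone logit couplings,
independent events given the latent score, exponential survival,
state-structured cells). Real cohorts add batch effects, correlated events,
alignment artifacts, subtype mixtures beyond two, and non-proportional
hazards, none of which are emulated; recovery here validates correctness of
the machinery, not performance on any real cohort. Reference cardinalities
(1,300 events, 200 signature events, 40 score events, 29/276 RBPs,
thresholds 50/100/200) are used as design constants, not as numbers this
package claims to reproduce from data.

## Scale-downs and budgets

Stated scale-downs, used by the default test run: consensus clustering runs
200 resampling iterations instead of the reference 1,000; survival-recovery
replicates simulate only the 200 signature events (the AS score reads
nothing else); module tests shrink problem *sizes* but never generator
*parameters*. The acceptance suite runs the full stated scales.

## Known limitations

Two-isoform events only (multi-isoform PSI rows are rejected at ingestion);
no read-level simulation or alignment artifacts; no branch-point model; the
cluster count defaults to 2 with only a transparency report for other k;
MISO concordance is statistical, not bit-exact.
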