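# spliceHet

Alternative-splicing (AS) heterogeneity analysis for bulk and single-cell
tumor RNA-seq, written for the kind of question asked in adult glioma:
does a tumor cohort stratify by its exon-skipping landscape, is that
stratification prognostic, and which upstream regulators and sequence
features travel with it?

The package takes per-event inclusion/skipping junction counts and

1. estimates **PSI** (percent spliced in, ψ ∈ [0,1]) per event and sample
   with a 95% credible interval, using the length-normalized plug-in
   estimate ψ̂ = I·lS / (I·lS + S·lI) and a closed-form Beta posterior in
   read space (`estimate_psi`, `build_psi_matrix`);
2. applies sample QC and the three-criterion event filter
   (range > 0.6, SD > 0.1, CI width < 0.5 in > 80% of samples;
   `qc_samples`, `filter_events`);
3. discovers subtypes by **consensus k-means** under Pearson geometry and
   selects representative samples by silhouette width
   (`consensus_cluster`, `select_representatives`);
4. ranks events by random-forest **Mean Decrease Gini**, splits the top
   events into survival-directed groups, and computes the **AS score** =
   mean(group-1 PSI) − mean(group-2 PSI) (`rank_events_by_mdg`,
   `assign_groups`, `as_score`);
5. couples the score to survival with Kaplan-Meier/log-rank and a
   multivariable Cox model (`km_logrank`, `cox_multivariable`);
6. aggregates single-cell junction counts into cell-state **pseudobulks**
   and clusters them Cluster-3.0-style (uncentered correlation, centroid
   linkage; `aggregate_pseudobulk`, `hcluster_cluster3`);
7. screens **RBP expression** against the AS score across datasets and
   against event PSI at single-cell resolution (`correlate_rbp_score`,
   `consistent_rbps`, `rbp_event_correlation`);
8. profiles **sequence features**: GC content upstream of the 3' splice
   site, splice-site strength under three log-odds models, and degenerate
   IUPAC motif / de-novo k-mer enrichment (`gc_profile`,
   `train_splice_model`, `motif_enrichment`, `denovo_kmers`).

A first-class synthetic-data generator (`sim_config`, `simulate_bulk`,
`simulate_sc`, `simulate_rbp`, `simulate_sequences`) emulates the
statistical structure of multi-cohort glioma splicing data with known
ground truth — a latent per-sample score with two cluster modes, events
coupled positively or negatively to it, survival driven by the true AS
score, coupled RBPs, state-structured sparse single-cell coverage, and
planted motifs — so every stage is validated by recovery of planted
structure. See `vignettes/splicing-heterogeneity-methods.Rmd` for the
model, parameter choices and limitations.

## Worked example

```r
library(spliceHet)

cfg    <- sim_config(n_samples = 150, n_events = 400, n_informative = 100, seed = 7)
sim    <- simulate_bulk(cfg)
psi    <- build_psi_matrix(sim$counts, sim$events)
qc     <- qc_samples(psi)
kept   <- filter_events(subset_psi(psi, samples = qc$kept))$kept
res    <- consensus_cluster(subset_psi(psi, events = kept), k = 2,
                            n_iter = 100, seed = 7)
reps   <- select_representatives(res, 100)
model  <- rank_events_by_mdg(subset_psi(psi, samples = reps), res$labels,
                             n_select = 60, seed = 7)
model  <- assign_groups(psi, model, res$labels, sim$metadata)
scores <- as_score(psi, model)
km     <- km_logrank(scores, sim$metadata)
cox    <- cox_multivariable(scores, sim$metadata, covariates = c("age", "sex"))
```

Output printed by this run:

```
PsiMatrix: 400 events x 150 samples; 100.0% detected
events kept by the three criteria: 100
ConsensusResult: k=2, 150 samples, 100 iterations
 1  2
75 75
ARI vs planted clusters: 1
SignatureModel: 400 ranked events; groups 20/20 (worse cluster: 2)
log-rank p: 1.12e-07
      term    hr ci_low ci_high        p
1 as_score 2.877  1.935    4.28 1.79e-07
2      age 1.003  0.984    1.02 7.93e-01
3     sexM 0.839  0.570    1.23 3.72e-01
Spearman(AS score, latent truth): 0.997
```

Reading it: the 100 planted informative events are exactly the ones that
survive the variability filter; consensus clustering recovers the planted
subtypes perfectly (adjusted Rand index 1); the signature model picks 20
events per survival direction from the worse-survival cluster 2; and the
fitted per-unit hazard ratio of the AS score (2.88, CI 1.9–4.3) brackets
the planted hazard ratio of 3 while the score tracks the hidden latent
score at Spearman 0.997.

## Command line

One executable with subcommands mirroring the stages:

```sh
exec/splicehet simulate --preset bulk --config sim.cfg --seed 1 --outdir out/
exec/splicehet psi      --counts out/junction_counts.tsv --events out/events.tsv --outdir out/
exec/splicehet filter   --counts out/junction_counts.tsv --events out/events.tsv --outdir out/
exec/splicehet cluster  --psi out/psi_wide.tsv --k 2 --iterations 1000 --seed 1 --outdir out/
# ... signature, score, survival, pseudobulk, rbp-screen, seqfeat
```

Each run appends a JSON-lines record (command, config hash, seed, version)
to `out/manifest.jsonl`.

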