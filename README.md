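# armsig

Arm-wise copy-number signatures and mutation associations in tumour
cohorts.

## What this is for

Aneuploidy — the gain and loss of whole chromosomes and chromosome arms —
is one of the most visible features of cancer genomes, and its pattern
differs sharply between tumour types. `armsig` is an R toolkit for
quantifying those patterns from standard segmented copy-number data and
relating them to somatic mutations. It is written for analysts working
with TCGA-style cohorts (SEG copy-number segments, MAF mutation calls,
UCSC cytoBand centromere tables) and for method developers who need a
fully synthetic, ground-truthed cohort to validate arm-level analyses
against.

The pipeline:

1. **CCN conversion** — segment means (log2 ratios) become linear-scale
   chromosomal copy number, CCN = 2^s × 2, so diploid = 2.
2. **Filtering** — segments below the cohort's 25th length percentile or
   with fewer than 10 probes are removed.
3. **Arm projection** — segments are split at centromeres and averaged
   (overlap-weighted) into a patients × 39-arm CCN matrix.
4. **Mutation-vs-ploidy screen** — per gene, a Welch t-test of
   genome-wide |segment mean| between mutated and wild-type patients,
   Bonferroni-corrected over the top 250 most mutated genes.
5. **Arm-pair correlations** — Pearson r within tissue, with permutation
   significance (1000 relabellings of one arm).
6. **Arm-ploidy signatures** — non-negative matrix factorisation
   X ≈ H Wᵀ of the CCN matrix (Lee–Seung multiplicative updates), with the
   rank chosen from consensus cophenetic stability over seeded restarts
   and each patient assigned to its argmax signature.
7. **Signature–mutation statistics** — cosine distance between median
   signature compositions of mutated vs wild-type patients
   (label-permutation p), and within-signature mutation enrichment
   against a Monte-Carlo hypergeometric null.
8. **Classification** — random forest (1000 trees, min leaf 30), SVM,
   Bernoulli naive Bayes and ridge logistic regression predicting
   mutation status from arm profiles; ROC AUC with a 0.70 pass cutoff and
   permutation feature importance on the held-out test set.

A seeded generator (`make_truth()` / `simulate_cohort()`) emits SEG/MAF
cohorts with planted signatures, exposures and gene couplings, so every
stage above has a recovery test with known truth.

## Worked example

Simulate the default synthetic cohort (300 patients, 4 planted
signatures), run it through the pipeline, and check signature recovery:

```r
library(armsig)

truth <- make_truth(synthetic_config(), seed = 1)
coh   <- simulate_cohort(truth, seed = 2, dir = tempdir())

fl <- filter_segments(read_seg(coh$seg))
fl$report
#>   n_input n_retained n_removed_length n_removed_probes length_threshold_bp
#> 1   38710      27622             9678             1410             3837181

am <- arm_matrix_from_segments(fl$segments, truth$arm_table)
dim(am)
#> [1] 300  39

scan <- select_rank(am, 2:6, n_runs = 30, seed = 3)
scan$scan
#>  k cophenetic n_runs
#>  2  0.9991150     30
#>  3  0.9946004     30
#>  4  0.9984199     30
#>  5  0.9877006     30
#>  6  0.9818006     30

fit <- nmf_factorize(am, 4, seed = 4)
fit
#> Arm-ploidy signature model: k = 4, 300 patients x 39 arms
#>   objective: frobenius, 500 iterations, reconstruction error 76.74

match_signatures(truth$W_true, fit$W)$cosine
#> [1] 0.988 0.992 0.996 0.991
```

The filter removed 25% of segments by length (the injected short
contaminants plus the shortest real segments) and 1410 more for probe
support. Factorising at the planted rank recovers all four planted
signatures with matched cosine similarity ≥ 0.988. The cophenetic profile
is tight at this seed (all ranks ≥ 0.98): stability differences between
candidate ranks are small on a single cohort draw, which is why the rank
is best read from the scan across replicates, and why both the
local-minimum selection and the argmax candidate are reported.

The mutation screens behave as planted: the five global-shift genes (whose
carriers gain ±0.3 in |segment mean| genome-wide) top the ploidy ranking,
e.g.

```r
mm <- build_mutation_matrix(read_maf(coh$maf), rownames(am))
ps <- patient_summary(fl$segments)
res <- rank_genes_ploidy(setNames(ps$abs_segmean, ps$patient_id), mm,
                         setNames(ps$mean_ccn, ps$patient_id))
head(res[, c("gene", "n_mut", "direction", "p_raw", "p_bonferroni")], 3)
#>      gene n_mut direction    p_raw p_bonferroni
#> 1 GENE006    84      gain 8.44e-07     0.000211
#> 2 GENE009    88      gain 1.08e-06     0.000270
#> 3 GENE010    77      gain 1.73e-06     0.000432
```

(GENE006–GENE010 are the planted global-shift genes in this cohort.)

`run_pipeline()` chains all stages from a config list or YAML file and
writes every result table plus a checksummed manifest; see
`?run_pipeline` and the vignette in `vignettes/arm-ploidy-signatures.Rmd`
for the models, parameter meanings and design choices.

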