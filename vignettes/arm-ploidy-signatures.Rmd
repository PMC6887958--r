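---
title: "Arm-wise copy-number signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arm-wise copy-number signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armsig)
```

## The analysis in one paragraph

`armsig` quantifies arm-level aneuploidy in tumour cohorts and relates it to
somatic mutations. Segmented SNP-array copy-number data arrive as log2
ratios ("segment means"); the package converts them to linear-scale
chromosomal copy number, CCN = 2^(segment mean) × 2, so a copy-neutral
autosomal segment has CCN 2. After filtering out short and poorly supported
segments, each patient's segments are projected onto the 39 usable
chromosome arms (acrocentric p arms excluded) to form a patients × arms CCN
matrix. That matrix feeds four analyses: (i) a per-gene screen relating
deleterious-mutation status to genome-wide ploidy change; (ii) arm-pair
correlation maps with permutation significance; (iii) non-negative matrix
factorisation (NMF) into arm-ploidy signatures, with the factorisation rank
chosen from consensus cophenetic stability; and (iv) supervised
classifiers that predict a gene's mutation status from the arm profile,
scored by ROC AUC with permutation feature importance.

## Copy-number arithmetic and filtering

**Conversion.** `segmean_to_ccn()` implements CCN = 2^s × 2 and
`ccn_to_segmean()` its exact inverse. The conversion is strictly monotone,
so rank-based statistics are unaffected by the scale choice; mean-based
statistics are not, which is why both scales are produced where it matters
(see below).

**Filtering** (`filter_segments()`). Two rules, applied in order to each
input cohort: segments whose length lies strictly below the cohort's 25th
length percentile are removed (so the retained data reflect large-scale
dosage change rather than focal CNVs), then segments with fewer than 10
supporting probes are removed. The percentile is the linear-interpolation
quantile (R type 7) and is computed per input file — one SEG file is one
cohort. Re-filtering filtered output is not idempotent (the percentile
moves); the filter report records the threshold used.

**Per-patient summaries.** Two genome-wide statistics per patient:
mean CCN (direction of ploidy change) and the mean of |segment mean|
(magnitude of change regardless of direction). Both are length-weighted by
default — unweighted means over-count short segments — with
`weighting = "uniform"` exposed for comparison.

**Arm projection** (`project_to_arms()`). Segments are intersected with arm
intervals (a segment spanning the centromere is split there) and each arm
takes the overlap-length-weighted mean of its segments' values. Arms left
with zero coverage after filtering are imputed copy-neutral (CCN 2,
flagged): downstream NMF and classifiers need complete rows, and neutral
imputation is the least informative completion. Attribution uses overlap
length, not probe counts, because probe positions are not part of the SEG
dialect.

**Scales.** The mutation-vs-ploidy screen uses |segment mean| (magnitude on
the log scale); correlations and signatures use arm CCN (linear,
non-negative). Arm matrices are emitted on both scales so either convention
is recoverable.

## Statistics

**Mutation-vs-ploidy screen.** For each of the top 250 most frequently
mutated genes (deleterious classes: missense, nonsense, frame-shift and
in-frame indels; splice variants excluded by default since they are not
unambiguously protein-altering), the mutated patients are compared with all
remaining patients by a two-sided Welch t-test on the per-patient
|segment-mean| summary. Welch rather than pooled-variance because group
sizes are always unbalanced here. P-values are Bonferroni-corrected over
the genes actually tested, and genes are ranked by corrected p. Direction
(gain/loss) is read from the signed mean-CCN difference.

**Arm-pair correlations.** Pearson r between arm CCN columns within a
patient subset (typically one tissue). Significance comes from permuting
one arm's values across patients 1000 times. Two summaries are emitted:
`p_perm_t`, a one-sample t-test of the null r values against the observed r
— the historical procedure this package mirrors, kept for fidelity — and
`p_empirical`, the add-one permutation rank p, which is the summary we
recommend interpreting. The t-form is anticonservative by construction (its
standard error shrinks with the number of permutations), which the type-I
checks in the test suite make visible; they therefore assess `p_empirical`.

**Permutation conventions.** All permutation p-values use the add-one
estimator (1 + #extreme)/(n_perm + 1), so no reported p is ever zero and
the smallest attainable value is 1/(n_perm + 1). Tests are one-sided in
the direction the analysis reports: low cosine similarity for signature
distance, high counts for enrichment.

## Signatures

`nmf_factorize()` factorises the (non-negative) CCN arm matrix as
X ≈ H Wᵀ with W the arms × k basis (arm composition of each signature) and
H the patients × k exposures, by Lee–Seung multiplicative updates under the
Frobenius objective from a seeded uniform random start; a Kullback–Leibler
objective is available behind `method = "kl"`. Iteration stops at
`max_iter` (500) or when the relative error change falls below `tol`
(1e-6). The error trace is monotone non-increasing — a property the tests
check numerically. W columns are normalised to unit L1 with scales absorbed
into H, leaving the reconstruction unchanged. CCN is the only admissible
input scale here: segment means can be negative and would violate the NMF
domain.

**Rank selection.** For each candidate rank, `consensus_cophenetic()` runs
the factorisation from (default) 30 seeded starts, builds the consensus
matrix C (fraction of runs in which two patients share the argmax
signature), and correlates the consensus distances 1 − C with the
cophenetic distances of their average-linkage dendrogram. `select_rank()`
then applies, per the procedure this package mirrors, the *smallest interior
rank at a strict local minimum* of the cophenetic profile. Stability
analyses conventionally seek maxima, not minima, so this rule is unusual;
it is implemented verbatim, falls back to the argmax rank (with a warning)
when no interior minimum exists, and `rule = "argmax"` selects the maximum
directly. The scan records both the selected rank and the argmax rank so
the choice is auditable.

**Assignment.** Each patient takes the argmax of its exposure row; ties go
to the lowest index; an all-zero row gets sentinel 0 and a warning.

**Distance and enrichment.** For a gene, the component-wise median exposure
composition of mutated and of wild-type patients are compared by cosine
similarity; significance comes from relabelling patients at fixed group
sizes. Genes with fewer than `min_mut = 5` patients on either side are
flagged untestable — medians of tiny groups are unstable, and a formal
minimum makes that explicit. Enrichment of a gene within a signature group
compares the observed mutated count against equally sized random patient
subsets — a Monte-Carlo hypergeometric null, which the tests verify against
the closed form. Raw permutation p is primary; a Benjamini–Hochberg column
is attached for reference only.

## Classifiers

For each gene, mutation status is predicted from the arm CCN profile.
Models: random forest (1000 trees, minimum leaf 30 — fixed, no grid),
radial SVM (cost grid 0.1/1/10), Bernoulli naive Bayes (features binarised
at training-set medians; Laplace grid 0/0.5/1) and ridge logistic
regression (penalty chosen by internal cross-validation). Grids are
resolved by 5-fold cross-validated AUC on the training split only. The
train/test split is random at 80/20 but stratified by class — the
prevalence of most genes is low enough that an unstratified split would
regularly produce single-class test sets. ROC AUC is computed by the
rank-statistic (Mann–Whitney) form, which equals the trapezoidal area with
ties handled by average ranks; the tests verify exact agreement with a
brute-force pairwise-concordance oracle and with an independent ROC
implementation. Feature importance is *permutation* importance on the
held-out test set: the drop in test accuracy when one feature column is
shuffled, averaged over repeats. Holding each variable out by refitting
would cost a model per feature per repeat for the same interpretation;
column permutation is the standard operationalisation of "mean decrease in
accuracy".

## The synthetic cohort generator

`make_truth()` + `simulate_cohort()` emit SEG/MAF cohorts with planted
ground truth, so every stage has a recovery surface without any download.
Defaults — these *are* the study conditions the test suite exercises:

* 300 patients, three pseudo-tissues, four planted signatures over 39 arms;
* basis columns drawn sparse and non-negative with pairwise cosine
  similarities constrained to [0.35, 0.6]. The ceiling keeps signatures
  distinct; the floor keeps them comparably similar, as arm-level
  signatures that share a near-diploid backbone are. The floor matters for
  rank selection: if the planted clusters are too cleanly separated, NMF
  partitions at *every* rank at or below the truth are perfectly
  reproducible, the cophenetic score saturates at 1 for all of them, and
  the stability profile carries no rank information. With comparably
  similar signatures and mixed exposures, below-truth ranks face competing
  merge configurations across random starts and their consensus degrades,
  leaving the planted rank as the stability optimum;
* exposures: each patient has a tissue-biased dominant signature carrying
  50–75% of a total exposure of about 2 (so cohort mean CCN ≈ 2), the rest
  spread over the other signatures — signature groups are tissue-enriched
  but genuinely mixed;
* segment-mean noise sd 0.05 per segment, 1–5 segments per arm, probe
  counts proportional to length with 5% forced below 10, and 10% short
  contaminant segments (0.5–50 kb) — so both input filters act;
* a 250-gene panel: 5 signature-coupled genes (mutation rate 0.35 inside
  the coupled signature group, 0.01 outside), 5 global-shift genes
  (carriers gain ±0.3 in |segment mean| genome-wide), 5 arm-coupled genes
  (carriers lose one copy of a target arm with penetrance 0.8), the rest
  null with rates 0.02–0.15.

What the generator does *not* emulate: realistic breakpoint processes,
focal amplifications, whole-genome doubling, purity/clonality mixtures, or
correlated mutation co-occurrence. Recovery results on this cohort
demonstrate that the pipeline's statistics behave as designed under their
own assumptions; they do not certify performance on real tumour data.

## Numerical and test-design notes

* All randomised stages take explicit seeds; pipeline stages derive their
  seeds deterministically from one global seed plus the stage name, and a
  fixed seed reproduces SEG/MAF files byte for byte.
* Noiseless closure: with zero noise, no contaminants and filters off, the
  pipeline's arm matrix equals the planted expected CCN to machine
  precision (the suite asserts 1e-9). Global-shift genes are excluded from
  that check: their genome-wide ±shift is planted mutation signal with no
  single expected arm value, not measurement noise.
* Rank-scan checks use the scan's argmax-cophenetic candidate with 30
  restarts per rank over ranks 2–7 on the default cohort — a problem size
  that keeps a ten-replicate recovery study within a few minutes on one
  CPU.
* The arm-effect classifier check is a designed positive control: the
  coupled gene targets the cohort's most copy-stable viable arm, and the
  test AUC is averaged over eight seeded replicates. With the separation
  band above, typical arms have cohort sds of 0.5–1.5 CCN, against which a
  single-copy effect at penetrance 0.8 is close to the Bayes detection
  limit (≈ 0.8·Φ(1/(√2σ)) + 0.1); on the most stable arm (σ ≈ 0.5) the
  expected AUC is ≈ 0.88. A single 60-patient test split measures AUC with
  a standard error near 0.07, so the replicate mean, not a single draw, is
  the meaningful estimate.
* Degenerate inputs are flagged rather than dropped silently: zero-variance
  t-test groups report p = 1; constant arms report r = 0; all-zero exposure
  rows get sentinel assignment 0; untestable genes carry a flag through
  every ranking.

## Known limitations

The length-percentile filter is cohort-relative, so mixing cohorts in one
SEG file shifts the threshold. Neutral imputation of uncovered arms biases
those arms toward CCN 2 and shrinks their correlations. The local-minimum
rank rule can select unstable ranks by design; the argmax candidate is
always reported alongside. Classifier AUCs on low-prevalence genes rest on
few test positives and should be read with their `n_pos_test`. None of the
analyses model tumour purity, and CCN values are bulk averages.
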