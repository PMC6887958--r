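# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# Default-condition synthetic cohort, parsed and filtered, with its arm
# matrix and mutation matrix.
get_default_cohort <- function() {
  if (!is.null(.fixtures$default)) return(.fixtures$default)
  truth <- make_truth(synthetic_config(), seed = 42)
  coh <- simulate_cohort(truth, seed = 43,
                         dir = file.path(tempdir(), "armsig_fixture_default"))
  seg <- filter_segments(read_seg(coh$seg))$segments
  am <- arm_matrix_from_segments(seg, truth$arm_table)
  mm <- build_mutation_matrix(read_maf(coh$maf), rownames(am))
  .fixtures$default <- list(truth = truth, coh = coh, seg = seg,
                            am = am, mm = mm)
  .fixtures$default
}

# Small, fast cohort for unit tests.
get_small_cohort <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  cfg <- synthetic_config(n_patients = 80L, n_genes = 30L,
                          n_sig_coupled = 2L, n_global_shift = 2L,
                          n_arm_coupled = 2L)
  truth <- make_truth(cfg, seed = 7)
  coh <- simulate_cohort(truth, seed = 8,
                         dir = file.path(tempdir(), "armsig_fixture_small"))
  seg <- filter_segments(read_seg(coh$seg))$segments
  am <- arm_matrix_from_segments(seg, truth$arm_table)
  mm <- build_mutation_matrix(read_maf(coh$maf), rownames(am), top_n = 30L)
  .fixtures$small <- list(truth = truth, coh = coh, seg = seg,
                          am = am, mm = mm)
  .fixtures$small
}

# Write a tiny SEG file from a data.frame with columns
# sample, chrom, start, end, probes, mean (1-based inclusive coordinates).
write_seg_fixture <- function(rows, path = tempfile(fileext = ".seg")) {
  lines <- c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
             sprintf("%s\t%s\t%d\t%d\t%d\t%s", rows$sample, rows$chrom,
                     rows$start, rows$end, rows$probes,
                     formatC(rows$mean, format = "g", digits = 15)))
  writeLines(lines, path)
  path
}

write_maf_fixture <- function(rows, path = tempfile(fileext = ".maf")) {
  lines <- c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
             sprintf("%s\t%s\t%s", rows$gene, rows$sample, rows$class))
  writeLines(lines, path)
  path
}

# Brute-force AUC oracle: mean pairwise concordance over positive-negative
# pairs, ties counted half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Brute-force optimal signature matching over all column permutations.
match_bruteforce <- function(W_true, W_est) {
  k <- ncol(W_true)
  stopifnot(ncol(W_est) == k, k <= 6)
  sim <- outer(seq_len(k), seq_len(k),
               Vectorize(function(i, j) cosine_similarity(W_true[, i], W_est[, j])))
  perms <- gtools_permutations(k)
  best <- -Inf
  best_p <- NULL
  for (r in seq_len(nrow(perms))) {
    tot <- sum(sim[cbind(seq_len(k), perms[r, ])])
    if (tot > best) { best <- tot; best_p <- perms[r, ] }
  }
  list(mapping = best_p, total = best)
}

# All permutations of 1..n (tiny n), base R.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
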