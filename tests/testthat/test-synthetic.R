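test_that("the generator is deterministic and its files parse cleanly", {
  truth <- get_small_cohort()$truth
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  c1 <- simulate_cohort(truth, seed = 99, dir = d1)
  c2 <- simulate_cohort(truth, seed = 99, dir = d2)
  expect_identical(readLines(c1$seg), readLines(c2$seg))
  expect_identical(readLines(c1$maf), readLines(c2$maf))
  # a different seed changes the realisation
  c3 <- simulate_cohort(truth, seed = 100, dir = file.path(tempdir(), "det3"))
  expect_false(identical(readLines(c1$seg), readLines(c3$seg)))
  # generated SEG parses with zero row errors and only autosomes
  seg <- read_seg(c1$seg)
  expect_equal(nrow(seg), length(readLines(c1$seg)) - 1L)
  expect_true(all(seg$chrom %in% 1:22))
  # fixed truth seed reproduces the truth
  t2 <- make_truth(truth$config, seed = truth$seed)
  expect_identical(t2$W_true, truth$W_true)
  expect_identical(t2$exposures, truth$exposures)
})

test_that("planted signatures respect the separation band", {
  truth <- get_default_cohort()$truth
  k <- ncol(truth$W_true)
  cs <- combn(k, 2, function(ij) {
    cosine_similarity(truth$W_true[, ij[1]], truth$W_true[, ij[2]])
  })
  expect_true(all(cs <= truth$config$separation_max))
  expect_true(all(cs >= truth$config$separation_min))
  expect_true(all(truth$W_true >= 0))
  expect_true(all(truth$exposures >= 0))
  # k_true = 1: every expected profile is proportional to the single column
  t1 <- make_truth(synthetic_config(n_patients = 20L, k_true = 1L,
                                    n_genes = 10L, n_sig_coupled = 0L,
                                    n_global_shift = 0L, n_arm_coupled = 0L),
                   seed = 3)
  prof <- t1$exposures %*% t(t1$W_true)
  ratio <- sweep(prof, 2, t1$W_true[, 1], "/")
  expect_equal(apply(ratio, 1, sd), rep(0, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("noiseless generation closes exactly through the pipeline", {
  cfg <- synthetic_config(n_patients = 50L, n_genes = 20L,
                          n_global_shift = 0L)
  truth <- make_truth(cfg, seed = 5)
  coh <- simulate_cohort(truth, seed = 6, dir = tempfile(), noise_sd = 0,
                         contaminant_rate = 0, lowprobe_frac = 0,
                         seg_per_arm = 1)
  am <- arm_matrix_from_segments(read_seg(coh$seg), truth$arm_table)
  expect_lt(max(abs(am[, colnames(coh$expected_ccn)] - coh$expected_ccn)),
            1e-9)
})

test_that("contaminant injection drives the length filter as configured", {
  cfg <- synthetic_config(n_patients = 60L, n_genes = 10L,
                          n_sig_coupled = 1L, n_global_shift = 1L,
                          n_arm_coupled = 1L)
  truth <- make_truth(cfg, seed = 9)
  coh <- simulate_cohort(truth, seed = 10, dir = tempfile(),
                         contaminant_rate = 0.25, lowprobe_frac = 0)
  fl <- filter_segments(read_seg(coh$seg))
  frac_len <- fl$report$n_removed_length / fl$report$n_input
  expect_lt(abs(frac_len - 0.25), 0.05)
})

test_that("null gene mutations are unrelated to the arm profiles", {
  dc <- get_default_cohort()
  gm <- dc$truth$gene_models
  nulls <- gm$gene[gm$type == "null"]
  nulls <- intersect(nulls, colnames(dc$mm))[1:20]
  r <- sapply(nulls, function(g) {
    y <- as.numeric(dc$mm[, g])
    if (sd(y) == 0) return(0)
    max(abs(cor(dc$am, y)))
  })
  expect_lt(mean(r), 0.25)   # point-biserial correlations stay small
})

test_that("signature matching is exact under permutation and rescaling", {
  set.seed(11)
  W <- matrix(rexp(20 * 4), 20, 4)
  perm <- c(3, 1, 4, 2)
  ms <- match_signatures(W, W[, perm])
  expect_equal(ms$mapping, order(perm))
  expect_equal(ms$cosine, rep(1, 4))
  ms2 <- match_signatures(W, sweep(W, 2, c(10, 0.2, 3, 7), "*"))
  expect_equal(ms2$cosine, rep(1, 4))
  expect_false(ms2$partial)
  # rank mismatch gives a flagged partial matching
  ms3 <- match_signatures(W, W[, 1:3])
  expect_true(ms3$partial)
  expect_equal(sum(is.na(ms3$mapping)), 1L)
})

test_that("Hungarian matching equals brute-force search on random instances", {
  set.seed(12)
  for (i in 1:6) {
    Wt <- matrix(rexp(15 * 4), 15, 4)
    We <- matrix(rexp(15 * 4), 15, 4)
    ms <- match_signatures(Wt, We)
    bf <- match_bruteforce(Wt, We)
    expect_equal(sum(ms$cosine), bf$total, tolerance = 1e-12)
  }
  # and the internal solver minimises arbitrary costs
  for (i in 1:6) {
    cost <- matrix(runif(25), 5, 5)
    a <- armsig:::hungarian_min(cost)
    best <- min(apply(gtools_permutations(5), 1, function(p) {
      sum(cost[cbind(1:5, p)])
    }))
    expect_equal(sum(cost[cbind(1:5, a)]), best, tolerance = 1e-12)
  }
})
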