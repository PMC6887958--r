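test_that("mutation matrix collapses calls, ranks by frequency and breaks ties", {
  calls <- data.frame(
    sample_id = c("P1", "P1", "P2", "P3", "P1"),
    patient_id = c("P1", "P1", "P2", "P3", "P1"),
    gene = c("G", "G", "G", "B", "A"),
    variant_class = "Missense_Mutation",
    deleterious = TRUE
  )
  mm <- build_mutation_matrix(calls, c("P1", "P2", "P3"), top_n = 10L)
  expect_equal(sum(mm[, "G"]), 2L)   # duplicate call in P1 counted once
  expect_equal(colnames(mm)[1], "G")
  # tie between A and B broken lexicographically at top_n = 1 after G
  mm2 <- build_mutation_matrix(calls, c("P1", "P2", "P3"), top_n = 2L)
  expect_equal(colnames(mm2), c("G", "A"))
  calls$deleterious <- FALSE
  expect_error(build_mutation_matrix(calls, c("P1", "P2", "P3")), "deleterious")
})

test_that("mutation-ploidy test handles null, strong-effect and degenerate cases", {
  set.seed(1)
  patients <- sprintf("P%03d", 1:100)
  abs_sm <- stats::setNames(abs(rnorm(100, 0.3, 0.05)), patients)
  mm <- matrix(FALSE, 100, 2, dimnames = list(patients, c("NULLG", "EFFECT")))
  mm[1:50, "EFFECT"] <- TRUE
  mm[seq(1, 99, 2), "NULLG"] <- TRUE
  # strong effect: mutated group shifted by +5 SD
  abs_shift <- abs_sm
  abs_shift[1:50] <- abs_shift[1:50] + 5 * sd(abs_sm)
  res <- mutation_ploidy_test(abs_shift, mm, "EFFECT")
  expect_lt(res$p_raw, 1e-10)
  # permutation oracle agrees the observed difference is extreme
  obs <- mean(abs_shift[mm[, "EFFECT"]]) - mean(abs_shift[!mm[, "EFFECT"]])
  null <- replicate(500, {
    idx <- sample(100, 50)
    mean(abs_shift[idx]) - mean(abs_shift[-idx])
  })
  expect_true(all(abs(null) < abs(obs)))
  # identical values in both groups: zero-variance flag, p = 1
  flat <- stats::setNames(rep(0.3, 100), patients)
  res2 <- mutation_ploidy_test(flat, mm, "NULLG")
  expect_equal(res2$p_raw, 1)
  expect_equal(res2$flag, "zero_variance")
  # single mutated patient is untestable
  mm3 <- mm; mm3[, "EFFECT"] <- FALSE; mm3[1, "EFFECT"] <- TRUE
  expect_equal(mutation_ploidy_test(abs_sm, mm3, "EFFECT")$flag, "untestable")
  # direction from the signed mean-CCN scale
  ccn <- stats::setNames(rep(2, 100), patients)
  ccn[1:50] <- 2.5
  expect_equal(mutation_ploidy_test(abs_sm, mm, "EFFECT", mean_ccn = ccn)$direction,
               "gain")
})

test_that("gene ranking applies Bonferroni over tested genes and stays monotone", {
  set.seed(2)
  patients <- sprintf("P%03d", 1:60)
  abs_sm <- stats::setNames(abs(rnorm(60, 0.3, 0.05)), patients)
  mm <- matrix(runif(60 * 20) < 0.3, 60, 20,
               dimnames = list(patients, sprintf("G%02d", 1:20)))
  res <- rank_genes_ploidy(abs_sm, mm)
  m <- attr(res, "n_tested")
  ok <- res$flag != "untestable"
  expect_equal(res$p_bonferroni[ok], pmin(1, res$p_raw[ok] * m))
  expect_true(all(res$p_bonferroni[ok] <= 1))
  # ordering by corrected p preserves raw-p ordering among tested genes
  expect_false(is.unsorted(res$p_raw[ok & res$p_bonferroni < 1]))
  # raw p of 0.01 at m = 250 would cap at 1
  expect_equal(min(1, 0.01 * 250), 1)
})

test_that("arm correlations recover exact and null relationships", {
  set.seed(3)
  n <- 500
  x <- rnorm(n)
  m <- cbind(a1 = x, a2 = x, a3 = -x + 5, a4 = rnorm(n), a5 = rep(2, n))
  rownames(m) <- sprintf("P%03d", 1:n)
  res <- arm_correlation_matrix(m)
  r <- attr(res, "matrix")
  expect_equal(r["a1", "a2"], 1)
  expect_equal(r["a1", "a3"], -1)
  expect_lt(abs(r["a1", "a4"]), 0.15)   # independent columns, n = 500
  expect_equal(r["a1", "a5"], 0)        # constant arm flagged as r = 0
  expect_equal(res$flag[res$arm_a == "a1" & res$arm_b == "a5"], "constant_arm")
  expect_equal(r, t(r))
  # invariant under adding a constant to a column
  m2 <- m; m2[, "a4"] <- m2[, "a4"] + 100
  expect_equal(attr(arm_correlation_matrix(m2), "matrix")["a1", "a4"],
               r["a1", "a4"])
  expect_error(arm_correlation_matrix(m[1:2, ]), "at least 3")
})

test_that("permutation significance separates planted from null arm pairs", {
  set.seed(4)
  n <- 200
  x <- rnorm(n)
  # perfectly correlated pair: no permutation can match the observed r
  res <- arm_correlation_significance(x, 2 * x + 1, n_perm = 1000, seed = 9)
  expect_equal(res$p_empirical, 1 / 1001)
  # independent pair: the empirical summary is unremarkable; the historical
  # t-summary is reported but lies in [0, 1] (its anticonservatism is why
  # p_empirical is the documented default)
  res2 <- arm_correlation_significance(x, rnorm(n), n_perm = 500, seed = 9)
  expect_gt(res2$p_empirical, 0.01)
  expect_true(res2$p_perm_t >= 0 && res2$p_perm_t <= 1)
  expect_lt(res$p_perm_t, 0.05)   # planted pair is extreme on both summaries
  # p_empirical respects its add-one lower bound
  expect_gte(res$p_empirical, 1 / (res$n_perm + 1))
  expect_warning(arm_correlation_significance(x, rnorm(n), n_perm = 50),
                 "n_perm")
})
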