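test_that("labels align to patient order and flag untrainable genes", {
  mm <- matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE), 3, 2,
               dimnames = list(c("P1", "P2", "P3"), c("G1", "G2")))
  y <- make_labels(mm, "G1")
  expect_equal(as.logical(y), c(TRUE, FALSE, FALSE))
  expect_false(attr(y, "trainable"))      # single positive
  expect_equal(sum(y), sum(mm[, "G1"]))
  expect_false(attr(make_labels(mm, "G2"), "trainable"))
})

test_that("the stratified split preserves class balance and is seeded", {
  set.seed(1)
  x <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(sprintf("P%03d", 1:100)))
  y <- rep(c(TRUE, FALSE), c(30, 70))
  sp <- split_train_test(x, y, 0.2, seed = 4)
  expect_equal(length(sp$test$y), 20L)
  expect_equal(length(sp$train$y), 80L)
  # class ratio in the test set within one patient of the overall ratio
  expect_lte(abs(sum(sp$test$y) - 0.3 * 20), 1)
  sp2 <- split_train_test(x, y, 0.2, seed = 4)
  expect_identical(sp$test_idx, sp2$test_idx)
  sp3 <- split_train_test(x, y, 0.2, seed = 5)
  expect_false(identical(sp$test_idx, sp3$test_idx))
})

test_that("roc_auc equals the brute-force pairwise concordance everywhere", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 0, 1, 0)), 1)
  # positives score 0.4 and 0.6 against negatives 0.9 and 0.1: two of the
  # four positive-negative pairs are concordant
  expect_equal(roc_auc(c(0.4, 0.9, 0.6, 0.1), c(1, 0, 1, 0)), 0.5)
  expect_equal(auc_bruteforce(c(0.4, 0.9, 0.6, 0.1), c(1, 0, 1, 0)), 0.5)
  set.seed(2)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    y <- logical(n)
    y[sample(n, sample(seq_len(n - 1), 1))] <- TRUE
    if (!any(y) || all(y)) next
    s <- round(runif(n), 2)   # rounding forces ties
    expect_identical(roc_auc(s, y), auc_bruteforce(s, y))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:20) {
    y <- c(rep(TRUE, 10), rep(FALSE, 15))
    s <- rnorm(25) + y
    ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                          quiet = TRUE, direction = "<")))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("roc_curve starts at the origin and ends at (1, 1)", {
  rc <- roc_curve(c(0.9, 0.4, 0.6, 0.1), c(1, 0, 1, 0))
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("every classifier separates a linearly separable toy problem", {
  set.seed(4)
  n <- 120
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("a", 1:4)))
  y <- x[, 1] > 0
  x[, 1] <- x[, 1] + ifelse(y, 3, -3)
  sp <- split_train_test(x, y, 0.2, seed = 1)
  for (model in c("random_forest", "naive_bayes_bernoulli", "svm",
                  "logistic_regression")) {
    cfg <- classifier_config(model = model, seed = 9,
                             rf_n_estimators = 200L, rf_min_leaf = 5L)
    fit <- fit_predict(sp$train, sp$test, cfg)
    expect_equal(roc_auc(fit$scores, sp$test$y), 1,
                 tolerance = 0.051, label = model)
  }
})

test_that("random forests score near chance on permuted labels and reproduce", {
  set.seed(5)
  n <- 150
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("a", 1:6)))
  aucs <- sapply(1:8, function(i) {
    y <- sample(rep(c(TRUE, FALSE), c(50, 100)))
    sp <- split_train_test(x, y, 0.3, seed = i)
    fit <- fit_predict(sp$train, sp$test,
                       classifier_config(seed = i, rf_n_estimators = 300L))
    roc_auc(fit$scores, sp$test$y)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
  # fixed seed => identical scores
  y <- x[, 2] > 0.5
  sp <- split_train_test(x, y, 0.2, seed = 2)
  f1 <- fit_predict(sp$train, sp$test, classifier_config(seed = 3))
  f2 <- fit_predict(sp$train, sp$test, classifier_config(seed = 3))
  expect_identical(f1$scores, f2$scores)
})

test_that("permutation importance singles out the informative feature", {
  set.seed(6)
  n <- 200
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("a", 1:5)))
  y <- x[, 3] + rnorm(n, 0, 0.3) > 0
  sp <- split_train_test(x, y, 0.25, seed = 1)
  fit <- fit_predict(sp$train, sp$test,
                     classifier_config(seed = 2, rf_n_estimators = 300L,
                                       rf_min_leaf = 10L))
  imp <- feature_importance(fit, sp$test$x, sp$test$y, n_repeats = 20, seed = 3)
  expect_equal(imp$feature[1], "a3")
  # uninformative features sit near zero importance
  expect_lt(max(abs(imp$importance[imp$feature != "a3"])), 0.1)
  expect_warning(feature_importance(fit, sp$test$x, sp$test$y, n_repeats = 1),
                 "n_repeats")
})

test_that("the gene panel reports per-gene results and records failures", {
  sc <- get_small_cohort()
  genes <- colnames(sc$mm)[1:3]
  cfg <- classifier_config(seed = 7, rf_n_estimators = 100L)
  # add an untrainable gene
  mm <- cbind(sc$mm, DEAD = FALSE)
  res <- run_gene_panel(sc$am, mm, c(genes, "DEAD"), cfg, importance = TRUE)
  expect_equal(nrow(res$reports), 4L)
  expect_match(res$reports$note[res$reports$gene == "DEAD"], "untrainable")
  ok <- !is.na(res$reports$roc_auc)
  expect_false(is.unsorted(rev(res$reports$roc_auc[ok])))
  expect_equal(res$reports$passes_cutoff[ok],
               res$reports$roc_auc[ok] >= 0.70)
  # importance table covers every arm for every modelled gene
  expect_equal(nrow(res$importance), 3L * ncol(sc$am))
})
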