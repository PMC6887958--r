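# Supervised stage: predict per-gene mutation status from arm-wise ploidy
# features; ROC AUC evaluation and permutation feature importance on a
# held-out test set.

#' Classifier configuration
#'
#' @param model one of `"random_forest"`, `"naive_bayes_bernoulli"`,
#'   `"svm"`, `"logistic_regression"`.
#' @param test_fraction held-out fraction; default 0.2.
#' @param cv_folds folds for the hyperparameter grid search; default 5.
#' @param rf_n_estimators random-forest trees; default 1000.
#' @param rf_min_leaf random-forest minimum leaf size; default 30. The
#'   forest uses these fixed values and skips the grid.
#' @param svm_cost cost grid for the radial SVM.
#' @param nb_laplace Laplace-smoothing grid for Bernoulli naive Bayes
#'   (features are binarised at the training medians).
#' @param seed integer seed governing split, folds and model fitting.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(model = "random_forest", test_fraction = 0.2,
                              cv_folds = 5L, rf_n_estimators = 1000L,
                              rf_min_leaf = 30L, svm_cost = c(0.1, 1, 10),
                              nb_laplace = c(0, 0.5, 1), seed = NULL) {
  model <- match.arg(model, c("random_forest", "naive_bayes_bernoulli",
                              "svm", "logistic_regression"))
  stopifnot(test_fraction > 0, test_fraction < 1, cv_folds >= 2L)
  structure(list(model = model, test_fraction = test_fraction,
                 cv_folds = as.integer(cv_folds),
                 rf_n_estimators = as.integer(rf_n_estimators),
                 rf_min_leaf = as.integer(rf_min_leaf),
                 svm_cost = svm_cost, nb_laplace = nb_laplace, seed = seed),
            class = "classifier_config")
}

#' Mutation-status labels for one gene
#'
#' @param mutation_matrix logical patient x gene matrix.
#' @param gene gene symbol.
#' @param patients patient order to align to (arm-matrix rows).
#' @return named logical vector with attribute `trainable` (FALSE when
#'   either class has fewer than 2 patients).
#' @export
make_labels <- function(mutation_matrix, gene, patients = rownames(mutation_matrix)) {
  stopifnot(gene %in% colnames(mutation_matrix))
  y <- mutation_matrix[patients, gene]
  names(y) <- patients
  attr(y, "trainable") <- sum(y) >= 2L && sum(!y) >= 2L
  y
}

#' Stratified train/test split
#'
#' Random split preserving class proportions (each class sampled
#' separately), seeded for reproducibility.
#'
#' @param features numeric matrix (patients x arms).
#' @param labels logical vector aligned to `features` rows.
#' @param test_fraction held-out fraction.
#' @param seed integer seed.
#' @return list with `train` and `test`, each `list(x, y)`, plus
#'   `test_idx`.
#' @export
split_train_test <- function(features, labels, test_fraction = 0.2,
                             seed = NULL) {
  stopifnot(nrow(features) == length(labels))
  idx_pos <- which(labels)
  idx_neg <- which(!labels)
  n_test_pos <- max(1L, min(length(idx_pos) - 1L,
                            round(length(idx_pos) * test_fraction)))
  n_test_neg <- max(1L, min(length(idx_neg) - 1L,
                            round(length(idx_neg) * test_fraction)))
  test_idx <- with_seed(seed, {
    sort(c(sample(idx_pos, n_test_pos), sample(idx_neg, n_test_neg)))
  })
  if (sum(labels[test_idx]) == 0L) {
    stop("stratified split produced a test set without positives", call. = FALSE)
  }
  list(train = list(x = features[-test_idx, , drop = FALSE],
                    y = labels[-test_idx]),
       test = list(x = features[test_idx, , drop = FALSE],
                   y = labels[test_idx]),
       test_idx = test_idx)
}

# Internal: k-fold CV over a 1-d hyperparameter grid, scored by AUC.
# Refolds (bounded) when a fold's training part is single-class.
.cv_tune <- function(x, y, grid, folds, seed, fit_score) {
  if (length(grid) <= 1L) return(grid[1L])
  n <- length(y)
  fold_of <- NULL
  for (try in 1:10) {
    fold_of <- with_seed(derive_seed(seed %||% 0L, paste0("cv_fold_", try)), {
      sample(rep_len(seq_len(folds), n))
    })
    ok <- all(vapply(seq_len(folds), function(f) {
      yy <- y[fold_of != f]
      sum(yy) >= 1L && sum(!yy) >= 1L && any(y[fold_of == f]) && any(!y[fold_of == f])
    }, logical(1)))
    if (ok) break
    if (try == 10) {
      message("degenerate CV folds after 10 reseeds; using the first grid value")
      return(grid[1L])
    }
  }
  score <- vapply(grid, function(g) {
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold_of != f
      s <- fit_score(x[tr, , drop = FALSE], y[tr], x[!tr, , drop = FALSE], g)
      roc_auc(s, y[!tr])
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  grid[which.max(score)]
}

#' Fit a classifier on the training set and score the test set
#'
#' Hyperparameters (SVM cost, naive-Bayes Laplace smoothing, logistic ridge
#' penalty) are chosen by `cv_folds`-fold cross-validation on the training
#' set only; the random forest uses its fixed tree count and leaf size.
#' Returns continuous scores (class probability or margin) for the test
#' set, plus score/classify closures for importance analysis.
#'
#' @param train,test lists with `x` (matrix) and `y` (logical), as produced
#'   by [split_train_test()].
#' @param config a [classifier_config()].
#' @return list of class `armsig_fit`: `scores` (test scores), `score(newx)`
#'   and `classify(newx)` closures, `model`, `config`, `tuned` (chosen
#'   hyperparameter, if any).
#' @export
fit_predict <- function(train, test, config = classifier_config()) {
  x <- train$x; y <- train$y
  seed <- config$seed
  tuned <- NULL
  if (config$model == "random_forest") {
    fit <- with_seed(seed, {
      randomForest::randomForest(x = x, y = factor(y, levels = c(FALSE, TRUE)),
                                 ntree = config$rf_n_estimators,
                                 nodesize = config$rf_min_leaf)
    })
    score <- function(newx) {
      unname(stats::predict(fit, newx, type = "prob")[, "TRUE"])
    }
  } else if (config$model == "svm") {
    fs <- function(xt, yt, xv, cost) {
      m <- e1071::svm(x = xt, y = factor(yt, levels = c(FALSE, TRUE)),
                      kernel = "radial", cost = cost, scale = TRUE)
      d <- attr(stats::predict(m, xv, decision.values = TRUE),
                "decision.values")
      if (grepl("^TRUE", colnames(d)[1L])) d[, 1L] else -d[, 1L]
    }
    tuned <- .cv_tune(x, y, config$svm_cost, config$cv_folds, seed, fs)
    fit <- with_seed(seed, {
      e1071::svm(x = x, y = factor(y, levels = c(FALSE, TRUE)),
                 kernel = "radial", cost = tuned, scale = TRUE)
    })
    score <- function(newx) {
      d <- attr(stats::predict(fit, newx, decision.values = TRUE),
                "decision.values")
      if (grepl("^TRUE", colnames(d)[1L])) unname(d[, 1L]) else -unname(d[, 1L])
    }
  } else if (config$model == "naive_bayes_bernoulli") {
    med <- apply(x, 2L, stats::median)
    binar <- function(m) {
      b <- sweep(m, 2L, med, ">")
      data.frame(lapply(seq_len(ncol(b)), function(j) {
        factor(b[, j], levels = c(FALSE, TRUE))
      }), row.names = NULL) |> stats::setNames(colnames(m))
    }
    fs <- function(xt, yt, xv, lap) {
      medt <- apply(xt, 2L, stats::median)
      bt <- data.frame(lapply(seq_len(ncol(xt)), function(j) {
        factor(xt[, j] > medt[j], levels = c(FALSE, TRUE))
      })) |> stats::setNames(colnames(xt))
      bv <- data.frame(lapply(seq_len(ncol(xv)), function(j) {
        factor(xv[, j] > medt[j], levels = c(FALSE, TRUE))
      })) |> stats::setNames(colnames(xv))
      m <- e1071::naiveBayes(bt, factor(yt, levels = c(FALSE, TRUE)),
                             laplace = lap)
      stats::predict(m, bv, type = "raw")[, "TRUE"]
    }
    tuned <- .cv_tune(x, y, config$nb_laplace, config$cv_folds, seed, fs)
    fit <- e1071::naiveBayes(binar(x), factor(y, levels = c(FALSE, TRUE)),
                             laplace = tuned)
    score <- function(newx) {
      unname(stats::predict(fit, binar(newx), type = "raw")[, "TRUE"])
    }
  } else {  # logistic_regression (ridge, lambda by internal CV)
    foldid <- with_seed(derive_seed(seed %||% 0L, "glmnet_folds"), {
      sample(rep_len(seq_len(config$cv_folds), length(y)))
    })
    fit <- glmnet::cv.glmnet(x, factor(y, levels = c(FALSE, TRUE)),
                             family = "binomial", alpha = 0, foldid = foldid)
    tuned <- fit$lambda.min
    score <- function(newx) {
      as.numeric(stats::predict(fit, newx, s = "lambda.min",
                                type = "response"))
    }
  }
  classify <- function(newx) {
    s <- score(newx)
    thr <- if (config$model == "svm") 0 else 0.5
    s > thr
  }
  structure(list(scores = score(test$x), score = score, classify = classify,
                 model = fit, config = config, tuned = tuned),
            class = "armsig_fit")
}

#' ROC area under the curve
#'
#' Rank-statistic (Mann-Whitney) AUC, equivalent to the trapezoidal area
#' under the ROC curve with tied scores handled by average ranks: the
#' probability that a random positive scores above a random negative, with
#' ties counted half.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical (or 0/1) true labels; both classes must be present.
#' @return numeric AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("roc_auc requires both classes in the labels", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return `data.frame` with `threshold`, `fpr`, `tpr`, from the most to
#'   the least stringent threshold.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tpr <- cumsum(lab) / sum(lab)
  fpr <- cumsum(!lab) / sum(!lab)
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(threshold = c(Inf, scores[ord][keep]),
             fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' Permutation feature importance on held-out data
#'
#' Mean decrease in test-set classification accuracy when one feature's
#' column is randomly permuted, averaged over `n_repeats` permutations per
#' feature; the operational form of holding a variable out of a fitted
#' model.
#'
#' @param fit an `armsig_fit` from [fit_predict()].
#' @param x_test,y_test held-out features and labels.
#' @param n_repeats permutations per feature; default 10 (a warning below 2).
#' @param seed integer seed.
#' @return `data.frame` with `feature`, `importance` (mean decrease in
#'   accuracy), `sd`, sorted by importance descending.
#' @export
feature_importance <- function(fit, x_test, y_test, n_repeats = 10L,
                               seed = NULL) {
  if (n_repeats < 2L) warning("n_repeats < 2 gives no sd estimate", call. = FALSE)
  baseline <- mean(fit$classify(x_test) == y_test)
  res <- with_seed(seed, {
    lapply(seq_len(ncol(x_test)), function(j) {
      acc <- vapply(seq_len(n_repeats), function(r) {
        xp <- x_test
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        mean(fit$classify(xp) == y_test)
      }, numeric(1))
      data.frame(feature = colnames(x_test)[j],
                 importance = baseline - mean(acc),
                 sd = stats::sd(acc), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline_accuracy") <- baseline
  out
}

#' Classification panel over a gene list
#'
#' For each requested gene: build labels, stratified split, fit the
#' configured model (per-gene seed derived from the config seed), score the
#' test set, and report ROC AUC against the 0.70 cutoff. Per-gene failures
#' are recorded and the panel continues.
#'
#' @param arm_matrix patients x arms feature matrix.
#' @param mutation_matrix logical patient x gene matrix.
#' @param genes character vector of genes to model.
#' @param config a [classifier_config()].
#' @param importance compute permutation feature importance per gene.
#' @param auc_cutoff pass threshold for `passes_cutoff`; default 0.70.
#' @return list with `reports` (`data.frame` sorted by `roc_auc`
#'   descending) and `importance` (long `data.frame` or `NULL`).
#' @export
run_gene_panel <- function(arm_matrix, mutation_matrix, genes,
                           config = classifier_config(), importance = FALSE,
                           auc_cutoff = 0.70) {
  patients <- intersect(rownames(arm_matrix), rownames(mutation_matrix))
  x_all <- arm_matrix[patients, , drop = FALSE]
  reports <- list()
  imps <- list()
  for (g in genes) {
    row <- data.frame(gene = g, model = config$model, roc_auc = NA_real_,
                      n_train = NA_integer_, n_test = NA_integer_,
                      n_pos_test = NA_integer_, passes_cutoff = NA,
                      note = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      y <- make_labels(mutation_matrix, g, patients)
      if (!attr(y, "trainable")) stop("untrainable: fewer than 2 patients in a class")
      gseed <- if (is.null(config$seed)) NULL else derive_seed(config$seed, paste0("split_", g))
      sp <- split_train_test(x_all, y, config$test_fraction, seed = gseed)
      cfg <- config
      cfg$seed <- if (is.null(config$seed)) NULL else derive_seed(config$seed, paste0("fit_", g))
      fit <- fit_predict(sp$train, sp$test, cfg)
      row$roc_auc <- roc_auc(fit$scores, sp$test$y)
      row$n_train <- length(sp$train$y)
      row$n_test <- length(sp$test$y)
      row$n_pos_test <- sum(sp$test$y)
      row$passes_cutoff <- row$roc_auc >= auc_cutoff
      if (importance) {
        im <- feature_importance(fit, sp$test$x, sp$test$y,
                                 seed = if (is.null(config$seed)) NULL
                                        else derive_seed(config$seed, paste0("imp_", g)))
        im$gene <- g
        imps[[g]] <- im
      }
      row
    }, error = function(e) {
      row$note <- conditionMessage(e)
      row
    })
    reports[[g]] <- res
  }
  reports <- do.call(rbind, reports)
  reports <- reports[order(-reports$roc_auc, reports$gene, na.last = TRUE), ,
                     drop = FALSE]
  rownames(reports) <- NULL
  list(reports = reports,
       importance = if (length(imps)) do.call(rbind, c(imps, make.row.names = FALSE)) else NULL)
}
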