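# Mutation-vs-ploidy t-test screen with Bonferroni correction, and arm-pair
# correlation matrices with permutation significance.

#' Build a boolean patient-by-gene mutation matrix
#'
#' Collapses deleterious mutation calls to patient level, ranks genes by the
#' number of patients carrying at least one deleterious call (ties broken
#' lexicographically) and keeps the `top_n` most frequently mutated genes.
#' Calls whose patient is not in `patients` are dropped and counted in the
#' `n_unmatched` attribute.
#'
#' @param calls mutation call `data.frame` from [read_maf()].
#' @param patients character vector of patient identifiers (the arm-matrix
#'   row order).
#' @param top_n number of genes to retain; default 250.
#' @return logical matrix (patients x genes) with attribute `gene_counts`.
#' @export
build_mutation_matrix <- function(calls, patients, top_n = 250L) {
  del <- calls[calls$deleterious, , drop = FALSE]
  unmatched <- !(del$patient_id %in% patients)
  del <- del[!unmatched, , drop = FALSE]
  if (nrow(del) == 0L) {
    stop("no deleterious mutation calls match the patient set", call. = FALSE)
  }
  pairs <- unique(del[, c("patient_id", "gene")])
  counts <- table(pairs$gene)
  ord <- order(-as.integer(counts), names(counts))
  genes <- names(counts)[ord][seq_len(min(top_n, length(counts)))]
  m <- matrix(FALSE, nrow = length(patients), ncol = length(genes),
              dimnames = list(patients, genes))
  keep <- pairs$gene %in% genes
  m[cbind(match(pairs$patient_id[keep], patients),
          match(pairs$gene[keep], genes))] <- TRUE
  attr(m, "gene_counts") <- as.integer(counts)[ord][seq_along(genes)]
  attr(m, "n_unmatched") <- sum(unmatched)
  m
}

#' Test one gene's mutation status against overall ploidy change
#'
#' Two-sided Welch two-sample t-test of the average absolute genome-wide
#' segment mean between patients carrying a deleterious mutation in `gene`
#' and all other patients. Direction of the associated ploidy change
#' (gain/loss) is read from the sign of the mean difference on the signed
#' mean-CCN scale when `mean_ccn` is supplied.
#'
#' @param abs_segmean named numeric vector, per-patient average absolute
#'   segment mean.
#' @param mutation_matrix logical matrix from [build_mutation_matrix()].
#' @param gene gene symbol (column of `mutation_matrix`).
#' @param mean_ccn optional named numeric vector of per-patient mean CCN.
#' @return one-row `data.frame`: `gene`, `n_mut`, `n_wt`, `mean_mut`,
#'   `mean_wt`, `direction`, `p_raw`, `flag` (`"ok"`, `"untestable"` or
#'   `"zero_variance"`).
#' @export
mutation_ploidy_test <- function(abs_segmean, mutation_matrix, gene,
                                 mean_ccn = NULL) {
  stopifnot(gene %in% colnames(mutation_matrix))
  patients <- intersect(rownames(mutation_matrix), names(abs_segmean))
  mut <- patients[mutation_matrix[patients, gene]]
  wt <- setdiff(patients, mut)
  x <- abs_segmean[mut]
  y <- abs_segmean[wt]
  direction <- NA_character_
  if (!is.null(mean_ccn) && length(mut) > 0L && length(wt) > 0L) {
    d <- mean(mean_ccn[mut]) - mean(mean_ccn[wt])
    direction <- if (d > 0) "gain" else if (d < 0) "loss" else NA_character_
  }
  res <- data.frame(gene = gene, n_mut = length(mut), n_wt = length(wt),
                    mean_mut = if (length(mut)) mean(x) else NA_real_,
                    mean_wt = if (length(wt)) mean(y) else NA_real_,
                    direction = direction, p_raw = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE)
  if (length(mut) < 2L || length(wt) < 2L) {
    res$flag <- "untestable"
    return(res)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    res$p_raw <- 1
    res$flag <- "zero_variance"
    return(res)
  }
  res$p_raw <- stats::t.test(x, y, var.equal = FALSE)$p.value
  res
}

#' Rank genes by Bonferroni-corrected mutation-vs-ploidy significance
#'
#' Runs [mutation_ploidy_test()] for every gene in the mutation matrix,
#' Bonferroni-corrects over the genes actually tested, and sorts ascending
#' by corrected p (untestable genes last).
#'
#' @inheritParams mutation_ploidy_test
#' @return `data.frame` of per-gene results with `p_bonferroni` added.
#' @export
rank_genes_ploidy <- function(abs_segmean, mutation_matrix, mean_ccn = NULL) {
  res <- do.call(rbind, lapply(colnames(mutation_matrix), function(g) {
    mutation_ploidy_test(abs_segmean, mutation_matrix, g, mean_ccn)
  }))
  m <- sum(res$flag != "untestable")
  res$p_bonferroni <- pmin(1, res$p_raw * m)
  res <- res[order(res$p_bonferroni, res$p_raw, res$gene, na.last = TRUE), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- m
  res
}

#' Pearson correlation for all arm pairs
#'
#' Correlates arm CCN across patients for every pair of arms, optionally
#' restricted to a patient subset (e.g. one tissue). Constant columns yield
#' r = 0 with a flag.
#'
#' @param arm_matrix patients x arms matrix (CCN scale).
#' @param patients optional character vector restricting to a patient
#'   subset; default all rows.
#' @return long `data.frame` (`arm_a`, `arm_b`, `r`, `flag`) over unordered
#'   pairs `arm_a` < `arm_b` in column order, with the full symmetric
#'   correlation matrix as attribute `matrix`.
#' @export
arm_correlation_matrix <- function(arm_matrix, patients = NULL) {
  x <- if (is.null(patients)) arm_matrix else arm_matrix[patients, , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 patients for correlations", call. = FALSE)
  constant <- apply(x, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(x))
  r[is.na(r)] <- 0
  arms <- colnames(x)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(
    arm_a = arms[idx[, 1L]],
    arm_b = arms[idx[, 2L]],
    r = r[idx],
    flag = ifelse(constant[idx[, 1L]] | constant[idx[, 2L]],
                  "constant_arm", "ok"),
    stringsAsFactors = FALSE
  )
  attr(out, "matrix") <- r
  out
}

#' Permutation significance for one arm-pair correlation
#'
#' Builds a null distribution of Pearson r by randomly permuting one arm's
#' values across patients `n_perm` times. Two significance summaries are
#' returned: `p_perm_t`, a two-sided one-sample t-test of the null r values
#' against the observed r (the historical procedure this package mirrors),
#' and `p_empirical`, the add-one two-sided permutation rank p-value, which
#' is the recommended summary for interpretation.
#'
#' @param x,y numeric vectors of equal length >= 3 (arm CCN across patients).
#' @param n_perm number of permutations; default 1000.
#' @param seed integer seed for the permutation stream.
#' @return one-row `data.frame`: `r`, `p_perm_t`, `p_empirical`, `n_perm`.
#' @export
arm_correlation_significance <- function(x, y, n_perm = 1000L, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (n_perm < 100L) warning("n_perm < 100 gives coarse p-values", call. = FALSE)
  n <- length(x)
  r_obs <- stats::cor(x, y)
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  r_null <- with_seed(seed, {
    perm <- replicate(n_perm, sample.int(n))
    yp <- matrix(y[perm], nrow = n)
    ypc <- sweep(yp, 2, colMeans(yp))
    sy <- sqrt(colSums(ypc^2))
    as.numeric(crossprod(xc, ypc)) / (sx * sy)
  })
  p_t <- stats::t.test(r_null, mu = r_obs)$p.value
  p_emp <- (1 + sum(abs(r_null) >= abs(r_obs))) / (n_perm + 1)
  data.frame(r = r_obs, p_perm_t = p_t, p_empirical = p_emp, n_perm = n_perm)
}
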