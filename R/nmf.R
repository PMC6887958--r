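# Arm-ploidy signature extraction: non-negative matrix factorisation with
# multiplicative updates, consensus/cophenetic rank selection and argmax
# signature assignment.

#' Non-negative matrix factorisation of an arm matrix
#'
#' Factorises the non-negative patients x arms CCN matrix `x` as
#' `x ~ H %*% t(W)` with `W` (arms x k, the basis: arm composition of each
#' signature) and `H` (patients x k, the coefficients: signature exposure
#' of each patient), minimising the Frobenius reconstruction error by
#' Lee-Seung multiplicative updates from a seeded random non-negative start.
#' A Kullback-Leibler objective is available via `method`. On return each
#' column of `W` is scaled to unit L1 norm with the scale absorbed into `H`,
#' leaving the reconstruction unchanged.
#'
#' @param x non-negative numeric matrix, patients x arms (CCN scale).
#' @param k factorisation rank, `1 <= k < min(dim(x))`.
#' @param seed integer seed for the random initialisation.
#' @param max_iter maximum number of update iterations.
#' @param tol relative change in reconstruction error that stops iteration.
#' @param method `"frobenius"` (default) or `"kl"`.
#' @return object of class `signature_model`: list with `W`, `H`, `k`,
#'   `reconstruction_error` (Frobenius norm), `error_trace`, `n_iter`,
#'   `seed`, `method`.
#' @export
nmf_factorize <- function(x, k, seed = NULL, max_iter = 500L, tol = 1e-6,
                          method = c("frobenius", "kl")) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(x < 0) || any(!is.finite(x))) {
    stop("nmf_factorize requires a finite non-negative matrix", call. = FALSE)
  }
  if (all(x == 0)) stop("all-zero matrix cannot be factorised", call. = FALSE)
  if (k < 1L || k >= min(dim(x))) {
    stop(sprintf("k must satisfy 1 <= k < min(dim(x)) = %d", min(dim(x))),
         call. = FALSE)
  }
  eps <- .Machine$double.eps
  n <- nrow(x); m <- ncol(x)
  init <- with_seed(seed, {
    s <- sqrt(mean(x) / k)
    list(H = matrix(stats::runif(n * k, 0.1, 1) * s, n, k),
         W = matrix(stats::runif(m * k, 0.1, 1) * s, m, k))
  })
  H <- init$H; W <- init$W
  err <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    if (method == "frobenius") {
      H <- H * (x %*% W) / (H %*% crossprod(W) + eps)
      W <- W * crossprod(x, H) / (W %*% crossprod(H) + eps)
      e <- sqrt(sum((x - H %*% t(W))^2))
    } else {
      V <- H %*% t(W) + eps
      H <- H * ((x / V) %*% W) / matrix(colSums(W), n, k, byrow = TRUE)
      V <- H %*% t(W) + eps
      W <- W * crossprod(x / V, H) / matrix(colSums(H), m, k, byrow = TRUE)
      V <- H %*% t(W) + eps
      e <- sum(x * log((x + eps) / V) - x + V)
    }
    err <- c(err, e)
    if (is.finite(prev) && abs(prev - e) / max(prev, eps) < tol) break
    prev <- e
  }
  s <- colSums(W)
  s[s == 0] <- 1
  W <- sweep(W, 2, s, "/")
  H <- sweep(H, 2, s, "*")
  rownames(W) <- colnames(x)
  rownames(H) <- rownames(x)
  colnames(W) <- colnames(H) <- paste0("S", seq_len(k))
  structure(list(W = W, H = H, k = as.integer(k),
                 reconstruction_error = sqrt(sum((x - H %*% t(W))^2)),
                 error_trace = err, n_iter = length(err),
                 seed = seed, method = method),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("Arm-ploidy signature model: k = %d, %d patients x %d arms\n",
              x$k, nrow(x$H), nrow(x$W)))
  cat(sprintf("  objective: %s, %d iterations, reconstruction error %.4g\n",
              x$method, x$n_iter, x$reconstruction_error))
  invisible(x)
}

#' Assign each patient to its dominant signature
#'
#' Per patient, the argmax over the coefficient (exposure) row; ties go to
#' the lowest signature index. An all-zero row receives the sentinel 0 and
#' is flagged.
#'
#' @param model a `signature_model`.
#' @return named integer vector (patient -> signature index 1..k) with
#'   attribute `group_sizes`; zero rows are 0.
#' @export
assign_signatures <- function(model) {
  H <- model$H
  a <- apply(H, 1L, function(r) if (all(r == 0)) 0L else which.max(r))
  a <- stats::setNames(as.integer(a), rownames(H))
  if (any(a == 0L)) {
    warning(sum(a == 0L), " patient(s) with all-zero exposures assigned sentinel 0",
            call. = FALSE)
  }
  attr(a, "group_sizes") <- table(factor(a, levels = seq_len(model$k)))
  a
}

#' Cophenetic stability of a rank-k consensus
#'
#' Runs the factorisation `n_runs` times from distinct seeded starts,
#' builds the patients x patients consensus matrix (fraction of runs in
#' which two patients share the argmax signature) and returns the Pearson
#' correlation between the consensus distances (1 - C) and the cophenetic
#' distances of their average-linkage hierarchical clustering. Values near
#' 1 indicate a stable clustering at this rank.
#'
#' @param x non-negative patients x arms matrix.
#' @param k rank to assess.
#' @param n_runs number of factorisation restarts (>= 2; >= 10 recommended).
#' @param seed integer seed; run `i` uses a seed derived from it.
#' @param ... further arguments to [nmf_factorize()].
#' @return numeric cophenetic correlation in `[0, 1]`, with the consensus
#'   matrix as attribute `consensus` and a `degenerate` flag when the
#'   consensus is constant (reported as 1).
#' @export
consensus_cophenetic <- function(x, k, n_runs = 30L, seed = NULL, ...) {
  if (n_runs < 2L) stop("consensus requires n_runs >= 2", call. = FALSE)
  if (n_runs < 10L) warning("n_runs < 10 gives an unstable cophenetic estimate",
                            call. = FALSE)
  n <- nrow(x)
  C <- matrix(0, n, n)
  base <- seed %||% 0L
  for (i in seq_len(n_runs)) {
    fit <- nmf_factorize(x, k, seed = derive_seed(base, paste0("nmf_run_", i, "_k", k)), ...)
    a <- suppressWarnings(assign_signatures(fit))
    C <- C + outer(a, a, "==")
  }
  C <- C / n_runs
  dimnames(C) <- list(rownames(x), rownames(x))
  d <- stats::as.dist(1 - C)
  if (stats::sd(d) == 0) {
    return(structure(1, degenerate = TRUE, consensus = C))
  }
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cor(d, stats::cophenetic(hc))
  structure(as.numeric(coph), degenerate = FALSE, consensus = C)
}

#' Scan candidate ranks and select one by the cophenetic profile
#'
#' Computes the consensus cophenetic score for each rank in `k_range` and
#' selects the smallest interior rank at a strict local minimum of the
#' profile (the historical rule this package mirrors). When no interior
#' local minimum exists the rank with the maximum cophenetic score is used
#' instead, with a warning. `rule = "argmax"` selects the maximum directly,
#' the conventional stability criterion.
#'
#' @param x non-negative patients x arms matrix.
#' @param k_range contiguous integer vector of candidate ranks, length >= 3.
#' @param n_runs factorisation restarts per rank.
#' @param seed integer seed.
#' @param rule `"local_min"` (default) or `"argmax"`.
#' @param ... further arguments to [nmf_factorize()].
#' @return object of class `rank_scan`: list with `scan` (`data.frame` of
#'   `k`, `cophenetic`, `n_runs`), `selected_k`, `argmax_k`,
#'   `selection_rule`.
#' @export
select_rank <- function(x, k_range = 2:10, n_runs = 30L, seed = NULL,
                        rule = c("local_min", "argmax"), ...) {
  rule <- match.arg(rule)
  k_range <- sort(as.integer(k_range))
  if (length(k_range) < 3L || any(diff(k_range) != 1L)) {
    stop("k_range must be a contiguous integer range of length >= 3", call. = FALSE)
  }
  coph <- vapply(k_range, function(k) {
    as.numeric(consensus_cophenetic(x, k, n_runs = n_runs,
                                    seed = derive_seed(seed %||% 0L, paste0("rank_k", k)),
                                    ...))
  }, numeric(1))
  sel <- .select_k(k_range, coph, rule)
  structure(list(scan = data.frame(k = k_range, cophenetic = coph,
                                   n_runs = n_runs),
                 selected_k = sel$selected_k, argmax_k = sel$argmax_k,
                 selection_rule = sel$selection_rule),
            class = "rank_scan")
}

# Internal: apply the rank-selection rule to a cophenetic profile.
.select_k <- function(k_range, coph, rule = c("local_min", "argmax")) {
  rule <- match.arg(rule)
  argmax_k <- k_range[which.max(coph)]
  interior <- seq(2L, length(k_range) - 1L)
  is_min <- vapply(interior, function(i) {
    coph[i] < coph[i - 1L] && coph[i] < coph[i + 1L]
  }, logical(1))
  if (rule == "local_min" && any(is_min)) {
    selected <- k_range[interior[which(is_min)[1L]]]
    path <- "local_min"
  } else {
    if (rule == "local_min") {
      warning("no interior local minimum in the cophenetic profile; ",
              "falling back to the argmax rank", call. = FALSE)
      path <- "argmax_fallback"
    } else {
      path <- "argmax"
    }
    selected <- argmax_k
  }
  list(selected_k = selected, argmax_k = argmax_k, selection_rule = path)
}

#' @export
print.rank_scan <- function(x, ...) {
  cat("Cophenetic rank scan:\n")
  print(x$scan, row.names = FALSE)
  cat(sprintf("selected k = %d (%s); argmax k = %d\n",
              x$selected_k, x$selection_rule, x$argmax_k))
  invisible(x)
}
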