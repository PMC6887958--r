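# Optimal matching of recovered signatures to planted ones.

# Internal: Kuhn-Munkres (Hungarian) algorithm, minimising total cost over
# a square cost matrix. Returns, for each row, the assigned column.
hungarian_min <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)    # p[j+1]: row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  }
  assignment
}

#' Match estimated signatures to planted ones by cosine similarity
#'
#' Finds the one-to-one assignment of estimated basis columns to planted
#' basis columns maximising total cosine similarity (Hungarian algorithm).
#' When the ranks differ the smaller side is fully matched and the result
#' flagged partial; cosine similarity is scale-invariant, so column
#' normalisation conventions do not matter.
#'
#' @param W_true planted basis, arms x k_true.
#' @param W_est estimated basis, arms x k_est.
#' @return list with `mapping` (for each true signature, the matched
#'   estimated column index, NA when unmatched), `cosine` (matched cosine
#'   similarity per true signature), and `partial` flag.
#' @export
match_signatures <- function(W_true, W_est) {
  stopifnot(nrow(W_true) == nrow(W_est))
  kt <- ncol(W_true)
  ke <- ncol(W_est)
  sim <- matrix(0, kt, ke)
  for (i in seq_len(kt)) {
    for (j in seq_len(ke)) {
      sim[i, j] <- cosine_similarity(W_true[, i], W_est[, j])
    }
  }
  n <- max(kt, ke)
  cost <- matrix(0, n, n)           # padding: zero-similarity dummies
  cost[seq_len(kt), seq_len(ke)] <- 1 - sim
  assign_full <- hungarian_min(cost)
  mapping <- assign_full[seq_len(kt)]
  mapping[mapping > ke] <- NA_integer_
  cosine <- rep(NA_real_, kt)
  ok <- !is.na(mapping)
  cosine[ok] <- sim[cbind(which(ok), mapping[ok])]
  list(mapping = mapping, cosine = cosine, partial = kt != ke)
}
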