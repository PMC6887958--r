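# Mutation-signature statistics: cosine distance between median signature
# compositions of mutated vs wild-type patients with label-permutation
# significance, and within-signature mutation enrichment permutation tests.

#' Cosine similarity of two vectors
#'
#' `u . v / (||u|| ||v||)`; for the non-negative compositions used here the
#' value lies in `[0, 1]`. A zero vector yields `NA` with a warning.
#'
#' @param u,v numeric vectors of equal length.
#' @return numeric cosine similarity.
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("cosine similarity undefined for a zero vector", call. = FALSE)
    return(NA_real_)
  }
  sum(u * v) / (nu * nv)
}

#' Component-wise median signature composition of a patient subset
#'
#' @param H patients x k exposure matrix (rows named by patient).
#' @param patients character vector of patient identifiers, non-empty.
#' @return numeric k-vector of per-component medians.
#' @export
median_composition <- function(H, patients) {
  if (length(patients) == 0L) stop("empty patient subset", call. = FALSE)
  sub <- H[patients, , drop = FALSE]
  apply(sub, 2L, stats::median)
}

#' Signature-composition distance between mutated and wild-type patients
#'
#' Computes the cosine similarity between the median exposure compositions
#' of patients with and without a deleterious mutation in `gene`, and its
#' one-sided label-permutation significance: the null is built by randomly
#' relabelling patients `n_perm` times preserving group sizes, and
#' `p_perm = (1 + #\{null cosine <= observed\}) / (n_perm + 1)`; low cosine
#' (large distance) is the extreme direction.
#'
#' @param H patients x k exposure matrix.
#' @param mutation_matrix logical patient x gene matrix.
#' @param gene gene symbol.
#' @param n_perm permutations for the null; 0 skips the test (`p_perm` NA).
#' @param seed integer seed.
#' @param min_mut minimum patients required in each group; smaller groups
#'   are flagged untestable (medians of tiny groups are unstable).
#' @return one-row `data.frame`: `gene`, `n_mut`, `n_wt`, `cosine_sim`,
#'   `distance`, `p_perm`, `n_perm`, `flag`; the two median compositions
#'   are attached as attributes `median_mut` and `median_wt`.
#' @export
gene_signature_distance <- function(H, mutation_matrix, gene, n_perm = 1000L,
                                    seed = NULL, min_mut = 5L) {
  stopifnot(gene %in% colnames(mutation_matrix))
  patients <- intersect(rownames(H), rownames(mutation_matrix))
  mut <- patients[mutation_matrix[patients, gene]]
  wt <- setdiff(patients, mut)
  out <- data.frame(gene = gene, n_mut = length(mut), n_wt = length(wt),
                    cosine_sim = NA_real_, distance = NA_real_,
                    p_perm = NA_real_, n_perm = as.integer(n_perm),
                    flag = "ok", stringsAsFactors = FALSE)
  if (length(mut) < min_mut || length(wt) < min_mut) {
    out$flag <- "untestable"
    return(out)
  }
  cm <- median_composition(H, mut)
  cw <- median_composition(H, wt)
  obs <- cosine_similarity(cm, cw)
  out$cosine_sim <- obs
  out$distance <- 1 - obs
  if (n_perm > 0L) {
    Hsub <- H[patients, , drop = FALSE]
    n <- length(patients); nm <- length(mut)
    null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, nm)
        cosine_similarity(apply(Hsub[idx, , drop = FALSE], 2L, stats::median),
                          apply(Hsub[-idx, , drop = FALSE], 2L, stats::median))
      }, numeric(1))
    })
    out$p_perm <- (1 + sum(null <= obs)) / (n_perm + 1)
  }
  attr(out, "median_mut") <- cm
  attr(out, "median_wt") <- cw
  out
}

#' Rank genes by mutated-vs-wild-type signature-composition distance
#'
#' Applies [gene_signature_distance()] to every gene of the mutation matrix
#' and sorts by distance descending (cosine similarity ascending), ties
#' broken by gene symbol; untestable genes sort last.
#'
#' @inheritParams gene_signature_distance
#' @return `data.frame` of per-gene results in rank order.
#' @export
rank_genes_by_distance <- function(H, mutation_matrix, n_perm = 1000L,
                                   seed = NULL, min_mut = 5L) {
  res <- do.call(rbind, lapply(colnames(mutation_matrix), function(g) {
    gene_signature_distance(H, mutation_matrix, g, n_perm = n_perm,
                            seed = if (is.null(seed)) NULL
                                   else derive_seed(seed, paste0("dist_", g)),
                            min_mut = min_mut)
  }))
  res <- res[order(-res$distance, res$gene, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mutation enrichment of a gene within one signature group
#'
#' Counts mutated patients inside the signature group and compares the
#' count with a null of `n_perm` equally sized patient subsets drawn
#' without replacement from the whole cohort (so the null is
#' hypergeometric); `p_perm = (1 + #\{null >= observed\}) / (n_perm + 1)`,
#' one-sided for enrichment.
#'
#' @param assignment named integer vector from [assign_signatures()].
#' @param mutation_matrix logical patient x gene matrix.
#' @param gene gene symbol; must be a column of `mutation_matrix`.
#' @param signature signature index (1..k).
#' @param n_perm number of null draws.
#' @param seed integer seed.
#' @return one-row `data.frame`: `gene`, `signature`, `n_group`,
#'   `observed_mut_count`, `observed_frequency`, `p_perm`, `n_perm`; the
#'   null counts are attached as attribute `null_counts`.
#' @export
signature_enrichment <- function(assignment, mutation_matrix, gene, signature,
                                 n_perm = 1000L, seed = NULL) {
  if (!gene %in% colnames(mutation_matrix)) {
    stop("gene not present in the mutation matrix: ", gene, call. = FALSE)
  }
  patients <- intersect(names(assignment), rownames(mutation_matrix))
  group <- patients[assignment[patients] == signature]
  if (length(group) == 0L) stop("signature group is empty", call. = FALSE)
  status <- mutation_matrix[patients, gene]
  obs <- sum(status[match(group, patients)])
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sum(status[sample.int(length(patients), length(group))])
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  out <- data.frame(gene = gene, signature = as.integer(signature),
                    n_group = length(group), observed_mut_count = obs,
                    observed_frequency = obs / length(group),
                    p_perm = p, n_perm = as.integer(n_perm),
                    stringsAsFactors = FALSE)
  attr(out, "null_counts") <- null
  out
}

#' Enrichment of every gene in every signature group
#'
#' Vectorised panel version of [signature_enrichment()]: per signature, one
#' set of `n_perm` null subsets is drawn and all gene columns are counted
#' against it.
#'
#' @inheritParams signature_enrichment
#' @return long `data.frame` (gene x signature) sorted by `p_perm`, with a
#'   Benjamini-Hochberg `p_bh` column for reference (raw permutation p is
#'   primary).
#' @export
signature_enrichment_panel <- function(assignment, mutation_matrix,
                                       n_perm = 1000L, seed = NULL) {
  patients <- intersect(names(assignment), rownames(mutation_matrix))
  mm <- mutation_matrix[patients, , drop = FALSE]
  sigs <- sort(unique(assignment[patients]))
  sigs <- sigs[sigs > 0L]
  res <- lapply(sigs, function(s) {
    group <- patients[assignment[patients] == s]
    obs <- colSums(mm[group, , drop = FALSE])
    null <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, paste0("enrich_s", s)), {
      t(vapply(seq_len(n_perm), function(i) {
        colSums(mm[sample.int(length(patients), length(group)), , drop = FALSE])
      }, numeric(ncol(mm))))
    })
    p <- (1 + colSums(sweep(null, 2, obs, ">=") * 1)) / (n_perm + 1)
    data.frame(gene = colnames(mm), signature = as.integer(s),
               n_group = length(group), observed_mut_count = as.integer(obs),
               observed_frequency = obs / length(group),
               p_perm = p, n_perm = as.integer(n_perm),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p_perm, method = "BH")
  out <- out[order(out$p_perm, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
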