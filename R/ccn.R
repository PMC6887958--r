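# Copy-number arithmetic: segment-mean <-> CCN conversion, cohort-level
# segment filtering, per-patient genome-wide summaries, and projection of
# segments onto chromosome arms.

#' Convert a segment mean (log2 ratio) to chromosomal copy number
#'
#' CCN = 2^(segment mean) * 2, so a copy-neutral segment (segment mean 0)
#' has CCN 2 and the map is strictly increasing.
#'
#' @param segment_mean numeric vector of log2 ratios.
#' @return numeric vector of copy numbers (copies).
#' @export
#' @examples
#' segmean_to_ccn(c(-1, 0, 1))  # 1, 2, 4
segmean_to_ccn <- function(segment_mean) {
  if (!is.numeric(segment_mean) || any(!is.finite(segment_mean))) {
    stop("segment_mean must be finite numeric", call. = FALSE)
  }
  2^segment_mean * 2
}

#' Convert chromosomal copy number back to a segment mean
#'
#' Exact inverse of [segmean_to_ccn()].
#'
#' @param ccn numeric vector of copy numbers, strictly positive.
#' @return numeric vector of log2 ratios.
#' @export
ccn_to_segmean <- function(ccn) {
  if (!is.numeric(ccn) || any(!is.finite(ccn)) || any(ccn <= 0)) {
    stop("ccn must be finite and > 0", call. = FALSE)
  }
  log2(ccn / 2)
}

#' Filter segments by length percentile and probe support
#'
#' Removes segments whose length falls strictly below the given percentile
#' of lengths in the input cohort (linear-interpolation quantile), then
#' removes segments supported by fewer than `min_probes` probes. The length
#' percentile is computed over the file's whole cohort so short, focal
#' events are excluded before arm-level averaging.
#'
#' @param segments segment `data.frame` from [read_seg()].
#' @param length_percentile percentile (0-100) of segment length below which
#'   segments are removed; default 25.
#' @param min_probes minimum probe count; default 10.
#' @return A list with `segments` (the retained rows) and `report`, a
#'   one-row `data.frame` with `n_input`, `n_retained`, `n_removed_length`,
#'   `n_removed_probes`, `length_threshold_bp`.
#' @export
filter_segments <- function(segments, length_percentile = 25, min_probes = 10) {
  if (!is.data.frame(segments) || nrow(segments) == 0L) {
    stop("filter_segments requires a non-empty segment table", call. = FALSE)
  }
  len <- segments$end - segments$start
  thr <- as.numeric(stats::quantile(len, length_percentile / 100,
                                    type = 7, names = FALSE))
  keep_len <- len >= thr
  s2 <- segments[keep_len, , drop = FALSE]
  keep_probes <- s2$num_probes >= min_probes
  out <- s2[keep_probes, , drop = FALSE]
  rownames(out) <- NULL
  report <- data.frame(
    n_input = nrow(segments),
    n_retained = nrow(out),
    n_removed_length = sum(!keep_len),
    n_removed_probes = sum(!keep_probes),
    length_threshold_bp = thr
  )
  list(segments = out, report = report)
}

.weights <- function(segments, weighting) {
  if (weighting == "length") segments$end - segments$start
  else rep(1, nrow(segments))
}

#' Per-patient genome-wide mean chromosomal copy number
#'
#' Length-weighted mean of segment CCNs over a patient's retained autosomal
#' segments (uniform weighting available for comparison).
#'
#' @param segments segments of one patient.
#' @param weighting `"length"` (default) or `"uniform"`.
#' @return numeric mean CCN; `NA` (with a warning) when no segments remain.
#' @export
patient_mean_ccn <- function(segments, weighting = c("length", "uniform")) {
  weighting <- match.arg(weighting)
  if (nrow(segments) == 0L) {
    warning("patient has no retained segments; mean CCN is NA", call. = FALSE)
    return(NA_real_)
  }
  w <- .weights(segments, weighting)
  sum(w * segmean_to_ccn(segments$segment_mean)) / sum(w)
}

#' Per-patient average absolute segment mean
#'
#' Length-weighted mean of |segment mean|: the magnitude of genome-wide
#' ploidy change regardless of direction, used for the mutation-vs-ploidy
#' screen.
#'
#' @inheritParams patient_mean_ccn
#' @return numeric mean |segment mean|; `NA` when no segments remain.
#' @export
patient_abs_segmean <- function(segments, weighting = c("length", "uniform")) {
  weighting <- match.arg(weighting)
  if (nrow(segments) == 0L) {
    warning("patient has no retained segments; abs segment mean is NA",
            call. = FALSE)
    return(NA_real_)
  }
  w <- .weights(segments, weighting)
  sum(w * abs(segments$segment_mean)) / sum(w)
}

#' Per-patient genome-wide summaries for a cohort
#'
#' Groups segments by patient (barcode prefix) and computes mean CCN and
#' average absolute segment mean per patient.
#'
#' @param segments segment `data.frame` (whole cohort).
#' @param weighting `"length"` or `"uniform"`.
#' @param barcode_length barcode prefix length defining patient identity.
#' @return `data.frame` with `patient_id`, `n_segments`, `mean_ccn`,
#'   `abs_segmean`.
#' @export
patient_summary <- function(segments, weighting = c("length", "uniform"),
                            barcode_length = 12L) {
  weighting <- match.arg(weighting)
  pid <- patient_id(segments$sample_id, barcode_length)
  split_idx <- split(seq_len(nrow(segments)), pid)
  res <- lapply(names(split_idx), function(p) {
    s <- segments[split_idx[[p]], , drop = FALSE]
    data.frame(patient_id = p, n_segments = nrow(s),
               mean_ccn = patient_mean_ccn(s, weighting),
               abs_segmean = patient_abs_segmean(s, weighting),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Project one patient's segments onto chromosome arms
#'
#' Intersects segments with arm intervals (segments spanning the centromere
#' are split at it) and computes the overlap-length-weighted mean value per
#' arm, on the CCN scale (default) or the segment-mean scale. Arms with zero
#' covered length are imputed copy-neutral (CCN 2 / segment mean 0) and
#' listed in `missing_arms`. Segments extending past the chromosome end are
#' clipped with a warning.
#'
#' @param segments segments of one patient.
#' @param arm_table arm table from [read_centromeres()].
#' @param scale `"ccn"` or `"segmean"`.
#' @return A list with `arm_values` (named numeric vector over non-zero-length
#'   arms, genomic order), `arm_covered_bp`, and `missing_arms`.
#' @export
project_to_arms <- function(segments, arm_table, scale = c("ccn", "segmean")) {
  scale <- match.arg(scale)
  arms <- arm_table[!arm_table$zero_length, , drop = FALSE]
  arms <- arms[match(order_arm_labels(arms$arm), arms$arm), , drop = FALSE]
  clen <- attr(arm_table, "chrom_length")
  over <- segments$end > clen[as.character(segments$chrom)]
  if (any(over, na.rm = TRUE)) {
    warning(sum(over), " segment(s) extend past the chromosome end; clipped",
            call. = FALSE)
  }
  vals <- if (scale == "ccn") segmean_to_ccn(segments$segment_mean)
          else segments$segment_mean
  neutral <- if (scale == "ccn") 2 else 0
  vsum <- stats::setNames(numeric(nrow(arms)), arms$arm)
  cov <- vsum
  for (i in seq_len(nrow(arms))) {
    on_chrom <- which(segments$chrom == arms$chrom[i])
    if (length(on_chrom) == 0L) next
    ov <- pmin(segments$end[on_chrom], arms$end[i]) -
      pmax(segments$start[on_chrom], arms$start[i])
    pos <- ov > 0
    vsum[i] <- sum(ov[pos] * vals[on_chrom][pos])
    cov[i] <- sum(ov[pos])
  }
  arm_values <- ifelse(cov > 0, vsum / pmax(cov, 1e-300), neutral)
  names(arm_values) <- arms$arm
  list(arm_values = arm_values,
       arm_covered_bp = cov,
       missing_arms = arms$arm[cov == 0])
}

#' Build the patients-by-arms matrix
#'
#' Stacks per-patient arm profiles into a dense matrix with deterministic
#' row (patient order given) and column (genomic arm order) ordering.
#'
#' @param profiles named list of profiles from [project_to_arms()], names
#'   being unique patient identifiers.
#' @param scale scale of the profiles (recorded as an attribute).
#' @return numeric matrix (patients x arms) with attributes `scale` and
#'   `missing` (logical matrix of imputed cells).
#' @export
build_arm_matrix <- function(profiles, scale = "ccn") {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  ids <- names(profiles)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("profiles must be uniquely named by patient_id", call. = FALSE)
  }
  arms <- names(profiles[[1L]]$arm_values)
  m <- do.call(rbind, lapply(profiles, function(p) p$arm_values[arms]))
  rownames(m) <- ids
  colnames(m) <- arms
  miss <- do.call(rbind, lapply(profiles, function(p) arms %in% p$missing_arms))
  dimnames(miss) <- dimnames(m)
  attr(m, "scale") <- scale
  attr(m, "missing") <- miss
  m
}

#' Arm matrix straight from a cohort segment table
#'
#' Convenience wrapper: groups segments by patient, projects each onto arms
#' and assembles the matrix.
#'
#' @param segments cohort segment `data.frame` (ideally filtered).
#' @param arm_table arm table.
#' @param scale `"ccn"` or `"segmean"`.
#' @param barcode_length barcode prefix length defining patient identity.
#' @return patients x arms matrix; see [build_arm_matrix()].
#' @export
arm_matrix_from_segments <- function(segments, arm_table,
                                     scale = c("ccn", "segmean"),
                                     barcode_length = 12L) {
  scale <- match.arg(scale)
  pid <- patient_id(segments$sample_id, barcode_length)
  split_idx <- split(seq_len(nrow(segments)), pid)
  profiles <- lapply(split_idx, function(i) {
    project_to_arms(segments[i, , drop = FALSE], arm_table, scale)
  })
  build_arm_matrix(profiles, scale)
}
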