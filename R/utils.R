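# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded package functions never perturb the user's random stream.
#' A `NULL` seed evaluates `code` with the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministic mapping from a global integer seed plus a stage label to a
#' stage seed, so every stochastic stage of a run is reproducible from one
#' number. Result is always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
#' @examples
#' derive_seed(1, "nmf")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 100000
  as.integer((abs(as.numeric(seed)) * 977 + h) %% 2147483647)
}

# Order arm labels "1p","1q",...,"22q" genomically.
order_arm_labels <- function(arms) {
  chrom <- as.integer(sub("[pq]$", "", arms))
  side <- sub("^[0-9]+", "", arms)
  arms[order(chrom, side)]
}

# Normalise a chromosome label: strip "chr" prefix, return integer for
# autosomes 1-22, NA otherwise (X, Y, 23, 24, MT, unparsable).
normalise_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  n <- suppressWarnings(as.integer(x))
  n[!is.na(n) & (n < 1L | n > 22L)] <- NA_integer_
  n
}

#' Truncate sample barcodes to patient identifiers
#'
#' TCGA-style barcodes identify aliquots; the first 12 characters identify
#' the patient. Identifiers shorter than the prefix (e.g. plain synthetic
#' IDs) are returned unchanged.
#'
#' @param x character vector of sample barcodes.
#' @param barcode_length prefix length defining patient identity.
#' @return character vector of patient identifiers.
#' @export
#' @examples
#' patient_id(c("TCGA-A3-3308-01A-02R", "P17"))
patient_id <- function(x, barcode_length = 12L) {
  substr(as.character(x), 1L, barcode_length)
}
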