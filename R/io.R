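# Readers and writers for the three input dialects (SEG, MAF-lite, cytoBand)
# and for result tables. All genomic intervals are stored 0-based half-open
# internally; SEG input is interpreted as 1-based inclusive (TCGA convention).

.seg_aliases <- list(
  sample_id    = c("sample", "sample_id", "id", "samplename", "sample_name"),
  chrom        = c("chromosome", "chrom", "chr"),
  start        = c("start", "start_position", "loc_start"),
  end          = c("end", "end_position", "loc_end"),
  num_probes   = c("num_probes", "num_mark", "probes", "markers", "n_probes"),
  segment_mean = c("segment_mean", "seg_mean", "segmean", "mean")
)

.maf_aliases <- list(
  gene          = c("hugo_symbol", "gene", "gene_symbol"),
  sample_id     = c("tumor_sample_barcode", "sample", "sample_id", "barcode"),
  variant_class = c("variant_classification", "variant_class", "classification")
)

#' Variant classes treated as deleterious by default
#'
#' Protein-altering classes: missense, nonsense, frame-shift and in-frame
#' insertions/deletions. Splice-site and silent variants are excluded.
#'
#' @return character vector of variant classification strings.
#' @export
deleterious_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
    "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del")
}

# Variant classes recognised as valid but non-deleterious.
.known_benign <- c(
  "Silent", "Splice_Site", "Splice_Region", "Nonstop_Mutation", "RNA",
  "Intron", "IGR", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
  "Translation_Start_Site", "Targeted_Region"
)

.norm_header <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))

.match_columns <- function(header, aliases, what) {
  hn <- .norm_header(header)
  idx <- vapply(names(aliases), function(field) {
    hit <- which(hn %in% aliases[[field]])
    if (length(hit) == 0L) {
      stop(sprintf("%s file is missing a required column: %s (accepted names: %s)",
                   what, field, paste(aliases[[field]], collapse = ", ")),
           call. = FALSE)
    }
    hit[1L]
  }, integer(1))
  idx
}

#' Read a SEG copy-number segment file
#'
#' Parses a tab-delimited TCGA Level-3 style SEG file. Header names are
#' matched case-insensitively against common aliases (e.g. `Sample`/`ID`,
#' `Chromosome`/`chrom`, `Num_Probes`/`Num.mark`, `Segment_Mean`/`Seg.mean`).
#' Sex chromosomes (X, Y, 23, 24) are excluded; remaining chromosome labels
#' are normalised to integers 1-22. Input coordinates are treated as 1-based
#' inclusive and converted to 0-based half-open.
#'
#' @param path path to a tab-delimited SEG file with a header row.
#' @param extra_aliases optional named list extending the header aliases;
#'   names are `sample_id`, `chrom`, `start`, `end`, `num_probes`,
#'   `segment_mean`.
#' @return A `data.frame` of segments with columns `sample_id`, `chrom`
#'   (integer 1-22), `start`, `end` (0-based half-open), `num_probes`,
#'   `segment_mean` (log2 ratio).
#' @export
read_seg <- function(path, extra_aliases = list()) {
  aliases <- .seg_aliases
  for (nm in names(extra_aliases)) {
    aliases[[nm]] <- c(aliases[[nm]], .norm_header(extra_aliases[[nm]]))
  }
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE,
                           showProgress = FALSE)
  idx <- .match_columns(names(raw), aliases, "SEG")
  if (nrow(raw) == 0L) {
    return(data.frame(sample_id = character(), chrom = integer(),
                      start = numeric(), end = numeric(),
                      num_probes = integer(), segment_mean = numeric(),
                      stringsAsFactors = FALSE))
  }
  sm <- suppressWarnings(as.numeric(raw[[idx["segment_mean"]]]))
  bad <- which(is.na(sm))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric segment mean value '%s' at line %d of %s",
                 raw[[idx["segment_mean"]]][bad[1L]], bad[1L] + 1L, path),
         call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(raw[[idx["start"]]]))
  end <- suppressWarnings(as.numeric(raw[[idx["end"]]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric coordinate at line %d of %s", bad[1L] + 1L, path),
         call. = FALSE)
  }
  probes <- suppressWarnings(as.integer(raw[[idx["num_probes"]]]))
  bad <- which(is.na(probes) | probes < 0L)
  if (length(bad) > 0L) {
    stop(sprintf("invalid probe count at line %d of %s", bad[1L] + 1L, path),
         call. = FALSE)
  }
  chrom <- normalise_chrom(raw[[idx["chrom"]]])
  seg <- data.frame(
    sample_id = as.character(raw[[idx["sample_id"]]]),
    chrom = chrom,
    start = start - 1,          # 1-based inclusive -> 0-based half-open
    end = end,
    num_probes = probes,
    segment_mean = sm,
    stringsAsFactors = FALSE
  )
  seg <- seg[!is.na(seg$chrom), , drop = FALSE]
  bad <- which(seg$end <= seg$start)
  if (length(bad) > 0L) {
    stop(sprintf("segment with end <= start for sample %s chromosome %d",
                 seg$sample_id[bad[1L]], seg$chrom[bad[1L]]), call. = FALSE)
  }
  rownames(seg) <- NULL
  seg
}

#' Read a minimal MAF mutation file
#'
#' Parses a tab-delimited mutation table with gene symbol, tumour sample
#' barcode and variant classification columns. Each call is flagged
#' deleterious when its variant classification belongs to the configured
#' deleterious set; classifications outside both the deleterious set and the
#' known benign set are retained as non-deleterious with a warning.
#'
#' @param path path to the tab-delimited mutation file.
#' @param deleterious character vector of variant classes counted as
#'   deleterious; defaults to [deleterious_classes()].
#' @param barcode_length barcode prefix length defining patient identity.
#' @return A `data.frame` with columns `sample_id`, `patient_id`, `gene`,
#'   `variant_class`, `deleterious`.
#' @export
read_maf <- function(path, deleterious = deleterious_classes(),
                     barcode_length = 12L) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE,
                           showProgress = FALSE)
  idx <- .match_columns(names(raw), .maf_aliases, "MAF")
  if (nrow(raw) == 0L) {
    return(data.frame(sample_id = character(), patient_id = character(),
                      gene = character(), variant_class = character(),
                      deleterious = logical(), stringsAsFactors = FALSE))
  }
  vc <- as.character(raw[[idx["variant_class"]]])
  unknown <- setdiff(unique(vc), c(deleterious, .known_benign))
  if (length(unknown) > 0L) {
    warning("unknown variant classification(s) retained as non-deleterious: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  sample_id <- as.character(raw[[idx["sample_id"]]])
  data.frame(
    sample_id = sample_id,
    patient_id = patient_id(sample_id, barcode_length),
    gene = as.character(raw[[idx["gene"]]]),
    variant_class = vc,
    deleterious = vc %in% deleterious,
    stringsAsFactors = FALSE
  )
}

#' Read centromere positions and derive chromosome-arm intervals
#'
#' Accepts either the 5-column UCSC cytoBand dialect (chrom, start, end,
#' band, stain; no header; optionally gzipped) or a simple 3-column header
#' table (`chrom`, `centromere`, `length`). For cytoBand input, the
#' centromere of each autosome is the boundary between the last p band and
#' the first q band. Arms are labelled `<chrom>p` / `<chrom>q`, 0-based
#' half-open, and tile each chromosome. A zero-length p arm (acrocentric
#' convention: centromere at 0) is retained and flagged.
#'
#' @param path path to the centromere/cytoBand file.
#' @return An arm table `data.frame` with columns `chrom`, `arm`, `start`,
#'   `end`, `length`, `zero_length`, carrying per-chromosome lengths as the
#'   `chrom_length` attribute.
#' @export
read_centromeres <- function(path) {
  first <- utils::read.table(path, sep = "\t", nrows = 1,
                             stringsAsFactors = FALSE)
  if (ncol(first) >= 4L) {
    raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end",
                                           "band", "stain")[seq_len(ncol(first))])
    raw$chrom <- normalise_chrom(raw$chrom)
    raw <- raw[!is.na(raw$chrom), , drop = FALSE]
    cen <- vapply(1:22, function(cc) {
      b <- raw[raw$chrom == cc, , drop = FALSE]
      if (nrow(b) == 0L) return(NA_real_)
      p <- b[grepl("^p", b$band), , drop = FALSE]
      q <- b[grepl("^q", b$band), , drop = FALSE]
      if (nrow(p) == 0L || nrow(q) == 0L) return(NA_real_)
      pe <- max(p$end)
      qs <- min(q$start)
      if (pe != qs) return(NA_real_)
      pe
    }, numeric(1))
    len <- vapply(1:22, function(cc) {
      b <- raw[raw$chrom == cc, , drop = FALSE]
      if (nrow(b) == 0L) NA_real_ else max(b$end)
    }, numeric(1))
  } else {
    raw <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("chrom", "centromere", "length")
    if (!all(need %in% names(raw))) {
      stop("3-column centromere table must have header: chrom, centromere, length",
           call. = FALSE)
    }
    raw$chrom <- normalise_chrom(raw$chrom)
    cen <- rep(NA_real_, 22)
    len <- rep(NA_real_, 22)
    ok <- !is.na(raw$chrom)
    cen[raw$chrom[ok]] <- raw$centromere[ok]
    len[raw$chrom[ok]] <- raw$length[ok]
  }
  missing <- which(is.na(cen) | is.na(len))
  if (length(missing) > 0L) {
    stop("no centromere derivable for chromosome(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(cen < 0 | cen > len)) {
    stop("centromere position outside chromosome for chromosome(s): ",
         paste(which(cen < 0 | cen > len), collapse = ", "), call. = FALSE)
  }
  make_arm_table(centromere = cen, chrom_length = len)
}

#' Construct an arm table from centromere positions
#'
#' @param centromere numeric vector of centromere positions (bp) for
#'   chromosomes 1-22, in order.
#' @param chrom_length numeric vector of chromosome lengths (bp).
#' @return Arm table `data.frame`; see [read_centromeres()].
#' @export
make_arm_table <- function(centromere, chrom_length) {
  stopifnot(length(centromere) == 22L, length(chrom_length) == 22L,
            all(centromere >= 0), all(centromere <= chrom_length))
  at <- data.frame(
    chrom = rep(1:22, each = 2L),
    arm = paste0(rep(1:22, each = 2L), c("p", "q")),
    start = as.numeric(rbind(0, centromere)),
    end = as.numeric(rbind(centromere, chrom_length)),
    stringsAsFactors = FALSE
  )
  at$length <- at$end - at$start
  at$zero_length <- at$length == 0
  attr(at, "chrom_length") <- stats::setNames(as.numeric(chrom_length),
                                              as.character(1:22))
  class(at) <- c("arm_table", "data.frame")
  at
}

#' Arm labels of an arm table
#'
#' @param arm_table an arm table from [read_centromeres()].
#' @param drop_zero drop zero-length (acrocentric p) arms; these carry no
#'   segment data and are excluded from arm matrices.
#' @return character vector of arm labels in genomic order.
#' @export
arm_labels <- function(arm_table, drop_zero = TRUE) {
  a <- if (drop_zero) arm_table[!arm_table$zero_length, , drop = FALSE] else arm_table
  order_arm_labels(a$arm)
}

#' Write a result table as deterministic TSV
#'
#' Columns are written in their given order; doubles are formatted at six
#' significant digits, so repeated writes of the same records are
#' byte-identical.
#'
#' @param records a `data.frame` of records sharing one schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  cols <- lapply(records, function(col) {
    if (is.double(col)) {
      # whole-number columns (e.g. genomic coordinates) keep full precision;
      # fractional columns are statistics, written at 6 significant digits
      whole <- all(is.na(col) | col == round(col))
      out <- if (whole) formatC(col, format = "f", digits = 0)
             else formatC(col, digits = 6, format = "g")
      out[is.na(col)] <- "NA"
      out
    } else {
      as.character(col)
    }
  })
  header <- paste(names(records), collapse = "\t")
  body <- if (nrow(records) > 0L) do.call(paste, c(cols, sep = "\t")) else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
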