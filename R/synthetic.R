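# Seeded generator of SEG + MAF-lite cohorts with planted arm-ploidy
# signatures and gene couplings. Every pipeline stage can be tested against
# the planted truth without any external download.

#' Default synthetic arm table
#'
#' Approximate human autosome lengths (bp) with acrocentric chromosomes
#' (13, 14, 15, 21, 22) modelled with zero-length p arms, since their short
#' arms carry no usable array data; this yields the 39-arm feature set used
#' throughout.
#'
#' @return an arm table; see [make_arm_table()].
#' @export
synthetic_arm_table <- function() {
  len <- c(248, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
           114, 107, 102, 90, 83, 80, 59, 64, 47, 51) * 1e6
  frac <- c(0.50, 0.38, 0.46, 0.26, 0.26, 0.35, 0.38, 0.31, 0.31, 0.30,
            0.40, 0.28, 0, 0, 0, 0.41, 0.30, 0.23, 0.42, 0.44, 0, 0)
  make_arm_table(centromere = round(len * frac), chrom_length = len)
}

#' Default synthetic-cohort configuration
#'
#' The generator's defaults define the study conditions the test-suite
#' exercises: 300 patients over three pseudo-tissues, four planted
#' signatures with pairwise cosine similarities in `[0.35, 0.6]` (distinct
#' but comparably similar, as arm-level signatures sharing a near-diploid
#' backbone are), mixed per-patient exposures with a dominant signature
#' weight of 0.5-0.75, segment-mean noise sd 0.05, 1-5 segments per arm, a
#' 250-gene panel with 5
#' signature-coupled, 5 global-shift and 5 arm-coupled genes (the rest
#' null), 10% short contaminant segments and 5% low-probe segments so both
#' input filters act.
#'
#' @param ... overrides for individual fields.
#' @return named list of generator settings.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_patients = 300L,
    k_true = 4L,
    n_tissues = 3L,
    n_genes = 250L,
    n_sig_coupled = 5L,
    n_global_shift = 5L,
    n_arm_coupled = 5L,
    separation_min = 0.35,
    separation_max = 0.6,
    noise_sd = 0.05,
    seg_per_arm = 1:5,
    contaminant_rate = 0.10,
    lowprobe_frac = 0.05,
    probe_per_bp = 1 / 10000,
    primary_weight = c(0.5, 0.75),
    total_exposure = c(mean = 2, sd = 0.1),
    sig_rate_in = 0.35,
    sig_rate_out = 0.01,
    global_delta = 0.3,
    global_rate = 0.3,
    arm_ccn_effect = -1,
    arm_penetrance = 0.8,
    arm_rate = 0.3,
    arm_coupled_arms = NULL,
    null_rate_range = c(0.02, 0.15)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown synthetic_config key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(ov)] <- ov
  cfg
}

# Internal: draw k sparse non-negative basis columns (column mean 1) whose
# pairwise cosine similarities all fall in [floor, ceiling]; bounded
# retries. The floor keeps signatures comparably similar to one another
# (arm-ploidy signatures share a common near-diploid backbone), which is
# what makes consensus clustering below the true rank genuinely unstable.
.draw_basis <- function(n_arms, k, floor_, ceiling, max_tries = 2000L) {
  for (tr in seq_len(max_tries)) {
    W <- matrix(stats::rexp(n_arms * k), n_arms, k)
    damp <- matrix(stats::runif(n_arms * k) < 0.4, n_arms, k)
    W[damp] <- W[damp] * 0.3
    W <- sweep(W, 2, colMeans(W), "/")
    ok <- TRUE
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        for (j in seq(i + 1L, k)) {
          cs <- cosine_similarity(W[, i], W[, j])
          if (cs > ceiling || cs < floor_) ok <- FALSE
        }
      }
    }
    if (ok) return(W)
  }
  stop("could not draw a basis with the requested separation after ",
       max_tries, " tries", call. = FALSE)
}

#' Draw the planted truth for a synthetic cohort
#'
#' Draws the planted signature basis (well-separated sparse columns),
#' per-patient exposures dominated by a tissue-biased primary signature,
#' and the gene panel with its couplings. Everything downstream of
#' [simulate_cohort()] is determined by this object plus a seed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return object of class `synthetic_truth`: list with `W_true` (arms x
#'   k), `exposures` (patients x k), `primary_signature`, `tissue`,
#'   `gene_models` (`data.frame`), `arm_table`, `config`, `seed`.
#' @export
make_truth <- function(config = synthetic_config(), seed = 1L) {
  at <- synthetic_arm_table()
  arms <- arm_labels(at)
  n_arms <- length(arms)
  k <- config$k_true
  n <- config$n_patients
  n_coupled <- config$n_sig_coupled + config$n_global_shift +
    config$n_arm_coupled
  if (n_coupled > config$n_genes) {
    stop("gene panel too small: ", n_coupled, " coupled genes but n_genes = ",
         config$n_genes, call. = FALSE)
  }
  with_seed(seed, {
    W <- .draw_basis(n_arms, k, config$separation_min, config$separation_max)
    rownames(W) <- arms
    colnames(W) <- paste0("S", seq_len(k))
    # tissue-specific signature preferences: each tissue strongly favours a
    # distinct subset of signatures (round-robin), emulating tissue-enriched
    # signature groups.
    tw <- matrix(0.05, config$n_tissues, k)
    for (s in seq_len(k)) tw[((s - 1L) %% config$n_tissues) + 1L, s] <- 1
    tw <- sweep(tw, 1, rowSums(tw), "/")
    tissue <- paste0("T", sample.int(config$n_tissues, n, replace = TRUE))
    tissue_idx <- as.integer(sub("T", "", tissue))
    primary <- vapply(tissue_idx, function(t) {
      sample.int(k, 1L, prob = tw[t, ])
    }, integer(1))
    dom <- stats::runif(n, config$primary_weight[1], config$primary_weight[2])
    expo <- matrix(0, n, k)
    for (i in seq_len(n)) {
      rest <- stats::rexp(k)
      rest[primary[i]] <- 0
      if (sum(rest) > 0) rest <- rest / sum(rest) * (1 - dom[i])
      w <- rest
      w[primary[i]] <- dom[i]
      total <- max(1.2, stats::rnorm(1, config$total_exposure["mean"],
                                     config$total_exposure["sd"]))
      expo[i, ] <- w * total
    }
    patients <- sprintf("P%03d", seq_len(n))
    rownames(expo) <- patients
    colnames(expo) <- colnames(W)
    # gene panel: couplings first, then null genes with varying base rates
    genes <- sprintf("GENE%03d", seq_len(config$n_genes))
    type <- rep("null", config$n_genes)
    i <- 1L
    if (config$n_sig_coupled > 0L) {
      type[i:(i + config$n_sig_coupled - 1L)] <- "signature_coupled"
      i <- i + config$n_sig_coupled
    }
    if (config$n_global_shift > 0L) {
      type[i:(i + config$n_global_shift - 1L)] <- "global_shift"
      i <- i + config$n_global_shift
    }
    if (config$n_arm_coupled > 0L) {
      type[i:(i + config$n_arm_coupled - 1L)] <- "arm_coupled"
    }
    base_expected <- expo %*% t(W)
    # arm-coupled genes target arms whose cohort-average CCN can absorb the
    # planted effect without hitting zero
    viable_arms <- arms[colMeans(base_expected) >= 1.5]
    gm <- data.frame(gene = genes, type = type,
                     signature = NA_integer_, arm = NA_character_,
                     rate = NA_real_, rate_out = NA_real_,
                     delta = NA_real_, ccn_effect = NA_real_,
                     penetrance = NA_real_, stringsAsFactors = FALSE)
    sc <- which(type == "signature_coupled")
    gm$signature[sc] <- ((seq_along(sc) - 1L) %% k) + 1L
    gm$rate[sc] <- config$sig_rate_in
    gm$rate_out[sc] <- config$sig_rate_out
    gs <- which(type == "global_shift")
    gm$rate[gs] <- config$global_rate
    gm$delta[gs] <- config$global_delta
    ac <- which(type == "arm_coupled")
    if (!is.null(config$arm_coupled_arms)) {
      # explicit coupling targets, e.g. a copy-stable arm as positive control
      gm$arm[ac] <- rep_len(config$arm_coupled_arms, length(ac))
    } else if (length(ac) > 0L) {
      gm$arm[ac] <- sample(viable_arms, length(ac),
                           replace = length(viable_arms) < length(ac))
    }
    gm$rate[ac] <- config$arm_rate
    gm$ccn_effect[ac] <- config$arm_ccn_effect
    gm$penetrance[ac] <- config$arm_penetrance
    nu <- which(type == "null")
    gm$rate[nu] <- stats::runif(length(nu), config$null_rate_range[1],
                                config$null_rate_range[2])
    structure(list(W_true = W, exposures = expo, primary_signature = primary,
                   tissue = tissue, gene_models = gm, arm_table = at,
                   config = config, seed = seed),
              class = "synthetic_truth")
  })
}

#' Simulate a SEG + MAF cohort from a planted truth
#'
#' Draws mutations per gene model, applies arm-coupled CCN effects to
#' penetrant carriers, emits each arm as 1-5 segments whose segment means
#' are the arm's expected value on the log2 scale plus Gaussian noise,
#' injects short contaminant segments and low-probe segments (so the length
#' and probe filters have work to do), and writes the SEG and MAF files.
#' With the same truth and seed the written files are byte-identical.
#'
#' @param truth a `synthetic_truth` from [make_truth()].
#' @param seed integer seed for the realisation.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param noise_sd override of the config segment-mean noise sd (e.g. 0 for
#'   noiseless closure checks).
#' @param contaminant_rate override of the short-contaminant fraction.
#' @param lowprobe_frac override of the low-probe fraction.
#' @param seg_per_arm override of the segments-per-arm candidate counts.
#' @return list of class `synthetic_cohort`: `seg` and `maf` file paths,
#'   `truth`, `expected_ccn` (patients x arms after gene effects),
#'   `mutations` (logical patients x genes), `seed`.
#' @export
simulate_cohort <- function(truth, seed = 1L, dir = tempdir(),
                            prefix = "synthetic", noise_sd = NULL,
                            contaminant_rate = NULL, lowprobe_frac = NULL,
                            seg_per_arm = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  noise_sd <- noise_sd %||% cfg$noise_sd
  contaminant_rate <- contaminant_rate %||% cfg$contaminant_rate
  lowprobe_frac <- lowprobe_frac %||% cfg$lowprobe_frac
  seg_per_arm <- seg_per_arm %||% cfg$seg_per_arm
  at <- truth$arm_table
  arms <- at[!at$zero_length, , drop = FALSE]
  arms <- arms[match(order_arm_labels(arms$arm), arms$arm), , drop = FALSE]
  patients <- rownames(truth$exposures)
  n <- length(patients)
  gm <- truth$gene_models
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    # mutations
    mut <- matrix(FALSE, n, nrow(gm), dimnames = list(patients, gm$gene))
    affected_arm <- vector("list", nrow(gm))
    for (g in seq_len(nrow(gm))) {
      p <- switch(gm$type[g],
        signature_coupled = ifelse(truth$primary_signature == gm$signature[g],
                                   gm$rate[g], gm$rate_out[g]),
        rep(gm$rate[g], n))
      mut[, g] <- stats::runif(n) < p
      if (gm$type[g] == "arm_coupled") {
        affected_arm[[g]] <- mut[, g] & (stats::runif(n) < gm$penetrance[g])
      }
    }
    # expected arm CCN after arm-coupled effects
    expected <- truth$exposures %*% t(truth$W_true)
    for (g in which(gm$type == "arm_coupled")) {
      hit <- affected_arm[[g]]
      expected[hit, gm$arm[g]] <- pmax(0.05,
                                       expected[hit, gm$arm[g]] + gm$ccn_effect[g])
    }
    # per-patient genome-wide |segment mean| shift from global_shift carriers
    shift <- as.numeric(mut[, gm$type == "global_shift", drop = FALSE] %*%
                          gm$delta[gm$type == "global_shift"])
    # segments
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      recs <- vector("list", nrow(arms))
      for (a in seq_len(nrow(arms))) {
        ns <- if (length(seg_per_arm) == 1L) seg_per_arm
              else sample(seg_per_arm, 1L)
        cuts <- sort(stats::runif(ns - 1L))
        bounds <- round(arms$start[a] + c(0, cuts, 1) * (arms$end[a] - arms$start[a]))
        bounds <- unique(bounds)
        ns <- length(bounds) - 1L
        st <- bounds[-length(bounds)]
        en <- bounds[-1L]
        sm <- ccn_to_segmean(expected[i, arms$arm[a]]) +
          stats::rnorm(ns, 0, noise_sd)
        if (shift[i] > 0) {
          sm <- sm + shift[i] * sample(c(-1, 1), ns, replace = TRUE)
        }
        probes <- pmax(10L, as.integer(round((en - st) * cfg$probe_per_bp)))
        low <- stats::runif(ns) < lowprobe_frac
        if (any(low)) probes[low] <- sample(1:9, sum(low), replace = TRUE)
        recs[[a]] <- data.frame(sample_id = patients[i], chrom = arms$chrom[a],
                                start = st, end = en, num_probes = probes,
                                segment_mean = sm, stringsAsFactors = FALSE)
      }
      rows[[i]] <- do.call(rbind, recs)
    }
    seg <- do.call(rbind, rows)
    # short contaminant segments (bottom of the length distribution)
    if (contaminant_rate > 0) {
      n_cont <- round(contaminant_rate * nrow(seg) / (1 - contaminant_rate))
      ci <- sample.int(n, n_cont, replace = TRUE)
      ca <- sample.int(nrow(arms), n_cont, replace = TRUE)
      clen <- round(stats::runif(n_cont, 500, 50000))
      cst <- floor(arms$start[ca] +
                     stats::runif(n_cont) * pmax(1, arms$end[ca] - arms$start[ca] - clen))
      cont <- data.frame(sample_id = patients[ci], chrom = arms$chrom[ca],
                         start = cst, end = cst + clen,
                         num_probes = pmax(10L, as.integer(round(clen * cfg$probe_per_bp))),
                         segment_mean = stats::rnorm(n_cont, 0, 0.5),
                         stringsAsFactors = FALSE)
      seg <- rbind(seg, cont)
    }
    seg <- seg[order(seg$sample_id, seg$chrom, seg$start, seg$end), , drop = FALSE]
    # MAF rows: one deleterious call per mutated patient-gene pair, plus a
    # sprinkling of silent calls that the reader must ignore
    mm_idx <- which(mut, arr.ind = TRUE)
    del_classes <- deleterious_classes()
    maf <- data.frame(
      Hugo_Symbol = gm$gene[mm_idx[, 2L]],
      Tumor_Sample_Barcode = patients[mm_idx[, 1L]],
      Variant_Classification = sample(del_classes, nrow(mm_idx), replace = TRUE),
      stringsAsFactors = FALSE
    )
    n_silent <- max(1L, round(0.1 * nrow(maf)))
    silent <- data.frame(
      Hugo_Symbol = sample(gm$gene, n_silent, replace = TRUE),
      Tumor_Sample_Barcode = sample(patients, n_silent, replace = TRUE),
      Variant_Classification = "Silent",
      stringsAsFactors = FALSE
    )
    maf <- rbind(maf, silent)
    maf <- maf[order(maf$Tumor_Sample_Barcode, maf$Hugo_Symbol,
                     maf$Variant_Classification), , drop = FALSE]
    seg_path <- file.path(dir, paste0(prefix, ".seg"))
    maf_path <- file.path(dir, paste0(prefix, ".maf"))
    .write_seg_file(seg, seg_path)
    .write_maf_file(maf, maf_path)
    structure(list(seg = seg_path, maf = maf_path, truth = truth,
                   expected_ccn = expected, mutations = mut, seed = seed),
              class = "synthetic_cohort")
  })
}

# Internal: emit SEG with 1-based inclusive coordinates and full-precision
# segment means (deterministic formatting).
.write_seg_file <- function(seg, path) {
  lines <- c(
    "Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
    sprintf("%s\t%d\t%.0f\t%.0f\t%d\t%.17g",
            seg$sample_id, seg$chrom, seg$start + 1, seg$end,
            seg$num_probes, seg$segment_mean)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

.write_maf_file <- function(maf, path) {
  lines <- c(
    "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
    sprintf("%s\t%s\t%s", maf$Hugo_Symbol, maf$Tumor_Sample_Barcode,
            maf$Variant_Classification)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Serialise a planted truth to a plain-text file
#'
#' Writes the scalar configuration, the gene models and the planted basis
#' as YAML so a cohort's provenance can be stored beside its SEG/MAF files.
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    seed = truth$seed,
    config = truth$config,
    tissue = truth$tissue,
    primary_signature = truth$primary_signature,
    W_true = apply(truth$W_true, 2, as.numeric, simplify = FALSE),
    arms = rownames(truth$W_true),
    gene_models = truth$gene_models
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}
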