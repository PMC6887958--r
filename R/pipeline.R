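# End-to-end orchestration: config validation, stage sequencing, output
# tables and a checksummed run manifest.

#' Default pipeline configuration
#'
#' Nested list of every stage's settings. `run_pipeline()` rejects unknown
#' keys, and every stochastic stage derives its seed deterministically from
#' the global `seed` plus the stage name.
#'
#' @return named nested list.
#' @export
default_config <- function() {
  list(
    seg = NULL,                      # path to SEG file (required)
    maf = NULL,                      # path to MAF-lite file (required)
    centromeres = NULL,              # path to cytoBand / arm table (required)
    out_dir = NULL,                  # output directory (required)
    cohort = "cohort",
    seed = 1L,
    barcode_length = 12L,
    weighting = "length",
    filters = list(enabled = TRUE, length_percentile = 25, min_probes = 10),
    stats = list(n_perm = 1000L, top_genes = 250L, alpha = 0.05),
    nmf = list(k_range = 2:8, n_runs = 20L, max_iter = 500L, tol = 1e-6,
               selection = "local_min"),
    sig_stats = list(n_perm = 1000L, min_mut = 5L),
    classifier = list(model = "random_forest", genes = NULL, n_top_genes = 5L,
                      test_fraction = 0.2, cv_folds = 5L,
                      rf_n_estimators = 1000L, rf_min_leaf = 30L,
                      importance = TRUE)
  )
}

.merge_config <- function(base, user, path = "") {
  bad <- setdiff(names(user), names(base))
  if (length(bad)) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]], paste0(path, ".", nm))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the whole arm-ploidy analysis pipeline
#'
#' Executes the stages in order: read inputs, filter segments, build arm
#' matrices (CCN and segment-mean scale), per-patient ploidy summaries,
#' gene-vs-ploidy screen, arm-pair correlations with permutation
#' significance, cophenetic rank scan + NMF fit + signature assignment,
#' signature distance ranking and enrichment panel, and the mutation
#' classifiers. All result tables are written as TSV under `out_dir` and
#' listed, with MD5 checksums and the effective configuration, in the
#' returned manifest. A stage failure aborts with the stage name; outputs
#' of completed stages are preserved.
#'
#' @param config nested list of overrides of [default_config()], or the
#'   path to a YAML file of the same shape. `seg`, `maf`, `centromeres`
#'   and `out_dir` are required.
#' @return list with `manifest` (`data.frame` of file, md5), `config`
#'   (effective), and the in-memory stage results (`arm_matrix`,
#'   `rank_scan`, `model`, `assignment`, ...).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(default_config(), config)
  for (key in c("seg", "maf", "centromeres", "out_dir")) {
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required",
                                  call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, paste0(cfg$cohort, "_", name, ".tsv"))
    write_table(df, p)
    outputs <<- c(outputs, p)
  }

  segments <- .stage("read_inputs", read_seg(cfg$seg))
  calls <- .stage("read_inputs", read_maf(cfg$maf,
                                          barcode_length = cfg$barcode_length))
  arm_table <- .stage("read_inputs", read_centromeres(cfg$centromeres))

  if (isTRUE(cfg$filters$enabled)) {
    fl <- .stage("filter", filter_segments(segments,
                                           cfg$filters$length_percentile,
                                           cfg$filters$min_probes))
    segments <- fl$segments
    emit(fl$report, "filter_report")
  }

  summary <- .stage("patient_summary",
                    patient_summary(segments, cfg$weighting,
                                    cfg$barcode_length))
  emit(summary, "patient_summary")

  am_ccn <- .stage("arm_matrix",
                   arm_matrix_from_segments(segments, arm_table, "ccn",
                                            cfg$barcode_length))
  am_sm <- .stage("arm_matrix",
                  arm_matrix_from_segments(segments, arm_table, "segmean",
                                           cfg$barcode_length))
  emit(data.frame(patient_id = rownames(am_ccn), am_ccn, check.names = FALSE),
       "arm_matrix_ccn")
  emit(data.frame(patient_id = rownames(am_sm), am_sm, check.names = FALSE),
       "arm_matrix_segmean")

  mm <- .stage("mutation_matrix",
               build_mutation_matrix(calls, rownames(am_ccn),
                                     cfg$stats$top_genes))

  abs_sm <- stats::setNames(summary$abs_segmean, summary$patient_id)
  mean_ccn <- stats::setNames(summary$mean_ccn, summary$patient_id)
  ploidy <- .stage("ploidy_tests", rank_genes_ploidy(abs_sm, mm, mean_ccn))
  emit(ploidy, "gene_ploidy_tests")

  corr <- .stage("arm_correlations", {
    long <- arm_correlation_matrix(am_ccn)
    sig <- do.call(rbind, lapply(seq_len(nrow(long)), function(i) {
      arm_correlation_significance(
        am_ccn[, long$arm_a[i]], am_ccn[, long$arm_b[i]],
        n_perm = cfg$stats$n_perm,
        seed = derive_seed(cfg$seed, paste0("corr_", long$arm_a[i], "_",
                                            long$arm_b[i])))
    }))
    cbind(long[, c("arm_a", "arm_b")], sig, flag = long$flag)
  })
  emit(corr, "arm_correlations")

  scan <- .stage("rank_scan",
                 select_rank(am_ccn, cfg$nmf$k_range, cfg$nmf$n_runs,
                             seed = derive_seed(cfg$seed, "rank_scan"),
                             rule = cfg$nmf$selection,
                             max_iter = cfg$nmf$max_iter, tol = cfg$nmf$tol))
  emit(scan$scan, "rank_scan")

  model <- .stage("nmf_fit",
                  nmf_factorize(am_ccn, scan$selected_k,
                                seed = derive_seed(cfg$seed, "nmf_fit"),
                                max_iter = cfg$nmf$max_iter,
                                tol = cfg$nmf$tol))
  emit(data.frame(arm = rownames(model$W), model$W, check.names = FALSE),
       "signature_basis")
  emit(data.frame(patient_id = rownames(model$H), model$H,
                  check.names = FALSE), "signature_exposures")

  assignment <- .stage("assignment", assign_signatures(model))
  emit(data.frame(patient_id = names(assignment),
                  signature = as.integer(assignment)), "signature_assignment")

  dist_rank <- .stage("signature_distance",
                      rank_genes_by_distance(model$H, mm,
                                             n_perm = cfg$sig_stats$n_perm,
                                             seed = derive_seed(cfg$seed, "distance"),
                                             min_mut = cfg$sig_stats$min_mut))
  emit(dist_rank, "signature_distance")

  enrich <- .stage("signature_enrichment",
                   signature_enrichment_panel(assignment, mm,
                                              n_perm = cfg$sig_stats$n_perm,
                                              seed = derive_seed(cfg$seed, "enrichment")))
  emit(enrich, "signature_enrichment")

  cls <- .stage("classify", {
    genes <- cfg$classifier$genes %||%
      colnames(mm)[seq_len(min(cfg$classifier$n_top_genes, ncol(mm)))]
    cc <- classifier_config(model = cfg$classifier$model,
                            test_fraction = cfg$classifier$test_fraction,
                            cv_folds = cfg$classifier$cv_folds,
                            rf_n_estimators = cfg$classifier$rf_n_estimators,
                            rf_min_leaf = cfg$classifier$rf_min_leaf,
                            seed = derive_seed(cfg$seed, "classify"))
    run_gene_panel(am_ccn, mm, genes, cc,
                   importance = isTRUE(cfg$classifier$importance))
  })
  emit(cls$reports, "classifier_reports")
  if (!is.null(cls$importance)) emit(cls$importance, "classifier_importance")

  cfg_path <- file.path(cfg$out_dir, paste0(cfg$cohort, "_effective_config.yaml"))
  yaml::write_yaml(cfg, cfg_path)
  outputs <- c(outputs, cfg_path)
  manifest <- data.frame(file = basename(outputs),
                         md5 = as.character(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(cfg$out_dir, paste0(cfg$cohort, "_manifest.tsv"))
  write_table(manifest, manifest_path)

  list(manifest = manifest, config = cfg, arm_matrix = am_ccn,
       arm_matrix_segmean = am_sm, mutation_matrix = mm,
       patient_summary = summary, ploidy_tests = ploidy,
       arm_correlations = corr, rank_scan = scan, model = model,
       assignment = assignment, signature_distance = dist_rank,
       signature_enrichment = enrich, classifier = cls)
}
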