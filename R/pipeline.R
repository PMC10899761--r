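#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs.  Inputs can be given as
#' file paths (DIA-NN report, MaxQuant tables, design TSV/YAML) or as
#' in-memory objects (long records and a `silac_design`), which is how the
#' synthetic generator feeds the pipeline.
#'
#' @param acquisition "DDA" or "DIA".
#' @param design A `silac_design` or a path readable by
#'   [read_sample_design()].
#' @param diann_report Path to a DIA-NN style report (DIA route).
#' @param maxquant_peptides Path to peptides.txt (DDA peptide route).
#' @param records In-memory long records (alternative to the path inputs).
#' @param normalization A [normalization_config()] or a method name.
#' @param q_max,translated_q_max DIA q-value filters.
#' @param min_peptides,min_reps,n_reps Detection-filter parameters.
#' @param alpha Significance level for the differential test.
#' @param var_equal Use the pooled-variance Student test instead of Welch
#'   in the differential comparison (see [welch_t_test()]).
#' @param impute Optional [imputation_config()].
#' @param enrichment Optional [crosslink_enrichment()] result to join.
#' @param out_dir Optional output directory; when set, tables and a
#'   summary JSON are written there.
#' @param seed Seed recorded in the fingerprint and used for imputation
#'   when its config carries none.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(acquisition = c("DIA", "DDA"),
                            design,
                            diann_report = NULL,
                            maxquant_peptides = NULL,
                            records = NULL,
                            normalization = normalization_config(),
                            q_max = 0.01, translated_q_max = 0.01,
                            min_peptides = 2L, min_reps = 2L, n_reps = 3L,
                            alpha = 0.05,
                            var_equal = FALSE,
                            impute = NULL,
                            enrichment = NULL,
                            out_dir = NULL,
                            seed = 1L) {
  acquisition <- match.arg(acquisition)
  if (is.character(normalization)) {
    normalization <- normalization_config(method = normalization)
  }
  if (is.character(design)) {
    if (!file.exists(design)) {
      abort_silac(sprintf("design file not found: %s", design),
        class = "silacquant_error_config")
    }
    design <- read_sample_design(design)
  }
  for (p in c(diann_report, maxquant_peptides)) {
    if (!is.null(p) && !file.exists(p)) {
      abort_silac(sprintf("input file not found: %s", p),
        class = "silacquant_error_config")
    }
  }
  if (is.null(records) && is.null(diann_report) && is.null(maxquant_peptides)) {
    abort_silac("no input: provide records, diann_report or maxquant_peptides",
      class = "silacquant_error_config")
  }
  structure(
    list(acquisition = acquisition, design = design,
      diann_report = diann_report, maxquant_peptides = maxquant_peptides,
      records = records, normalization = normalization,
      q_max = q_max, translated_q_max = translated_q_max,
      min_peptides = as.integer(min_peptides),
      min_reps = as.integer(min_reps), n_reps = as.integer(n_reps),
      alpha = alpha, var_equal = var_equal, impute = impute,
      enrichment = enrichment,
      out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# Stable fingerprint of the analysis settings (not the data).
config_fingerprint <- function(config) {
  rlang::hash(list(
    acquisition = config$acquisition,
    normalization = config$normalization,
    q_max = config$q_max, translated_q_max = config$translated_q_max,
    min_peptides = config$min_peptides, min_reps = config$min_reps,
    n_reps = config$n_reps, alpha = config$alpha,
    var_equal = config$var_equal,
    impute = config$impute, seed = config$seed
  ))
}

#' Run the full quantitation pipeline
#'
#' Executes ingest, normalization, ratio computation with singleton
#' masking, median aggregation, the detection-filter chain, optional
#' imputation, the differential RNA-association test and the metrics
#' report.  With `out_dir` set, writes the protein table, differential
#' results and a summary JSON (stage counts, thresholds, config
#' fingerprint); identical config, inputs and seed produce identical
#' files.
#'
#' @param config A [pipeline_config()].
#' @return A `silac_run` list: `matrix_raw`, `matrix_norm`,
#'   `peptide_ratios`, `protein_table`, `differential`, `metrics`,
#'   `counts`, `fingerprint`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design

  records <- config$records
  if (is.null(records)) {
    records <- if (config$acquisition == "DIA") {
      read_diann_report(config$diann_report, q_max = config$q_max,
        translated_q_max = config$translated_q_max) |>
        diann_records_to_long()
    } else {
      read_maxquant_peptides(config$maxquant_peptides)
    }
  }

  mat_raw <- build_intensity_matrix(records, design)
  norm_method <- config$normalization$method
  mat_norm <- if (norm_method == "vsn") {
    normalize_vsn(mat_raw, config$normalization)
  } else if (norm_method == "none_passthrough") {
    log2_transform(mat_raw)
  } else {
    normalize_intensities(log2_transform(mat_raw), config$normalization)
  }

  ratios <- compute_peptide_ratios(mat_norm, design) |>
    mask_single_peptide_quantitations()
  protein_table <- aggregate_protein_ratios(ratios) |>
    apply_detection_filters(design,
      min_peptides = config$min_peptides,
      min_reps = config$min_reps, n_reps = config$n_reps)

  diff_input <- filter(protein_table, .data$processed_flag)
  if (!is.null(config$impute)) {
    imp <- config$impute
    if (imp$method == "random_forest" && is.null(imp$seed)) {
      imp$seed <- config$seed
    }
    # Imputation takes every gene quantified at least twice at either time
    # point (the stage-1 gate), so proteins missing a whole time point can
    # be filled in; predictions resting on a near-empty time point are
    # excluded from significance only for the random-forest route (the
    # half-minimum route exists precisely to call such proteins).
    stage1 <- protein_table |>
      filter(.data$stage1_flag) |>
      select(-"processed_flag")
    diff_input <- impute_protein_ratios(stage1, imp)
    if (imp$method == "random_forest") {
      diff_input <- filter(diff_input, .data$imputation_robust)
    }
  }
  differential <- differential_association(diff_input,
    alpha = config$alpha, enrichment = config$enrichment,
    var_equal = config$var_equal %||% FALSE)
  metrics <- metrics_report(mat_raw, design, protein_table,
    arm = config$acquisition)

  counts <- list(
    n_features = nrow(mat_raw),
    n_genes = n_distinct(protein_table$gene),
    n_stage1 = protein_table |> distinct(.data$gene, .data$stage1_flag) |>
      pull(.data$stage1_flag) |> sum(),
    n_processed = protein_table |> distinct(.data$gene, .data$processed_flag) |>
      pull(.data$processed_flag) |> sum(),
    n_tested = attr(differential, "n_tested"),
    n_excluded = attr(differential, "n_excluded"),
    n_significant_primary = sum(differential$significant_primary, na.rm = TRUE),
    n_significant_bh = sum(differential$significant_bh, na.rm = TRUE)
  )
  stopifnot(counts$n_stage1 >= counts$n_processed,
    counts$n_processed >= counts$n_tested || !is.null(config$impute))

  run <- structure(
    list(matrix_raw = mat_raw, matrix_norm = mat_norm,
      peptide_ratios = ratios, protein_table = protein_table,
      differential = differential, metrics = metrics, counts = counts,
      fingerprint = config_fingerprint(config), config = config),
    class = "silac_run"
  )
  if (!is.null(config$out_dir)) {
    write_run(run, config$out_dir)
  }
  run
}

#' @export
print.silac_run <- function(x, ...) {
  cat(sprintf("# silac_run (%s): %d features, %d genes, %d processed, %d tested\n",
    x$config$acquisition, x$counts$n_features, x$counts$n_genes,
    x$counts$n_processed, x$counts$n_tested))
  cat(sprintf("  significant (primary/BH): %d / %d; thresholds p10=%.4f p90=%.4f\n",
    x$counts$n_significant_primary, x$counts$n_significant_bh,
    attr(x$differential, "thresholds")["p10"],
    attr(x$differential, "thresholds")["p90"]))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- run$fingerprint
  write_matrix_tsv(run$protein_table, file.path(out_dir, "protein_table.tsv"),
    comment = paste("config", fp))
  write_matrix_tsv(as_tibble(run$differential),
    file.path(out_dir, "differential.tsv"), comment = paste("config", fp))
  thresholds <- attr(run$differential, "thresholds")
  summary <- list(
    acquisition = run$config$acquisition,
    fingerprint = fp,
    counts = run$counts,
    thresholds = list(p10 = unname(thresholds["p10"]),
      p90 = unname(thresholds["p90"])),
    alpha = run$config$alpha,
    median_max_sd = run$metrics$median_max_sd,
    mean_pct_missing = mean(run$metrics$missingness$pct_missing)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Compare two completed acquisition runs
#'
#' Builds the cross-acquisition report: detected / processed / tested
#' protein counts per arm, significant-gene counts with their overlap and
#' any sign conflicts among commonly significant genes (expected zero on
#' concordant data), median MaxSD per arm, realized missingness, and the
#' fold-change R-squared ladder at increasingly restricted gene sets
#' (all shared tested genes; crosslink-enriched; enriched and significant
#' in arm B; significant in both).
#'
#' @param run_a,run_b `silac_run` objects (conventionally DDA then DIA)
#'   on designs with matching time points.
#' @param enriched_genes Optional character vector of crosslink-enriched
#'   genes for the restricted correlation levels.
#' @return A `silac_comparison` list.
#' @export
compare_acquisitions <- function(run_a, run_b, enriched_genes = NULL) {
  stopifnot(inherits(run_a, "silac_run"), inherits(run_b, "silac_run"))
  tps <- function(r) sort(unique(r$protein_table$timepoint))
  if (!identical(tps(run_a), tps(run_b))) {
    abort_silac("runs cover different time points; cannot compare",
      class = "silacquant_error_comparison"
    )
  }
  d_a <- run_a$differential
  d_b <- run_b$differential
  fc_a <- select(as_tibble(d_a), "gene", "log2fc")
  fc_b <- select(as_tibble(d_b), "gene", "log2fc")

  sig <- function(d) d$gene[!is.na(d$significant_primary) & d$significant_primary]
  sig_a <- sig(d_a)
  sig_b <- sig(d_b)
  common <- intersect(sig_a, sig_b)
  sign_a <- sign(d_a$log2fc[match(common, d_a$gene)])
  sign_b <- sign(d_b$log2fc[match(common, d_b$gene)])
  n_conflict <- sum(sign_a != sign_b, na.rm = TRUE)

  safe_r2 <- function(genes = NULL) {
    tryCatch(
      cross_acquisition_fc_correlation(fc_a, fc_b, genes = genes)[c("r2", "n")],
      silacquant_error = function(e) list(r2 = NA_real_, n = 0L)
    )
  }
  r2 <- list(all_tested = safe_r2())
  if (!is.null(enriched_genes)) {
    r2$enriched <- safe_r2(enriched_genes)
    r2$enriched_significant_b <- safe_r2(intersect(enriched_genes, sig_b))
    r2$significant_both <- safe_r2(
      if (is.null(enriched_genes)) common else intersect(enriched_genes, common))
  }

  structure(
    list(
      arms = c(run_a$config$acquisition, run_b$config$acquisition),
      detected = c(a = run_a$counts$n_genes, b = run_b$counts$n_genes),
      processed = c(a = run_a$counts$n_processed, b = run_b$counts$n_processed),
      tested = c(a = run_a$counts$n_tested, b = run_b$counts$n_tested),
      significant = c(a = length(sig_a), b = length(sig_b)),
      n_common_significant = length(common),
      n_sign_conflicts = n_conflict,
      median_max_sd = c(a = run_a$metrics$median_max_sd,
        b = run_b$metrics$median_max_sd),
      mean_pct_missing = c(
        a = mean(run_a$metrics$missingness$pct_missing),
        b = mean(run_b$metrics$missingness$pct_missing)),
      r2 = r2
    ),
    class = "silac_comparison"
  )
}

#' @export
print.silac_comparison <- function(x, ...) {
  cat(sprintf("# acquisition comparison: %s (a) vs %s (b)\n",
    x$arms[1], x$arms[2]))
  cat(sprintf("  detected: %d vs %d; processed: %d vs %d; tested: %d vs %d\n",
    x$detected["a"], x$detected["b"], x$processed["a"], x$processed["b"],
    x$tested["a"], x$tested["b"]))
  cat(sprintf("  significant: %d vs %d (common %d, sign conflicts %d)\n",
    x$significant["a"], x$significant["b"], x$n_common_significant,
    x$n_sign_conflicts))
  cat(sprintf("  median MaxSD: %.3f vs %.3f; %% missing: %.1f vs %.1f\n",
    x$median_max_sd["a"], x$median_max_sd["b"],
    x$mean_pct_missing["a"], x$mean_pct_missing["b"]))
  cat(sprintf("  R2 (all tested): %.3f (n=%d)\n",
    x$r2$all_tested$r2, x$r2$all_tested$n))
  invisible(x)
}
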