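#' Inter-replicate correlation of raw log2 intensities
#'
#' For every pair of replicate samples in a group, the Pearson correlation
#' (squared) over features non-missing in both, summarized as mean and SD
#' over pairs.  Pairs sharing fewer than three features are skipped with a
#' warning.
#'
#' @param mat A log2-scale `silac_matrix` (raw, not normalized, by
#'   convention).
#' @param replicate_samples Character vector of >= 2 sample column names
#'   forming the replicate group.
#' @return A list: `mean_r2`, `sd_r2`, and a `pairs` tibble.
#' @export
replicate_correlation <- function(mat, replicate_samples) {
  if (length(replicate_samples) < 2) {
    abort_silac("replicate correlation needs >= 2 samples",
      class = "silacquant_error_design")
  }
  m <- matrix_values(mat)[, replicate_samples, drop = FALSE]
  combs <- utils::combn(replicate_samples, 2, simplify = FALSE)
  pairs <- purrr::map_dfr(combs, function(pr) {
    ok <- complete.cases(m[, pr])
    if (sum(ok) < 3) {
      warn(sprintf("pair %s / %s shares < 3 features; skipped", pr[1], pr[2]))
      return(tibble(sample_a = pr[1], sample_b = pr[2],
        n_shared = sum(ok), r2 = NA_real_))
    }
    r <- cor(m[ok, pr[1]], m[ok, pr[2]])
    tibble(sample_a = pr[1], sample_b = pr[2], n_shared = sum(ok), r2 = r^2)
  })
  list(
    mean_r2 = mean(pairs$r2, na.rm = TRUE),
    sd_r2 = sd(pairs$r2, na.rm = TRUE),
    pairs = pairs
  )
}

#' Maximum inter-replicate standard deviation of protein ratios
#'
#' Per gene, the replicate SD (n - 1 denominator) of the light/heavy ratio
#' at each time point, keeping the higher of the two --- the
#' inter-replicate consistency metric.  Time points with fewer than two
#' non-missing ratios are excluded from the maximum; a gene with no
#' qualifying time point gets a missing value.  Ratios enter on linear
#' scale by default, with a log2 option recorded in the output.
#'
#' @param table A protein quant table.
#' @param log2_ratios Compute SDs on log2 ratios instead of linear.
#' @return A tibble: `gene`, `max_sd`, and the scale used.
#' @export
max_replicate_sd <- function(table, log2_ratios = FALSE) {
  assert_columns(table, c("gene", "timepoint", "replicate", "ratio_lh"),
    what = "protein quant table")
  vals <- if (log2_ratios) log2(table$ratio_lh) else table$ratio_lh
  table |>
    mutate(.val = vals) |>
    group_by(.data$gene, .data$timepoint) |>
    summarise(
      tp_sd = if (sum(!is.na(.data$.val)) >= 2) sd(.data$.val, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    group_by(.data$gene) |>
    summarise(
      max_sd = if (all(is.na(.data$tp_sd))) NA_real_ else max(.data$tp_sd, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(ratio_scale = if (log2_ratios) "log2" else "linear")
}

#' Detection counts, missingness and spread per condition
#'
#' Summarizes a feature (or protein) intensity matrix against its design:
#' per condition, the mean and SD over replicates of the number of
#' detected features (non-missing intensity); the percentage of missing
#' cells; and the per-sample interquartile range of log2 intensities.
#'
#' @param mat A `silac_matrix` (linear or log2 scale).
#' @param design A [sample_design()].
#' @return A list of tibbles: `detection` (per condition), `missingness`
#'   (per condition), `iqr` (per sample).
#' @export
detection_and_missingness_summary <- function(mat, design) {
  units <- normalization_groups(design)
  m <- matrix_values(mat)[, units$sample, drop = FALSE]
  if (intensity_scale(mat) == "linear") {
    m[!is.na(m) & m == 0] <- NA_real_
    m <- log2(m)
  }

  per_sample <- units |>
    mutate(
      n_detected = colSums(!is.na(m))[.data$sample],
      pct_missing = 100 * colMeans(is.na(m))[.data$sample],
      log2_iqr = apply(m, 2, stats::IQR, na.rm = TRUE)[.data$sample],
      condition = paste(.data$timepoint, .data$channel, sep = "_")
    )
  detection <- per_sample |>
    group_by(.data$condition) |>
    summarise(
      mean_detected = mean(.data$n_detected),
      sd_detected = sd(.data$n_detected),
      .groups = "drop"
    )
  missingness <- per_sample |>
    group_by(.data$condition) |>
    summarise(pct_missing = mean(.data$pct_missing), .groups = "drop")
  list(
    detection = detection,
    missingness = missingness,
    iqr = select(per_sample, "sample", "condition", "log2_iqr")
  )
}

#' Cross-acquisition fold-change correlation
#'
#' Pearson R-squared between per-gene log2 fold changes measured in two
#' acquisitions, over the genes non-missing in both.  Optional
#' restriction to a gene subset (e.g. crosslink-enriched, or significant
#' in one or both arms) never reaches outside the intersection.
#'
#' @param fc_a,fc_b Tibbles with columns `gene` and `log2fc`.
#' @param genes Optional character vector restricting the comparison.
#' @return A list: `r2`, `n`, and the joined tibble.
#' @export
cross_acquisition_fc_correlation <- function(fc_a, fc_b, genes = NULL) {
  assert_columns(fc_a, c("gene", "log2fc"), "fc_a")
  assert_columns(fc_b, c("gene", "log2fc"), "fc_b")
  joined <- inner_join(
    select(as_tibble(fc_a), "gene", fc_a = "log2fc"),
    select(as_tibble(fc_b), "gene", fc_b = "log2fc"),
    by = "gene"
  ) |>
    filter(!is.na(.data$fc_a), !is.na(.data$fc_b))
  if (!is.null(genes)) {
    joined <- filter(joined, .data$gene %in% genes)
  }
  if (nrow(joined) == 0) {
    abort_silac("no shared genes with fold changes in both acquisitions",
      class = "silacquant_error_insufficient_data")
  }
  if (nrow(joined) < 3) {
    abort_silac("fold-change correlation needs >= 3 shared genes",
      class = "silacquant_error_insufficient_data")
  }
  list(r2 = cor(joined$fc_a, joined$fc_b)^2, n = nrow(joined), data = joined)
}

#' Assemble the acquisition metrics report
#'
#' Bundles the per-condition detection/missingness summary, replicate
#' R-squared of raw log2 intensities in the heavy (control) channel, and
#' the median/mean MaxSD of the protein quant table into one report
#' object, the per-arm half of an acquisition comparison.
#'
#' @param mat The raw (unnormalized) feature intensity matrix.
#' @param design The arm's [sample_design()].
#' @param protein_table The arm's protein quant table (post-filter).
#' @param arm Label for the arm ("DDA"/"DIA").
#' @return A `silac_metrics` list.
#' @export
metrics_report <- function(mat, design, protein_table, arm = "arm") {
  summ <- detection_and_missingness_summary(mat, design)
  units <- normalization_groups(design)
  heavy_by_tp <- units |>
    filter(.data$channel == "heavy", !is.na(.data$timepoint)) |>
    group_by(.data$timepoint) |>
    summarise(samples = list(.data$sample), .groups = "drop")
  log2_mat <- if (intensity_scale(mat) == "linear") log2_transform(mat) else mat
  r2 <- purrr::map(setNames(heavy_by_tp$samples, heavy_by_tp$timepoint),
    ~ replicate_correlation(log2_mat, .x))
  maxsd <- max_replicate_sd(protein_table)
  processed <- if ("processed_flag" %in% names(protein_table)) {
    protein_table |>
      distinct(.data$gene, .data$processed_flag) |>
      pull(.data$processed_flag) |>
      sum()
  } else {
    NA_integer_
  }
  structure(
    list(
      arm = arm,
      detection = summ$detection,
      missingness = summ$missingness,
      iqr = summ$iqr,
      replicate_r2 = r2,
      max_sd = maxsd,
      n_proteins = n_distinct(protein_table$gene),
      n_processed = processed,
      median_max_sd = median(maxsd$max_sd, na.rm = TRUE),
      mean_max_sd = mean(maxsd$max_sd, na.rm = TRUE)
    ),
    class = "silac_metrics"
  )
}

#' @export
print.silac_metrics <- function(x, ...) {
  cat(sprintf("# acquisition metrics: %s\n", x$arm))
  cat(sprintf("  proteins: %d (processed: %s)\n", x$n_proteins,
    format(x$n_processed)))
  cat(sprintf("  median/mean MaxSD: %.3f / %.3f\n", x$median_max_sd,
    x$mean_max_sd))
  cat(sprintf("  mean %% missing: %.1f\n", mean(x$missingness$pct_missing)))
  invisible(x)
}
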