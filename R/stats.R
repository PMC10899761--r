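#' Two-sided Welch t-test with degenerate-case handling
#'
#' Wraps [stats::t.test()] (unequal-variance by default, the safer choice
#' at n = 3) and pins down the corner cases a screening pipeline hits:
#' fewer than two non-missing values in either group gives a missing
#' p-value; two zero-variance groups give p = 1 when the means agree and
#' the smallest representable p when they differ.
#'
#' @param group_a,group_b Numeric vectors; missing values are dropped.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return A one-row tibble: `t`, `df`, `p_value`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t_test <- function(group_a, group_b, var_equal = FALSE) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    return(tibble(t = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2, p_value = 1))
    }
    return(tibble(t = sign(mean(a) - mean(b)) * Inf,
      df = length(a) + length(b) - 2, p_value = .Machine$double.xmin))
  }
  fit <- t.test(a, b, var.equal = var_equal)
  tibble(t = unname(fit$statistic), df = unname(fit$parameter),
    p_value = fit$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values by the BH step-up rule with m equal to the number of
#' non-missing entries; missing entries pass through as missing.  Delegates
#' to [stats::p.adjust()] on the non-missing subset.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\], possibly with
#'   missing entries.
#' @return Adjusted q-values, same length and missingness as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort_silac("p-values must lie in [0, 1]",
      class = "silacquant_error_domain")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}

#' Percentile fold-change thresholds
#'
#' The 10th and 90th percentiles of the log2 fold-change distribution,
#' estimated with the linear-interpolation (type 7) quantile: index
#' h = (n - 1) q, interpolated between the flanking order statistics.
#' These empirical tails replace an arbitrary fixed fold-change cutoff so
#' that stringency stays comparable across datasets.
#'
#' @param log2fc Numeric vector; needs at least 10 non-missing values.
#' @param probs The two tail probabilities (default 0.1 and 0.9).
#' @return Named numeric vector `c(p10, p90)`.
#' @export
percentile_thresholds <- function(log2fc, probs = c(0.1, 0.9)) {
  x <- log2fc[!is.na(log2fc)]
  if (length(x) < 10) {
    abort_silac(
      sprintf("percentile thresholds need >= 10 non-missing values (got %d)",
        length(x)),
      class = "silacquant_error_insufficient_data"
    )
  }
  q <- quantile(x, probs = probs, type = 7, names = FALSE)
  c(p10 = q[1], p90 = q[2])
}

#' Crosslink-enrichment classification
#'
#' Classifies proteins as genuinely RNA-bound by comparing UV-crosslinked
#' against non-crosslinked samples on mean-normalized log2 protein
#' intensities.  A protein is enriched when it is detected exclusively in
#' crosslinked samples, or when a two-sided Welch t-test across samples
#' (light and heavy channels counted as separate samples) survives BH
#' correction at `alpha` with a linear fold change above `fc_threshold`.
#'
#' @param cl_matrix,noncl_matrix Tibbles with a `gene` column and one
#'   numeric log2-intensity column per sample (>= 2 samples each side), or
#'   `silac_matrix` objects.
#' @param alpha FDR threshold (default 0.05).
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param var_equal Passed to [welch_t_test()].
#' @return A `silac_enrichment` tibble: `gene`, `n_detected_cl`,
#'   `n_detected_noncl`, `mean_log2fc`, `p_value`, `q_value`,
#'   `exclusive_to_cl`, `enriched`.
#' @export
crosslink_enrichment <- function(cl_matrix, noncl_matrix, alpha = 0.05,
                                 fc_threshold = 1.5, var_equal = FALSE) {
  get_vals <- function(x) {
    x <- as_tibble(x)
    assert_columns(x, "gene", what = "intensity table")
    vals <- x[setdiff(names(x), c("gene", "feature_id", "protein_ids", "peptide_seq"))]
    if (ncol(vals) < 2) {
      abort_silac("crosslink enrichment needs >= 2 samples per side",
        class = "silacquant_error_design")
    }
    stats::aggregate(as.matrix(vals), by = list(gene = x$gene), FUN = mean,
      na.rm = TRUE) |>
      as_tibble()
  }
  cl <- get_vals(cl_matrix)
  noncl <- get_vals(noncl_matrix)
  genes <- union(cl$gene, noncl$gene)
  cl_m <- as.matrix(cl[-1])[match(genes, cl$gene), , drop = FALSE]
  noncl_m <- as.matrix(noncl[-1])[match(genes, noncl$gene), , drop = FALSE]
  cl_m[is.nan(cl_m)] <- NA_real_
  noncl_m[is.nan(noncl_m)] <- NA_real_

  n_cl <- rowSums(!is.na(cl_m))
  n_noncl <- rowSums(!is.na(noncl_m))
  present <- n_cl + n_noncl > 0
  res <- tibble(
    gene = genes[present],
    n_detected_cl = n_cl[present],
    n_detected_noncl = n_noncl[present]
  )
  cl_m <- cl_m[present, , drop = FALSE]
  noncl_m <- noncl_m[present, , drop = FALSE]

  res$mean_log2fc <- rowMeans(cl_m, na.rm = TRUE) - rowMeans(noncl_m, na.rm = TRUE)
  res$mean_log2fc[is.nan(res$mean_log2fc)] <- NA_real_
  tests <- purrr::map2_dfr(
    seq_len(nrow(res)), res$n_detected_noncl,
    function(i, nn) {
      if (nn == 0) {
        return(tibble(t = NA_real_, df = NA_real_, p_value = NA_real_))
      }
      welch_t_test(cl_m[i, ], noncl_m[i, ], var_equal = var_equal)
    }
  )
  res$p_value <- tests$p_value
  res$q_value <- benjamini_hochberg(res$p_value)
  res$exclusive_to_cl <- res$n_detected_cl >= 1 & res$n_detected_noncl == 0
  res$enriched <- res$exclusive_to_cl |
    (!is.na(res$q_value) & res$q_value < alpha &
      !is.na(res$mean_log2fc) & 2^res$mean_log2fc > fc_threshold)
  class(res) <- c("silac_enrichment", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "fc_threshold") <- fc_threshold
  res
}

#' Differential RNA-association between time points
#'
#' Tests each protein for a change in light/heavy ratio between the 10 min
#' and 1 h time points.  Genes with fewer than two non-missing ratios at
#' either time point are excluded (their dynamics are not reliably
#' measured).  Per tested gene: a two-sided Welch t-test on log2 ratios,
#' BH correction over tested genes, and a log2 fold change (mean log2
#' ratio at 1 h minus 10 min).  The primary significance call combines
#' p < `alpha` with the empirical 10th/90th percentile fold-change gates
#' computed over all tested genes; the BH call is flagged separately.
#'
#' @param table A protein quant table; rows with `processed_flag == FALSE`
#'   are dropped when the column is present.
#' @param alpha Significance level (default 0.05).
#' @param enrichment Optional [crosslink_enrichment()] result; joins
#'   `crosslink_enriched` and sets `significant_rbp` (primary call AND
#'   enrichment).
#' @param var_equal Passed to [welch_t_test()].
#' @param timepoints The two time points compared, baseline first.
#' @return A `silac_differential` tibble: per gene, means, `log2fc`,
#'   `p_value`, `q_value`, `tested`, `significant_primary`,
#'   `significant_bh` (and crosslink columns when supplied), with the
#'   percentile thresholds, alpha and counts in attributes.
#' @export
differential_association <- function(table, alpha = 0.05, enrichment = NULL,
                                     var_equal = FALSE,
                                     timepoints = TIMEPOINT_LEVELS) {
  assert_columns(table, c("gene", "timepoint", "replicate", "ratio_lh"),
    what = "protein quant table")
  if ("processed_flag" %in% names(table)) {
    table <- filter(table, .data$processed_flag)
  }
  table <- filter(table, .data$timepoint %in% timepoints)

  per_gene <- table |>
    mutate(log2_ratio = log2(.data$ratio_lh)) |>
    group_by(.data$gene) |>
    summarise(
      vals_t0 = list(.data$log2_ratio[.data$timepoint == timepoints[1]]),
      vals_t1 = list(.data$log2_ratio[.data$timepoint == timepoints[2]]),
      .groups = "drop"
    ) |>
    mutate(
      n_t0 = purrr::map_int(.data$vals_t0, ~ sum(!is.na(.x))),
      n_t1 = purrr::map_int(.data$vals_t1, ~ sum(!is.na(.x))),
      tested = .data$n_t0 >= 2 & .data$n_t1 >= 2,
      mean_log2_ratio_t10 = purrr::map_dbl(.data$vals_t0,
        ~ if (any(!is.na(.x))) mean(.x, na.rm = TRUE) else NA_real_),
      mean_log2_ratio_t1h = purrr::map_dbl(.data$vals_t1,
        ~ if (any(!is.na(.x))) mean(.x, na.rm = TRUE) else NA_real_),
      log2fc = .data$mean_log2_ratio_t1h - .data$mean_log2_ratio_t10
    )

  tests <- purrr::pmap_dfr(
    list(per_gene$vals_t1, per_gene$vals_t0, per_gene$tested),
    function(v1, v0, ok) {
      if (!ok) {
        return(tibble(t = NA_real_, df = NA_real_, p_value = NA_real_))
      }
      welch_t_test(v1, v0, var_equal = var_equal)
    }
  )
  res <- per_gene |>
    select(-"vals_t0", -"vals_t1") |>
    mutate(
      t = tests$t, df = tests$df, p_value = tests$p_value,
      q_value = benjamini_hochberg(tests$p_value)
    )

  tested_fc <- res$log2fc[res$tested]
  thresholds <- c(p10 = NA_real_, p90 = NA_real_)
  if (sum(!is.na(tested_fc)) >= 10) {
    thresholds <- percentile_thresholds(tested_fc)
    res$significant_primary <- res$tested &
      !is.na(res$p_value) & res$p_value < alpha &
      (res$log2fc > thresholds["p90"] | res$log2fc < thresholds["p10"])
  } else {
    warn("fewer than 10 testable genes: percentile thresholds unavailable, significance limited to the BH call")
    res$significant_primary <- NA
  }
  res$significant_bh <- res$tested & !is.na(res$q_value) & res$q_value < alpha

  if (!is.null(enrichment)) {
    res <- left_join(res,
      tibble(gene = enrichment$gene, crosslink_enriched = enrichment$enriched),
      by = "gene") |>
      mutate(
        crosslink_enriched = tidyr::replace_na(.data$crosslink_enriched, FALSE),
        significant_rbp = .data$significant_primary & .data$crosslink_enriched
      )
  }
  res <- arrange(res, .data$gene)
  class(res) <- c("silac_differential", class(res))
  attr(res, "thresholds") <- thresholds
  attr(res, "alpha") <- alpha
  attr(res, "n_tested") <- sum(res$tested)
  attr(res, "n_excluded") <- sum(!res$tested)
  res
}
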