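# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @exportS3Method generics::tidy
tidy.silac_differential <- function(x, ...) {
  as_tibble(x) |>
    select("gene", "mean_log2_ratio_t10", "mean_log2_ratio_t1h", "log2fc",
      "p_value", "q_value", "tested", dplyr::any_of(c(
        "significant_primary", "significant_bh", "crosslink_enriched",
        "significant_rbp")))
}

#' @exportS3Method generics::glance
glance.silac_differential <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble(
    n_genes = nrow(x),
    n_tested = attr(x, "n_tested"),
    n_excluded = attr(x, "n_excluded"),
    n_significant_primary = sum(x$significant_primary, na.rm = TRUE),
    n_significant_bh = sum(x$significant_bh, na.rm = TRUE),
    p10 = unname(thr["p10"]),
    p90 = unname(thr["p90"]),
    alpha = attr(x, "alpha")
  )
}

#' @exportS3Method generics::tidy
tidy.silac_enrichment <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.silac_enrichment <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_exclusive = sum(x$exclusive_to_cl),
    n_enriched = sum(x$enriched),
    alpha = attr(x, "alpha"),
    fc_threshold = attr(x, "fc_threshold")
  )
}

#' Volcano-style plot of a differential RNA-association result
#'
#' log2 fold change against -log10 p, with the percentile fold-change
#' gates and the significance calls highlighted.
#'
#' @param object A `silac_differential` result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.silac_differential <- function(object, ...) {
  thr <- attr(object, "thresholds")
  df <- as_tibble(object) |>
    filter(.data$tested) |>
    mutate(call = dplyr::case_when(
      .data$significant_bh ~ "BH significant",
      .data$significant_primary ~ "primary significant",
      TRUE ~ "not significant"
    ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$p_value), colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = unname(thr), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
      linetype = "dotted") +
    ggplot2::labs(
      x = "log2 fold change (1 h vs 10 min, L/H ratio)",
      y = expression(-log[10] ~ p),
      colour = NULL,
      title = "Differential RNA association"
    ) +
    ggplot2::theme_minimal()
}

#' MA plot for a pair of samples
#'
#' @param mat A log2-scale `silac_matrix`.
#' @param sample_i,sample_j Sample columns (defaults: first two).
#' @return A ggplot with the loess trend overlaid.
#' @export
plot_ma <- function(mat, sample_i = NULL, sample_j = NULL) {
  df <- ma_trend(mat, sample_i, sample_j)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$m)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend), colour = "red") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "A (mean log2 intensity)", y = "M (log2 difference)") +
    ggplot2::theme_minimal()
}

#' Max-replicate-SD comparison across acquisition arms
#'
#' @param ... Named protein quant tables (e.g. `DDA = ..., DIA = ...`).
#' @param log2_ratios Passed to [max_replicate_sd()].
#' @return A ggplot of the per-arm MaxSD distributions.
#' @export
plot_max_sd <- function(..., log2_ratios = FALSE) {
  tables <- list(...)
  df <- purrr::imap_dfr(tables, function(tbl, arm) {
    mutate(max_replicate_sd(tbl, log2_ratios = log2_ratios), arm = arm)
  }) |>
    filter(!is.na(.data$max_sd))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$max_sd)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL,
      y = "max inter-replicate SD of L/H ratio") +
    ggplot2::theme_minimal()
}
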