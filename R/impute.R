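#' Imputation configuration
#'
#' @param method "min_half" (half the sample minimum, a limit-of-detection
#'   assumption) or "random_forest" (iterative missForest-style
#'   prediction, a missing-at-random assumption).
#' @param rf_trees Trees per random forest (default 100).
#' @param rf_max_iter Maximum imputation sweeps (default 10).
#' @param seed Random seed; mandatory for `random_forest`.
#' @return An `imputation_config` list.
#' @export
imputation_config <- function(method = c("min_half", "random_forest"),
                              rf_trees = 100L, rf_max_iter = 10L,
                              seed = NULL) {
  method <- match.arg(method)
  if (method == "random_forest" && is.null(seed)) {
    abort_silac("random_forest imputation requires a seed",
      class = "silacquant_error_config")
  }
  structure(
    list(method = method, rf_trees = as.integer(rf_trees),
      rf_max_iter = as.integer(rf_max_iter), seed = seed),
    class = "imputation_config"
  )
}

# Pull the numeric sample columns of a wide gene-by-sample tibble.
wide_value_cols <- function(wide) {
  setdiff(names(wide), c("gene", "feature_id", "protein_ids"))
}

#' Half-minimum imputation
#'
#' Replaces every missing cell of a sample column with half that column's
#' minimum non-missing value (on linear scale), i.e. the column's log2
#' minimum minus one when the values are log2 --- the two phrasings are
#' mathematically identical.  Encodes the assumption that values are
#' missing because the analyte sat below the limit of detection.
#'
#' @param wide A wide tibble (`gene` plus numeric sample columns) of
#'   positive values, with missing cells.
#' @param scale "linear" (multiply the minimum by 0.5) or "log2" (subtract
#'   1 from the minimum).
#' @return The tibble with missing cells filled; the logical imputation
#'   mask is in attribute `imputed`.
#' @export
impute_min_half <- function(wide, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  cols <- wide_value_cols(wide)
  mask <- is.na(as.matrix(wide[cols]))
  for (col in cols) {
    v <- wide[[col]]
    if (all(is.na(v))) {
      abort_silac(sprintf("sample '%s' has no observed values to impute from", col),
        class = "silacquant_error_degenerate_sample")
    }
    fill <- if (scale == "linear") 0.5 * min(v, na.rm = TRUE) else min(v, na.rm = TRUE) - 1
    v[is.na(v)] <- fill
    wide[[col]] <- v
  }
  attr(wide, "imputed") <- mask
  wide
}

#' Iterative random-forest imputation
#'
#' missForest-style imputation: missing cells start at their column means;
#' columns are then visited in order of increasing missingness, each
#' regressed on all other columns with a random forest trained on the rows
#' where it is observed, and its missing cells re-predicted.  Sweeps stop
#' when the change in imputed values stalls (starts increasing) or
#' `rf_max_iter` is reached; on a stall the previous sweep's values are
#' kept.  Fully deterministic for a given seed.
#'
#' @param wide A wide tibble (`gene` plus >= 2 numeric sample columns).
#' @param config An [imputation_config()] with method "random_forest".
#' @return The tibble with missing cells filled; attributes `imputed`
#'   (logical mask) and `rf_deltas` (per-sweep change trace).
#' @export
impute_random_forest <- function(wide, config) {
  stopifnot(inherits(config, "imputation_config"),
    config$method == "random_forest")
  cols <- wide_value_cols(wide)
  if (length(cols) < 2) {
    abort_silac("random-forest imputation needs >= 2 sample columns",
      class = "silacquant_error_method_unavailable")
  }
  x <- as.matrix(wide[cols])
  mask <- is.na(x)
  if (!any(mask)) {
    attr(wide, "imputed") <- mask
    return(wide)
  }
  high_miss <- colMeans(mask) >= 0.5
  if (any(high_miss)) {
    warn(sprintf("column(s) with >= 50%% missing values: %s",
      paste(cols[high_miss], collapse = ", ")))
  }

  col_means <- colMeans(x, na.rm = TRUE)
  for (j in seq_along(cols)) x[mask[, j], j] <- col_means[j]
  visit <- order(colSums(mask))
  visit <- visit[colSums(mask)[visit] > 0]

  deltas <- numeric(0)
  best <- x
  withr::with_seed(config$seed, {
    for (it in seq_len(config$rf_max_iter)) {
      x_old <- x
      for (j in visit) {
        obs <- !mask[, j]
        fit <- randomForest::randomForest(
          x = x[obs, -j, drop = FALSE], y = x[obs, j],
          ntree = config$rf_trees
        )
        x[mask[, j], j] <- predict(fit, x[mask[, j], -j, drop = FALSE])
      }
      delta <- sum((x[mask] - x_old[mask])^2) / max(sum(x[mask]^2), .Machine$double.eps)
      deltas <- c(deltas, delta)
      if (it > 1 && delta > deltas[it - 1]) {
        x <- x_old  # stalled: keep the previous sweep
        break
      }
      best <- x
    }
  })
  wide[cols] <- as_tibble(as.data.frame(best, check.names = FALSE) |> setNames(cols))
  attr(wide, "imputed") <- mask
  attr(wide, "rf_deltas") <- deltas
  wide
}

#' Impute protein-level ratios and flag non-robust predictions
#'
#' Applies either imputation method to the gene-by-sample protein ratio
#' matrix (genes quantified at least twice at either time point) and
#' returns a protein quant table with the missing ratios filled.  Genes
#' whose observed support at some time point falls below `min_obs_robust`
#' values before imputation are flagged `imputation_robust = FALSE`: their
#' imputed time-point means rest almost entirely on predicted values and
#' should be excluded from significance calls.
#'
#' @param table A protein quant table (post-filtering).
#' @param config An [imputation_config()].
#' @param min_obs_robust Minimum observed values per time point for the
#'   robust flag (default 2).
#' @return The protein quant table with imputed `ratio_lh`, plus
#'   `imputed` and `imputation_robust` columns.
#' @export
impute_protein_ratios <- function(table, config, min_obs_robust = 2L) {
  wide <- protein_ratio_matrix(table)
  cols <- wide_value_cols(wide)
  imputed <- switch(config$method,
    min_half = impute_min_half(wide, scale = "linear"),
    random_forest = impute_random_forest(wide, config)
  )
  mask <- attr(imputed, "imputed")

  tp_of <- sub("_r\\d+$", "", cols)
  obs_per_tp <- vapply(unique(tp_of), function(tp) {
    rowSums(!is.na(as.matrix(wide[cols[tp_of == tp]])))
  }, numeric(nrow(wide)))
  robust <- apply(obs_per_tp >= min_obs_robust, 1, all)

  mask_long <- tibble(
    gene = rep(wide$gene, times = length(cols)),
    sample = rep(cols, each = nrow(wide)),
    imputed = as.vector(mask)
  ) |>
    tidyr::separate_wider_regex("sample",
      c(timepoint = ".+", "_r", replicate = "\\d+")) |>
    mutate(replicate = as.integer(.data$replicate))

  protein_ratio_table(imputed, table) |>
    left_join(mask_long, by = c("gene", "timepoint", "replicate")) |>
    left_join(tibble(gene = wide$gene, imputation_robust = robust), by = "gene")
}

#' Write an imputed matrix with its companion mask
#'
#' @param wide An imputed wide matrix carrying the `imputed` attribute.
#' @param path Output TSV path; the mask goes to `<path>.mask.tsv`.
#' @return `path`, invisibly.
#' @export
write_imputed_tsv <- function(wide, path) {
  readr::write_tsv(as_tibble(wide), path)
  mask <- attr(wide, "imputed")
  if (!is.null(mask)) {
    mask_df <- as_tibble(as.data.frame(mask)) |>
      mutate(gene = wide$gene, .before = 1)
    readr::write_tsv(mask_df, paste0(path, ".mask.tsv"))
  }
  invisible(path)
}
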