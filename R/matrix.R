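#' Feature-by-sample intensity tables
#'
#' A `silac_matrix` is a tibble with one row per feature (precursor or
#' peptide), annotation columns `feature_id`, `gene`, `protein_ids` (and
#' optionally `peptide_seq`), and one numeric column per sample unit
#' ("run_H" / "run_L").  The attribute `scale` records whether the values
#' are linear intensities, log2 intensities, or glog-transformed values, so
#' transforms can refuse inputs on the wrong scale.
#'
#' @param df Data frame with annotation and sample columns.
#' @param sample_cols Character vector naming the sample columns.
#' @param scale One of "linear", "log2", "glog".
#' @return A `silac_matrix` tibble.
#' @export
as_silac_matrix <- function(df, sample_cols, scale = c("linear", "log2", "glog")) {
  scale <- match.arg(scale)
  df <- as_tibble(df)
  assert_columns(df, c("feature_id", sample_cols), what = "intensity matrix")
  if (anyDuplicated(df$feature_id)) {
    abort_silac("intensity matrix: duplicate feature_id rows",
      class = "silacquant_error_duplicate_cell")
  }
  vals <- as.matrix(df[sample_cols])
  if (scale == "linear" && any(vals[is.finite(vals)] < 0)) {
    abort_silac("linear-scale intensities must be non-negative",
      class = "silacquant_error_scale")
  }
  structure(df,
    class = c("silac_matrix", class(df)),
    sample_cols = sample_cols,
    scale = scale
  )
}

#' @export
print.silac_matrix <- function(x, ...) {
  cat(sprintf(
    "# silac_matrix: %d features x %d samples (scale: %s)\n",
    nrow(x), length(sample_cols(x)), intensity_scale(x)
  ))
  NextMethod()
}

#' Sample columns of a silac_matrix
#' @param x A `silac_matrix`.
#' @return Character vector of sample column names.
#' @export
sample_cols <- function(x) {
  attr(x, "sample_cols") %||%
    setdiff(names(x), c("feature_id", "gene", "protein_ids", "peptide_seq", "charge"))
}

#' Intensity scale marker
#' @param x A `silac_matrix`.
#' @return "linear", "log2" or "glog".
#' @export
intensity_scale <- function(x) attr(x, "scale") %||% "linear"

# Numeric matrix view (features x samples), rownames = feature_id.
matrix_values <- function(x) {
  m <- as.matrix(as_tibble(x)[sample_cols(x)])
  rownames(m) <- x$feature_id
  m
}

# Replace values, keeping annotation and attributes; optionally flip scale.
set_matrix_values <- function(x, m, scale = intensity_scale(x)) {
  sc <- sample_cols(x)
  stopifnot(identical(dim(m), c(nrow(x), length(sc))))
  x[sc] <- as_tibble(as.data.frame(m, check.names = FALSE) |> setNames(sc))
  attr(x, "scale") <- scale
  x
}

#' Switch a silac_matrix between linear and log2 scale
#'
#' Values are log2-transformed (or exponentiated back); missing cells stay
#' missing.  Zeros are treated as missing before taking logs, per the
#' zero-means-non-detection convention.
#'
#' @param x A `silac_matrix`.
#' @return A `silac_matrix` on the other scale.
#' @export
log2_transform <- function(x) {
  if (intensity_scale(x) != "linear") {
    abort_silac("log2_transform() expects a linear-scale matrix",
      class = "silacquant_error_scale")
  }
  m <- matrix_values(x)
  m[!is.na(m) & m == 0] <- NA_real_
  set_matrix_values(x, log2(m), scale = "log2")
}

#' @rdname log2_transform
#' @export
delog2_transform <- function(x) {
  if (intensity_scale(x) != "log2") {
    abort_silac("delog2_transform() expects a log2-scale matrix",
      class = "silacquant_error_scale")
  }
  set_matrix_values(x, 2^matrix_values(x), scale = "linear")
}

#' Write a silac_matrix or long-format records to TSV
#'
#' `write_matrix_tsv()` writes the wide matrix; `write_long_tsv()` writes the
#' canonical three-column long format (Sample, Feature, Intensity).
#'
#' @param x A `silac_matrix` (or long records for `write_long_tsv`).
#' @param path Output file path.
#' @param comment Optional `#`-prefixed header line (e.g. a config hash).
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(x, path, comment = NULL) {
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(as_tibble(x), path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(as_tibble(x), path)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
write_long_tsv <- function(x, path) {
  assert_columns(x, c("run_id", "channel", "feature_id", "intensity"),
    what = "long-format records")
  out <- tibble(
    Sample = sample_unit(x$run_id, x$channel),
    Feature = x$feature_id,
    Intensity = x$intensity
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Pivot long-format records into a feature-by-sample matrix
#'
#' One cell per (feature, sample unit); duplicate cells are an error, never
#' silently aggregated.  Sample units present in the design but absent from
#' the records become all-missing columns with a warning, so downstream
#' pairing logic always sees the full design.
#'
#' @param records Long tibble with columns `run_id`, `channel`,
#'   `feature_id`, `gene`, `protein_ids`, `intensity` (and optionally
#'   `peptide_seq`).
#' @param design A [sample_design()] covering every `run_id` in `records`.
#' @return A linear-scale `silac_matrix`.
#' @export
build_intensity_matrix <- function(records, design) {
  assert_columns(records,
    c("run_id", "channel", "feature_id", "gene", "protein_ids", "intensity"),
    what = "records")
  unknown <- setdiff(unique(records$run_id), design$run_id)
  if (length(unknown) > 0) {
    abort_silac(
      sprintf("records reference run_id(s) absent from the design: %s",
        paste(unknown, collapse = ", ")),
      class = "silacquant_error_unknown_run"
    )
  }
  records <- mutate(records, sample = sample_unit(.data$run_id, .data$channel))
  dup <- records |>
    dplyr::count(.data$feature_id, .data$sample) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_silac(
      sprintf("duplicate (feature, sample) cells, e.g. %s / %s",
        dup$feature_id[1], dup$sample[1]),
      class = "silacquant_error_duplicate_cell"
    )
  }

  units <- normalization_groups(design)$sample
  anno_cols <- intersect(
    c("feature_id", "gene", "protein_ids", "peptide_seq"), names(records))
  anno <- distinct(records[anno_cols])
  wide <- records |>
    select("feature_id", "sample", "intensity") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "intensity")
  empty <- setdiff(units, names(wide))
  if (length(empty) > 0) {
    warn(sprintf(
      "%d design sample unit(s) have no records and were added as all-missing columns: %s",
      length(empty), paste(empty, collapse = ", ")))
    for (u in empty) wide[[u]] <- NA_real_
  }
  out <- left_join(anno, wide, by = "feature_id")
  as_silac_matrix(out, sample_cols = units, scale = "linear")
}
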