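#' Compute per-peptide light/heavy ratios
#'
#' For every (timepoint, replicate) run in the design, divides the light
#' (treated) by the heavy (mock control) intensity of each feature.  Ratios
#' are carried on linear scale; log2 inputs are handled as
#' \eqn{2^{(L - H)}} (glog values are treated the same way, which is exact
#' for large intensities).  A ratio is missing whenever either channel is
#' missing.
#'
#' @param mat A `silac_matrix` whose sample units pair `<run>_L` with
#'   `<run>_H` for every timepoint run in `design`.
#' @param design A [sample_design()]; only runs with a non-missing
#'   timepoint are used.
#' @return A peptide ratio table: `gene`, `protein_ids`, `peptide_id`,
#'   `peptide_seq`, `timepoint`, `replicate`, `run_id`, `ratio_lh`,
#'   `intensity_l`, `intensity_h` (linear scale).
#' @export
compute_peptide_ratios <- function(mat, design) {
  runs <- filter(as_tibble(design), !is.na(.data$timepoint))
  if (nrow(runs) == 0) {
    abort_silac("design has no timepoint runs to compute ratios for",
      class = "silacquant_error_design")
  }
  sc <- sample_cols(mat)
  log_scale <- intensity_scale(mat) %in% c("log2", "glog")

  purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    run <- runs$run_id[i]
    col_l <- sample_unit(run, "light")
    col_h <- sample_unit(run, "heavy")
    if (!(col_l %in% sc) || !(col_h %in% sc)) {
      abort_silac(
        sprintf("run '%s' lacks a paired light/heavy sample unit in the matrix", run),
        class = "silacquant_error_design"
      )
    }
    l <- unname(as.numeric(mat[[col_l]]))
    h <- unname(as.numeric(mat[[col_h]]))
    ratio <- if (log_scale) 2^(l - h) else l / h
    tibble(
      gene = mat$gene,
      protein_ids = if ("protein_ids" %in% names(mat)) mat$protein_ids else NA_character_,
      peptide_id = mat$feature_id,
      peptide_seq = if ("peptide_seq" %in% names(mat)) {
        mat$peptide_seq
      } else {
        stringr::str_remove(mat$feature_id, "\\d+$")
      },
      timepoint = runs$timepoint[i],
      replicate = runs$replicate[i],
      run_id = run,
      ratio_lh = ratio,
      intensity_l = if (log_scale) 2^l else l,
      intensity_h = if (log_scale) 2^h else h
    )
  })
}

#' Mask singleton peptide quantitations
#'
#' Within each (gene, timepoint, replicate) group, a single surviving
#' non-missing peptide ratio carries no support from a second measurement
#' and is replaced by missing; groups with zero or two-plus non-missing
#' ratios are untouched.
#'
#' @param table A peptide ratio table from [compute_peptide_ratios()].
#' @return The table with singleton ratios set to missing.
#' @export
mask_single_peptide_quantitations <- function(table) {
  assert_columns(table, c("gene", "timepoint", "replicate", "ratio_lh"),
    what = "peptide ratio table")
  table |>
    group_by(.data$gene, .data$timepoint, .data$replicate) |>
    mutate(ratio_lh = if (sum(!is.na(.data$ratio_lh)) == 1L) {
      NA_real_
    } else {
      .data$ratio_lh
    }) |>
    ungroup()
}

#' Aggregate peptide ratios to protein (gene) ratios
#'
#' The protein-level light/heavy ratio per (gene, timepoint, replicate) is
#' the median over non-missing peptide ratios (arithmetic mean of the two
#' middle values for even counts).  `n_peptides_quantified` counts distinct
#' peptide sequences (charge states of one sequence count once), and a
#' protein is `detected` in a sample when that count is at least two.
#'
#' @param table A masked peptide ratio table.
#' @return A protein quant table: `gene`, `timepoint`, `replicate`,
#'   `ratio_lh`, `n_peptides_quantified`, `detected`.
#' @export
aggregate_protein_ratios <- function(table) {
  assert_columns(table, c("gene", "timepoint", "replicate", "ratio_lh"),
    what = "peptide ratio table")
  seq_col <- if ("peptide_seq" %in% names(table)) "peptide_seq" else "peptide_id"
  table |>
    group_by(.data$gene, .data$timepoint, .data$replicate) |>
    summarise(
      # peptide tally first: distinct sequences with a surviving ratio
      # (charge states of one sequence count once)
      n_peptides_quantified = n_distinct(.data[[seq_col]][!is.na(.data$ratio_lh)]),
      ratio_lh = if (all(is.na(.data$ratio_lh))) {
        NA_real_
      } else {
        median(.data$ratio_lh, na.rm = TRUE)
      },
      .groups = "drop"
    ) |>
    select("gene", "timepoint", "replicate", "ratio_lh",
      "n_peptides_quantified") |>
    mutate(detected = .data$n_peptides_quantified >= 2L)
}

#' Apply the detection-filter chain ("processed dataset")
#'
#' Two stages, with the casualty count of each reported:
#'
#' * stage 1 keeps genes with non-missing protein ratios in at least
#'   `min_reps` of `n_reps` replicates at **any** time point;
#' * stage 2 (`processed_flag`) additionally requires the gene to be
#'   represented by at least `min_peptides` quantitated peptides and to be
#'   detected (two-plus quantitated peptides, which implies heavy-channel
#'   support since a ratio needs both channels) in at least `min_reps`
#'   replicates at **both** time points.
#'
#' Filters are monotone: tightening `min_reps` or `min_peptides` can only
#' remove genes.
#'
#' @param table A protein quant table from [aggregate_protein_ratios()].
#' @param design Optional [sample_design()]; used to check both time points
#'   are represented.
#' @param min_peptides Minimum peptide representation (default 2).
#' @param min_reps Replicate threshold (default 2).
#' @param n_reps Replicates per time point (default 3; reporting only).
#' @return The table with gene-level `stage1_flag` and `processed_flag`
#'   columns added.
#' @export
apply_detection_filters <- function(table, design = NULL, min_peptides = 2L,
                                    min_reps = 2L, n_reps = 3L) {
  assert_columns(table,
    c("gene", "timepoint", "replicate", "ratio_lh", "n_peptides_quantified"),
    what = "protein quant table")
  tps <- sort(unique(table$timepoint))
  if (!is.null(design)) {
    design_tps <- sort(unique(design$timepoint[!is.na(design$timepoint)]))
    if (length(design_tps) < 2) {
      abort_silac("design lacks heavy-control runs at both time points",
        class = "silacquant_error_design")
    }
    tps <- design_tps
  }
  if (length(tps) < 2) {
    abort_silac("protein quant table covers fewer than two time points",
      class = "silacquant_error_design")
  }

  per_tp <- table |>
    group_by(.data$gene, .data$timepoint) |>
    summarise(
      n_quant = sum(!is.na(.data$ratio_lh)),
      n_detect = sum(.data$n_peptides_quantified >= 2L),
      .groups = "drop"
    )
  gene_flags <- per_tp |>
    tidyr::complete(gene = unique(per_tp$gene), timepoint = tps,
      fill = list(n_quant = 0L, n_detect = 0L)) |>
    group_by(.data$gene) |>
    summarise(
      stage1_flag = any(.data$n_quant >= min_reps),
      both_tp_detected = all(.data$n_detect >= min_reps),
      .groups = "drop"
    )
  pep_repr <- table |>
    group_by(.data$gene) |>
    summarise(max_peptides = max(.data$n_peptides_quantified), .groups = "drop")
  gene_flags <- gene_flags |>
    left_join(pep_repr, by = "gene") |>
    mutate(processed_flag = .data$stage1_flag &
      .data$both_tp_detected &
      .data$max_peptides >= min_peptides)

  n_genes <- nrow(gene_flags)
  inform(sprintf(
    "detection filters: %d gene(s); stage 1 (>=%d/%d replicates, any time point) removed %d; stage 2 (>=%d peptides, detected >=%d/%d replicates at both time points) removed %d more; %d processed",
    n_genes, min_reps, n_reps, sum(!gene_flags$stage1_flag),
    min_peptides, min_reps, n_reps,
    sum(gene_flags$stage1_flag & !gene_flags$processed_flag),
    sum(gene_flags$processed_flag)
  ))

  left_join(table,
    select(gene_flags, "gene", "stage1_flag", "processed_flag"),
    by = "gene")
}

#' Pivot a protein quant table to a gene-by-sample ratio matrix
#'
#' Columns are named `<timepoint>_r<replicate>`.  The companion
#' [protein_ratio_table()] pivots back, preserving the peptide-count and
#' flag columns of the source table.
#'
#' @param table A protein quant table.
#' @return A wide tibble: `gene` plus one ratio column per sample.
#' @export
protein_ratio_matrix <- function(table) {
  table |>
    mutate(sample = paste0(.data$timepoint, "_r", .data$replicate)) |>
    select("gene", "sample", "ratio_lh") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "ratio_lh") |>
    arrange(.data$gene)
}

#' @rdname protein_ratio_matrix
#' @param wide A wide ratio matrix from [protein_ratio_matrix()].
#' @param template The protein quant table the matrix came from; its
#'   non-ratio columns are re-attached.
#' @export
protein_ratio_table <- function(wide, template) {
  long <- wide |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "ratio_lh") |>
    tidyr::separate_wider_regex("sample",
      c(timepoint = ".+", "_r", replicate = "\\d+")) |>
    mutate(replicate = as.integer(.data$replicate))
  template |>
    select(-"ratio_lh") |>
    inner_join(long, by = c("gene", "timepoint", "replicate"))
}
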