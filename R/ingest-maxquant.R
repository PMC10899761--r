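#' Read a MaxQuant peptides.txt table
#'
#' Parses the peptides.txt dialect: one row per peptide sequence with
#' per-experiment `Intensity L <exp>` / `Intensity H <exp>` columns.  Only
#' peptides flagged unique are kept; zero intensities become missing.
#'
#' @param path Path to peptides.txt.
#' @param drop_multi_gene Drop peptides whose gene annotation names several
#'   ";"-separated symbols (count reported).
#' @return Long records: `run_id` (experiment name), `channel`,
#'   `feature_id` (sequence), `gene`, `protein_ids`, `peptide_seq`,
#'   `intensity`.
#' @export
read_maxquant_peptides <- function(path, drop_multi_gene = TRUE) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  seq_col <- match_column(names(raw), "Sequence")
  gene_col <- match_column(names(raw), "Gene names")
  prot_col <- match_column(names(raw), "Proteins")
  if (is.na(prot_col)) prot_col <- match_column(names(raw), "Leading razor protein")
  uniq_col <- match_column(names(raw), "Unique (Groups)")
  if (is.na(uniq_col)) uniq_col <- match_column(names(raw), "Unique")
  if (is.na(seq_col) || is.na(gene_col)) {
    abort_silac("peptides.txt is missing 'Sequence' or 'Gene names'",
      class = "silacquant_error_schema")
  }
  int_cols <- grep("^Intensity [HL] ", names(raw), value = TRUE)
  if (length(int_cols) == 0) {
    abort_silac("peptides.txt has no per-experiment 'Intensity H/L <exp>' columns",
      class = "silacquant_error_schema")
  }

  if (!is.na(uniq_col)) {
    keep <- tolower(trimws(raw[[uniq_col]])) %in% c("yes", "true", "+")
    n_drop <- sum(!keep)
    if (n_drop > 0) inform(sprintf("dropped %d non-unique peptide(s)", n_drop))
    raw <- raw[keep, ]
  }

  base <- tibble(
    feature_id = raw[[seq_col]],
    gene = raw[[gene_col]],
    protein_ids = if (!is.na(prot_col)) raw[[prot_col]] else NA_character_,
    peptide_seq = raw[[seq_col]]
  )
  if (drop_multi_gene) {
    multi <- grepl(";", base$gene, fixed = TRUE)
    if (any(multi)) {
      inform(sprintf("dropped %d peptide(s) with multi-gene annotations", sum(multi)))
      base <- base[!multi, ]
      raw <- raw[!multi, ]
    }
  }

  long <- purrr::map_dfr(int_cols, function(col) {
    m <- stringr::str_match(col, "^Intensity ([HL]) (.+)$")
    mutate(base,
      run_id = m[, 3],
      channel = if_else(m[, 2] == "H", "heavy", "light"),
      intensity = parse_numeric_cells(raw[[col]], col, zero_as_na = TRUE)
    )
  })
  select(long, "run_id", "channel", "feature_id", "gene", "protein_ids",
    "peptide_seq", "intensity")
}

#' Read a MaxQuant proteinGroups.txt table
#'
#' Parses the proteinGroups.txt dialect, removes rows flagged as potential
#' contaminants or reverse decoys and keratin annotations, and inverts the
#' normalized heavy/light ratio to light/heavy (treated/control).
#'
#' @param path Path to proteinGroups.txt.
#' @return Tibble with one row per (gene, experiment): `gene`, `run_id`,
#'   `ratio_lh` (inverted normalized ratio), plus linear `intensity_l` /
#'   `intensity_h` when the columns are present.
#' @export
read_maxquant_protein_groups <- function(path) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  gene_col <- match_column(names(raw), "Gene names")
  if (is.na(gene_col)) {
    abort_silac("proteinGroups.txt is missing 'Gene names'",
      class = "silacquant_error_schema")
  }
  ratio_cols <- grep("^Ratio H/L normalized ", names(raw), value = TRUE)
  if (length(ratio_cols) == 0) {
    abort_silac("proteinGroups.txt has no 'Ratio H/L normalized <exp>' columns",
      class = "silacquant_error_schema")
  }

  flagged <- rep(FALSE, nrow(raw))
  for (fcol in c("Reverse", "Potential contaminant", "Contaminant")) {
    col <- match_column(names(raw), fcol)
    if (!is.na(col)) flagged <- flagged | (trimws(raw[[col]]) %in% "+")
  }
  keratin <- grepl("^KRT\\d", raw[[gene_col]]) |
    grepl("keratin", raw[[gene_col]], ignore.case = TRUE)
  n_removed <- sum(flagged | keratin, na.rm = TRUE)
  if (n_removed > 0) {
    inform(sprintf("removed %d contaminant/reverse/keratin protein group(s)",
      n_removed))
  }
  raw <- raw[!(flagged | keratin), ]

  purrr::map_dfr(ratio_cols, function(col) {
    exp_name <- stringr::str_match(col, "^Ratio H/L normalized (.+)$")[, 2]
    hl <- parse_numeric_cells(raw[[col]], col, zero_as_na = TRUE)
    out <- tibble(
      gene = raw[[gene_col]],
      run_id = exp_name,
      ratio_lh = 1 / hl
    )
    for (ch in c("L", "H")) {
      icol <- match_column(names(raw), paste("Intensity", ch, exp_name))
      if (!is.na(icol)) {
        out[[paste0("intensity_", tolower(ch))]] <-
          parse_numeric_cells(raw[[icol]], icol, zero_as_na = TRUE)
      }
    }
    out
  })
}
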