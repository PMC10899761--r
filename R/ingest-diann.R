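SILAC_TAGS <- c(
  heavy = "(SILAC-K-H)", heavy = "(SILAC-R-H)",
  light = "(SILAC-K-L)", light = "(SILAC-R-L)"
)

#' Parse SILAC channel tags out of a DIA-NN precursor id
#'
#' Precursor ids carry their SILAC label as `(SILAC-K-H)` / `(SILAC-R-H)`
#' (heavy) or `(SILAC-K-L)` / `(SILAC-R-L)` (light) tags after the labelled
#' residue.  The channel is read off the tags and the tags are removed, so
#' the heavy and light forms of the same precursor collapse to one
#' identifier.  Tag matching is case-exact.
#'
#' @param raw_id Character vector of precursor ids (non-empty).
#' @param on_unlabeled What to do with ids carrying no SILAC tag: `"error"`
#'   aborts, `"drop"` returns `NA` channel with a warning so callers can
#'   discard the rows.
#' @return A tibble with columns `raw_id`, `channel` ("light"/"heavy") and
#'   `stripped_id`.
#' @examples
#' parse_silac_precursor_id("SEQVENCEK(SILAC-K-H)2")
#' @export
parse_silac_precursor_id <- function(raw_id, on_unlabeled = c("error", "drop")) {
  on_unlabeled <- match.arg(on_unlabeled)
  if (length(raw_id) == 0 || any(is.na(raw_id) | raw_id == "")) {
    abort_silac("precursor ids must be non-empty", class = "silacquant_error_schema")
  }
  has_h <- stringr::str_detect(raw_id, stringr::fixed("(SILAC-K-H)")) |
    stringr::str_detect(raw_id, stringr::fixed("(SILAC-R-H)"))
  has_l <- stringr::str_detect(raw_id, stringr::fixed("(SILAC-K-L)")) |
    stringr::str_detect(raw_id, stringr::fixed("(SILAC-R-L)"))
  both <- has_h & has_l
  if (any(both)) {
    abort_silac(
      sprintf("precursor id(s) carry both heavy and light tags, e.g. '%s'",
        raw_id[both][1]),
      class = "silacquant_error_malformed_channel"
    )
  }
  neither <- !has_h & !has_l
  if (any(neither)) {
    if (on_unlabeled == "error") {
      abort_silac(
        sprintf("precursor id(s) carry no SILAC channel tag, e.g. '%s'",
          raw_id[neither][1]),
        class = "silacquant_error_unlabeled_precursor"
      )
    }
    warn(sprintf("%d unlabeled precursor id(s) assigned missing channel",
      sum(neither)))
  }
  stripped <- raw_id
  for (tag in SILAC_TAGS) {
    stripped <- stringr::str_replace_all(stripped, stringr::fixed(tag), "")
  }
  tibble(
    raw_id = raw_id,
    channel = dplyr::case_when(has_h ~ "heavy", has_l ~ "light",
      TRUE ~ NA_character_),
    stripped_id = stripped
  )
}

#' Read a DIA-NN style precursor report
#'
#' Reads the tab-separated `Report.tsv` dialect (columns `Run`,
#' `Protein.Ids`, `Genes`, `Precursor.Id`, `Precursor.Translated`,
#' `Q.Value`, `Translated.Q.Value`), applies the precursor and translated
#' q-value filters, assigns SILAC channels from the precursor-id tags, and
#' returns one record per precursor per run.  Zero or blank intensities are
#' stored as missing (an MS intensity of zero means non-detection).
#'
#' Feature identity downstream is the concatenation of protein ids, gene and
#' the stripped precursor id; the components are kept as separate columns.
#'
#' @param path Path to the report TSV.
#' @param q_max,translated_q_max Q-value cutoffs in (0, 1]; rows above either
#'   are removed (default 1% for both).
#' @param drop_multi_gene Drop records whose `Genes` field names several
#'   ";"-separated symbols (no defensible single-gene assignment exists for
#'   them at aggregation); the dropped count is reported.
#' @param on_unlabeled Passed to [parse_silac_precursor_id()]; default drops
#'   unlabeled precursors with a warning.
#' @return Tibble of precursor records: `run_id`, `protein_ids`, `genes`,
#'   `precursor_id` (stripped), `charge`, `channel`, `intensity`, `q_value`,
#'   `translated_q`.
#' @export
read_diann_report <- function(path, q_max = 0.01, translated_q_max = 0.01,
                              drop_multi_gene = TRUE,
                              on_unlabeled = c("drop", "error")) {
  on_unlabeled <- match.arg(on_unlabeled)
  stopifnot(q_max > 0, q_max <= 1, translated_q_max > 0, translated_q_max <= 1)
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  wanted <- c("Run", "Protein.Ids", "Genes", "Precursor.Id",
    "Precursor.Translated", "Q.Value", "Translated.Q.Value")
  found <- vapply(wanted, function(w) match_column(names(raw), w), character(1))
  if (anyNA(found)) {
    abort_silac(
      sprintf("DIA-NN report is missing column(s): %s",
        paste(wanted[is.na(found)], collapse = ", ")),
      class = "silacquant_error_schema"
    )
  }
  df <- tibble(
    run_id = raw[[found["Run"]]],
    protein_ids = raw[[found["Protein.Ids"]]],
    genes = raw[[found["Genes"]]],
    raw_precursor = raw[[found["Precursor.Id"]]],
    intensity = parse_numeric_cells(raw[[found["Precursor.Translated"]]],
      "Precursor.Translated", zero_as_na = TRUE),
    q_value = parse_numeric_cells(raw[[found["Q.Value"]]], "Q.Value"),
    translated_q = parse_numeric_cells(raw[[found["Translated.Q.Value"]]],
      "Translated.Q.Value")
  )
  df <- filter(df,
    !is.na(.data$q_value), .data$q_value <= q_max,
    !is.na(.data$translated_q), .data$translated_q <= translated_q_max
  )
  parsed <- parse_silac_precursor_id(df$raw_precursor, on_unlabeled = on_unlabeled)
  df$channel <- parsed$channel
  df$precursor_id <- parsed$stripped_id
  df <- filter(df, !is.na(.data$channel))
  if (drop_multi_gene) {
    multi <- grepl(";", df$genes, fixed = TRUE)
    if (any(multi)) {
      inform(sprintf("dropped %d record(s) with multi-gene annotations", sum(multi)))
      df <- df[!multi, ]
    }
  }
  df |>
    mutate(
      charge = as.integer(stringr::str_match(.data$precursor_id, "(\\d+)$")[, 2])
    ) |>
    select("run_id", "protein_ids", "genes", "precursor_id", "charge",
      "channel", "intensity", "q_value", "translated_q")
}

#' Turn DIA precursor records into matrix-ready long records
#'
#' Adds the concatenated feature identity and the charge-stripped peptide
#' sequence used by the distinct-peptide counting rule.
#'
#' @param records Output of [read_diann_report()].
#' @return Long records suitable for [build_intensity_matrix()].
#' @export
diann_records_to_long <- function(records) {
  records |>
    mutate(
      feature_id = paste(.data$protein_ids, .data$genes, .data$precursor_id,
        sep = "|"),
      gene = .data$genes,
      peptide_seq = stringr::str_remove(.data$precursor_id, "\\d+$")
    ) |>
    select("run_id", "channel", "feature_id", "gene", "protein_ids",
      "peptide_seq", "intensity")
}
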