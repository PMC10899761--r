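# Synthetic-dialect writers: emit the same table dialects the readers
# parse, so write -> read round trips exercise the full ingest surface.

# Insert the SILAC tag after the last K or R of the sequence part of a
# stripped precursor id ("PEPTIDEK2" -> "PEPTIDEK(SILAC-K-H)2").
reinsert_silac_tag <- function(precursor_id, channel) {
  seq_part <- stringr::str_remove(precursor_id, "\\d+$")
  charge_part <- stringr::str_extract(precursor_id, "\\d+$")
  charge_part[is.na(charge_part)] <- ""
  locs <- stringr::str_locate_all(seq_part, "[KR]")
  vapply(seq_along(precursor_id), function(i) {
    loc <- locs[[i]]
    if (nrow(loc) == 0) {
      abort_silac(
        sprintf("precursor '%s' has no K/R residue to carry a SILAC tag",
          precursor_id[i]),
        class = "silacquant_error_schema"
      )
    }
    pos <- loc[nrow(loc), 1]
    residue <- substr(seq_part[i], pos, pos)
    tag <- sprintf("(SILAC-%s-%s)", residue,
      if (channel[i] == "heavy") "H" else "L")
    paste0(substr(seq_part[i], 1, pos), tag,
      substr(seq_part[i], pos + 1, nchar(seq_part[i])), charge_part[i])
  }, character(1))
}

#' Write records as a DIA-NN style Report.tsv
#'
#' Emits the tab-separated report dialect with SILAC tags re-inserted into
#' the precursor ids according to each record's channel.  Readable back by
#' [read_diann_report()]; the write/read round trip preserves the record
#' multiset.
#'
#' @param records Long records with `run_id`, `channel`, `protein_ids`,
#'   `gene`, `peptide_seq`, `charge`, `intensity`, and optionally
#'   `q_value` / `translated_q` (default 0.001 when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diann_like <- function(records, path) {
  assert_columns(records,
    c("run_id", "channel", "protein_ids", "gene", "peptide_seq", "charge",
      "intensity"),
    what = "DIA records")
  records <- filter(records, !is.na(.data$intensity))
  stripped <- paste0(records$peptide_seq, records$charge)
  out <- tibble(
    Run = records$run_id,
    Protein.Ids = records$protein_ids,
    Genes = records$gene,
    Precursor.Id = reinsert_silac_tag(stripped, records$channel),
    Precursor.Translated = records$intensity,
    Q.Value = records[["q_value"]] %||% rep(0.001, nrow(records)),
    Translated.Q.Value = records[["translated_q"]] %||% rep(0.001, nrow(records))
  )
  names(out) <- c("Run", "Protein.Ids", "Genes", "Precursor.Id",
    "Precursor.Translated", "Q.Value", "Translated.Q.Value")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write records as MaxQuant style peptides.txt and proteinGroups.txt
#'
#' peptides.txt gets one row per peptide sequence with per-experiment
#' `Intensity L/H <exp>` columns (missing written as 0, the MaxQuant
#' convention) and unique flags; proteinGroups.txt gets per-gene summed
#' intensities and `Ratio H/L normalized <exp>` columns computed as the
#' median peptide heavy/light ratio.  Decoy rows (a reverse hit, a
#' contaminant, a keratin, and a non-unique peptide) are injected so the
#' reader's removal rules are exercised by round trips.
#'
#' @param records Long records with `run_id`, `channel`, `gene`,
#'   `protein_ids`, `peptide_seq`, `intensity`.
#' @param path_peptides,path_proteingroups Output paths.
#' @param decoys Inject decoy rows (default TRUE).
#' @return The two paths, invisibly.
#' @export
write_maxquant_like <- function(records, path_peptides, path_proteingroups,
                                decoys = TRUE) {
  assert_columns(records,
    c("run_id", "channel", "gene", "protein_ids", "peptide_seq", "intensity"),
    what = "DDA records")
  records <- filter(records, !is.na(.data$intensity))
  runs <- sort(unique(records$run_id))

  wide <- records |>
    mutate(col = sprintf("Intensity %s %s",
      if_else(.data$channel == "heavy", "H", "L"), .data$run_id)) |>
    select("peptide_seq", "gene", "protein_ids", "col", "intensity") |>
    tidyr::pivot_wider(names_from = "col", values_from = "intensity",
      values_fill = 0)
  int_cols <- as.vector(outer(c("L", "H"), runs,
    function(ch, r) sprintf("Intensity %s %s", ch, r)))
  for (col in setdiff(int_cols, names(wide))) wide[[col]] <- 0

  peptides <- tibble(
    Sequence = wide$peptide_seq,
    Proteins = wide$protein_ids,
    `Gene names` = wide$gene,
    `Unique (Groups)` = "yes"
  )
  peptides[int_cols] <- wide[int_cols]
  if (decoys) {
    decoy <- peptides[1, ]
    decoy$Sequence <- paste0(decoy$Sequence, "SHAREDK")
    decoy$`Unique (Groups)` <- "no"
    peptides <- bind_rows(peptides, decoy)
  }
  readr::write_tsv(peptides, path_peptides)

  # proteinGroups: summed intensities; normalized ratio = median peptide H/L
  ratios <- records |>
    select("gene", "protein_ids", "peptide_seq", "run_id", "channel",
      "intensity") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "intensity",
      values_fill = NA) |>
    group_by(.data$gene, .data$protein_ids, .data$run_id) |>
    summarise(
      ratio_hl = median(.data$heavy / .data$light, na.rm = TRUE),
      intensity_l = sum(.data$light, na.rm = TRUE),
      intensity_h = sum(.data$heavy, na.rm = TRUE),
      .groups = "drop"
    )

  pg <- distinct(ratios, .data$gene, .data$protein_ids)
  for (r in runs) {
    sub <- filter(ratios, .data$run_id == r)
    idx <- match(pg$gene, sub$gene)
    pg[[sprintf("Ratio H/L normalized %s", r)]] <- sub$ratio_hl[idx]
    pg[[sprintf("Intensity L %s", r)]] <-
      tidyr::replace_na(sub$intensity_l[idx], 0)
    pg[[sprintf("Intensity H %s", r)]] <-
      tidyr::replace_na(sub$intensity_h[idx], 0)
  }
  pg <- rename(pg, `Gene names` = "gene", `Majority protein IDs` = "protein_ids")
  pg$Reverse <- ""
  pg$`Potential contaminant` <- ""
  if (decoys) {
    mk_decoy <- function(gene, prot, reverse = "", contam = "") {
      row <- pg[1, ]
      row$`Gene names` <- gene
      row$`Majority protein IDs` <- prot
      row$Reverse <- reverse
      row$`Potential contaminant` <- contam
      row
    }
    pg <- bind_rows(pg,
      mk_decoy("DECOYREV", "REV__P99999", reverse = "+"),
      mk_decoy("DECOYCON", "CON__P99998", contam = "+"),
      mk_decoy("KRT1", "P04264"))
  }
  readr::write_tsv(pg, path_proteingroups)
  invisible(c(path_peptides, path_proteingroups))
}
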