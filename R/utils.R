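# Shared internal helpers.

CHANNEL_LEVELS <- c("light", "heavy")
TIMEPOINT_LEVELS <- c("t10min", "t1h")

channel_suffix <- function(channel) {
  unname(c(light = "L", heavy = "H")[channel])
}

# Sample units follow the run-id-plus-channel-letter convention used by the
# long-format quantitation tables ("run_H" / "run_L").
sample_unit <- function(run_id, channel) {
  paste0(run_id, "_", channel_suffix(channel))
}

abort_silac <- function(message, class, ...) {
  abort(message, class = c(class, "silacquant_error"), ...)
}

assert_columns <- function(df, cols, what = "input") {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort_silac(
      sprintf(
        "%s is missing required column(s): %s",
        what, paste(missing_cols, collapse = ", ")
      ),
      class = "silacquant_error_schema"
    )
  }
  invisible(df)
}

# Exact-first column lookup with a tolerant fallback (case-insensitive,
# dots and spaces interchangeable) to absorb dialect drift across tool
# versions.  Returns the actual column name or NA.
match_column <- function(nms, wanted) {
  hit <- match(wanted, nms)
  if (!is.na(hit)) {
    return(nms[hit])
  }
  canon <- function(x) gsub("[. _]", "", tolower(x))
  hit <- match(canon(wanted), canon(nms))
  if (!is.na(hit)) {
    return(nms[hit])
  }
  NA_character_
}

# Parse a character vector as numbers, reporting (not silently eating) cells
# that are neither blank nor numeric.  Blank / "NA" / zero handling is left
# to callers.
parse_numeric_cells <- function(x, column, zero_as_na = FALSE) {
  x_chr <- trimws(as.character(x))
  blank <- is.na(x_chr) | x_chr == "" | x_chr == "NA" | x_chr == "NaN"
  out <- suppressWarnings(as.numeric(x_chr))
  bad <- !blank & is.na(out)
  if (any(bad)) {
    warn(sprintf(
      "column '%s': %d cell(s) could not be parsed as numbers and were set to missing",
      column, sum(bad)
    ))
  }
  if (zero_as_na) {
    out[!is.na(out) & out == 0] <- NA_real_
  }
  out
}
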