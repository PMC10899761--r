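#' Construct and validate a sample design
#'
#' The sample design maps every mass-spec run to its acquisition mode,
#' treatment time point, biological replicate, SILAC channel conditions and
#' crosslink status.  Every downstream operation that needs to know which
#' sample is which takes this table.
#'
#' Normalization group ids follow the four-group scheme used for
#' two-timepoint SILAC designs: 10 min light = 1, 10 min heavy = 2,
#' 1 h light = 3, 1 h heavy = 4.  Groups are attached per sample unit (run
#' crossed with channel) by [normalization_groups()] and are used for
#' reporting only.
#'
#' @param df A data frame with columns `run_id`, `acquisition` ("DDA" or
#'   "DIA"), `timepoint` ("t10min", "t1h", or `NA` for crosslink-comparison
#'   runs), `replicate` (integer >= 1), `light_condition`, `heavy_condition`
#'   and `crosslinked` (logical).
#'
#' @return A tibble of class `silac_design`.
#' @examples
#' sample_design(tibble::tibble(
#'   run_id = c("r1", "r2"), acquisition = "DIA",
#'   timepoint = "t10min", replicate = 1:2,
#'   light_condition = "arsenite", heavy_condition = "mock",
#'   crosslinked = TRUE
#' ))
#' @export
sample_design <- function(df) {
  df <- as_tibble(df)
  assert_columns(
    df,
    c("run_id", "acquisition", "timepoint", "replicate",
      "light_condition", "heavy_condition", "crosslinked"),
    what = "sample design"
  )
  df$run_id <- as.character(df$run_id)
  df$acquisition <- as.character(df$acquisition)
  df$timepoint <- as.character(df$timepoint)
  df$replicate <- as.integer(df$replicate)
  df$crosslinked <- as.logical(df$crosslinked)

  if (anyDuplicated(df$run_id)) {
    abort_silac("sample design: run_id values must be unique",
      class = "silacquant_error_design")
  }
  if (!all(df$acquisition %in% c("DDA", "DIA"))) {
    abort_silac("sample design: acquisition must be 'DDA' or 'DIA'",
      class = "silacquant_error_design")
  }
  bad_tp <- !is.na(df$timepoint) & !(df$timepoint %in% TIMEPOINT_LEVELS)
  if (any(bad_tp)) {
    abort_silac(
      sprintf("sample design: unknown timepoint(s): %s",
        paste(unique(df$timepoint[bad_tp]), collapse = ", ")),
      class = "silacquant_error_design"
    )
  }
  if (any(!is.na(df$replicate) & df$replicate < 1L)) {
    abort_silac("sample design: replicate must be >= 1",
      class = "silacquant_error_design")
  }
  keyed <- df[!is.na(df$timepoint), ]
  if (nrow(keyed) > 0) {
    key <- paste(keyed$acquisition, keyed$timepoint, keyed$replicate)
    if (anyDuplicated(key)) {
      abort_silac(
        "sample design: each (acquisition, timepoint, replicate) may appear at most once",
        class = "silacquant_error_design"
      )
    }
  }
  class(df) <- c("silac_design", class(df))
  df
}

#' Read a sample design from TSV or YAML
#'
#' @param path Path to a tab-separated file with the [sample_design()]
#'   columns, or a YAML file holding a list of run records.
#' @return A `silac_design` tibble.
#' @export
read_sample_design <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    df <- purrr::map_dfr(raw, ~ as_tibble(purrr::map(.x, ~ .x %||% NA)))
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  sample_design(df)
}

#' Expand a design into per-channel sample units with normalization groups
#'
#' @param design A `silac_design`.
#' @return A tibble with one row per (run, channel): `sample`, `run_id`,
#'   `channel`, `timepoint`, `replicate`, `group_id`.
#' @export
normalization_groups <- function(design) {
  units <- tidyr::crossing(
    run_id = design$run_id,
    channel = CHANNEL_LEVELS
  ) |>
    left_join(
      select(as_tibble(design), "run_id", "timepoint", "replicate"),
      by = "run_id"
    ) |>
    mutate(sample = sample_unit(.data$run_id, .data$channel))
  group_key <- tibble(
    timepoint = rep(TIMEPOINT_LEVELS, each = 2),
    channel = rep(c("light", "heavy"), times = 2),
    group_id = 1:4
  )
  units |>
    left_join(group_key, by = c("timepoint", "channel")) |>
    select("sample", "run_id", "channel", "timepoint", "replicate", "group_id")
}
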