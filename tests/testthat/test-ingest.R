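test_that("SILAC channel tags are parsed, stripped and validated", {
  res <- parse_silac_precursor_id(c("SEQVENCEK(SILAC-K-H)2", "SEQVENCER(SILAC-R-L)3"))
  expect_equal(res$channel, c("heavy", "light"))
  expect_equal(res$stripped_id, c("SEQVENCEK2", "SEQVENCER3"))
  expect_false(any(grepl("(SILAC-", res$stripped_id, fixed = TRUE)))

  # contradictory tags
  expect_error(
    parse_silac_precursor_id("PEPK(SILAC-K-H)TIDER(SILAC-R-L)2"),
    class = "silacquant_error_malformed_channel"
  )
  # no tag: error by default, droppable on request
  expect_error(parse_silac_precursor_id("PEPTIDEK2"),
    class = "silacquant_error_unlabeled_precursor")
  expect_warning(
    res2 <- parse_silac_precursor_id("PEPTIDEK2", on_unlabeled = "drop"),
    "unlabeled"
  )
  expect_true(is.na(res2$channel))
  # tag matching is case-exact: a lowercased tag is not a channel tag
  expect_error(parse_silac_precursor_id("PEPK(silac-k-h)2"),
    class = "silacquant_error_unlabeled_precursor")

  # idempotent on already-stripped ids (modulo the unlabeled warning path)
  suppressWarnings({
    again <- parse_silac_precursor_id(res$stripped_id, on_unlabeled = "drop")
  })
  expect_equal(again$stripped_id, res$stripped_id)
})

write_diann_fixture <- function(rows, path = withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())) {
  header <- "Run\tProtein.Ids\tGenes\tPrecursor.Id\tPrecursor.Translated\tQ.Value\tTranslated.Q.Value"
  writeLines(c(header, rows), path)
  path
}

test_that("DIA-NN reports are filtered, channel-assigned and typed", {
  rows <- c(
    "r1\tP1\tGENE1\tAAADDDK(SILAC-K-H)2\t1000\t0.001\t0.002",
    "r1\tP1\tGENE1\tAAADDDK(SILAC-K-L)2\t500\t0.001\t0.02",   # fails translated q
    "r1\tP2\tGENE2\tCCCEEER(SILAC-R-L)3\t\t0.001\t0.001",     # empty intensity kept
    "r1\tP3\tGENE3\tGGGFFFK(SILAC-K-H)2\t10\t0.05\t0.001"     # fails q
  )
  path <- write_diann_fixture(rows)
  rec <- read_diann_report(path)
  # hand-filtered: rows 1 and 3 survive
  expect_equal(nrow(rec), 2L)
  expect_equal(sort(rec$genes), c("GENE1", "GENE2"))
  expect_equal(rec$channel[rec$genes == "GENE1"], "heavy")
  expect_true(is.na(rec$intensity[rec$genes == "GENE2"]))
  expect_equal(rec$charge, c(2L, 3L))
})

test_that("DIA-NN reader reports schema problems and drops multi-gene rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Run\tGenes\tPrecursor.Id", "r1\tG1\tAAAK(SILAC-K-H)2"), path)
  expect_error(read_diann_report(path), class = "silacquant_error_schema")
  expect_error(read_diann_report(path), "Protein.Ids")

  rows <- c(
    "r1\tP1;P2\tGENE1;GENE2\tAAADDDK(SILAC-K-H)2\t100\t0.001\t0.001",
    "r1\tP3\tGENE3\tCCCEEER(SILAC-R-L)2\t100\t0.001\t0.001"
  )
  path2 <- write_diann_fixture(rows)
  expect_message(rec <- read_diann_report(path2), "multi-gene")
  expect_equal(rec$genes, "GENE3")

  # zero intensity is stored as missing
  path3 <- write_diann_fixture("r1\tP1\tG1\tAAADDDK(SILAC-K-H)2\t0\t0.001\t0.001")
  expect_true(is.na(read_diann_report(path3)$intensity))
})

write_peptides_fixture <- function(path = withr::local_tempfile(fileext = ".txt",
                                     .local_envir = parent.frame())) {
  lines <- c(
    "Sequence\tProteins\tGene names\tUnique (Groups)\tIntensity L exp1\tIntensity H exp1",
    "AAAK\tP1\tG1\tyes\t100\t200",
    "CCCR\tP2\tG2\tyes\t0\t400",
    "DDDK\tP3\tG3\tyes\t300\t600",
    "EEEK\tP4\tG4\tno\t50\t50"
  )
  writeLines(lines, path)
  path
}

test_that("MaxQuant peptides are unique-filtered with zero-as-missing", {
  path <- write_peptides_fixture()
  expect_message(rec <- read_maxquant_peptides(path), "non-unique")
  expect_equal(sort(unique(rec$feature_id)), c("AAAK", "CCCR", "DDDK"))
  expect_true(is.na(rec$intensity[rec$feature_id == "CCCR" & rec$channel == "light"]))
  expect_equal(rec$intensity[rec$feature_id == "AAAK" & rec$channel == "heavy"], 200)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Sequence\tGene names", "AAAK\tG1"), bad)
  expect_error(read_maxquant_peptides(bad), class = "silacquant_error_schema")
})

test_that("proteinGroups parsing removes decoys/keratins and inverts ratios", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "Gene names\tRatio H/L normalized exp1\tReverse\tPotential contaminant",
    "G1\t0.5\t\t",
    "G2\t2\t+\t",
    "KRT1\t1\t\t",
    "G3\t4\t\t+"
  ), path)
  expect_message(pg <- read_maxquant_protein_groups(path), "removed 3")
  expect_equal(pg$gene, "G1")
  expect_equal(pg$ratio_lh, 2)  # 1 / 0.5
})

test_that("pivoting to a matrix validates runs, duplicates and conserves values", {
  design <- sample_design(tibble::tibble(
    run_id = c("r1", "r2"), acquisition = "DIA", timepoint = "t10min",
    replicate = 1:2, light_condition = "a", heavy_condition = "m",
    crosslinked = TRUE
  ))
  rec <- tibble::tibble(
    run_id = c("r1", "r1", "r2", "r2"),
    channel = c("light", "heavy", "light", "heavy"),
    feature_id = c("F1", "F1", "F2", "F2"),
    gene = c("G1", "G1", "G2", "G2"),
    protein_ids = "P",
    intensity = c(10, 20, 30, 40)
  )
  suppressWarnings(mat <- build_intensity_matrix(rec, design))
  expect_s3_class(mat, "silac_matrix")
  expect_equal(nrow(mat), 2)
  expect_setequal(sample_cols(mat), c("r1_L", "r1_H", "r2_L", "r2_H"))
  # same precursor in one run lands in two distinct channel columns
  expect_equal(mat$r1_L[mat$feature_id == "F1"], 10)
  expect_equal(mat$r1_H[mat$feature_id == "F1"], 20)
  # conservation: every record appears in exactly one cell
  expect_equal(sum(!is.na(matrix_values_for_test(mat))), nrow(rec))

  expect_error(
    build_intensity_matrix(dplyr::mutate(rec, run_id = "rX"), design),
    class = "silacquant_error_unknown_run"
  )
  expect_error(
    build_intensity_matrix(rec[c(1, 1, 2), ], design),
    class = "silacquant_error_duplicate_cell"
  )
})

test_that("sample designs validate their invariants", {
  base <- tibble::tibble(
    run_id = c("a", "b"), acquisition = "DDA", timepoint = "t10min",
    replicate = 1:2, light_condition = "x", heavy_condition = "y",
    crosslinked = FALSE
  )
  expect_s3_class(sample_design(base), "silac_design")
  expect_error(sample_design(dplyr::mutate(base, run_id = "a")),
    class = "silacquant_error_design")
  expect_error(sample_design(dplyr::mutate(base, replicate = c(1L, 1L))),
    class = "silacquant_error_design")
  expect_error(sample_design(dplyr::mutate(base, timepoint = "t2h")),
    class = "silacquant_error_design")

  groups <- normalization_groups(make_design())
  expect_equal(sort(unique(groups$group_id)), 1:4)
  # group id is constant within (timepoint, channel)
  per_combo <- dplyr::count(groups, timepoint, channel, group_id)
  expect_equal(nrow(per_combo), 4)
})
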