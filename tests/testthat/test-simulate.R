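# Shared small simulations (computed once per test run).
noiseless_config <- function(n = 40, seed = 101) {
  simulation_config(
    n_proteins = n, seed = seed,
    replicate_sd_log2 = 0, channel_sd_log2 = 0, peptide_offset_sd_log2 = 0,
    mnar_midpoint_log2 = -100, dia_mnar_midpoint_log2 = -100,
    mcar_rate = 0
  )
}

test_that("the generator is deterministic and label-consistent", {
  cfg <- simulation_config(n_proteins = 60, seed = 5)
  sim1 <- simulate_experiment(cfg)
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(sim1$dda$records, sim2$dda$records)
  expect_identical(sim1$dia$records, sim2$dia$records)
  expect_identical(sim1$crosslink$cl, sim2$crosslink$cl)

  # changed/unchanged partition; unchanged ratios exactly 1 at both points
  tr <- sim1$truth
  expect_equal(sum(tr$changed) + sum(!tr$changed), nrow(tr))
  expect_true(all(tr$true_ratio_t10min[!tr$changed] == 1))
  expect_true(all(tr$true_ratio_t1h[!tr$changed] == 1))
  expect_true(all(tr$rbp != tr$background_binder))

  expect_error(simulation_config(n_proteins = 10),
    class = "silacquant_error_config")
  expect_error(simulation_config(n_proteins = 10, seed = 1, mcar_rate = 1.5),
    class = "silacquant_error_config")
})

test_that("noiseless simulation recovers the truth exactly", {
  sim <- simulate_experiment(noiseless_config())
  mat <- suppressWarnings(build_intensity_matrix(sim$dia$records, sim$dia$design))
  tbl <- compute_peptide_ratios(mat, sim$dia$design) |>
    mask_single_peptide_quantitations() |>
    aggregate_protein_ratios()
  joined <- dplyr::inner_join(
    dplyr::filter(tbl, !is.na(ratio_lh)),
    sim$truth, by = "gene")
  truth_ratio <- ifelse(joined$timepoint == "t10min",
    joined$true_ratio_t10min, joined$true_ratio_t1h)
  expect_equal(joined$ratio_lh, truth_ratio, tolerance = 1e-9)
})

test_that("realized missingness tracks the generator's own expectation", {
  sim <- simulate_experiment(simulation_config(n_proteins = 400, seed = 11))
  for (arm in list(sim$dda, sim$dia)) {
    expect_lt(abs(arm$realized_missingness - arm$expected_missingness), 0.03)
  }
  # with non-detection switched off, the per-sample median log2 intensity
  # sits at the configured baseline mean (the intensity model itself is
  # unbiased; MNAR necessarily shifts detected medians upward)
  sim_full <- simulate_experiment(simulation_config(n_proteins = 400, seed = 11,
    mnar_midpoint_log2 = -100, dia_mnar_midpoint_log2 = -100, mcar_rate = 0))
  med <- sim_full$dda$records |>
    dplyr::group_by(run_id, channel) |>
    dplyr::summarise(med = median(log2(intensity)), .groups = "drop")
  expect_true(all(abs(med$med - 17) <= 0.5))
})

test_that("the DIA arm is deeper but sparser than the DDA arm", {
  sim <- simulate_experiment(simulation_config(n_proteins = 400, seed = 12))
  mat_dda <- suppressWarnings(build_intensity_matrix(sim$dda$records, sim$dda$design))
  mat_dia <- suppressWarnings(build_intensity_matrix(sim$dia$records, sim$dia$design))
  miss <- function(m, d) {
    mean(suppressWarnings(
      detection_and_missingness_summary(m, d))$missingness$pct_missing)
  }
  expect_gt(dplyr::n_distinct(mat_dia$gene), dplyr::n_distinct(mat_dda$gene))
  expect_gt(miss(mat_dia, sim$dia$design), miss(mat_dda, sim$dda$design))
  # charge expansion gives DIA more precursors than DDA has peptides
  expect_gt(nrow(mat_dia), nrow(mat_dda))
})

test_that("DIA-dialect writing reinserts tags and round trips", {
  rec <- tibble::tibble(
    run_id = "r1", channel = c("heavy", "light"),
    protein_ids = "P1", gene = "G1",
    peptide_seq = "PEPTIDEK", charge = 2L,
    intensity = c(100, 50)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diann_like(rec, path)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(raw$Precursor.Id,
    c("PEPTIDEK(SILAC-K-H)2", "PEPTIDEK(SILAC-K-L)2"))

  sim <- simulate_experiment(simulation_config(n_proteins = 30, seed = 13))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_diann_like(sim$dia$records, path2)
  back <- read_diann_report(path2)
  expect_equal(nrow(back), nrow(sim$dia$records))  # q <= 0.01: none filtered
  orig <- sim$dia$records |>
    dplyr::transmute(run_id, channel, gene,
      precursor_id = paste0(peptide_seq, charge), intensity) |>
    dplyr::arrange(run_id, channel, precursor_id)
  got <- back |>
    dplyr::transmute(run_id, channel, gene = genes, precursor_id, intensity) |>
    dplyr::arrange(run_id, channel, precursor_id)
  expect_equal(got$precursor_id, orig$precursor_id)
  expect_equal(got$intensity, orig$intensity, tolerance = 1e-9)
})

test_that("MaxQuant-dialect writing round trips and decoys are removed", {
  sim <- simulate_experiment(simulation_config(n_proteins = 25, seed = 14))
  p_pep <- withr::local_tempfile(fileext = ".txt")
  p_pg <- withr::local_tempfile(fileext = ".txt")
  write_maxquant_like(sim$dda$records, p_pep, p_pg)

  suppressMessages(pep <- read_maxquant_peptides(p_pep))
  # the injected non-unique decoy is gone
  expect_false(any(grepl("SHAREDK$", pep$feature_id)))
  orig <- sim$dda$records |>
    dplyr::arrange(run_id, channel, peptide_seq)
  got <- dplyr::semi_join(pep, orig,
    by = c("run_id", "channel", "peptide_seq")) |>
    dplyr::filter(!is.na(intensity)) |>
    dplyr::arrange(run_id, channel, peptide_seq)
  expect_equal(nrow(got), nrow(orig))
  expect_equal(got$intensity, orig$intensity, tolerance = 1e-9)

  suppressMessages(pg <- read_maxquant_protein_groups(p_pg))
  expect_false(any(pg$gene %in% c("DECOYREV", "DECOYCON", "KRT1")))
  expect_true(all(pg$ratio_lh > 0, na.rm = TRUE))
})

test_that("noiseless proteinGroups ratios invert back to the truth", {
  sim <- simulate_experiment(noiseless_config(n = 20, seed = 15))
  p_pep <- withr::local_tempfile(fileext = ".txt")
  p_pg <- withr::local_tempfile(fileext = ".txt")
  write_maxquant_like(sim$dda$records, p_pep, p_pg, decoys = FALSE)
  suppressMessages(pg <- read_maxquant_protein_groups(p_pg))
  joined <- pg |>
    dplyr::mutate(timepoint = ifelse(grepl("t10min", run_id), "t10min", "t1h")) |>
    dplyr::inner_join(sim$truth, by = "gene")
  truth_ratio <- ifelse(joined$timepoint == "t10min",
    joined$true_ratio_t10min, joined$true_ratio_t1h)
  expect_equal(joined$ratio_lh, truth_ratio, tolerance = 1e-9)
})

test_that("the crosslink arm separates binders from background", {
  sim <- simulate_experiment(simulation_config(n_proteins = 150, seed = 16,
    background_cl_fc = 8))
  log2_tbl <- function(x) {
    dplyr::mutate(x, dplyr::across(-gene, log2))
  }
  res <- crosslink_enrichment(log2_tbl(sim$crosslink$cl),
    log2_tbl(sim$crosslink$noncl))
  joined <- dplyr::inner_join(tibble::as_tibble(res), sim$truth, by = "gene")
  # enrichment calls should hit true binders far more often than background
  frac_rbp <- mean(joined$enriched[joined$rbp])
  frac_bg <- mean(joined$enriched[joined$background_binder])
  expect_gt(frac_rbp, frac_bg)
  expect_lt(frac_bg, 0.2)
})
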