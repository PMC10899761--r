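two_run_design <- function() {
  sample_design(tibble::tibble(
    run_id = c("q_t10min_r1", "q_t1h_r1"), acquisition = "DIA",
    timepoint = c("t10min", "t1h"), replicate = 1L,
    light_condition = "arsenite", heavy_condition = "mock", crosslinked = TRUE
  ))
}

test_that("peptide ratios honor scale and missingness", {
  design <- two_run_design()
  v <- cbind(
    q_t10min_r1_L = c(10, NA), q_t10min_r1_H = c(5, 7),
    q_t1h_r1_L = c(4, 6), q_t1h_r1_H = c(2, NA)
  )
  mat <- make_matrix(v, scale = "linear")
  r <- compute_peptide_ratios(mat, design)
  expect_equal(r$ratio_lh[r$timepoint == "t10min" & r$peptide_id == "F001"], 2)
  expect_true(is.na(r$ratio_lh[r$timepoint == "t10min" & r$peptide_id == "F002"]))
  expect_true(is.na(r$ratio_lh[r$timepoint == "t1h" & r$peptide_id == "F002"]))

  # log2 inputs: (4, 3) -> ratio 2
  vl <- cbind(
    q_t10min_r1_L = 4, q_t10min_r1_H = 3,
    q_t1h_r1_L = 5, q_t1h_r1_H = 5
  )
  rl <- compute_peptide_ratios(make_matrix(vl, scale = "log2"), design)
  expect_equal(rl$ratio_lh[rl$timepoint == "t10min"], 2)

  # unpaired sample unit is a design error
  v_un <- v[, 1:3]
  expect_error(
    compute_peptide_ratios(make_matrix(v_un, scale = "linear"), design),
    class = "silacquant_error_design"
  )
})

test_that("singleton masking matches its brute-force definition", {
  tbl <- tibble::tibble(
    gene = "G1", peptide_id = paste0("p", 1:3), peptide_seq = paste0("p", 1:3),
    timepoint = "t10min", replicate = 1L,
    ratio_lh = c(NA, NA, 1.3)
  )
  masked <- mask_single_peptide_quantitations(tbl)
  expect_true(all(is.na(masked$ratio_lh)))

  tbl2 <- dplyr::mutate(tbl, ratio_lh = c(1.1, 0.9, NA))
  expect_equal(mask_single_peptide_quantitations(tbl2)$ratio_lh, c(1.1, 0.9, NA))

  tbl3 <- dplyr::mutate(tbl[1:2, ], ratio_lh = c(NA_real_, NA_real_))
  expect_equal(mask_single_peptide_quantitations(tbl3)$ratio_lh, c(NA_real_, NA_real_))

  set.seed(61)
  for (i in 1:50) {
    tbl_r <- random_ratio_table()
    expect_equal(
      mask_single_peptide_quantitations(tbl_r)$ratio_lh,
      oracle_mask(tbl_r)$ratio_lh
    )
  }
})

test_that("median aggregation counts distinct sequences and handles parity", {
  tbl <- tibble::tibble(
    gene = "G1",
    peptide_id = c("p1_2", "p1_3", "p2_2", "p3_2"),
    peptide_seq = c("p1", "p1", "p2", "p3"),
    timepoint = "t10min", replicate = 1L,
    ratio_lh = c(1, 2, 4, NA)
  )
  agg <- aggregate_protein_ratios(tbl)
  expect_equal(agg$ratio_lh, 2)
  # two charge states of p1 count once toward the peptide tally
  expect_equal(agg$n_peptides_quantified, 2L)
  expect_true(agg$detected)

  tbl4 <- dplyr::mutate(tbl, peptide_seq = peptide_id, ratio_lh = c(1, 2, 4, 8))
  expect_equal(aggregate_protein_ratios(tbl4)$ratio_lh, 3)

  # a post-masking singleton group aggregates to missing with n = 0
  single <- tibble::tibble(gene = "G9", peptide_id = "p1", peptide_seq = "p1",
    timepoint = "t1h", replicate = 2L, ratio_lh = 5) |>
    mask_single_peptide_quantitations()
  agg_s <- aggregate_protein_ratios(single)
  expect_true(is.na(agg_s$ratio_lh))
  expect_equal(agg_s$n_peptides_quantified, 0L)
  expect_false(agg_s$detected)

  # permutation invariance in peptide order
  set.seed(62)
  tbl_r <- random_ratio_table(n_genes = 6)
  shuffled <- tbl_r[sample(nrow(tbl_r)), ]
  expect_equal(
    aggregate_protein_ratios(tbl_r),
    aggregate_protein_ratios(shuffled)
  )
})

# Build a protein quant table directly: detection pattern per timepoint given
# as counts of replicates with >= 2 quantified peptides.
protein_table_fixture <- function(det_t10, det_t1h, n_pep = 2L, gene = "G1") {
  tidyr::crossing(timepoint = c("t10min", "t1h"), replicate = 1:3) |>
    dplyr::mutate(
      gene = gene,
      detected_here = (timepoint == "t10min" & replicate <= det_t10) |
        (timepoint == "t1h" & replicate <= det_t1h),
      n_peptides_quantified = ifelse(detected_here, n_pep, 0L),
      ratio_lh = ifelse(detected_here, 1.2, NA_real_),
      detected = n_peptides_quantified >= 2
    ) |>
    dplyr::select(gene, timepoint, replicate, ratio_lh, n_peptides_quantified,
      detected)
}

test_that("the detection-filter chain enforces the both-time-points rule", {
  tbl <- dplyr::bind_rows(
    protein_table_fixture(3, 2, gene = "Gpass"),
    protein_table_fixture(2, 1, gene = "GfailTP"),
    protein_table_fixture(3, 3, n_pep = 1L, gene = "GfailPep")
  )
  suppressMessages(out <- apply_detection_filters(tbl))
  flags <- dplyr::distinct(out, gene, stage1_flag, processed_flag)
  expect_true(flags$processed_flag[flags$gene == "Gpass"])
  expect_false(flags$processed_flag[flags$gene == "GfailTP"])
  expect_true(flags$stage1_flag[flags$gene == "GfailTP"])
  # one peptide only: masking logic upstream would null these, and the
  # peptide-representation gate refuses them regardless
  expect_false(flags$processed_flag[flags$gene == "GfailPep"])
})

test_that("filters are monotone in their thresholds", {
  set.seed(63)
  tbl <- purrr::map_dfr(1:30, function(g) {
    protein_table_fixture(sample(0:3, 1), sample(0:3, 1),
      n_pep = sample(1:4, 1), gene = sprintf("G%02d", g))
  })
  suppressMessages({
    loose <- apply_detection_filters(tbl, min_peptides = 2, min_reps = 2)
    tight_pep <- apply_detection_filters(tbl, min_peptides = 3, min_reps = 2)
    tight_rep <- apply_detection_filters(tbl, min_peptides = 2, min_reps = 3)
  })
  genes_of <- function(x) unique(x$gene[x$processed_flag])
  expect_true(all(genes_of(tight_pep) %in% genes_of(loose)))
  expect_true(all(genes_of(tight_rep) %in% genes_of(loose)))
})

test_that("protein ratio matrix pivots round trip", {
  set.seed(64)
  tbl <- aggregate_protein_ratios(random_ratio_table(n_genes = 5))
  wide <- protein_ratio_matrix(tbl)
  expect_equal(nrow(wide), 5)
  back <- protein_ratio_table(wide, tbl)
  merged <- dplyr::inner_join(
    tbl, back,
    by = c("gene", "timepoint", "replicate"), suffix = c("", ".back"))
  expect_equal(merged$ratio_lh, merged$ratio_lh.back)
})
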