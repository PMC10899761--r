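test_that("Welch test matches the reference distribution and corner cases", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3)),
    tibble::tibble(t = 0, df = 4, p_value = 1))

  res <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4, tolerance = 1e-6)
  expect_equal(res$p_value, 0.02131, tolerance = 1e-3)

  expect_true(is.na(welch_t_test(5, c(1, 2, 3))$p_value))
  # zero variance, different means: smallest representable p
  res0 <- welch_t_test(c(2, 2), c(3, 3))
  expect_equal(res0$p_value, .Machine$double.xmin)
  # agreement with stats::t.test on random draws
  set.seed(71)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), 0.5)
    expect_equal(welch_t_test(a, b)$p_value, t.test(a, b)$p.value)
  }
})

test_that("BH adjustment uses the non-missing m and handles examples", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
    rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  expect_error(benjamini_hochberg(c(0.5, 1.2)),
    class = "silacquant_error_domain")
})

test_that("BH matches the naive step-up oracle and is monotone", {
  set.seed(72)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- runif(m)
    p[runif(m) < 0.2] <- NA
    q <- benjamini_hochberg(p)
    expect_equal(q, oracle_bh(p))
    ok <- !is.na(p)
    expect_true(all(q[ok] >= p[ok] - 1e-12))
    expect_false(is.unsorted(q[ok][order(p[ok])]))
  }
})

test_that("percentile thresholds are the type-7 estimator", {
  thr <- percentile_thresholds(0:10)
  expect_equal(unname(thr), c(1, 9))
  expect_equal(unname(percentile_thresholds(rep(3.5, 12))), c(3.5, 3.5))
  x <- c(-5:-1, 1:5) / 2
  thr_s <- percentile_thresholds(x)
  expect_equal(thr_s[["p10"]], -thr_s[["p90"]], tolerance = 1e-12)
  expect_error(percentile_thresholds(1:9),
    class = "silacquant_error_insufficient_data")

  set.seed(73)
  for (i in 1:100) {
    x <- rnorm(sample(10:40, 1))
    thr <- percentile_thresholds(x)
    expect_equal(thr[["p10"]], oracle_percentile(x, 0.1))
    expect_equal(thr[["p90"]], oracle_percentile(x, 0.9))
  }
})

make_cl_fixture <- function() {
  # 20 null genes + three genes exercising each branch of the rule
  set.seed(74)
  genes <- c(sprintf("N%02d", 1:20), "EXCL", "SMALLFC", "NOQ")
  cl_cols <- paste0("CL", 1:4)
  nc_cols <- paste0("NC", 1:4)
  cl <- tibble::tibble(gene = genes)
  nc <- tibble::tibble(gene = genes)
  for (s in cl_cols) cl[[s]] <- rnorm(length(genes), 20, 0.1)
  for (s in nc_cols) nc[[s]] <- rnorm(length(genes), 20, 0.1)
  # exclusive: absent from all non-crosslinked samples
  for (s in nc_cols) nc[[s]][genes == "EXCL"] <- NA
  # tight but small fold change: log2FC = 0.26 (FC about 1.2)
  for (s in cl_cols) cl[[s]][genes == "SMALLFC"] <- 20.26 + rnorm(1, 0, 0.001)
  for (s in nc_cols) nc[[s]][genes == "SMALLFC"] <- 20 + rnorm(1, 0, 0.001)
  # big fold change but noisy: fails the FDR gate
  cl[cl$gene == "NOQ", cl_cols] <- as.list(20 + 1.585 + c(-2, 2, -2, 2))
  nc[nc$gene == "NOQ", nc_cols] <- as.list(20 + c(2, -2, 2, -2))
  list(cl = cl, nc = nc)
}

test_that("crosslink enrichment applies the exclusive-or-significant rule", {
  fx <- make_cl_fixture()
  res <- crosslink_enrichment(fx$cl, fx$nc)
  expect_s3_class(res, "silac_enrichment")
  r <- function(g) res[res$gene == g, ]
  expect_true(r("EXCL")$exclusive_to_cl)
  expect_true(r("EXCL")$enriched)
  expect_true(is.na(r("EXCL")$p_value))

  expect_false(r("SMALLFC")$enriched)   # significant but FC <= 1.5
  expect_lt(r("SMALLFC")$q_value, 0.05)
  expect_false(r("NOQ")$enriched)       # big FC but q >= 0.05
  expect_gt(2^r("NOQ")$mean_log2fc, 1.5)

  gl <- glance(res)
  expect_equal(gl$n_exclusive, 1)
})

test_that("differential association excludes, gates and flags correctly", {
  set.seed(75)
  n <- 40
  base <- purrr::map_dfr(seq_len(n), function(g) {
    shift <- if (g <= 2) 2 else 0  # two genes with a strong true change
    tidyr::crossing(timepoint = c("t10min", "t1h"), replicate = 1:3) |>
      dplyr::mutate(
        gene = sprintf("G%02d", g),
        ratio_lh = 2^(rnorm(6, 0, 0.1) + ifelse(timepoint == "t1h", shift, 0)),
        n_peptides_quantified = 2L, detected = TRUE
      )
  })
  # one gene quantified only at 1 h: excluded from testing
  only_t1h <- base |>
    dplyr::filter(gene == "G40") |>
    dplyr::mutate(ratio_lh = ifelse(timepoint == "t10min", NA_real_, ratio_lh),
      gene = "GONLY1H")
  res <- differential_association(dplyr::bind_rows(base, only_t1h))
  expect_s3_class(res, "silac_differential")
  expect_false(res$tested[res$gene == "GONLY1H"])
  expect_true(all(res$significant_primary[res$gene %in% c("G01", "G02")]))
  thr <- attr(res, "thresholds")
  expect_true(thr["p10"] < 0, thr["p90"] > 0)

  # flags invariant to row order
  shuffled <- dplyr::bind_rows(base, only_t1h)
  shuffled <- shuffled[sample(nrow(shuffled)), ]
  res2 <- differential_association(shuffled)
  expect_equal(tibble::as_tibble(res), tibble::as_tibble(res2))

  # tidy/glance surface
  td <- tidy(res)
  expect_true(all(c("gene", "log2fc", "p_value", "q_value") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_tested, sum(res$tested))
})

test_that("differential association joins crosslink enrichment", {
  set.seed(76)
  tbl <- purrr::map_dfr(1:12, function(g) {
    tidyr::crossing(timepoint = c("t10min", "t1h"), replicate = 1:3) |>
      dplyr::mutate(
        gene = sprintf("G%02d", g),
        ratio_lh = 2^(rnorm(6, 0, 0.1) +
          ifelse(timepoint == "t1h" & g <= 2, 1.5, 0)),
        n_peptides_quantified = 2L, detected = TRUE
      )
  })
  enr <- structure(
    tibble::tibble(gene = sprintf("G%02d", 1:12),
      enriched = c(TRUE, FALSE, rep(TRUE, 10))),
    class = c("silac_enrichment", "tbl_df", "tbl", "data.frame")
  )
  res <- differential_association(tbl, enrichment = enr)
  expect_true(res$significant_rbp[res$gene == "G01"])
  expect_false(res$significant_rbp[res$gene == "G02"])  # significant, not enriched
})
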