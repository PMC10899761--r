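# Fixture builders and independent brute-force oracles used across tests.

make_design <- function(n_rep = 3, acquisition = "DIA", prefix = "run") {
  sample_design(tidyr::crossing(
    timepoint = c("t10min", "t1h"), replicate = seq_len(n_rep)
  ) |>
    dplyr::mutate(
      run_id = sprintf("%s_%s_r%d", prefix, timepoint, replicate),
      acquisition = acquisition,
      light_condition = "arsenite", heavy_condition = "mock",
      crosslinked = TRUE
    ))
}

# Small silac_matrix from a features x samples value matrix.
make_matrix <- function(values, sample_names = colnames(values),
                        genes = NULL, scale = "log2") {
  n <- nrow(values)
  genes <- genes %||% sprintf("G%03d", seq_len(n))
  df <- tibble::tibble(
    feature_id = sprintf("F%03d", seq_len(n)),
    gene = genes,
    protein_ids = sprintf("P%03d", seq_len(n))
  )
  for (j in seq_along(sample_names)) df[[sample_names[j]]] <- values[, j]
  as_silac_matrix(df, sample_cols = sample_names, scale = scale)
}

# ---- independent oracles (deliberately naive) ------------------------------

# BH step-up as the literal min-over-suffix definition, O(m^2).
oracle_bh <- function(p) {
  ok <- which(!is.na(p))
  m <- length(ok)
  q <- rep(NA_real_, length(p))
  if (m == 0) return(q)
  ord <- ok[order(p[ok])]
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[ord[i]] <- min(1, min(cand))
  }
  q
}

# Sort-based median of the non-missing values.
oracle_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Singleton masking by per-group count-and-replace.
oracle_mask <- function(tbl) {
  key <- paste(tbl$gene, tbl$timepoint, tbl$replicate)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (sum(!is.na(tbl$ratio_lh[idx])) == 1) tbl$ratio_lh[idx] <- NA_real_
  }
  tbl
}

# Type-7 percentile by explicit interpolation between order statistics.
oracle_percentile <- function(x, q) {
  x <- sort(x[!is.na(x)])
  h <- (length(x) - 1) * q
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  x[lo] + (h - floor(h)) * (x[hi] - x[lo])
}

# Pearson r^2 via the raw covariance formula.
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
}

# Pearson r^2 via the regression SSE formula.
oracle_r2_sse <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  fit <- lm(y ~ x)
  1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
}

# Random peptide ratio table for masking/aggregation property tests.
random_ratio_table <- function(n_genes = 4, n_pep_max = 4, p_missing = 0.4) {
  purrr::map_dfr(seq_len(n_genes), function(g) {
    n_pep <- sample(seq_len(n_pep_max), 1)
    tidyr::crossing(
      timepoint = c("t10min", "t1h"), replicate = 1:2,
      peptide = seq_len(n_pep)
    ) |>
      dplyr::mutate(
        gene = sprintf("G%02d", g),
        peptide_id = sprintf("G%02d_p%d", g, peptide),
        peptide_seq = peptide_id,
        ratio_lh = ifelse(runif(dplyr::n()) < p_missing, NA_real_,
          2^rnorm(dplyr::n(), 0, 0.5))
      ) |>
      dplyr::select(gene, peptide_id, peptide_seq, timepoint, replicate, ratio_lh)
  })
}

matrix_values_for_test <- function(mat) {
  as.matrix(tibble::as_tibble(mat)[sample_cols(mat)])
}

# Correlated gene-by-sample matrix with MCAR holes plus its ground truth.
correlated_fixture <- function(n = 80, p_missing = 0.2, seed = 82) {
  withr::with_seed(seed, {
    shared <- rnorm(n, 0, 1)
    x <- vapply(1:6, function(j) shared + rnorm(n, 0, 0.5), numeric(n))
    colnames(x) <- paste0("s", 1:6)
    mask <- matrix(runif(n * 6) < p_missing, n, 6)
    x_miss <- x
    x_miss[mask] <- NA
    list(truth = x, observed = x_miss, mask = mask)
  })
}

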