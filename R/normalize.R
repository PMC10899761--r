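#' Normalization configuration
#'
#' @param method One of "mean", "median", "cyclic_loess", "vsn",
#'   "none_passthrough".  Passthrough exists for DDA pipelines that carry
#'   pre-normalized light/heavy ratios from proteinGroups.txt.
#' @param loess_span Loess span in (0, 1]; default 0.7.
#' @param loess_iterations Maximum cyclic-loess sweeps; default 3.
#' @param loess_mode "fast_reference" (each sample against the row-mean
#'   reference) or "pairwise" (all sample pairs, half the fit applied to
#'   each side).
#' @param vsn_max_iter Maximum calibration iterations for the glog fit.
#' @param convergence_tol Early-stop tolerance on the largest per-sample
#'   shift (log2 units).
#' @return A `normalization_config` list.
#' @export
normalization_config <- function(method = c("cyclic_loess", "median", "mean",
                                            "vsn", "none_passthrough"),
                                 loess_span = 0.7, loess_iterations = 3L,
                                 loess_mode = c("fast_reference", "pairwise"),
                                 vsn_max_iter = 20L, convergence_tol = 1e-4) {
  method <- match.arg(method)
  loess_mode <- match.arg(loess_mode)
  stopifnot(loess_span > 0, loess_span <= 1, loess_iterations >= 1,
    vsn_max_iter >= 1, convergence_tol > 0)
  structure(
    list(method = method, loess_span = loess_span,
      loess_iterations = as.integer(loess_iterations),
      loess_mode = loess_mode, vsn_max_iter = as.integer(vsn_max_iter),
      convergence_tol = convergence_tol),
    class = "normalization_config"
  )
}

#' Apply a configured normalization to an intensity matrix
#'
#' Dispatches to [normalize_scalar()], [normalize_cyclic_loess()] or
#' [normalize_vsn()].  Scalar and loess methods expect log2 intensities;
#' the vsn-style transform expects linear intensities and returns glog
#' values.  `none_passthrough` returns the input unchanged.
#'
#' @param mat A `silac_matrix`.
#' @param config A [normalization_config()].
#' @return A normalized `silac_matrix`.
#' @export
normalize_intensities <- function(mat, config = normalization_config()) {
  switch(config$method,
    mean = normalize_scalar(mat, "mean"),
    median = normalize_scalar(mat, "median"),
    cyclic_loess = normalize_cyclic_loess(mat,
      span = config$loess_span, iterations = config$loess_iterations,
      mode = config$loess_mode, tol = config$convergence_tol),
    vsn = normalize_vsn(mat, config),
    none_passthrough = mat
  )
}

#' Scalar (mean/median) normalization
#'
#' Shifts each sample so that its mean or median over non-missing log2
#' intensities equals the grand mean of the per-sample statistics.  The
#' missingness pattern is untouched.
#'
#' @param mat A log2-scale `silac_matrix` with at least one non-missing
#'   value per sample.
#' @param statistic "median" or "mean".
#' @return A log2-scale `silac_matrix` with equalized sample statistics.
#' @export
normalize_scalar <- function(mat, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (intensity_scale(mat) != "log2") {
    abort_silac("scalar normalization expects log2 intensities",
      class = "silacquant_error_scale")
  }
  m <- matrix_values(mat)
  fun <- if (statistic == "median") median else mean
  stats <- apply(m, 2, fun, na.rm = TRUE)
  if (anyNA(stats) || any(!is.finite(stats))) {
    abort_silac("sample(s) with no non-missing values cannot be normalized",
      class = "silacquant_error_degenerate_sample")
  }
  target <- mean(stats)
  set_matrix_values(mat, sweep(m, 2, stats - target, "-"))
}

# One cyclic-loess sweep; returns the corrected matrix.  Missing cells are
# excluded from every fit and never filled in.
cyclic_loess_sweep <- function(m, span, mode) {
  n <- ncol(m)
  if (mode == "fast_reference") {
    ref <- rowMeans(m, na.rm = TRUE)
    for (i in seq_len(n)) {
      ok <- !is.na(m[, i]) & !is.na(ref)
      check_loess_overlap(sum(ok))
      a <- (m[ok, i] + ref[ok]) / 2
      mm <- m[ok, i] - ref[ok]
      fit <- stats::lowess(a, mm, f = span)
      m[ok, i] <- m[ok, i] - stats::approx(fit$x, fit$y, xout = a,
        rule = 2, ties = mean)$y
    }
  } else {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- !is.na(m[, i]) & !is.na(m[, j])
        check_loess_overlap(sum(ok))
        a <- (m[ok, i] + m[ok, j]) / 2
        mm <- m[ok, i] - m[ok, j]
        fit <- stats::lowess(a, mm, f = span)
        half <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y / 2
        m[ok, i] <- m[ok, i] - half
        m[ok, j] <- m[ok, j] + half
      }
    }
  }
  m
}

check_loess_overlap <- function(n_shared) {
  if (n_shared < 10) {
    abort_silac(
      sprintf("cyclic loess needs >= 10 shared features per comparison (got %d)",
        n_shared),
      class = "silacquant_error_insufficient_overlap"
    )
  }
  invisible(n_shared)
}

#' Cyclic loess normalization
#'
#' Removes intensity-dependent (MA-trend) biases between samples, the
#' two-color microarray idea carried over to SILAC channels.  Each sweep
#' fits a loess curve of M (difference) on A (average) per sample pair
#' (`pairwise`) or per sample against the row-mean reference
#' (`fast_reference`, the default) over features non-missing in both, and
#' subtracts the fitted trend; sweeps repeat until the largest per-sample
#' shift drops below `tol` or `iterations` is reached.
#'
#' @param mat A log2-scale `silac_matrix` with >= 2 samples.
#' @param span Loess span (default 0.7).
#' @param iterations Maximum sweeps (default 3).
#' @param mode "fast_reference" or "pairwise".
#' @param tol Early-stop tolerance on the largest absolute correction.
#' @return A log2-scale `silac_matrix`.
#' @export
normalize_cyclic_loess <- function(mat, span = 0.7, iterations = 3L,
                                   mode = c("fast_reference", "pairwise"),
                                   tol = 1e-4) {
  mode <- match.arg(mode)
  if (intensity_scale(mat) != "log2") {
    abort_silac("cyclic loess expects log2 intensities",
      class = "silacquant_error_scale")
  }
  m <- matrix_values(mat)
  if (ncol(m) < 2) {
    abort_silac("cyclic loess needs >= 2 samples",
      class = "silacquant_error_degenerate_sample")
  }
  for (it in seq_len(iterations)) {
    m_new <- cyclic_loess_sweep(m, span = span, mode = mode)
    shift <- max(apply(abs(m_new - m), 2, max, na.rm = TRUE))
    m <- m_new
    if (shift < tol) break
  }
  set_matrix_values(mat, m)
}

#' MA-trend diagnostic for a pair of samples
#'
#' Returns the per-feature M (difference) and A (average) values for two
#' samples of a log2 matrix, plus the loess-smoothed trend, for judging how
#' well normalization removed intensity-dependent bias.
#'
#' @param mat A log2-scale `silac_matrix`.
#' @param sample_i,sample_j Sample column names (defaults: first two).
#' @param span Loess span for the smoothed trend.
#' @return Tibble with `a`, `m`, `trend`.
#' @export
ma_trend <- function(mat, sample_i = NULL, sample_j = NULL, span = 0.7) {
  sc <- sample_cols(mat)
  sample_i <- sample_i %||% sc[1]
  sample_j <- sample_j %||% sc[2]
  x <- matrix_values(mat)
  ok <- complete.cases(x[, c(sample_i, sample_j)])
  a <- (x[ok, sample_i] + x[ok, sample_j]) / 2
  mm <- x[ok, sample_i] - x[ok, sample_j]
  fit <- stats::lowess(a, mm, f = span)
  tibble(a = a, m = mm,
    trend = stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y)
}
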