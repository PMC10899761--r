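#' Variance-stabilizing glog normalization
#'
#' A deliberately simple two-step calibration in the spirit of
#' variance-stabilizing normalization.  Step 1 aligns each sample to the
#' row-median reference profile with an affine fit
#' \eqn{x_{fs} \approx a^{cal}_s + b^{cal}_s \, \mu_f} estimated by a
#' least-trimmed-squares iteration (the worst 10% of features are dropped
#' from the fit each round, making the calibration robust to
#' differentially abundant features).  Step 2 applies a generalized-log
#' transform \eqn{h(y) = \operatorname{arsinh}(y / \lambda) / \log 2} to
#' the calibrated values, with the single dispersion parameter
#' \eqn{\lambda} chosen to flatten the SD-versus-rank-mean trend across
#' features --- the defining property of a variance-stabilizing
#' transform.  For large y the transform behaves like log2 up to an
#' affine shift; near zero it stays finite, which is what tames the
#' additive noise floor of weak intensities.
#'
#' This is a reimplementation of the idea, not of the reference
#' maximum-likelihood fit; it is documented as such and is adequate for
#' flattening multiplicative-plus-additive noise.
#'
#' @param mat A linear-scale `silac_matrix` with non-negative intensities.
#' @param config A [normalization_config()] (uses `vsn_max_iter` as the
#'   cap on calibration rounds).
#' @return A `silac_matrix` on "glog" scale.  The per-sample coefficients
#'   of the equivalent form \eqn{h(x) = \operatorname{arsinh}(a_s + b_s
#'   x)/\log 2} are in attribute `vsn_coefficients`.
#' @export
normalize_vsn <- function(mat, config = normalization_config(method = "vsn")) {
  if (intensity_scale(mat) != "linear") {
    abort_silac("vsn-style normalization expects linear-scale intensities",
      class = "silacquant_error_scale")
  }
  x <- matrix_values(mat)
  n_s <- ncol(x)
  for (s in seq_len(n_s)) {
    if (all(is.na(x[, s]))) {
      abort_silac("sample with no usable intensities in vsn fit",
        class = "silacquant_error_degenerate_sample")
    }
  }

  if (n_s == 1) {
    # no cross-sample calibration possible; glog against the sample scale
    lambda <- median(x[, 1], na.rm = TRUE)
    h <- asinh(x / lambda) / log(2)
    out <- set_matrix_values(mat, h, scale = "glog")
    attr(out, "vsn_coefficients") <- tibble(
      sample = sample_cols(mat), a = 0, b = 1 / lambda)
    return(out)
  }

  # Step 1: robust affine calibration of each sample against the
  # row-median reference.
  ref <- apply(x, 1, median, na.rm = TRUE)
  a_cal <- numeric(n_s)
  b_cal <- numeric(n_s)
  rounds <- min(config$vsn_max_iter, 5L)
  for (s in seq_len(n_s)) {
    ok <- which(!is.na(x[, s]) & !is.na(ref))
    keep <- ok
    fit <- NULL
    for (it in seq_len(rounds)) {
      fit <- lm(x[keep, s] ~ ref[keep])
      res <- abs(x[ok, s] - (coef(fit)[1] + coef(fit)[2] * ref[ok]))
      keep_new <- ok[res <= quantile(res, 0.9)]
      if (identical(keep_new, keep)) break
      keep <- keep_new
    }
    a_cal[s] <- unname(coef(fit)[1])
    b_cal[s] <- max(unname(coef(fit)[2]), .Machine$double.eps)
  }
  calibrated <- sweep(sweep(x, 2, a_cal, "-"), 2, b_cal, "/")

  # Step 2: one dispersion parameter, fitted so the per-feature SD of the
  # transformed values no longer depends on intensity.
  scale0 <- median(calibrated, na.rm = TRUE)
  trend_for <- function(log_lambda) {
    abs(sd_rank_trend(asinh(calibrated / exp(log_lambda)) / log(2)))
  }
  opt <- stats::optimize(trend_for,
    interval = log(c(scale0 * 1e-6, scale0 * 10)))
  lambda <- exp(opt$minimum)

  h <- asinh(calibrated / lambda) / log(2)
  out <- set_matrix_values(mat, h, scale = "glog")
  attr(out, "vsn_coefficients") <- tibble(
    sample = sample_cols(mat),
    a = -a_cal / (b_cal * lambda),
    b = 1 / (b_cal * lambda)
  )
  out
}

#' Slope of the SD-versus-rank-mean trend
#'
#' Diagnostic used to judge variance stabilization: per-feature standard
#' deviation across samples regressed on the rank of the feature mean
#' (rank scaled to \[0, 1\]).  A flat trend (slope near 0) means the
#' variance no longer depends on intensity.
#'
#' @param mat A `silac_matrix` (any scale) or numeric matrix.
#' @return The fitted slope (change in SD across the full intensity range).
#' @export
sd_rank_trend <- function(mat) {
  m <- if (inherits(mat, "silac_matrix")) matrix_values(mat) else as.matrix(mat)
  n_obs <- rowSums(!is.na(m))
  m <- m[n_obs >= 2, , drop = FALSE]
  feat_sd <- apply(m, 1, sd, na.rm = TRUE)
  feat_mean <- rowMeans(m, na.rm = TRUE)
  r <- rank(feat_mean) / length(feat_mean)
  unname(coef(lm(feat_sd ~ r))[2])
}
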