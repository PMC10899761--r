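#' Simulation configuration for synthetic SILAC experiments
#'
#' Defines the generative model for ground-truthed two-timepoint,
#' three-replicate, two-channel SILAC experiments in both acquisition
#' dialects, plus a crosslinked versus non-crosslinked arm.  The model per
#' feature f (peptide or precursor) of protein p in run s:
#' \deqn{\log_2 H = \mu_p + \delta_f + \rho_s + \varepsilon_H, \qquad
#'       \log_2 L = \log_2 H + \log_2 r_{p,t} + \varepsilon_L}
#' where \eqn{\mu_p} is the protein baseline, \eqn{\delta_f} a peptide
#' ionization offset, \eqn{\rho_s} a run-level loading shift (cancels in
#' ratios), \eqn{r_{p,t}} the true light/heavy ratio at time point t, and
#' the \eqn{\varepsilon} terms channel noise.  Non-detection is
#' intensity-dependent (logistic MNAR on log2 intensity) plus a flat MCAR
#' rate.  The DIA arm gets more precursors per protein (charge-state
#' expansion), a lower/softer MNAR curve and smaller channel noise than
#' the DDA arm, emulating the deeper but sparser detection and the better
#' quantitation precision of MS2-level DIA quantitation.
#'
#' The default MNAR calibration anchors the two arms to the published
#' acquisition-comparison regime: realized missingness of roughly 19%
#' (DDA) versus 33% (DIA) among detected features, while DIA detects more
#' proteins overall and retains more analyzable (filter-passing) proteins.
#'
#' @param n_proteins Number of simulated proteins.
#' @param peptides_per_protein_mean Mean of the shifted-geometric peptide
#'   count per protein (default 4).
#' @param peptides_per_protein_min Hard floor on peptides per protein
#'   (default 1); counts below it are lifted to the floor.
#' @param baseline_log2_mean,baseline_log2_sd Protein baseline log2
#'   intensity distribution (default 17 and 2).
#' @param peptide_offset_sd_log2 SD of per-peptide ionization offsets.
#' @param fraction_changed Fraction of proteins with a true ratio change
#'   between time points.
#' @param effect_log2 Absolute log2 effect per changed protein (random
#'   sign; unchanged proteins have ratio exactly 1 at both time points).
#' @param replicate_sd_log2 SD of the run-level loading shift.
#' @param channel_sd_log2 SD of per-cell channel noise (DDA; the DIA arm
#'   uses `dia_channel_sd_factor` times this).
#' @param mnar_midpoint_log2,mnar_slope Logistic detection curve for the
#'   DDA arm: detection probability `plogis(slope * (log2 I - midpoint))`.
#' @param dia_mnar_midpoint_log2,dia_mnar_slope Same for the DIA arm.
#' @param mcar_rate Flat missing-completely-at-random rate.
#' @param correlated_channels Use one detection draw per (feature, run) so
#'   SILAC channel pairs co-drop (they co-elute); default independent.
#' @param dia_extra_charge_prob Probability a DIA peptide contributes a
#'   second (charge 3) precursor.
#' @param dia_channel_sd_factor Multiplier on `channel_sd_log2` for DIA.
#' @param fraction_background_binders Fraction of proteins that bind the
#'   silica column irrespective of crosslinking.
#' @param background_cl_fc Linear fold-change by which true RNA-binders are
#'   depleted in non-crosslinked samples.
#' @param seed Mandatory random seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 1000L,
                              peptides_per_protein_mean = 4,
                              peptides_per_protein_min = 1L,
                              baseline_log2_mean = 17,
                              baseline_log2_sd = 2,
                              peptide_offset_sd_log2 = 1,
                              fraction_changed = 0.1,
                              effect_log2 = 1,
                              replicate_sd_log2 = 0.2,
                              channel_sd_log2 = 0.25,
                              mnar_midpoint_log2 = 16.5,
                              mnar_slope = 10,
                              dia_mnar_midpoint_log2 = 14.8,
                              dia_mnar_slope = 0.5,
                              mcar_rate = 0.02,
                              correlated_channels = FALSE,
                              dia_extra_charge_prob = 0.5,
                              dia_channel_sd_factor = 0.7,
                              fraction_background_binders = 0.25,
                              background_cl_fc = 4,
                              seed = NULL) {
  if (is.null(seed)) {
    abort_silac("simulation_config requires a seed",
      class = "silacquant_error_config")
  }
  rates <- c(fraction_changed = fraction_changed, mcar_rate = mcar_rate,
    dia_extra_charge_prob = dia_extra_charge_prob,
    fraction_background_binders = fraction_background_binders)
  if (any(rates < 0 | rates > 1)) {
    abort_silac(
      sprintf("rate parameter(s) outside [0, 1]: %s",
        paste(names(rates)[rates < 0 | rates > 1], collapse = ", ")),
      class = "silacquant_error_config"
    )
  }
  if (n_proteins < 1 || peptides_per_protein_mean < 1) {
    abort_silac("n_proteins and peptides_per_protein_mean must be >= 1",
      class = "silacquant_error_config")
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      peptides_per_protein_mean = peptides_per_protein_mean,
      peptides_per_protein_min = as.integer(peptides_per_protein_min),
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      peptide_offset_sd_log2 = peptide_offset_sd_log2,
      fraction_changed = fraction_changed,
      effect_log2 = effect_log2,
      replicate_sd_log2 = replicate_sd_log2,
      channel_sd_log2 = channel_sd_log2,
      mnar_midpoint_log2 = mnar_midpoint_log2,
      mnar_slope = mnar_slope,
      dia_mnar_midpoint_log2 = dia_mnar_midpoint_log2,
      dia_mnar_slope = dia_mnar_slope,
      mcar_rate = mcar_rate,
      correlated_channels = correlated_channels,
      dia_extra_charge_prob = dia_extra_charge_prob,
      dia_channel_sd_factor = dia_channel_sd_factor,
      fraction_background_binders = fraction_background_binders,
      background_cl_fc = background_cl_fc,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# Random tryptic-looking peptide sequences: non-K/R residues, C-terminal
# K or R (where the SILAC tag sits).
random_peptide_seqs <- function(n, min_len = 7, max_len = 12) {
  alphabet <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N", "P", "Q",
    "S", "T", "V", "W", "Y")
  lens <- sample(min_len:max_len, n, replace = TRUE)
  body <- vapply(lens, function(l) {
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, character(1))
  seqs <- paste0(body, sample(c("K", "R"), n, replace = TRUE))
  # de-duplicate deterministically by suffixing a distinguishing residue run
  while (anyDuplicated(seqs)) {
    dup <- duplicated(seqs)
    seqs[dup] <- paste0(
      substr(seqs[dup], 1, nchar(seqs[dup]) - 1), "A",
      substr(seqs[dup], nchar(seqs[dup]), nchar(seqs[dup]))
    )
  }
  seqs
}

timepoint_design <- function(acquisition, prefix) {
  sample_design(tidyr::crossing(
    timepoint = TIMEPOINT_LEVELS, replicate = 1:3
  ) |>
    mutate(
      run_id = sprintf("%s_%s_r%d", prefix, .data$timepoint, .data$replicate),
      acquisition = acquisition,
      light_condition = "arsenite", heavy_condition = "mock",
      crosslinked = TRUE
    ))
}

# Generate one acquisition arm: long detected-only records plus bookkeeping.
simulate_arm <- function(features, truth, design, midpoint, slope,
                         channel_sd, config, with_q = FALSE) {
  runs <- as_tibble(design)
  n_f <- nrow(features)
  rep_shift <- rnorm(nrow(runs), 0, config$replicate_sd_log2)
  out <- vector("list", nrow(runs))
  exp_miss <- 0
  real_miss <- 0
  n_cells <- 0
  for (i in seq_len(nrow(runs))) {
    tp <- runs$timepoint[i]
    ratio_col <- if (tp == "t10min") "true_ratio_t10min" else "true_ratio_t1h"
    log2_ratio <- log2(truth[[ratio_col]][features$protein_index])
    log2_h <- features$baseline + features$offset + rep_shift[i] +
      rnorm(n_f, 0, channel_sd)
    log2_l <- log2_h + log2_ratio + rnorm(n_f, 0, channel_sd)

    p_h <- stats::plogis(slope * (log2_h - midpoint))
    p_l <- stats::plogis(slope * (log2_l - midpoint))
    if (config$correlated_channels) {
      u <- runif(n_f)
      det_h <- u < p_h
      det_l <- u < p_l
    } else {
      det_h <- runif(n_f) < p_h
      det_l <- runif(n_f) < p_l
    }
    det_h <- det_h & (runif(n_f) >= config$mcar_rate)
    det_l <- det_l & (runif(n_f) >= config$mcar_rate)

    exp_miss <- exp_miss + sum(1 - p_h * (1 - config$mcar_rate)) +
      sum(1 - p_l * (1 - config$mcar_rate))
    real_miss <- real_miss + sum(!det_h) + sum(!det_l)
    n_cells <- n_cells + 2 * n_f

    rec <- tibble(
      run_id = runs$run_id[i],
      channel = rep(c("heavy", "light"), each = n_f),
      feature_id = rep(features$feature_id, 2),
      gene = rep(features$gene, 2),
      protein_ids = rep(features$protein_ids, 2),
      peptide_seq = rep(features$peptide_seq, 2),
      charge = rep(features$charge, 2),
      intensity = c(if_else(det_h, 2^log2_h, NA_real_),
        if_else(det_l, 2^log2_l, NA_real_))
    )
    out[[i]] <- filter(rec, !is.na(.data$intensity))
  }
  records <- bind_rows(out)
  if (with_q) {
    records$q_value <- runif(nrow(records), 0, 0.009)
    records$translated_q <- runif(nrow(records), 0, 0.009)
  }
  list(
    records = records,
    design = design,
    expected_missingness = exp_miss / n_cells,
    realized_missingness = real_miss / n_cells
  )
}

#' Simulate a ground-truthed SILAC experiment
#'
#' Generates the full study layout: a DDA arm and a DIA arm over two time
#' points with three replicates each (light = treated, heavy = mock), and
#' a crosslinked versus non-crosslinked protein-intensity arm (two runs
#' per side, light and heavy channels counted as separate samples).  All
#' randomness derives from `config$seed`; the same config reproduces the
#' same experiment bit for bit.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `truth` (per-protein ground truth),
#'   `peptides` (per-peptide offsets), `dda`, `dia` (each: detected-only
#'   long `records`, `design`, expected and realized missingness), and
#'   `crosslink` (`cl` / `noncl` linear protein intensity tibbles plus
#'   `design`), and the `config` itself.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    truth <- tibble(
      gene = sprintf("GENE%05d", seq_len(n)),
      protein_ids = sprintf("P%05d", seq_len(n)),
      baseline_log2 = rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd),
      changed = runif(n) < config$fraction_changed,
      effect_sign = sample(c(-1, 1), n, replace = TRUE),
      background_binder = runif(n) < config$fraction_background_binders
    ) |>
      mutate(
        rbp = !.data$background_binder,
        true_ratio_t10min = 1,
        true_ratio_t1h = if_else(.data$changed,
          2^(.data$effect_sign * config$effect_log2), 1),
        true_log2fc = log2(.data$true_ratio_t1h) - log2(.data$true_ratio_t10min)
      )

    geo_p <- 1 / config$peptides_per_protein_mean
    n_pep <- pmax(config$peptides_per_protein_min, 1L + stats::rgeom(n, geo_p))
    peptides <- tibble(
      protein_index = rep(seq_len(n), n_pep),
      gene = rep(truth$gene, n_pep),
      protein_ids = rep(truth$protein_ids, n_pep),
      peptide_seq = random_peptide_seqs(sum(n_pep)),
      offset = rnorm(sum(n_pep), 0, config$peptide_offset_sd_log2)
    ) |>
      mutate(baseline = truth$baseline_log2[.data$protein_index])

    # DDA: one feature per peptide sequence (no charge bookkeeping).
    dda_features <- mutate(peptides, charge = NA_integer_,
      feature_id = .data$peptide_seq)
    dda <- simulate_arm(dda_features, truth, timepoint_design("DDA", "DDA"),
      midpoint = config$mnar_midpoint_log2, slope = config$mnar_slope,
      channel_sd = config$channel_sd_log2, config = config)

    # DIA: charge-state expansion; charge-3 precursors ionize less well.
    extra <- peptides[runif(nrow(peptides)) < config$dia_extra_charge_prob, ]
    dia_features <- bind_rows(
      mutate(peptides, charge = 2L),
      mutate(extra, charge = 3L, offset = .data$offset + rnorm(nrow(extra), -1, 0.5))
    ) |>
      mutate(
        precursor_id = paste0(.data$peptide_seq, .data$charge),
        feature_id = paste(.data$protein_ids, .data$gene, .data$precursor_id,
          sep = "|")
      )
    dia <- simulate_arm(dia_features, truth, timepoint_design("DIA", "DIA"),
      midpoint = config$dia_mnar_midpoint_log2, slope = config$dia_mnar_slope,
      channel_sd = config$channel_sd_log2 * config$dia_channel_sd_factor,
      config = config, with_q = TRUE)

    crosslink <- simulate_crosslink_arm(truth, config)

    list(truth = truth, peptides = peptides, dda = dda, dia = dia,
      crosslink = crosslink, config = config)
  })
}

# Protein-level crosslinked vs non-crosslinked arm: 2 runs per side, each
# contributing a light and a heavy sample.  True RNA-binders are depleted
# in non-crosslinked samples; background silica binders are not.
simulate_crosslink_arm <- function(truth, config) {
  design <- sample_design(tibble(
    run_id = c("CL_r1", "CL_r2", "NC_r1", "NC_r2"),
    acquisition = "DDA",
    timepoint = NA_character_,
    replicate = c(1L, 2L, 1L, 2L),
    light_condition = "mock", heavy_condition = "mock",
    crosslinked = c(TRUE, TRUE, FALSE, FALSE)
  ))
  units <- tidyr::crossing(run_id = design$run_id, channel = CHANNEL_LEVELS) |>
    left_join(select(as_tibble(design), "run_id", "crosslinked"), by = "run_id") |>
    mutate(sample = sample_unit(.data$run_id, .data$channel))

  n <- nrow(truth)
  depletion <- if_else(truth$rbp, log2(config$background_cl_fc), 0)
  vals <- purrr::map(seq_len(nrow(units)), function(i) {
    log2_i <- truth$baseline_log2 + rnorm(1, 0, config$replicate_sd_log2) +
      rnorm(n, 0, config$channel_sd_log2)
    if (!units$crosslinked[i]) log2_i <- log2_i - depletion
    p_det <- stats::plogis(config$mnar_slope * (log2_i - config$mnar_midpoint_log2))
    det <- (runif(n) < p_det) & (runif(n) >= config$mcar_rate)
    if_else(det, 2^log2_i, NA_real_)
  })
  names(vals) <- units$sample
  intensities <- tibble(gene = truth$gene, !!!vals)
  list(
    cl = intensities[c("gene", units$sample[units$crosslinked])],
    noncl = intensities[c("gene", units$sample[!units$crosslinked])],
    design = design
  )
}
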