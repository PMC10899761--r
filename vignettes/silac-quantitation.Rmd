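---
title: "SILAC ratio quantitation and acquisition comparison: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SILAC ratio quantitation and acquisition comparison: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacquant)
```

This vignette is the package's own account of the quantitative model it
implements, the parameters that matter, what the synthetic data generator
does and does not emulate, and the numerical and design choices that were
genuinely open.

## The quantitation model

A SILAC RNA-interactome experiment mixes a treated culture grown on
light lysine/arginine with a mock-treated culture grown on the heavy
isotopes, so every mass-spec run carries an internal control.  The
pipeline's chain is:

1. **Ingest.** DIA precursor reports (DIA-NN `Report.tsv` dialect) are
   filtered at 1% precursor *and* 1% translated q-value; the SILAC
   channel is read off the `(SILAC-K-H/L)` / `(SILAC-R-H/L)` tags in the
   precursor id and the tags are stripped so both channel forms of a
   precursor share one identity (protein ids ⊕ gene ⊕ stripped
   precursor id).  DDA tables (MaxQuant dialect) contribute unique
   peptides only; contaminant, reverse-decoy and keratin protein groups
   are removed, and stored heavy/light ratios are inverted to
   light/heavy so that "up" always means more RNA association after
   treatment.  Everywhere, an intensity of zero or blank is treated as
   *missing*: a zero in MS quantitation means non-detection, not
   absence of signal.
2. **Normalization** (below) on the feature-by-sample matrix, where a
   sample unit is a run crossed with a channel (`run_H`, `run_L`).
3. **Ratios.** Per peptide and run, ratio = light/heavy on linear scale
   (log2 inputs: \(2^{L-H}\)); missing if either channel is missing.
4. **Singleton masking.** Within each (gene, time point, replicate), a
   single surviving peptide ratio has no second measurement backing it
   and is set to missing; groups with zero or two-plus survive
   unchanged.  Masking runs *before* aggregation, so a masked singleton
   can never become a protein ratio.
5. **Aggregation.** The protein ratio is the median over non-missing
   peptide ratios (even counts: mean of the two middle values).  The
   peptide tally counts distinct stripped sequences — two charge states
   of one modified sequence count once.  A protein is *detected* in a
   sample when that tally is ≥ 2.
6. **Filters.** Stage 1 keeps genes with non-missing ratios in ≥ 2 of 3
   replicates at any time point; stage 2 (the "processed" set)
   additionally requires ≥ 2 peptides and detection in ≥ 2 of 3
   replicates at *both* time points.  Both thresholds are arguments;
   each stage's casualty count is reported.
7. **Differential association.** Genes with ≥ 2 ratios at both time
   points are tested (two-sided t-test on log2 ratios, 1 h vs 10 min);
   BH correction runs over the tested genes.  The primary significance
   rule is p < 0.05 *and* log2FC outside the dataset's own 10th/90th
   percentiles; BH-significant genes are flagged separately.  Where a
   crosslink-enrichment result is supplied, the final RBP call
   intersects the primary call with enrichment.
8. **Crosslink enrichment.** On mean-normalized log2 protein
   intensities, a gene is enriched when detected exclusively in
   crosslinked samples, or when the t-test survives BH at FDR < 0.05
   with linear fold change > 1.5.  Light and heavy channels count as
   separate samples (4 vs 4 in the emulated design).

Assumptions worth stating: log2 L/H ratios are approximately normal
across replicates (the t-test's requirement); peptide ratios of a gene
are exchangeable (the median is a pure location summary); and the
detection filter's heavy-control requirement is equivalent to the ≥ 2
quantitated-peptides rule, since a ratio exists only where both channels
were observed.

## Normalization methods

All scalar and loess methods operate on log2 intensities (the convention
of the frameworks these algorithms come from); the vsn-style transform
takes linear intensities.  The four-group annotation of the design
(10 min light = 1, 10 min heavy = 2, 1 h light = 3, 1 h heavy = 4) is
reporting metadata; normalization always runs over the full matrix.

* **Mean / median shift** — each sample is shifted so its statistic over
  non-missing values equals the grand mean of the per-sample statistics;
  equality is exact to machine precision.
* **Cyclic loess** — removes intensity-dependent (MA-trend) bias.  Each
  sweep fits a loess curve of M on A per sample pair (`pairwise`) or per
  sample against the row-mean reference (`fast_reference`, the default,
  matching the cited framework's default) over features present in both,
  and subtracts the fit (half to each side in pairwise mode).  Span 0.7,
  up to 3 sweeps, early stop when the largest per-sample correction
  drops below 1e-4 log2 units.  Fewer than 10 shared features in a
  comparison is an error, not a silent skip.  The implementation is the
  package's own (`stats::lowess` per comparison) because per-pair
  missing-value handling and the overlap guard are part of the contract;
  the test suite cross-checks it against `limma::normalizeCyclicLoess`
  on complete data.
* **vsn-style glog** — a deliberately simplified variance-stabilizing
  transform, in two steps: (i) each sample is calibrated against the
  row-median reference by an affine fit estimated with least-trimmed
  squares (the worst 10% of features are dropped from the fit each
  round, shielding the calibration from differentially abundant
  features); (ii) a single dispersion parameter λ of
  \(h(y)=\operatorname{arsinh}(y/\lambda)/\log 2\) is chosen to flatten
  the SD-versus-rank-mean trend.  An earlier coordinate-wise
  maximum-likelihood-style iteration was abandoned: with the mean
  profile recomputed each sweep, any common transform is a fixed point,
  so the fit never left its initialization.  The two-step scheme is not
  the reference ML estimator and is documented as such; its output is
  marked `glog` (≈ log2 up to an affine factor for large intensities).
* **Passthrough** — DDA pipelines may carry MaxQuant's own
  ratio-level normalization from `proteinGroups.txt`; that normalization
  is not reimplemented.

## Statistical choices

* **Welch by default, Student available.**  The unequal-variance test is
  the safer default at n = 3.  It is, however, conservative at that
  depth: on exactly normal null data its empirical type-I error is about
  0.035 at α = 0.05, because the Satterthwaite degrees of freedom are
  themselves noisy.  The pooled Student test is exact when the two
  groups share a variance, which is true under the null of the
  generator's model; the acceptance checks of type-I calibration
  therefore use `var_equal = TRUE`, and separately assert that the Welch
  default never exceeds the nominal band.  Degenerate inputs are pinned:
  two zero-variance groups give p = 1 on equal means and the smallest
  representable double otherwise; groups of fewer than two values give a
  missing p.
* **BH with m = number of tested genes.**  Missing p-values pass through
  as missing and do not count toward m (`stats::p.adjust` on the
  non-missing subset).
* **Percentile gates, type 7.**  The 10th/90th percentiles use the
  linear-interpolation quantile (index \(h=(n-1)q\)), computed over the
  genes actually tested — not over a pre-filter superset and not
  recomputed after restricting to enriched genes.  Fewer than 10 tested
  genes leaves the gates undefined and significance limited to the BH
  call, with a warning.
* **Fold changes are differences of log-means.**  log2FC = mean log2
  ratio at 1 h minus mean at 10 min; the ratio-of-means alternative was
  considered and rejected as the default because the log-mean convention
  matches how the fold changes are plotted and thresholded.

## Imputation

Both methods operate on the gene-by-sample matrix of protein ratios for
genes quantified at least twice at *either* time point (the stage-1
gate) — deliberately wider than the processed set, since the entire
point of imputation is to say something about proteins missing a whole
time point.

* **Half-minimum** encodes a limit-of-detection assumption: every
  missing cell becomes 0.5× the column minimum, identically the column's
  log2 minimum − 1.  The two phrasings are the same number; the package
  implements the rule once per scale and the tests assert exact
  equivalence.
* **Random forest** (missForest-style) encodes a missing-at-random
  assumption: initialize missing cells at column means, then repeatedly
  regress each column on the others (columns visited in increasing
  missingness order, 100 trees by default) and re-predict its missing
  cells, stopping when the change in imputed values stalls; the previous
  sweep is kept on a stall.  A seed is mandatory and the result is
  bit-reproducible for a given seed.  Genes whose observed support at
  some time point is below 2 values are flagged `imputation_robust =
  FALSE` and excluded from significance calls on the random-forest route
  only — their imputed time-point means rest almost entirely on
  predictions.  The half-minimum route keeps them: calling proteins that
  appear only after prolonged treatment is what that method is for.

## The synthetic generator

`simulate_experiment()` draws, per protein, a baseline log2 intensity
(normal, mean 17, SD 2 — the scale of published RNA-interactome
intensity distributions), a shifted-geometric peptide count (mean 4),
and per-peptide ionization offsets (SD 1 log2 unit).  Heavy intensity is
baseline + offset + a run-level loading shift (SD 0.2) + channel noise
(SD 0.25 log2); light is heavy × true ratio × its own channel noise, so
the loading shift cancels in ratios and per-peptide ratio noise equals
the channel noise.  A changed protein (10% by default) has ratio 1 at
10 min and \(2^{\pm 1}\) at 1 h; unchanged proteins have ratio exactly 1
at both points.  Non-detection is a logistic function of log2 intensity
(MNAR) plus a 2% MCAR floor, drawn independently per feature, sample and
channel (a correlated-channel option exists because SILAC pairs
co-elute).

The two acquisition arms differ in three calibrated ways: the DIA arm
expands peptides into charge-2 plus (with probability 0.5) charge-3
precursors sitting ~1 log2 unit lower; its detection curve is deeper and
softer (midpoint 14.8, slope 0.5 versus 16.5 and 10 for DDA — DDA's
intensity-ranked precursor selection behaves like a sharp cliff); and
its channel noise is 0.7× the DDA value (MS2-level quantitation is the
more precise one).  These defaults were calibrated once so the arms land
in the published comparison regime — DIA detects more proteins and keeps
more through the filters with visibly lower replicate MaxSD, while
carrying roughly a third missing cells among everything it detects
versus roughly a fifth for DDA — and they are generator defaults, not
claims about any real dataset.  One consequence of MNAR worth knowing:
medians of *detected* intensities sit above the configured baseline
mean; the generator's intensity model is unbiased only with
non-detection switched off, and that is how the tests check it.

The crosslink arm produces protein-level intensities for two crosslinked
and two non-crosslinked runs (each contributing both channels); true
RNA-binders (75% of proteins by default) are depleted 4-fold in the
non-crosslinked samples, background silica binders are not.

What the generator does **not** emulate: retention time, m/z or
spectrum-level structure; shared (razor) peptides across proteins;
correlated biological replicate effects on ratios; batch drift within an
acquisition; or heavy-channel arginine-to-proline conversion.  Passing
tests therefore demonstrate that the pipeline's logic and statistics are
correct under a faithful noise-and-missingness model, not that any
specific biological dataset will reproduce.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to run
comfortably on one CPU: 2,000 proteins for the null-calibration check,
20 × 400 proteins for the FDR check, 1,000 proteins (≥ 4 peptides each)
for fold-change recovery, and 800 proteins for the acquisition
comparison; oracle-equivalence checks (BH, median, masking, percentiles)
run on around a thousand small random instances each.  Every stochastic
step in the package takes an explicit seed — the generator refuses to
run without one — and a pipeline run with a fixed config and seed writes
byte-identical outputs, which the acceptance suite asserts literally.

## Known limitations

* Gene-symbol-level quantitation only: protein groups with multiple
  ";"-separated gene symbols are dropped (with a reported count) because
  no defensible single-gene assignment exists at aggregation; there is
  no parsimony inference.
* The vsn-style transform is a calibration heuristic, not the reference
  maximum-likelihood fit; with a single sample it applies the glog with
  no cross-sample calibration at all.
* MaxSD is computed on linear ratios by default (a log2 option exists
  and is recorded in the output) — the convention for this metric is
  genuinely ambiguous in the field.
* The CL vs non-CL test treats light and heavy channels as independent
  samples; a paired treatment would be defensible and is not provided.
* Welch p-values at n = 3 are conservative (see above); users wanting
  exactly nominal type-I under equal variances should set
  `var_equal = TRUE`.
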