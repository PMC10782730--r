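---
title: "Paired differential peptidomics of brain microdialysate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired differential peptidomics of brain microdialysate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialyspep)
```

## The experiment this package models

Microdialysis samples the brain's extracellular fluid through a semi-permeable
probe. When a potassium-channel blocker such as 4-aminopyridine (4-AP) is
perfused to induce epileptiform activity, the extracellular peptidome changes:
proteases are released or activated, synaptic and structural proteins are
cleaved, and the fragments that cross the probe membrane can be quantified by
label-free LC-MS. The design is paired: each animal contributes one
control-phase and one treated-phase sample through the same probe, so all
contrasts are within subject (n = 11 pairs in the setting the defaults
emulate). A parallel EEG recording confirms the seizure state
electrophysiologically: 4-AP suppresses urethane-induced ~1 Hz slow waves and
drives a gamma-band (~60 Hz) power increase.

`dialyspep` implements the complete downstream analysis: ingestion and
validation of peptide quantification tables, two-stage normalization,
missingness filtering, presence/absence marker detection, paired differential
testing with multiplicity adjustment and a fold-change gate, positional and
cleavage-site annotation, sample embedding and consensus feature selection,
and the EEG spectral confirmation. A synthetic-data generator reproduces the
statistical structure of all inputs so that every stage is testable without
access to instrument data.

## Data model

The central container is the `AbundanceMatrix`: a peptide-by-sample grid of
strictly positive abundances with `NA` encoding *not detected*, carried
together with the peptide records (sequence, precursor accession, 1-based
inclusive start/end positions, modifications) and the paired design. Zeros
are rejected at ingestion rather than coerced to missing: label-free
quantification reports intensities or nothing, and a silent zero-to-missing
coercion hides upstream errors.

Peptide identity is the tuple (sequence, modification set, precursor
accession, start position). Proteomics search engines report modification
variants of the same sequence as separate quantifiable species, and the same
sequence can occur at different positions of different precursors; the tuple
is the finest identity the table schema supports. Duplicate identity rows are
collapsed by summing (with a warning), treating them as split quantifications
of one species.

## Two-stage normalization

Stage 1 scales every sample so its total present intensity equals the grand
mean of per-sample totals. Using the grand mean rather than 1 keeps values on
the instrument's intensity scale, which matters only for interpretability:
the statistics are scale-free.

Stage 2 re-anchors each sample on *stable reference peptides* - complete-case
peptides whose coefficient of variation across all samples and whose absolute
log2 treated/control mean ratio both fall at or below a quantile (default
0.1) of their respective distributions. The joint rule selects peptides that
are both tightly measured and unchanged by treatment, which is the evident
intent of normalizing to "least variance and abundance ratio" peptides. Each
sample is divided by the mean of its reference values and rescaled by the
grand mean of those means; afterwards the per-sample reference means are
equal (to 1e-9 relative) and the operation is idempotent.

A reference mean computed over very few peptides is itself a noisy quantity,
and dividing by it injects per-sample noise instead of removing it. The
pipeline wrapper `normalize_two_stage()` therefore escalates the quantile
(doubling, with a warning) until at least five reference peptides qualify.
On heavily censored data - the realistic case, where complete-case peptides
are the abundant minority - this trades a stricter stability definition for
an estimable correction.

## Missingness, markers, and probe yield

Peptides with more than four missing values in either phase are excluded from
testing; with 11 subjects this keeps peptides present in more than six
samples of each group. The filter is monotone in its threshold and is applied
*after* normalization, because the supplementary-table convention is that
pre-filter tables already carry normalized abundances.

Presence/absence *treatment markers* are peptides detected in at least 9 of
11 treated samples and at most 2 of 11 control samples. These are computed on
the pre-filter matrix: by construction a marker has at least nine missing
control values and can never survive the missingness filter, so markers and
tested peptides are disjoint readouts of the same matrix. Marker status
depends only on the presence pattern, never on magnitudes.

Probe-yield summaries take, per peptide and probe, the larger of the two
phase abundances (one probe serves both phases of one animal), then report
per-subject detection counts and abundance distributions, plus paired t-tests
comparing phases on detection counts and mean abundances.

## Differential testing

Testing is the classical paired two-tailed t-test on per-subject differences,
applied to normalized abundances on the **linear** scale - the convention of
the analysis this package reimplements (a `log2_transform` option exists but
is off by default). Subjects missing a value in either phase are dropped
(complete-pair deletion); fewer than three complete pairs yields no test, and
zero-variance differences yield a flagged degenerate result (t = 0, p = 1)
rather than an error.

Raw p-values are adjusted by Benjamini-Hochberg step-up (`stats::p.adjust`
under a validated wrapper), and a peptide is *significant* when its adjusted
p < 0.05 **and** its fold change - max(ratio, 1/ratio), covering both
directions - is at least 2. Per-peptide normality screening is available as
an advisory report (`normality_screen()`), never as an exclusion rule.

Supporting comparisons: two-sample Kolmogorov-Smirnov tests for length
distributions, pairwise-complete Spearman correlation between replicates
(pairs sharing fewer than three values are reported `NA`), and agglomerative
clustering of samples (Euclidean distance, complete linkage) on the imputed
significant-peptide submatrix. Offline over-representation analysis uses the
hypergeometric upper tail over user-supplied gene sets, retaining terms with
at least 4 query proteins and fold enrichment at least 4, with BH adjustment
across retained terms.

## Positional and cleavage annotation

A peptide is an *N-terminal fragment* when it starts at precursor position 1
or 2 - position 2 is the mature N-terminus after initiator-methionine loss -
and a *C-terminal fragment* when it ends at the precursor's last residue (the
window is configurable via `met_loss_window`). N-terminal acetylation is
detected by a case-insensitive "acetyl" match on the first residue's
modifications, tolerant of search-engine naming differences.

Cleavage contexts follow Schechter-Berger nomenclature: for each peptide
terminus the four residues on each side of the scissile bond (P4..P1 |
P1'..P4') are read from the precursor, with gap symbols where the protein
ends - positions beyond a protein terminus are never invented. The 4+4 width
is the standard protease-specificity convention. Residue frequency matrices
exclude gaps from each position's denominator so protein-terminal peptides do
not distort the profile; an information-content (bits) weighting is available
for logo rendering by external tools.

Dibasic-flank detection implements the prohormone-convertase signature: the
two residues immediately before the peptide start and the two immediately
after its end must each be a K/R pair. Domain overlap classification
(`CONTAINED` / `PARTIAL` / `NONE`) is plain interval arithmetic on matching
precursors, for questions like whether significant peptides fall inside a
known bioactive region (e.g. secretoneurin within secretogranin-2, residues
184-216).

## Imputation, embedding, and consensus feature selection

Missing cells are imputed deterministically; the default fills each missing
cell with half the peptide's minimum present value, the standard
left-censoring surrogate in proteomics. Present values are never altered.

Sample embedding offers PCA (`prcomp`, deterministic up to sign) and
classical multidimensional scaling of Euclidean sample distances
(`cmdscale`). These are the package's two embeddings: one linear
variance-maximizing view and one distance-preserving view; both place the 22
samples (not the 11 subjects) as points.

Consensus feature selection ranks features by four algorithms - recursive
feature elimination with a linear-SVM base ranker (one feature eliminated per
step down to the top-k), random forest impurity importance, extra-trees
impurity importance, and lasso coefficients at the cross-validated penalty
(3-fold, appropriate for 22 samples) - and admits a feature into the
consensus when it appears in the top ten of at least two algorithms.
Features are standardized before the lasso and the SVM; tree ensembles see
raw abundances, to which they are invariant under monotone scaling. The
whole procedure is deterministic for a fixed seed. With n = 11 pairs no
claim of classifier generalization is made or tested; the consensus is a
stability filter over rankings, nothing more.

## EEG spectral pipeline

Traces (2 kHz sampling in the emulated setting) are low-pass filtered by
zeroing FFT components above 200 Hz (idempotent, length-preserving), and
power spectra are estimated by Welch averaging of Hanning-windowed 1024-point
segments with 50% overlap - with two-minute epochs at this window length,
segment averaging is the only stable estimator, and the PSD scaling satisfies
Parseval (integral of PSD ~ signal variance, verified in tests to 5%). Band
power is the trapezoidal integral of the PSD between band edges, with exact
edges interpolated on the frequency grid so areas are additive over adjacent
bands. The bands of interest are 0-5 Hz (urethane slow waves) and 50-80 Hz
(4-AP gamma activity); phase comparison is a paired two-tailed t-test on
per-subject band areas with a Shapiro-Wilk advisory on the differences.

Band areas carry arbitrary voltage²/Hz units: a gain change rescales every
area quadratically, so absolute areas are not comparable across set-ups and
only the within-subject contrast structure is meaningful.

## The synthetic-data generator

`synth_config()` fixes the study conditions; all randomness flows from one
seed through named substreams, so every artifact is reproducible
independently of evaluation order.

* **Precursors**: random proteins at natural amino-acid frequencies, lengths
  80-800, initiator methionine.
* **Peptidome** (~2,500 peptides): 16.6% N-terminal fragments (start <= 2),
  93% of them acetylated; internal cut points placed after K/R with
  probability 0.7 (trypsin-like P1 bias). Lengths are drawn from a clipped
  gamma distribution with mean 16.8 and sd 7 within [7, 50]: observed
  microdialysate peptide lengths are strongly right-skewed with means near
  16, which a uniform draw over [7, 50] (mean 28.5) cannot reproduce.
* **Abundances**: log-normal baselines (meanlog 1, sdlog 1.5, spanning the
  ~0.1-170 intensity range), per-cell biological noise at CV 0.3, and
  per-sample multiplicative scale corruption (sdlog 0.25) for the
  normalization stage to undo.
* **Effects**: 45% of peptides carry a true fold in [2, 6] applied in the
  treated phase, 30% of them upward. The fractions look large, but the
  filter only ever tests the consistently detected minority; after
  left-censoring the realized significant set is ~270-320 peptides with a
  near-balanced up/down split, matching the structure of real 4-AP data.
  Upregulated effects are sampled with an exponential length tilt so their
  mean length sits 1.7 residues below the population mean (shorter fragments
  rise, longer fall).
* **Missingness**: each cell is dropped with probability logistic in
  standardized -log(abundance) (slope 2, strongly left-censored), with the
  intercept solved so the expected overall rate is exactly 0.5. Under the
  default conditions roughly a third of peptides survive the
  more-than-six-per-group filter.
* **EEG**: per subject, a 1/f background and a ~1 Hz slow wave shared by
  both phases (same animal, same anaesthesia, same electrodes), plus a 60 Hz
  gamma component whose treated amplitude is twice the control amplitude,
  plus small per-recording sensor noise. Doubling the amplitude quadruples
  gamma-band power.

What the generator deliberately does **not** emulate: peptide-correlated
precursor structure (co-regulated fragments of one protein), retention-time
or charge-state artifacts, inter-animal covariance beyond a shared scale, and
identification error. Passing tests therefore demonstrate the correctness and
calibration of the statistical machinery under the stated generative
assumptions, not robustness to every pathology of real instrument data.

## Numerical choices and degenerate inputs

* Tie-breaks in clustering are deterministic by sample order; `cutree` on a
  single sample returns a single-leaf labelling.
* Reference normalization and stage-1 normalization preserve `NA` patterns
  bit-exactly and conserve the grand total (stage 1) to 1e-9 relative.
* The band-area integrator interpolates the exact band edges, making
  adjacent-band additivity an identity rather than an approximation.
* Degenerate paired tests (zero-variance differences) are flagged, not
  fatal; insufficient pairs (< 3) are an error for a single test and an
  `NA` row in the table-level runner.
* Sub-seeds are derived by a string-hash mix of the master seed and a module
  key, kept below 2^31.

## Calibration behaviour worth knowing

On null data at the study's scale (866 tested peptides, n = 11, no planted
effects) the raw-p < 0.05 fraction sits near 0.05 and essentially nothing
passes the combined BH + fold gate; planted fold-3 effects at CV 0.3 are
recovered with sensitivity near 1 at false-discovery proportion near 0.
These calibration checks run on clean matrices: the error-rate property
belongs to the paired test itself, and routing null data through scale
corruption and its subsequent renormalization measures a different (and
slightly conservative) composite.

One subtlety: in the EEG module the 0-5 Hz band is an exact within-subject
null under the default generator (the slow wave is identical across phases),
so its paired p-value is uniformly distributed - any single simulation can
produce a small slow-band p with the corresponding probability. This mirrors
real paired null comparisons; a high slow-band p in any one cohort is one
draw from that distribution, not a guarantee of the generator.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
study's scale (~2,500 peptides, 22 samples), the calibration simulations at
866 peptides, the selection benchmark at 200 features with 5 planted
separators, and the EEG cohort at 11 subjects, two phases, 120 s at 2 kHz.
Smaller instances (tens of peptides, seconds of signal) are used where a
property is structural rather than statistical.

## Limitations

* The reference-peptide rule ("least variance and abundance ratios") is one
  operationalization of an under-specified convention; the quantile is
  exposed so alternatives can be swept.
* Linear-scale t-testing is faithful to the reimplemented analysis but is
  not the package authors' recommendation for new designs; use
  `log2_transform = TRUE` for variance stabilization.
* Consensus membership with n = 11 pairs is sensitive to algorithm settings;
  treat the consensus list as a stability ranking, not as inference.
* Offline over-representation requires user-supplied gene sets and a
  universe; no annotation databases are bundled or queried.
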