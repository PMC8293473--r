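---
title: "Methods: urinary peptidomics grading of renal fibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary peptidomics grading of renal fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibropep)
```

## The problem and the data model

Interstitial fibrosis and tubular atrophy (IFTA), scored on kidney biopsy
as the percentage of fibrotic interstitial area, is the common final path
of most progressive chronic kidney diseases. Because biopsy is invasive
and rarely repeated, a urinary readout of IFTA is clinically attractive:
fibrotic matrix remodelling changes the population of naturally occurring
peptides filtered into urine, and CE-MS profiling measures thousands of
them per sample as (mass, migration time, normalized intensity) triples.

`fibropep` consumes that data at the peak-list level. The core container
is a samples-by-peptides table of non-negative relative abundances in
which **zero encodes not-detected**. This convention is deliberate: the
discovery statistics operate on presence/absence and intensity jointly, so
absent detections are informative observations, not missing data. Raw
spectral processing (peak picking, calibration, charge deconvolution,
MS/MS identification) is out of scope; the package starts where a peak
list ends. One identification-level check is included because it operates
on the peak list itself: the plausibility filter that compares a sequence
candidate's predicted CE migration time — a least-squares linear fit of
user-supplied (basic-residue count, migration time) calibrants, with
K/R/H counted as basic at the working pH of 2 — against the observed time
within a tolerance in minutes (`check_migration_time()`).

Internal-standard normalization (`normalize_to_standards()`) rescales each
sample multiplicatively so that the mean (or median) of a configurable set
of housekeeping peptides equals a common reference level. A multiplicative
per-sample model is the simplest mechanism consistent with how such
standards are used; the identities of the 29 standards customary in this
field are laboratory-defined and not published, so they are a parameter,
and the synthetic cohorts plant their own (`IS_01` ... `IS_29`). The
operation is idempotent, and when no reference level is given the grand
mean of the per-sample aggregates is used so the overall intensity scale
is preserved.

## Cohort construction

Groups follow the IFTA cut-offs used in the fibrosis-biomarker literature:
fibrosis at IFTA ≥ 15 %, no fibrosis at IFTA < 10 %, with the 10–15 % band
excluded so that borderline early fibrosis dilutes neither group. Both
cut-offs are parameters of `group_rule()`.

Confounder control is by 1:1 nearest-neighbor matching without
replacement on eGFR, 24-h proteinuria and age (proteinuria log-transformed
first, since it is analysed on a logarithmic scale), each standardized to
zero mean and unit variance over the two groups; sex is an exact-match
constraint that falls back, with a loud warning, to unconstrained matching
when a stratum runs out of controls. "Nearest neighbor" matching has
several defensible readings; we use the simplest reproducible one — greedy,
processing fibrosis samples in ascending `sample_id`, breaking distance
ties toward the lower control id — which makes the procedure deterministic
and invariant to input row order. Optimal (Hungarian) or propensity-score
matching is intentionally out of scope. An etiology-matched sub-cohort is
available by adding `etiology` to the exact-match covariates. Post-matching
balance is reported as Wilcoxon p-values for continuous covariates and a
Fisher exact p-value for sex.

## Discovery statistics

Discovery runs in a fixed order, and the order matters for the multiple
testing family:

1. **Frequency filter**: a peptide is tested only if detected in at least
   30 % of the samples of at least one group. The comparison is `>=`
   ("at least 30 %"); the threshold is a parameter.
2. **Wilcoxon rank-sum test**, two-sided, per retained peptide, with zeros
   included as ordinary (tied) values. For groups of at most 8 samples
   each, the p-value is computed by exact enumeration of all assignments
   of the observed mid-ranks; above that, a normal approximation with tie
   correction (no continuity correction) is used. If all values are
   identical the comparison is degenerate and p = 1.
3. **Benjamini–Hochberg step-up adjustment** applied to the retained
   family only — peptides removed by the frequency filter are not part of
   the tested family and do not dilute the correction.
4. **Selection** at adjusted p < 0.05 (parameter `alpha`).

Fold changes are ratios of group means computed over *all* group samples,
zeros included. The alternative (detected-only means) is available via
`means = "detected"`, but the default is the zero-inclusive version: with
a detection process in the data-generating mechanism, the group-mean ratio
is the quantity that reflects abundance and detection-rate shifts jointly,
which is what a presence/absence-aware pipeline tests.

## The panel classifier

Selected peptides are combined in a C-classification support vector
machine. Panel intensities are `log1p`-transformed (to tame the roughly
log-normal intensity scale; the offset of 1 keeps zeros finite) and
standardized with training-set means and SDs. Kernel and hyperparameters
for this class of classifier are typically not disclosed in the
application literature, so the defaults are explicit and deliberately
plain: RBF kernel with `gamma = 1/panel size` and `cost = 1`, both
configurable, with a linear kernel available. The fitted decision function
is stored as explicit support coefficients, kernel parameters and bias, so
a classifier round-trips through a JSON text file with identical scores;
scores are oriented so that larger means more fibrosis-like.

Validation is leave-one-out: for each training sample the entire
procedure — including the standardization — is refitted without it, and
the held-out sample is scored; the pooled out-of-fold scores form one ROC.
The classification threshold is always data-derived as the Youden-index
operating point (on the training scores by default); published operating
points such as 0.025 for the shipped 29-peptide panel live on the original
software's score scale and are retained only as documentation, never
applied to scores produced here.

## Evaluation

The ROC is the empirical sweep over all distinct score thresholds
(positive when `score >= threshold`); the trapezoid AUC then equals the
Mann–Whitney concordance statistic with ties counted one half, and the
test suite asserts that identity to 1e-12. AUC confidence intervals
default to the Hanley–McNeil variance formula — the closest match to the
MedCalc-era tooling customary in this literature — with DeLong available;
both are Wald intervals clipped to [0, 1]. The Youden point maximizes
`J = sensitivity + specificity − 1`, with ties broken toward higher
specificity, matching the high-specificity operating points typical of
confirmatory urine tests. Sensitivity and specificity intervals are always
exact binomial (Clopper–Pearson). Score–IFTA association uses Spearman's
rho on mid-ranks, with an exact permutation p-value for n ≤ 9 without ties
and the t-approximation otherwise.

## The synthetic cohort generator

The generator exists so that every stage is verifiable at desk scale
without patient data. It is an explicit assumption, not a fact about
CE-MS data, and it is documented as such.

Each peptide's intensity is zero-inflated log-normal:

\[ I = B \cdot \exp(\mu + \delta\,[\text{fibrosis}] + \sigma Z), \qquad
   B \sim \text{Bernoulli}(p_g), \]

with detection probability \(p_g\) depending on the group. The defaults
are chosen once, on first principles:

* `base_log_sd = 0.5` (geometric SD ≈ 1.65, CV ≈ 55 %): a plausible
  inter-individual spread for internal-standard-normalized urinary peptide
  intensities.
* Detection-frequency coupling: abundance shifts in CE-MS data manifest
  jointly as intensity shifts among detections and as detection-rate
  shifts. The planted total fold change `R` (the bundled panel's printed
  group-mean ratio) is therefore split: detection probabilities move apart
  on the logit scale by `2 × 0.25 × log R` around a baseline of 0.85, and
  the remainder of `log R` is planted as the intensity shift δ. With this
  split the zero-inclusive group-mean ratio converges to `R` — so the
  planted effect equals the printed fold change — and effects of the
  panel's magnitude are recoverable after BH at the 100/100 design size,
  as they evidently were in the cohort the panel was derived from. A pure
  intensity-shift model with large variance cannot reproduce that, which
  is the empirical reason detection coupling is part of the default.
* IFTA is uniform on [15, 60) / [0, 10) / [10, 15) for the three strata,
  mirroring the group definitions; eGFR falls, proteinuria (log scale) and
  age rise linearly in IFTA with Gaussian noise, giving the moderate
  Spearman correlations seen in biopsy series (roughly −0.5 for eGFR at
  the defaults). The slopes and noise scales are parameters.
* 300 null peptides with base-10-spanning abundances and detection 0.6,
  29 always-detected internal standards, and a per-sample global scale
  factor (log-SD 0.15) emulating urine concentration variability that
  normalization is meant to remove.
* One integer seed fixes all draws; identical specs give byte-identical
  cohorts.

What the generator does **not** emulate: batch effects and migration-time
drift, correlated peptide families (fragments of one protein are drawn
independently), heavy-tailed contamination, etiology structure in the
peptidome, and any real link between the planted effects and the clinical
covariates beyond the IFTA grouping. Consequently, passing recovery and
AUC tests on synthetic cohorts demonstrates that the *pipeline* is
correct and well-calibrated under its assumed model — not that the shipped
panel achieves any particular performance on real patients. The published
cohort-dependent metrics (test AUC, score–IFTA rho, the 243 → 29 discovery
counts) require the deposited study data and are deliberately not asserted
anywhere in the test suite; the simulation analogues are qualitative.

## Protease inference

A peptide observed at positions `start..stop` of its parent protein
implies cleavage events at `start − 1` (unless the peptide begins at the
protein N-terminus) and `stop` (unless it ends at the C-terminus; with
unknown protein length the site is emitted but flagged uncertain).
Observed-mode prediction intersects these sites exactly with a
literature-derived (protease, substrate accession, position) table.
Per-protease summaries count cleavage events on up- and down-regulated
peptides (direction from the discovery fold change; exactly 1 counts as
neither and is warned about), and aggregate intensity per sample as the
*sum* over the protease's matched peptides before taking group means —
the published per-protease averages are not exact means of the per-peptide
means, so the aggregation rule is necessarily this package's own choice,
stated and configurable (`aggregate = "mean"`).

The bundled association table uses **synthetic** cleavage coordinates
(the true parent-protein positions of the panel peptides were not
published) and exists to exercise the machinery; real analyses should
supply a curated table in the same four-column format.

## Numerical choices and degenerate inputs

* Exact-enumeration cut-off for the rank test: 8 per group
  (`choose(16, 8) = 12870` assignments), balancing exactness against cost.
* Distance ties in matching: toward the lower control `sample_id`;
  standardization guards against zero-variance covariates by using SD 1.
* Standardization in the classifier maps zero-variance panel peptides to
  SD 1 instead of dividing by zero; all-identical samples therefore score
  identically rather than erroring.
* Degenerate ROC inputs (a single class) error; degenerate AUC 0/1 with
  zero variance yields a clipped interval with a warning.
* Sample with no detected internal standard: normalization errors naming
  the sample — silently keeping an uncorrectable sample would bias every
  downstream stage.
* Serialization uses shortest-round-trip number formatting (readr) and
  maximum-precision JSON (`digits = NA`), so write/read cycles are exact.

## Problem sizes used in the test suite

The suite verifies oracle identities (BH vs a brute-force step-up,
rank-sum vs exact enumeration, trapezoid AUC vs pairwise concordance,
leave-one-out vs per-sample retraining) at small n, FDR control on 200
all-null replicates of a 25/25, 60-peptide design, and recovery/AUC
properties on the default 100/100 design with Table-scale planted
effects — sizes chosen so the full suite runs in a few minutes on one CPU
while leaving the statistical assertions comfortable margins (recovery and
permutation-null bands are at least three simulation standard errors away
from their thresholds).

## Known limitations

* The generator's independence assumptions make synthetic discovery easier
  than real discovery at matched effect sizes; treat simulation AUCs as
  upper bounds.
* Greedy matching is order-defined, not globally optimal; with strongly
  separated covariate distributions it cannot balance groups and the
  balance report will say so.
* The Hanley–McNeil interval is known to be slightly anticonservative for
  AUCs near 1 at small n; DeLong is provided for that regime.
* The shipped panel lacks masses, migration times and parent-protein
  coordinates (not published); migration-time checking and protease
  mapping on the real panel therefore require user-supplied annotations.
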