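---
title: "Methods: qPCR miRNA panels as risk classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR miRNA panels as risk classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirisk)
```

## The problem

Small qPCR panels of circulating microRNAs, profiled in urine or plasma
collected before radical prostatectomy, have been proposed as
non-invasive classifiers that separate indolent prostate cancer from the
high-risk phenotype.  The measurement is a cycle-threshold (Ct) value
per sample, assay and replicate; lower Ct means more template.  `mirisk`
implements the complete analysis such a study runs — pre-processing,
normalization, differential expression, feature-selection stability,
classification, validation transfer and cross-platform concordance —
together with a synthetic-cohort generator so that every stage can be
exercised and verified against known ground truth without any patient
data.

## Pre-processing rules

Pre-processing runs in a fixed order; each step records a provenance
flag so out-of-order use is detectable.

1. **Expression ceiling.** Ct values above 34 cycles are treated as not
   expressed and set to 34; undetermined reactions map to 34 as well.
   Values exactly at 34 are kept.  The operation is idempotent and
   never increases a value.
2. **Triplicate outlier rule.** Within each (sample, miR) triplet, a
   replicate is removed when it differs by more than 20% from the
   remaining values.  "Differs by more than 20%" is interpreted as
   relative deviation from the *mean of the other two replicates*
   (|x − m|/m > 0.2); the reference value is a genuinely open choice
   (mean, median and pairwise readings all exist in practice) and the
   mean-of-others rule is symmetric and cheap.  At most one replicate —
   the worst offender — is removed per triplet, so a triplet can never
   collapse to a single value by this rule.
3. **Aggregation.** The default aggregate is the *mean* of surviving
   replicates.  Protocol descriptions for this kind of assay sometimes
   say the triplicate *median* enters the final analysis while the
   analysis description says mean; both are supported
   (`aggregate = "median"`), mean is the default because it is the rule
   stated where the analysis itself is defined.
4. **Sample detection QC.** A sample is removed when more than half of
   its panel miRs sit at the ceiling.  No published rule exists for
   this step (studies report *that* low-detection samples were removed,
   not the cut-off), so the 0.5 threshold is an explicit, configurable
   package choice and every removal is reported with its fraction.

PSA doubling time, used to label clinical risk, is computed by the
log-slope method: least squares of ln PSA on time, doubling time
= ln 2 / slope, reported in months, with a non-positive slope mapped to
`Inf` (no doubling).  All available points enter the fit; at least two
are required.

## Normalization

An endogenous control is assessed on three criteria before use:
detection fraction (< 0.5 disqualifies), rank of its Ct standard
deviation within the panel (a top-3 rank disqualifies) and risk-group
dependence (two-sided t-test p < 0.05 disqualifies).  All three
thresholds are configurable; controls failing any criterion should not
be used, which is why geometric-mean normalization is the default path:
subtracting each sample's mean Ct across the panel equals dividing by
the geometric mean on the linear scale and removes per-sample
loading/input offsets exactly.  Normalized values are real numbers
centred at zero per sample; the operation is idempotent to numerical
tolerance.

Two scale conventions coexist deliberately:

* **Differential expression is computed on raw aggregated Ct.**
  Published group-mean tables for this assay class sit in the 19–31
  cycle range, i.e. on the raw Ct scale, and the package reproduces
  their arithmetic exactly on that scale.
* **Classification** accepts either scale
  (`normalize = "geomean"`/`"none"`).

A caveat worth stating explicitly: per-sample normalization subtracts
the panel-mean shift from every feature.  On a small validation panel
(three assays with similar group shifts) this removes most of the very
signal under study, so the transfer analyses in this package's
`analysis/` scripts and acceptance harness classify on raw Ct, where
the sign-reversal logic of the validation experiment applies cleanly.
For full-size panels with heterogeneous shifts, normalized
classification remains the default recommendation.

## Differential expression

Per miR: group means over low- and high-risk samples, ΔΔCt =
mean(high) − mean(low), fold change = 2^ΔΔCt, two-sided t-test, and
Benjamini–Hochberg step-up q-values.  Three conventions deserve note:

* **Sign convention.** Fold change is 2^(mean_high − mean_low); this is
  the convention that reproduces published tables of this type row for
  row.  Because higher Ct means less template, the package reports ΔΔCt
  and fold change without asserting an abundance direction.
* **t-test variant.** Welch (unequal variances) is the default; the
  pooled variant is available since the original analyses cannot be
  re-derived from deposited data and either may have been used.
* **Family size `m`.** The BH adjustment exposes `m` because a printed
  q-value column can be consistent with a family larger than the
  printed table — e.g. a 13-row table whose ties at a common q-value
  only reconcile with m = 14, one assay (the rejected endogenous
  control) having been tested but never printed.  A unit test
  demonstrates that reconstruction; the default remains
  m = number of tested miRs.

`benjamini_hochberg()` is backed by `stats::p.adjust(method = "BH")`
and is verified in the test suite against an independent brute-force
min-over-suffix evaluation of the step-up formula.

## Feature selection and its stability

Two rankings are implemented: the t-score
(mean difference scaled by the pooled per-class standard errors,
ranked by |t|) and the centroid score (absolute mean difference,
variances ignored).  Ties break by descending score then lexicographic
miR id, so rankings are deterministic.

Stability is quantified by Monte-Carlo cross-validation: 30 stratified
random splits with a held-out third, the ranking recomputed on each
training subset, and for each n ≤ 8 the percentage of splits in which
each miR lands in the top n.  The 30/⅓ defaults reflect the resolution
(multiples of ~3.3%) at which such stability percentages are typically
reported; both knobs and the seed are arguments.  Percentages are
non-decreasing in n by construction, and a fixed seed reproduces the
table bit-exactly.  When the two leading effects are separated by much
less than the between-sample noise (as the published urine shifts are:
3.018 vs 3.014 with the next three within 0.4 cycles), the identity of
the leaders is itself a random variable — the tests therefore assert
leader identity only where the injected separation makes it stable.

## The classifier

The classifier is the primal hinge-loss linear SVM: minimize over
(w, b)

  ½‖w‖² + C · Σᵢ max(0, 1 − yᵢ(w·xᵢ + b)),   C = 1 by default.

The solver is a smoothing homotopy: the hinge is replaced by a Huber
smoothing of width δ, minimized by BFGS, and δ is lowered geometrically
from 1 to 10⁻⁹ with warm starts.  The smoothed objective underestimates
the true one by at most C·n·δ/2, which bounds the final objective gap
far below the 10⁻⁶ contract at panel problem sizes; the test suite
additionally checks agreement within 10⁻⁵ against an independent
convex solver (libsvm) on random instances.  The best-so-far true
objective per stage is recorded (`objective_trace`) and never
increases.

Features are standardized with training-split statistics only; the
center/scale vectors are frozen inside the model and re-applied at
prediction, so no information leaks from evaluation samples.  Features
are matched by name at prediction and a missing feature is a hard
error.

ROC curves are built by a descending-score sweep (ties move as a
block); AUC is the trapezoidal area, which equals the Mann–Whitney
pair-counting statistic, and is tested against exhaustive pair
enumeration.  Cross-validated AUC pools out-of-split decision values
across the Monte-Carlo splits and computes a single ROC — the only
protocol that yields one curve rather than an average of per-split
AUCs.  Whether published AUCs of this study type are cross-validated
or resubstitution is usually unstated; both are computed and reported.

## The synthetic generator

`cohort_spec()` defines ground truth: per-miR baseline Ct in the
low-risk group, a signed additive shift in the high-risk group,
Gaussian biological noise between samples, Gaussian technical noise
within triplicates, and deterministic dropout — any noisy replicate
value above the ceiling is emitted as "Undetermined", exactly as an
instrument does.  Gaussian noise on the Ct scale is the standard model
for ΔCt analyses; dropout-by-thresholding (rather than a separate
Bernoulli) makes dropout interact with the ceiling rule the way a real
run does.  The generator writes the same long-format text dialect the
reader consumes, so the full pipeline is exercised end to end.

Three scenarios pin the study conditions: `discovery_urine` (17/16
samples, 13 miRs, baselines and shifts equal to the published discovery
group means and ΔΔCt values), `validation_flipped` (14/22 samples,
the three validated miRs with the published *negative* shifts, plus a
platform spec with unit slope, +2 cycle offset and 0.5 cycles extra
noise) and `plasma_weak` (33/37 samples, 12 miRs, shifts ≤ 0.5 Ct and
high baselines giving near-ceiling dropout, so the best single miR
reaches only AUC ≈ 0.6).  No within-group variance was ever published
for these fluids; biological_sd = 1.5 and replicate_sd = 0.3 cycles are
plausible defaults for biofluid qPCR, exposed as parameters rather than
asserted as facts.

What the generator does **not** emulate: correlated per-sample loading
offsets (each miR's biological noise is independent), hemolysis or
contamination artefacts, PSA kinetics, or miR–miR correlation
structure.  Passing tests therefore demonstrate correctness of the
algorithms under a clean noise model, not robustness to every artefact
of real biofluid data.  One quantitative consequence of the independent
noise model is worth recording: with biological sd 1.5 and 16/17
samples per group, the standard error of a ΔΔCt estimate is
1.5·√(1/16+1/17) ≈ 0.53 cycles, so a 3.0-cycle injected shift lands
within ±0.5 of its estimate in only about two-thirds of simulated
cohorts — a property of the stated study conditions themselves, which
the acceptance harness measures and reports honestly.

## Problem sizes and numerical choices

The test suite and acceptance script run at the study's own scale
(33–70 samples, 3–13 features, 30 CV splits) and use 20–1000 random
instances for the oracle-equivalence checks, 100 seeds for parameter
recovery and 200 for null error control.  Tolerances: SVM objective
gap 10⁻⁶ (contract) / 10⁻⁵ (oracle agreement), BH and AUC oracle
agreement 10⁻¹², table arithmetic 10⁻³ relative.  Degenerate inputs are
defined rather than left to chance: zero variance in both groups gives
p = 1 with a warning and a t-score of 0 ranked last; a (sample, miR)
cell with no surviving replicate aggregates to the ceiling with a
warning; constant features pass through standardization unscaled with
a warning.

## Limitations

The pipeline validates algorithmic correctness, not clinical utility;
the synthetic cohorts encode the published summary statistics, not
re-sampled patient data, and the original per-sample Ct values were
never deposited, so published p-values, q-values and AUCs can only be
reproduced where they are pure functions of printed summaries (ΔΔCt,
fold change, BH arithmetic) or mirrored qualitatively (CV AUC at
discovery, below-chance transfer after sign reversal).
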