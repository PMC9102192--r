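---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cafcoculture)
```

This vignette documents the statistical and physical models behind each
stage of the pipeline, the tunable parameters with their defaults and
units, the choices made where the original analysis left the design open,
and what the synthetic-data generator does and does not emulate.

## The mRNA-subtype prototype rule

Head and neck squamous cell carcinomas fall into four expression-defined
subtypes — atypical (AT), basal (BA), classical (CL) and mesenchymal (ME).
The classifier is a prototype rule over six marker genes (TP63, EGFR,
SOX2, VIM, DES, NFE2L2) plus two binary covariates (smoking history, p16
status):

1. every feature is z-scored across the cohort,
   $z = (x - \bar{x}) / s$ with the $n-1$ denominator for $s$;
2. each category's score is the mean of its signed z-values
   ("high X" contributes $+z_X$, "low X" contributes $-z_X$):
   BA = high TP63, EGFR / low SOX2; ME = high VIM, DES / low TP63;
   CL = high SOX2, NFE2L2 / smoker; AT = high SOX2 / p16-positive;
3. the patient is attributed to the category with the highest mean.

Design choices that were genuinely open:

* **Encoding of "low".** "Low X" is encoded as sign $-1$ on the
  standardised value; the direction is stated by the rule, the arithmetic
  encoding is ours.
* **Binary covariates.** Smoking and p16 are z-scored exactly like
  expression by default (`standardize_binary = TRUE`), reading
  "standardised expression/smoking/p16 values" as standardising all
  three. Because the sentence admits the other reading, raw 0/1 coding is
  available as a switch; on well-separated synthetic cohorts both recover
  the planted labels.
* **Reference population.** Standardisation uses the analysed cohort
  itself (means/sds over the records passed in), not an external
  reference — the natural choice for a self-contained cohort analysis,
  and the only one possible without a published reference panel.
* **Ties.** Exact or near ties (top two scores within $10^{-12}$) are
  resolved by the fixed priority order AT > BA > CL > ME and flagged with
  `tied = TRUE`. Ties are a measure-zero event for continuous expression;
  the deterministic order exists so that degenerate inputs (e.g. an
  all-zero z-vector) remain reproducible.

The $n-1$ denominator is immaterial for assignment at $n = 55$ (it scales
all z-values of a feature equally) but is fixed for reproducibility.

## Colony-forming-assay quantification

Plates are photographed, registered to a reference image carrying a
manually labelled region of interest, segmented, and summarised as the
fraction of ROI area covered by colonies.

* **Registration** is restricted to integer-pixel translation, found by
  exhaustive normalised cross-correlation of grayscale versions
  (grayscale = channel mean) within a configurable search radius
  (default ±32 px). Ties break to the smallest $|dy|+|dx|$, then
  row-major order. A peak correlation below 0.2 — or a degenerate
  constant overlap — flags "poor registration" but still returns the best
  offset. Sub-pixel shifts and rotation are out of scope.
* **Segmentation** thresholds the raw blue channel with one fixed
  threshold for the whole batch. The threshold is a required
  configuration value: it is plate- and staining-dependent and is not a
  universal constant. Polarity is a switch (`"bright"`/`"dark"`) because
  real stain/background contrast can invert; the synthetic renderer makes
  colonies blue-bright, so `"bright"` with threshold 130 sits midway
  between the background blue level (100) and colony level (160).
* **Area fraction** is computed over ROI pixels only, after translating
  the ROI by the registration offset; ROI pixels shifted out of bounds
  leave the denominator.
* **Colony support.** A coculture is *colony-supporting* when a
  two-sided Welch t-test of treated vs non-cocultured control fractions
  gives $p < 0.05$ *and* the treated mean is larger; *suppressing* is the
  mirrored condition. Two zero-variance groups with equal means return
  $p = 1$ rather than erroring.

## Hertz–Sneddon force-curve fitting

Cell stiffness is estimated from AFM approach curves via the quadratic
Hertz–Sneddon contact law

$$F(\delta) = C(\theta)\,\frac{E}{1-\nu^2}\,\delta^2,$$

with indentation $\delta$ (µm), Young's modulus $E$ (Pa) and force in nN
(Pa·µm² → nN via $10^{-3}$). $C(\theta) = (2/\pi)\tan\theta$ for a cone
and $0.7453\tan\theta$ (Bilodeau) for a four-sided pyramid — the default,
appropriate for pyramidal silicon tips on silicon-nitride cantilevers.
The half angle $\theta$ must come from the probe datasheet; $\nu = 0.5$
(incompressible cell) is the standard convention, config-exposed.

Fitting decomposes into:

1. baseline $F_0$ = median force over the first 20% of the approach;
2. coarse grid of candidate contact points $z_0$ every 2% of the height
   span; at each, $\delta = \max(0, z_0 - h)$ and the modulus follows by
   linear least squares of $F - F_0$ on $\delta^2$;
3. local refinement of $z_0$ between the best grid point's neighbours.

Contact-point handling dominates fit quality and is unspecified by
typical batch-processing descriptions; the grid-plus-refinement scheme is
our choice and inverts noiseless synthetic curves to better than 0.1%.
Non-convergence (not an exception) is declared for fewer than 10
post-contact samples, relative improvement over the baseline-only model
below 1%, or $E$ outside [1 Pa, 1 MPa]. Indentation is computed from
piezo height without cantilever-deflection correction — the exported
curves carry force vs height and no spring constant — a documented
approximation that biases $E$ slightly low for stiff samples. Force maps
(64 × 64 by default) are summarised per cell as the median modulus over
converged masked fits.

## RT-DC event gating

Events are retained iff cell area ∈ [70, 2000] µm² (debris/cluster
removal) **and** porosity ∈ [1.00, 1.05] (damaged-cell removal), both
intervals closed. Exclusions are attributed to the first failing rule
(area, then porosity) so the per-rule counts and the retained count sum
to the input count. Measurements with fewer than 1000 retained events are
flagged. Per-measurement medians of modulus, deformation and area are
averaged across the duplicate measurements of a treatment. The
deformation-to-modulus conversion is *not* implemented: it is a published
lookup performed upstream by the acquisition software, and the modulus
arrives as an input column.

## Comparative Ct

With PSMB2 as the reference gene, $\Delta C_t = C_t^{target} -
C_t^{ref}$ per record; $\Delta\Delta C_t$ subtracts the arithmetic mean
control $\Delta C_t$ of the same gene; the log2 fold change is
$-\Delta\Delta C_t$ and the fold change $2^{-\Delta\Delta C_t}$.
Coculture-vs-control comparisons use a two-sided one-sample t-test of the
log2 fold changes against zero; paired designs use the paired t-test.

## Exact Fisher tests

Contingency tables of subtype/cluster against clinical factors are tested
with an exact conditional r×c Fisher test implemented by recursive
enumeration: all tables with the observed margins are generated cell by
cell with infeasible branches pruned, each receives its multivariate
hypergeometric probability, and the two-sided p-value is the total
probability of tables at most as probable as the observed one. The
probability-mass two-sided definition (with relative slack $10^{-7}$
against floating-point ties) matches the convention of mainstream
statistics environments; other two-sided definitions exist and give
different answers on asymmetric tables. Enumeration is guarded at a table
total of 500; beyond that a seeded Monte-Carlo version samples tables
from the conditional null (Patefield's algorithm) with $10^6$ draws by
default.

## Lactate-gene clustering and survival

Tumour-tissue expression of MCT1, MCT4, CD147, CAV1 and ACTA2 is
clustered into two groups: per-gene z-scoring, Euclidean distance, Ward
linkage (`ward.D2`), tree cut at $k = 2$. The heatmap behind the original
two-cluster split does not state metric, linkage or scaling, so these are
design choices; consequently the original cluster sizes (39/16) are not
an exact target — only the two-cluster contract and the survival
association are. Cluster 1 is deterministically the cluster with lower
mean panel expression, making labels invariant to sample order.

Survival uses the Kaplan–Meier product-limit estimator with the log-rank
test between clusters, and a Cox proportional-hazards model
(partial likelihood, Efron tie handling) with bidirectional stepwise
selection by AIC starting from the full model over cluster, pN, stage,
p16, grade (optional — it is absent from some cohort tables) and smoking.
The stepwise *criterion* is AIC: the strategy (backward and forward) is
named by the original analysis, the criterion is not, and AIC is what the
standard stepwise implementation optimises. Covariates that separate
completely or prevent convergence are flagged and excluded before
selection, which continues without them. No multiple-testing correction
is applied anywhere, matching the original convention of a flat
$p < 0.05$.

## The synthetic-data generator

No raw data are deposited for this study, so every input is emulated with
planted ground truth:

* **Cohort**: subtype-specific marker shifts of ±Δ on the standardised
  scale with Gaussian noise; smoking forced for CL-planted and p16 for
  AT-planted patients (with a small flip probability); clinical factor
  frequencies match the 55-patient cohort (subtype mix 18/11/14/12,
  cluster-2 probability 16/55, 37/55 smokers, 20/55 p16-positive).
  Survival is exponential with the hazard scaled by the planted
  lactate cluster (default hazard ratio 3) and independent uniform
  censoring whose horizon is solved to hit the target censoring fraction.
* **Colony plates**: colonies are filled disks whose blue channel exceeds
  background by a contrast margin (default 60 of 255, so a fixed
  threshold is meaningful); non-reference images are the reference
  content translated by known integer shifts plus pixel noise; true area
  fractions are counted on the rendered mask, not analytically.
* **Force curves**: built from the same forward model the fitter inverts,
  with a baseline region, a uniformly drawn contact point, and additive
  Gaussian force noise (default 0.02 nN against a ~1 nN setpoint-scale
  signal).
* **RT-DC events**: in-gate events drawn inside both gates; contaminants
  violate at least one bound by construction (debris, clusters, damaged
  cells).
* **qPCR plates**: $C_t^{target} = C_t^{ref} + \Delta C_t^{base} -
  \log_2\mathrm{FC} + \varepsilon$, so comparative Ct recovers the
  planted fold change in expectation.

Effect sizes are not reported by the study, so the marker shift default
(Δ = 3 sd, noise 0.5) is chosen for testability: strong enough that a
correct implementation recovers ≥95% of planted labels, weak enough that
order-of-operations mistakes (e.g. standardising before vs after
assignment) are visible. All generators derive their random substreams
deterministically from one master seed and restore the caller's RNG
state, so regeneration is byte-identical.

**What passing tests do and do not show.** The generators are
deliberately simple: Gaussian expression on the standardised scale,
exponential survival, disk-shaped colonies, noise-free gate membership,
and force curves generated by the very model family being fitted. Tests
against this ground truth establish that the *computations* are correct
— not that the models are adequate for real tissue, real plates (uneven
illumination, stain gradients, out-of-focus colonies), real force curves
(adhesion, viscoelasticity, substrate effects) or real cytometry
(correlated gates, drift). Parameter recovery on synthetic data is a
floor, not a ceiling, for real-data difficulty.

## Problem sizes and numerical settings

The test suite and the acceptance script use scaled study dimensions
chosen as representative working sizes: 200-patient cohorts for
classifier recovery, 200 force curves of 300 samples, six 128×128 plate
images, 2000 cytometry events, 300-patient survival simulations, 25/200
seed replicates for the stepwise-selection calibrations and 1000
replicates for the t-test type-I calibration. Tolerances follow the
contracts above: 0.1% noiseless / 5% noisy for modulus recovery, 0.02
mean absolute error for area fractions, $10^{-10}$ agreement between the
Fisher enumeration and a hypergeometric oracle on exhaustive small-table
sweeps.

## Known limitations

* Only integer-translation registration; no rotation, scaling or
  sub-pixel refinement.
* Indentation from piezo height, not tip–sample separation (no
  deflection correction).
* No adhesion or retract-segment analysis; no viscoelastic models.
* The exact Fisher test enumerates; tables with totals beyond 500 need
  the Monte-Carlo path.
* No proportional-hazards diagnostics; stepwise selection inherits the
  usual instability of stepwise procedures on correlated covariates.
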