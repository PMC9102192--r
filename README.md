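# cafcoculture

Analysis pipeline for cancer-associated fibroblast (CAF) coculture
studies in head and neck squamous cell carcinoma (HNSCC).

Tumour progression in HNSCC depends on cooperation between epithelial
cancer cells and the CAFs of the tumour microenvironment — exchange of
lactate through the MCT1/MCT4 transporters and their chaperone CD147,
reprogramming of cancer-cell glycolysis, and modulation of cell
stiffness. Studies of this interplay combine very different computational
steps: expression-based tumour subtyping, quantification of
colony-forming assays from plate photographs, stiffness estimation from
atomic force microscopy (AFM) and real-time deformability cytometry
(RT-DC), relative qPCR quantification, and survival modelling. This
package implements that full computational layer as tested, reusable R
functions, for researchers who want to run, check or extend such
analyses.

## What is implemented

* **mRNA-subtype prototype classifier** — assigns tumours to the
  atypical (AT), basal (BA), classical (CL) or mesenchymal (ME) subtype.
  Features (log2 expression of TP63, EGFR, SOX2, VIM, DES, NFE2L2, plus
  smoking and p16 status) are z-scored over the cohort; each category's
  score is the mean of its signed z-values (e.g. basal = high TP63, high
  EGFR, low SOX2); the patient goes to the arg-max category
  (`classify_subtypes()`).
* **Colony quantification** — integer-translation registration to a
  reference image by normalised cross-correlation, blue-channel
  thresholding with one fixed threshold per batch, ROI area fraction,
  and the Welch-test definition of a *colony-supporting* CAF
  (`quantify_colonies()`, `support_test()`).
* **Hertz–Sneddon AFM fitting** — the contact law
  `F = C(θ) E/(1−ν²) δ²` (cone `C = (2/π)tanθ`; four-sided pyramid
  `C = 0.7453 tanθ`), with baseline estimation and contact-point search
  (`fit_curve()`, `summarize_map()`).
* **RT-DC gating** — closed-interval filters (area 70–2000 µm²,
  porosity 1.00–1.05), minimum-1000-events QC, duplicate averaging
  (`filter_events()`, `summarize_measurement()`).
* **Cohort statistics** — comparative Ct (`ddct()`, reference gene
  PSMB2), one-sample/paired t-tests, Pearson correlation matrices with
  the p < 0.05 asterisk mask, two-cluster Ward clustering of the lactate
  panel MCT1/MCT4/CD147/CAV1/ACTA2 (`cluster_two()`), an exact r×c
  Fisher test by full enumeration (`fisher_exact()`), Kaplan–Meier with
  log-rank (`km_logrank()`), and bidirectional AIC-stepwise Cox
  regression (`cox_stepwise()`).
* **Synthetic-data generator** — every input the pipeline consumes, with
  planted ground truth (subtype labels, colony area fractions and
  shifts, moduli, gate membership, fold changes, survival clusters) and
  byte-identical regeneration under a fixed seed (`sim_config()`,
  `simulate_study()`).
* **Packaged cohort table** — the 55-patient clinico-pathological
  cross-tabulations ship as a plain-text fixture (`hn_cohort_tables()`).

## Worked example

```r
library(cafcoculture)

# a synthetic 55-patient cohort with planted subtypes and clusters
cfg <- sim_config(seed = 42)
sim <- gen_cohort(cfg)

cls <- classify_subtypes(sim$cohort)
print(cls)
#> mRNA subtype classification of 55 patients
#>
#> AT BA CL ME
#> 23  8 14 10
mean(cls$label == sim$truth$subtype)
#> [1] 1

# the packaged cohort table: nodal stage vs subtype, exact Fisher test
t1 <- hn_cohort_tables()
fisher_exact(t1$subtype$pN)
#> Fisher exact test (exact): two-sided p = 0.0305874  (n = 55)

long <- cohort_table_long(t1$subtype$p16)
crosstab(long$label, long$level)
#>            AT         BA         CL         ME
#>   p16 neg. 0 (0.0%)   10 (28.6%) 14 (40.0%) 11 (31.4%)
#>   p16 pos. 18 (90.0%) 1 (5.0%)   0 (0.0%)   1 (5.0%)

# AFM: 200 synthetic curves at a true modulus of 1000 Pa, 0.02 nN noise
m <- indenter_model("four_sided_pyramid", half_angle = 35)
fits <- fit_curves(gen_force_curves(cfg)$curves, m)
median(fits$E[fits$converged])
#> [1] 998.5903

# lactate-gene clustering and stepwise Cox survival selection
d <- sim$cohort
d$cluster <- factor(cluster_two(sim$cohort[LACTATE_PANEL]))
cox_stepwise(d, c("cluster", "pN", "stage", "p16", "smoking"))
#> Stepwise Cox model (Efron ties, AIC both directions): 44 events
#>   retained: cluster, p16
#>     cluster2           HR 4.649 (95% CI 2.302-9.387), p = 1.822e-05
#>     p16                HR 0.559 (95% CI 0.285-1.097), p = 0.09071
```

Reading the output: the classifier recovers every planted label at the
default (strong) marker effect; the nodal-stage-by-subtype table is
significant at p ≈ 0.031 while p16 concentrates in the atypical column
(90% of p16-positive tumours); the batch fit recovers the planted
1000 Pa modulus to 0.14%; and stepwise selection keeps the planted
lactate-gene cluster as a survival predictor (the true simulated hazard
ratio is 3; n = 55 gives a wide confidence interval around it).

## Documentation

The methods vignette (`vignettes/cafcoculture-methods.Rmd`) describes
the models and their assumptions, all tunable parameters with units and
defaults, the design decisions taken where the original analysis was
underspecified, what the synthetic generator does and does not emulate,
and known limitations.
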