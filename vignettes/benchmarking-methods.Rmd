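---
title: "Benchmarking cell-level PD-L1 scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking cell-level PD-L1 scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdl1bench)
library(dplyr)
```

## The problem

PD-L1 immunohistochemistry is scored in the clinic as the tumor proportion
score (TPS): the percentage of viable tumor cells showing membranous PD-L1
staining among all viable tumor cells. TPS gates immunotherapy eligibility
at the clinical cutoffs <1%, 1-49% and >=50%, yet visual TPS estimation is
known to vary substantially between pathologists. Evaluating an automated
PD-L1 cell detector therefore requires two layers of analysis:

* **cell level** — does the detector place and classify individual cells
  (PD-L1 negative tumor, PD-L1 positive tumor, other) as well as a human
  annotator would, measured against each reader of a panel; and
* **slide level** — does the TPS computed from its detections agree with
  the panel's visual estimates as well as the readers agree among
  themselves.

This package implements that benchmarking battery as reusable, tested
components, together with a synthetic multi-reader study generator so every
statistic can be exercised, end to end, against known ground truth and
closed-form expectations.

## Hit-criterion matching

Two point sets on the same ROI are compared with a distance-gated matching:
a prediction can hit a reference cell only within a fixed radius (default
8 um, the typical tumor/immune nucleus diameter), and where several
predictions fall inside the radius only the closest one takes the hit. A
distance exactly equal to the radius counts as a hit.

`match_points()` realizes this as a symmetric, global-greedy, one-to-one
matching: all in-radius pairs are sorted by ascending distance and accepted
when neither member is already matched. Ties in distance are broken by the
(reference, prediction) ranks after sorting each set lexicographically by
(y, x), which makes the result deterministic and independent of input row
order; for continuous coordinates exact ties have probability zero and the
matching is also direction-free. The one-sided variant in which each
reference simply takes its closest in-radius prediction (predictions
reusable) is available as `mode = "reference"` for sensitivity analysis —
the hit rule is stated from the reference side in clinical practice and
does not by itself force one-to-one-ness, so we expose both readings and
default to the symmetric one because pairwise agreement between two readers
is a single number with no privileged direction.

Matched pairs, unmatched references and unmatched predictions feed a 4x4
confusion matrix over the three cell classes plus a `background` sentinel:
an unmatched reference is a (class, background) count — a cell one source
saw and the other did not — and an unmatched prediction a (background,
class) count. `background_disagreement_fraction()` reports the share of
all disagreements that are such presence/absence disagreements rather than
class confusions; it is flagged `NA` (never 0) when there are no
disagreements at all.

## Cell-level F1

For each class, `f1_from_confusions()` pools TP/FP/FN by summation across
ROIs before forming ratios, then computes

F1 = 2 TP / (2 TP + FP + FN),

the harmonic mean of precision and recall. The macro F1 averages the
per-class values; classes absent from both sources everywhere are excluded
from the macro mean (and flagged), not counted as zero, so an ROI without
positive tumor cells does not spuriously penalize a detector. The
alternative pooling order — macro F1 per case, then averaged across cases —
is available through `pairwise_f1(mode = "per_case")`; the two orders
genuinely differ and the test suite pins each to a fixture where they
disagree. We default to full pooling, which weights every cell equally
rather than every case.

`pairwise_f1()` assembles the symmetric matrix of macro F1 over all source
pairs (readers and detector), and `summarize_groups()` reports
reader-reader versus reader-AI group means with the 95% interval formed as
mean ± 1.96 SD, gated on a Shapiro-Wilk normality test at the 0.05 level;
non-normal groups are reported with median and range and flagged.

## Slide-level agreement battery

`compute_tps()` forms TPS from detection counts (other cells ignored by
construction) and refuses to score a record with no tumor cells — an
undefined TPS is a QC signal, not a zero. `discretize_tps()` maps TPS onto
the clinical bands with [1, 50) as the middle band, so 1.0 is "1-49%" and
50.0 is ">=50%".

Agreement is then measured four ways (`tps_agreement_report()` bundles
them):

* **Linear weighted Cohen's kappa** over the three ordered bands, weights
  `1 - |i-j|/(k-1)`, chance agreement from marginal products. With two
  categories the weights reduce to 0/1 and the statistic is plain Cohen's
  kappa, which is how the per-cutoff kappas at 1% and 50% are computed. A
  cutoff table with every case on the same side for both raters is
  reported as flagged `NA` — vacuous, not perfect, agreement.
* **ICC(2,1)** — single-rater intraclass correlation from the two-way
  random-effects ANOVA with absolute agreement,
  `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`. Its confidence
  interval is the F-based interval for this estimator (McGraw & Wong)
  rather than a 1.96-SD interval: the SD rule applies to means of kappas or
  F1 values across pairs, not to a single variance-component estimator.
  Both the mean pairwise ICC per group and the joint panel ICC are
  reported.
* **Bland-Altman** — mean difference and 1.96-SD limits of agreement
  between the detector TPS and the median reader TPS per case.
* **Majority vote** — each source's binary kappa against the majority of
  the human readers at each cutoff, always excluding the source's own
  rating from its reference. Tied majorities (possible with even voter
  counts) are excluded and counted by default; `tie = "higher"` breaks
  them toward the positive category instead. The tie rule is a genuine
  design choice with no field convention; exclusion was chosen because an
  evenly split panel expresses no opinion for that case.

Missing readings drop a case pairwise, never panel-wide.

## Semi-automatic annotation

The two-step annotation pipeline decouples localization from
classification: a class-agnostic nucleus detector proposes centers, and
free-hand polygons drawn over regions of homogeneous cell type transfer
their label to every detected center inside them
(`label_points_by_polygons()`). Points inside no polygon are discarded —
the annotator did not vouch for them; whether such points should instead
become "other" cells is configurable territory, and discarding is the
default because an unenclosed detection carries no class information.
Points inside several polygons take the label of the smallest-area polygon
(annotators refine inside larger regions); a strict mode errors instead.
Point-in-polygon uses the even-odd rule with boundary points counting as
inside.

The detector itself (`detect_nuclei()`) is a deliberately classical
operator: Ruifrok-Johnston-style color deconvolution into hematoxylin and
DAB optical densities (`separate_stains()`), then scale-normalized
Laplacian-of-Gaussian blob detection on the hematoxylin map over scales
covering 3-10 um nucleus diameters, with non-maximum suppression at 4 um.
It is a simple, reproducible stand-in that makes the annotation pipeline
runnable and testable; each lobe of a multinucleated cell is detected
separately, and no attempt is made to model nucleus shape.

Detectors trained with bounding boxes use the 20 x 20 um convention:
`points_to_boxes()` inflates point annotations to boxes for training,
`boxes_to_points()` takes box centers as detection locations, and the two
are exact mutual inverses on centers.

## The synthetic study generator

Because multi-reader clinical annotations are not generally shareable, the
package ships a generator that emulates the *structure* of such a study:

* `generate_tissue_roi()` draws a hard-core point pattern (uniform
  proposals, rejection within `d_min`, bounded attempts with an explicit
  infeasibility error) with Poisson cell counts per class and a
  configurable tumor positivity fraction. The default `d_min` of 6 um
  keeps distinct cells distinguishable under the 8 um matching radius.
  Optional rendering paints hematoxylin-toned Gaussian nuclei and
  DAB-toned membrane rings on positive tumor cells through the Beer-Lambert
  law with the same stain vectors used for unmixing, so stain separation
  is a left inverse of rendering by construction.
* `simulate_reader()` applies a `reader_model()` — per-class miss rates, a
  row-stochastic class confusion matrix, isotropic Gaussian localization
  jitter (clipped to the ROI so the miss rate is governed solely by the
  miss parameter), and spurious Poisson extras. Randomness is drawn in a
  fixed documented order per cell, so output is reproducible across
  platforms from one integer seed.
* `simulate_tps_panel()` produces visual TPS estimates: truth plus
  Gaussian reader noise, clipped to [0, 100] and rounded to 5% increments
  (half away from zero — visual estimates are not banker's-rounded).
* `expected_recall_under_jitter()` gives the closed-form Rayleigh matched
  fraction `1 - exp(-r^2 / (2 sigma^2))` used as an independent oracle on
  the simulator-plus-matcher path.

The generator emulates point-pattern geometry, reader noise structure and
panel composition. It does **not** emulate tissue texture, staining
variability across centers and antibodies, nucleus morphology, or the
spatial correlation of reader errors (a real reader misses faint cells,
not random ones). Passing tests therefore certify the *statistical
machinery* — matching, F1, kappa, ICC, Bland-Altman, majority voting — on
data of known structure; they are not evidence about detector performance
on real slides.

### Default study conditions

The default configuration (`default_config()`) fixes one set of synthetic
study conditions, chosen once as plausible for NSCLC PD-L1 fields of this
kind and then left alone: a cell-level panel of 10 cases x 2 ROIs of
150 x 150 um at 0.5 um/px, tumor density 2500/mm2, other-cell density
1500/mm2, positivity 0.3; three readers (miss 5%, 90%-diagonal confusion,
1.5 um jitter, 50 extras/mm2) and a simulated detector (miss 10%,
85%-diagonal, 0.8 um jitter, 100 extras/mm2 — localizing better but
classifying worse than a human, the pattern reported for detectors of this
kind); a slide-level panel of 100 cases x 6 readers with 10% visual-noise
SD rounded to 5% increments, and a detector TPS with a -4.7% systematic
bias (the documented direction and size of detector-vs-reader TPS offset
for this task) and 8% SD, left unrounded because a detector computes a
continuous ratio. Reader noise magnitudes are testing conditions, not
estimates of any particular reader panel.

## Numerical choices

* Coordinates are continuous micrometers, origin at the ROI top-left, x
  rightward, y downward; pixel (i, j) centers at ((j-0.5)s, (i-0.5)s) for
  spacing s.
* Matching boundary: distance equal to the radius is a hit (<=).
* Rounding to increments is half-away-from-zero.
* Degenerate inputs are flagged, never silently coerced: zero tumor cells
  (TPS), zero disagreements (background fraction), degenerate marginals
  (kappa), zero between-case variance (ICC), infeasible packing
  (generator).
* All simulation entry points take one explicit integer seed;
  `run_pipeline()` derives per-stage sub-seeds from the master seed, and
  identical (config, seed) runs are byte-identical on disk.

## Problem sizes

The shipped tests run the matching oracle on 1,000 random instances of up
to 10 points per side, the jitter-recall check on a single ~10,000-cell
pattern at four jitter levels, the F1 enumeration oracle on 500 random
confusion matrices, kappa/ICC asymptotics at n = 10,000 and n = 1,000, and
the full pipeline at 2 cases x 1 ROI plus a 30-case TPS panel; these sizes
give stable Monte-Carlo comparisons at three standard errors while keeping
the suite quick on a single CPU.

## Limitations

* The nucleus detector is a classical stand-in; its near-perfect scores on
  rendered blobs say nothing about CNN-grade performance on real IHC.
* The reader model treats errors as independent across cells and readers;
  real disagreement is spatially and perceptually structured.
* The agreement battery assumes a complete or pairwise-completable panel;
  designs where reader groups annotate disjoint case subsets are handled
  only through the pairwise drops.
* F1 pooling granularity (fully pooled vs per-case) is a reporting choice;
  both are implemented and neither is asserted as *the* convention.
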