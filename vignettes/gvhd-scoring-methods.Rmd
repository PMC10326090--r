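---
title: "Methods: multi-observer scoring of colonic acute GvHD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-observer scoring of colonic acute GvHD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvhdscore)
```

## The scoring problem

Acute graft-versus-host disease (aGvHD) of the colon is diagnosed on
biopsies, where the cardinal lesion is the crypt apoptotic body (CAB):
apoptotic debris in the crypt epithelium, counted per 10 contiguous crypts
in the most affected area. Around the CAB count sit a handful of ordinal
morphology parameters — crypt destruction and crypt loss (0 = none, 1 =
individual non-contiguous crypts, 2 = two or more neighbouring crypts),
epithelial denudation, architectural distortion, and increased eosinophilic
or neutrophilic granulocytes (at least 5 per high-power field), each coded
absent/present. Several pathologists score the same slides; the analytical
questions are (i) how well the observers agree, (ii) how the morphology
maps onto established grading systems and simpler additive scores, and
(iii) how either relates to ordinal clinical outcomes.

`gvhdscore` implements that workflow end to end on plain CSV tables: one
row per (biopsy, rater) for the morphology and one row per biopsy for the
clinical outcomes.

## Panel means and the CAB score

All multi-observer summaries are arithmetic means over the raters that
scored a field (field-wise deletion of missing ratings, so the effective
`n` may vary by parameter). The mean CAB count is binned into the CAB
score: 0 below one apoptotic body per 10 crypts, 1 for 1 to below 5, 2 for
5 to below 10, 3 for 10 or more. The bottom bin edge is a genuine design
choice: the verbal definition of bin 0 is "no apoptosis", but four-rater
means are fractional, so we read "no" as *below one apoptotic body per 10
crypts* — which keeps the bins exhaustive for fractional means and
coincides with the empirical observation that counts under 1 per 10 crypts
behave clinically like negative biopsies.

## Grading systems

Four grading systems are computed from morphology alone — deliberately
without clinical input, so that a grade can never leak outcome information
into an association analysis:

* **Lerner (adapted)** — 0 no findings; 1 CAB only; 2 crypt destruction;
  3 focal crypt loss; 4 diffuse crypt loss or epithelial denudation. The
  focal/diffuse split is "below versus at least half of the mucosa
  involved"; when no extent fraction is recorded we use crypt-loss score 1
  as the focal proxy and score 2 (contiguous loss) as the diffuse proxy.
* **Sale and Melson (adapted)** — 0 none; 1 CAB only; 2 destruction *or*
  loss of individual crypts; 3 contiguous destruction or loss; 4
  denudation. The two systems share this adapted skeleton and differ only
  in their descriptive labels, so they are numerically identical here; we
  keep both columns because users compare against both literatures.
* **NIH category** — no (0) / possible (1) / likely (2) GvHD, based on
  histology alone: likely when the CAB score reaches bin 2 or any
  destructive change is present; possible when apoptosis is present but
  sparse; no when there is neither. Any positive CAB count below bin 1
  counts as "possible", which makes "NIH = no" exactly equivalent to
  "Lerner = 0".

Every rule is implemented as "highest grade whose trigger fires", which
makes monotonicity in each component a structural property rather than an
accident; the test suite sweeps every single-component increment over the
full component grid to confirm it.

## Sum scores

Three additive severity scores are built from panel means: sum score 1 is
the CAB score plus the mean crypt-loss score (range 0–5); sum score 2 adds
the mean crypt destruction and epithelial denudation (0–8); sum score 3
adds the mean architectural distortion and both granulocyte indicators
(0–11). Because they add fractional means instead of forcing a qualitative
grade, they lose less information and are less sensitive to single-rater
disagreement. A one-rater "panel" is a legitimate input (the single-
pathologist validation-style use), in which case means reduce to that
rater's values.

## Agreement statistics

* **Consensus rule** — a biopsy reaches consensus on a parameter when the
  modal rating covers at least 75% of the non-missing raters; with four
  raters that is "at least 3 of 4". Semi-quantitative parameters are
  dichotomized (0 absent, 1–2 present) before the consensus rate is
  reported, matching the usual reporting convention; kappa and ICC use the
  raw codes.
* **Fleiss kappa** — the classical multi-rater chance-corrected agreement
  for categorical ratings, applied to every morphology parameter (all have
  at most 5 levels). The estimator assumes a constant number of raters per
  subject; biopsies with missing raters are dropped from the kappa
  computation and their number is reported. This drop rule is our decision
  (the simplest faithful reading of the estimator), not a claim about how
  any particular study handled it.
* **ICC(A,1)** — the two-way, absolute-agreement, single-measure
  intraclass correlation, computed from the subject/rater/residual mean
  squares; systematic rater offsets lower it, which is the point of the
  agreement (rather than consistency) definition. Subjects with missing
  cells are removed listwise.
* **CAB counts** — being (half-)continuous, they get no consensus rate or
  kappa; their reliability is summarised by ICC(A,1) and the pairwise
  Spearman matrix between raters.

Undefined statistics (all ratings in one category; zero variance) return
`NA` sentinels with an attached reason, never a silent zero.

## Association with clinical outcomes

Clinical severity enters as ordinal grades: the overall Glucksberg grade
and the lower-GI GvHD stage (each 0–4, collapsed to none / low-grade (1–2)
/ high-grade (3–4)), steroid response (not applied / responsive /
refractory / intolerant) and survival (alive / non-relapse mortality /
relapse mortality). For each histological measure we report per-group
medians and ranges, a Kruskal-Wallis test across groups, and two-sided
Mann-Whitney tests of each group against its reference (grade 0 groups,
"not applied", "alive"). The Mann-Whitney implementation uses the
tie-corrected normal approximation without continuity correction, switching
to exact enumeration when both groups have at most 8 tie-free
observations. Stars (0.05/0.01/0.001) are attached to the raw p-values; a
Bonferroni-adjusted column is emitted alongside, because no correction
convention is universal in this literature and readers should see both.
"Intolerant" steroid cases are retained in the data model but excluded
from the summary table, which compares not-applied, responsive and
refractory only.

Cross-tabulations use the Pearson chi-square test with per-cell post-hoc
adjusted standardized residuals, `z = (O - E) / sqrt(E (1 - r/N)(1 -
c/N))`, converted to two-sided normal p-values and Bonferroni-adjusted
across the cells of the table. The CAB cut-off sweep applies this to the
2x2 tables formed by "mean CAB below versus at or above c" for c in
0.5, 1, 2, 3, 5, 6, 7 against five dichotomized outcomes (any GvHD and
high-grade GvHD by Glucksberg, any lower-GI stage, death, and
refractoriness among steroid-treated-or-untreated cases); cut-offs that
leave one side of a split empty are flagged and skipped rather than
tested.

## The synthetic cohort generator

No patient-level data ship with the package; every analysis stage is
exercised on a generator whose structure mirrors what the analysis
presumes. Each biopsy draws a latent severity class — none / low / high
with default weights 0.10 / 0.40 / 0.50 — which drives everything else:

* **CAB counts** are negative-binomial (dispersion 1.5) with class means
  0.5 / 4 / 8 per 10 crypts. The over-dispersion produces the long right
  tails (occasional counts in the 20s and 30s) seen in real cohorts, where
  printed ranges run from 0 to above 30.
* **Ordinal morphology** comes from class-conditional emission tables
  (e.g. contiguous crypt loss has probability 0 / 0.10 / 0.50 across the
  classes).
* **Rater noise** is a single knob per parameter: with probability `p`
  (default 0.15) a rater mis-scores by one level in a uniform direction,
  clamped at the scale ends; CAB counts get multiplicative log-normal
  noise (sd 0.25 on the log scale) and are recorded on a half-unit grid.
* **Clinical outcomes** follow an ordered logit on the severity score
  (0/1/2): `P(Y <= j) = plogis(cut_j - beta * severity)` with default
  slope 4 and intercepts chosen so that about 8% of biopsies land in
  clinical grade 0 with very low CAB counts, roughly 40% in low-grade and
  50% in high-grade — the subgroup structure of published Round-Robin
  cohorts. Steroid response and survival are drawn from class-conditional
  category probabilities. Setting the slope to 0 severs the
  histology–clinic link entirely, which is how the null calibration of the
  group tests is run.
* **Missingness** removes 2% of rating cells at random, reproducing the
  "n varies by a few biopsies per parameter" texture of real tables.

Clinical outcomes are conditionally independent of rater noise given the
truth: the histology–clinical association flows only through latent
severity. That is exactly the structure the association analysis assumes,
so passing tests demonstrate internal consistency of the pipeline — they do
*not* demonstrate that real biopsies follow this generative model. Known
departures from real data: the generator has no per-patient clustering of
repeated biopsies, no site effects between centres, rater noise is
symmetric and independent across parameters (real pathologists disagree
systematically), and the negative-binomial tail occasionally places a
high-CAB biopsy inside clinical grade 0, which printed cohort tables
suggest is rarer than our mixture makes it.

`calibrate_agreement()` inverts the noise knob: given a target Fleiss
kappa it bisects over the mis-scoring probability, estimating the expected
kappa at each level from at least 50 simulated cohorts with common random
numbers (which keeps the estimated kappa-versus-noise curve monotone), and
stops when the expected kappa is within 0.05 of the target. Targets above
the no-noise ceiling of a parameter's emission distribution fail loudly
with the achievable range.

## Numerical and design choices

* Ordinal codes are stored as plain small integers; labels are metadata.
* Means use field-wise deletion; kappa drops incomplete subjects; ICC uses
  listwise deletion — each statistic follows the convention of its own
  literature, and the reports record the `n` actually used.
* Ties in rank statistics use average ranks (`stats::cor`,
  `stats::wilcox.test` and `stats::kruskal.test` handle the corrections).
* A consensus tie (no modal value reaching the threshold) is "no
  consensus", never a tie-broken value; thresholds are restricted to
  (0.5, 1], so at most one value can qualify.
* Degenerate inputs return reasoned sentinels (`sentinel_reason()`), and
  degenerate cut-off splits are flagged, not tested.
* CSV reading is all-or-nothing on the header but row-tolerant on cells:
  range-violating cells become missing values and are reported with line
  numbers, so one typo does not discard a cohort.

## Problem sizes used in the shipped checks

The test-suite calibration checks use cohorts of 100–123 biopsies with 4
raters: 1000 null replicates for the type-I error of the Mann-Whitney
comparison (binomial 95% band around 0.05), 200 replicates each for power
(observed around 0.87–0.89 against the none-versus-any-GvHD contrast) and
for kappa-target recovery at 0.4 / 0.6 / 0.8 (recovered within 0.05).
These sizes give Monte-Carlo standard errors comfortably below the margins
being asserted while keeping the default check run quick on a laptop.

## Limitations

The grading-rule tables reconstruct adapted systems from their published
skeletons; laboratories using different adaptations can swap the rule
functions without touching the agreement or association machinery. The
association module treats biopsies as independent — repeated biopsies per
patient need patient-level aggregation upstream. Survival is categorical
(alive / NRM / RM), not time-to-event; no hazard modelling is attempted.
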