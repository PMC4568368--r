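---
title: "Design-based stereology for wound healing: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology for wound healing: models, estimators, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereowound)
```

## The problem

Experimental wound-healing studies in rodents quantify repair along two
axes: macroscopically, how fast the wound surface contracts; and
microscopically, how much new tissue has been laid down in the dermis —
fibroblast numbers, collagen content, and vascularization. Design-based
stereology provides unbiased estimators for all of these from 2D sections
and photographs, without reconstructing the tissue in 3D. `stereowound`
implements the complete estimation chain and, because raw histological
counts from such studies are rarely published, a synthetic 3D dermis
generator with known ground truth against which every estimator is
validated by parameter recovery.

## Estimators

**Wound area.** A point grid with spacing $d$ (mm) and a uniform random
offset is laid over the wound photograph;
$\hat{A} = \sum P \cdot a/p$ with $a/p = d^2$. Systematic uniform random
offsets make this estimator exactly unbiased for any measurable region;
`estimate_area()` and `count_points_on_mask()` implement it over binary
masks.

**Closure rate.** Closure at visit $t$ is
$100\,(A_0 - A_t)/A_0$ per cent; negative values (the wound grew, common
in untreated wounds during early inflammation) are kept deliberately.
Published "%/day" figures rarely state the averaging convention, so
`closure_rate_per_day()` implements two: final closure divided by elapsed
days (default) and the OLS slope of closure against day. The two agree
exactly on linear profiles, which the tests assert; neither is claimed to
be the convention behind any particular published figure.

**Volume density.** $V_V = \sum P_\text{phase} / \sum P_\text{dermis}$,
pooled across fields as a ratio of sums. A mean of per-field ratios would
weight small fields as heavily as large ones and is biased; ratio-of-sums
pooling within animal is standard practice and makes estimates invariant
under replication of the field list.

**Numerical density.** The optical dissector counts nuclei coming into
focus inside an unbiased counting frame (left/bottom edges include,
right/top exclude) within a height $h$ after discarding guard zones:
$N_V = \sum Q / (\sum A \cdot h)$. Dividing by the probed volume
$\sum A \cdot h$ is the only dimensionally coherent form of the
estimator — counts per area *times* height would carry units of
cells·length/area. Defaults are 15 µm sections with 5 µm guards top and
bottom, i.e. $h = 5$ µm.

**Length density.** Vessels are curves; on isotropic uniform random (IUR)
sections the expected number of transects per unit area is $L_V/2$, so
$L_V = 2 Q_A$. This estimator is only valid because the synthetic
sectioner honours IUR orientations (one uniform-on-the-sphere normal per
tissue block, drawn by Marsaglia's method); on preferentially oriented
sections it would be biased by up to a factor of 2.

**Vessel diameter.** Each transect of a (locally) cylindrical vessel is
an ellipse whose *minor* axis equals the true diameter at any sectioning
angle; the package records and averages minor axes, making the mean
diameter angle-independent. Profile sampling is transect-weighted
(probability $\propto$ projected height), which is independent of radius
when radius and orientation are independent, as in the generator.

## The synthetic dermis

`simulate_volume()` realizes one tissue block from `tissue_params()`:

- **fibroblast nuclei**: homogeneous Poisson points at `nv_fibroblast`
  (default 284.5×10³ cells/mm³, an untreated diabetic-dermis scale);
- **collagen bundles**: a Boolean model of 12 µm spheres;
- **hair follicles**: a Boolean model of 25 µm spheres;
- **vessels**: isotropic uniform random segments (capsules) of uniform
  length 50–200 µm, radius from a normal truncated at zero
  (default 11.7 ± 3.1 µm diameter), with expected centerline length per
  unit volume equal to `lv_vessel` (default 17.2 mm/mm³).

Three numerical choices matter:

- **Plus-sampling.** Grains and segments are generated in a guard band
  one grain radius (or half segment length plus a radius allowance)
  beyond the block, so interior intersection densities are free of
  boundary depletion.
- **Phase precedence.** Overlapping phases are resolved as
  vessel > hair > collagen > ground everywhere (rendering and oracles
  alike), so the phases are mutually exclusive fractions of dermis as the
  estimators assume. Because an independent Boolean phase would lose
  exactly the overlapped fraction, grain intensities are solved on the
  precedence-adjusted scale (using the Boolean vacancy probability
  $p = 1 - e^{-\lambda \bar v}$), so realized fractions equal the
  requested `vv_*` in expectation; without this, collagen at control
  scale would read ~4 points low.
- **Infeasible mixtures** (total solid fraction reaching 1) are rejected
  at construction.

Grain shapes are deliberately simple: only volume fractions, lengths and
diameters enter the estimators, so sphere/capsule grains validate the
estimation chain without pretending to be histology. The generator does
not emulate staining variation, section compression or deformation,
anisotropic vessel trees, or spatial clustering of cells — passing
recovery tests therefore demonstrates correctness of the estimators under
the model's assumptions (stationarity, isotropy, cylindrical vessels),
not robustness to every artefact of real material.

## Sectioning and field sampling

`simulate_animal()` emulates the laboratory workflow: the sample is cut
into `n_blocks` blocks (default 9, matching systematic random sampling of
nine ~1 mm² pieces), each block receives its own IUR orientation and
`section_stack()` places disjoint parallel slabs at systematic uniform
random positions; `render_field_counts()` then drops counting frames
(default 200 × 200 µm) at uniform random in-plane positions constrained
so the whole frame-by-thickness prism stays inside the block at any
orientation, throws the point grid (default 20 µm spacing) with a fresh
SUR offset per field, and records exactly what a microscopist would:
per-phase point counts, dissector counts under the unbiased-frame rule,
and vessel transects with minor-axis diameters on the central focal
plane.

Fields per animal default to 30, a typical counting effort. For the
*validation cohort* (the recovery tests and the acceptance script) we use
108 fields spread over 36 blocks of 0.5 mm side at 4 sections each. The
driving consideration is counting statistics for the rarest event: at
control-scale $L_V$ a 200 µm frame expects only ~0.3 vessel transects,
and within one block all sections share one orientation, so per-block
transect counts are strongly correlated. Spreading the same number of
fields over more independently oriented blocks is the standard
stereological remedy (count more, smaller, independent samples), and
brings the Monte-Carlo standard error of the 100-animal cohort mean to
about 2%, so the ±5% recovery band tests estimator bias rather than
sectioning noise. These are sampling-effort choices for the validation
design; the tissue parameters, group sizes, and noise levels are the
study conditions themselves and are never adjusted.

## Wound timecourse generator

`simulate_wound_series()` draws day-0 areas from a normal distribution
(default 103.53 ± 7.11 mm², truncated positive) on the visit grid
0, 3, …, 15 days, with additive measurement noise (default 4 mm²) and
clipping at zero (flagged). The expected relative area is piecewise
exponential: untreated profiles rise ~20% until day 3 — the early
inflammatory enlargement — then decay; treated profiles decay from day 0.
Default decay rates place the untreated arms near 4.4 and 4.9 %/day under
the final/elapsed convention and carry the treated arms to ~95–98%
closure by day 15 (the study design ends when the first wound closes).
The treated arms' published per-day rates cannot be reproduced by any
closure-over-elapsed-time convention (8.61 %/day × 15 days exceeds 100%),
which is why the package exposes both conventions and asserts only
closed-form and ordering behaviour.

## Group statistics

The animal — never the field or section — is the statistical unit; fields
are pooled within animal upstream. `compare_groups()` runs the
Kruskal-Wallis omnibus test and pairwise Mann-Whitney U tests at
α = 0.05. The Mann-Whitney p-value is computed by full permutation
enumeration whenever the combined sample size is ≤ 12 (exact even under
ties, which the usual closed form is not), and by the tie-corrected
normal approximation with continuity correction otherwise. Two-sided
p-values are the default; no multiple-testing correction is applied by
default (a `p_adjust = "holm"` option exists), matching common practice
in this literature — users performing many pairwise contrasts should turn
it on. SDs use the sample (n − 1) convention; single-animal groups report
SD = 0 and are flagged.

Percent differences between group means are reported at full precision by
`percent_difference()`; the two-decimal column of
`percent_difference_table()` *truncates* rather than rounds, because
published tables of this design truncate, and reproducing a printed
contrast from printed means requires matching that convention. The
package ships the reference group-mean table of the four-arm diabetic-rat
study its defaults emulate (`reference_group_summaries()`); applying
`percent_difference_table()` to it reproduces all eight published
fibroblast and collagen contrasts to two decimals, which the test suite
asserts.

## Degenerate inputs and tie-breaks

- Zero reference (dermis) points, empty diameter pools, zero frame area,
  and mixed dissector heights are hard errors, not silent zeros.
- All-tied Kruskal-Wallis data yields H = 0 (the tie-corrected formula is
  0/0 in `kruskal.test`; the package returns the defined limit).
- Counting-frame membership is half-open (`[lo, hi)`) in all three axes,
  so a nucleus on an inclusion edge is counted exactly once in a tiling
  of frames.
- Grid points are classified at exact 3D positions; ties with grain
  boundaries (measure zero) resolve by `<=` on the squared distance.

## Problem sizes used in the automated checks

Chosen to resolve each property's Monte-Carlo error well inside its
acceptance band: 100 synthetic animals (36 blocks × 3 fields each) for
estimator recovery; 200 seeds for the segment-length calibration and 25
for the Boolean-model calibration at 0.3 mm extent with a uniform-point
volume-fraction oracle; 1000 grid offsets over a 0.02 mm/pixel rasterized
disk for area unbiasedness; 2000 null simulations for the Kruskal-Wallis
type-I rate; full enumeration for every Mann-Whitney split with combined
n ≤ 8.

## Worked example

```{r example, eval = FALSE}
library(stereowound)

# one synthetic animal at control-scale truth
params <- tissue_params(seed = 1)
fields <- simulate_animal(params, n_fields = 60, group = "control")
summarize_animals(fields)

# wound closure timecourse for the four default arms
series <- simulate_wound_study(seed = 1)
closure <- group_closure_table(series)
autoplot(closure)

# published-style group report from per-animal estimates
cohort <- simulate_cohort(n_animals = 4, n_fields = 24, seed = 1)
report <- table1_report(summarize_animals(cohort$fields))
report
```

## Known limitations

- The generator validates estimators, not biology: no diabetes
  physiology, no staining simulation, no image segmentation (wound masks
  are assumed given, with an external mm-per-pixel calibration).
- $L_V = 2 Q_A$ presumes IUR sections; applying the estimator to
  preferentially oriented material will bias it.
- The per-day closure-rate conventions are conventions; with only
  endpoint summaries published, neither can be singled out as the one
  behind any given published rate.
- No coefficient-of-error machinery beyond plain SD across animals is
  provided, and no surface-density or fractionator estimators.
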