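---
title: "CT ventilation and perfusion biomarkers with pathology concordance: methods"
author: "lungfx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT ventilation and perfusion biomarkers with pathology concordance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lungfx)
```

# Scope

`lungfx` implements the image-analysis side of a regional radiotherapy
response study in the lung: voxel-wise ventilation estimation from
multi-phase breathing CT, perfusion summaries from dynamic
contrast-enhanced CT, construction of the nine standard analysis contours
(dose level crossed with vessel-tree topology plus ventilation-selected
points), and the tabulation of biomarker change classes against ordinal
histopathology findings. Because the underlying animal scans are not
public, the package pairs two data sources with identical schemas: a
synthetic-study generator with closed-form ground truth for every stage,
and the packaged per-subject, per-contour findings tables of the porcine
validation study the thresholds derive from.

# Ventilation model

## LER-N

Each breathing phase is registered to the end-exhale phase, giving a
displacement field $u$ on the exhale grid with the convention that the
phase volume sampled at $x + u(x)$ reproduces the exhale volume. The
Jacobian determinant

$$J(x) = \det\!\left(I + \nabla u(x)\right)$$

is the local volume-change factor of that phase relative to exhale
($J > 1$ = expansion). Gradients are central differences in physical
units, one-sided at the grid boundary. Over the $N$ registered phases
the local expansion ratio is

$$\mathrm{LER\!-\!N}(x) \;=\;
  \frac{\max\{1,\, J_1(x), \dots, J_N(x)\}}
       {\min\{1,\, J_1(x), \dots, J_N(x)\}},$$

with the constant 1 representing the exhale reference itself. This
realises "expansion between the minimal and maximal expansion states of
the cycle": it reduces to the plain inhale/exhale Jacobian for a
two-phase cycle, is $\ge 1$ everywhere, is invariant to phase order, and
can only grow when a phase is added. Voxels where any phase has
$J \le 0$ (non-physical folding) are flagged invalid and excluded from
ROI statistics. Typical lung values lie in $[1, 1.6]$.

## Effort correction

Maps acquired at different tidal volumes are rescaled by a single global
factor: the excess expansion $\mathrm{LER}-1$ is multiplied by
$\mathrm{TV}_\mathrm{ref} / \mathrm{TV}_\mathrm{measured}$ and the
result clipped below at 1. To first order the lung-summed excess
expansion is proportional to the inhaled volume, so this is the simplest
rule consistent with a tidal-volume-based correction; the exact
correction used in prior ventilation work is not published in closed
form, and this global linear stand-in is flagged as such.

## Classification thresholds

* Level: `High` at $\mathrm{LER\!-\!N} \ge 1.2$, `Low` at $\le 1.1$,
  `Moderate` strictly between. Moderate values are retained as their own
  class rather than forced into either side.
* Change: the ratio $r = \mathrm{LER}_{post}/\mathrm{LER}_{pre}$ is
  `Decline` when $r < 0.94$ (at least a 6% reduction, a conservative
  repeatability-based threshold), `Increase` when $r > 1.06$, `Stable`
  otherwise. All four comparisons are exactly as printed: level
  thresholds inclusive, change thresholds strict, so $r = 0.94$ and
  $r = 1.06$ are both Stable.
* Contour-level change is the ratio of ROI means by default
  (`roi_change(method = "ratio_of_means")`), which is robust to
  voxel-level registration noise; the mean of voxel ratios is available
  because published contour ratios do not state their convention.

## Registration backend

`register_to_exhale()` estimates fields with a multi-resolution
intensity demons scheme: residual-driven forces along the averaged
fixed/warped gradients with Thirion step normalisation, Gaussian fluid
smoothing of each update, compositive accumulation (`u <- v + u(x+v)`,
markedly better than additive updates for large expansions), Gaussian
diffusion smoothing of the field, and a short lightly-regularised
refinement stage at the finest level. Adjacent breathing phases differ
little, so each phase is initialised from the previous phase's recovered
field (phase chaining). The backend is pluggable: precomputed fields can
be passed straight through (`fields =`), which is how ground-truth
fields enter the pipeline for oracle testing.

A B-spline free-form deformation would be the other natural backend;
demons with Gaussian regularisation was chosen because it is
dependency-free, deterministic and accurate enough on smooth phantoms,
and because its regularisation scales are transparent
(`registration_config()`). Jacobian maps of *estimated* fields carry
voxel-level noise that inflates the max/min expansion ratio, so the
pipeline smooths measured Jacobian maps with a 1-voxel Gaussian
(`jacobian_map(smooth_sigma = 1)`); analytic/bypass fields are not
smoothed.

# Perfusion model

A dynamic contrast study is an ordered set of grid-congruent frames with
strictly increasing acquisition times. The mean HU over an ROI per frame
is its time-attenuation curve; from it the package computes

* baseline: mean of the pre-injection frames (the injection frame is
  rarely recorded, so by default the pre-contrast window ends before the
  first frame exceeding baseline + 3 baseline SDs, overridable);
* peak enhancement: curve maximum minus baseline;
* AUC: trapezoidal integral of the baseline-subtracted curve from the
  first post-injection frame to the last frame. Baseline subtraction
  makes the area contrast-specific rather than anatomy-specific and is
  the default; the raw-curve area is available
  (`curve_auc(baseline_subtract = FALSE)`). Negative excursions are
  included as-is.

Dose-binned measurements use half-open 10-Gy bins from 0 to 60 Gy (last
bin closed). Vessels contribute the change in peak enhancement and
surrounding parenchyma the change in baseline HU; a vessel ROI's bin is
decided by its mean dose, and paired parenchyma shells can inherit their
vessel's bin (`pair_by_vessel`) so both tissues describe the same dose
neighbourhoods. The vessel-versus-parenchyma relation over bins at or
above 25 Gy is summarised by a least-squares slope and Pearson r; an
anticorrelated slope (blood/contrast leaving damaged vessels while the
surrounding tissue gains attenuation) is the expected signature, with a
magnitude below 1.

# Contours

The five vessel contours are classified from a rooted vessel tree and a
dose grid: `MaxDose` when the ROI intersects the PTV, otherwise by mean
ROI dose with `LowDose` in $[5, 20]$ Gy inclusive and `NoDose` strictly
below 5 Gy (an out-of-PTV ROI above 20 Gy is flagged and excluded). Mean
rather than maximum dose is used because it is stable for small ROIs; a
`stat = "max"` switch exists. A vessel is `Fed` exactly when it is a
strict descendant of the maximally irradiated node. The contralateral
control is the MD contour mirrored across the mid-sagittal plane of the
combined lung bounding box, snapped to the nearest contralateral lung
voxel.

The three ventilation points are spheres (default radius 10 mm in the
API; 8 mm in the shipped study runs, standing in for the study's
roughly one-inch histology sections) whose voxels satisfy a class pair:
High/High (HHV), Low/Low (LLV) and High pre with Low post (HLV).
Candidate centres must have at least 90% of in-sphere lung voxels in
the pair (the "region of similar ventilation values" requirement); the
purity-maximising candidate wins, with deterministic tie-breaks (most
superior, then most anterior, then most right voxel). A pair with no
qualifying candidate is reported unavailable rather than failing, since
availability is subject-dependent.

# Concordance model

Trichrome collagen grades use the six-step ordinal scale *no
significant* (0) through *severe* (5); hyphenated range readings map to
midpoints (e.g. minimal-mild = 1.5), preserving order with minimal
assumptions. Histologic diagnoses come from a closed vocabulary with
strengths on the same scale.

Each subject-contour point is reduced to a damage class: `Damaged` when
collagen reaches Mild (2) or fibrosis is present at strength $\ge 2$,
with collagen findings flagged as suspected fixation artifacts excluded
from the evidence; `NotDamaged` when collagen is at most 0.5 and no
diagnosis reaches 2; `Intermediate` otherwise. The matched ventilation
change class is binarised (`Decline` versus `NoDecline`). Agreement is a
policy table: Decline agrees with Damaged, NoDecline with NotDamaged,
and NoDecline with Intermediate (sub-threshold findings do not count
against a biomarker that reports no decline); all other pairs disagree.
Published concordance tallies never print their operational rule; this
table is the unique reading we found that reproduces both the printed
45-point tally (41 agreements) and the identity of all four
disagreements, it is exposed in `default_agreement_policy()`, and
alternatives can be substituted.

The paired two-tailed Student t-test is implemented directly from its
definition ($t = \bar d / (s_d/\sqrt n)$ on the paired differences, $p$
from the t distribution with $n-1$ degrees of freedom) so that
`stats::t.test` and a quadrature of the t density can serve as
independent oracles in the tests; constant differences are flagged
degenerate.

# Packaged study tables

`load_study_fixture()` returns the group A and group B findings as
delimited tables with md5-verified packaging. The published per-cell
figures are images, so cell-level grades, strengths and subject
identities were reconstructed from the textual descriptions (ranges,
counts, per-subject narratives) under the constraint of matching every
printed count; where the text leaves a choice free, the assignment
consistent with the damage rule and the printed tally was used. The
study's own results sections disagree in places (the count of subjects
with decline at the maximum-dose and low-dose-fed points differs between
the results and discussion sections); the tables follow the discussion's
per-point accounting, which is the one the 45-point tally is built from.
Group A collagen was reported as a binary finding and is stored as
grades {0, 2} for damage-rule compatibility.

# Synthetic study

`make_lung_phantom()` builds a thoracic phantom: two disjoint ellipsoidal
lungs (parenchyma about -750 HU with two-scale mottle, so the
registration pyramid has structure at every level), a soft-tissue body
with mild texture, an embedded bifurcating vessel tree (about 50 HU) and
a thin proximal airway. The HU scene is built once at twice the grid
resolution and every frame — exhale included — is sampled from it, so no
frame is artificially sharper than another. The tree is laid out in
radial shells around the designated maximum-dose node (one generation in
the high-dose fall-off, one in the 5-20 Gy shell, one below 5 Gy, with
not-fed branches sampling the same shells) so the five vessel contour
classes exist on every phantom by construction.

`make_breathing_series()` turns a target LER field into displacement
fields with *exact* closed-form Jacobians: the superior-inferior
component is the cumulative integral (from the apex down) of
$t(x) - 1$, so the deformation gradient differs from the identity in a
single row and $\det(I + \nabla u) = t$ analytically. Phases scale that
field by a raised-cosine waveform that is 0 at end exhale; phase images
are produced by inverting the forward map by fixed-point iteration and
sampling the high-resolution scene. Targets requiring $|J - 1| > 0.6$
leave the small-deformation regime and warn.

The expansion model plants regions at printed physiological values:
consistently high 1.28-1.45, consistently low 1.03-1.09, high 1.21-1.26
declining to 1.04-1.09, a maximum-dose region declining by 10-16%, and
milder subject-dependent decline around fed vessels, over a moderate
1.15 background. Region centres are placed with an explicit feasibility
search that keeps them inside the lung, clear of each other and of at
least one vessel-contour candidate per dose/fed class.

Contrast kinetics are a peak-normalised gamma-variate bolus
($A\,((t-t_0)/\alpha\beta)^\alpha e^{\alpha-(t-t_0)/\beta}$, maximum
exactly $A$ at $t_0+\alpha\beta$), a delayed scaled copy in parenchyma,
and additive Gaussian noise (default 5 HU). Post-treatment effects are a
vessel peak reduction of `k_vessel` (4 HU/Gy) per Gy of local dose above
25 Gy, a parenchymal baseline rise of 0.6 of the vessel reduction
(leakage), and a supply multiplier of 0.6 on every fed vessel. These
defaults make the area under the curve drop significantly in the
maximum-dose and fed contours but not in not-fed or contralateral ones,
and give an anticorrelated vessel/parenchyma slope above 25 Gy.

Pathology outcomes are sampled from a latent grade that is monotone in
dose level, increased for fed vessels, declining ventilation and
high-to-low ventilation regions, and suppressed in the contralateral
control; diagnosis probabilities follow the same latent grade.
`effect_scale = 0` is the exact null model.

# Problem sizes and numerical choices

The default simulated cohort is 5 subjects, 10 breathing phases and
about 20 contrast frames on a 64^3 grid at 3 mm spacing (192 mm field of
view) — a full study runs in a few minutes on one CPU. Registration
fidelity is resolution-limited: validating measured (as opposed to
bypass) LER against the generator targets is done on the 96^3, 2 mm
version of the same phantom, where ROI-mean errors stay within about 4%;
at 3 mm the finite-difference and regularisation scales are too coarse
for that bound. Dose uses an isotropic 18-mm-sigma Gaussian at 60 Gy
with the contralateral lung scaled below 5 Gy. Default registration
settings are three pyramid levels with 100/80/80 iterations plus 30
refinement iterations; all randomness everywhere derives from explicit
integer seeds, and rerunning any generator or the whole study at one
seed is byte-identical.

# What the synthetic study does and does not show

The phantom emulates the geometry, kinetics and effect structure of the
study — not scanner physics. Passing tests demonstrate that every
computational stage is correct against closed forms and recovers
injected effects at realistic noise; they do not demonstrate robustness
to reconstruction artifacts, irregular breathing, real vessel/airway
segmentation error, or anatomy beyond two-lung topology, all of which
are out of scope. The concordance worked example, by contrast, runs on
the packaged study tables and reproduces the published tally exactly.

# Known limitations

* The effort correction is a first-order global scaling; regional
  effort heterogeneity is not modelled.
* The agreement policy table is an interpretation (documented above)
  and is configurable rather than claimed unique a priori.
* Pre/post ROI pairing relies on congruent grids; deformable pre/post
  alignment of real scans is out of scope.
* The demons backend is validated on smooth textured phantoms only; for
  clinical images a dedicated registration package would be swapped in
  through the bypass interface.
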