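---
title: "Methods: phMRI BOLD activation mapping and dose-response analysis"
author: "phbold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phMRI BOLD activation mapping and dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

Pharmacological MRI (phMRI) measures how a drug challenge changes brain
activity by comparing BOLD signal acquired after an injection with a
pre-injection control window, without any task or stimulus model. The
design this package implements is the awake-mouse dose-response study:
each subject contributes one uninterrupted functional run of 150
whole-brain acquisitions (18 slices, 96 x 96 in-plane, 187.5 um
in-plane resolution, 0.75 mm slices), of which the first 50 form a
5-minute baseline; the injection (saline vehicle or one of three drug
doses, 1.0 / 3.3 / 10 mg/kg) is followed by 100 more acquisitions over
10 minutes. Group sizes are eight per group before quality control.

`phbold` implements the full chain from raw 4D series to regional
dose-response tables, plus a synthetic-data generator with known ground
truth, because the original scans are not redistributable. Everything
the tests and the acceptance script assert is computed on synthetic
cohorts or on the published regional median tables shipped in
`inst/extdata/`.

# Stage by stage

## Motion quality control

Per-subject displacement traces (micrometres, per acquisition, per
axis) are summarized by mean, population SD and maximum absolute
displacement from the reference (first) acquisition. A subject is
excluded when its maximum *in-plane* (X or Y) displacement strictly
exceeds half of one in-plane voxel. The default threshold is
187.5/2 = 93.75 um, derived from the stated in-plane resolution rather
than the rounded "about 90 um" figure; it is configurable
(`half_voxel_um`). Through-plane (Z) motion is reported but never
excludes, and no motion correction is attempted: the design excludes
rather than realigns. An open choice is whether the criterion applies
to scan-to-scan (framewise) or cumulative displacement; we use maximum
absolute displacement from the reference position, which is the
stricter reading for slow drifts.

## Voxelwise activation

For voxel $v$ with baseline mean $B(v)$ over the control window, the
percent-change series is

$$\mathrm{PC}(v,t) = 100\,\frac{S(v,t) - B(v)}{B(v)}.$$

Each in-brain voxel's baseline acquisitions are compared with its
post-injection acquisitions by a two-tailed unequal-variance (Welch)
t-test with Welch-Satterthwaite degrees of freedom, treating
acquisitions as independent samples. Temporal autocorrelation is
ignored on purpose: the procedure being modelled does the same, and the
downstream magnitude threshold absorbs the resulting optimism.

The multiple-testing control is the rank-based step-up rule. With the
$V$ in-mask p-values sorted ascending, $P_{(i)}$ at rank $i$, the
retained set is every voxel with $p \le P_{(i^*)}$ where

$$i^* = \max\{\, i : P_{(i)} \le \tfrac{i}{V}\,\tfrac{q}{c_V} \,\},$$

with $q = 0.2$ and $c_V = 1$. This is the Benjamini-Hochberg step-up
rule; with these settings the realized false-positive rate of the whole
activation procedure stays well below 0.05 (the acceptance suite
measures it on null cohorts). The region of interest for the voxel-level
filter is the whole brain mask per subject (~15,000 voxels at full
scale); no per-structure filtering happens at this stage. Ties in the
p-value ranking are harmless: step-up semantics make the retained set
tie-invariant, and the implementation retains everything at or below
$P_{(i^*)}$.

A voxel finally enters the activation map only if it is retained by the
filter, individually significant at the 95% level (two-tailed
$\alpha = 0.05$), *and* its stim-window mean percent change is at least
2% in magnitude. The 2% threshold accounts for normal fluctuations of
BOLD signal in the awake rodent brain. The conjunction (filter AND
$\alpha$ AND threshold) is the strict reading; the threshold is applied
two-sided to the stim-window mean, and retained voxels keep their
percent-change values, sign-split into positive and negative component
maps that never mix.

## Registration and composites

Each subject's anatomy is registered to the template with a
9-parameter affine (translation, rotation, per-axis scaling — no shear,
no nonlinear warp), maximizing normalized cross-correlation (NCC). The
configuration mirrors the SPM-style settings: quality 0.97, smoothing
0.35 mm (FWHM of the pre-smoothing applied to both images), separation
0.50 mm (spacing of the template sample grid). Because "quality" is an
SPM coregister knob without a literal equivalent here, it is mapped to
sampling density: a fraction $1-q$ of candidate sample points is
dropped in a regular pattern. The similarity metric is not stated in
the source configuration; NCC is the natural intra-modality choice.

The optimizer is deliberately boring: a coarse exhaustive search over
translations (to escape the identity basin), then coarse-to-fine
Nelder-Mead with parameter scaling (mm-scale translations vs
$10^{-2}$-scale rotations and log-scales), each stage polished by a
short finite-difference BFGS. Scales are optimized in log space so the
identity is an interior point. Self-registration recovers the identity
to < 0.01 mm / 0.01 rad / 0.5% scale, and known synthetic transforms
(2 mm, 5 degrees, 3% scale) are recovered within 5% of each magnitude
on the 48 x 48 x 18 test grid; through-plane scale is the least
constrained parameter at coarse slice counts, which is why the
registration tests keep 18 slices while the purely statistical tests
run on 9.

All spatial transforms are compiled into a per-subject matrix $T_j$
(mm units, subject to atlas, rotation/scaling about the grid centre).
Composites go the other way: each atlas voxel is mapped through
$T_j^{-1}$ into every subject of a group and the subject's
percent-change map is sampled there by trilinear interpolation, which
guarantees the full composite volume is populated wherever the mapped
point stays inside the subject's field of view. Out-of-bounds samples
are *missing*, not zero, and drop out of the average. The average runs
over all contributing subjects, counting non-retained (zero) voxels as
zeros — that is the literal "average of all contributions" convention;
averaging over nonzero contributors only is available behind
`nonzero_only = TRUE`. Positive and negative components are composited
separately.

Gaussian smoothing at FWHM 0.8 mm is available for subject
percent-change maps before compositing (`smooth_maps` in the pipeline
config, default off). The source configuration states the FWHM inside
the registration paragraph without fixing its placement, so the
placement is flag-controlled rather than hard-wired.

## Regional statistics

Regional counting uses nearest-neighbour transfer of each subject's
activation map onto the atlas grid, so a count is a count: trilinear
transfer would smear nonzero values across boundaries and inflate the
volume of activation. Per region and sign, the number of nonzero voxels
is the subject's volume of activation. Group comparison is a
Kruskal-Wallis test on the per-subject count vectors (medians are
reporting only), with the p-value from the chi-square approximation;
post hoc two-sided Wilcoxon rank-sum tests compare each dose against
vehicle (exact enumeration for both $n \le 8$ without ties, normal
approximation with tie correction otherwise, no extra multiplicity
correction — post hocs are read at $p \le .05$).

The ranked region list is then filtered by the *same* step-up rule as
the voxel filter (one implementation, two call sites), with $V$ equal
to the number of regions analyzed. The realized cutoff is
$(i^*/V)(q/c_V)$: with 134 regions, 54 retained rows give 0.0806
(printed as .08) and 52 give 0.0776 (printed as .077).

The effect-size column is a rank-based analogue reported alongside the
omnibus p. The published tables name "omega squared" without a formula;
we default to $(H - k + 1)/(n - k)$, clipped to $[0,1]$ — zero at the
null expectation $H = k-1$ — with the simpler $H/(n-1)$
(epsilon-squared) variant behind `variant = "simple"`. For $H = 14.8$,
$n = 29$, $k = 4$ the default gives 0.472 against a printed 0.483 for a
row at $p \approx .002$; exact reproduction is impossible without the
raw per-subject counts, which is why no test asserts equality with the
printed effect sizes.

Dose-response profiles are classified from the four group medians with
strict inequalities among the three doses: descending
($d_1 > d_{3.3} > d_{10}$), ascending (reverse), U-shaped (middle dose
strictly smallest, both neighbours larger), single-dose-max (a strict
maximum without those orderings), comparable otherwise. A configurable
tolerance folds near-equal medians into "comparable", because the
published prose calls a region with a 1-voxel strict maximum
"comparable across doses" — any faithful classifier needs that knob.
The default tolerance is 0 (purely strict), which reproduces the
published most-effective-dose tally for the negative table (15 of 52
regions maximal at 3.3 mg/kg).

## Time courses and ANOVA

Region-set time courses are per-acquisition means of the
percent-change series over a voxel population. Two conventions are
supported: all voxels of the set (default in the pipeline, so vehicle
subjects contribute a trace) or only voxels retained in the subject's
activation map of the given sign. The published figures do not state
which convention they use; both are available and the choice is a
config field (`timecourse_use`).

The treatment comparison is a two-factor fixed-effects ANOVA
(treatment x time) on subject-by-time-bin values over the
post-injection window only, with configurable time binning (10 bins by
default in the pipeline). The printed denominator degrees of freedom in
the source figures are not derivable without knowing their binning, so
no test asserts the printed F values; the implementation is instead
validated against textbook sums-of-squares arithmetic to $10^{-8}$ and
by its exact SS decomposition. A treatment sum of squares at
floating-point-noise level relative to the total is reported as a null
effect ($F = 0$, $p = 1$) rather than a 0/0 ratio.

# The synthetic cohort generator

The generator emulates the study conditions, not mouse physiology:

* **Atlas** — an ellipsoidal brain mask partitioned into connected
  parcels by seeded Voronoi growth; at full scale (134 regions,
  96 x 96 x 18, 0.1875 x 0.1875 x 0.75 mm voxels) the mask holds about
  15,000 voxels. Tests mostly run the same construction at
  48 x 48 x 9 (about 1,900 in-mask voxels, 20 regions).
* **Anatomy** — per-region mean intensities plus smoothed texture on a
  dim background, lightly smoothed so that intensity gradients support
  sub-voxel registration. A pure piecewise-constant phantom makes the
  NCC optimum measurably biased at coarse slice counts; the smoothing
  choice is a property of the phantom, not of the registration.
* **Subjects** — each subject's anatomy is the shared template
  resampled through a random ground-truth transform (uniform jitters,
  defaults +-0.4 mm translation, +-0.05 rad rotation, +-3% scale).
* **Signal** — responding voxels are a seeded random subset (fraction
  configurable) of a region's subject-space voxels; their series is
  multiplied by $1 + a/100$ from the onset acquisition (default: step
  at the injection, acquisition 50 0-based; an optional 5-acquisition
  linear ramp emulates drug levels peaking within minutes). With zero
  noise the realized percent change equals the specified amplitude to
  rounding error, which the tests assert exactly.
* **Noise** — independent Gaussian per voxel and acquisition, SD
  expressed as percent of each voxel's baseline, default 1%. The
  original study never states its intra-subject noise SD; 1% makes
  vehicle region-mean time courses stay visibly under the 2% threshold
  (as reported for the real vehicle group) while single-voxel
  stim-window means have SD about 0.17%, so the 2% threshold is doing
  real work. An optional global linear drift is centred on the baseline
  window so baseline means stay nominal in expectation.
* **Motion** — mean-reverting random walks (stationary SD 10 um by
  default, matching the reported magnitudes; largest in-plane
  excursions a few tens of um), optionally spiked to trigger the
  exclusion rule.

What the generator does *not* model: hemodynamic response convolution,
physiological (cardiac/respiratory) noise, spatial noise correlation,
temporal autocorrelation, k-space/reconstruction artifacts, partial
volume effects. Passing tests therefore demonstrate that the pipeline's
arithmetic and inference behave as specified under the stated noise
model — not that the pipeline is robust to structured physiological
noise in real scans.

# Problem sizes and numerical choices

The tests and the acceptance script use these scales, chosen as the
smallest that keep every stage's behaviour representative:

* null false-positive calibration: 48 x 48 x 9 grid, 150 acquisitions,
  8 subjects x 50 Monte-Carlo replicates;
* registration recovery: 48 x 48 x 18 grid (through-plane scale needs
  slices to be identifiable);
* end-to-end dose-response recovery: 29 subjects (7/8/6/8, the
  post-exclusion group sizes) at 48 x 48 x 9 with estimated — not
  ground-truth — registration;
* oracle equivalence: exhaustive group-size configurations to total
  $n \le 8$, plus 50+ random cases per statistic.

Numerical conventions: 0-based continuous voxel coordinates with
centres at integers; mm coordinates are index times voxel size;
transforms act on mm. Trilinear sampling outside the grid returns
missing. Welch tests with zero variance in both windows give $p = 1$
for equal means and $p = 0$ otherwise. `fdr_filter` on an empty vector
returns an empty mask. Atlas parcels are Voronoi cells in index space
with ties to the lowest region id, which keeps them
convex-intersect-ellipsoid and hence connected. Per-subject seeds are
expanded deterministically from one root seed.

# Known limitations

* The noise model is white; real BOLD noise is temporally and
  spatially correlated, so the measured null false-positive rate
  (essentially zero under the 2% threshold) is a best case.
* The affine registration assumes the atlas and subject differ only by
  translation/rotation/scale, as the source procedure does; real mouse
  brains need at least a careful global scale prior.
* Printed effect sizes and F statistics from the original tables are
  not reproducible without raw data; the package reproduces the
  self-contained arithmetic (cutoffs, tallies, profile labels) and
  validates its statistics against independent oracles instead.
* The "quality" registration setting is an interpretation (sampling
  density), not an SPM reimplementation.
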