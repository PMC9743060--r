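# phbold

Pharmacological MRI (phMRI) BOLD activation mapping and regional
dose-response analysis for awake-rodent drug-challenge studies — with a
synthetic 4D cohort generator so the whole chain is testable without
scanner data.

The package is written for imaging statisticians and preclinical
pharmacologists who need the standard awake-mouse phMRI analysis as
reproducible, tested code: from a subject's raw 4D BOLD series to
ranked regional volume-of-activation tables across a vehicle group and
three drug doses (1.0, 3.3, 10 mg/kg).

## The analysis

For each subject (150 acquisitions: 50 baseline, 100 post-injection):

1. **Motion QC** — per-axis displacement summaries; exclusion when the
   maximum in-plane displacement exceeds half of one voxel
   (187.5/2 = 93.75 um).
2. **Percent signal change** — `PC(v,t) = 100 (S(v,t) − B(v)) / B(v)`
   with `B(v)` the mean over the 50-scan control window.
3. **Voxelwise inference** — two-tailed Welch *t*-tests (baseline vs
   post-injection acquisitions), then the rank-based step-up
   false-positive filter over the `V` in-brain voxels,

   `P(i) ≤ (i/V) · (q/cV)`,  `q = 0.2`, `cV = 1`,

   intersected with per-voxel significance at α = 0.05 and a 2%
   magnitude threshold. Surviving voxels keep their percent-change
   values, sign-split into positive and negative maps.
4. **Atlas registration** — 9-parameter affine (translation, rotation,
   per-axis scaling) to a segmented atlas by normalized
   cross-correlation (quality 0.97, smoothing 0.35 mm, separation
   0.50 mm), compiled into a per-subject matrix `T_j`.
5. **Composites** — each atlas voxel is mapped through `T_j⁻¹` into
   every subject, sampled trilinearly, and the contributions averaged
   per group (zeros counted; out-of-view samples excluded).
6. **Regional statistics** — per-region volumes of activation
   (voxel counts) compared across groups by Kruskal–Wallis with a
   rank-based effect size ((H − k + 1)/(n − k)) and Wilcoxon post hocs
   against vehicle; the ranked region list is filtered by the same
   step-up rule, whose realized cutoff reproduces the published
   region-list significance levels (.08 at 54/134, .077 at 52/134).
7. **Time courses** — region-set mean percent change per acquisition,
   compared drug vs vehicle over the post-injection window with a
   two-way (treatment × time) ANOVA.

The synthetic module generates cohorts with known ground truth
(labeled atlas, template anatomy, per-subject affine transforms,
step/ramp dose responses, Gaussian noise + drift, motion traces), so
sensitivity, false-positive rate, registration recovery and the full
dose-response chain are all measurable against truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → QC → activation → registration/composites → regional
tables → time courses), writing its outputs under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # 29 subjects, 7/8/6/8 per group
Rscript analysis/02_motion_qc.R
Rscript analysis/03_voxel_activation.R
Rscript analysis/04_register_composite.R
Rscript analysis/05_regional_tables.R
Rscript analysis/06_timecourses.R
```

The simulated cohort injects four known dose profiles (descending,
U-shaped, lowest-dose-only, negative descending) plus one subject with
a motion spike. Stage 2 prints:

```
28 of 29 subjects retained
excluded sub02: max in-plane displacement 150.00 um on X axis exceeds 93.75 um
largest in-plane excursion among retained subjects: 38.1 um
```

Stage 5 recovers every injected profile at the top of the ranked
positive table (region 3 descending, region 7 responsive only to
1 mg/kg, region 5 U-shaped), all passing the region-list cutoff:

```
positive volume of activation (20 regions, 3 pass, cutoff 0.03):
 region median_vehicle median_mg1 median_mg3.3 median_mg10        p omega_sq         profile  pass
      3              0       71.0         47.0        17.5 1.03e-05   0.9515      descending  TRUE
      7              0      110.0          0.0         0.0 2.15e-05   0.8881 single-dose-max  TRUE
      5              0       87.5         21.0        86.0 5.47e-05   0.8070        U-shaped  TRUE
```

and reprints the published-table arithmetic it reproduces:

```
  54 of 134 regions retained -> cutoff 0.0806 (printed as .08)
  52 of 134 regions retained -> cutoff 0.0776 (printed as .077)
  negative table (52 regions): most-effective-dose tally 1.0 mg 28, 3.3 mg 15, 10 mg 5 (4 ties)
```

Here `median_*` are per-group median activated voxel counts (the
volume of activation), `p` the Kruskal–Wallis omnibus p-value,
`omega_sq` the rank-based effect size, and `pass` the region-list
step-up decision. Stage 6 confirms vehicle time courses never cross
the 2% threshold (largest excursion 0.35%) and detects the
1 mg/kg-vs-vehicle treatment effect.

Equivalent one-call orchestration, including provenance stamping and
motion-aware group bookkeeping, is available as
`run_pipeline(pipeline_config(...))`.

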