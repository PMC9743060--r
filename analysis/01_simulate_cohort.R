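#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Builds a desk-scale analogue of the awake-mouse esketamine study:
# four groups (vehicle, 1.0, 3.3, 10 mg/kg) at the post-exclusion sizes
# 7/8/6/8, on a reduced 48 x 48 x 9 grid with 50 baseline + 100
# post-injection acquisitions per subject. Injected effects emulate the
# dose profiles reported for the real cohort: a descending positive
# response, a U-shaped response with the middle dose weakest, a region
# responsive only to the lowest dose, and a descending negative
# response. Ground truth (transforms, responder masks) is written next
# to the data.

suppressPackageStartupMessages(library(phbold))

out_dir <- "results/cohort"

effects <- rbind(
  # region 3: descending positive dose-response (strongest at 1 mg/kg)
  effect_spec(3, c("mg1", "mg3.3", "mg10"), amplitude = 5,
              fraction = c(0.60, 0.40, 0.15)),
  # region 5: U-shaped positive response, 3.3 mg/kg weakest
  effect_spec(5, c("mg1", "mg3.3", "mg10"), amplitude = 5,
              fraction = c(0.50, 0.12, 0.50)),
  # region 7: responsive only to the lowest dose
  effect_spec(7, "mg1", amplitude = 5, fraction = 0.50),
  # region 4: descending negative BOLD response
  effect_spec(4, c("mg1", "mg3.3", "mg10"), amplitude = -5,
              fraction = c(0.50, 0.30, 0.20))
)

config <- list(
  groups = c(vehicle = 7L, mg1 = 8L, mg3.3 = 6L, mg10 = 8L),
  effects = effects,
  seed = 20260920L,
  n_regions = 20L,
  shape = c(48L, 48L, 9L),
  voxel_size = c(0.375, 0.375, 1.5),
  noise_sd = 1, drift_slope = 0.002,
  n_baseline = 50L, n_stim = 100L,
  motion_sd_um = 10,
  # one subject with a motion spike large enough to trip the
  # half-voxel exclusion rule
  motion_spikes = list(sub02 = list(axis = "x", index = 75,
                                    magnitude_um = 150))
)

manifest <- make_cohort(config, out_dir)
cat(sprintf("wrote %d subjects to %s\n", length(manifest$subjects), out_dir))
cat(sprintf("groups: %s\n",
            paste(names(manifest$groups), unlist(manifest$groups),
                  sep = "=", collapse = ", ")))
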