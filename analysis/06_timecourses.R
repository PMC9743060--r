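#!/usr/bin/env Rscript
# Stage 6: regional BOLD time courses and treatment-by-time ANOVA.
#
# Extracts per-subject mean percent-change time courses for a target
# region set (averaging all voxels of the set, so vehicle subjects
# contribute a trace), then compares the 1.0 mg/kg group against
# vehicle over the post-injection window with a two-way fixed-effects
# ANOVA (treatment x time, 10 time bins).

suppressPackageStartupMessages(library(phbold))

cohort <- read_cohort("results/cohort")
qc <- read.delim("results/motion_qc.tsv")
used <- qc$subject_id[!qc$excluded]

# the descending-response region and the low-dose-only region together
# play the role of a composite "hippocampus" set
region_set <- c(3L, 7L)

rows <- lapply(used, function(sid) {
  b <- cohort$subjects[[sid]]
  tc <- region_timecourse(b, region_set, sign = "positive", use = "all")
  data.frame(subject_id = sid, treatment = b$group,
             acquisition = tc$acquisition, value = tc$value)
})
tcs <- do.call(rbind, rows)
write.table(tcs, "results/timecourses.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

veh_max <- max(abs(tcs$value[tcs$treatment == "vehicle"]))
cat(sprintf("largest vehicle excursion: %.2f%% (2%% threshold never exceeded: %s)\n",
            veh_max, veh_max < 2))

sel <- tcs$treatment %in% c("vehicle", "mg1")
res <- two_way_anova(tcs[sel, ], n_baseline = 50, n_bins = 10)
cat(sprintf("treatment effect, 1.0 mg/kg vs vehicle: F(%d,%d) = %.2f, p = %.3g; %s > other\n",
            res$df1, res$df2, res$F, res$p, res$direction))
jsonlite::write_json(res[c("F", "df1", "df2", "p", "direction")],
                     "results/anova_mg1_vs_vehicle.json",
                     auto_unbox = TRUE, digits = NA)
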