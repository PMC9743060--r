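#!/usr/bin/env Rscript
# Stage 2: motion quality control.
#
# Summarizes each subject's displacement trace (mean, population SD and
# maximum per axis, in micrometres) and applies the half-voxel
# exclusion rule: any in-plane excursion beyond 93.75 um (half the
# 187.5 um in-plane voxel) excludes the subject from all further
# analysis. Through-plane motion is reported but never excludes.

suppressPackageStartupMessages(library(phbold))

cohort <- read_cohort("results/cohort")
qc <- motion_qc_table(cohort$subjects, half_voxel_um = 93.75)

dir.create("results", showWarnings = FALSE)
write.table(qc, "results/motion_qc.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cat(sprintf("%d of %d subjects retained\n", sum(!qc$excluded), nrow(qc)))
if (any(qc$excluded)) {
  for (i in which(qc$excluded)) {
    cat(sprintf("excluded %s: %s\n", qc$subject_id[i], qc$reason[i]))
  }
}
cat(sprintf("largest in-plane excursion among retained subjects: %.1f um\n",
            max(qc[!qc$excluded, c("x_max", "y_max")])))
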