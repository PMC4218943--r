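#!/usr/bin/env Rscript

# Runs the full segmentation and volumetry pipeline end to end on a
# 5-subject phantom cohort at 64^3 and scores it against the known truth:
# per-subject Dice of the merged cerebrum+CSF region, cerebellum and
# brainstem, and the error of the CSF-thresholded cerebrum volume.
#
# Finding (seed 1): merged-region Dice >= 0.96, cerebellum >= 0.99,
# cerebrum volumes within 0.2% of truth. The groupwise average atlas built
# from the cohort is also exercised here; its per-round template change
# shrinks across the non-rigid rounds.

library(pmbrainvol)

dir.create("results", showWarnings = FALSE)

rec <- experiment_parameter_recovery(n_subjects = 5, grid = 64, seed = 1)
print(rec, digits = 4)
write.csv(rec, "results/parameter_recovery.csv", row.names = FALSE)

atlas <- attr(rec, "atlas")
cat("groupwise schedule:",
    paste(atlas$provenance$schedule, collapse = " "), "\n")
cat("template change by round:",
    paste(signif(atlas$provenance$template_change, 3), collapse = " "),
    "\n")

cat(sprintf(
  "min Dice cerebrum+CSF %.3f | min Dice cerebellum %.3f | max volume error %.2f%%\n",
  min(rec$dice_cerebrum_csf), min(rec$dice_cerebellum),
  100 * max(rec$volume_error_fraction)))
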