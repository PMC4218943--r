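#!/usr/bin/env Rscript

# Component-level validation on phantoms: bias-field recovery and
# known-transform registration recovery.
#
# Finding (seed defaults): the estimated bias field correlates with the
# simulated field at r > 0.99 (amplitude 1.4); a known 3-voxel rigid
# translation is recovered to < 0.01 voxels; a known smooth warp (RMS
# 1.5 mm) of a textured phantom is reduced to < 1 voxel mean displacement
# error inside the head.

library(pmbrainvol)

dir.create("results", showWarnings = FALSE)

r <- experiment_bias_recovery(amplitude = 1.4, seed = 13)
cat(sprintf("bias-field recovery Pearson r: %.4f\n", r))

reg <- experiment_registration_recovery(seed = 11)
cat(sprintf("rigid translation error: %.4f voxels\n",
            reg$translation_error_vox))
cat(sprintf("warp error: %.3f voxels (from %.3f before registration)\n",
            reg$warp_error_vox, reg$warp_error_before_vox))

out <- data.frame(
  quantity = c("bias_field_recovery_r", "rigid_translation_error_vox",
               "bspline_warp_error_vox", "bspline_warp_error_before_vox"),
  value = c(r, reg$translation_error_vox, reg$warp_error_vox,
            reg$warp_error_before_vox))
write.csv(out, "results/component_validation.csv", row.names = FALSE)
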