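#!/usr/bin/env Rscript

# Generates the synthetic study cohorts: a "newborn" phantom cohort under
# the default acquisition conditions (0.6 mm isotropic voxels, additive
# noise SD 30, multiplicative bias amplitude 1.3, per-subject smooth
# deformations of RMS 1.5 mm) and an independent cohort that plays the
# publicly available prior atlas. Writes NIfTI volumes and a truth table
# under results/simulated/.
#
# Sizes are kept desk-scale (64^3 voxels, 5 + 3 subjects), matching the
# validation experiments.

library(pmbrainvol)

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- phantom_spec(grid_shape = 64, seed = 1)
cohort <- generate_cohort(spec, 5)

truth_rows <- lapply(seq_along(cohort), function(i) {
  s <- cohort[[i]]
  id <- sprintf("S%02d", i)
  write_volume(s$image, file.path(out, paste0(id, "_image.nii.gz")))
  write_volume(s$truth$label_map, file.path(out, paste0(id, "_truth.nii.gz")))
  data.frame(subject_id = id,
             t(s$truth$true_volumes_mL))
})
truth <- do.call(rbind, truth_rows)
write.csv(truth, file.path(out, "true_volumes_mL.csv"), row.names = FALSE)
cat("cohort of", length(cohort), "subjects written;",
    "cerebrum volumes [mL]:\n")
print(round(truth$cerebrum, 3))

prior_spec <- phantom_spec(grid_shape = 64, seed = 102, deform_sd = 1.0)
prior_atlas <- atlas_from_truth(
  lapply(generate_cohort(prior_spec, 3), `[[`, "truth"),
  smoothing_mm = 1.8)
write_volume(prior_atlas$template, file.path(out, "atlas_template.nii.gz"))
write_volume(prior_atlas$mask, file.path(out, "atlas_mask.nii.gz"))
for (cl in names(prior_atlas$priors))
  write_volume(prior_atlas$priors[[cl]],
               file.path(out, sprintf("atlas_prior_%s.nii.gz", cl)))
jsonlite::write_json(prior_atlas$provenance,
                     file.path(out, "atlas_provenance.json"),
                     auto_unbox = TRUE)
cat("prior atlas written to", out, "\n")
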