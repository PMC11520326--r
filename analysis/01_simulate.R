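#!/usr/bin/env Rscript
# Build the study conditions: a digital rat-brain label atlas, the smoothed
# brain-mask registration target, a 12 KO / 14 WT two-timepoint phantom
# cohort with known poses and regional uptake truth (43 scans, mirroring the
# study layout with its missing cells), and the 23-measure behavioral table.
# Everything downstream is reproducible from the seed printed below.

suppressMessages(library(fdgpet))
seed <- 7
out <- "results"
dir.create(out, showWarnings = FALSE)

atlas <- make_label_phantom(voxel_mm = 0.6, seed = seed)
mask <- make_smoothed_mask(atlas, 0.85)
rv <- region_volumes(atlas)
cat(sprintf("atlas: %s voxels, brain %.0f mm^3, median a-priori region %.2f mm^3\n",
            paste(dim(atlas$voxels), collapse = "x"),
            sum(rv$volume_mm3),
            median(rv$volume_mm3[rv$name != "Brain (rest)"])))

write_nifti3(atlas, file.path(out, "atlas_labels.nii.gz"))
write_nifti3(mask, file.path(out, "brain_mask_smoothed.nii.gz"))
write.csv(rv, file.path(out, "region_volumes.csv"), row.names = FALSE)

cohort <- generate_cohort(cohort_design(), atlas = atlas, seed = seed + 1)
print(cohort)
write.csv(cohort$records, file.path(out, "scan_records.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(levels = cohort$truth$levels,
       poses = lapply(cohort$truth$poses, function(p)
         list(translation_mm = p$translation, rotation_deg = p$rotation_deg,
              scale = p$scale)),
       seed = cohort$truth$seed),
  file.path(out, "cohort_truth.json"), auto_unbox = TRUE, digits = NA)

# one demo dynamic scan on the reconstruction-like schedule
fs <- make_frame_schedule(90, 1)
demo_id <- cohort$records$scan_id[1]
demo <- render_scan(atlas, cohort, demo_id, fs = fs, seed = seed + 2)
write_dynamic_nifti(demo, file.path(out, paste0(demo_id, "_dynamic.nii.gz")))
cat(sprintf("demo scan %s: %d frames, whole-image max %.0f Bq/mL\n",
            demo_id, dim(demo$voxels)[4], max(demo$voxels)))

behavior <- generate_behavior(cohort_design(), seed = seed + 3)
write.csv(behavior, file.path(out, "behavior.csv"), row.names = FALSE)
cat(sprintf("behavior table: %d rows, %d measures\n",
            nrow(behavior), length(unique(behavior$measure))))
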