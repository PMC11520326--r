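#!/usr/bin/env Rscript
# Render every scan of the phantom cohort and run the full alignment and
# quantification chain: 30-60 min sum images, coarse + fine (6 then 9 df)
# registration to the smoothed mask, within-subject pairing, one study-
# template refinement pass, single-interpolation 4D resampling into atlas
# space, TAC extraction, SUV and SUVr. Writes the uptake table, per-scan
# transforms, pose-recovery errors against the known truth, and the
# per-genotype volume-scale-product summary.

suppressMessages(library(fdgpet))
out <- "results"
dir.create(out, showWarnings = FALSE)

t0 <- Sys.time()
res <- suppressWarnings(run_pipeline(list(
  seed = 7, out_dir = out, voxel_mm = 0.6, n_frames = 12, frame_min = 5,
  template_pass = TRUE, stats = FALSE, maxit = c(350, 200))))
cat(sprintf("pipeline: %d scans in %.1f min\n",
            nrow(res$cohort$records),
            as.numeric(difftime(Sys.time(), t0, units = "mins"))))

# pose recovery against truth
errs <- do.call(rbind, lapply(names(res$transforms), function(id) {
  tru <- res$cohort$truth$poses[[id]]
  est <- res$transforms[[id]][[1]]
  data.frame(scan_id = id,
             err_shift_mm = max(abs(est$translation - tru$translation)),
             err_rot_deg = max(abs(est$rotation_deg - tru$rotation_deg)),
             err_scale = max(abs(est$scale - tru$scale)))
}))
write.csv(errs, file.path(out, "pose_recovery.csv"), row.names = FALSE)
cat(sprintf("pose recovery (default noise): median shift %.3f mm, rot %.3f deg, scale %.4f\n",
            median(errs$err_shift_mm), median(errs$err_rot_deg),
            median(errs$err_scale)))

# combined 3D scale factors (x*y*z) per genotype, and their comparison
write.csv(res$scale_summary, file.path(out, "scale_products.csv"),
          row.names = FALSE)
print(res$scale_summary)
sc <- vapply(res$transforms, function(ch) volume_scale_product(ch[[1]]),
             numeric(1))
g <- res$cohort$records$genotype[match(names(sc),
                                       res$cohort$records$scan_id)]
tt <- t.test(sc[g == "WT"], sc[g == "KO"])
cat(sprintf("volume products: WT %.3f vs KO %.3f (two-sample t, p = %.3f)\n",
            mean(sc[g == "WT"]), mean(sc[g == "KO"]), tt$p.value))

cat("uptake table written to", file.path(out, "uptake.csv"), "\n")
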