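## Validation studies run by the test suite, the acceptance script, and the
## analysis drivers: pose-recovery on phantoms with known transforms, and
## operating characteristics (power, sign, type-I error) of the 2x2 model
## under the cohort generator.

#' Pose-recovery study on phantoms with known transforms
#'
#' Renders `n` single-frame phantom scans with randomized known poses
#' (shifts, rotations, per-axis scales drawn uniformly), registers each to
#' the smoothed brain mask (coarse + fine 6 then 9 df), optionally refines
#' against a study template built from the first-pass alignments, and
#' reports per-phantom parameter errors.
#'
#' @param n Number of phantoms.
#' @param noise_sd_frac Image noise fraction (0 = noise free).
#' @param max_shift_mm,max_rot_deg Uniform half-ranges of the true pose.
#' @param scale_range True per-axis scales drawn from this interval.
#' @param voxel_mm Phantom grid resolution.
#' @param psf_fwhm_mm Scanner PSF.
#' @param template_pass Refine against a study template (default TRUE).
#' @param maxit Optimizer budget per resolution level (see [fine_align()]);
#'   the study default trades a little of the (large) accuracy margin for
#'   run time.
#' @param supersample Sub-voxel render sampling (see [render_scan()]); the
#'   study uses 3 so that edge-voxelization artifacts of the renderer, which
#'   have no counterpart in real scans, stay well below the recovery
#'   tolerances.
#' @param seed Integer seed.
#' @return data.frame with one row per phantom: true and recovered
#'   parameters plus `err_shift_mm`, `err_rot_deg`, `err_scale` (each the
#'   maximum absolute component error).
#' @export
assess_registration_recovery <- function(n = 20, noise_sd_frac = 0,
                                         max_shift_mm = 4, max_rot_deg = 5,
                                         scale_range = c(0.97, 1.03),
                                         voxel_mm = 0.6, psf_fwhm_mm = 2,
                                         template_pass = TRUE,
                                         maxit = c(400, 250),
                                         supersample = 3L, seed = 1) {
  atlas <- make_label_phantom(voxel_mm = voxel_mm, seed = seed)
  mask <- make_smoothed_mask(atlas, 0.85)
  center <- grid_center(atlas)
  design <- cohort_design(ceiling(n / 2), floor(n / 2), "none")[seq_len(n), ]
  cohort <- generate_cohort(design, atlas = atlas,
                            noise_sd_frac = noise_sd_frac, seed = seed)
  ## overwrite poses with the requested uniform draws (baseline scans only)
  set.seed(seed + 17L)
  ids <- cohort$records$scan_id[cohort$records$timepoint == "baseline"][seq_len(n)]
  for (id in ids)
    cohort$truth$poses[[id]] <- affine_params(
      stats::runif(3, -max_shift_mm, max_shift_mm),
      stats::runif(3, -max_rot_deg, max_rot_deg),
      stats::runif(3, scale_range[1], scale_range[2]),
      center = center, df = 9L)

  fs <- frame_schedule(data.frame(start = 30, end = 60))
  sums <- lapply(seq_along(ids), function(i)
    sum_image(render_scan(atlas, cohort, ids[i], fs = fs,
                          psf_fwhm_mm = psf_fwhm_mm,
                          noise_sd_frac = noise_sd_frac,
                          supersample = supersample,
                          seed = seed + 1000L + i),
              c(30, 60)))
  fits <- lapply(sums, function(s) align_scan(s, mask, maxit = maxit))
  if (template_pass) {
    aligned <- mapply(function(s, p) resample_to(s, compose_chain(p), mask),
                      sums, fits, SIMPLIFY = FALSE)
    template <- build_template(aligned, mask)
    fits <- mapply(function(s, p) refine_to_template(s, template, p),
                   sums, fits, SIMPLIFY = FALSE)
  }
  do.call(rbind, lapply(seq_along(ids), function(i) {
    tru <- cohort$truth$poses[[ids[i]]]
    est <- fits[[i]]
    data.frame(scan_id = ids[i],
               err_shift_mm = max(abs(est$translation - tru$translation)),
               err_rot_deg = max(abs(est$rotation_deg - tru$rotation_deg)),
               err_scale = max(abs(est$scale - tru$scale)),
               score = attr(est, "score"),
               true_scale_prod = volume_scale_product(tru),
               est_scale_prod = volume_scale_product(est),
               stringsAsFactors = FALSE)
  }))
}

#' Power and sign recovery of the genotype effect over cohort replicates
#'
#' Draws `n_rep` tabular uptake cohorts at the default genotype effects,
#' fits the genotype-by-time model on one region's SUVr per replicate, and
#' summarizes detection rate (genotype main effect p < alpha), the fraction
#' of detections with the correct sign, and LS-mean bias.
#'
#' @param n_rep Number of replicate cohorts.
#' @param region Region to test (default `"Striatum"`, expected KO < WT).
#' @param alpha Significance level.
#' @param design See [cohort_design()].
#' @param effect_scale Passed to [generate_cohort()] (0 for the null).
#' @param seed Integer seed.
#' @return List with per-replicate `results` and scalar `power`,
#'   `sign_correct_frac`, `mean_ko_minus_wt`.
#' @export
assess_inference_recovery <- function(n_rep = 200, region = "Striatum",
                                      alpha = 0.05,
                                      design = cohort_design(),
                                      effect_scale = 1, seed = 1) {
  eff <- region_defaults()
  true_dir <- sign(eff$suvr_ko[eff$name == region] -
                   eff$suvr_wt[eff$name == region])
  res <- lapply(seq_len(n_rep), function(r) {
    cohort <- generate_cohort(design, effect_scale = effect_scale,
                              seed = seed + r)
    up <- simulate_uptake(cohort, seed = seed + 100000L + r)
    d <- up[up$region == region, ]
    fit <- fit_lme_2x2(d, "suvr")
    p_gen <- fit$effects$p[fit$effects$effect == "genotype"]
    ls <- fit$lsmeans
    diff_ko_wt <- mean(ls$lsmean[ls$genotype == "KO"]) -
      mean(ls$lsmean[ls$genotype == "WT"])
    data.frame(rep = r, p_genotype = p_gen, ko_minus_wt = diff_ko_wt)
  })
  res <- do.call(rbind, res)
  det <- res$p_genotype < alpha
  list(results = res,
       power = mean(det),
       sign_correct_frac = if (any(det))
         mean(sign(res$ko_minus_wt[det]) == true_dir) else NA_real_,
       mean_ko_minus_wt = mean(res$ko_minus_wt))
}

#' Type-I error of the 2x2 tests under the null generator
#'
#' Replicate null cohorts (all genotype multipliers 1), one model fit per
#' replicate; returns the rejection rate of each reported test at `alpha`
#' together with the binomial 95% interval around `alpha`.
#'
#' @param n_rep Number of null replicates.
#' @param region Region whose SUVr is tested.
#' @param alpha Nominal level.
#' @param design See [cohort_design()].
#' @param seed Integer seed.
#' @return List with `rates` (named: genotype x time, genotype, time),
#'   `ci` (the binomial interval), `n_rep`.
#' @export
assess_type1_error <- function(n_rep = 500, region = "Striatum",
                               alpha = 0.05, design = cohort_design(),
                               seed = 1) {
  hits <- matrix(NA, n_rep, 3,
                 dimnames = list(NULL, c("genotype x time", "genotype", "time")))
  for (r in seq_len(n_rep)) {
    cohort <- generate_cohort(design, effect_scale = 0, seed = seed + r)
    up <- simulate_uptake(cohort, seed = seed + 200000L + r)
    fit <- fit_lme_2x2(up[up$region == region, ], "suvr")
    hits[r, fit$effects$effect] <- fit$effects$p < alpha
  }
  half <- 1.96 * sqrt(alpha * (1 - alpha) / n_rep)
  list(rates = colMeans(hits, na.rm = TRUE),
       ci = c(lower = alpha - half, upper = alpha + half),
       n_rep = n_rep)
}
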