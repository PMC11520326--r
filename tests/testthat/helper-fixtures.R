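# shared fixtures, built once per test run
.fix <- new.env()

fix_atlas <- function() {
  if (is.null(.fix$atlas))
    .fix$atlas <- make_label_phantom(voxel_mm = 0.6, seed = 1)
  .fix$atlas
}

fix_mask <- function() {
  if (is.null(.fix$mask)) .fix$mask <- make_smoothed_mask(fix_atlas(), 0.85)
  .fix$mask
}

fix_cohort <- function() {
  if (is.null(.fix$cohort))
    .fix$cohort <- generate_cohort(cohort_design(), atlas = fix_atlas(),
                                   seed = 42)
  .fix$cohort
}

# render one scan with a forced pose (modifying a copy of the cohort truth)
render_with_pose <- function(pose, psf_fwhm_mm = 0, noise_sd_frac = 0,
                             fs = frame_schedule(data.frame(start = 30, end = 60)),
                             scan_id = NULL, seed = 7) {
  cohort <- fix_cohort()
  if (is.null(scan_id)) scan_id <- cohort$records$scan_id[1]
  cohort$truth$poses[[scan_id]] <- pose
  render_scan(fix_atlas(), cohort, scan_id, fs = fs,
              psf_fwhm_mm = psf_fwhm_mm, noise_sd_frac = noise_sd_frac,
              seed = seed)
}

identity_pose <- function() affine_params(center = grid_center(fix_atlas()))

# balanced toy data with one observation per subject x timepoint
balanced_2x2 <- function(n_per_geno = 6, seed = 1, delta_geno = 0,
                         delta_time = 0, delta_int = 0, sd_b = 1, sd_e = 0.5) {
  set.seed(seed)
  subj <- c(sprintf("K%d", 1:n_per_geno), sprintf("W%d", 1:n_per_geno))
  geno <- rep(c("KO", "WT"), each = n_per_geno)
  b <- rnorm(2 * n_per_geno, 0, sd_b)
  out <- list()
  for (i in seq_along(subj)) for (tp in c("baseline", "final")) {
    mu <- 10 + (geno[i] == "KO") * delta_geno + (tp == "final") * delta_time +
      (geno[i] == "KO") * (tp == "final") * delta_int
    out[[length(out) + 1]] <- data.frame(
      subject = subj[i], genotype = geno[i], timepoint = tp,
      value = mu + b[i] + rnorm(1, 0, sd_e))
  }
  do.call(rbind, out)
}

# brute-force majority-vote downsampling oracle (integer block only)
oracle_majority_downsample <- function(vox, b) {
  d <- dim(vox)
  n_out <- ceiling(d / b)
  out <- array(NA_integer_, n_out)
  for (i in seq_len(n_out[1])) for (j in seq_len(n_out[2]))
    for (k in seq_len(n_out[3])) {
      xs <- ((i - 1) * b[1] + 1):min(i * b[1], d[1])
      ys <- ((j - 1) * b[2] + 1):min(j * b[2], d[2])
      zs <- ((k - 1) * b[3] + 1):min(k * b[3], d[3])
      cnt <- table(vox[xs, ys, zs])
      best <- max(cnt)
      out[i, j, k] <- min(as.integer(names(cnt)[cnt == best]))
    }
  out
}
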