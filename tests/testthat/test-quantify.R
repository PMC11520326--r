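make_tac_df <- function(vals, frame_min = 1) {
  n <- length(vals)
  data.frame(region = "r", frame = seq_len(n),
             start = (seq_len(n) - 1) * frame_min,
             end = seq_len(n) * frame_min, mean_conc = vals)
}

test_that("decay correction applies the closed-form factor once only", {
  fs <- frame_schedule(data.frame(start = c(0, 1, 59), end = c(1, 59, 60)))
  arr <- array(50, c(2, 2, 2, 3))
  img <- dyn_image(arr, 1, fs, decay_corrected = FALSE)
  cor <- decay_correct(img)
  # frame midpoints 0.5 and 30 min; lambda = ln 2 / 109.77
  expect_equal(cor$voxels[1, 1, 1, 1], 50 * exp(log(2) * 0.5 / 109.77))
  expect_equal(cor$voxels[1, 1, 1, 2] / 50, 1.209, tolerance = 1e-3)
  expect_true(cor$decay_corrected)
  expect_error(decay_correct(cor), "already")

  # a frame whose midpoint is one half-life doubles
  fs2 <- frame_schedule(data.frame(start = 109.27, end = 110.27))
  img2 <- dyn_image(array(50, c(1, 1, 1, 1)), 1, fs2, decay_corrected = FALSE)
  expect_equal(as.vector(decay_correct(img2)$voxels), 100, tolerance = 1e-9)
})

test_that("TAC extraction averages member voxels (constant field sanity)", {
  atlas <- fix_atlas()
  fs <- make_frame_schedule(10, 5)
  arr <- array(3.5, c(dim(atlas$voxels), 2))
  img <- dyn_image(arr, atlas$voxel_size, fs, atlas$origin)
  tacs <- extract_tacs(img, atlas)
  expect_true(all(abs(tacs$mean_conc - 3.5) < 1e-12))
  expect_true("Whole brain" %in% tacs$region)
  bad <- dyn_image(array(1, c(2, 2, 2, 2)), 1, fs)
  expect_error(extract_tacs(bad, atlas), "atlas grid")
})

test_that("SUV arithmetic matches the hand-checkable example", {
  # mean 86,500 Bq/mL over 30-60, ID 25 MBq, BW 500 g -> 1.73 g/mL
  tac <- make_tac_df(c(rep(0, 30), rep(86500, 60)))
  rec <- list(injected_activity_bq = 25e6, body_weight_g = 500)
  expect_equal(compute_suv(tac, rec), 1.73, tolerance = 1e-12)
  # identity case: mean concentration equal to dose/weight gives SUV 1
  rec1 <- list(injected_activity_bq = 1e6, body_weight_g = 1)
  tac1 <- make_tac_df(rep(1e6, 60))
  expect_equal(compute_suv(tac1, rec1), 1)
  # homogeneity: doubling injected dose halves SUV
  rec2 <- list(injected_activity_bq = 50e6, body_weight_g = 500)
  expect_equal(compute_suv(tac, rec2), 1.73 / 2, tolerance = 1e-12)
  expect_error(compute_suv(tac, list(injected_activity_bq = 0,
                                     body_weight_g = 500)), "> 0")
})

test_that("partial window frames are weighted by overlap duration", {
  tac <- make_tac_df(1:60)  # frame i covers [i-1, i), value i
  # window (30, 60): frames 31..60
  expect_equal(fdgpet:::window_mean(tac, c(30, 60)), mean(31:60))
  # window (29.5, 60): frame 30 contributes half a minute
  expect_equal(fdgpet:::window_mean(tac, c(29.5, 60)),
               (0.5 * 30 + sum(31:60)) / 30.5)
  expect_error(fdgpet:::window_mean(tac, c(70, 80)), "window")
})

test_that("SUVr normalizes to whole brain and cancels dose errors", {
  tab <- data.frame(scan_id = rep(c("a", "b"), each = 3),
                    region = rep(c("Whole brain", "r1", "r2"), 2),
                    suv = c(1.6, 2.0, 1.6, 0.8, 1.0, 0.72))
  out <- compute_suvr(tab)
  expect_equal(out$suvr[out$scan_id == "a"], c(1, 1.25, 1))
  expect_equal(out$suvr[out$scan_id == "b"], c(1, 1.25, 0.9))
  # global rescaling of SUV (dose/weight error) leaves SUVr untouched
  tab2 <- tab; tab2$suv <- tab2$suv * 3.7
  expect_equal(compute_suvr(tab2)$suvr, out$suvr, tolerance = 1e-14)
  expect_error(compute_suvr(data.frame(scan_id = "a", region = "r1",
                                       suv = 1)), "Whole brain")
})

test_that("noise-free PSF-free phantom SUVr equals the truth multipliers", {
  atlas <- fix_atlas()
  cohort <- fix_cohort()
  id <- cohort$records$scan_id[1]
  rec <- cohort$records[1, ]
  fs <- make_frame_schedule(60, 10)
  scan <- render_with_pose(identity_pose(), psf_fwhm_mm = 0,
                           noise_sd_frac = 0, fs = fs, scan_id = id)
  up <- uptake_table(scan, atlas, rec, regions = default_region_set(atlas))
  lv <- cohort$truth$levels
  s <- if (rec$genotype == "KO") lv$suvr_ko else lv$suvr_wt
  names(s) <- lv$name
  for (nm in default_region_set()$name) {
    expect_lt(abs(up$suvr[up$region == nm] - s[[nm]]) / s[[nm]], 1e-3)
  }
  expect_equal(up$suvr[up$region == "Whole brain"], 1)
  # SUV of the whole brain reproduces the configured true value
  expect_equal(up$suv[up$region == "Whole brain"], rec$suv_wb_true,
               tolerance = 1e-6)
})
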