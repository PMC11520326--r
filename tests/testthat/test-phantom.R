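test_that("frame schedules are uniform, truncated, and validated", {
  fs <- make_frame_schedule(90, 1)
  expect_equal(nrow(fs$frames), 90L)
  expect_equal(fs$frames$start, 0:89)
  expect_equal(make_frame_schedule(10, 2)$frames$end, c(2, 4, 6, 8, 10))
  expect_warning(fs3 <- make_frame_schedule(10, 3), "truncating")
  expect_equal(nrow(fs3$frames), 3L)
  expect_error(make_frame_schedule(0, 1), "empty")
  expect_error(frame_schedule(data.frame(start = c(0, 2), end = c(1, 3))),
               "contiguous")
  expect_error(frame_schedule(data.frame(start = 0, end = 0)), "> 0")
})

test_that("plateau TACs integrate exactly and saturate by 30 min", {
  fs <- make_frame_schedule(90, 1)
  expect_equal(simulate_tac(kinetic_params(0, 5), fs), rep(0, 90))
  tac <- simulate_tac(kinetic_params(100, 5), fs)
  expect_true(all(diff(tac) >= 0))
  # frame mean over 30-60 min: exact analytic integral, frozen value, and an
  # independent numerical quadrature oracle
  one <- frame_schedule(data.frame(start = 30, end = 60))
  got <- simulate_tac(kinetic_params(100, 5), one)
  expect_equal(got, 99.9588, tolerance = 1e-6)
  oracle <- stats::integrate(function(t) 100 * (1 - exp(-t / 5)), 30, 60)$value / 30
  expect_equal(got, oracle, tolerance = 1e-8)
  # >= 95% of plateau by 30 min for tau <= 10 (narrow frame at t = 30)
  at30 <- frame_schedule(data.frame(start = 30, end = 30.001))
  expect_gte(simulate_tac(kinetic_params(1, 10), at30), 0.95)
  expect_gte(simulate_tac(kinetic_params(1, 5), at30), 0.95)
  # tau -> 0 limit: constant amplitude from the first frame
  expect_equal(simulate_tac(kinetic_params(7, 1e-15), fs), rep(7, 90))
})

test_that("label phantom is deterministic with volumes accurate to a voxel", {
  a1 <- make_label_phantom(voxel_mm = 0.6, seed = 1)
  a2 <- make_label_phantom(voxel_mm = 0.6, seed = 1)
  expect_identical(a1$voxels, a2$voxels)
  rv <- region_volumes(a1)
  tgt <- region_defaults()
  vv <- prod(a1$voxel_size)
  ach <- rv$volume_mm3[match(tgt$name, rv$name)]
  expect_true(all(abs(ach - tgt$volume_mm3) <= vv))
  med <- median(ach)
  expect_lte(abs(med - 6), vv)
})

test_that("rendered scans recover painted TACs exactly without PSF or noise", {
  atlas <- fix_atlas()
  cohort <- fix_cohort()
  id <- cohort$records$scan_id[1]
  rec <- cohort$records[1, ]
  fs <- make_frame_schedule(60, 10)
  scan <- render_with_pose(identity_pose(), psf_fwhm_mm = 0,
                           noise_sd_frac = 0, fs = fs, scan_id = id)
  tacs <- extract_tacs(scan, atlas)
  lv <- cohort$truth$levels
  s <- if (rec$genotype == "KO") lv$suvr_ko else lv$suvr_wt
  names(s) <- lv$name
  shape <- simulate_tac(kinetic_params(1, 5), fs)
  winm <- simulate_tac(kinetic_params(1, 5),
                       frame_schedule(data.frame(start = 30, end = 60)))
  amp <- rec$suv_wb_true * rec$injected_activity_bq / rec$body_weight_g / winm
  for (nm in c("Striatum", "Brain (rest)", "Cerebellum")) {
    got <- tacs$mean_conc[tacs$region == nm]
    expect_equal(got, amp * s[[nm]] * shape, tolerance = 1e-10)
  }
})

test_that("rendering is linear in amplitude and PSF conserves total activity", {
  cohort <- fix_cohort()
  id <- cohort$records$scan_id[2]
  fs <- frame_schedule(data.frame(start = 30, end = 60))
  base <- render_with_pose(identity_pose(), 0, 0, fs, id)
  cohort2 <- cohort
  cohort2$records$suv_wb_true[2] <- 2 * cohort2$records$suv_wb_true[2]
  cohort2$truth$poses[[id]] <- identity_pose()
  doubled <- render_scan(fix_atlas(), cohort2, id, fs = fs, psf_fwhm_mm = 0,
                         noise_sd_frac = 0)
  expect_equal(doubled$voxels, 2 * base$voxels, tolerance = 1e-12)

  blurred <- render_with_pose(identity_pose(), 2, 0, fs, id)
  expect_lt(abs(sum(blurred$voxels) - sum(base$voxels)) / sum(base$voxels),
            1e-6)
  # partial-volume loss: a small hot region's mean drops under the PSF
  atlas <- fix_atlas()
  t0 <- extract_tacs(base, atlas); t1 <- extract_tacs(blurred, atlas)
  hot <- "Prelimbic area"  # 6 mm^3, hotter than surrounding tissue
  expect_lt(t1$mean_conc[t1$region == hot], t0$mean_conc[t0$region == hot])
})

test_that("cohort generator reproduces the study layout and is seeded", {
  cohort <- fix_cohort()
  r <- cohort$records
  expect_equal(nrow(r), 43L)
  expect_equal(sum(r$genotype == "KO"), 23L)
  expect_equal(sum(r$genotype == "WT"), 20L)
  # younger group: no WT baselines
  expect_equal(sum(r$genotype == "WT" & r$timepoint == "baseline" &
                   r$group == 1), 0L)
  c2 <- generate_cohort(cohort_design(), atlas = fix_atlas(), seed = 42)
  expect_identical(cohort$records, c2$records)
  expect_equal(cohort$truth$poses[[r$scan_id[5]]]$translation,
               c2$truth$poses[[r$scan_id[5]]]$translation)
})

test_that("cohort truth satisfies the whole-brain constraint; null nulls out", {
  cohort <- fix_cohort()
  rv <- region_volumes(fix_atlas())
  lv <- cohort$truth$levels
  w <- rv$volume_mm3[match(lv$name, rv$name)]
  expect_equal(sum(w * lv$suvr_wt) / sum(w), 1, tolerance = 1e-12)
  expect_equal(sum(w * lv$suvr_ko) / sum(w), 1, tolerance = 1e-12)
  null <- generate_cohort(cohort_design(), effect_scale = 0, seed = 3)
  expect_equal(null$truth$levels$suvr_ko, null$truth$levels$suvr_wt,
               tolerance = 1e-12)
  # default KO effects carry the expected signs
  eff <- cohort$truth$effects
  expect_lt(eff$suvr_ko[eff$name == "Striatum"],
            eff$suvr_wt[eff$name == "Striatum"])
  expect_gt(eff$suvr_ko[eff$name == "Nucleus ambiguus"],
            eff$suvr_wt[eff$name == "Nucleus ambiguus"])
})

test_that("tabular uptake draws respect the whole-brain invariant", {
  up <- simulate_uptake(fix_cohort(), seed = 9)
  wb <- up[up$region == "Whole brain", ]
  expect_true(all(wb$suvr == 1))
  up2 <- simulate_uptake(fix_cohort(), seed = 9)
  expect_identical(up, up2)
  expect_equal(nrow(up), 43L * 19L)
})

test_that("behavior generator hits configured means and Table-like gaps", {
  b0 <- generate_behavior(noise_scale = 0, seed = 1)
  expect_equal(length(unique(b0$measure)), 23L)
  mp <- b0[b0$measure == "Mean power simple" & b0$timepoint == "baseline", ]
  gap <- mean(mp$value[mp$genotype == "KO"]) -
    mean(mp$value[mp$genotype == "WT"])
  expect_equal(gap, -9.3, tolerance = 1e-9)

  # law-of-large-numbers check on one measure at n = 1000 per genotype
  big <- generate_behavior(cohort_design(1000, 1000, "none"),
                           measures = "Rears", seed = 2)
  cell <- big[big$genotype == "KO" & big$timepoint == "baseline", ]
  sd_tot <- 1.0 * sqrt(1000)  # configured SE x sqrt(n)
  expect_lt(abs(mean(cell$value) - 15.2), 4 * sd_tot / sqrt(1000))
})
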