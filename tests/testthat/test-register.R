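# one shared noise-free rendered scan with a known 9-df pose
reg_fixture <- function() {
  if (is.null(.fix$reg)) {
    atlas <- fix_atlas()
    pose <- affine_params(c(1.5, -0.8, 0.6), c(3, -2, 1.5),
                          c(1.03, 0.98, 1.01), center = grid_center(atlas),
                          df = 9L)
    fs <- frame_schedule(data.frame(start = 30, end = 60))
    scan <- render_with_pose(pose, psf_fwhm_mm = 2, noise_sd_frac = 0.05,
                             fs = fs, seed = 31)
    .fix$reg <- list(pose = pose, sum = sum_image(scan, c(30, 60)))
  }
  .fix$reg
}

test_that("sum images are duration-weighted window means", {
  fs <- make_frame_schedule(90, 1)
  arr <- array(rep(1:90, each = 8), c(2, 2, 2, 90))
  img <- dyn_image(arr, 1, fs)
  s <- sum_image(img, c(30, 60))
  expect_equal(as.vector(s$voxels), rep(mean(31:60), 8))
  cimg <- dyn_image(array(2.5, c(2, 2, 2, 90)), 1, fs)
  expect_equal(unique(as.vector(sum_image(cimg, c(0, 90))$voxels)), 2.5)
  expect_error(sum_image(img, c(95, 99)), "window")
})

test_that("resampling is exact on the lattice and stable under round-trip", {
  atlas <- fix_atlas()
  mask <- fix_mask()
  ident <- resample_to(mask, diag(4), mask)
  expect_identical(ident$voxels, mask$voxels)

  # shift by exactly one voxel pitch: interior values shift by one index
  M <- affine_matrix(affine_params(translation = c(atlas$voxel_size[1], 0, 0)))
  sh <- resample_to(mask, M, mask)
  d <- dim(mask$voxels)
  expect_equal(sh$voxels[1:(d[1] - 1), , ], mask$voxels[2:d[1], , ],
               tolerance = 1e-12)

  # T then T-inverse: interior error below 1% of the local value
  p <- affine_params(c(1.2, -0.7, 0.4), c(4, 3, -2), c(1.02, 0.99, 1.01),
                     center = grid_center(mask), df = 9)
  fwd <- resample_to(mask, affine_matrix(p), mask)
  back <- resample_to(fwd, affine_invert(p), mask)
  core <- mask$voxels > 0.9999  # flat interior, clear of the edge ramp
  err <- abs(back$voxels[core] - mask$voxels[core]) / mask$voxels[core]
  expect_lt(max(err), 0.01)
})

test_that("4D resampling composes the chain into a single interpolation", {
  atlas <- fix_atlas()
  fs <- make_frame_schedule(10, 5)
  arr <- array(0, c(dim(atlas$voxels), 2))
  arr[, , , 1] <- fix_mask()$voxels
  arr[, , , 2] <- 2 * fix_mask()$voxels
  img <- dyn_image(arr, atlas$voxel_size, fs, atlas$origin)
  A <- affine_params(c(0.7, 0, -0.3), c(2, 0, 1), center = grid_center(atlas))
  B <- affine_params(c(-0.2, 0.4, 0), c(0, -1, 0), center = grid_center(atlas))
  out <- resample_4d(img, list(A, B), atlas)
  direct <- resample_to(fix_mask(), compose_chain(list(A, B)), atlas)
  expect_equal(out$voxels[, , , 1], direct$voxels, tolerance = 1e-12)
  expect_equal(out$voxels[, , , 2], 2 * direct$voxels, tolerance = 1e-12)
})

test_that("coarse grid search finds the true cell and honors manual starts", {
  atlas <- fix_atlas()
  mask <- fix_mask()
  pose <- affine_params(c(2, -2, 0), center = grid_center(atlas))
  fs <- frame_schedule(data.frame(start = 30, end = 60))
  s <- sum_image(render_with_pose(pose, 2, 0, fs, seed = 33), c(30, 60))
  p <- coarse_align(s, mask)
  # the true shift lies on the search grid and must win its cell
  expect_equal(p$translation, c(2, -2, 0), tolerance = 1e-9)
  # an exact manual start is kept
  p2 <- coarse_align(s, mask, init = pose)
  expect_equal(p2$translation, c(2, -2, 0), tolerance = 1e-9)
  # aligned input recovers (near-)identity
  s0 <- sum_image(render_with_pose(identity_pose(), 2, 0, fs, seed = 34),
                  c(30, 60))
  p0 <- suppressWarnings(coarse_align(s0, mask))  # identity may win outright
  expect_lt(max(abs(p0$translation)), 1)
  expect_lt(max(abs(p0$rotation_deg)), 2.5)
})

test_that("fine alignment recovers a known pose at default noise", {
  fx <- reg_fixture()
  mask <- fix_mask()
  est <- suppressWarnings(align_scan(fx$sum, mask))
  expect_lt(max(abs(est$translation - fx$pose$translation)), 0.25)
  expect_lt(max(abs(est$rotation_deg - fx$pose$rotation_deg)), 1)
  expect_lt(max(abs(est$scale - fx$pose$scale)), 0.01)
  expect_gt(attr(est, "score"), 0.95)
  .fix$reg_est <- est
})

test_that("the similarity metric is invariant to global intensity scaling", {
  fx <- reg_fixture()
  mask <- fix_mask()
  init <- .fix$reg_est
  skip_if(is.null(init))
  scaled <- image3(fx$sum$voxels * 37, fx$sum$voxel_size, fx$sum$origin)
  a <- suppressWarnings(fine_align(fx$sum, mask, df = 9, init = init,
                                   maxit = c(50, 25)))
  b <- suppressWarnings(fine_align(scaled, mask, df = 9, init = init,
                                   maxit = c(50, 25)))
  expect_equal(a$translation, b$translation, tolerance = 1e-10)
  expect_equal(a$scale, b$scale, tolerance = 1e-10)
  expect_equal(attr(a, "score"), attr(b, "score"), tolerance = 1e-10)
})

test_that("within-subject pairing recovers motion and maps both scans to atlas", {
  atlas <- fix_atlas()
  mask <- fix_mask()
  cohort <- fix_cohort()
  subj <- cohort$records$subject[duplicated(cohort$records$subject)][1]
  ids <- cohort$records$scan_id[cohort$records$subject == subj]
  fs <- frame_schedule(data.frame(start = 30, end = 60))
  sums <- lapply(ids, function(id)
    sum_image(render_scan(atlas, cohort, id, fs = fs, psf_fwhm_mm = 2,
                          noise_sd_frac = 0, seed = 40), c(30, 60)))
  names(sums) <- cohort$records$timepoint[match(ids, cohort$records$scan_id)]
  wa <- suppressWarnings(
    within_subject_align(sums$baseline, sums$final, mask))
  # known inter-scan motion: difference of the two true poses
  tb <- cohort$truth$poses[[ids[1]]]; tf <- cohort$truth$poses[[ids[2]]]
  expect_lt(max(abs(wa$pair6$translation -
                    (tf$translation - tb$translation))), 0.5)
  # composed chains land the brain on the atlas mask: Dice > 0.95
  dice <- vapply(list(wa$chain_baseline, wa$chain_final), function(ch) {
    which_img <- if (identical(ch, wa$chain_baseline)) sums$baseline
                 else sums$final
    al <- resample_to(which_img, compose_chain(ch), mask)
    a <- al$voxels > 0.5 * median(al$voxels[al$voxels > 0.25 * max(al$voxels)])
    b <- atlas$voxels > 0
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1))
  expect_gt(min(dice), 0.95)

  # identical images: pair transform is the identity
  wa0 <- suppressWarnings(coarse_align(sums$baseline, sums$baseline,
                                       shift_range_mm = 2, shift_step_mm = 1,
                                       rot_range_deg = 2, rot_step_deg = 1,
                                       downsample = 2L))
  expect_equal(wa0$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("study template matches its members and preserves contrast", {
  mask <- fix_mask()
  # two synthetic aligned images with different global contrast
  im1 <- image3(fix_mask()$voxels * 1.0, mask$voxel_size, mask$origin)
  im2 <- image3(fix_mask()$voxels * 3.0, mask$voxel_size, mask$origin)
  tmpl <- build_template(list(im1, im2), mask = NULL)
  expect_equal(tmpl$voxels, (im1$voxels + im2$voxels) / 2, tolerance = 1e-12)
  # identical inputs with the 9-df polish: template stays put
  tmpl2 <- suppressWarnings(build_template(list(im1, im1), mask))
  core <- mask$voxels > 0.9
  expect_lt(mean(abs(tmpl2$voxels[core] - im1$voxels[core])), 0.05)
})
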