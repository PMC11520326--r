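#' Time-window sum image
#'
#' Duration-weighted mean concentration per voxel over all frames
#' intersecting the window (partial frames weighted by overlap).
#'
#' @param img A [dyn_image()] (frames must be decay corrected).
#' @param window Length-2 numeric, minutes post scan start (default 30-60).
#' @return A [image3()].
#' @export
sum_image <- function(img, window = c(30, 60)) {
  fr <- img$schedule$frames
  ov <- pmax(0, pmin(fr$end, window[2]) - pmax(fr$start, window[1]))
  if (sum(ov) <= 0) stop("window does not intersect the frame schedule")
  w <- ov / sum(ov)
  d3 <- dim(img$voxels)[1:3]
  acc <- array(0, d3)
  for (f in which(w > 0)) acc <- acc + w[f] * img$voxels[, , , f]
  image3(acc, img$voxel_size, img$origin)
}

## normalized cross-correlation of two equal-length vectors
ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Soft silhouette of a PET sum image
#'
#' Thresholds the image at half its interior level (median of voxels above
#' half maximum) and re-smooths the binary result with the mask's Gaussian,
#' producing a brain outline whose edge profile matches the smoothed-mask
#' target. Mask-based registration stages correlate this silhouette with the
#' mask, which makes the similarity optimum insensitive to the scan's
#' interior uptake texture; texture-matched targets (within-subject pairs,
#' the study template) use raw intensities instead.
#'
#' @param img A [image3()] sum image.
#' @param sigma_mm Gaussian sigma of the mask target (default 0.85).
#' @return A [image3()] with values in `[0, 1]`.
#' @export
soft_silhouette <- function(img, sigma_mm = 0.85) {
  v <- img$voxels
  hi <- stats::median(v[v > 0.5 * max(v)])
  bin <- (v > 0.5 * hi) * 1.0
  smooth_gaussian(image3(bin, img$voxel_size, img$origin), sigma_mm)
}

prep_for_target <- function(moving, target, silhouette = FALSE) {
  if (silhouette && inherits(target, "smoothed_mask"))
    soft_silhouette(moving, target$sigma_mm) else moving
}

## crop a target image to the bounding box of |values| > tol, padded (mm)
crop_to_support <- function(img, tol = 1e-4, pad_mm = 2.5) {
  idx <- which(abs(img$voxels) > tol, arr.ind = TRUE)
  if (nrow(idx) == 0) return(img)
  pad <- ceiling(pad_mm / img$voxel_size)
  lo <- pmax(apply(idx, 2, min) - pad, 1)
  hi <- pmin(apply(idx, 2, max) + pad, dim(img$voxels))
  image3(img$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
         img$voxel_size, img$origin + (lo - 1) * img$voxel_size)
}

## registration scoring context at one resolution level
reg_level <- function(moving, target, crop = TRUE) {
  tgt <- if (crop) crop_to_support(target) else target
  list(moving = moving, pts = grid_points(tgt),
       vals = as.vector(tgt$voxels))
}

theta_to_params <- function(theta, center) {
  if (length(theta) == 6)
    affine_params(theta[1:3], theta[4:6], center = center, df = 6L)
  else
    affine_params(theta[1:3], theta[4:6], theta[7:9], center = center, df = 9L)
}

params_to_theta <- function(p, df) {
  th <- c(p$translation, p$rotation_deg)
  if (df == 9) th <- c(th, if (p$df == 9) p$scale else c(1, 1, 1))
  th
}

reg_score <- function(theta, lvl, center, pre_matrix = NULL) {
  M <- affine_matrix(theta_to_params(theta, center))
  if (!is.null(pre_matrix)) M <- pre_matrix %*% M
  ncc(sample_trilinear(lvl$moving, apply_affine(M, lvl$pts)), lvl$vals)
}

#' Coarse 6-df alignment by multi-start grid search
#'
#' Automated stand-in for manual initial placement: scores a grid of shifts
#' (at zero rotation), then a grid of rotations at the best shift, on
#' downsampled images, and returns the best candidate. A user-supplied
#' `init` mimics a manual start and is always among the candidates.
#'
#' @param moving A [image3()] sum image in scanner space.
#' @param target The registration target (e.g. [make_smoothed_mask()]).
#' @param init Optional [affine_params()] candidate.
#' @param shift_range_mm,shift_step_mm Shift grid half-range and step.
#' @param rot_range_deg,rot_step_deg Rotation grid half-range and step.
#' @param downsample Block-mean factor applied to both images for scoring.
#' @return A 6-df [affine_params()] (identity, with a warning, if nothing
#'   beats it).
#' @export
coarse_align <- function(moving, target, init = NULL,
                         shift_range_mm = 4, shift_step_mm = 2,
                         rot_range_deg = 5, rot_step_deg = 2.5,
                         downsample = 3L) {
  center <- grid_center(target)
  moving <- prep_for_target(moving, target)
  lvl <- reg_level(downsample_mean(moving, downsample),
                   downsample_mean(target, downsample))
  g <- seq(-shift_range_mm, shift_range_mm, by = shift_step_mm)
  shifts <- as.matrix(expand.grid(g, g, g))
  sc <- apply(shifts, 1, function(s) reg_score(c(s, 0, 0, 0), lvl, center))
  best_shift <- shifts[which.max(sc), ]
  r <- seq(-rot_range_deg, rot_range_deg, by = rot_step_deg)
  rots <- as.matrix(expand.grid(r, r, r))
  sc2 <- apply(rots, 1, function(rr)
    reg_score(c(best_shift, rr), lvl, center))
  best <- c(best_shift, rots[which.max(sc2), ])
  best_score <- max(sc2)
  if (!is.null(init)) {
    s_init <- reg_score(params_to_theta(init, 6), lvl, center)
    if (s_init > best_score) {
      best <- params_to_theta(init, 6)
      best_score <- s_init
    }
  }
  s_id <- reg_score(rep(0, 6), lvl, center)
  if (best_score <= s_id) {
    warning("no grid candidate improved on identity; returning identity")
    best <- rep(0, 6)
  }
  theta_to_params(best, center)
}

#' Fine alignment by derivative-free optimization
#'
#' Locally optimizes the normalized cross-correlation between the resampled
#' moving image and the target, by Nelder-Mead simplex (which only ever
#' accepts non-worsening steps) at two resolutions: block-2 downsampled,
#' then full resolution. A 9-df run should be seeded with the 6-df result.
#'
#' @param moving A [image3()] in scanner space.
#' @param target Target image ([make_smoothed_mask()] or a study template).
#' @param df 6 or 9.
#' @param init [affine_params()] starting point (e.g. from [coarse_align()]).
#' @param pre_matrix Optional fixed 4x4 matrix applied after the optimized
#'   transform (left-multiplied), used when refining the shared atlas
#'   transform of a within-subject pair while holding the pair transform
#'   fixed.
#' @param maxit Iteration budget per resolution level.
#' @return An [affine_params()] with attributes `score` (final NCC) and
#'   `converged`.
#' @export
fine_align <- function(moving, target, df = 6, init = NULL,
                       pre_matrix = NULL, maxit = c(600, 400)) {
  center <- grid_center(target)
  moving <- prep_for_target(moving, target)
  if (is.null(init)) init <- affine_params(center = center)
  theta <- params_to_theta(init, df)
  parscale <- c(rep(0.5, 3), rep(0.5, 3), rep(0.005, 3))[seq_along(theta)]
  levels <- list(reg_level(downsample_mean(moving, 2L),
                           downsample_mean(target, 2L)),
                 reg_level(moving, target))
  conv <- TRUE
  for (li in seq_along(levels)) {
    lvl <- levels[[li]]
    ## restart at the coarse level to re-expand the collapsed simplex
    for (pass in seq_len(if (li == 1) 2 else 1)) {
      opt <- stats::optim(theta, function(th)
        -reg_score(th, lvl, center, pre_matrix),
        method = "Nelder-Mead",
        control = list(maxit = maxit[li], reltol = 1e-8,
                       parscale = parscale))
      theta <- opt$par
    }
    conv <- opt$convergence == 0
  }
  if (!conv) {
    ## budget hit at full resolution: a short restart tells a stalled
    ## simplex apart from a genuinely unconverged one
    lvl <- levels[[length(levels)]]
    opt2 <- stats::optim(theta, function(th)
      -reg_score(th, lvl, center, pre_matrix),
      method = "Nelder-Mead",
      control = list(maxit = 100, reltol = 1e-8, parscale = parscale))
    if (opt$value - opt2$value < 1e-6) conv <- TRUE
    if (opt2$value < opt$value) {
      theta <- opt2$par
      opt <- opt2
    }
  }
  out <- theta_to_params(theta, center)
  attr(out, "score") <- -opt$value
  attr(out, "converged") <- conv
  if (!conv) warning("optimizer iteration budget reached; returning best iterate")
  out
}

#' Full mask-based alignment of one scan (coarse + fine 6 then 9 df)
#'
#' @inheritParams fine_align
#' @param init Optional manual-start parameters passed to [coarse_align()].
#' @return A 9-df [affine_params()].
#' @export
align_scan <- function(moving, target, init = NULL, maxit = c(600, 400)) {
  p0 <- coarse_align(moving, target, init = init)
  p6 <- fine_align(moving, target, df = 6, init = p0, maxit = maxit)
  fine_align(moving, target, df = 9, init = p6, maxit = maxit)
}

#' Within-subject paired alignment
#'
#' The final scan is first aligned to the baseline scan with 6 df, and a
#' single shared 9-df transform (estimated from the pair mean) maps both
#' into atlas space. Each scan's transform chain is returned: the baseline
#' chain is `[shared9]`, the final chain `[shared9, pair6]`.
#'
#' @param base_img,final_img Baseline and final sum images ([image3()]).
#' @param atlas_target The smoothed mask (or template) in atlas space.
#' @return List with `pair6` (final-to-baseline 6-df), `shared9`, and
#'   per-scan transform chains `chain_baseline`, `chain_final`.
#' @export
within_subject_align <- function(base_img, final_img, atlas_target,
                                 maxit = c(600, 400)) {
  p0 <- coarse_align(final_img, base_img,
                     shift_range_mm = 2, shift_step_mm = 1,
                     rot_range_deg = 2, rot_step_deg = 1, downsample = 2L)
  pair6 <- fine_align(final_img, base_img, df = 6, init = p0, maxit = maxit)
  final_in_base <- resample_to(final_img, compose_chain(pair6), base_img)
  pair_mean <- image3((base_img$voxels + final_in_base$voxels) / 2,
                      base_img$voxel_size, base_img$origin)
  shared9 <- align_scan(pair_mean, atlas_target, maxit = maxit)
  list(pair6 = pair6, shared9 = shared9,
       chain_baseline = list(shared9),
       chain_final = list(shared9, pair6))
}

#' Build a study template from atlas-space images
#'
#' Voxel-wise mean of already-aligned images, polished by one 9-df alignment
#' of the mean to the smoothed mask; the fine alignment can then be repeated
#' per scan against the template as a second-pass refinement.
#'
#' @param aligned_images List of [image3()] on a common atlas grid.
#' @param mask Optional [make_smoothed_mask()] target for the 9-df polish
#'   (skipped when `NULL`).
#' @return A [image3()] template.
#' @export
build_template <- function(aligned_images, mask = NULL,
                           maxit = c(600, 400)) {
  stopifnot(length(aligned_images) >= 1)
  ref <- aligned_images[[1]]
  acc <- Reduce(`+`, lapply(aligned_images, function(im) im$voxels))
  tmpl <- image3(acc / length(aligned_images), ref$voxel_size, ref$origin)
  if (!is.null(mask)) {
    p9 <- fine_align(tmpl, mask, df = 9,
                     init = affine_params(center = grid_center(mask), df = 9L),
                     maxit = maxit)
    tmpl <- resample_to(tmpl, compose_chain(p9), mask)
  }
  tmpl
}

#' Refine a scan's atlas transform against the study template
#'
#' Second-pass fine alignment: re-optimizes the shared 9-df transform with
#' the template as the target, holding any within-subject pair transform
#' fixed. First-pass and refined transforms are both retained by the caller.
#'
#' @param moving Scanner-space sum image.
#' @param template Study template ([build_template()]).
#' @param shared9 First-pass 9-df transform.
#' @param pair6 Optional pair transform (for final scans).
#' @return Refined 9-df [affine_params()].
#' @export
refine_to_template <- function(moving, template, shared9, pair6 = NULL,
                               maxit = c(600, 400)) {
  pre <- if (is.null(pair6)) NULL else affine_matrix(pair6)
  fine_align(moving, template, df = 9, init = shared9, pre_matrix = pre,
             maxit = maxit)
}

#' Resample a 3D image through an affine matrix onto a target grid
#'
#' @param img Moving [image3()].
#' @param M 4x4 matrix (or [affine_params()]) mapping target world
#'   coordinates to moving coordinates.
#' @param grid Object carrying the target geometry (`voxels` dim,
#'   `voxel_size`, `origin`).
#' @return A [image3()] on the target grid.
#' @export
resample_to <- function(img, M, grid) {
  M <- affine_matrix(M)
  d3 <- dim(grid$voxels)[1:3]
  vals <- sample_trilinear(img, apply_affine(M, grid_points(grid)))
  image3(array(vals, d3), grid$voxel_size, grid$origin)
}

#' Resample a dynamic image into atlas space
#'
#' Composes the transform chain into a single matrix and resamples every
#' frame with one trilinear interpolation (never stage by stage, to avoid
#' cumulative blurring).
#'
#' @param img A [dyn_image()] in scanner space.
#' @param chain List of [affine_params()]/matrices (see [compose_chain()]).
#' @param grid Target (atlas) geometry.
#' @return A [dyn_image()] on the target grid.
#' @export
resample_4d <- function(img, chain, grid) {
  M <- compose_chain(chain)
  d3 <- dim(grid$voxels)[1:3]
  pts <- apply_affine(M, grid_points(grid))
  nfr <- dim(img$voxels)[4]
  out <- array(0, c(d3, nfr))
  frame <- image3(img$voxels[, , , 1], img$voxel_size, img$origin)
  for (f in seq_len(nfr)) {
    frame$voxels <- img$voxels[, , , f]
    out[, , , f] <- sample_trilinear(frame, pts)
  }
  dyn_image(out, grid$voxel_size, img$schedule, grid$origin,
            decay_corrected = img$decay_corrected)
}
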