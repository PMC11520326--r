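#' Uniform frame schedule
#'
#' @param total_min Total scan duration in minutes (> 0).
#' @param frame_min Frame duration in minutes (> 0). If `total_min` is not a
#'   multiple, the schedule is truncated to whole frames with a warning.
#' @return An object of class `frame_schedule` with element `frames`, a
#'   data.frame of `start`/`end` minutes relative to scan start.
#' @export
make_frame_schedule <- function(total_min = 90, frame_min = 1) {
  stopifnot(frame_min > 0)
  n <- floor(total_min / frame_min + 1e-9)
  if (n < 1) stop("schedule would be empty: total_min shorter than one frame")
  if (abs(n * frame_min - total_min) > 1e-9)
    warning(sprintf("total %g min not divisible by %g min frames; truncating to %d frames",
                    total_min, frame_min, n))
  frame_schedule(data.frame(start = (seq_len(n) - 1) * frame_min,
                            end = seq_len(n) * frame_min))
}

#' Frame schedule from explicit start/end times
#'
#' @param frames data.frame with `start` and `end` columns in minutes;
#'   must be contiguous, non-overlapping, strictly increasing.
#' @return A `frame_schedule` object.
#' @export
frame_schedule <- function(frames) {
  stopifnot(is.data.frame(frames), all(c("start", "end") %in% names(frames)))
  if (nrow(frames) == 0) stop("schedule would be empty")
  if (any(frames$end <= frames$start)) stop("frame durations must be > 0")
  if (nrow(frames) > 1 &&
      any(abs(frames$start[-1] - frames$end[-nrow(frames)]) > 1e-9))
    stop("frames must be contiguous and non-overlapping")
  structure(list(frames = frames), class = "frame_schedule")
}

frame_durations <- function(fs) fs$frames$end - fs$frames$start
frame_midpoints <- function(fs) (fs$frames$start + fs$frames$end) / 2

#' Kinetic parameters of the uptake model
#'
#' The plateau model `C(t) = A (1 - exp(-t / tau))` captures FDG's rapid
#' uptake after bolus injection and sustained (irreversibly trapped)
#' radioactivity for the rest of the scan.
#'
#' @param amplitude Plateau amplitude A in Bq/mL (>= 0).
#' @param tau Rise time constant in minutes (> 0).
#' @param model Currently only `"plateau"`.
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(amplitude, tau = 5, model = "plateau") {
  stopifnot(amplitude >= 0, tau > 0, model == "plateau")
  structure(list(amplitude = amplitude, tau = tau, model = model),
            class = "kinetic_params")
}

## exact mean of (1 - exp(-t/tau)) over [t1, t2]
plateau_frame_mean <- function(t1, t2, tau) {
  if (tau < 1e-12) return(rep(1, length(t1)))
  1 - tau * (exp(-t1 / tau) - exp(-t2 / tau)) / (t2 - t1)
}

#' Simulate a time-activity curve
#'
#' Integrates the plateau model analytically over each frame, returning the
#' frame-mean concentration (what a reconstructed frame reports).
#'
#' @param kp [kinetic_params()].
#' @param fs [frame_schedule()].
#' @return Numeric vector of per-frame mean concentrations (Bq/mL),
#'   monotone non-decreasing.
#' @export
simulate_tac <- function(kp, fs) {
  kp$amplitude * plateau_frame_mean(fs$frames$start, fs$frames$end, kp$tau)
}

## Brain outline: additive ellipsoids (cerebrum, lateral temporal bulges,
## cerebellum, brainstem, olfactory bulb; x = anterior-posterior) minus
## carved fissures (longitudinal, transverse, rhinal), clipped by a flat
## ventral plane. The bumps, grooves and flat base are what make all three
## rotations well determined when aligning a resolution-blurred brain edge
## to the smoothed mask; a single smooth ellipsoid leaves rotation about its
## long axis almost unconstrained.
brain_components <- function() {
  list(list(center = c(2.0, 0, 0.8), semi = c(8.0, 7.0, 5.2)),
       list(center = c(3.0, -5.3, -1.8), semi = c(4.5, 3.4, 3.0)),
       list(center = c(3.0, 5.3, -1.8), semi = c(4.5, 3.4, 3.0)),
       list(center = c(-7.8, 0, 0.6), semi = c(4.4, 5.4, 3.9)),
       list(center = c(-9.5, 0, -2.8), semi = c(3.6, 2.6, 2.1)),
       list(center = c(10.8, 0, -1.6), semi = c(3.1, 2.4, 2.1)))
}
brain_carves <- function() {
  list(list(center = c(2.0, 0, 6.6), semi = c(6.5, 1.8, 3.4)),
       list(center = c(-3.6, 0, 5.2), semi = c(1.4, 7.0, 2.4)),
       list(center = c(3.0, -7.2, 1.2), semi = c(5.5, 2.0, 1.6)),
       list(center = c(3.0, 7.2, 1.2), semi = c(5.5, 2.0, 1.6)))
}
VENTRAL_FLOOR_MM <- -5.0
## nominal whole-brain volume of the default outline (mm^3), used when no
## voxelized atlas is supplied
NOMINAL_BRAIN_VOLUME_MM3 <- 1735

#' Generate a digital rat-brain label phantom
#'
#' A rat-brain-like outline (cerebrum, cerebellar/brainstem bulge, olfactory
#' bulb, flat ventral surface; label 1 = rest-of-brain tissue) containing
#' non-overlapping labelled blobs for the a-priori regions. Each region
#' receives exactly `round(volume / voxel volume)` voxels (the nearest
#' voxels to its center), so requested volumes are achieved to within half a
#' voxel; the default region table has a median volume of 6 mm^3.
#'
#' @param voxel_mm Isotropic voxel size in mm (default 0.5).
#' @param regions Region table with `name`, `group`, `volume_mm3` columns
#'   (default [default_region_set()] volumes).
#' @param margin_mm Empty margin around the brain (keeps PSF mass inside the
#'   field of view).
#' @param seed Integer seed controlling blob placement (same seed, same
#'   volume, bit for bit).
#' @return A [label_volume()]; label 1 is `Brain (rest)`, regions get
#'   labels 2, 3, ... in table order.
#' @export
make_label_phantom <- function(voxel_mm = 0.5, regions = region_defaults(),
                               margin_mm = 4.5, seed = 1) {
  stopifnot(nrow(regions) >= 1, all(regions$volume_mm3 > 0))
  set.seed(seed)
  comps <- brain_components()
  carves <- brain_carves()
  lo <- apply(vapply(comps, function(e) e$center - e$semi, numeric(3)), 1, min)
  hi <- apply(vapply(comps, function(e) e$center + e$semi, numeric(3)), 1, max)
  lo <- lo - margin_mm; hi <- hi + margin_mm
  d <- ceiling((hi - lo) / voxel_mm)
  d <- d + (d %% 2 == 0)  # odd dims: a voxel center sits on the midline
  origin <- (lo + hi) / 2 - (d - 1) / 2 * voxel_mm
  xs <- origin[1] + (seq_len(d[1]) - 1) * voxel_mm
  ys <- origin[2] + (seq_len(d[2]) - 1) * voxel_mm
  zs <- origin[3] + (seq_len(d[3]) - 1) * voxel_mm
  vox <- array(0L, d)
  E2_of <- function(e)
    outer(outer(((xs - e$center[1]) / e$semi[1])^2,
                ((ys - e$center[2]) / e$semi[2])^2, "+"),
          ((zs - e$center[3]) / e$semi[3])^2, "+")
  for (e in comps) vox[E2_of(e) <= 1] <- 1L
  for (e in carves) vox[E2_of(e) <= 1] <- 0L
  vox[, , zs < VENTRAL_FLOOR_MM] <- 0L

  vv <- voxel_mm^3
  radii <- (3 * regions$volume_mm3 / (4 * pi))^(1 / 3)
  vol_w <- vapply(comps, function(e) prod(e$semi), numeric(1))
  inside_shrunk <- function(cand, r) {
    if (cand[3] - r - 0.5 < VENTRAL_FLOOR_MM) return(FALSE)
    for (e in carves) {
      s <- e$semi + r + 0.5
      if (sum(((cand - e$center) / s)^2) <= 1) return(FALSE)
    }
    for (e in comps) {
      s <- e$semi - r - 1.0
      if (all(s > 0) && sum(((cand - e$center) / s)^2) <= 1) return(TRUE)
    }
    FALSE
  }
  place_all <- function(spacing_mm) {
    ord <- order(regions$volume_mm3, decreasing = TRUE)  # big blobs first
    centers <- matrix(NA_real_, nrow(regions), 3)
    for (i in ord) {
      ok <- FALSE
      for (try in 1:20000) {
        e <- comps[[sample.int(length(comps), 1, prob = vol_w)]]
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) > 1) next
        cand <- e$center + u * pmax(e$semi - radii[i] - 1.0, 0)
        if (!inside_shrunk(cand, radii[i])) next
        placed <- which(!is.na(centers[, 1]))
        if (length(placed)) {
          dd <- sqrt(colSums((t(centers[placed, , drop = FALSE]) - cand)^2))
          if (any(dd < radii[placed] + radii[i] + spacing_mm)) next
        }
        centers[i, ] <- cand
        ok <- TRUE
        break
      }
      if (!ok) return(NULL)
    }
    centers
  }
  ## greedy packing can dead-end for some seeds: retry deterministically with
  ## a re-seeded draw, relaxing the inter-blob spacing on late attempts
  centers <- NULL
  for (attempt in 1:12) {
    set.seed(seed + 7919L * (attempt - 1L))
    centers <- place_all(spacing_mm = if (attempt <= 6) 0.8 else 0.5)
    if (!is.null(centers)) break
  }
  if (is.null(centers))
    stop("could not place all regions; reduce volumes or enlarge the brain")

  for (i in seq_len(nrow(regions))) {
    k <- max(1L, round(regions$volume_mm3[i] / vv))
    r <- radii[i] + 2 * voxel_mm
    ix <- which(abs(xs - centers[i, 1]) <= r)
    iy <- which(abs(ys - centers[i, 2]) <= r)
    iz <- which(abs(zs - centers[i, 3]) <= r)
    sub <- as.matrix(expand.grid(ix, iy, iz))
    free <- vox[sub] == 1L
    sub <- sub[free, , drop = FALSE]
    if (nrow(sub) < k) stop("not enough free voxels for region '",
                            regions$name[i], "'")
    d2 <- (xs[sub[, 1]] - centers[i, 1])^2 +
          (ys[sub[, 2]] - centers[i, 2])^2 +
          (zs[sub[, 3]] - centers[i, 3])^2
    take <- sub[order(d2)[seq_len(k)], , drop = FALSE]
    vox[take] <- i + 1L
  }

  labels <- data.frame(id = c(1L, seq_len(nrow(regions)) + 1L),
                       name = c("Brain (rest)", regions$name),
                       group = c(NA_character_, regions$group),
                       stringsAsFactors = FALSE)
  label_volume(vox, rep(voxel_mm, 3), labels, origin)
}

#' Cohort design mirroring the study layout
#'
#' Two overlapping age groups, 12 knockout (KO) and 14 wild-type (WT)
#' subjects, baseline and final timepoints about 6 weeks apart, with the
#' study's missing cells: the younger group has no WT baseline scans, one
#' younger KO lacks a baseline, and one older WT lacks a final scan. The
#' default yields 43 scans (23 KO, 20 WT).
#'
#' @param n_ko,n_wt Subjects per genotype (defaults 12 and 14).
#' @param missing_cells `"table1"` for the study layout or `"none"` for a
#'   complete two-by-two design.
#' @return data.frame with one row per subject: `subject`, `genotype`,
#'   `group`, `has_baseline`, `has_final`.
#' @export
cohort_design <- function(n_ko = 12, n_wt = 14, missing_cells = "table1") {
  subj <- data.frame(
    subject = c(sprintf("KO%02d", seq_len(n_ko)),
                sprintf("WT%02d", seq_len(n_wt))),
    genotype = c(rep("KO", n_ko), rep("WT", n_wt)),
    stringsAsFactors = FALSE)
  subj$group <- 2L
  subj$has_baseline <- TRUE
  subj$has_final <- TRUE
  if (missing_cells == "table1" && n_ko == 12 && n_wt == 14) {
    ## younger group: KO 1-8 (one missing baseline), WT 1-7 (no baselines)
    subj$group[c(1:8, n_ko + 1:7)] <- 1L
    subj$has_baseline[8] <- FALSE
    subj$has_baseline[n_ko + 1:7] <- FALSE
    subj$has_final[n_ko + 14] <- FALSE  # one older WT missing final
  }
  subj
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces per-scan records (injected activity, body weight), true poses
#' (atlas-to-scanner affine transforms; baseline and final share the subject
#' pose up to a small motion perturbation), and true regional SUVr levels per
#' genotype. The rest-of-brain level is solved so that the volume-weighted
#' whole-brain mean of the regional levels is exactly 1 for each genotype.
#'
#' @param design See [cohort_design()].
#' @param atlas Optional [label_volume()] phantom; when given, the actual
#'   voxelized region volumes are used for the whole-brain constraint (so
#'   measured noise-free SUVr equals the truth exactly).
#' @param effects Region table with `name`, `volume_mm3`, `suvr_wt`,
#'   `suvr_ko` (default the built-in Table of a-priori regions with the four
#'   default genotype effects).
#' @param effect_scale Scales the KO log-ratios; 0 gives a null cohort
#'   (all genotype multipliers 1).
#' @param max_shift_mm,max_rot_deg Half-ranges of the uniform true pose
#'   distributions.
#' @param scale_mean Named per-genotype mean axis scale (defaults reproduce
#'   the reported volume products: WT 1.08^(1/3), KO 1.03^(1/3)).
#' @param scale_sd Per-axis SD of true scales.
#' @param motion_sd_mm,motion_sd_deg Within-subject baseline-to-final motion.
#' @param suv_wb_mean Named per-genotype/timepoint whole-brain SUV means
#'   (g/mL); defaults to the reported 1.73/1.73/1.53/1.64.
#' @param suvr_between_sd,suvr_within_sd Relative SDs of the tabular SUVr
#'   observation model (subject-level and scan-level).
#' @param noise_sd_frac Image-noise fraction used by [render_scan()].
#' @param seed Integer seed; everything is reproducible from (design, seed).
#' @return A `phantom_cohort` object: list with `records` (one row per scan),
#'   `subjects`, `truth` (poses, region levels, noise settings, seed).
#' @export
generate_cohort <- function(design = cohort_design(), atlas = NULL,
                            effects = region_defaults(), effect_scale = 1,
                            max_shift_mm = 3, max_rot_deg = 5,
                            scale_mean = c(WT = 1.08^(1 / 3), KO = 1.03^(1 / 3)),
                            scale_sd = 0.015,
                            motion_sd_mm = 0.3, motion_sd_deg = 0.5,
                            suv_wb_mean = c(WT.baseline = 1.73, WT.final = 1.73,
                                            KO.baseline = 1.53, KO.final = 1.64),
                            suvr_between_sd = 0.035, suvr_within_sd = 0.025,
                            noise_sd_frac = 0.05, seed = 1) {
  set.seed(seed)
  eff <- effects
  eff$suvr_ko <- eff$suvr_wt * exp(effect_scale * log(eff$suvr_ko / eff$suvr_wt))

  ## region levels incl. rest-of-brain, per genotype
  if (!is.null(atlas)) {
    rv <- region_volumes(atlas)
    vols <- rv$volume_mm3[match(eff$name, rv$name)]
    v_rest <- rv$volume_mm3[match("Brain (rest)", rv$name)]
    if (anyNA(vols) || is.na(v_rest))
      stop("atlas labels do not match the effects table")
  } else {
    vols <- eff$volume_mm3
    v_rest <- NOMINAL_BRAIN_VOLUME_MM3 - sum(vols)
  }
  rest_level <- function(s) (sum(vols) + v_rest - sum(vols * s)) / v_rest
  levels_tab <- data.frame(name = c("Brain (rest)", eff$name),
                           suvr_wt = c(rest_level(eff$suvr_wt), eff$suvr_wt),
                           suvr_ko = c(rest_level(eff$suvr_ko), eff$suvr_ko),
                           stringsAsFactors = FALSE)

  ## subject poses and per-scan records
  rows <- list(); poses <- list()
  center <- if (!is.null(atlas)) grid_center(atlas) else c(0, 0, 0)
  for (i in seq_len(nrow(design))) {
    g <- design$genotype[i]
    base_t <- stats::runif(3, -max_shift_mm, max_shift_mm)
    base_r <- stats::runif(3, -max_rot_deg, max_rot_deg)
    base_s <- rnorm_trunc(3, scale_mean[[g]], scale_sd, 0.9, 1.15)
    wb_b <- exp(stats::rnorm(1, 0, 0.20))  # subject-level ADME variation
    for (tp in c("baseline", "final")) {
      if (tp == "baseline" && !design$has_baseline[i]) next
      if (tp == "final" && !design$has_final[i]) next
      if (tp == "baseline") {
        p <- affine_params(base_t, base_r, base_s, center = center, df = 9L)
      } else {
        p <- affine_params(base_t + stats::rnorm(3, 0, motion_sd_mm),
                           base_r + stats::rnorm(3, 0, motion_sd_deg),
                           base_s, center = center, df = 9L)
      }
      sid <- sprintf("%s_%s", design$subject[i], tp)
      poses[[sid]] <- p
      rows[[sid]] <- data.frame(
        scan_id = sid, subject = design$subject[i], genotype = g,
        timepoint = tp, group = design$group[i],
        injected_activity_bq = rnorm_trunc(1, 21.5e6, 7.0e6, 5e6, 45e6),
        body_weight_g = rnorm_trunc(1, 530, 40, 400, 700),
        injection_offset_min = stats::runif(1, 0, 3),
        suv_wb_true = suv_wb_mean[[paste(g, tp, sep = ".")]] * wb_b *
          exp(stats::rnorm(1, 0, 0.08)),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  structure(list(records = records, subjects = design,
                 truth = list(poses = poses, levels = levels_tab,
                              effects = eff, tau_min = 5,
                              suvr_between_sd = suvr_between_sd,
                              suvr_within_sd = suvr_within_sd,
                              noise_sd_frac = noise_sd_frac,
                              center = center, seed = seed)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d scans from %d subjects (%d KO, %d WT), seed %d\n",
              nrow(x$records), nrow(x$subjects),
              sum(x$subjects$genotype == "KO"),
              sum(x$subjects$genotype == "WT"), x$truth$seed))
  invisible(x)
}

## per-label window-referenced TAC levels for one scan
scan_label_levels <- function(cohort, rec) {
  lv <- cohort$truth$levels
  s <- if (rec$genotype == "KO") lv$suvr_ko else lv$suvr_wt
  names(s) <- lv$name
  s
}

#' Render one dynamic scan of the phantom
#'
#' Paints the region-wise plateau TACs into the label map, applies the true
#' pose (atlas-to-scanner affine), convolves each frame with the scanner PSF,
#' and adds zero-mean Gaussian noise with sd = `noise_sd_frac` x local mean /
#' sqrt(frame duration in min). The phantom emits decay-corrected
#' concentrations referenced to scan start.
#'
#' @param atlas The [label_volume()] used to build the cohort.
#' @param cohort A `phantom_cohort`.
#' @param scan_id Which scan to render.
#' @param fs [frame_schedule()] (default 90 x 1 min).
#' @param psf_fwhm_mm Scanner point-spread FWHM in mm (default 2; 0 disables).
#' @param noise_sd_frac Noise fraction (default from the cohort truth;
#'   0 disables).
#' @param grid Target scanner grid geometry as a [image3()]-like object
#'   (default: the atlas grid).
#' @param supersample Sub-voxel sampling factor per axis when painting the
#'   transformed label map (default 2). Averaging the painted values over
#'   sub-voxel positions antialiases region edges — a voxel-quantized edge
#'   otherwise imprints a grid-aligned staircase on the image that biases
#'   weakly-constrained registration parameters.
#' @param noise_model `"gaussian"` (default): zero-mean Gaussian with
#'   sd = `noise_sd_frac` x local mean / sqrt(frame min). `"poisson"`:
#'   scaled Poisson counts calibrated so the relative sd at the mean brain
#'   concentration of a 1-min frame equals `noise_sd_frac`.
#' @param seed Optional integer seed for the noise draw.
#' @return A [dyn_image()] in scanner space.
#' @export
render_scan <- function(atlas, cohort, scan_id, fs = make_frame_schedule(90, 1),
                        psf_fwhm_mm = 2, noise_sd_frac = NULL, grid = atlas,
                        supersample = 2L, noise_model = c("gaussian", "poisson"),
                        seed = NULL) {
  noise_model <- match.arg(noise_model)
  rec <- cohort$records[cohort$records$scan_id == scan_id, ]
  if (nrow(rec) != 1) stop("unknown scan_id: ", scan_id)
  if (is.null(noise_sd_frac)) noise_sd_frac <- cohort$truth$noise_sd_frac
  if (!is.null(seed)) set.seed(seed)

  tau <- cohort$truth$tau_min
  shape <- plateau_frame_mean(fs$frames$start, fs$frames$end, tau)
  win_mean <- plateau_frame_mean(30, 60, tau)
  amp <- rec$suv_wb_true * (rec$injected_activity_bq / rec$body_weight_g) /
    win_mean
  s <- scan_label_levels(cohort, rec)
  lev <- c(0, s[atlas$labels$name])          # index = label id + 1
  lev_ids <- c(0L, atlas$labels$id)

  M_inv <- affine_invert(cohort$truth$poses[[scan_id]])
  d3 <- dim(grid$voxels)[1:3]
  ss <- max(1L, as.integer(supersample))
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss
  lev_map <- 0
  base_pts <- grid_points(grid)
  for (ox in sub) for (oy in sub) for (oz in sub) {
    pts <- base_pts
    pts[, 1] <- pts[, 1] + ox * grid$voxel_size[1]
    pts[, 2] <- pts[, 2] + oy * grid$voxel_size[2]
    pts[, 3] <- pts[, 3] + oz * grid$voxel_size[3]
    labmap <- sample_nearest(atlas, apply_affine(M_inv, pts))
    lev_map <- lev_map + lev[match(labmap, lev_ids)]
  }
  lev_map <- lev_map / ss^3

  nfr <- nrow(fs$frames)
  out <- array(0, c(d3, nfr))
  sigma <- psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  durs <- frame_durations(fs)
  base <- array(lev_map * amp, d3)
  base_img <- image3(base, grid$voxel_size, grid$origin)
  if (psf_fwhm_mm > 0) base_img <- smooth_gaussian(base_img, sigma)
  cal <- if (noise_sd_frac > 0 && noise_model == "poisson") {
    cbar <- mean(base_img$voxels[base_img$voxels > 0])
    1 / (noise_sd_frac^2 * cbar)  # counts per (Bq/mL x min)
  } else NA_real_
  for (f in seq_len(nfr)) {
    arr <- base_img$voxels * shape[f]
    if (noise_sd_frac > 0) {
      if (noise_model == "gaussian") {
        arr <- arr + stats::rnorm(length(arr), 0,
                                  noise_sd_frac * pmax(arr, 0) / sqrt(durs[f]))
      } else {
        lam <- pmax(arr, 0) * durs[f] * cal
        arr <- stats::rpois(length(lam), lam) / (durs[f] * cal)
      }
    }
    out[, , , f] <- arr
  }
  dyn_image(out, grid$voxel_size, fs, grid$origin, decay_corrected = TRUE)
}

#' Draw an observed regional uptake table from the cohort truth
#'
#' The tabular observation model: for each scan and region,
#' `SUVr_obs = level * (1 + b + e)` with a subject-by-region random effect
#' `b ~ N(0, suvr_between_sd)` shared across timepoints and scan-level noise
#' `e ~ N(0, suvr_within_sd)`; the whole-brain row is identically 1 and
#' `SUV = SUVr * whole-brain SUV`. This is the desk-scale stand-in for
#' rendering, registering and quantifying every scan, used for replicate
#' inference studies; the image route is exercised separately.
#'
#' @param cohort A `phantom_cohort`.
#' @param seed Optional integer seed.
#' @return An uptake table (data.frame): `scan_id`, `subject`, `genotype`,
#'   `timepoint`, `region`, `suv`, `suvr`.
#' @export
simulate_uptake <- function(cohort, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lv <- cohort$truth$levels
  regions <- lv$name[lv$name != "Brain (rest)"]
  sb <- cohort$truth$suvr_between_sd
  sw <- cohort$truth$suvr_within_sd
  subs <- unique(cohort$records$subject)
  b <- matrix(stats::rnorm(length(subs) * length(regions), 0, sb),
              length(subs), length(regions),
              dimnames = list(subs, regions))
  out <- list()
  for (i in seq_len(nrow(cohort$records))) {
    rec <- cohort$records[i, ]
    s <- scan_label_levels(cohort, rec)[regions]
    suvr <- s * (1 + b[rec$subject, ] + stats::rnorm(length(regions), 0, sw))
    out[[i]] <- data.frame(
      scan_id = rec$scan_id, subject = rec$subject,
      genotype = rec$genotype, timepoint = rec$timepoint,
      region = c("Whole brain", regions),
      suv = rec$suv_wb_true * c(1, suvr),
      suvr = c(1, suvr), stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Generate a synthetic behavioral table
#'
#' Per subject and timepoint draws for each measure: cell mean + subject
#' random intercept + residual. Default cell means and standard errors come
#' from the built-in 23-measure catalogue (ultrasonic vocalization, tapered
#' balance beam, cylinder test, 5-choice serial reaction time task); the
#' total SD is derived from the printed LS-mean SE as `SE * sqrt(n)` and
#' split between subject and residual variance by `icc`.
#'
#' @param design See [cohort_design()].
#' @param measures Optional character vector restricting the measures.
#' @param icc Fraction of variance assigned to the subject intercept.
#' @param noise_scale Scales all SDs; 0 gives exact cell means.
#' @param seed Integer seed.
#' @return data.frame: `subject`, `genotype`, `timepoint`, `assay`,
#'   `measure`, `unit`, `value`.
#' @export
generate_behavior <- function(design = cohort_design(), measures = NULL,
                              icc = 0.5, noise_scale = 1, seed = 1) {
  set.seed(seed)
  cat_tab <- behavior_defaults()
  if (!is.null(measures)) {
    cat_tab <- cat_tab[cat_tab$measure %in% measures, , drop = FALSE]
    if (nrow(cat_tab) == 0) stop("no matching measures")
  }
  n_g <- table(design$genotype)
  out <- list()
  for (m in seq_len(nrow(cat_tab))) {
    row <- cat_tab[m, ]
    for (i in seq_len(nrow(design))) {
      g <- tolower(design$genotype[i])
      sd_tot <- row[[paste0("se_", g, "_baseline")]] *
        sqrt(n_g[[design$genotype[i]]])
      b <- stats::rnorm(1, 0, sqrt(icc) * sd_tot * noise_scale)
      for (tp in c("baseline", "final")) {
        mu <- row[[paste0("mean_", g, "_", tp)]]
        sd_e <- row[[paste0("se_", g, "_", tp)]] *
          sqrt(n_g[[design$genotype[i]]]) * sqrt(1 - icc)
        out[[length(out) + 1]] <- data.frame(
          subject = design$subject[i], genotype = design$genotype[i],
          timepoint = tp, assay = row$assay, measure = row$measure,
          unit = row$unit,
          value = mu + b + stats::rnorm(1, 0, sd_e * noise_scale),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' The built-in behavioral measure catalogue
#'
#' @return data.frame of 23 measures with assay, unit, and per-cell LS means
#'   and SEs used as generator defaults.
#' @export
behavior_defaults <- function() {
  read.csv(system.file("extdata", "behavior_defaults.csv",
                       package = "fdgpet"),
           check.names = TRUE, stringsAsFactors = FALSE)
}
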