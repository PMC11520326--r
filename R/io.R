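## NIfTI-1 I/O. Frame schedules travel as JSON sidecars (start/end minutes)
## rather than NIfTI time-axis metadata, which is unreliable across tools.

axis_aligned_xform <- function(voxel_size, origin) {
  M <- diag(4)
  M[1:3, 1:3] <- diag(voxel_size)
  M[1:3, 4] <- origin
  M
}

check_axis_aligned <- function(M) {
  R <- M[1:3, 1:3]
  if (max(abs(R - diag(diag(R)))) > 1e-4 || any(diag(R) <= 0))
    stop("only axis-aligned NIfTI orientations with positive scales are supported")
}

#' Write a 3D image or label volume as NIfTI-1
#'
#' @param img [image3()] / [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti3 <- function(img, path) {
  arr <- img$voxels
  nim <- RNifti::asNifti(arr * 1.0)
  nim <- RNifti::`sform<-`(nim, structure(axis_aligned_xform(img$voxel_size,
                                                             img$origin),
                                          code = 2L))
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path NIfTI file.
#' @return A [image3()].
#' @export
read_nifti3 <- function(path) {
  nim <- RNifti::readNifti(path)
  M <- RNifti::xform(nim)
  check_axis_aligned(M)
  image3(as.array(nim), diag(M)[1:3], M[1:3, 4])
}

#' Write a dynamic image with its frame-schedule sidecar
#'
#' @param img [dyn_image()].
#' @param path Output `.nii`/`.nii.gz`; the sidecar is written next to it
#'   with extension `.frames.json`.
#' @return `path`, invisibly.
#' @export
write_dynamic_nifti <- function(img, path) {
  nim <- RNifti::asNifti(img$voxels * 1.0)
  nim <- RNifti::`sform<-`(nim, structure(axis_aligned_xform(img$voxel_size,
                                                             img$origin),
                                          code = 2L))
  RNifti::writeNifti(nim, path)
  jsonlite::write_json(list(frames = img$schedule$frames,
                            decay_corrected = img$decay_corrected,
                            units = "Bq/mL"),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".frames.json", path)

#' Read a dynamic NIfTI-1 image and its frame-schedule sidecar
#'
#' @param path 4D NIfTI file.
#' @param sidecar Path to the frame-schedule JSON (default: derived from
#'   `path`).
#' @return A [dyn_image()].
#' @export
read_dynamic_nifti <- function(path, sidecar = sidecar_path(path)) {
  nim <- RNifti::readNifti(path)
  arr <- as.array(nim)
  if (length(dim(arr)) != 4) stop("expected a 4D NIfTI image")
  M <- RNifti::xform(nim)
  check_axis_aligned(M)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  fr <- as.data.frame(side$frames)
  if (nrow(fr) != dim(arr)[4])
    stop(sprintf("frame count mismatch: image has %d frames, sidecar lists %d",
                 dim(arr)[4], nrow(fr)))
  dyn_image(arr, diag(M)[1:3], frame_schedule(fr), M[1:3, 4],
            decay_corrected = isTRUE(side$decay_corrected))
}

#' Serialize affine transforms as JSON
#'
#' Writes the parameters plus the composed 4x4 row-major matrix.
#'
#' @param chain [affine_params()] or a list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(chain, path) {
  if (inherits(chain, "affine_params")) chain <- list(chain)
  jsonlite::write_json(list(
    members = lapply(chain, function(p)
      list(translation_mm = p$translation, rotation_deg = p$rotation_deg,
           scale = p$scale, center_mm = p$center, df = p$df)),
    composed_matrix_row_major = as.vector(t(compose_chain(chain)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read affine transforms from JSON
#'
#' @param path JSON written by [write_transform_json()].
#' @return List of [affine_params()].
#' @export
read_transform_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(js$members)), function(i) {
    m <- js$members[i, ]
    affine_params(unlist(m$translation_mm), unlist(m$rotation_deg),
                  unlist(m$scale), unlist(m$center_mm), m$df)
  })
}

#' Run the end-to-end pipeline on a phantom cohort
#'
#' Simulates a cohort, renders and aligns each scan (coarse + fine 6/9 df to
#' the smoothed mask, within-subject pairing when both timepoints exist,
#' then one template refinement pass), resamples the dynamic images into
#' atlas space, computes the regional uptake table, and fits the
#' genotype-by-time model per a-priori region. Deterministic given
#' (`config`, `config$seed`); stage parameters and outputs are written under
#' `config$out_dir` when it is non-NULL.
#'
#' @param config List: `seed`, `out_dir` (NULL to skip writing), `voxel_mm`,
#'   `n_ko`, `n_wt`, `window` (c(30, 60)), `sigma_mask_mm` (0.85),
#'   `psf_fwhm_mm` (2), `noise_sd_frac`, `n_frames`, `frame_min`,
#'   `template_pass` (TRUE), `stats` (TRUE), `maxit` (optimizer budget per
#'   resolution level, c(600, 400)). Missing entries take these defaults.
#' @return List: `atlas`, `mask`, `cohort`, `transforms`, `uptake`,
#'   `suvr_models`, `scale_summary`, and (if written) `paths`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    seed = 1, out_dir = NULL, voxel_mm = 0.6, n_ko = 12, n_wt = 14,
    missing_cells = "table1", window = c(30, 60), sigma_mask_mm = 0.85,
    psf_fwhm_mm = 2, noise_sd_frac = NULL, n_frames = 18, frame_min = 5,
    template_pass = TRUE, stats = TRUE, maxit = c(600, 400)), config)
  seed <- as.integer(cfg$seed)

  atlas <- make_label_phantom(voxel_mm = cfg$voxel_mm, seed = seed)
  mask <- make_smoothed_mask(atlas, cfg$sigma_mask_mm)
  design <- cohort_design(cfg$n_ko, cfg$n_wt, cfg$missing_cells)
  cohort <- generate_cohort(design, atlas = atlas,
                            noise_sd_frac = if (is.null(cfg$noise_sd_frac))
                              0.05 else cfg$noise_sd_frac,
                            seed = seed + 1L)
  fs <- make_frame_schedule(cfg$n_frames * cfg$frame_min, cfg$frame_min)

  recs <- cohort$records
  sums <- list(); dyns <- list()
  for (i in seq_len(nrow(recs))) {
    dyns[[recs$scan_id[i]]] <- render_scan(
      atlas, cohort, recs$scan_id[i], fs = fs,
      psf_fwhm_mm = cfg$psf_fwhm_mm, seed = seed + 100L + i)
    sums[[recs$scan_id[i]]] <- sum_image(dyns[[recs$scan_id[i]]], cfg$window)
  }

  transforms <- list()
  for (s in unique(recs$subject)) {
    ids <- recs$scan_id[recs$subject == s]
    tps <- recs$timepoint[recs$subject == s]
    if (length(ids) == 2) {
      bid <- ids[tps == "baseline"]; fid <- ids[tps == "final"]
      wa <- within_subject_align(sums[[bid]], sums[[fid]], mask,
                                 maxit = cfg$maxit)
      transforms[[bid]] <- wa$chain_baseline
      transforms[[fid]] <- wa$chain_final
    } else {
      transforms[[ids]] <- list(align_scan(sums[[ids]], mask,
                                           maxit = cfg$maxit))
    }
  }

  if (isTRUE(cfg$template_pass)) {
    aligned <- lapply(names(transforms), function(id)
      resample_to(sums[[id]], compose_chain(transforms[[id]]), mask))
    template <- build_template(aligned, mask, maxit = cfg$maxit)
    for (id in names(transforms)) {
      ch <- transforms[[id]]
      pair6 <- if (length(ch) == 2) ch[[2]] else NULL
      ch[[1]] <- refine_to_template(sums[[id]], template, ch[[1]], pair6,
                                    maxit = cfg$maxit)
      transforms[[id]] <- ch
    }
  } else template <- NULL

  uptake <- do.call(rbind, lapply(names(transforms), function(id) {
    al <- resample_4d(dyns[[id]], transforms[[id]], atlas)
    uptake_table(al, atlas, recs[recs$scan_id == id, ],
                 regions = default_region_set(atlas), window = cfg$window)
  }))

  sc <- vapply(transforms, function(ch) volume_scale_product(ch[[1]]),
               numeric(1))
  scale_summary <- do.call(rbind, lapply(split(
    data.frame(v = sc, genotype = recs$genotype[match(names(sc), recs$scan_id)],
               timepoint = recs$timepoint[match(names(sc), recs$scan_id)]),
    recs$genotype[match(names(sc), recs$scan_id)]),
    function(d) data.frame(genotype = d$genotype[1], n = nrow(d),
                           mean = mean(d$v), sd = stats::sd(d$v))))
  rownames(scale_summary) <- NULL

  suvr_models <- NULL
  if (isTRUE(cfg$stats)) {
    rs <- default_region_set(atlas)
    suvr_models <- lapply(rs$name, function(r) {
      d <- uptake[uptake$region == r, ]
      tryCatch(fit_lme_2x2(d, "suvr"), error = function(e) NULL)
    })
    names(suvr_models) <- rs$name
  }

  out <- list(atlas = atlas, mask = mask, cohort = cohort,
              transforms = transforms, template = template,
              uptake = uptake, suvr_models = suvr_models,
              scale_summary = scale_summary, config = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(uptake, file.path(cfg$out_dir, "uptake.csv"),
                     row.names = FALSE)
    utils::write.csv(recs, file.path(cfg$out_dir, "scan_records.csv"),
                     row.names = FALSE)
    write_nifti3(atlas, file.path(cfg$out_dir, "atlas_labels.nii.gz"))
    write_nifti3(mask, file.path(cfg$out_dir, "brain_mask_smoothed.nii.gz"))
    for (id in names(transforms))
      write_transform_json(transforms[[id]],
                           file.path(cfg$out_dir, paste0(id, "_transform.json")))
    jsonlite::write_json(list(seed = seed, config = cfg[!vapply(cfg, is.null, TRUE)],
                              n_scans = nrow(recs)),
                         file.path(cfg$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$paths <- cfg$out_dir
  }
  out
}
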