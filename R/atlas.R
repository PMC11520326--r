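#' Construct a label volume
#'
#' An integer-labelled anatomy volume (label 0 = background) with a label-id
#' to region-name table.
#'
#' @param voxels Integer 3D array of label ids; 0 is background.
#' @param voxel_size mm per axis.
#' @param labels Named integer vector or data.frame with columns `id`, `name`
#'   (and optionally `group`) mapping label ids to region names. Every
#'   non-zero id present in `voxels` must appear.
#' @param origin World mm of the first voxel center; defaults to centering
#'   the volume on the world origin.
#' @return An object of class `label_volume` (also a `pet_image3`).
#' @export
label_volume <- function(voxels, voxel_size, labels, origin = NULL) {
  if (length(voxels) == 0) stop("empty atlas")
  if (is.data.frame(labels)) {
    tab <- labels
  } else {
    tab <- data.frame(id = as.integer(labels),
                      name = names(labels), stringsAsFactors = FALSE)
  }
  if (is.null(tab$group)) tab$group <- rep(NA_character_, nrow(tab))
  storage.mode(voxels) <- "integer"
  present <- setdiff(sort(unique(as.vector(voxels))), 0L)
  missing <- setdiff(present, tab$id)
  if (length(missing))
    stop("label ids present in voxels but absent from the label table: ",
         paste(missing, collapse = ", "))
  img <- image3(voxels, voxel_size, origin)
  img$labels <- tab[, c("id", "name", "group")]
  class(img) <- c("label_volume", class(img))
  img
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels @ %s mm, %d labels\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              nrow(x$labels)))
  invisible(x)
}

## block label counts: number of source voxels of value `lab` per output block
block_count <- function(mask_arr, b) {
  arr <- mask_arr * 1.0
  for (ax in 1:3) {
    if (b[ax] > 1L) {
      W <- block_mean_matrix(dim(arr)[ax], b[ax])
      ## convert means back to sums so trailing partial blocks count correctly
      W <- W * matrix(rowSums(W > 0), nrow(W), ncol(W))
      W[W > 0] <- 1
      arr <- contract_axis(arr, W, ax)
    }
  }
  arr
}

#' Downsample a label atlas
#'
#' When the target voxel size is an integer multiple of the source size on
#' every axis, each output voxel takes the majority label of the source
#' voxels it covers, with ties broken toward the lowest label id (background
#' 0 competes like any other label). Small regions may vanish entirely.
#' For non-integer ratios the output is resampled by the source voxel nearest
#' to each output voxel center (documented fallback).
#'
#' @param atlas A [label_volume()].
#' @param target_voxel_mm Target voxel size in mm (scalar isotropic or
#'   length 3); must be >= the source voxel size on every axis.
#' @return A [label_volume()] at the target resolution (labels restricted to
#'   those that survive).
#' @export
downsample_labels <- function(atlas, target_voxel_mm) {
  target <- rep_len(as.numeric(target_voxel_mm), 3)
  if (any(target < atlas$voxel_size - 1e-9))
    stop("target voxel size must be >= source voxel size")
  ratio <- target / atlas$voxel_size
  b <- round(ratio)
  if (all(abs(ratio - b) < 1e-6)) {
    b <- as.integer(b)
    if (all(b == 1L)) {
      out_vox <- atlas$voxels
      out_voxel <- atlas$voxel_size
      out_origin <- atlas$origin
    } else {
      ids <- sort(unique(as.vector(atlas$voxels)))
      best_cnt <- NULL
      best_lab <- NULL
      for (lab in ids) {  # ascending: ties keep the lowest label id
        cnt <- block_count(atlas$voxels == lab, b)
        if (is.null(best_cnt)) {
          best_cnt <- cnt
          best_lab <- array(lab, dim(cnt))
        } else {
          win <- cnt > best_cnt
          best_cnt[win] <- cnt[win]
          best_lab[win] <- lab
        }
      }
      out_vox <- best_lab
      out_voxel <- atlas$voxel_size * b
      out_origin <- atlas$origin + (b - 1) / 2 * atlas$voxel_size
    }
  } else {
    ## nearest-source-voxel fallback
    d <- dim(atlas$voxels)
    extent <- d * atlas$voxel_size
    n_out <- pmax(1L, floor(extent / target + 1e-9))
    out <- image3(array(0L, n_out), target,
                  atlas$origin - atlas$voxel_size / 2 + target / 2)
    out_vox <- array(sample_nearest(atlas, grid_points(out)), n_out)
    out_voxel <- target
    out_origin <- out$origin
  }
  keep <- atlas$labels$id %in% setdiff(unique(as.vector(out_vox)), 0L)
  label_volume(out_vox, out_voxel, atlas$labels[keep, , drop = FALSE],
               out_origin)
}

#' Region volumes of a label atlas
#'
#' @param atlas A [label_volume()].
#' @return A data.frame with columns `id`, `name`, `n_voxels`, `volume_mm3`,
#'   with the median non-background region volume attached as attribute
#'   `median_volume_mm3` (`NA` if there are no regions).
#' @export
region_volumes <- function(atlas) {
  vv <- prod(atlas$voxel_size)
  counts <- table(factor(as.vector(atlas$voxels),
                         levels = atlas$labels$id))
  out <- data.frame(id = atlas$labels$id, name = atlas$labels$name,
                    n_voxels = as.integer(counts),
                    volume_mm3 = as.numeric(counts) * vv,
                    stringsAsFactors = FALSE)
  med <- if (nrow(out)) stats::median(out$volume_mm3[out$n_voxels > 0])
         else NA_real_
  attr(out, "median_volume_mm3") <- med
  out
}

#' Smoothed brain mask registration target
#'
#' Takes the binary union of all non-background labels and convolves it with
#' an isotropic Gaussian, emulating the scanner's resolution so that PET
#' brain edges match the mask's edge profile (sigma = 0.85 mm corresponds to
#' a 2 mm FWHM scanner).
#'
#' @param atlas A [label_volume()].
#' @param sigma_mm Gaussian sigma in mm (>= 0; 0 returns the binary mask).
#' @return A `smoothed_mask` object (a [image3()] with values in `[0, 1]`,
#'   plus `sigma_mm` and `source` fields).
#' @export
make_smoothed_mask <- function(atlas, sigma_mm = 0.85) {
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  bin <- image3((atlas$voxels > 0) * 1.0, atlas$voxel_size, atlas$origin)
  sm <- smooth_gaussian(bin, sigma_mm)
  sm$sigma_mm <- sigma_mm
  sm$source <- sprintf("union of %d labels, Gaussian sigma %.3g mm",
                       nrow(atlas$labels), sigma_mm)
  class(sm) <- c("smoothed_mask", class(sm))
  sm
}

#' The a-priori region set
#'
#' The 18 regions analysed a priori, grouped as catecholaminergic
#' (noradrenergic and dopaminergic), dysarthria-related, and Parkinson
#' Disease Related Pattern (PDRP) regions. Striatum and caudate putamen are
#' kept as distinct entries. The table is editable: pass your own data.frame
#' with the same columns to any function accepting a region set.
#'
#' @param atlas Optional [label_volume()]; if given, region label ids are
#'   taken from its label table by name match.
#' @return An object of class `region_set`: a data.frame with columns
#'   `name`, `group`, `id` (label id, `NA` if no atlas given), plus attribute
#'   `whole_brain` (all non-background label ids of the atlas).
#' @export
default_region_set <- function(atlas = NULL) {
  rs <- region_defaults()[, c("name", "group")]
  rs$id <- NA_integer_
  if (!is.null(atlas)) {
    m <- match(rs$name, atlas$labels$name)
    rs$id <- atlas$labels$id[m]
    attr(rs, "whole_brain") <- setdiff(atlas$labels$id, 0L)
  }
  class(rs) <- c("region_set", class(rs))
  rs
}

## built-in region table: name, functional group, phantom target volume
## (mm^3, median 6 by construction), and default SUVr levels for the two
## genotypes (whole-brain-normalized uptake; KO differs from WT in the four
## regions with genotype effects).
region_defaults <- function() {
  tab <- read.csv(system.file("extdata", "region_defaults.csv",
                              package = "fdgpet"),
                  stringsAsFactors = FALSE)
  tab
}
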