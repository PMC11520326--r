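#' @keywords internal
"_PACKAGE"

## Coordinate convention used throughout the package:
## right-handed world space in mm; the center of voxel [1,1,1] sits at
## `origin`, and voxel [i,j,k] has world coordinate origin + (c(i,j,k)-1) *
## voxel_size. All affine transforms act on world coordinates.

#' Construct a 3D image
#'
#' A minimal in-memory container for a scalar 3D volume: a numeric array plus
#' voxel size (mm) and the world coordinate (mm) of the first voxel center.
#'
#' @param voxels Numeric 3D array.
#' @param voxel_size Numeric length-3, mm per axis (strictly positive).
#' @param origin Numeric length-3, world mm of the center of voxel `[1,1,1]`.
#'   Default centers the volume on the world origin.
#' @return An object of class `pet_image3`.
#' @export
image3 <- function(voxels, voxel_size, origin = NULL) {
  stopifnot(length(dim(voxels)) == 3)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be strictly positive")
  if (is.null(origin)) origin <- -(dim(voxels) - 1) / 2 * voxel_size
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "pet_image3")
}

#' Construct a dynamic (4D) image
#'
#' @param voxels Numeric 4D array `(x, y, z, frame)` of radioactivity
#'   concentration in Bq/mL.
#' @param voxel_size,origin As in [image3()].
#' @param schedule Frame schedule, see [make_frame_schedule()].
#' @param decay_corrected Logical; `TRUE` if frames are already decay
#'   corrected to the scan start.
#' @return An object of class `pet_dynimage`.
#' @export
dyn_image <- function(voxels, voxel_size, schedule, origin = NULL,
                      decay_corrected = TRUE) {
  stopifnot(length(dim(voxels)) == 4)
  if (dim(voxels)[4] != nrow(schedule$frames))
    stop(sprintf("frame count mismatch: image has %d frames, schedule has %d",
                 dim(voxels)[4], nrow(schedule$frames)))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be strictly positive")
  if (is.null(origin)) origin <- -(dim(voxels)[1:3] - 1) / 2 * voxel_size
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 origin = as.numeric(origin), schedule = schedule,
                 decay_corrected = isTRUE(decay_corrected)),
            class = "pet_dynimage")
}

#' @export
print.pet_image3 <- function(x, ...) {
  cat(sprintf("<pet_image3> %s voxels @ %s mm, origin (%s) mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.pet_dynimage <- function(x, ...) {
  cat(sprintf("<pet_dynimage> %s voxels @ %s mm, %d frames (%g-%g min)%s\n",
              paste(dim(x$voxels)[1:3], collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              dim(x$voxels)[4], min(x$schedule$frames$start),
              max(x$schedule$frames$end),
              if (x$decay_corrected) ", decay corrected" else ""))
  invisible(x)
}

#' World coordinates of every voxel center
#'
#' @param img An image-like object (`voxels`, `voxel_size`, `origin`).
#' @return N x 3 matrix of world mm coordinates, in array (column-major)
#'   order.
#' @export
grid_points <- function(img) {
  d <- dim(img$voxels)[1:3]
  cbind(rep(img$origin[1] + (seq_len(d[1]) - 1) * img$voxel_size[1],
            times = d[2] * d[3]),
        rep(rep(img$origin[2] + (seq_len(d[2]) - 1) * img$voxel_size[2],
                each = d[1]), times = d[3]),
        rep(img$origin[3] + (seq_len(d[3]) - 1) * img$voxel_size[3],
            each = d[1] * d[2]))
}

#' Geometric center of an image volume (world mm)
#'
#' The default rotation/scaling center for registration.
#'
#' @inheritParams grid_points
#' @return Numeric length 3.
#' @export
grid_center <- function(img) {
  img$origin + (dim(img$voxels)[1:3] - 1) / 2 * img$voxel_size
}

#' Sample a 3D image at arbitrary world points (trilinear)
#'
#' Points outside the volume evaluate to `fill`.
#'
#' @param img A [image3()] object.
#' @param pts N x 3 matrix of world coordinates (mm).
#' @param fill Value for points outside the volume (default 0).
#' @return Numeric vector of length N.
#' @export
sample_trilinear <- function(img, pts, fill = 0) {
  d <- dim(img$voxels)
  f1 <- (pts[, 1] - img$origin[1]) / img$voxel_size[1] + 1
  f2 <- (pts[, 2] - img$origin[2]) / img$voxel_size[2] + 1
  f3 <- (pts[, 3] - img$origin[3]) / img$voxel_size[3] + 1
  ## snap to the lattice: points that land on voxel centers up to float
  ## round-off are read out exactly (identity resampling is bit-identical)
  snap <- function(f) { r <- round(f); ifelse(abs(f - r) < 1e-7, r, f) }
  f1 <- snap(f1); f2 <- snap(f2); f3 <- snap(f3)
  out <- rep(as.numeric(fill), nrow(pts))
  inside <- f1 >= 1 & f1 <= d[1] & f2 >= 1 & f2 <= d[2] & f3 >= 1 & f3 <= d[3]
  if (!any(inside)) return(out)
  f1 <- f1[inside]; f2 <- f2[inside]; f3 <- f3[inside]
  i0 <- floor(f1); j0 <- floor(f2); k0 <- floor(f3)
  wx <- f1 - i0; wy <- f2 - j0; wz <- f3 - k0
  ## clamped upper-corner offsets (weight is 0 exactly when clamped)
  ox <- as.numeric(i0 < d[1]); oy <- as.numeric(j0 < d[2]) * d[1]
  oz <- as.numeric(k0 < d[3]) * d[1] * d[2]
  idx <- i0 + (j0 - 1) * d[1] + (k0 - 1) * d[1] * d[2]
  v <- img$voxels
  c00 <- v[idx] * (1 - wx) + v[idx + ox] * wx
  c10 <- v[idx + oy] * (1 - wx) + v[idx + ox + oy] * wx
  c01 <- v[idx + oz] * (1 - wx) + v[idx + ox + oz] * wx
  c11 <- v[idx + oy + oz] * (1 - wx) + v[idx + ox + oy + oz] * wx
  out[inside] <- (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
                 (c01 * (1 - wy) + c11 * wy) * wz
  out
}

#' Sample a label volume at arbitrary world points (nearest neighbor)
#'
#' @param img A [image3()] or [label_volume()]-like object with integer voxels.
#' @param pts N x 3 matrix of world coordinates (mm).
#' @param fill Label for points outside the volume (default 0, background).
#' @return Integer vector of length N.
#' @export
sample_nearest <- function(img, pts, fill = 0L) {
  d <- dim(img$voxels)
  f <- sweep(sweep(pts, 2, img$origin, "-"), 2, img$voxel_size, "/") + 1
  i <- round(f)
  out <- rep(as.integer(fill), nrow(pts))
  ok <- i[, 1] >= 1 & i[, 1] <= d[1] &
        i[, 2] >= 1 & i[, 2] <= d[2] &
        i[, 3] >= 1 & i[, 3] <= d[3]
  if (any(ok))
    out[ok] <- img$voxels[cbind(i[ok, 1], i[ok, 2], i[ok, 3])]
  out
}

## normalized 1D Gaussian kernel sampled at voxel centers, radius 4 sigma
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

## apply a (n_out x n_in) matrix along one axis of a 3D array
contract_axis <- function(arr, mat, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  dp <- dim(a)
  res <- mat %*% matrix(a, nrow = dp[1])
  dim(res) <- c(nrow(mat), dp[2], dp[3])
  aperm(res, order(perm))
}

band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  W <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n - abs(o))
    if (o >= 0) W[cbind(idx, idx + o)] <- kernel[o + r + 1L]
    else W[cbind(idx - o, idx)] <- kernel[o + r + 1L]
  }
  W
}

#' Isotropic Gaussian smoothing of a 3D image
#'
#' Separable convolution with a unit-mass Gaussian; `sigma_mm` is converted to
#' voxel units per axis, so anisotropic grids are smoothed isotropically in
#' world space. Boundaries are zero-padded; mass is conserved for structures
#' further than the kernel radius (4 sigma) from the array edge.
#'
#' @param img A [image3()] object.
#' @param sigma_mm Gaussian standard deviation in mm (>= 0; 0 is a no-op).
#' @return A smoothed [image3()] on the same grid.
#' @export
smooth_gaussian <- function(img, sigma_mm) {
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  if (sigma_mm == 0) return(img)
  arr <- img$voxels
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm / img$voxel_size[ax])
    if (length(k) > 1)
      arr <- contract_axis(arr, band_matrix(dim(arr)[ax], k), ax)
  }
  image3(arr, img$voxel_size, img$origin)
}

#' Convert a Gaussian sigma to its full width at half maximum
#'
#' `FWHM = 2 sqrt(2 ln 2) sigma`; links the mask-smoothing sigma to the
#' scanner's stated resolution (sigma = 0.85 mm gives FWHM close to 2 mm).
#'
#' @param sigma_mm Gaussian standard deviation in mm (>= 0).
#' @return FWHM in mm.
#' @export
fwhm_from_sigma <- function(sigma_mm) {
  stopifnot(sigma_mm >= 0)
  2 * sqrt(2 * log(2)) * sigma_mm
}

## block-mean downsample by integer factor per axis (used for multi-resolution
## registration); trailing partial blocks are averaged over their members.
block_mean_matrix <- function(n, b) {
  n_out <- ceiling(n / b)
  W <- matrix(0, n_out, n)
  for (i in seq_len(n_out)) {
    cols <- ((i - 1L) * b + 1L):min(i * b, n)
    W[i, cols] <- 1 / length(cols)
  }
  W
}

downsample_mean <- function(img, factor = 2L) {
  factor <- as.integer(rep_len(factor, 3))
  arr <- img$voxels
  for (ax in 1:3)
    if (factor[ax] > 1L)
      arr <- contract_axis(arr, block_mean_matrix(dim(arr)[ax], factor[ax]), ax)
  image3(arr, img$voxel_size * factor,
         img$origin + (factor - 1) / 2 * img$voxel_size)
}
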