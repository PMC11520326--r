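## Affine transforms: 6 df (3 shifts + 3 rotations) or 9 df (+ 3 axis scales).
## A transform maps target-space world coordinates q (mm) to moving-space
## coordinates:  A(q) = R S (q - c) + c + t,
## with R = Rz Ry Rx (extrinsic rotations about the fixed world x, then y,
## then z axes, degrees), S = diag(scales), c the rotation center (by
## convention the geometric center of the target volume), t the shifts in mm.
## Resampling pulls values back through A, so "moving shifted +4 mm in x"
## is recovered as tx = +4.

#' Create affine transform parameters
#'
#' @param translation Shifts in mm, length 3.
#' @param rotation_deg Rotations in degrees about the world x, y, z axes
#'   (applied in that, extrinsic, order), length 3.
#' @param scale Axis scale factors, length 3; must be 1 for `df = 6`.
#' @param center Rotation/scaling center in world mm (default the origin).
#' @param df Degrees of freedom, 6 (rigid) or 9 (rigid + axis scales).
#' @return An object of class `affine_params`.
#' @export
affine_params <- function(translation = c(0, 0, 0),
                          rotation_deg = c(0, 0, 0),
                          scale = c(1, 1, 1),
                          center = c(0, 0, 0),
                          df = if (all(scale == 1)) 6L else 9L) {
  df <- as.integer(df)
  stopifnot(df %in% c(6L, 9L))
  scale <- rep_len(as.numeric(scale), 3)
  if (any(scale <= 0)) stop("scales must be strictly positive")
  if (df == 6L && any(scale != 1))
    stop("a 6-df transform cannot carry non-unit scales")
  structure(list(translation = rep_len(as.numeric(translation), 3),
                 rotation_deg = rep_len(as.numeric(rotation_deg), 3),
                 scale = scale, center = rep_len(as.numeric(center), 3),
                 df = df),
            class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat(sprintf("<affine_params %d df> t = (%s) mm, r = (%s) deg, s = (%s)\n",
              x$df, paste(signif(x$translation, 4), collapse = ", "),
              paste(signif(x$rotation_deg, 4), collapse = ", "),
              paste(signif(x$scale, 5), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(r_deg) {
  r <- r_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Homogeneous 4x4 matrix of an affine transform
#'
#' @param p An [affine_params()] object (or an already-built 4x4 matrix,
#'   returned unchanged).
#' @return 4x4 matrix acting on world-space column vectors.
#' @export
affine_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(all(dim(p) == c(4, 4)))
    return(p)
  }
  A <- rotation_matrix(p$rotation_deg) %*% diag(p$scale)
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- p$center + p$translation - A %*% p$center
  M
}

#' Compose a chain of transforms into a single matrix
#'
#' Members are listed in the order they are applied to a target-space point:
#' the composed matrix is the right-to-left product
#' `M_n %*% ... %*% M_2 %*% M_1`.
#'
#' @param chain List of [affine_params()] objects and/or 4x4 matrices.
#' @return 4x4 composed matrix.
#' @export
compose_chain <- function(chain) {
  if (inherits(chain, "affine_params") || is.matrix(chain))
    chain <- list(chain)
  M <- diag(4)
  for (p in chain) M <- affine_matrix(p) %*% M
  M
}

#' Invert an affine transform
#'
#' @param p [affine_params()] or 4x4 matrix.
#' @return 4x4 inverse matrix.
#' @export
affine_invert <- function(p) solve(affine_matrix(p))

apply_affine <- function(M, pts) {
  ## pts: N x 3; returns N x 3
  sweep(pts %*% t(M[1:3, 1:3]), 2, M[1:3, 4], "+")
}

#' Product of the three axis scale factors of a 9-df transform
#'
#' The combined three-dimensional scale factor (x * y * z), the volume ratio
#' a 9-df alignment applies to the moving brain; summarized per group in
#' cohort reports.
#'
#' @param p An [affine_params()] with `df = 9` (accepted for `df = 6` too,
#'   where it is identically 1).
#' @return Numeric scalar.
#' @export
volume_scale_product <- function(p) prod(p$scale)
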