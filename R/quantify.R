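#' F-18 physical half-life (minutes)
#' @export
F18_HALF_LIFE_MIN <- 109.77

#' Decay-correct a dynamic image to scan start
#'
#' Multiplies each frame by `exp(lambda * t_mid)` with
#' `lambda = ln 2 / half-life` and `t_mid` the frame midpoint, and sets the
#' corrected flag. Refuses to correct twice.
#'
#' @param img A [dyn_image()] with `decay_corrected = FALSE`.
#' @param half_life_min Isotope half-life in minutes (default F-18).
#' @return The corrected [dyn_image()].
#' @export
decay_correct <- function(img, half_life_min = F18_HALF_LIFE_MIN) {
  if (isTRUE(img$decay_corrected))
    stop("image is already decay corrected")
  lambda <- log(2) / half_life_min
  fac <- exp(lambda * frame_midpoints(img$schedule))
  for (f in seq_along(fac)) img$voxels[, , , f] <- img$voxels[, , , f] * fac[f]
  img$decay_corrected <- TRUE
  img
}

#' Extract regional time-activity curves
#'
#' Unweighted mean concentration over each region's member voxels, per
#' frame; a whole-brain TAC (union of all non-background labels) is always
#' included. The image must already be aligned to (and resampled on) the
#' atlas grid.
#'
#' @param img A [dyn_image()] on the atlas grid.
#' @param atlas A [label_volume()].
#' @param regions A [default_region_set()]-style data.frame with `name` and
#'   `id` (one or more label ids per region may be given as a list column);
#'   default: every atlas label as its own region.
#' @return data.frame in long format: `region`, `frame`, `start`, `end`,
#'   `mean_conc` (Bq/mL).
#' @export
extract_tacs <- function(img, atlas, regions = NULL) {
  if (!all(dim(img$voxels)[1:3] == dim(atlas$voxels)))
    stop("image is not on the atlas grid")
  if (is.null(regions)) {
    regions <- data.frame(name = atlas$labels$name, stringsAsFactors = FALSE)
    regions$id <- as.list(atlas$labels$id)
  }
  ids <- if (is.list(regions$id)) regions$id else as.list(regions$id)
  members <- c(list(which(atlas$voxels > 0)),
               lapply(ids, function(v) which(atlas$voxels %in% v)))
  names(members) <- c("Whole brain", regions$name)
  nfr <- dim(img$voxels)[4]
  nvox <- prod(dim(img$voxels)[1:3])
  mat <- matrix(img$voxels, nvox, nfr)
  fr <- img$schedule$frames
  out <- lapply(names(members), function(nm) {
    idx <- members[[nm]]
    mc <- if (length(idx)) colMeans(mat[idx, , drop = FALSE]) else rep(NA_real_, nfr)
    data.frame(region = nm, frame = seq_len(nfr), start = fr$start,
               end = fr$end, mean_conc = mc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## duration-weighted window mean of a single TAC (long-format rows)
window_mean <- function(tac, window) {
  ov <- pmax(0, pmin(tac$end, window[2]) - pmax(tac$start, window[1]))
  if (sum(ov) <= 0) stop("window does not intersect the frame schedule")
  sum(tac$mean_conc * ov) / sum(ov)
}

#' Standardized uptake value of one TAC
#'
#' `SUV = mean concentration over the window / (injected activity / body
#' weight)`; Bq/mL over Bq/g gives g/mL. Frames partially inside the window
#' are weighted by their overlap duration.
#'
#' @param tac Long-format TAC rows for one region (from [extract_tacs()]).
#' @param rec List/row with `injected_activity_bq` and `body_weight_g`.
#' @param window Minutes post scan start (default 30-60).
#' @return SUV in g/mL.
#' @export
compute_suv <- function(tac, rec, window = c(30, 60)) {
  if (!is.finite(rec$injected_activity_bq) || rec$injected_activity_bq <= 0)
    stop("injected activity must be > 0")
  if (!is.finite(rec$body_weight_g) || rec$body_weight_g <= 0)
    stop("body weight must be > 0")
  window_mean(tac, window) / (rec$injected_activity_bq / rec$body_weight_g)
}

#' Regional uptake table for one aligned scan
#'
#' Extracts TACs, computes SUV per region (whole brain included), and the
#' whole-brain-normalized SUVr. Negative concentrations (possible in real
#' filtered-back-projection data) are clamped to 0 before averaging; the
#' clamp count is attached as attribute `n_clamped`.
#'
#' @param img A [dyn_image()] on the atlas grid.
#' @param atlas A [label_volume()].
#' @param rec Scan record row (`scan_id`, `subject`, `genotype`,
#'   `timepoint`, `injected_activity_bq`, `body_weight_g`).
#' @param regions See [extract_tacs()].
#' @param window SUV window, minutes (default 30-60).
#' @return data.frame rows: scan metadata + `region`, `suv`, `suvr`.
#' @export
uptake_table <- function(img, atlas, rec, regions = NULL,
                         window = c(30, 60)) {
  n_clamped <- sum(img$voxels < 0)
  if (n_clamped > 0) img$voxels[img$voxels < 0] <- 0
  tacs <- extract_tacs(img, atlas, regions)
  regs <- unique(tacs$region)
  suv <- vapply(regs, function(r)
    compute_suv(tacs[tacs$region == r, ], rec, window), numeric(1))
  out <- data.frame(scan_id = rec$scan_id, subject = rec$subject,
                    genotype = rec$genotype, timepoint = rec$timepoint,
                    region = regs, suv = unname(suv),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- compute_suvr(out)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Add whole-brain-normalized SUVr to an uptake table
#'
#' `SUVr = SUV_region / SUV_wholebrain` per scan; the whole-brain row is
#' identically 1, and injected-dose / body-weight errors cancel (ADME
#' correction).
#'
#' @param table data.frame with `scan_id`, `region`, `suv` columns and a
#'   `"Whole brain"` row per scan.
#' @return The table with a `suvr` column.
#' @export
compute_suvr <- function(table) {
  wb <- table[table$region == "Whole brain", c("scan_id", "suv")]
  if (nrow(wb) == 0) stop("no 'Whole brain' rows present")
  denom <- wb$suv[match(table$scan_id, wb$scan_id)]
  if (anyNA(denom)) stop("missing whole-brain SUV for some scans")
  table$suvr <- table$suv / denom
  table
}
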