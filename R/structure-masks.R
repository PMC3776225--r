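#' Basal ganglia label codes
#'
#' The subcortical label codes used throughout the pipeline: the FSL-FIRST
#' codes for caudate (11/50), putamen (12/51) and globus pallidus (13/52),
#' two additional codes for the derived left/right internal capsule masks
#' (14/55), and the thalamus codes (10/49) that are consumed only by the
#' internal-capsule derivation.
#'
#' @return A tibble with columns `code`, `structure`, `hemisphere`, and
#'   `in_label_set` (whether components may be assigned this code).
#' @export
bg_labels <- function() {
  tibble::tibble(
    code = c(10L, 11L, 12L, 13L, 14L, 49L, 50L, 51L, 52L, 55L),
    structure = rep(c("thalamus", "caudate", "putamen", "pallidum", "capsule"), 2),
    hemisphere = rep(c("left", "right"), each = 5),
    in_label_set = rep(c(FALSE, TRUE, TRUE, TRUE, TRUE), 2)
  )
}

LABEL_SET <- c(11L, 12L, 13L, 14L, 50L, 51L, 52L, 55L)
LEFT_CODES <- c(11L, 12L, 13L, 14L)
RIGHT_CODES <- c(50L, 51L, 52L, 55L)
THALAMUS_CODES <- c(10L, 49L)

structure_name <- function(code) {
  lab <- bg_labels()
  out <- lab$structure[match(code, lab$code)]
  out[code == 0L] <- "outside"
  out
}

## in-plane disk offsets with dx^2 + dy^2 <= r^2 in world mm
disk_offsets <- function(radius_mm, voxel_size) {
  rx <- floor(radius_mm / voxel_size[1])
  ry <- floor(radius_mm / voxel_size[2])
  off <- expand.grid(dx = -rx:rx, dy = -ry:ry)
  keep <- (off$dx * voxel_size[1])^2 + (off$dy * voxel_size[2])^2 <= radius_mm^2 + 1e-9
  off[keep, , drop = FALSE]
}

## per-slice (axial) 2D dilation of a mask by a world-mm disk; the shifts run
## on the mask's padded bounding box only, which matters on full-size volumes
dilate_disk2d <- function(m, radius_mm) {
  stopifnot_mask(m)
  off <- disk_offsets(radius_mm, m$voxel_size)
  full <- m$values > 0L
  d <- dim(full)
  idx <- which(full, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(mask_like(m, full))
  pad <- c(max(abs(off$dx)), max(abs(off$dy)), 0L)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  arr <- full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  db <- dim(arr)
  out <- array(FALSE, dim = db)
  for (i in seq_len(nrow(off))) {
    dx <- off$dx[i]; dy <- off$dy[i]
    sx_dst <- max(1, 1 + dx):min(db[1], db[1] + dx)
    sy_dst <- max(1, 1 + dy):min(db[2], db[2] + dy)
    out[sx_dst, sy_dst, ] <- out[sx_dst, sy_dst, , drop = FALSE] |
      arr[sx_dst - dx, sy_dst - dy, , drop = FALSE]
  }
  res <- array(FALSE, dim = d)
  res[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- out
  mask_like(m, res)
}

#' Derive an internal-capsule mask from subcortical segmentations
#'
#' The internal capsule is approximated by dilating the globus pallidus mask
#' with a disk-shaped 2D kernel (applied slice-wise in the axial plane, radius
#' in world mm so the kernel adapts to in-plane voxel size) and subtracting the
#' thalamus, globus pallidus and caudate masks. The putamen is deliberately not
#' subtracted; overlaps between the derived capsule and the putamen are
#' resolved at labeling time in favour of the putamen.
#'
#' @param gp globus pallidus mask to dilate (typically one hemisphere).
#' @param thalamus,caudate masks subtracted from the dilation.
#' @param gp_all globus pallidus mask(s) subtracted from the dilation; defaults
#'   to `gp`. Pass the union of both hemispheres when they are close.
#' @param radius_mm disk radius in mm (default 6).
#' @return A binary [voxel_grid] mask. An empty `gp` yields an empty mask with
#'   a warning.
#' @export
derive_internal_capsule <- function(gp, thalamus, caudate, gp_all = gp,
                                    radius_mm = 6) {
  stopifnot_mask(gp); stopifnot_mask(thalamus); stopifnot_mask(caudate)
  if (radius_mm <= 0) stop("`radius_mm` must be > 0", call. = FALSE)
  if (sum(gp$values) == 0L) {
    warning("empty globus pallidus mask; internal capsule is empty")
    return(mask_like(gp, array(FALSE, dim = vg_shape(gp))))
  }
  dil <- dilate_disk2d(gp, radius_mm)
  out <- dil$values > 0L & !(thalamus$values > 0L) &
    !(gp_all$values > 0L) & !(caudate$values > 0L)
  mask_like(gp, out)
}

#' Intracranial volume from a brain mask
#'
#' @param brain_mask nonempty binary [voxel_grid] brain mask.
#' @return ICV in mm^3.
#' @export
intracranial_volume <- function(brain_mask) {
  stopifnot_mask(brain_mask)
  if (sum(brain_mask$values) == 0L)
    stop("brain mask is empty; cannot estimate ICV", call. = FALSE)
  mask_volume_mm3(brain_mask)
}

#' Normal-appearing tissue mask
#'
#' The portion of a structure mask not covered by the hypointensity mask
#' (structure ∩ complement of hypo), used as the per-subject intensity
#' reference for thresholds and appearance classification.
#'
#' @param structure,hypo binary [voxel_grid] masks of identical shape.
#' @return A binary [voxel_grid]; if the result is empty the attribute
#'   `qc_empty` is set to `TRUE`.
#' @export
normal_appearing_mask <- function(structure, hypo) {
  stopifnot_mask(structure); stopifnot_mask(hypo)
  if (!identical(dim(structure$values), dim(hypo$values)))
    stop("mask shapes differ", call. = FALSE)
  out <- mask_diff(structure, hypo)
  if (sum(out$values) == 0L) attr(out, "qc_empty") <- TRUE
  out
}
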