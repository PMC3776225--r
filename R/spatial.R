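#' Per-subject spatial probability map in the reference grid
#'
#' Resamples a subject's hypointensity mask into the reference grid and
#' normalizes it into a spatial probability density. The warp is a 4D
#' displacement field on the reference grid holding, for each reference
#' voxel, the world-mm displacement that the subject's content undergoes on
#' its way into reference space (forward convention): the mask is sampled
#' trilinearly at `reference_world - d`, so a pure translation warp `d`
#' shifts the density's mass centroid by exactly `+d`. `warp = NULL` means
#' identity. Sampled values are clipped to \[0, 1\] and divided by their sum
#' so the map's voxel values sum to 1.
#'
#' @param hypo binary [voxel_grid] mask in subject space.
#' @param warp `NULL` (identity) or a 4D numeric array
#'   `dim = c(reference shape, 3)` of mm displacements; all values finite.
#' @param reference a [voxel_grid] defining the reference lattice.
#' @param normalize if `FALSE`, retain fractional occupancy without unit-sum
#'   normalization (the alternative convention).
#' @return A density [voxel_grid] on the reference grid summing to 1, or an
#'   all-zero map with `attr(, "qc_empty") = TRUE` if nothing maps inside.
#' @export
subject_spatial_map <- function(hypo, warp = NULL, reference, normalize = TRUE) {
  stopifnot_mask(hypo)
  stopifnot(is_voxel_grid(reference))
  ref_shape <- vg_shape(reference)
  if (!is.null(warp)) {
    if (!is.array(warp) || length(dim(warp)) != 4L ||
        !identical(dim(warp)[1:3], as.integer(ref_shape)) || dim(warp)[4] != 3L)
      stop("`warp` must be a (ref shape) x 3 displacement array", call. = FALSE)
    if (any(!is.finite(warp))) stop("non-finite warp values", call. = FALSE)
  }
  if (is.null(warp) && same_grid(hypo, reference)) {
    vals <- as.numeric(hypo$values)
  } else {
    ## world coordinates of every reference voxel centre
    org_r <- vg_origin(reference)
    vs_r <- reference$voxel_size
    ax <- lapply(1:3, function(a) (seq_len(ref_shape[a]) - 1) * vs_r[a] + org_r[a])
    nvox <- prod(ref_shape)
    wx <- rep(ax[[1]], times = ref_shape[2] * ref_shape[3])
    wy <- rep(rep(ax[[2]], each = ref_shape[1]), times = ref_shape[3])
    wz <- rep(ax[[3]], each = ref_shape[1] * ref_shape[2])
    if (!is.null(warp)) {
      wx <- wx - as.numeric(warp[, , , 1])
      wy <- wy - as.numeric(warp[, , , 2])
      wz <- wz - as.numeric(warp[, , , 3])
    }
    org_s <- vg_origin(hypo)
    vs_s <- hypo$voxel_size
    vals <- trilinear_sample(hypo$values,
                             (wx - org_s[1]) / vs_s[1] + 1,
                             (wy - org_s[2]) / vs_s[2] + 1,
                             (wz - org_s[3]) / vs_s[3] + 1)
  }
  vals <- pmin(pmax(vals, 0), 1)
  tot <- sum(vals)
  out <- voxel_grid(array(if (normalize && tot > 0) vals / tot else vals,
                          dim = ref_shape),
                    voxel_size = reference$voxel_size,
                    affine = reference$affine, kind = "density")
  if (tot == 0) attr(out, "qc_empty") <- TRUE
  out
}

## vectorized trilinear interpolation at fractional 1-based voxel coordinates;
## points outside the lattice contribute 0
trilinear_sample <- function(arr, x, y, z) {
  d <- dim(arr)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- numeric(length(x))
  gather <- function(ix, iy, iz) {
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    v <- numeric(length(ix))
    if (any(ok))
      v[ok] <- arr[cbind(ix[ok], iy[ok], iz[ok])]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    nz <- w > 0
    if (any(nz)) {
      v <- gather(x0[nz] + dx, y0[nz] + dy, z0[nz] + dz)
      out[nz] <- out[nz] + w[nz] * v
    }
  }
  out
}

#' Aggregate per-subject spatial maps
#'
#' Voxelwise equal-weight mean of the per-subject spatial probability maps
#' (weights 1/k over k subjects), the cohort spatial probability distribution.
#' Flagged all-zero maps (subjects with no hypointensities) stay in the
#' average, so the output sums to (number of non-empty maps) / (number of
#' maps) <= 1.
#'
#' @param maps list of density [voxel_grid]s on the same reference grid.
#' @return A density [voxel_grid].
#' @export
aggregate_spatial <- function(maps) {
  if (is_voxel_grid(maps)) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  for (m in maps[-1]) if (!same_grid(maps[[1]], m))
    stop("spatial maps are not on a common grid", call. = FALSE)
  acc <- Reduce(`+`, lapply(maps, function(m) m$values))
  voxel_grid(acc / length(maps), voxel_size = maps[[1]]$voxel_size,
             affine = maps[[1]]$affine, kind = "density")
}

#' Identity-plus-translation displacement field
#'
#' Convenience constructor of a constant displacement field on a reference
#' grid, mainly for testing warp handling.
#'
#' @param reference a [voxel_grid].
#' @param translation_mm length-3 world displacement in mm.
#' @return A 4D array suitable for [subject_spatial_map()]'s `warp`.
#' @export
translation_warp <- function(reference, translation_mm) {
  shp <- vg_shape(reference)
  w <- array(0, dim = c(shp, 3L))
  for (a in 1:3) w[, , , a] <- translation_mm[a]
  w
}
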