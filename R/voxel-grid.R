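#' 3D voxel lattice with world placement
#'
#' `voxel_grid()` is the basic spatial container of the package: a 3D scalar
#' lattice together with its voxel dimensions (mm) and a 4x4 grid-to-world
#' affine. It carries image intensities, binary masks, probability densities,
#' or integer label maps, distinguished by `kind`.
#'
#' The convention throughout the package is that the third array index `z`
#' enumerates axial planes (the acquisition orientation of 2D T2*-weighted
#' gradient-echo sequences), and that the affine is axis-aligned:
#' `world = (index - 1) * voxel_size + origin`.
#'
#' @param values numeric 3D array. Masks must contain only 0/1.
#' @param voxel_size length-3 positive numeric, voxel edge lengths in mm.
#' @param affine optional 4x4 grid-to-world matrix; defaults to
#'   `diag(voxel_size)` with zero origin.
#' @param kind one of `"intensity"`, `"mask"`, `"density"`, `"label"`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, voxel_size = c(1, 1, 1), affine = NULL,
                       kind = c("intensity", "mask", "density", "label")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 1L)) stop("grid shape components must be >= 1", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive mm values", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4", call. = FALSE)
  if (kind == "mask") {
    if (!all(values == 0 | values == 1))
      stop("mask grid contains values other than {0, 1}", call. = FALSE)
    storage.mode(values) <- "integer"
  } else if (kind == "label") {
    storage.mode(values) <- "integer"
  } else {
    storage.mode(values) <- "double"
    if (kind == "density" && any(values[is.finite(values)] < 0))
      stop("density grid contains negative values", call. = FALSE)
  }
  structure(
    list(values = values, voxel_size = voxel_size, affine = affine, kind = kind),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid[%s]> %s, voxel %s mm\n",
              x$kind, paste(dim(x$values), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  if (x$kind == "mask")
    cat(sprintf("  %d set voxels (%.1f mm^3)\n", sum(x$values), mask_volume_mm3(x)))
  invisible(x)
}

#' @rdname voxel_grid
#' @param x object to test.
#' @export
is_voxel_grid <- function(x) inherits(x, "voxel_grid")

vg_shape <- function(g) dim(g$values)

vg_origin <- function(g) g$affine[1:3, 4]

## world coordinate of the voxel centre along one axis (1-based index)
vg_axis_world <- function(g, axis, idx) (idx - 1) * g$voxel_size[axis] + vg_origin(g)[axis]

stopifnot_mask <- function(g, arg = deparse(substitute(g))) {
  if (!is_voxel_grid(g)) stop(sprintf("`%s` must be a voxel_grid", arg), call. = FALSE)
  if (g$kind != "mask" && !all(g$values %in% c(0L, 1L)))
    stop(sprintf("`%s` must be a binary mask", arg), call. = FALSE)
  invisible(g)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$affine - b$affine) < tol)
}

voxel_volume_mm3 <- function(g) prod(g$voxel_size)

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [voxel_grid]. When a mask is requested
#' the values are checked to be exactly 0/1; any other content is rejected
#' rather than silently thresholded. Non-finite intensity voxels are preserved
#' and counted in the `qc_nonfinite` field of the result.
#'
#' @param path path to a NIfTI-1 file.
#' @param kind expected content; see [voxel_grid].
#' @return A [voxel_grid]; for intensities, `attr(, "qc_nonfinite")` holds the
#'   number of non-finite voxels.
#' @export
read_volume <- function(path, kind = c("intensity", "mask", "density", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("malformed NIfTI file %s: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  vals <- as.array(img)
  d <- dim(vals)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop(sprintf("%s is not a 3D volume", path), call. = FALSE)
  vals <- array(as.vector(vals), dim = d)   # strip niftiImage attributes
  vs <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  g <- voxel_grid(vals, voxel_size = vs, affine = aff, kind = kind)
  if (kind == "intensity") attr(g, "qc_nonfinite") <- sum(!is.finite(vals))
  g
}

#' Write a voxel grid as NIfTI-1
#'
#' Masks are written as unsigned 8-bit integers, label maps as signed 16-bit,
#' and intensities/densities as 32-bit float, so a write/read round trip is
#' bitwise for masks and labels.
#'
#' @param g a [voxel_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(g, path) {
  stopifnot(is_voxel_grid(g))
  dtype <- switch(g$kind, mask = "uint8", label = "int16", "float")
  img <- RNifti::asNifti(g$values)
  RNifti::pixdim(img) <- g$voxel_size
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Jaccard overlap between two masks
#'
#' The Jaccard similarity index |a ∩ b| / |a ∪ b| between two binary masks of
#' equal shape, used e.g. to quantify intra-rater segmentation agreement. Two
#' empty masks are identical, so the index is defined as 1 in that case.
#'
#' @param a,b binary [voxel_grid] masks of identical shape.
#' @return A fraction in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  stopifnot_mask(a); stopifnot_mask(b)
  if (!identical(dim(a$values), dim(b$values)))
    stop("mask shapes differ", call. = FALSE)
  av <- a$values > 0L; bv <- b$values > 0L
  uni <- sum(av | bv)
  if (uni == 0L) return(1)
  sum(av & bv) / uni
}

#' Volume of a binary mask in mm^3
#'
#' Count of set voxels times the volume of a single voxel.
#'
#' @param m a binary [voxel_grid] mask.
#' @return Volume in mm^3.
#' @export
mask_volume_mm3 <- function(m) {
  stopifnot_mask(m)
  sum(m$values > 0L) * voxel_volume_mm3(m)
}

#' Resample a mask to an isotropic lattice by nearest neighbour
#'
#' Regrids a binary mask onto an isotropic lattice (default 1 mm) covering the
#' mask's bounding box plus a one-voxel margin. Each output voxel takes the
#' value of the input voxel whose centre is nearest in world coordinates, so no
#' values absent from the input are ever introduced. Morphology metrics are
#' computed on this lattice so that objects acquired with anisotropic (e.g.
#' 2 mm slice) voxels are measured on a common discrete geometry.
#'
#' @param m a binary [voxel_grid] mask.
#' @param target_mm isotropic output voxel edge in mm (default 1).
#' @return A binary [voxel_grid] mask with `voxel_size = rep(target_mm, 3)`.
#'   An empty input yields an empty 1-voxel output.
#' @export
resample_nearest_isotropic <- function(m, target_mm = 1) {
  stopifnot_mask(m)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("`target_mm` must be a positive scalar", call. = FALSE)
  idx <- which(m$values > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(voxel_grid(array(0L, dim = c(1L, 1L, 1L)),
                      voxel_size = rep(target_mm, 3), kind = "mask"))
  }
  vs <- m$voxel_size
  org <- vg_origin(m)
  out_axes <- vector("list", 3L)
  near_idx <- vector("list", 3L)
  for (a in 1:3) {
    w <- (idx[, a] - 1) * vs[a] + org[a]
    lo <- min(w) - target_mm
    hi <- max(w) + target_mm
    centres <- seq(lo, hi, by = target_mm)
    if (centres[length(centres)] < hi - 1e-9) centres <- c(centres, centres[length(centres)] + target_mm)
    ## nearest input voxel centre, round-half-up for a deterministic tie rule
    ni <- floor((centres - org[a]) / vs[a] + 0.5) + 1L
    out_axes[[a]] <- centres
    near_idx[[a]] <- ni
  }
  n_out <- lengths(out_axes)
  shp <- vg_shape(m)
  inb <- function(ni, n) ni >= 1L & ni <= n
  ix <- near_idx[[1]]; iy <- near_idx[[2]]; iz <- near_idx[[3]]
  okx <- inb(ix, shp[1]); oky <- inb(iy, shp[2]); okz <- inb(iz, shp[3])
  ixc <- pmin(pmax(ix, 1L), shp[1])
  iyc <- pmin(pmax(iy, 1L), shp[2])
  izc <- pmin(pmax(iz, 1L), shp[3])
  vals <- m$values[ixc, iyc, izc, drop = FALSE]
  if (!all(okx)) vals[!okx, , ] <- 0L
  if (!all(oky)) vals[, !oky, ] <- 0L
  if (!all(okz)) vals[, , !okz] <- 0L
  aff <- diag(c(rep(target_mm, 3), 1))
  aff[1:3, 4] <- c(out_axes[[1]][1], out_axes[[2]][1], out_axes[[3]][1])
  voxel_grid(array(vals, dim = n_out), voxel_size = rep(target_mm, 3),
             affine = aff, kind = "mask")
}

## ---- internal mask algebra ------------------------------------------------

mask_like <- function(template, values) {
  voxel_grid(array(as.integer(values > 0), dim = vg_shape(template)),
             voxel_size = template$voxel_size, affine = template$affine,
             kind = "mask")
}

mask_and <- function(a, b) mask_like(a, a$values & b$values)
mask_or  <- function(a, b) mask_like(a, a$values | b$values)
mask_diff <- function(a, b) mask_like(a, a$values & !b$values)

## shift a 3D array by one voxel along an axis, zero-filled
shift3 <- function(arr, axis, by) {
  d <- dim(arr)
  out <- array(vector(typeof(arr), 1L), dim = d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { dst[[axis]] <- (1 + by):d[axis]; src[[axis]] <- 1:(d[axis] - by) }
  else if (by < 0) { dst[[axis]] <- 1:(d[axis] + by); src[[axis]] <- (1 - by):d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

## 6-neighbourhood erosion: keep voxels whose 6 face neighbours are all set
erode6 <- function(arr) {
  keep <- arr > 0
  for (axis in 1:3) for (by in c(-1L, 1L))
    keep <- keep & (shift3(arr, axis, by) > 0)
  keep
}
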