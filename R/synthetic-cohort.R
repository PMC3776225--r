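#' Specification of a synthetic multi-channel MRI phantom cohort
#'
#' Describes the geometry, contrast, lesion plan and noise of a fully
#' synthetic cohort with the statistical structure the analysis pipeline
#' assumes: three co-registered channels (T1w, T2w, T2*w; the latter named
#' `T2sw` in code), ellipsoidal brain/ventricle/deep-nucleus anatomy,
#' spherical hypointense lesions with channel-specific contrast, a per-subject
#' affine intensity distortion that the standardization stage can invert, and
#' a one-voxel partial-volume ("mixel") shell excluded from the tissue masks.
#'
#' Defaults encode the study conditions the pipeline targets: 1 x 1 x 2 mm
#' voxels (axial 2 mm slices), lesion counts Poisson per structure and
#' hemisphere with a pallidum-dominant plan whose expected inside-count shares
#' are roughly 72/18/8/2 percent for pallidum/capsule/putamen/caudate, lesion
#' radii uniform on 0.9-2.2 mm (median sphere volume near 12 mm^3), a
#' negatively skewed T2*w lesion intensity law (reflected Weibull below a dark
#' base level), T1w-dark / T2w-neutral lesion contrast, and caudate > putamen
#' > pallidum normal-tissue T2*w brightness ordering.
#'
#' @param n_subjects number of subjects (excluding the reference).
#' @param shape integer grid shape; default `c(128, 128, 64)`.
#' @param voxel_size voxel edges in mm; default `c(1, 1, 2)`.
#' @param seed master RNG seed; per-subject seeds are derived from it.
#' @param lesion_rate named Poisson means per hemisphere for
#'   caudate/putamen/pallidum/capsule.
#' @param lesion_asymmetry multiplier applied to left-hemisphere rates
#'   (1 = symmetric plan).
#' @param lesion_radius_mm range (min, max) of lesion sphere radii in mm.
#' @param noise_sd Gaussian intensity noise SD (intensity units).
#' @param bias_amplitude relative amplitude of a smooth multiplicative bias
#'   field (0 = bias-corrected input, the default).
#' @param distortion_slope,distortion_intercept uniform ranges for the
#'   per-subject affine intensity distortion `raw = a * true + b`.
#' @param lesion_t2sw list with `base`, `shape`, `scale`: T2*w lesion voxel
#'   intensities are `base - rweibull(shape, scale)` (plus noise), a negatively
#'   skewed law.
#' @param lesion_offsets additive lesion contrast on T1w and T2w relative to
#'   local normal tissue.
#' @param mixel_shell width (voxels) of the partial-volume shell eroded off
#'   the tissue masks.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_subjects = 10,
                         shape = c(128L, 128L, 64L),
                         voxel_size = c(1, 1, 2),
                         seed = 1L,
                         lesion_rate = c(caudate = 0.03, putamen = 0.13,
                                         pallidum = 1.15, capsule = 0.29),
                         lesion_asymmetry = 1,
                         lesion_radius_mm = c(0.9, 2.2),
                         noise_sd = 2,
                         bias_amplitude = 0,
                         distortion_slope = c(0.8, 1.2),
                         distortion_intercept = c(-10, 10),
                         lesion_t2sw = list(base = 55, shape = 1.5, scale = 8),
                         lesion_offsets = c(T1w = -25, T2w = 0),
                         mixel_shell = 1L) {
  stopifnot(n_subjects >= 1, length(shape) == 3L, all(shape >= 8),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(lesion_radius_mm) == 2L,
            lesion_radius_mm[1] > 0, diff(lesion_radius_mm) >= 0,
            noise_sd >= 0)
  if (!all(c("caudate", "putamen", "pallidum", "capsule") %in% names(lesion_rate)))
    stop("`lesion_rate` must name caudate, putamen, pallidum, capsule", call. = FALSE)
  fov <- shape * voxel_size
  s <- min(fov) / 128            # geometry scale relative to a 128 mm FOV
  c0 <- fov / 2
  ell <- function(dx, dy, dz, a, b, cc)
    list(center = c0 + c(dx, dy, dz) * s, semi = c(a, b, cc) * s)
  geometry <- list(
    brain = ell(0, 0, 0, 54, 58, 54),
    csf_l = ell(-6,  8, 6, 3, 14, 7),
    csf_r = ell( 6,  8, 6, 3, 14, 7),
    structures = list(
      `11` = ell(-15, 16, 4, 3.5, 7, 6),    # caudate L
      `50` = ell( 15, 16, 4, 3.5, 7, 6),
      `12` = ell(-26,  4, 0, 4.5, 9, 7),    # putamen L
      `51` = ell( 26,  4, 0, 4.5, 9, 7),
      `13` = ell(-16, -2, 0, 4,   6.5, 5.5),# pallidum L
      `52` = ell( 16, -2, 0, 4,   6.5, 5.5),
      `10` = ell(-11, -16, 0, 6, 8, 7),     # thalamus L
      `49` = ell( 11, -16, 0, 6, 8, 7)
    )
  )
  structure(list(
    n_subjects = as.integer(n_subjects),
    shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
    seed = as.integer(seed),
    lesion_rate = lesion_rate, lesion_asymmetry = lesion_asymmetry,
    lesion_radius_mm = as.numeric(lesion_radius_mm),
    noise_sd = noise_sd, bias_amplitude = bias_amplitude,
    distortion_slope = distortion_slope,
    distortion_intercept = distortion_intercept,
    lesion_t2sw = lesion_t2sw, lesion_offsets = lesion_offsets,
    mixel_shell = as.integer(mixel_shell),
    capsule_radius_mm = 6 * s,
    geometry_scale = s,
    geometry = geometry,
    ## normal-tissue intensity means per channel (arbitrary standardized units)
    tissue = list(
      T1w  = c(GMWM = 120, CSF = 40,
               caudate = 120, putamen = 120, pallidum = 120, thalamus = 120),
      T2w  = c(GMWM = 100, CSF = 180,
               caudate = 100, putamen = 100, pallidum = 100, thalamus = 100),
      T2sw = c(GMWM = 100, CSF = 150,
               caudate = 108, putamen = 104, pallidum = 93, thalamus = 100)
    )
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d subjects, grid %s @ %s mm, seed %d\n",
              x$n_subjects, paste(x$shape, collapse = "x"),
              paste(x$voxel_size, collapse = "x"), x$seed))
  invisible(x)
}

## deterministic per-subject seed (index 0 = reference); kept < 2^31
subject_seed <- function(master, index) {
  as.integer((as.double(master) * 99991 + index * 7919 + 12345) %% 2147483647)
}

rasterize_ellipsoid <- function(shape, voxel_size, center, semi) {
  wx <- (seq_len(shape[1]) - 1) * voxel_size[1]
  wy <- (seq_len(shape[2]) - 1) * voxel_size[2]
  wz <- (seq_len(shape[3]) - 1) * voxel_size[3]
  ex <- ((wx - center[1]) / semi[1])^2
  ey <- ((wy - center[2]) / semi[2])^2
  ez <- ((wz - center[3]) / semi[3])^2
  outer(outer(ex, ey, "+"), ez, "+") <= 1
}

## linear voxel indices of a sphere (world mm); always contains the voxel
## nearest to the centre so a lesion is never empty
rasterize_sphere <- function(shape, voxel_size, center, radius) {
  lo <- pmax(1L, floor((center - radius) / voxel_size) + 1L)
  hi <- pmin(shape, ceiling((center + radius) / voxel_size) + 1L)
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  w <- cbind((g$x - 1) * voxel_size[1], (g$y - 1) * voxel_size[2],
             (g$z - 1) * voxel_size[3])
  d2 <- (w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 + (w[, 3] - center[3])^2
  keep <- d2 <= radius^2
  if (!any(keep)) keep[which.min(d2)] <- TRUE
  gi <- g[keep, , drop = FALSE]
  as.integer(gi$x + (gi$y - 1L) * shape[1] + (gi$z - 1L) * shape[1] * shape[2])
}

## anatomy masks shared by every subject of a spec
phantom_anatomy <- function(spec) {
  shp <- spec$shape; vs <- spec$voxel_size
  geo <- spec$geometry
  brain <- rasterize_ellipsoid(shp, vs, geo$brain$center, geo$brain$semi)
  csf <- rasterize_ellipsoid(shp, vs, geo$csf_l$center, geo$csf_l$semi) |
    rasterize_ellipsoid(shp, vs, geo$csf_r$center, geo$csf_r$semi)
  structures <- lapply(geo$structures, function(e)
    rasterize_ellipsoid(shp, vs, e$center, e$semi))
  template <- voxel_grid(array(0L, dim = shp), voxel_size = vs, kind = "mask")
  as_mask <- function(a) mask_like(template, a)
  str_masks <- lapply(structures, as_mask)
  ## derived internal capsule per hemisphere, minus all FIRST structures
  first_union <- Reduce(`|`, structures)
  ic <- list()
  for (side in c("l", "r")) {
    gp <- if (side == "l") str_masks[["13"]] else str_masks[["52"]]
    thal <- mask_or(str_masks[["10"]], str_masks[["49"]])
    caud <- mask_or(str_masks[["11"]], str_masks[["50"]])
    gp_all <- mask_or(str_masks[["13"]], str_masks[["52"]])
    m <- derive_internal_capsule(gp, thal, caud, gp_all, spec$capsule_radius_mm)
    arr <- m$values > 0L & !first_union & brain & !csf
    ic[[side]] <- arr
  }
  list(brain = brain, csf = csf, structures = structures,
       capsule = list(`14` = ic$l, `55` = ic$r), template = template)
}

## ---- sample-level generative laws ----------------------------------------

#' Sample from the phantom's generative intensity laws
#'
#' Draws lesion or normal-tissue voxel intensities from the laws the image
#' generator uses, without rasterizing a volume. These are the building blocks
#' for distribution-shape and appearance recovery experiments at scale.
#'
#' @param spec a [phantom_spec].
#' @param n number of draws.
#' @param channel `"T1w"`, `"T2w"` or `"T2sw"`.
#' @param structure structure name for the local normal-tissue level.
#' @param skew for `sample_lesion_intensity` on T2sw: `"negative"` (default,
#'   the reflected-Weibull law) or `"symmetric"` (Gaussian about the same
#'   base level), for experiments contrasting skewed and symmetric regimes.
#' @return Numeric vector of intensities (noise included).
#' @export
sample_lesion_intensity <- function(spec, n, channel = c("T2sw", "T1w", "T2w"),
                                    structure = "pallidum",
                                    skew = c("negative", "symmetric")) {
  channel <- match.arg(channel); skew <- match.arg(skew)
  noise <- stats::rnorm(n, 0, spec$noise_sd)
  if (channel == "T2sw") {
    p <- spec$lesion_t2sw
    core <- if (skew == "negative") {
      p$base - stats::rweibull(n, shape = p$shape, scale = p$scale)
    } else {
      ## symmetric law with the same mean and spread as the reflected Weibull
      mu <- p$base - p$scale * gamma(1 + 1 / p$shape)
      sdv <- p$scale * sqrt(gamma(1 + 2 / p$shape) - gamma(1 + 1 / p$shape)^2)
      stats::rnorm(n, mu, sdv)
    }
    return(core + noise)
  }
  base <- spec$tissue[[channel]][[structure]] + spec$lesion_offsets[[channel]]
  base + noise
}

#' @rdname sample_lesion_intensity
#' @export
sample_tissue_intensity <- function(spec, n, channel = c("T2sw", "T1w", "T2w"),
                                    structure = "pallidum") {
  channel <- match.arg(channel)
  stats::rnorm(n, spec$tissue[[channel]][[structure]], spec$noise_sd)
}

#' @rdname sample_lesion_intensity
#' @export
sample_lesion_radius <- function(spec, n) {
  stats::runif(n, spec$lesion_radius_mm[1], spec$lesion_radius_mm[2])
}

#' Sample per-structure lesion counts from the phantom lesion plan
#'
#' @param spec a [phantom_spec].
#' @param n_subjects number of subjects to draw.
#' @return A tibble with `subject`, `code`, `n`.
#' @export
sample_lesion_counts <- function(spec, n_subjects = spec$n_subjects) {
  codes <- c(`11` = "caudate", `12` = "putamen", `13` = "pallidum",
             `14` = "capsule", `50` = "caudate", `51` = "putamen",
             `52` = "pallidum", `55` = "capsule")
  grid <- expand.grid(subject = seq_len(n_subjects),
                      code = as.integer(names(codes)))
  rate <- spec$lesion_rate[codes[as.character(grid$code)]]
  rate <- rate * ifelse(grid$code %in% LEFT_CODES, spec$lesion_asymmetry, 1)
  tibble::tibble(subject = grid$subject, code = grid$code,
                 n = stats::rpois(nrow(grid), rate))
}

## ---- subject generation ---------------------------------------------------

place_lesions <- function(spec, anat) {
  shp <- spec$shape; vs <- spec$voxel_size
  rates <- c(`11` = unname(spec$lesion_rate["caudate"] * spec$lesion_asymmetry),
             `12` = unname(spec$lesion_rate["putamen"] * spec$lesion_asymmetry),
             `13` = unname(spec$lesion_rate["pallidum"] * spec$lesion_asymmetry),
             `14` = unname(spec$lesion_rate["capsule"] * spec$lesion_asymmetry),
             `50` = unname(spec$lesion_rate["caudate"]),
             `51` = unname(spec$lesion_rate["putamen"]),
             `52` = unname(spec$lesion_rate["pallidum"]),
             `55` = unname(spec$lesion_rate["capsule"]))
  lesions <- list()
  hypo_arr <- array(FALSE, dim = shp)
  ## a candidate sphere is admissible if neither its voxels nor any of their
  ## 6-neighbours are already occupied, so distinct lesions can never merge
  ## into one face-connected component
  touches_existing <- function(vox) {
    if (any(hypo_arr[vox])) return(TRUE)
    co <- arrayInd(vox, shp)
    for (a in 1:3) for (s in c(-1L, 1L)) {
      nb <- co
      nb[, a] <- pmin(pmax(nb[, a] + s, 1L), shp[a])
      li <- nb[, 1] + (nb[, 2] - 1L) * shp[1] + (nb[, 3] - 1L) * shp[1] * shp[2]
      if (any(hypo_arr[li])) return(TRUE)
    }
    FALSE
  }
  for (code in names(rates)) {
    n_les <- stats::rpois(1L, rates[[code]])
    if (n_les == 0L) next
    ic_code <- code %in% c("14", "55")
    region_idx <- NULL
    if (ic_code) {
      region <- anat$capsule[[code]]
      region_idx <- which(region)
      if (length(region_idx) == 0L)
        stop(sprintf("lesion placement failed: empty capsule region (code %s)", code),
             call. = FALSE)
    } else {
      e <- spec$geometry$structures[[code]]
    }
    for (les in seq_len(n_les)) {
      r <- stats::runif(1, spec$lesion_radius_mm[1], spec$lesion_radius_mm[2])
      placed <- FALSE
      for (attempt in seq_len(240L)) {
        if (attempt %% 60L == 0L) r <- max(spec$lesion_radius_mm[1], r * 0.85)
        if (ic_code) {
          pick <- region_idx[sample.int(length(region_idx), 1L)]
          ctr <- (c((pick - 1L) %% shp[1],
                    ((pick - 1L) %/% shp[1]) %% shp[2],
                    (pick - 1L) %/% (shp[1] * shp[2]))) * vs
          vox <- rasterize_sphere(shp, vs, ctr, r)
          if (!all(region[vox])) next
        } else {
          semi_in <- e$semi - r
          if (any(semi_in <= 0)) { r <- r * 0.85; next }
          repeat {
            u <- stats::runif(3, -1, 1)
            if (sum(u^2) <= 1) break
          }
          ctr <- e$center + u * semi_in
          vox <- rasterize_sphere(shp, vs, ctr, r)
        }
        if (touches_existing(vox)) next
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("lesion placement failed in structure code %s after bounded retries",
                     code), call. = FALSE)
      hypo_arr[vox] <- TRUE
      lesions[[length(lesions) + 1L]] <- list(code = as.integer(code),
                                              center = ctr, radius = r,
                                              voxels = vox)
    }
  }
  lesions
}

structure_of_voxels <- function(anat, shp) {
  lab <- array(0L, dim = shp)
  for (code in names(anat$structures)) lab[anat$structures[[code]]] <- as.integer(code)
  lab[anat$capsule[["14"]]] <- 14L
  lab[anat$capsule[["55"]]] <- 55L
  lab
}

#' Generate one synthetic subject
#'
#' Builds a complete subject bundle: three channel volumes with tissue-class
#' contrast (CSF bright on T2w and dark on T1w, deep gray nuclei with the
#' caudate > putamen > pallidum T2*w brightness ordering), spherical lesions
#' with channel-specific contrast inserted into the basal ganglia and derived
#' internal-capsule region, a known per-subject affine intensity distortion,
#' and tissue masks with the partial-volume shell removed. The paired ground
#' truth records every lesion and the generative coefficients.
#'
#' @param spec a [phantom_spec].
#' @param subject_index positive subject number; 0 is reserved for the
#'   reference subject (see [generate_reference()]).
#' @return A list with elements `bundle` (class `subject_bundle`) and `truth`.
#' @export
generate_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "phantom_spec"), subject_index >= 0)
  set.seed(subject_seed(spec$seed, subject_index))
  is_reference <- subject_index == 0L
  shp <- spec$shape; vs <- spec$voxel_size
  anat <- phantom_anatomy(spec)
  lesions <- if (is_reference) list() else place_lesions(spec, anat)

  hypo <- array(0L, dim = shp)
  for (l in lesions) hypo[l$voxels] <- 1L

  strl <- structure_of_voxels(anat, shp)
  name_of <- c(`10` = "thalamus", `11` = "caudate", `12` = "putamen",
               `13` = "pallidum", `49` = "thalamus", `50` = "caudate",
               `51` = "putamen", `52` = "pallidum",
               `14` = "GMWM", `55` = "GMWM")
  channels <- list()
  for (ch in c("T1w", "T2w", "T2sw")) {
    tis <- spec$tissue[[ch]]
    vol <- array(0, dim = shp)
    vol[anat$brain] <- tis[["GMWM"]]
    vol[anat$csf] <- tis[["CSF"]]
    for (code in c("10", "11", "12", "13", "49", "50", "51", "52"))
      vol[anat$structures[[code]]] <- tis[[name_of[[code]]]]
    if (length(lesions) > 0) {
      for (l in lesions) {
        if (ch == "T2sw") {
          p <- spec$lesion_t2sw
          vol[l$voxels] <- p$base - stats::rweibull(length(l$voxels),
                                                    shape = p$shape, scale = p$scale)
        } else {
          vol[l$voxels] <- vol[l$voxels] + spec$lesion_offsets[[ch]]
        }
      }
    }
    if (spec$noise_sd > 0)
      vol[anat$brain] <- vol[anat$brain] +
        stats::rnorm(sum(anat$brain), 0, spec$noise_sd)
    if (spec$bias_amplitude > 0) {
      wx <- cos(pi * (seq_len(shp[1]) - 1) / (shp[1] - 1))
      wy <- cos(pi * (seq_len(shp[2]) - 1) / (shp[2] - 1))
      wz <- cos(pi * (seq_len(shp[3]) - 1) / (shp[3] - 1))
      field <- 1 + spec$bias_amplitude * outer(outer(wx, wy), wz)
      vol <- vol * field
    }
    channels[[ch]] <- vol
  }

  if (is_reference) {
    a <- 1; b <- 0
  } else {
    a <- stats::runif(1, spec$distortion_slope[1], spec$distortion_slope[2])
    b <- stats::runif(1, spec$distortion_intercept[1], spec$distortion_intercept[2])
  }
  for (ch in names(channels)) {
    v <- channels[[ch]]
    v[anat$brain] <- a * v[anat$brain] + b
    channels[[ch]] <- v
  }

  ## tissue masks: GM/WM and CSF with lesions and the mixel shell excluded
  gmwm_region <- anat$brain & !anat$csf & !(hypo > 0L)
  csf_region <- anat$csf & !(hypo > 0L)
  for (i in seq_len(spec$mixel_shell)) {
    gmwm_region <- erode6(gmwm_region)
    csf_region <- erode6(csf_region)
  }

  template <- anat$template
  grid_of <- function(arr, kind) {
    voxel_grid(if (kind == "mask") array(as.integer(arr), dim = shp)
               else array(arr, dim = shp),
               voxel_size = vs, kind = kind)
  }
  structure_masks <- lapply(anat$structures, function(a) grid_of(a, "mask"))
  subject_id <- if (is_reference) "reference" else sprintf("sub%03d", subject_index)
  bundle <- structure(list(
    subject_id = subject_id,
    channels = lapply(channels, grid_of, kind = "intensity"),
    hypo_mask = grid_of(hypo > 0L, "mask"),
    brain_mask = grid_of(anat$brain, "mask"),
    structure_masks = structure_masks,
    tissue_masks = list(GMWM = grid_of(gmwm_region, "mask"),
                        CSF = grid_of(csf_region, "mask")),
    warp = NULL
  ), class = "subject_bundle")

  icv <- mask_volume_mm3(bundle$brain_mask)
  les_tbl <- if (length(lesions) == 0) {
    tibble::tibble(subject_id = character(), lesion = integer(), code = integer(),
                   cx = numeric(), cy = numeric(), cz = numeric(),
                   radius_mm = numeric(), n_voxels = integer())
  } else {
    tibble::tibble(
      subject_id = subject_id,
      lesion = seq_along(lesions),
      code = vapply(lesions, `[[`, integer(1), "code"),
      cx = vapply(lesions, function(l) l$center[1], numeric(1)),
      cy = vapply(lesions, function(l) l$center[2], numeric(1)),
      cz = vapply(lesions, function(l) l$center[3], numeric(1)),
      radius_mm = vapply(lesions, `[[`, numeric(1), "radius"),
      n_voxels = vapply(lesions, function(l) length(l$voxels), integer(1))
    )
  }
  vox_mm3 <- prod(vs)
  counts <- tibble::tibble(code = LABEL_SET) |>
    dplyr::left_join(
      les_tbl |> dplyr::count(.data$code, wt = .data$n_voxels, name = "n_voxels") |>
        dplyr::left_join(dplyr::count(les_tbl, .data$code), by = "code"),
      by = "code") |>
    dplyr::mutate(subject_id = subject_id,
                  n = dplyr::coalesce(.data$n, 0L),
                  volume_mm3 = dplyr::coalesce(.data$n_voxels, 0L) * vox_mm3,
                  load_ppm = 1e6 * .data$volume_mm3 / icv) |>
    dplyr::select("subject_id", "code", "n", "volume_mm3", "load_ppm")
  truth <- list(
    lesions = les_tbl,
    lesion_voxels = lapply(lesions, `[[`, "voxels"),
    counts = counts,
    distortion = tibble::tibble(subject_id = subject_id, slope = a, intercept = b),
    icv_mm3 = icv
  )
  list(bundle = bundle, truth = truth)
}

#' Generate the lesion-free reference subject
#'
#' One bundle with undistorted intensities (unit slope, zero intercept) and no
#' lesions, serving as the intensity-standardization and spatial reference.
#'
#' @param spec a [phantom_spec].
#' @return A `subject_bundle`.
#' @export
generate_reference <- function(spec) {
  generate_subject(spec, 0L)$bundle
}

#' Generate a full synthetic cohort
#'
#' `n_subjects` bundles plus the reference, with per-subject seeds derived
#' deterministically from the master seed, pooled ground-truth tables and a
#' manifest.
#'
#' @param spec a [phantom_spec].
#' @return A list with `subjects` (list of bundles), `reference`, `truth`
#'   (pooled tables plus per-subject lesion voxel sets) and `manifest`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$n_subjects >= 1)
  subs <- lapply(seq_len(spec$n_subjects), function(i) generate_subject(spec, i))
  bundles <- lapply(subs, `[[`, "bundle")
  ids <- vapply(bundles, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject_id in cohort", call. = FALSE)
  reference <- generate_reference(spec)
  truth <- list(
    lesions = dplyr::bind_rows(lapply(subs, function(s) s$truth$lesions)),
    counts = dplyr::bind_rows(lapply(subs, function(s) s$truth$counts)),
    distortion = dplyr::bind_rows(lapply(subs, function(s) s$truth$distortion)),
    lesion_voxels = stats::setNames(lapply(subs, function(s) s$truth$lesion_voxels), ids),
    icv_mm3 = stats::setNames(vapply(subs, function(s) s$truth$icv_mm3, numeric(1)), ids)
  )
  manifest <- tibble::tibble(
    entry = seq_len(spec$n_subjects + 1L),
    subject_id = c(ids, "reference"),
    type = c(rep("subject", spec$n_subjects), "reference")
  )
  list(subjects = bundles, reference = reference, truth = truth,
       manifest = manifest, spec = spec)
}

#' Write a synthetic cohort to disk
#'
#' Writes each bundle's NIfTI volumes and masks, the ground-truth CSV tables
#' and a JSON manifest under `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bundle <- function(b) {
    sd <- file.path(dir, b$subject_id)
    dir.create(sd, showWarnings = FALSE)
    for (ch in names(b$channels))
      write_volume(b$channels[[ch]], file.path(sd, paste0(ch, ".nii.gz")))
    write_volume(b$hypo_mask, file.path(sd, "hypo_mask.nii.gz"))
    write_volume(b$brain_mask, file.path(sd, "brain_mask.nii.gz"))
    for (code in names(b$structure_masks))
      write_volume(b$structure_masks[[code]],
                   file.path(sd, sprintf("structure_%s.nii.gz", code)))
    write_volume(b$tissue_masks$GMWM, file.path(sd, "tissue_GMWM.nii.gz"))
    write_volume(b$tissue_masks$CSF, file.path(sd, "tissue_CSF.nii.gz"))
  }
  for (b in cohort$subjects) write_bundle(b)
  write_bundle(cohort$reference)
  utils::write.csv(cohort$truth$lesions, file.path(dir, "truth_lesions.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$counts, file.path(dir, "truth_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$distortion, file.path(dir, "truth_distortion.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
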