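#' Per-structure hypointensity burden
#'
#' Counts and ICV-normalized loads of labeled components per structure code,
#' with left / right / all aggregates. The load is the total component volume
#' in a structure divided by intracranial volume, reported in parts per
#' million (ppm = 1e6 * V / ICV). Outside components (label 0) are excluded.
#'
#' @param cs a labeled `component_set`.
#' @param icv intracranial volume in mm^3 (> 0).
#' @param subject_id id recorded in the table.
#' @return A `burden_table` tibble: `subject_id`, `structure` (code as
#'   character, plus `"left"`, `"right"`, `"all"`), `n`, `volume_mm3`,
#'   `load_ppm`.
#' @export
burden <- function(cs, icv, subject_id = NA_character_) {
  stopifnot(inherits(cs, "component_set"), isTRUE(cs$labeled))
  if (!is.numeric(icv) || icv <= 0) stop("`icv` must be > 0", call. = FALSE)
  vox_mm3 <- prod(cs$voxel_size)
  comp <- cs$components[cs$components$label != 0L, ]
  per_code <- tibble::tibble(code = LABEL_SET) |>
    dplyr::left_join(
      comp |> dplyr::group_by(code = .data$label) |>
        dplyr::summarise(n = dplyr::n(), nv = sum(.data$n_voxels)),
      by = "code") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  volume_mm3 = dplyr::coalesce(.data$nv, 0L) * vox_mm3,
                  load_ppm = 1e6 * .data$volume_mm3 / icv) |>
    dplyr::select("code", "n", "volume_mm3", "load_ppm")
  agg <- function(codes, tag) {
    sub <- per_code[per_code$code %in% codes, ]
    tibble::tibble(structure = tag, n = sum(sub$n),
                   volume_mm3 = sum(sub$volume_mm3),
                   load_ppm = sum(sub$load_ppm))
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(per_code, structure = as.character(.data$code)) |>
      dplyr::select("structure", "n", "volume_mm3", "load_ppm"),
    agg(LEFT_CODES, "left"), agg(RIGHT_CODES, "right"), agg(LABEL_SET, "all")
  )
  out <- dplyr::mutate(out, subject_id = subject_id, icv_mm3 = icv, .before = 1)
  class(out) <- c("burden_table", class(out))
  out
}

#' Left/right burden asymmetry test
#'
#' Two-sided Wilcoxon rank sum tests comparing the per-subject left- and
#' right-hemisphere totals of component count and load across a cohort. The
#' exact null distribution is used when the combined sample size is at most 20
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param bt_list list of `burden_table`s (one per subject).
#' @return A tibble with one row per metric (`count`, `load_ppm`): `p_value`,
#'   `method`, and `degenerate` (all-zero on both sides, reported as p = 1).
#' @export
left_right_test <- function(bt_list) {
  if (inherits(bt_list, "burden_table")) bt_list <- list(bt_list)
  if (length(bt_list) < 2L) stop("need >= 2 subjects", call. = FALSE)
  pull_side <- function(side, col)
    vapply(bt_list, function(b) b[[col]][b$structure == side], numeric(1))
  one <- function(metric, col) {
    l <- pull_side("left", col); r <- pull_side("right", col)
    if (all(l == 0) && all(r == 0))
      return(tibble::tibble(metric = metric, p_value = 1,
                            method = "degenerate", degenerate = TRUE))
    res <- rank_sum_test(l, r, exact_max_n = 20L)
    tibble::tibble(metric = metric, p_value = res$p, method = res$method,
                   degenerate = FALSE)
  }
  dplyr::bind_rows(one("count", "n"), one("load_ppm", "load_ppm"))
}

## shared Wilcoxon/Mann-Whitney wrapper with explicit exact/approximate rule
rank_sum_test <- function(a, b, exact_max_n = NULL, exact_min_n = NULL) {
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties &&
    ((!is.null(exact_max_n) && length(a) + length(b) <= exact_max_n) ||
     (!is.null(exact_min_n) && min(length(a), length(b)) <= exact_min_n))
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(U = unname(res$statistic), p = res$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Morphology of a single component
#'
#' Discrete 3D shape descriptors of one hypointensity component. The number
#' of occupied axial slices is counted on the native grid, because the
#' inter-slice (`n_slices > 1`) vs intra-slice (`n_slices = 1`) dichotomy
#' reflects the acquisition slices; volume, maximum in-plane area, compactness
#' and relative anisotropy are computed after nearest-neighbour resampling to
#' a 1 mm isotropic lattice.
#'
#' Compactness is the discrete (enclosing-surface) compactness
#' `C = (n - A/6) / (n - n^(2/3))` with `n` the voxel count and `A` the number
#' of exposed faces, clamped to \[0, 1\] and defined as 1 for a single voxel;
#' cubes attain the maximum 1. Relative anisotropy is computed from the
#' eigenvalues (l1, l2, l3) of the voxel-centre covariance (no per-voxel
#' self-moment): `RA = sqrt(sum((li - lbar)^2)) / (sqrt(3) * lbar) / sqrt(2)`,
#' which is 0 for isotropic objects (equal eigenvalues), 1 for a straight
#' one-voxel-wide segment, and invariant to lattice rotations.
#'
#' @param component_mask nonempty binary [voxel_grid] mask of one component.
#' @param target_mm isotropic resampling edge (default 1 mm).
#' @return A one-row tibble: `n_slices`, `class` (`"inter"`/`"intra"`),
#'   `n_voxels_iso`, `volume_mm3`, `max_area_mm2`, `compactness`,
#'   `relative_anisotropy`.
#' @export
morphology <- function(component_mask, target_mm = 1) {
  stopifnot_mask(component_mask)
  if (sum(component_mask$values) == 0L)
    stop("empty component mask", call. = FALSE)
  idx_native <- which(component_mask$values > 0L, arr.ind = TRUE)
  n_slices <- length(unique(idx_native[, 3]))

  iso <- resample_nearest_isotropic(component_mask, target_mm)
  idx <- which(iso$values > 0L, arr.ind = TRUE)
  n <- nrow(idx)
  vox_vol <- target_mm^3
  volume <- n * vox_vol
  area <- max(table(idx[, 3])) * target_mm^2

  comp <- discrete_compactness(iso)
  ra <- relative_anisotropy(idx, target_mm)

  tibble::tibble(
    n_slices = n_slices,
    class = if (n_slices > 1L) "inter" else "intra",
    n_voxels_iso = n,
    volume_mm3 = volume,
    max_area_mm2 = area,
    compactness = comp,
    relative_anisotropy = ra
  )
}

## exposed-face count A and Bribiesca-style discrete compactness
discrete_compactness <- function(m) {
  arr <- m$values > 0L
  n <- sum(arr)
  if (n == 1L) return(1)
  adj <- 0L
  for (a in 1:3) adj <- adj + sum(arr & shift3(arr, a, 1L))
  A <- 6 * n - 2 * adj
  val <- (n - A / 6) / (n - n^(2 / 3))
  min(max(val, 0), 1)
}

relative_anisotropy <- function(idx, target_mm = 1) {
  if (nrow(idx) == 1L) return(0)
  xyz <- sweep(idx, 2, colMeans(idx)) * target_mm
  cv <- crossprod(xyz) / nrow(xyz)
  lam <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  lbar <- mean(lam)
  if (lbar <= 0) return(0)
  sqrt(sum((lam - lbar)^2)) / (sqrt(3) * lbar) / sqrt(2)
}

#' Morphology of all labeled components of a subject
#'
#' @param cs a labeled `component_set` (outside components are skipped).
#' @param subject_id id recorded in the table.
#' @param target_mm isotropic resampling edge.
#' @return A tibble, one row per inside component, with the [morphology()]
#'   columns plus `subject_id`, `component`, `label`.
#' @export
morphology_components <- function(cs, subject_id = NA_character_, target_mm = 1) {
  stopifnot(inherits(cs, "component_set"), isTRUE(cs$labeled))
  keep <- which(cs$components$label != 0L)
  purrr::map_dfr(keep, function(i) {
    rec <- morphology(component_mask(cs, cs$components$component[i]), target_mm)
    dplyr::mutate(rec, subject_id = subject_id,
                  component = cs$components$component[i],
                  label = cs$components$label[i], .before = 1)
  })
}

#' Quartile summary of morphology records by slice class
#'
#' 25th/50th/75th percentiles (type-7 linear interpolation) of each morphology
#' metric for inter-slice, intra-slice and all components, plus rank-sum
#' p-values comparing the two classes. A class with no records yields missing
#' percentiles.
#'
#' @param records tibble of [morphology()] rows.
#' @return A tibble: `metric`, `class`, `q25`, `q50`, `q75`, `n`,
#'   `p_inter_vs_intra`.
#' @export
morphology_summary <- function(records) {
  stopifnot(nrow(records) >= 1L)
  metrics <- c("volume_mm3", "max_area_mm2", "compactness", "relative_anisotropy")
  classes <- list(inter = records[records$class == "inter", ],
                  intra = records[records$class == "intra", ],
                  both = records)
  out <- purrr::map_dfr(metrics, function(mt) {
    xi <- records[[mt]][records$class == "inter"]
    xa <- records[[mt]][records$class == "intra"]
    p <- if (length(xi) > 0 && length(xa) > 0)
      rank_sum_test(xi, xa, exact_max_n = 20L)$p else NA_real_
    purrr::map_dfr(names(classes), function(cl) {
      x <- classes[[cl]][[mt]]
      q <- if (length(x) > 0) stats::quantile(x, c(.25, .5, .75), type = 7,
                                              names = FALSE)
           else rep(NA_real_, 3)
      tibble::tibble(metric = mt, class = cl, q25 = q[1], q50 = q[2],
                     q75 = q[3], n = length(x), p_inter_vs_intra = p)
    })
  })
  out
}
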