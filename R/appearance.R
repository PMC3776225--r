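#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank sum) test between two samples. The
#' exact null distribution is used when the smaller sample has at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity correction.
#'
#' @param a,b nonempty numeric samples.
#' @return A one-row tibble: `U` (statistic of `a`), `p_value`, `method`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample", call. = FALSE)
  res <- rank_sum_test(a, b, exact_min_n = 8L)
  tibble::tibble(U = res$U, p_value = res$p, method = res$method)
}

#' Classify hypointensity appearance relative to normal tissue
#'
#' A structure's hypointensities are called hypo- or hyperintense on a channel
#' only if (i) their standardized intensities differ significantly from the
#' normal-appearing tissue intensities (Mann-Whitney U, two-sided, level
#' `alpha`), and (ii) their median is darker or brighter than the
#' normal-appearing median. Otherwise they are isointense; a significant test
#' with exactly equal medians is classified isointense with a warning.
#'
#' The classification is invariant to any common affine intensity rescaling
#' of both samples with positive slope.
#'
#' @param hypo_sample standardized intensities inside the hypointensity mask.
#' @param nabg_sample standardized intensities of normal-appearing tissue.
#' @param alpha significance level in (0, 1), default 0.05.
#' @return `"hypo"`, `"iso"` or `"hyper"`.
#' @export
classify_appearance <- function(hypo_sample, nabg_sample, alpha = 0.05) {
  if (length(hypo_sample) == 0L || length(nabg_sample) == 0L)
    stop("empty sample", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)", call. = FALSE)
  p <- mann_whitney(hypo_sample, nabg_sample)$p_value
  if (p >= alpha) return("iso")
  mh <- stats::median(hypo_sample)
  mn <- stats::median(nabg_sample)
  if (mh < mn) "hypo"
  else if (mh > mn) "hyper"
  else { warning("significant test but equal medians; classified iso"); "iso" }
}

#' Classify all structures of a subject on T1w and T2w
#'
#' Pools each structure's labeled components (per-structure samples are the
#' subject's component voxels in that structure merged across hemispheres)
#' and classifies their appearance on the T1w and T2w channels against the
#' structure's normal-appearing tissue.
#'
#' @param bundle standardized `subject_bundle`.
#' @param cs labeled `component_set`.
#' @param channels channels to classify.
#' @param alpha significance level.
#' @param merge_hemispheres pool left/right structure samples (default TRUE).
#' @return A tibble: `subject_id`, `structure`, `channel`, `class`,
#'   `n_hypo_voxels`.
#' @export
classify_bundle_appearance <- function(bundle, cs, channels = c("T1w", "T2w"),
                                       alpha = 0.05, merge_hemispheres = TRUE) {
  stopifnot(inherits(cs, "component_set"), isTRUE(cs$labeled))
  lab_tbl <- bg_labels()
  comp <- cs$components[cs$components$label != 0L, ]
  if (nrow(comp) == 0L)
    return(tibble::tibble(subject_id = character(), structure = character(),
                          channel = character(), class = character(),
                          n_hypo_voxels = integer()))
  comp$structure <- lab_tbl$structure[match(comp$label, lab_tbl$code)]
  groups <- if (merge_hemispheres) split(comp, comp$structure)
            else split(comp, paste(comp$structure, comp$label))
  all_hypo <- unlist(cs$components$voxels)
  rows <- list()
  for (gname in names(groups)) {
    gr <- groups[[gname]]
    hypo_vox <- unlist(gr$voxels)
    codes <- lab_tbl$code[lab_tbl$structure == gr$structure[1]]
    if (!merge_hemispheres) codes <- unique(gr$label)
    smask <- Reduce(`|`, lapply(as.character(codes), function(cd) {
      m <- bundle$structure_masks[[cd]]
      if (is.null(m)) array(FALSE, dim = cs$shape) else m$values > 0L
    }))
    na_vox <- setdiff(which(smask), all_hypo)
    if (length(na_vox) == 0L) next
    for (ch in channels) {
      v <- bundle$channels[[ch]]$values
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = bundle$subject_id, structure = gr$structure[1],
        channel = ch,
        class = classify_appearance(v[hypo_vox], v[na_vox], alpha),
        n_hypo_voxels = length(hypo_vox))
    }
  }
  dplyr::bind_rows(rows)
}

#' Cohort appearance percentages
#'
#' Per structure and channel, the percentage of contributing subjects whose
#' hypointensities were classified hypo-, iso- or hyperintense. Denominators
#' are the subjects that have hypointensities in that structure, so
#' percentages sum to 100 within each structure/channel cell.
#'
#' @param classes tibble of per-subject classifications as returned by
#'   [classify_bundle_appearance()] (columns `subject_id`, `structure`,
#'   `channel`, `class`).
#' @return A tibble: `structure`, `channel`, `class`, `n`, `n_subjects`,
#'   `percent`.
#' @export
appearance_report <- function(classes) {
  stopifnot(nrow(classes) >= 1L)
  classes |>
    dplyr::count(.data$structure, .data$channel, .data$class, name = "n") |>
    dplyr::group_by(.data$structure, .data$channel) |>
    dplyr::mutate(n_subjects = sum(.data$n),
                  percent = 100 * .data$n / .data$n_subjects) |>
    dplyr::ungroup()
}
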