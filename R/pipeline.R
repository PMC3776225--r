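#' Validate a subject bundle
#'
#' Consistency checks run before analysis: all grids share shape and voxel
#' size (hard error otherwise, naming the offending volume), the channel set
#' is exactly T1w/T2w/T2sw, masks are binary, structure label codes are drawn
#' from the known set (basal ganglia + internal capsule labels plus thalamus,
#' which the internal-capsule derivation consumes), structures are nonempty,
#' and hypointensity voxels lie inside the brain mask.
#'
#' @param bundle a `subject_bundle`.
#' @return A QC tibble with columns `level` (`"warning"`), `check`, `detail`;
#'   zero rows means a clean bundle. Hard inconsistencies abort.
#' @export
validate_inputs <- function(bundle) {
  ref_dim <- vg_shape(bundle$channels[[1]])
  ref_vs <- bundle$channels[[1]]$voxel_size
  all_grids <- c(bundle$channels,
                 list(hypo_mask = bundle$hypo_mask, brain_mask = bundle$brain_mask),
                 bundle$structure_masks, bundle$tissue_masks)
  for (nm in names(all_grids)) {
    g <- all_grids[[nm]]
    if (!identical(vg_shape(g), ref_dim))
      stop(sprintf("shape mismatch in '%s': %s vs %s", nm,
                   paste(vg_shape(g), collapse = "x"),
                   paste(ref_dim, collapse = "x")), call. = FALSE)
    if (any(abs(g$voxel_size - ref_vs) > 1e-6))
      stop(sprintf("voxel size mismatch in '%s'", nm), call. = FALSE)
  }
  if (!setequal(names(bundle$channels), c("T1w", "T2w", "T2sw")))
    stop("channel set must be exactly {T1w, T2w, T2sw}", call. = FALSE)
  known <- c(LABEL_SET, THALAMUS_CODES)
  codes <- as.integer(names(bundle$structure_masks))
  bad <- setdiff(codes, known)
  if (length(bad) > 0)
    stop(sprintf("unknown structure label code(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  warn <- list()
  for (nm in names(bundle$structure_masks)) {
    if (sum(bundle$structure_masks[[nm]]$values) == 0L)
      warn[[length(warn) + 1L]] <- tibble::tibble(
        level = "warning", check = "empty_structure",
        detail = sprintf("structure mask %s is empty", nm))
  }
  n_out <- sum(bundle$hypo_mask$values > 0L & bundle$brain_mask$values == 0L)
  if (n_out > 0)
    warn[[length(warn) + 1L]] <- tibble::tibble(
      level = "warning", check = "hypo_outside_brain",
      detail = sprintf("%d hypointensity voxels outside the brain mask", n_out))
  for (nm in names(bundle$tissue_masks)) {
    if (!all(bundle$tissue_masks[[nm]]$values %in% c(0L, 1L)))
      stop(sprintf("tissue mask %s is not binary", nm), call. = FALSE)
  }
  if (length(warn)) dplyr::bind_rows(warn) else
    tibble::tibble(level = character(), check = character(), detail = character())
}

## structure masks used for labeling: FIRST nuclei plus the derived internal
## capsule, with capsule voxels ceded to any FIRST structure that claims them
labeling_structures <- function(bundle, capsule_radius_mm = 6) {
  sm <- bundle$structure_masks
  get <- function(code) sm[[as.character(code)]]
  thal <- mask_or(get(10), get(49))
  caud <- mask_or(get(11), get(50))
  gp_all <- mask_or(get(13), get(52))
  first_codes <- c(11L, 12L, 13L, 50L, 51L, 52L)
  first_union <- Reduce(mask_or, lapply(as.character(first_codes), function(cd) sm[[cd]]))
  out <- stats::setNames(lapply(as.character(first_codes), function(cd) sm[[cd]]),
                         as.character(first_codes))
  for (side in c(14L, 55L)) {
    gp <- if (side == 14L) get(13) else get(52)
    ic <- derive_internal_capsule(gp, thal, caud, gp_all, capsule_radius_mm)
    ic <- mask_diff(ic, first_union)
    ic <- mask_and(ic, bundle$brain_mask)
    ## midline voxels reached by both dilations go to the left capsule
    if (side == 55L) ic <- mask_diff(ic, out[["14"]])
    out[[as.character(side)]] <- ic
  }
  out
}

## default pipeline configuration; user config entries override
default_config <- function() {
  list(
    out_dir = NULL,
    simulate = list(n_subjects = 5, seed = 1L),
    input_dir = NULL,
    seed = 1L,
    alpha = 0.05,
    capsule_radius_mm = NULL,  # NULL = phantom-scaled (simulated) or 6 mm (loaded)
    resample_mm = 1,
    min_overlap_fraction = 0.5,
    threshold_quantile = 0.97,
    huber_c = 1.345,
    quantile_type = 7,
    bin_grid = list(n_candidates = 100, lo_divisor = 200, hi_divisor = 2),
    ground_truth = TRUE,
    resume = FALSE
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$out_dir)) stop("config must set `out_dir`", call. = FALSE)
  cfg
}

#' Run the full hypointensity analysis pipeline
#'
#' Orchestrates simulate (or load) -> validate -> standardize -> internal
#' capsule derivation -> component labeling -> burden and morphology ->
#' spatial probability mapping -> thresholds and intensity distributions ->
#' appearance classification, writing every stage's table under
#' `config$out_dir` along with a manifest and run log. Deterministic given
#' the seed and inputs.
#'
#' @param config a named list or path to a YAML file. Recognized entries:
#'   `out_dir` (required), `simulate` (arguments for [phantom_spec()]) or
#'   `input_dir` (a cohort directory written by [write_cohort()]), `seed`,
#'   `alpha`, `capsule_radius_mm`, `resample_mm`, `min_overlap_fraction`,
#'   `huber_c`, `ground_truth`, `resume`.
#' @return Invisibly, the cohort report: a list with burden tables, the
#'   left/right test, morphology records and summary, threshold report,
#'   aggregated histograms per channel, the appearance report, the aggregate
#'   spatial map, QC, and recovery metrics when ground truth is available.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- digest_config(cfg)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  if (isTRUE(cfg$resume) && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(old$config_hash, cfg_hash) &&
        all(file.exists(file.path(cfg$out_dir, unlist(old$files))))) {
      message("outputs up to date (config hash match); reusing cached run")
      return(invisible(read_report(cfg$out_dir)))
    }
  }
  log_lines <- c(sprintf("bghypo %s pipeline run", as.character(utils::packageVersion("bghypo"))),
                 sprintf("R %s", as.character(getRversion())),
                 sprintf("config hash %s", cfg_hash),
                 paste0("  ", names(flatten_config(cfg)), " = ",
                        unlist(flatten_config(cfg))))

  ## ---- inputs ----
  if (!is.null(cfg$input_dir)) {
    cohort <- read_cohort(cfg$input_dir)
    if (is.null(cfg$capsule_radius_mm)) cfg$capsule_radius_mm <- 6
  } else {
    sim <- cfg$simulate
    if (is.null(sim$seed)) sim$seed <- cfg$seed
    spec <- do.call(phantom_spec, sim)
    cohort <- generate_cohort(spec)
    ## keep the capsule kernel consistent with the phantom's geometry scale
    if (is.null(cfg$capsule_radius_mm)) cfg$capsule_radius_mm <- spec$capsule_radius_mm
  }
  subjects <- cohort$subjects
  reference <- cohort$reference
  qc <- purrr::map_dfr(subjects, function(b)
    dplyr::mutate(validate_inputs(b), subject_id = b$subject_id, .before = 1))

  ## ---- standardization ----
  std <- lapply(subjects, standardize_bundle, reference = reference, c = cfg$huber_c)
  models <- purrr::map_dfr(std, function(b)
    dplyr::mutate(purrr::map_dfr(b$models, glance), subject_id = b$subject_id,
                  .before = 1))

  ## ---- labeling ----
  labeled <- lapply(std, function(b) {
    structs <- labeling_structures(b, cfg$capsule_radius_mm)
    cs <- connected_components(b$hypo_mask)
    assign_labels(cs, structs, b$channels$T2sw,
                  min_fraction = cfg$min_overlap_fraction)
  })
  comp_tbl <- purrr::map_dfr(seq_along(std), function(i)
    component_table(labeled[[i]], std[[i]]$subject_id))
  fractions <- structure_fraction_report(labeled)

  ## ---- burden & morphology ----
  burdens <- lapply(seq_along(std), function(i)
    burden(labeled[[i]], intracranial_volume(std[[i]]$brain_mask),
           std[[i]]$subject_id))
  lr <- if (length(burdens) >= 2) left_right_test(burdens) else
    tibble::tibble(metric = c("count", "load_ppm"), p_value = NA_real_,
                   method = "not run (single subject)", degenerate = NA)
  morph <- purrr::map_dfr(seq_along(std), function(i)
    morphology_components(labeled[[i]], std[[i]]$subject_id, cfg$resample_mm))
  morph_sum <- if (nrow(morph) > 0) morphology_summary(morph) else NULL

  ## ---- spatial ----
  ref_grid <- reference$hypo_mask
  maps <- lapply(std, function(b)
    subject_spatial_map(b$hypo_mask, b$warp, ref_grid))
  spatial <- aggregate_spatial(maps)

  ## ---- intensity distributions & thresholds ----
  thresholds <- purrr::map_dfr(seq_along(std), function(i)
    threshold_report(std[[i]], labeled[[i]]))
  hist_samples <- function(ch) lapply(seq_along(std), function(i) {
    vox <- unlist(labeled[[i]]$components$voxels[labeled[[i]]$components$label != 0L])
    std[[i]]$channels[[ch]]$values[vox]
  })
  hists <- lapply(stats::setNames(nm = c("T1w", "T2w", "T2sw")), function(ch) {
    s <- hist_samples(ch)
    if (sum(lengths(s)) == 0) NULL else aggregate_histograms(s, ch)
  })

  ## ---- appearance ----
  classes <- purrr::map_dfr(seq_along(std), function(i)
    classify_bundle_appearance(std[[i]], labeled[[i]], alpha = cfg$alpha))
  appearance <- if (nrow(classes) > 0) appearance_report(classes) else NULL

  ## ---- ground-truth recovery ----
  recovery <- NULL
  if (isTRUE(cfg$ground_truth) && !is.null(cohort$truth)) {
    recovery <- recovery_metrics(cohort, labeled, burdens)
  }

  ## ---- outputs ----
  out <- cfg$out_dir
  wcsv <- function(x, f) { utils::write.csv(x, file.path(out, f), row.names = FALSE); f }
  files <- c(
    wcsv(qc, "qc.csv"),
    wcsv(models, "standardization_models.csv"),
    wcsv(comp_tbl, "components.csv"),
    wcsv(fractions, "structure_fractions.csv"),
    wcsv(dplyr::bind_rows(burdens), "burden.csv"),
    wcsv(lr, "left_right_test.csv"),
    wcsv(morph, "morphology.csv"),
    wcsv(thresholds, "thresholds.csv"),
    wcsv(classes, "appearance_classes.csv")
  )
  if (!is.null(morph_sum)) files <- c(files, wcsv(morph_sum, "morphology_summary.csv"))
  if (!is.null(appearance)) files <- c(files, wcsv(appearance, "appearance_report.csv"))
  if (!is.null(recovery)) files <- c(files, wcsv(recovery, "recovery.csv"))
  for (ch in names(hists)) {
    if (is.null(hists[[ch]])) next
    h <- hists[[ch]]
    files <- c(files, wcsv(
      tibble::tibble(edge_lo = h$edges[-length(h$edges)],
                     edge_hi = h$edges[-1], density = h$density),
      sprintf("histogram_%s.csv", ch)))
  }
  write_volume(spatial, file.path(out, "spatial_map.nii.gz"))
  files <- c(files, "spatial_map.nii.gz")
  shape_json <- purrr::compact(lapply(hists, function(h)
    if (is.null(h)) NULL else
      list(width = h$width, quartiles = as.list(h$quartiles), iqr = h$iqr,
           bowley = h$bowley, n_modes = h$n_modes)))
  jsonlite::write_json(shape_json, file.path(out, "distribution_shape.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "distribution_shape.json")
  jsonlite::write_json(list(config_hash = cfg_hash, files = files,
                            parameters = flatten_config(cfg)),
                       manifest_path, auto_unbox = TRUE)
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(list(
    config = cfg, qc = qc, models = models, components = comp_tbl,
    fractions = fractions, burden = burdens, left_right = lr,
    morphology = morph, morphology_summary = morph_sum,
    thresholds = thresholds, histograms = hists, appearance = appearance,
    classes = classes, spatial = spatial, recovery = recovery,
    labeled = labeled, truth = cohort$truth
  ))
}

## recovery metrics against the generator's ground truth
recovery_metrics <- function(cohort, labeled, burdens) {
  truth <- cohort$truth
  ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    cs <- labeled[[i]]
    bt <- burdens[[i]]
    tc <- truth$counts[truth$counts$subject_id == id, ]
    per_code <- bt[bt$structure %in% as.character(LABEL_SET), ]
    per_code$code <- as.integer(per_code$structure)
    j <- dplyr::left_join(tc, per_code, by = "code",
                          suffix = c("_true", "_est"))
    count_err <- sum(abs(j$n_est - j$n_true))
    load_err <- max(abs(j$load_ppm_est - j$load_ppm_true))
    lv <- if (!is.null(truth$lesion_voxels)) truth$lesion_voxels[[id]] else NULL
    n_correct <- 0L
    for (k in seq_along(lv)) {
      vox1 <- lv[[k]][1]
      hit <- which(vapply(cs$components$voxels, function(v) vox1 %in% v, logical(1)))
      code_true <- truth$lesions$code[truth$lesions$subject_id == id][k]
      if (length(hit) == 1L && cs$components$label[hit] == code_true)
        n_correct <- n_correct + 1L
    }
    rows[[i]] <- tibble::tibble(
      subject_id = id, n_lesions = length(lv),
      count_abs_error = count_err, load_max_abs_error_ppm = load_err,
      labels_correct = if (is.null(lv)) NA_integer_ else n_correct,
      label_accuracy = if (length(lv) > 0) n_correct / length(lv) else NA_real_)
  }
  dplyr::bind_rows(rows)
}

flatten_config <- function(cfg) {
  fl <- rapply(cfg, function(x) paste(x, collapse = ","), how = "unlist")
  as.list(fl)
}

digest_config <- function(cfg) {
  s <- jsonlite::toJSON(flatten_config(cfg), auto_unbox = TRUE)
  ## small FNV-1a style rolling hash; avoids a digest dependency
  h <- 216613626
  for (ch in utf8ToInt(as.character(s)))
    h <- (bitwXor(h %% 2^31, ch) * 16777619) %% 2^31
  sprintf("%08x", h)
}

read_report <- function(out_dir) {
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) tibble::as_tibble(utils::read.csv(p)) else NULL
  }
  list(qc = rd("qc.csv"), models = rd("standardization_models.csv"),
       components = rd("components.csv"), fractions = rd("structure_fractions.csv"),
       burden = rd("burden.csv"), left_right = rd("left_right_test.csv"),
       morphology = rd("morphology.csv"),
       morphology_summary = rd("morphology_summary.csv"),
       thresholds = rd("thresholds.csv"), appearance = rd("appearance_report.csv"),
       recovery = rd("recovery.csv"), cached = TRUE)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return A cohort list (`subjects`, `reference`, `truth` tables if present).
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  read_bundle <- function(id) {
    sd <- file.path(dir, id)
    chans <- lapply(stats::setNames(nm = c("T1w", "T2w", "T2sw")), function(ch)
      read_volume(file.path(sd, paste0(ch, ".nii.gz")), "intensity"))
    str_files <- list.files(sd, pattern = "^structure_.*\\.nii\\.gz$")
    codes <- sub("^structure_(\\d+)\\.nii\\.gz$", "\\1", str_files)
    structure(list(
      subject_id = id, channels = chans,
      hypo_mask = read_volume(file.path(sd, "hypo_mask.nii.gz"), "mask"),
      brain_mask = read_volume(file.path(sd, "brain_mask.nii.gz"), "mask"),
      structure_masks = stats::setNames(
        lapply(str_files, function(f) read_volume(file.path(sd, f), "mask")), codes),
      tissue_masks = list(
        GMWM = read_volume(file.path(sd, "tissue_GMWM.nii.gz"), "mask"),
        CSF = read_volume(file.path(sd, "tissue_CSF.nii.gz"), "mask")),
      warp = NULL
    ), class = "subject_bundle")
  }
  ids <- man$subject_id[man$type == "subject"]
  truth <- NULL
  tl <- file.path(dir, "truth_lesions.csv")
  if (file.exists(tl)) {
    truth <- list(
      lesions = tibble::as_tibble(utils::read.csv(tl)),
      counts = tibble::as_tibble(utils::read.csv(file.path(dir, "truth_counts.csv"))),
      distortion = tibble::as_tibble(utils::read.csv(file.path(dir, "truth_distortion.csv"))))
  }
  list(subjects = lapply(ids, read_bundle), reference = read_bundle("reference"),
       truth = truth, manifest = tibble::as_tibble(man))
}

#' @export
print.subject_bundle <- function(x, ...) {
  cat(sprintf("<subject_bundle> %s: %d channels, %d structure masks, %d hypo voxels\n",
              x$subject_id, length(x$channels), length(x$structure_masks),
              sum(x$hypo_mask$values)))
  invisible(x)
}
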