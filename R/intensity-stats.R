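#' Type-7 percentile
#'
#' Linear-interpolation (type-7) quantile, the single quantile convention used
#' throughout the pipeline (segmentation thresholds, medians, quartile
#' summaries).
#'
#' @param x nonempty numeric sample.
#' @param q fraction(s) in \[0, 1\].
#' @return Quantile value(s).
#' @export
percentile <- function(x, q) {
  if (length(x) == 0L) stop("empty sample", call. = FALSE)
  if (any(q < 0 | q > 1)) stop("`q` must be in [0, 1]", call. = FALSE)
  stats::quantile(x, q, type = 7, names = FALSE, na.rm = FALSE)
}

#' Bowley (quartile) skewness coefficient
#'
#' `(q1 - 2 q2 + q3) / (q3 - q1)`, a robust skewness measure in \[-1, 1\];
#' negative values indicate a heavier left tail.
#'
#' @param q1,q2,q3 first, second and third quartiles with `q1 <= q2 <= q3`.
#' @return The coefficient.
#' @export
bowley <- function(q1, q2, q3) {
  if (!(q1 <= q2 && q2 <= q3)) stop("quartiles must be ordered", call. = FALSE)
  if (q3 == q1) stop("undefined: q3 == q1 (zero IQR)", call. = FALSE)
  (q1 - 2 * q2 + q3) / (q3 - q1)
}

#' Segmentation-threshold report
#'
#' For every structure with hypointensities, recovers the rater's effective
#' segmentation threshold as the 97th percentile of the standardized T2*w
#' intensities inside the structure's hypointensity mask, references it to the
#' median standardized T2*w intensity of the structure's normal-appearing
#' tissue (structure mask minus hypointensity voxels), and reports
#' `percent_below = 100 * (1 - threshold / nabg_median)`.
#'
#' @param bundle a standardized `subject_bundle` (T2*w channel `T2sw`).
#' @param cs labeled `component_set` of the bundle's hypointensity mask.
#' @param structures named list (codes) of structure masks used for the
#'   normal-appearing reference; defaults to the bundle's masks restricted to
#'   the label set, i.e. thalamus is not reported.
#' @return A tibble: `subject_id`, `code`, `structure`, `s_thresh`, `s_nabg`,
#'   `percent_below`, `n_hypo_voxels`. Structures without hypointensities are
#'   omitted and counted in `attr(, "qc_omitted")`.
#' @export
threshold_report <- function(bundle, cs, structures = NULL) {
  stopifnot(inherits(cs, "component_set"), isTRUE(cs$labeled))
  if (is.null(structures))
    structures <- bundle$structure_masks[
      names(bundle$structure_masks) %in% as.character(LABEL_SET)]
  t2 <- bundle$channels$T2sw$values
  rows <- list()
  omitted <- 0L
  for (code_chr in names(structures)) {
    code <- as.integer(code_chr)
    comp <- cs$components[cs$components$label == code, ]
    if (nrow(comp) == 0L) { omitted <- omitted + 1L; next }
    hypo_vox <- unlist(comp$voxels)
    smask <- structures[[code_chr]]$values > 0L
    na_vox <- which(smask)
    na_vox <- setdiff(na_vox, unlist(cs$components$voxels))
    if (length(na_vox) == 0L) { omitted <- omitted + 1L; next }
    s_thresh <- percentile(t2[hypo_vox], 0.97)
    s_nabg <- percentile(t2[na_vox], 0.5)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subject_id = bundle$subject_id, code = code,
      structure = structure_name(code),
      s_thresh = s_thresh, s_nabg = s_nabg,
      percent_below = 100 * (1 - s_thresh / s_nabg),
      n_hypo_voxels = length(hypo_vox))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(subject_id = character(), code = integer(),
                   structure = character(), s_thresh = numeric(),
                   s_nabg = numeric(), percent_below = numeric(),
                   n_hypo_voxels = integer())
  attr(out, "qc_omitted") <- omitted
  out
}

#' Cost-optimal histogram bin width
#'
#' Selects the uniform bin width minimizing the Shimazaki-Shinomoto cost
#' `C(w) = (2 * mean(k) - var(k)) / w^2`, where `k` are the bin counts and
#' `var` the biased sample variance, over a 100-point logarithmic grid of
#' candidate widths between `range/200` and `range/2`. Ties resolve to the
#' smaller width.
#'
#' @param x numeric sample with at least 2 distinct values.
#' @param n_candidates size of the logarithmic candidate grid.
#' @return The selected bin width.
#' @export
optimal_bin_width <- function(x, n_candidates = 100L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L)
    stop("need >= 2 distinct values to optimize a bin width", call. = FALSE)
  rng <- range(x)
  span <- diff(rng)
  widths <- exp(seq(log(span / 200), log(span / 2), length.out = n_candidates))
  cost <- vapply(widths, function(w) {
    k <- bin_counts(x, rng[1], w)
    m <- mean(k)
    v <- mean((k - m)^2)
    (2 * m - v) / w^2
  }, numeric(1))
  widths[which.min(cost)]   # first minimum = smallest width on the ascending grid
}

## counts on a uniform grid anchored at `lo`; the maximum lands in the last bin
bin_counts <- function(x, lo, w) {
  nb <- max(1L, as.integer(ceiling((max(x) - lo) / w + 1e-12)))
  i <- pmin(pmax(floor((x - lo) / w) + 1L, 1L), nb)
  tabulate(i, nbins = nb)
}

#' Aggregate per-subject intensity histograms
#'
#' Builds one shared uniform bin grid (width from [optimal_bin_width()] on the
#' pooled sample), converts each subject's sample into a unit-integral density
#' over that grid, and averages densities with equal weights (1/k over k
#' subjects) into the cohort intensity distribution. Cohort quartiles are read
#' off the aggregated density's cumulative distribution by linear
#' interpolation; the Bowley coefficient and a mode count (strict local maxima
#' of the cohort density after merging equal-valued plateaus) summarize its
#' shape.
#'
#' @param samples list (one element per subject) of numeric intensity samples,
#'   e.g. standardized T2*w intensities inside each subject's hypointensity
#'   mask. Subjects with empty samples are dropped.
#' @param channel channel token recorded in the result.
#' @return An object of class `aggregated_histogram`: list with `channel`,
#'   `edges`, `width`, `subject_density` (matrix bins x subjects), `density`,
#'   `quartiles`, `iqr`, `bowley`, `n_modes`, `n_subjects`.
#' @export
aggregate_histograms <- function(samples, channel = "T2sw") {
  samples <- lapply(samples, function(s) s[is.finite(s)])
  samples <- samples[lengths(samples) > 0]
  if (length(samples) == 0L) stop("empty pooled sample", call. = FALSE)
  pooled <- unlist(samples, use.names = FALSE)
  w <- optimal_bin_width(pooled)
  lo <- min(pooled)
  nb <- length(bin_counts(pooled, lo, w))
  edges <- lo + (0:nb) * w
  dens <- vapply(samples, function(s) {
    k <- c(bin_counts(s, lo, w), numeric(nb))[1:nb]
    k / (length(s) * w)
  }, numeric(nb))
  dens <- matrix(dens, nrow = nb)
  avg <- rowMeans(dens)
  cdf <- c(0, cumsum(avg * w))
  cdf <- cdf / cdf[length(cdf)]
  qs <- vapply(c(.25, .5, .75), function(q) {
    i <- min(max(findInterval(q, cdf), 1L), nb)
    lo_c <- cdf[i]; hi_c <- cdf[i + 1]
    if (hi_c > lo_c) edges[i] + (q - lo_c) / (hi_c - lo_c) * w else edges[i]
  }, numeric(1))
  iqr <- qs[3] - qs[1]
  bw <- if (iqr > 0) bowley(qs[1], qs[2], qs[3]) else NA_real_
  structure(list(
    channel = channel, edges = edges, width = w,
    subject_density = dens, density = avg,
    quartiles = stats::setNames(qs, c("q25", "q50", "q75")),
    iqr = iqr, bowley = bw, n_modes = count_modes(avg),
    n_subjects = length(samples)
  ), class = "aggregated_histogram")
}

## strict local maxima after merging equal-valued plateau runs
count_modes <- function(d) {
  r <- rle(d)
  v <- r$values
  if (length(v) == 1L) return(as.integer(v[1] > 0))
  is_max <- logical(length(v))
  for (i in seq_along(v)) {
    left_ok <- i == 1L || v[i] > v[i - 1L]
    right_ok <- i == length(v) || v[i] > v[i + 1L]
    is_max[i] <- left_ok && right_ok && v[i] > 0
  }
  sum(is_max)
}

#' @export
print.aggregated_histogram <- function(x, ...) {
  cat(sprintf(
    "<aggregated_histogram> %s: %d bins of width %.4g, %d subjects\n  quartiles %.3f / %.3f / %.3f, Bowley %.4f, %d mode(s)\n",
    x$channel, length(x$density), x$width, x$n_subjects,
    x$quartiles[1], x$quartiles[2], x$quartiles[3], x$bowley, x$n_modes))
  invisible(x)
}

#' Tidy an aggregated histogram
#'
#' @param x an `aggregated_histogram`.
#' @param ... unused.
#' @return `tidy()`: tibble of bin midpoints and cohort density; `glance()`:
#'   one-row shape summary.
#' @method tidy aggregated_histogram
#' @export
tidy.aggregated_histogram <- function(x, ...) {
  nb <- length(x$density)
  tibble::tibble(channel = x$channel,
                 mid = (x$edges[-1] + x$edges[-(nb + 1)]) / 2,
                 density = x$density)
}

#' @rdname tidy.aggregated_histogram
#' @method glance aggregated_histogram
#' @export
glance.aggregated_histogram <- function(x, ...) {
  tibble::tibble(channel = x$channel, width = x$width,
                 n_bins = length(x$density), n_subjects = x$n_subjects,
                 q25 = x$quartiles[1], q50 = x$quartiles[2],
                 q75 = x$quartiles[3], iqr = x$iqr,
                 bowley = x$bowley, n_modes = x$n_modes)
}
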