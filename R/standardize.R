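#' Huber M-estimator of location
#'
#' Robust location estimate used for the tissue means entering the intensity
#' standardization fit: the Huber psi-function M-estimator with tuning
#' constant `c` (default 1.345, 95% Gaussian efficiency), scale fixed at
#' 1.4826 * MAD, iterated to convergence.
#'
#' `MASS::huber()` performs the iteration when the MAD is positive. A sample
#' whose MAD is zero (more than half the mass on one value) has no usable MAD
#' scale; the estimator then falls back to the consistency-scaled mean
#' absolute deviation about the median (1.2533 * mean |x - median|) and runs
#' the same clipped-mean fixed-point iteration. A constant sample returns the
#' common value.
#'
#' @param x numeric sample, length >= 1.
#' @param c Huber tuning constant.
#' @param tol convergence tolerance on the location update.
#' @param max_iter iteration cap.
#' @return The robust location estimate (scalar).
#' @export
robust_location <- function(x, c = 1.345, tol = 1e-8, max_iter = 100L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("empty sample", call. = FALSE)
  med <- stats::median(x)
  s <- stats::mad(x)           # 1.4826 * MAD
  if (s > 0) return(MASS::huber(x, k = c, tol = tol)$mu)
  s <- 1.2533 * mean(abs(x - med))
  if (s == 0) return(med)      # constant sample
  mu <- med
  for (i in seq_len(max_iter)) {
    mu_new <- mean(pmin(pmax(x, mu - c * s), mu + c * s))
    if (abs(mu_new - mu) < tol) return(mu_new)
    mu <- mu_new
  }
  mu
}

#' Fit a per-channel intensity standardization model
#'
#' Estimates the linear map `s_std = alpha * s + beta` that aligns a subject's
#' intensities with the reference subject: the robust (Huber) tissue-class
#' means of the reference are regressed on the corresponding robust means of
#' the subject by ordinary least squares across the shared tissue tags
#' (typically GM/WM and CSF; with exactly two tags the fit is exact).
#'
#' @param subject_tissues named list of numeric samples, one per tissue tag
#'   (e.g. `list(GMWM = ..., CSF = ...)`), from the subject volume.
#' @param reference_tissues same tags, samples from the reference volume.
#' @param channel channel token stored in the model.
#' @param c Huber tuning constant passed to [robust_location()].
#' @return An object of class `standardization_model` with fields `channel`,
#'   `alpha`, `beta`, `residual_sd` and `tissue_points`.
#' @export
fit_standardization <- function(subject_tissues, reference_tissues,
                                channel = "T2sw", c = 1.345) {
  tags <- intersect(names(subject_tissues), names(reference_tissues))
  if (length(tags) < 2L)
    stop("need >= 2 shared tissue tags to fit a standardization", call. = FALSE)
  subj <- vapply(subject_tissues[tags], robust_location, numeric(1), c = c)
  ref <- vapply(reference_tissues[tags], robust_location, numeric(1), c = c)
  if (max(subj) - min(subj) < 1e-12 * max(1, abs(max(subj))))
    stop("degenerate design: identical subject tissue means across tags", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, subj), ref)
  beta <- unname(fit$coefficients[1])
  alpha <- unname(fit$coefficients[2])
  rsd <- if (length(tags) > 2L) sqrt(sum(fit$residuals^2) / (length(tags) - 2L)) else 0
  structure(list(
    channel = channel, alpha = alpha, beta = beta, residual_sd = rsd,
    tissue_points = tibble::tibble(tissue = tags, subject_mean = unname(subj),
                                   reference_mean = unname(ref)),
    fitted = TRUE
  ), class = "standardization_model")
}

#' @export
print.standardization_model <- function(x, ...) {
  cat(sprintf("<standardization_model> %s: s_std = %.4f * s + %.4f (residual sd %.3g)\n",
              x$channel, x$alpha, x$beta, x$residual_sd))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a standardization model
#'
#' @param x a `standardization_model`.
#' @param ... unused.
#' @return `tidy()`: one row per tissue anchor point; `glance()`: one row of
#'   fit coefficients.
#' @method tidy standardization_model
#' @export
tidy.standardization_model <- function(x, ...) {
  dplyr::mutate(x$tissue_points, channel = x$channel, .before = 1)
}

#' @rdname tidy.standardization_model
#' @method glance standardization_model
#' @export
glance.standardization_model <- function(x, ...) {
  tibble::tibble(channel = x$channel, alpha = x$alpha, beta = x$beta,
                 residual_sd = x$residual_sd, n_tissues = nrow(x$tissue_points))
}

#' Apply a standardization model to a volume
#'
#' Maps every voxel through `alpha * s + beta`. Masks are never passed through
#' this transformation.
#'
#' @param v an intensity [voxel_grid].
#' @param m a fitted `standardization_model`.
#' @return The standardized [voxel_grid].
#' @export
apply_standardization <- function(v, m) {
  stopifnot(is_voxel_grid(v))
  if (!inherits(m, "standardization_model") || !isTRUE(m$fitted))
    stop("`m` must be a fitted standardization_model", call. = FALSE)
  if (v$kind == "mask") stop("refusing to standardize a mask", call. = FALSE)
  out <- v
  out$values <- m$alpha * v$values + m$beta
  out
}

#' Serialize / restore a standardization model as JSON
#'
#' @param m a `standardization_model`; `path` a file path.
#' @param path JSON file.
#' @return `write_standardization()` returns `path`; `read_standardization()`
#'   the model.
#' @export
write_standardization <- function(m, path) {
  jsonlite::write_json(
    list(channel = m$channel, alpha = m$alpha, beta = m$beta,
         residual_sd = m$residual_sd,
         tissue_points = m$tissue_points),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_standardization
#' @export
read_standardization <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(channel = j$channel, alpha = j$alpha, beta = j$beta,
                 residual_sd = j$residual_sd,
                 tissue_points = tibble::as_tibble(j$tissue_points),
                 fitted = TRUE),
            class = "standardization_model")
}

## tissue samples of one channel selected by the bundle's tissue masks
tissue_samples <- function(bundle, channel) {
  v <- bundle$channels[[channel]]$values
  lapply(bundle$tissue_masks, function(m) v[m$values > 0L])
}

#' Standardize all channels of a subject bundle against a reference
#'
#' Fits one model per channel from the robust GM/WM and CSF means (taken
#' within the bundles' mixel-free tissue masks) and applies it, returning the
#' bundle with standardized channels and the fitted models attached.
#'
#' @param bundle,reference `subject_bundle` objects sharing tissue-mask tags.
#' @param c Huber tuning constant.
#' @return The bundle with standardized `channels` and a `models` element.
#' @export
standardize_bundle <- function(bundle, reference, c = 1.345) {
  models <- list()
  for (ch in names(bundle$channels)) {
    m <- fit_standardization(tissue_samples(bundle, ch),
                             tissue_samples(reference, ch),
                             channel = ch, c = c)
    bundle$channels[[ch]] <- apply_standardization(bundle$channels[[ch]], m)
    models[[ch]] <- m
  }
  bundle$models <- models
  bundle
}
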