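test_that("type-7 percentile: constants, median convention, 97th of 1..100", {
  expect_equal(percentile(rep(7, 10), c(0, .5, .97, 1)), rep(7, 4))
  expect_equal(percentile(1:4, 0.5), 2.5)
  expect_equal(percentile(1:100, 0.97), 97.03)
  expect_error(percentile(numeric(), 0.5), "empty")
  expect_error(percentile(1:3, 1.5), "0, 1")
})

test_that("percentile agrees with a full-sort interpolation oracle", {
  set.seed(77)
  for (i in 1:200) {
    x <- rnorm(sample(2:60, 1))
    q <- runif(1)
    s <- sort(x)
    h <- (length(x) - 1) * q
    lo <- floor(h)
    oracle <- s[lo + 1] + (h - lo) * (s[min(lo + 2, length(x))] - s[lo + 1])
    expect_equal(percentile(x, q), oracle, tolerance = 1e-12)
  }
})

test_that("bowley: symmetric, asymmetric, bounds and antisymmetry", {
  expect_equal(bowley(1, 2, 3), 0)
  expect_equal(bowley(1, 2, 4), 1 / 3)
  expect_equal(bowley(1, 3, 4), -1 / 3)
  expect_error(bowley(2, 1, 3), "ordered")
  expect_error(bowley(1, 1, 1), "IQR")
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(101) * runif(1, .1, 10)
    q <- percentile(x, c(.25, .5, .75))
    b <- bowley(q[1], q[2], q[3])
    expect_gte(b, -1); expect_lte(b, 1)
    qn <- percentile(-x, c(.25, .5, .75))
    expect_equal(bowley(qn[1], qn[2], qn[3]), -b, tolerance = 1e-10)
  }
})

test_that("optimal bin width: domain bounds, scale equivariance, dense-grid oracle", {
  expect_error(optimal_bin_width(rep(1, 10)), "distinct")
  w01 <- optimal_bin_width(c(0, 1))
  expect_gt(w01, 0.005); expect_lte(w01, 0.5)

  set.seed(42)
  x <- rnorm(10000)
  w <- optimal_bin_width(x)
  ## dense brute-force grid: the selected width's cost is within a grid step
  ## of the dense minimum
  dense <- exp(seq(log(diff(range(x)) / 200), log(diff(range(x)) / 2),
                   length.out = 2000))
  cost <- function(d) {
    lo <- min(x)
    nb <- max(1L, ceiling((max(x) - lo) / d))
    k <- tabulate(pmin(pmax(floor((x - lo) / d) + 1L, 1L), nb), nbins = nb)
    (2 * mean(k) - mean((k - mean(k))^2)) / d^2
  }
  c_sel <- cost(w)
  c_best <- min(vapply(dense, cost, numeric(1)))
  expect_lt((c_sel - c_best) / abs(c_best), 0.02)

  ## doubling the sample scale doubles the selected width exactly on the
  ## logarithmic candidate grid
  expect_equal(optimal_bin_width(2 * x), 2 * w, tolerance = 1e-12)
})

test_that("aggregated histogram densities integrate to one and average correctly", {
  set.seed(9)
  samples <- lapply(1:5, function(i) rnorm(300, 50, 5))
  h <- aggregate_histograms(samples, "T2sw")
  expect_equal(sum(h$density) * h$width, 1, tolerance = 1e-9)
  for (j in seq_len(ncol(h$subject_density)))
    expect_equal(sum(h$subject_density[, j]) * h$width, 1, tolerance = 1e-9)
  expect_equal(h$density, rowMeans(h$subject_density), tolerance = 1e-12)

  ## one subject -> cohort density equals its density
  h1 <- aggregate_histograms(samples[1], "T2sw")
  expect_equal(h1$density, h1$subject_density[, 1])

  expect_error(aggregate_histograms(list(numeric())), "empty")
})

test_that("cohort quartiles follow the aggregated cumulative density", {
  set.seed(10)
  x <- runif(20000, 0, 10)       # uniform: quartiles 2.5 / 5 / 7.5
  h <- aggregate_histograms(list(x), "T1w")
  expect_equal(unname(h$quartiles), c(2.5, 5, 7.5), tolerance = 0.2)
  expect_equal(h$n_modes, 1)
  expect_lt(abs(h$bowley), 0.05)
})

test_that("mode counting merges plateaus and finds separated peaks", {
  expect_equal(bghypo:::count_modes(c(0, 1, 1, 1, 0)), 1)
  expect_equal(bghypo:::count_modes(c(1, 0, 2, 0, 1)), 3)
  expect_equal(bghypo:::count_modes(c(0, 2, 0, 0, 3, 3, 1)), 2)
  expect_equal(bghypo:::count_modes(rep(0, 4)), 0)
  set.seed(2)
  x <- c(rnorm(4000, 0), rnorm(4000, 12))
  h <- aggregate_histograms(list(x), "T2w")
  expect_equal(h$n_modes >= 2, TRUE)
})

test_that("Bowley sign tracks the generative skew at the cohort level", {
  spec <- small_spec(seed = 61)
  set.seed(606)
  n_neg <- 0
  bow_sym <- numeric(20)
  for (r in 1:20) {
    neg <- lapply(1:10, function(i) sample_lesion_intensity(spec, 120, "T2sw"))
    h <- aggregate_histograms(neg, "T2sw")
    if (h$bowley < 0) n_neg <- n_neg + 1
    sym <- lapply(1:10, function(i)
      sample_lesion_intensity(spec, 120, "T2sw", skew = "symmetric"))
    bow_sym[r] <- aggregate_histograms(sym, "T2sw")$bowley
  }
  expect_gte(n_neg / 20, 0.95)
  expect_lt(median(abs(bow_sym)), 0.08)
})

test_that("threshold report recovers generative separation arithmetic", {
  ## direct arithmetic: threshold 83.5 against NABG median 100 -> 16.5% below
  shp <- c(20, 20, 4)
  vs <- c(1, 1, 2)
  hypo_vox <- 1:40
  nabg_vox <- 41:400
  t2 <- array(100, shp)
  t2[hypo_vox] <- 83.5
  b <- list(subject_id = "s1",
            channels = list(T2sw = voxel_grid(array(t2, shp), voxel_size = vs)),
            structure_masks = list(`13` = mask_from_indices(shp, 1:400, vs)))
  class(b) <- "subject_bundle"
  cs <- assign_labels(connected_components(mask_from_indices(shp, hypo_vox, vs)),
                      list(`13` = mask_from_indices(shp, 1:400, vs)),
                      b$channels$T2sw)
  tr <- threshold_report(b, cs)
  expect_equal(tr$s_thresh, 83.5)
  expect_equal(tr$s_nabg, 100)
  expect_equal(tr$percent_below, 16.5, tolerance = 1e-12)

  ## hypo intensities equal to the NABG median -> 0% below
  t2b <- array(100, shp)
  b$channels$T2sw <- voxel_grid(array(t2b, shp), voxel_size = vs)
  tr2 <- threshold_report(b, cs)
  expect_equal(tr2$percent_below, 0)
})

test_that("recovered thresholds sit near the generative lesion intensity cut", {
  spec <- small_spec(n_subjects = 3, seed = 71)
  co <- generate_cohort(spec)
  for (i in seq_along(co$subjects)) {
    b <- standardize_bundle(co$subjects[[i]], co$reference)
    cs <- assign_labels(connected_components(b$hypo_mask),
                        bghypo:::labeling_structures(b, spec$capsule_radius_mm),
                        b$channels$T2sw)
    tr <- threshold_report(b, cs)
    if (nrow(tr) == 0) next
    ## all lesion intensities were drawn below base + noise; the recovered
    ## 97th-percentile threshold must respect that generative cut
    expect_true(all(tr$s_thresh <= spec$lesion_t2sw$base + 4 * spec$noise_sd))
    expect_true(all(tr$s_nabg > tr$s_thresh))
  }
})
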