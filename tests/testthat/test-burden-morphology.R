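make_labeled <- function(shp, voxel_size, spec_list, t2 = NULL) {
  ## spec_list: list of (code, voxel indices); builds structures = exact lesions
  hypo <- mask_from_indices(shp, unlist(lapply(spec_list, `[[`, 2)), voxel_size)
  structures <- lapply(spec_list, function(s)
    mask_from_indices(shp, s[[2]], voxel_size))
  names(structures) <- vapply(spec_list, function(s) as.character(s[[1]]), "")
  structures <- structures[!duplicated(names(structures))]
  if (is.null(t2)) t2 <- voxel_grid(array(100, shp), voxel_size = voxel_size)
  assign_labels(connected_components(hypo), structures, t2)
}

test_that("burden arithmetic: counts, ppm loads, aggregates, additivity", {
  shp <- c(20, 20, 10); vs <- c(1, 1, 2)
  ## one 50-voxel (100 mm^3) pallidal-left component
  cs <- make_labeled(shp, vs, list(list(13L, 1:50)))
  bt <- burden(cs, icv = 2e6, subject_id = "s1")
  expect_equal(bt$load_ppm[bt$structure == "13"], 50)   # 1e6 * 100 / 2e6
  expect_equal(bt$n[bt$structure == "13"], 1)
  expect_equal(bt$n[bt$structure == "left"], 1)
  expect_equal(bt$n[bt$structure == "right"], 0)
  ## additivity of loads to 1e-9 ppm
  per_code <- bt[bt$structure %in% as.character(c(11:14, 50:52, 55)), ]
  expect_equal(sum(per_code$load_ppm), bt$load_ppm[bt$structure == "all"],
               tolerance = 1e-9)
  expect_error(burden(cs, icv = 0), "icv")
})

test_that("empty component sets give all-zero burden", {
  cs <- assign_labels(connected_components(mask_from_indices(c(5, 5, 5), integer())),
                      list(`13` = mask_from_indices(c(5, 5, 5), 1:10)),
                      voxel_grid(array(0, c(5, 5, 5))))
  bt <- burden(cs, icv = 1e6)
  expect_true(all(bt$n == 0))
  expect_true(all(bt$load_ppm == 0))
})

test_that("burden counts equal generator ground truth in the separability regime", {
  spec <- small_spec(n_subjects = 2, seed = 41)
  co <- generate_cohort(spec)
  for (i in 1:2) {
    b <- standardize_bundle(co$subjects[[i]], co$reference)
    cs <- assign_labels(connected_components(b$hypo_mask),
                        bghypo:::labeling_structures(b, spec$capsule_radius_mm),
                        b$channels$T2sw)
    bt <- burden(cs, intracranial_volume(b$brain_mask), b$subject_id)
    truth <- co$truth$counts[co$truth$counts$subject_id == b$subject_id, ]
    got <- bt$n[match(as.character(truth$code), bt$structure)]
    expect_identical(as.integer(got), as.integer(truth$n))
    got_load <- bt$load_ppm[match(as.character(truth$code), bt$structure)]
    expect_equal(got_load, truth$load_ppm, tolerance = 1e-9)
  }
})

test_that("left/right rank-sum test: identity, enumerated case, degenerate case", {
  mk <- function(l, r, id) {
    shp <- c(30, 10, 2); vs <- c(1, 1, 1)
    lesions <- list()
    if (l > 0) lesions <- c(lesions, list(list(13L, 1:l)))
    if (r > 0) lesions <- c(lesions, list(list(52L, 200 + 1:r)))
    if (length(lesions) == 0)
      lesions <- list(list(13L, integer()))
    cs <- make_labeled(shp, vs, lesions)
    burden(cs, icv = 1e6, subject_id = id)
  }
  ## identical left/right load vectors -> p = 1
  bts <- list(mk(5, 5, "a"), mk(8, 8, "b"), mk(3, 3, "c"))
  lr <- left_right_test(bts)
  expect_equal(lr$p_value[lr$metric == "load_ppm"], 1)

  ## separated vectors: volumes l = {1,2,3}, r = {10,11,12} -> exact p = 0.1
  bts2 <- list(mk(1, 10, "a"), mk(2, 11, "b"), mk(3, 12, "c"))
  lr2 <- left_right_test(bts2)
  expect_equal(lr2$p_value[lr2$metric == "load_ppm"], 0.1, tolerance = 1e-12)
  expect_equal(lr2$p_value[lr2$metric == "load_ppm"],
               enum_ranksum_p(c(1, 2, 3), c(10, 11, 12)), tolerance = 1e-12)

  ## all-zero both sides -> degenerate flag with p = 1
  bts3 <- list(mk(0, 0, "a"), mk(0, 0, "b"))
  lr3 <- left_right_test(bts3)
  expect_true(all(lr3$degenerate))
  expect_true(all(lr3$p_value == 1))
  expect_error(left_right_test(bts3[1]), ">= 2")
})

test_that("a symmetric lesion plan rarely produces left/right significance", {
  spec <- small_spec(seed = 17)
  set.seed(1234)
  n_sig <- 0
  for (rep in 1:60) {
    cnt <- sample_lesion_counts(spec, 12)
    l <- tapply(cnt$n[cnt$code %in% c(11:14)], cnt$subject[cnt$code %in% c(11:14)], sum)
    r <- tapply(cnt$n[cnt$code %in% c(50:52, 55)], cnt$subject[cnt$code %in% c(50:52, 55)], sum)
    p <- bghypo:::rank_sum_test(as.numeric(l), as.numeric(r), exact_max_n = 20L)$p
    if (p < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / 60, 0.10)
})

test_that("morphology anchors: cube, domino, straight segment", {
  ## 5x5x5 cube: the compactness maximum and isotropic inertia
  cube <- mask_from_array(array(1L, c(5, 5, 5)))
  rec <- morphology(cube)
  expect_equal(rec$compactness, 1)
  expect_equal(rec$relative_anisotropy, 0, tolerance = 1e-12)
  expect_equal(rec$volume_mm3, 125)
  expect_equal(rec$max_area_mm2, 25)
  expect_equal(rec$n_slices, 5)
  expect_equal(rec$class, "inter")

  ## 1x1x2 domino at 1 mm: n = 2, A = 10 exposed faces
  dom <- mask_from_indices(c(3, 3, 4), c(14, 23))  # (2,2,2) and (2,2,3)
  rd <- morphology(dom)
  expect_equal(rd$compactness, (2 - 10 / 6) / (2 - 2^(2 / 3)), tolerance = 1e-12)
  expect_equal(rd$compactness, 0.8079, tolerance = 1e-4)

  ## long straight segment: RA = 1
  seg <- mask_from_indices(c(2, 2, 40), 4 * (0:29) + 1)
  rs <- morphology(seg)
  expect_equal(rs$relative_anisotropy, 1, tolerance = 1e-12)

  ## single voxel: compactness defined as 1, RA as 0
  one <- mask_from_indices(c(3, 3, 3), 14)
  ro <- morphology(one)
  expect_equal(ro$compactness, 1)
  expect_equal(ro$relative_anisotropy, 0)
  expect_equal(ro$class, "intra")

  expect_error(morphology(mask_from_indices(c(3, 3, 3), integer())), "empty")
})

test_that("compactness matches a brute-force face count on random blobs", {
  set.seed(31)
  for (i in 1:8) {
    arr <- array(0L, c(8, 8, 8))
    seedvox <- c(4, 4, 4)
    arr[4, 4, 4] <- 1L
    for (k in 1:40) {
      idx <- which(arr == 1L, arr.ind = TRUE)
      v <- idx[sample(nrow(idx), 1), ]
      a <- sample(3, 1); v[a] <- v[a] + sample(c(-1, 1), 1)
      if (all(v >= 1 & v <= 8)) arr[v[1], v[2], v[3]] <- 1L
    }
    idx <- which(arr == 1L, arr.ind = TRUE)
    n <- nrow(idx)
    ## brute-force exposed-face count
    A <- 0
    for (j in seq_len(n)) for (a in 1:3) for (s in c(-1, 1)) {
      nb <- idx[j, ]; nb[a] <- nb[a] + s
      if (any(nb < 1 | nb > 8) || arr[nb[1], nb[2], nb[3]] == 0L) A <- A + 1
    }
    expected <- min(max((n - A / 6) / (n - n^(2 / 3)), 0), 1)
    expect_equal(bghypo:::discrete_compactness(mask_from_array(arr)), expected,
                 tolerance = 1e-12)
  }
})

test_that("compactness decreases when low-exposure surface voxels are removed", {
  set.seed(8)
  for (rep in 1:5) {
    arr <- array(1L, c(6, 6, 6))
    prev <- bghypo:::discrete_compactness(mask_from_array(arr))
    for (step in 1:10) {
      idx <- which(arr == 1L, arr.ind = TRUE)
      expos <- apply(idx, 1, function(v) {
        e <- 0
        for (a in 1:3) for (s in c(-1, 1)) {
          nb <- v; nb[a] <- nb[a] + s
          if (any(nb < 1 | nb > 6) || arr[nb[1], nb[2], nb[3]] == 0L) e <- e + 1
        }
        e
      })
      cand <- which(expos >= 1 & expos <= 2)
      if (length(cand) == 0) break
      v <- idx[sample(cand, 1), ]
      arr[v[1], v[2], v[3]] <- 0L
      cur <- bghypo:::discrete_compactness(mask_from_array(arr))
      expect_lt(cur, prev)
      prev <- cur
    }
  }
})

test_that("relative anisotropy is invariant to 90-degree lattice rotations", {
  set.seed(12)
  arr <- array(0L, c(9, 9, 9))
  arr[3:7, 4:6, 4:5] <- 1L
  arr[5, 5, 6] <- 1L
  base <- morphology(mask_from_array(arr))$relative_anisotropy
  rot <- aperm(arr, c(2, 3, 1))
  expect_equal(morphology(mask_from_array(rot))$relative_anisotropy, base,
               tolerance = 1e-10)
  rot2 <- arr[9:1, , ]
  expect_equal(morphology(mask_from_array(rot2))$relative_anisotropy, base,
               tolerance = 1e-10)
})

test_that("slice count uses the native grid; metrics use the 1 mm lattice", {
  ## one 1x1x2 mm voxel: single native slice, but 2 voxels after resampling
  m <- mask_from_indices(c(5, 5, 5), 63, voxel_size = c(1, 1, 2))
  rec <- morphology(m)
  expect_equal(rec$n_slices, 1)
  expect_equal(rec$class, "intra")
  expect_equal(rec$volume_mm3, 2)
  expect_equal(rec$max_area_mm2, 1)
})

test_that("morphology summary: single record, class split, sorting oracle", {
  one <- morphology(mask_from_array(array(1L, c(2, 2, 2))))
  ms1 <- morphology_summary(dplyr::mutate(one, subject_id = "a"))
  vol <- ms1[ms1$metric == "volume_mm3" & ms1$class == "both", ]
  expect_equal(c(vol$q25, vol$q50, vol$q75), rep(8, 3))

  ## spheres of radius 4 mm (inter-slice) vs single voxels (intra-slice)
  spheres <- lapply(1:4, function(i) {
    arr <- array(0L, c(13, 13, 7))
    ctr <- c(6.5, 6.5, 6.5)
    for (x in 1:13) for (y in 1:13) for (z in 1:7)
      if (sum((c(x - 1, y - 1, (z - 1) * 2) - ctr)^2) <= 16) arr[x, y, z] <- 1L
    morphology(mask_from_array(arr, c(1, 1, 2)))
  })
  dots <- lapply(1:4, function(i)
    morphology(mask_from_indices(c(5, 5, 3), 30 + i, c(1, 1, 2))))
  recs <- dplyr::bind_rows(c(spheres, dots))
  ms <- morphology_summary(recs)
  med_inter <- ms$q50[ms$metric == "volume_mm3" & ms$class == "inter"]
  med_intra <- ms$q50[ms$metric == "volume_mm3" & ms$class == "intra"]
  expect_gt(med_inter, med_intra)

  ## percentile columns agree with a direct sort-based (type-7) computation
  x <- recs$volume_mm3
  expect_equal(ms$q25[ms$metric == "volume_mm3" & ms$class == "both"],
               unname(quantile(x, 0.25, type = 7)))

  ## a class with no records reports missing percentiles
  only_inter <- dplyr::bind_rows(spheres)
  ms2 <- morphology_summary(only_inter)
  expect_true(all(is.na(ms2$q50[ms2$class == "intra"])))
})
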