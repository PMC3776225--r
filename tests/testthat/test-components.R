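test_that("six-connectivity separates edge-touching voxels and finds simple shapes", {
  expect_equal(nrow(connected_components(mask_from_indices(c(4, 4, 4), integer()))$components), 0)

  ## two voxels sharing only an in-plane diagonal edge -> 2 components
  shp <- c(4, 4, 1)
  diag2 <- mask_from_indices(shp, c(1, 6))  # (1,1) and (2,2)
  expect_equal(nrow(connected_components(diag2)$components), 2)

  ## a face-adjacent pair -> 1 component
  pair <- mask_from_indices(shp, c(1, 2))
  expect_equal(nrow(connected_components(pair)$components), 1)
})

test_that("components match a brute-force flood fill on random masks", {
  set.seed(20)
  for (i in 1:12) {
    arr <- array(as.integer(runif(20^3) < 0.2), c(20, 20, 20))
    cs <- connected_components(mask_from_array(arr))
    lab <- ff_components(arr)
    expect_equal(nrow(cs$components), max(lab))
    ## identical partitions: every package component is one flood-fill label
    for (j in seq_len(nrow(cs$components))) {
      vox <- cs$components$voxels[[j]]
      expect_equal(length(unique(lab[vox])), 1)
      expect_equal(sum(lab == lab[vox[1]]), length(vox))
    }
  }
})

test_that("component ordering is deterministic by minimum linear index", {
  m <- mask_from_indices(c(5, 5, 5), c(100, 1, 50))
  cs <- connected_components(m)
  mins <- vapply(cs$components$voxels, min, numeric(1))
  expect_identical(mins, sort(mins))
})

test_that("50% rule labels, outside components, and conservation", {
  shp <- c(12, 12, 3)
  t2 <- voxel_grid(array(100, shp))
  pall <- mask_from_indices(shp, 1:48)      # rows y = 1..4 of slice 1
  structures <- list(`13` = pall)
  ## component fully inside code 13
  cs <- connected_components(mask_from_indices(shp, 25:30))
  cs <- assign_labels(cs, structures, t2)
  expect_equal(cs$components$label, 13L)

  ## vertical bar at x = 1, y = 1..10: 4 of 10 voxels inside (40%) -> outside
  bar10 <- mask_from_indices(shp, 1 + 12 * (0:9))
  cs2 <- assign_labels(connected_components(bar10), structures, t2)
  expect_equal(cs2$components$label, 0L)

  ## bar y = 1..8: exactly half inside -> labeled (>= 0.5)
  bar8 <- mask_from_indices(shp, 1 + 12 * (0:7))
  cs3 <- assign_labels(connected_components(bar8), structures, t2)
  expect_equal(cs3$components$label, 13L)

  ## conservation: labeled + outside = total
  n_in <- sum(cs3$components$label != 0L)
  n_out <- sum(cs3$components$label == 0L)
  expect_equal(n_in + n_out, nrow(cs3$components))
})

test_that("exact overlap ties break to the darkest standardized T2*w voxel", {
  shp <- c(12, 12, 1)
  ## a 6-voxel horizontal bar split 3/3 between codes 12 (x 1-3) and 13 (x 4-6)
  bar <- mask_from_indices(shp, 1:6)
  s12 <- mask_from_indices(shp, c(1:3, 13:15))
  s13 <- mask_from_indices(shp, c(4:6, 16:18))
  t2 <- array(100, shp)
  t2[5] <- 10      # darkest voxel inside code 13
  cs <- assign_labels(connected_components(bar),
                      list(`12` = s12, `13` = s13), voxel_grid(t2))
  expect_equal(cs$components$label, 13L)
  expect_true(cs$components$tie_broken)

  ## mirrored darkest voxel flips the label
  t2b <- array(100, shp); t2b[2] <- 10
  csb <- assign_labels(connected_components(bar),
                       list(`12` = s12, `13` = s13), voxel_grid(t2b))
  expect_equal(csb$components$label, 12L)

  ## darkest voxel in neither tied structure -> lowest code with a warning
  ## (bar of 8 voxels: 3 in 12, 3 in 13, 2 in no structure incl. the darkest)
  bar8 <- mask_from_indices(shp, 1:8)
  t2c <- array(100, shp); t2c[8] <- 5
  expect_warning(
    csc <- assign_labels(connected_components(bar8),
                         list(`12` = s12, `13` = s13), voxel_grid(t2c)),
    "lowest")
  expect_equal(csc$components$label, 12L)
})

test_that("labeling is invariant to structure-map insertion order", {
  set.seed(5)
  shp <- c(16, 16, 4)
  structures <- list(`11` = mask_from_indices(shp, 1:200),
                     `13` = mask_from_indices(shp, 301:500),
                     `51` = mask_from_indices(shp, 601:800))
  t2 <- voxel_grid(array(rnorm(prod(shp), 100), shp))
  hypo <- mask_from_indices(shp, c(150:210, 420:430, 700:705))
  cs1 <- assign_labels(connected_components(hypo), structures, t2)
  cs2 <- assign_labels(connected_components(hypo), rev(structures), t2)
  expect_identical(cs1$components$label, cs2$components$label)
})

test_that("structure fraction report reproduces published-style percentages", {
  counts <- tibble::tibble(
    region = c("caudate", "putamen", "pallidum", "capsule",
               "choroid plexus", "pineal gland", "substantia nigra", "other"),
    location = c(rep("inside", 4), rep("outside", 4)),
    count = c(5, 26, 229, 58, 325, 55, 32, 137))
  rep <- structure_fraction_report(counts)
  inside <- rep[rep$location == "inside", ]
  expect_equal(unique(inside$total), 318)
  expect_equal(inside$percent[match(c("pallidum", "capsule", "putamen", "caudate"),
                                    inside$region)], c(72L, 18L, 8L, 2L))
  outside <- rep[rep$location == "outside", ]
  expect_equal(unique(outside$total), 549)
  expect_equal(outside$percent[match(c("choroid plexus", "pineal gland",
                                       "substantia nigra", "other"),
                                     outside$region)], c(59L, 10L, 6L, 25L))

  ## single component in one structure -> 100%
  one <- structure_fraction_report(
    tibble::tibble(region = "pallidum", location = "inside", count = 1))
  expect_equal(one$percent, 100L)
})

test_that("component helpers export tables and label maps consistently", {
  shp <- c(8, 8, 2)
  hypo <- mask_from_indices(shp, c(1:3, 20:22))
  structures <- list(`13` = mask_from_indices(shp, 1:32))
  cs <- assign_labels(connected_components(hypo), structures,
                      voxel_grid(array(100, shp)))
  tbl <- component_table(cs, "subA")
  expect_equal(nrow(tbl), 2)
  expect_true(all(tbl$structure == "pallidum"))
  lm <- component_label_map(cs)
  expect_equal(sort(unique(as.vector(lm$values))), c(0L, 1L, 2L))
  expect_equal(sum(lm$values > 0L), sum(hypo$values))
  m1 <- component_mask(cs, 1)
  expect_equal(sum(m1$values), cs$components$n_voxels[1])
})
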