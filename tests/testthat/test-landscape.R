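test_that("proportion_habitat: constants and hand-counted window", {
  all1 <- gm_raster(1, nrow = 6, ncol = 6, cell_size = 1000)
  expect_true(all(proportion_habitat(all1, 3000) == 1))
  all0 <- gm_raster(0, nrow = 6, ncol = 6, cell_size = 1000)
  expect_true(all(proportion_habitat(all0, 3000) == 0))
  one <- matrix(0, 5, 5); one[3, 3] <- 1
  p <- proportion_habitat(gm_raster(one, cell_size = 1000), 3000)
  expect_equal(p[3, 3], 1 / 9)          # interior 3x3 window
  expect_equal(p[2, 2], 1 / 9)
  expect_equal(p[1, 1], 0)
  ## truncated edge window: corner sees a 2x2 window
  two <- matrix(0, 5, 5); two[1, 1] <- 1
  p2 <- proportion_habitat(gm_raster(two, cell_size = 1000), 3000)
  expect_equal(p2[1, 1], 1 / 4)
  expect_error(proportion_habitat(all1, 500), "window")
})

test_that("fragment sizes: areas, log10 scale, connectivity convention", {
  ## three cells in an L (one 300 ha fragment) plus one isolated cell
  h <- rast(list(c(1, 0, 0, 0),
                 c(1, 1, 0, 0),
                 c(0, 0, 0, 1)), cell_size = 1000)
  fr <- fragment_sizes(h)
  expect_equal(fr$areas_ha[fr$labels[3, 1]], 300)
  expect_equal(fr$log10_ha[3, 1], log10(300), tolerance = 1e-12)
  expect_equal(round(fr$log10_ha[3, 1], 3), 2.477)
  ## isolated 1 km2 cell -> 100 ha, log10(100) = 2
  expect_equal(fr$log10_ha[1, 4], 2)
  expect_equal(length(fr$areas_ha), 2)
  ## two cells touching only diagonally: one fragment under 8-connectivity,
  ## two under the 4-connectivity oracle
  dg <- rast(list(c(1, 0),
                  c(0, 1)), cell_size = 1000)
  expect_equal(length(fragment_sizes(dg, 8)$areas_ha), 1)
  expect_equal(length(fragment_sizes(dg, 4)$areas_ha), 2)
  ## conservation: fragment areas sum to habitat cell count x cell area
  set.seed(9)
  m <- matrix(rbinom(400, 1, 0.3), 20, 20)
  fr2 <- fragment_sizes(gm_raster(m, cell_size = 1000))
  expect_equal(sum(fr2$areas_ha), sum(m) * 100)
})

test_that("distance transform is exact against brute force", {
  ## hand cases: mask cell 0, orthogonal 1000 m, diagonal 1414.2 m
  m <- matrix(0, 3, 3); m[2, 2] <- 1
  d <- distance_to(gm_raster(m, cell_size = 1000))
  expect_equal(d[2, 2], 0)
  expect_equal(d[2, 3], 1000)
  expect_equal(d[1, 1], sqrt(2) * 1000)
  expect_equal(round(d[1, 1], 1), 1414.2)
  ## random 20x20 masks vs exhaustive search
  set.seed(31)
  for (i in 1:5) {
    mm <- matrix(rbinom(400, 1, 0.05), 20, 20)
    if (!any(mm == 1)) mm[7, 13] <- 1
    r <- gm_raster(mm, cell_size = 250)
    expect_equal(unclass(distance_to(r)), brute_distance(r),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(distance_to(gm_raster(0, nrow = 3, ncol = 3)), "empty mask")
})

test_that("functional connectivity merges patches across small gaps only", {
  ## two 100-ha patches (10x10 cells of 100 m): gap of one empty column is a
  ## 100 m edge-to-edge gap -> merge; log10(200 ha x 100) = 4.301
  m <- matrix(0, 10, 21)
  m[, 1:10] <- 1; m[, 12:21] <- 1
  h <- gm_raster(m, cell_size = 100)
  fc <- functional_connectivity(h, gap_m = 180)
  expect_equal(fc$log10_ha100[5, 5], log10(200 * 100), tolerance = 1e-12)
  expect_equal(round(fc$log10_ha100[5, 5], 3), 4.301)
  expect_equal(fc$log10_ha100[5, 15], fc$log10_ha100[5, 5])
  ## the gap column inherits the nearest patch's cluster value (<= 180 m off
  ## the forest edge scores as inside)
  expect_equal(fc$log10_ha100[5, 11], log10(20000))
  ## same patches, 2000 m gap -> no merge, each reports log10(100 x 100) = 4
  m2 <- matrix(0, 10, 40)
  m2[, 1:10] <- 1; m2[, 31:40] <- 1
  fc2 <- functional_connectivity(gm_raster(m2, cell_size = 100), gap_m = 180)
  expect_equal(fc2$log10_ha100[5, 5], 4)
  expect_equal(fc2$log10_ha100[5, 35], 4)
  ## isolated patch: connectivity area = fragment area (x100)
  one <- gm_raster(matrix(c(1, 0, 0, 0), 2, 2), cell_size = 1000)
  fc3 <- functional_connectivity(one, gap_m = 180)
  expect_equal(fc3$cluster_areas_ha, fragment_sizes(one)$areas_ha)
  expect_error(functional_connectivity(one, gap_m = -1), "gap_m")
})

test_that("gap_m = 0 reduces functional clusters to fragments", {
  set.seed(17)
  m <- matrix(rbinom(900, 1, 0.25), 30, 30)
  h <- gm_raster(m, cell_size = 100)
  fc <- functional_connectivity(h, gap_m = 0)
  fr <- fragment_sizes(h)
  expect_equal(sort(fc$cluster_areas_ha), sort(fr$areas_ha))
  hb <- !is.na(unclass(fr$log10_ha))
  expect_equal(unclass(fc$log10_ha100)[hb],
               unclass(fr$log10_ha)[hb] + 2)   # x100 on the log10 scale
})

test_that("homogeneity: constants, checkerboard, range", {
  cst <- gm_raster(0.7, nrow = 5, ncol = 5)
  expect_true(all(homogeneity(cst) == 1))
  ## checkerboard: orthogonal neighbours differ by the full range, diagonal
  ## neighbours are equal -> interior mean |diff| = 0.5 under 8 neighbours
  cb <- gm_raster(outer(1:6, 1:6, function(i, j) (i + j) %% 2))
  hm <- homogeneity(cb)
  expect_equal(hm[3, 3], 0.5)
  set.seed(4)
  rnd <- gm_raster(matrix(runif(100), 10, 10))
  hr <- homogeneity(rnd)
  expect_true(all(hr >= 0 & hr <= 1))
})

test_that("metrics_table flattens all six metrics per cell", {
  set.seed(21)
  hb <- generate_fragmented_habitat(small_scenario())
  mt <- metrics_table(landscape_metrics(hb$habitat, hb$roads, hb$urban,
                                        hb$veg, window_m = 3000))
  expect_named(mt, c("cell", "prop_habitat", "fragment_size", "connectivity",
                     "homogeneity", "dist_urban", "dist_road"))
  expect_equal(nrow(mt), 1600)
  hab_cells <- which(unclass(hb$habitat) == 1)
  expect_false(anyNA(mt$fragment_size[hab_cells]))
  expect_true(all(is.na(mt$fragment_size[-hab_cells])))
  ## fragment area (ha) never exceeds its functional-cluster area
  expect_true(all(mt$connectivity[hab_cells] - 2 >=            # /100 on log10
                    mt$fragment_size[hab_cells] - 1e-9))
  expect_true(all(mt$dist_road >= 0))
  expect_equal(sort(unique(mt$dist_road[unclass(hb$roads) == 1])), 0)
})
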