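test_that("scenario config validates its invariants", {
  expect_error(scenario_config(habitat_cover = 0), "habitat_cover")
  expect_error(scenario_config(habitat_cover = 1), "habitat_cover")
  expect_error(scenario_config(n_sites = 0), "n_sites")
  expect_error(scenario_config(bias_fragment = -1), "bias_fragment")
  expect_s3_class(scenario_config(), "scenario_config")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_scenario(seed = 5)
  a <- generate_climate_layers(cfg)
  b <- generate_climate_layers(cfg)
  expect_identical(a, b)
  ha <- generate_fragmented_habitat(cfg)
  hb <- generate_fragmented_habitat(cfg)
  expect_identical(ha, hb)
  ## the full scenario, records included
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  ## a different seed changes the world
  expect_false(identical(unclass(generate_fragmented_habitat(
    small_scenario(seed = 6))$habitat), unclass(ha$habitat)))
  ## generator calls do not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(generate_climate_layers(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("climate layers are smooth, finite and mutually correlated", {
  cfg <- small_scenario(seed = 2)
  cl <- generate_climate_layers(cfg)
  expect_length(cl, cfg$n_climate_layers)
  m <- unclass(cl[[1]])
  expect_true(all(is.finite(m)))
  ## lag-1 spatial autocorrelation above 0.9 at default smoothness
  expect_gt(cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)])), 0.9)
  expect_gt(cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ])), 0.9)
  ## layers share a dominant gradient
  mat <- vapply(cl, function(r) as.vector(unclass(r)), numeric(1600))
  cc <- cor(mat)
  expect_gt(mean(abs(cc[upper.tri(cc)])), 0.3)
})

test_that("habitat realizes the requested cover and fragment structure", {
  for (seed in 1:5) {
    hb <- generate_fragmented_habitat(small_scenario(seed = seed))
    cover <- mean(unclass(hb$habitat))
    expect_gte(cover, 0.07); expect_lte(cover, 0.17)
    expect_gt(sum(hb$habitat == 1), 0)
  }
  ## default fragmentation: fragment sizes span >= 2 orders of magnitude
  hb <- generate_fragmented_habitat(
    scenario_config(seed = 3, width = 100, height = 100))
  ar <- fragment_sizes(hb$habitat)$areas_ha
  expect_gte(log10(max(ar) / min(ar)), 2)
  ## very large fragmentation parameter: one patch dominates
  dom <- vapply(1:20, function(s) {
    h <- generate_fragmented_habitat(
      scenario_config(seed = s, width = 50, height = 50,
                      fragmentation = 30))$habitat
    a <- fragment_sizes(h)$areas_ha
    max(a) / sum(a)
  }, numeric(1))
  expect_gte(sum(dom >= 0.5), 18)
  ## road and urban masks are nonempty and urban centers lie on roads
  hb2 <- generate_fragmented_habitat(small_scenario(seed = 9))
  expect_gt(sum(hb2$roads == 1), 0)
  expect_gt(sum(hb2$urban == 1), 0)
  expect_true(all(hb2$veg >= 0 & hb2$veg <= 1))
})

test_that("unbiased surveys select sites uniformly; biased ones do not", {
  cfg <- small_scenario(seed = 4, imprecise_rate = 0, duplicate_rate = 0,
                        outside_rate = 0, centroid_rate = 0,
                        synonym_rate = 0, bad_name_rate = 0)
  scen <- simulate_scenario(cfg)
  p <- scen$truth$site_probabilities
  expect_equal(sum(p), 1)
  expect_equal(max(p) - min(p), 0)      # uniform over habitat cells
  expect_lte(max(scen$truth$true_richness), cfg$n_species)
  ## biased selection concentrates on large fragments: chosen-site mean
  ## log-fragment-size exceeds the habitat-wide mean in >= 95/100 seeds
  frag <- unclass(scen$metrics$fragment_size)
  hab_mean <- mean(frag[unclass(scen$habitat) == 1])
  hits <- 0L
  for (s in 1:100) {
    cfgb <- small_scenario(seed = s, bias_fragment = 2, n_species = 5,
                           effort_per_site = 1, imprecise_rate = 0,
                           duplicate_rate = 0, outside_rate = 0,
                           centroid_rate = 0, synonym_rate = 0,
                           bad_name_rate = 0)
    sv <- simulate_survey(cfgb, scen$habitat, scen$climate, scen$metrics)
    if (mean(frag[sv$truth$sites]) > hab_mean) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("record volume is Poisson-consistent and coordinates are precise", {
  cfg <- small_scenario(seed = 10, imprecise_rate = 0, duplicate_rate = 0,
                        outside_rate = 0, centroid_rate = 0,
                        synonym_rate = 0, bad_name_rate = 0)
  sv <- simulate_scenario(cfg)
  lambda <- cfg$n_sites * cfg$effort_per_site
  expect_lt(abs(nrow(sv$records) - lambda), 3 * sqrt(lambda))
  ## all coordinates carry >= 3 decimals when no degradation is planted
  dec <- nchar(sub("^[^.]*\\.", "", sv$records$lon))
  expect_true(all(dec >= 3))
  ## species names come from the declared pool
  expect_true(all(sv$records$species %in% sv$names))
})

test_that("planted defects are seen by the matching filters", {
  cfg <- small_scenario(seed = 11)
  scen <- simulate_scenario(cfg)
  poly <- polygon_rect(0, 0, cfg$width * cfg$cell_size,
                       cfg$height * cfg$cell_size)
  res <- clean_records(scen$records, poly, valid_names = scen$names,
                       synonym_map = scen$synonyms,
                       centroids = scen$urban_centers)
  rep <- res$report
  expect_gt(rep$removed_duplicates, 0)
  expect_gt(rep$removed_precision, 0)
  expect_gt(rep$removed_extent, 0)
  expect_gt(rep$removed_centroid, 0)
  expect_gt(rep$removed_taxonomy, 0)
  ## synonyms were canonicalized, not dropped
  expect_true(all(res$records$species %in% scen$names))
})
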