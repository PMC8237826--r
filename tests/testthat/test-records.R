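test_that("deduplicate keys on species + raw coords + date", {
  r <- make_records(c("Aus bus", "Aus bus", "Cus dus", "Aus bus"),
                    lon = c("-46.701", "-46.701", "-46.701", "-46.701"),
                    lat = c("-23.512", "-23.512", "-23.512", "-23.512"),
                    date = c("2001-01-01", "2001-01-01", "2001-01-01",
                             "2001-01-02"))
  out <- deduplicate(r)
  expect_equal(out$removed, 1)          # exact duplicate only
  expect_equal(nrow(out$records), 3)    # other species / other date kept
  ## first occurrence kept
  expect_equal(out$records$species[1], "Aus bus")
  ## name normalization: case and whitespace do not defeat the key
  r2 <- make_records(c("Aus bus", " aus  BUS "), "-46.701", "-23.512")
  expect_equal(deduplicate(r2)$removed, 1)
})

test_that("precision filter counts decimals on the raw string", {
  r <- make_records(rep("Aus bus", 4),
                    lon = c("-46.701", "-46.7", "-46.701", "-46.700"),
                    lat = c("-23.512", "-23.512", "-23", "-23.510"))
  out <- filter_precision(r, 3)
  expect_equal(out$removed, 2)
  ## trailing zeros count: "-46.700" has three decimals
  expect_true("-46.700" %in% out$records$lon)
  ## unparseable coordinates are removed here
  bad <- make_records("Aus bus", lon = "not-a-number", lat = "-23.512")
  expect_equal(filter_precision(bad)$removed, 1)
})

test_that("extent filter is boundary-inclusive", {
  sq <- polygon_rect(0, 0, 1, 1)
  r <- make_records(rep("x", 4),
                    lon = c("0.500", "2.000", "1.000", "0.000"),
                    lat = c("0.500", "0.500", "0.500", "0.000"))
  out <- filter_extent(r, sq)
  ## centroid in; outside bbox out; edge point and corner in
  expect_equal(out$removed, 1)
  expect_setequal(out$records$lon, c("0.500", "1.000", "0.000"))
})

test_that("centroid filter removes records within the radius only", {
  r <- make_records(rep("x", 3),
                    lon = c("50010.000", "55000.000", "50000.000"),
                    lat = c("50000.000", "50000.000", "50000.000"))
  out <- filter_centroids(r, cbind(50000, 50000), radius_m = 1000)
  expect_equal(out$removed, 2)          # 10 m and 0 m hits; 5 km survives
  expect_equal(out$records$lon, "55000.000")
  ## empty centroid list is the identity
  expect_equal(filter_centroids(r, NULL)$removed, 0)
  expect_equal(filter_centroids(r, cbind(numeric(0), numeric(0)))$removed, 0)
})

test_that("taxonomy filter canonicalizes synonyms and drops unknowns", {
  fx <- planted_fixture()
  r <- make_records(c("Aus bus", "Aus buso", "Zus zus"),
                    lon = c("1.000", "2.000", "3.000"),
                    lat = c("1.000", "2.000", "3.000"))
  out <- filter_taxonomy(r, fx$valid_names, fx$synonym_map)
  expect_equal(out$removed, 1)
  expect_equal(out$records$species, c("Aus bus", "Aus bus"))
  ## a synonym pointing outside the valid list is a configuration error
  expect_error(
    filter_taxonomy(r, fx$valid_names,
                    data.frame(synonym = "a", accepted = "Qus qus")),
    "valid-name")
})

test_that("full pipeline: planted counts, additivity, idempotence", {
  fx <- planted_fixture(k = 7)
  res <- clean_records(fx$records, fx$polygon, fx$valid_names,
                       fx$synonym_map, fx$centroids, min_decimals = 3,
                       radius_m = fx$radius_m)
  rep <- res$report
  expect_equal(rep$input, nrow(fx$records))
  expect_equal(rep$removed_duplicates, 7)
  expect_equal(rep$removed_precision, 7)
  expect_equal(rep$removed_extent, 7)
  expect_equal(rep$removed_centroid, 7)
  expect_equal(rep$removed_taxonomy, 7)
  expect_equal(rep$surviving, fx$n_clean)
  expect_equal(rep$input - rep$removed_duplicates - rep$removed_precision -
                 rep$removed_extent - rep$removed_centroid -
                 rep$removed_taxonomy, rep$surviving)
  ## idempotence: cleaning a cleaned set removes nothing
  res2 <- clean_records(res$records, fx$polygon, fx$valid_names,
                        fx$synonym_map, fx$centroids, min_decimals = 3,
                        radius_m = fx$radius_m)
  expect_equal(res2$report$surviving, res2$report$input)
  expect_equal(res2$records$species, res$records$species)
  expect_equal(res2$records$lon, res$records$lon)
})

test_that("grid assignment follows the half-open cell convention", {
  g <- grid_index(0, 0, cell_size = 1000, nrow = 10, ncol = 10)
  r <- make_records(rep("x", 4),
                    lon = c("500.000", "1000.000", "999.999", "1000.001"),
                    lat = c("500.000", "500.000", "500.000", "500.000"))
  out <- assign_to_grid(r, g)
  ## interior point; edge point belongs to the cell starting at the edge;
  ## two points 2/1000 m apart straddle the edge into different cells
  expect_equal(out$col, c(1L, 2L, 1L, 2L))
  expect_equal(out$row, rep(1L, 4))
  expect_equal(out$cell, c(1L, 11L, 1L, 11L))
  ## brute-force binning oracle on random in-extent points
  set.seed(42)
  pts <- data.frame(x = runif(200, 0, 10000), y = runif(200, 0, 10000))
  rr <- make_records(rep("x", 200), sprintf("%.3f", pts$x),
                     sprintf("%.3f", pts$y))
  out <- assign_to_grid(rr, g)
  for (i in c(1, 50, 113)) {
    ok_col <- which(pts$x[i] >= (0:9) * 1000 & pts$x[i] < (1:10) * 1000)
    expect_equal(out$col[i], ok_col)
  }
  ## out-of-extent record errors
  bad <- make_records("x", "10500.000", "500.000")
  expect_error(assign_to_grid(bad, g), "extent")
})

test_that("occurrence CSV round-trip preserves raw coordinate strings", {
  fx <- planted_fixture()
  f <- tempfile(fileext = ".csv")
  write_occurrences(fx$records, f)
  back <- read_occurrences(f)
  expect_equal(back$lon, fx$records$lon)
  expect_equal(back$lat, fx$records$lat)
  expect_equal(back$species, fx$records$species)
})
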