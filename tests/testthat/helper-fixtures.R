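## Shared fixtures, all built in code.

## occurrence data.frame from terse vectors
make_records <- function(species, lon, lat, date = "2000-01-01",
                         source = "database") {
  as_occurrences(data.frame(species = species, lat = lat, lon = lon,
                            date = date, source = source))
}

## planted-violation fixture: k records per violation type plus n_clean clean
## records, on a [0,100] x [0,100] polygon with one city centroid at (50,50)
## (radius 5 m). Filter order charges each planted record to exactly one
## cause.
planted_fixture <- function(k = 7, n_clean = 10) {
  valid <- c("Aus bus", "Cus dus")
  syn <- data.frame(synonym = "Aus buso", accepted = "Aus bus")
  clean <- make_records(
    species = rep(valid, length.out = n_clean),
    lon = sprintf("%.3f", seq(10, 30, length.out = n_clean)),
    lat = sprintf("%.3f", seq(70, 90, length.out = n_clean)),
    date = sprintf("2000-01-%02d", seq_len(n_clean)))
  dup <- clean[rep(seq_len(min(k, n_clean)), length.out = k), ]
  imprecise <- make_records(rep("Aus bus", k),
                            lon = sprintf("%.2f", 20 + seq_len(k)),
                            lat = sprintf("%.3f", 20 + seq_len(k)))
  outside <- make_records(rep("Aus bus", k),
                          lon = sprintf("%.3f", 150 + seq_len(k)),
                          lat = sprintf("%.3f", 20 + seq_len(k)))
  centroid <- make_records(rep("Cus dus", k),
                           lon = sprintf("%.3f", 50 + 0.001 * seq_len(k)),
                           lat = rep("50.001", k))
  badname <- make_records(rep("Xus yus", k),
                          lon = sprintf("%.3f", 60 + seq_len(k)),
                          lat = sprintf("%.3f", 10 + seq_len(k)))
  list(records = rbind(clean, dup, imprecise, outside, centroid, badname),
       polygon = polygon_rect(0, 0, 100, 100),
       centroids = cbind(50, 50), radius_m = 5,
       valid_names = valid, synonym_map = syn,
       k = k, n_clean = n_clean)
}

## binary raster from a 0/1 matrix written top-down for readability
rast <- function(rows, cell_size = 1000) {
  m <- do.call(rbind, rows)
  gm_raster(m[rev(seq_len(nrow(m))), , drop = FALSE], cell_size = cell_size)
}

## brute-force oracles -------------------------------------------------------

## nearest-mask-cell distance by exhaustive search
brute_distance <- function(mask) {
  m <- unclass(mask) == 1
  s <- cell_size(mask)
  xy <- cell_centers(mask)
  mc <- which(m)
  out <- vapply(seq_len(length(m)), function(i) {
    sqrt(min((xy[mc, 1] - xy[i, 1])^2 + (xy[mc, 2] - xy[i, 2])^2))
  }, numeric(1))
  matrix(out, nrow(mask), ncol(mask))
}

## O(n^2) k-NN mean distances with explicit loops
brute_knn <- function(points, K) {
  n <- nrow(points)
  per_site <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    d <- numeric(n - 1)
    kk <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      kk <- kk + 1
      d[kk] <- sqrt((points[i, 1] - points[j, 1])^2 +
                      (points[i, 2] - points[j, 2])^2)
    }
    per_site[i, ] <- sort(d)[seq_len(K)]
  }
  colMeans(per_site)
}

## invoke the installed CLI script in a child R process, propagating the
## current library paths (the package may live in a private library)
run_cli <- function(args) {
  script <- system.file("cli", "gapmeter", package = "gapmeter")
  stopifnot(nzchar(script))
  system2(file.path(R.home("bin"), "Rscript"), c(script, args),
          env = paste0("R_LIBS=", shQuote(paste(.libPaths(),
                                                collapse = .Platform$path.sep))),
          stdout = TRUE, stderr = TRUE)
}

small_scenario <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, width = 40, height = 40, n_species = 40,
         n_sites = 30, effort_per_site = 60, n_climate_layers = 6),
    list(...))
  do.call(scenario_config, args)
}
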