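#' Synthetic survey scenario configuration
#'
#' Defines the stated world of a synthetic sampling-coverage experiment: a
#' fragmented habitat map on a planar grid, spatially autocorrelated climate
#' layers, road/urban accessibility masks, a species pool with
#' environment-dependent occupancy, and a survey whose site selection can be
#' biased towards large/connected fragments and accessible places.
#'
#' Defaults mirror the study design the generator emulates: a 100 x 100 grid
#' of 1 km cells, 19 climate layers, 12% habitat cover (the biome's remnant
#' forest fraction), a 279-species pool, and 117 survey sites.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param width,height grid extent in cells.
#' @param cell_size cell edge, meters.
#' @param n_climate_layers number of climate rasters.
#' @param habitat_cover target habitat fraction, strictly in (0, 1).
#' @param fragmentation smoothness (in cells) of the Gaussian random field
#'   thresholded into habitat; larger values give fewer, larger fragments.
#' @param climate_smoothness smoothness (cells) of climate fields.
#' @param n_species species-pool size.
#' @param n_sites number of surveyed sites (cells).
#' @param bias_fragment coefficient (>= 0) weighting site choice by the
#'   z-score of log10 fragment size.
#' @param bias_access coefficient (>= 0) weighting site choice by the
#'   negative z-score of distance to the nearest road or urban area.
#' @param effort_per_site mean records per surveyed site (Poisson).
#' @param coord_decimals decimals used when formatting record coordinates.
#' @param imprecise_rate,duplicate_rate,outside_rate,centroid_rate,synonym_rate,bad_name_rate
#'   per-record probabilities of planted data-quality defects (low-precision
#'   coordinates, exact duplicates, out-of-extent coordinates, coordinates
#'   snapped to a city center, accepted-synonym names, erroneous names);
#'   each record receives at most one defect.
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L, width = 100L, height = 100L,
                            cell_size = 1000, n_climate_layers = 19L,
                            habitat_cover = 0.12, fragmentation = 5,
                            climate_smoothness = 6,
                            n_species = 279L, n_sites = 117L,
                            bias_fragment = 0, bias_access = 0,
                            effort_per_site = 250,
                            coord_decimals = 4L,
                            imprecise_rate = 0.03, duplicate_rate = 0.02,
                            outside_rate = 0.01, centroid_rate = 0.01,
                            synonym_rate = 0.02, bad_name_rate = 0.01) {
  cfg <- list(seed = as.integer(seed), width = as.integer(width),
              height = as.integer(height), cell_size = cell_size,
              n_climate_layers = as.integer(n_climate_layers),
              habitat_cover = habitat_cover, fragmentation = fragmentation,
              climate_smoothness = climate_smoothness,
              n_species = as.integer(n_species), n_sites = as.integer(n_sites),
              bias_fragment = bias_fragment, bias_access = bias_access,
              effort_per_site = effort_per_site,
              coord_decimals = as.integer(coord_decimals),
              imprecise_rate = imprecise_rate, duplicate_rate = duplicate_rate,
              outside_rate = outside_rate, centroid_rate = centroid_rate,
              synonym_rate = synonym_rate, bad_name_rate = bad_name_rate)
  stopifnot(cfg$habitat_cover > 0, cfg$habitat_cover < 1,
            cfg$width > 0, cfg$height > 0, cfg$cell_size > 0,
            cfg$n_climate_layers > 0, cfg$n_species > 0, cfg$n_sites > 0,
            cfg$bias_fragment >= 0, cfg$bias_access >= 0,
            cfg$effort_per_site > 0, cfg$fragmentation > 0)
  rates <- c(cfg$imprecise_rate, cfg$duplicate_rate, cfg$outside_rate,
             cfg$centroid_rate, cfg$synonym_rate, cfg$bad_name_rate)
  stopifnot(all(rates >= 0), sum(rates) < 1)
  class(cfg) <- "scenario_config"
  cfg
}

## Smooth spatially autocorrelated Gaussian field: white noise blurred by a
## separable Gaussian kernel of bandwidth `sigma` cells, standardized to
## mean 0 / sd 1. Lag-d autocorrelation ~ exp(-d^2 / (4 sigma^2)).
smooth_field <- function(nrow, ncol, sigma) {
  w <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  kr <- gauss_kernel(nrow, sigma)
  kc <- gauss_kernel(ncol, sigma)
  f <- kr %*% w %*% t(kc)
  (f - mean(f)) / stats::sd(f)
}

gauss_kernel <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), function(a, b) (a - b)^2)
  k <- exp(-d / (2 * sigma^2))
  k / rowSums(k)
}

species_pool <- function(n) sprintf("Species_%03d", seq_len(n))

#' Generate spatially autocorrelated climate layers
#'
#' Each layer is a weighted sum of one shared latent gradient and a
#' layer-specific smooth field plus a small white-noise nugget, so layers are
#' mutually correlated and a dominant gradient exists for PCA to recover.
#' The latent gradient is attached as attribute `"latent"` (a matrix) and
#' drives species occupancy in [simulate_survey()].
#'
#' @param config a [scenario_config()].
#' @return list of `n_climate_layers` [gm_raster] objects, attribute
#'   `latent` holding the shared gradient matrix.
#' @export
generate_climate_layers <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(derive_seed(config$seed, 1L), {
    nr <- config$height; nc <- config$width
    latent <- smooth_field(nr, nc, config$climate_smoothness)
    layers <- vector("list", config$n_climate_layers)
    for (i in seq_len(config$n_climate_layers)) {
      w <- stats::runif(1, 0.6, 0.95)
      own <- smooth_field(nr, nc, config$climate_smoothness)
      f <- w * latent + sqrt(1 - w^2) * own +
        0.1 * matrix(stats::rnorm(nr * nc), nr, nc)
      mu <- stats::runif(1, -5, 30); s <- stats::runif(1, 1, 8)
      layers[[i]] <- gm_raster(mu + s * f, cell_size = config$cell_size)
    }
    names(layers) <- sprintf("clim_%02d", seq_along(layers))
    attr(layers, "latent") <- latent
    layers
  })
}

#' Generate a fragmented binary habitat map with road and urban masks
#'
#' Habitat is a Gaussian random field (bandwidth = `fragmentation` cells)
#' thresholded at the quantile that realizes `habitat_cover`; larger
#' `fragmentation` yields fewer, larger, better-connected fragments. Roads
#' are 1-cell-wide wandering polylines crossing the extent; urban areas are
#' small clusters seeded on roads. A continuous vegetation-index layer
#' (smoothed habitat plus noise, rescaled to [0, 1]) stands in for remotely
#' sensed greenness.
#'
#' @param config a [scenario_config()].
#' @return list with elements `habitat`, `roads`, `urban` (0/1 rasters),
#'   `veg` (continuous raster) and `urban_centers` (matrix of city-center
#'   coordinates, used as the synthetic populated-place centroid list).
#' @export
generate_fragmented_habitat <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(derive_seed(config$seed, 2L), {
    nr <- config$height; nc <- config$width; s <- config$cell_size
    f <- smooth_field(nr, nc, config$fragmentation)
    if (stats::sd(f) == 0)
      stop("degenerate random field: cannot threshold to requested cover")
    thr <- stats::quantile(f, 1 - config$habitat_cover, names = FALSE)
    hab <- (f > thr) * 1
    if (!any(hab == 1)) stop("thresholding produced an empty habitat mask")

    roads <- matrix(0, nr, nc)
    n_roads <- max(2L, round((nr + nc) / 60))
    for (r in seq_len(n_roads)) {
      if (stats::runif(1) < 0.5) {           # west-east road
        i <- sample.int(nr, 1)
        for (j in seq_len(nc)) {
          roads[i, j] <- 1
          i <- min(nr, max(1L, i + sample(c(-1L, 0L, 1L), 1)))
        }
      } else {                               # south-north road
        j <- sample.int(nc, 1)
        for (i in seq_len(nr)) {
          roads[i, j] <- 1
          j <- min(nc, max(1L, j + sample(c(-1L, 0L, 1L), 1)))
        }
      }
    }

    urban <- matrix(0, nr, nc)
    road_cells <- which(roads == 1)
    n_urban <- max(2L, round(nr * nc / 2500))
    centers <- road_cells[sample.int(length(road_cells), n_urban)]
    for (cc in centers) {
      i <- (cc - 1L) %% nr + 1L; j <- (cc - 1L) %/% nr + 1L
      h <- sample(1:2, 1)                    # cluster half-width minus one
      urban[max(1, i - h + 1):min(nr, i + h - 1),
            max(1, j - h + 1):min(nc, j + h - 1)] <- 1
    }
    uc <- cell_centers(gm_raster(urban, cell_size = s), centers)

    veg <- gauss_kernel(nr, 2) %*% hab %*% t(gauss_kernel(nc, 2)) +
      0.05 * matrix(stats::rnorm(nr * nc), nr, nc)
    veg <- (veg - min(veg)) / (max(veg) - min(veg))

    list(habitat = gm_raster(hab, cell_size = s),
         roads = gm_raster(roads, cell_size = s),
         urban = gm_raster(urban, cell_size = s),
         veg = gm_raster(veg, cell_size = s),
         urban_centers = uc)
  })
}

## Site-selection probabilities over candidate (habitat) cells.
## P(site = cell) proportional to
##   exp(bias_fragment * z(log10 fragment size) - bias_access * z(access dist))
site_selection_probs <- function(config, candidates, frag_log_ha, access_dist) {
  lin <- config$bias_fragment * zscore(frag_log_ha) -
    config$bias_access * zscore(access_dist)
  w <- exp(lin - max(lin))
  p <- w / sum(w)
  names(p) <- as.character(candidates)
  p
}

#' Simulate a (possibly biased) survey with known ground truth
#'
#' Survey sites are cells drawn without replacement from the habitat cells
#' with probability proportional to
#' `exp(bias_fragment * z(log10 fragment size) - bias_access * z(distance to
#' nearest road or city))` (weighted sampling uses R's sequential algorithm,
#' fixed by the stage seed). Each site receives `Poisson(effort_per_site)`
#' records whose species are drawn uniformly from the cell's true community;
#' species occupancy is an independent Bernoulli draw with probability
#' logistic in the generator's latent climate gradient, with per-species
#' random midpoints and slopes of random sign. Coordinates are emitted as
#' strings (planar meters) so the precision filter is exercisable, and a
#' configurable fraction of records is planted with data-quality defects.
#'
#' @param config a [scenario_config()].
#' @param habitat habitat raster (or the list from
#'   [generate_fragmented_habitat()]).
#' @param climate climate-layer list from [generate_climate_layers()]
#'   (supplies the latent gradient).
#' @param metrics per-cell [landscape_metrics()] result (needs
#'   `fragment_size`, `dist_road`, `dist_urban`).
#' @param urban_centers optional city-center coordinate matrix used by the
#'   planted centroid-snap defect; when NULL it is re-derived from `config`
#'   (assumes `habitat` came from the same config).
#' @return list with `records` (occurrence data.frame with raw coordinate
#'   strings), `truth` (class `survey_truth`: per-cell true richness, site
#'   selection probabilities, chosen sites, bias coefficients), `names`
#'   (valid-name list) and `synonyms` (two-column synonym map).
#' @export
simulate_survey <- function(config, habitat, climate, metrics,
                            urban_centers = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.list(habitat) && !inherits(habitat, "gm_raster")) habitat <- habitat$habitat
  latent <- attr(climate, "latent")
  stopifnot(!is.null(latent))
  with_seed(derive_seed(config$seed, 3L), {
    nr <- config$height; nc <- config$width; s <- config$cell_size
    candidates <- which(unclass(habitat) == 1)
    if (config$n_sites > length(candidates))
      stop("n_sites exceeds the number of candidate (habitat) cells")

    frag <- unclass(metrics$fragment_size)[candidates]
    access <- pmin(unclass(metrics$dist_road), unclass(metrics$dist_urban))[candidates]
    probs <- site_selection_probs(config, candidates, frag, access)
    sites <- candidates[sample.int(length(candidates), config$n_sites,
                                   prob = probs)]

    ## species occupancy: logistic in the latent climate gradient, scaled by
    ## a log-uniform per-species prevalence (2-32%) so local communities are
    ## a small fraction of the pool, as in real assemblages
    pool <- species_pool(config$n_species)
    prev <- 10^stats::runif(config$n_species, -1.7, -0.5)
    mid <- stats::runif(config$n_species, -1.5, 1.5)
    slope <- stats::runif(config$n_species, 1, 3) *
      sample(c(-1, 1), config$n_species, replace = TRUE)
    g <- as.vector(latent)
    occ_p <- stats::plogis(rep(stats::qlogis(prev), each = length(g)) +
                             outer(g, mid, "-") *
                             rep(slope, each = length(g)))
    occ <- matrix(stats::runif(length(occ_p)) < occ_p, nrow = length(g))
    true_richness <- rowSums(occ)

    recs <- vector("list", length(sites))
    for (k in seq_along(sites)) {
      cell <- sites[k]
      n <- stats::rpois(1, config$effort_per_site)
      if (n == 0) next
      comm <- which(occ[cell, ])
      sp <- if (length(comm))
        comm[sample.int(length(comm), n, replace = TRUE)]
      else sample.int(config$n_species, n, replace = TRUE,
                      prob = occ_p[cell, ])
      ctr <- cell_centers(habitat, cell)
      recs[[k]] <- data.frame(
        species = pool[sp],
        x = ctr[1, 1] + stats::runif(n, -0.5, 0.5) * s,
        y = ctr[1, 2] + stats::runif(n, -0.5, 0.5) * s,
        date = as.character(as.Date("1970-01-01") +
                              sample.int(17800L, n, replace = TRUE)),
        stringsAsFactors = FALSE)
    }
    recs <- do.call(rbind, recs)
    if (is.null(recs)) stop("survey produced no records; increase effort_per_site")

    syn_map <- data.frame(synonym = sprintf("Synonym_%03d", seq_len(config$n_species)),
                          accepted = pool, stringsAsFactors = FALSE)

    m <- nrow(recs)
    dec <- rep(config$coord_decimals, m)
    u <- stats::runif(m)
    br <- cumsum(c(config$imprecise_rate, config$duplicate_rate,
                   config$outside_rate, config$centroid_rate,
                   config$synonym_rate, config$bad_name_rate))
    kind <- findInterval(u, br)           # 6 = clean record
    dec[kind == 0] <- sample(0:2, sum(kind == 0), replace = TRUE)
    out <- which(kind == 2)
    recs$x[out] <- nc * s + stats::runif(length(out), 1, 5) * s
    cen <- which(kind == 3)
    if (length(cen)) {
      if (is.null(urban_centers))      # deterministic re-derivation
        urban_centers <- generate_fragmented_habitat(config)$urban_centers
      pick <- sample.int(nrow(urban_centers), length(cen), replace = TRUE)
      recs$x[cen] <- urban_centers[pick, 1]
      recs$y[cen] <- urban_centers[pick, 2]
    }
    syn <- which(kind == 4)
    recs$species[syn] <- syn_map$synonym[match(recs$species[syn], syn_map$accepted)]
    bad <- which(kind == 5)
    recs$species[bad] <- paste0(recs$species[bad], "_err")

    records <- data.frame(
      species = recs$species,
      lat = formatC(recs$y, format = "f", digits = 1),  # overwritten below
      lon = formatC(recs$x, format = "f", digits = 1),
      date = recs$date, source = "database",
      stringsAsFactors = FALSE)
    for (i in seq_len(m)) {
      records$lat[i] <- formatC(recs$y[i], format = "f", digits = dec[i])
      records$lon[i] <- formatC(recs$x[i], format = "f", digits = dec[i])
    }
    dup <- which(kind == 1)
    if (length(dup)) records <- rbind(records, records[dup, , drop = FALSE])

    truth <- structure(
      list(true_richness = true_richness,
           site_probabilities = probs,
           sites = sites,
           bias_fragment = config$bias_fragment,
           bias_access = config$bias_access,
           n_records = nrow(records)),
      class = "survey_truth")
    list(records = records, truth = truth,
         names = pool, synonyms = syn_map)
  })
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining [generate_climate_layers()],
#' [generate_fragmented_habitat()], [landscape_metrics()] and
#' [simulate_survey()].
#'
#' @param config a [scenario_config()].
#' @param gap_m,window_m landscape-metric parameters, see
#'   [landscape_metrics()]; `window_m = NULL` (default) uses 3 cells, since
#'   a one-cell window over a binary cell-resolution habitat map would make
#'   the habitat proportion degenerate (0/1 only).
#' @return list with `config`, `climate`, `habitat`, `roads`, `urban`,
#'   `veg`, `urban_centers`, `metrics`, `records`, `truth`, `names`,
#'   `synonyms`.
#' @export
simulate_scenario <- function(config, gap_m = 180, window_m = NULL) {
  window_m <- window_m %||% (3 * config$cell_size)
  climate <- generate_climate_layers(config)
  hb <- generate_fragmented_habitat(config)
  metrics <- landscape_metrics(hb$habitat, hb$roads, hb$urban, hb$veg,
                               gap_m = gap_m, window_m = window_m)
  sv <- simulate_survey(config, hb$habitat, climate, metrics,
                        urban_centers = hb$urban_centers)
  c(list(config = config, climate = climate), hb,
    list(metrics = metrics), sv)
}
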