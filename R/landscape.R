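## Landscape metrics on binary habitat rasters, one value per grid cell.
## Conventions (documented in the methods vignette):
##   * fragments use 8-connectivity (diagonal adjacency joins patches);
##   * inter-patch edge-to-edge distance is measured between cell centers of
##     boundary cells minus one cell size (floored at 0);
##   * non-habitat cells carry NA for fragment/connectivity metrics unless
##     inherited through the functional-connectivity edge rule.

## summed-area moving-window mean with truncated edge windows
window_mean <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  sat <- function(x) {
    x <- apply(x, 2, cumsum)
    t(apply(x, 1, cumsum))
  }
  S <- sat(m)
  Sp <- matrix(0, nr + 1, nc + 1)
  Sp[-1, -1] <- S
  r1 <- pmax(seq_len(nr) - half, 1L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half, 1L); c2 <- pmin(seq_len(nc) + half, nc)
  tot <- Sp[r2 + 1, c2 + 1, drop = FALSE] - Sp[r1, c2 + 1, drop = FALSE] -
    Sp[r2 + 1, c1, drop = FALSE] + Sp[r1, c1, drop = FALSE]
  cnt <- outer(r2 - r1 + 1, c2 - c1 + 1)
  tot / cnt
}

#' Proportion of habitat in a square moving window
#'
#' Mean of the binary habitat raster within a square window centered on each
#' cell; edge cells use the truncated window.
#'
#' @param habitat binary `gm_raster`.
#' @param window_m window edge length, meters (default 1 km).
#' @return `gm_raster` of fractions in `[0, 1]`.
#' @export
proportion_habitat <- function(habitat, window_m = 1000) {
  s <- cell_size(habitat)
  if (window_m < s) stop("window smaller than one cell")
  half <- floor(round(window_m / s) / 2)
  as_raster_like(window_mean(unclass(habitat) * 1.0, half), habitat)
}

## label connected components of a binary matrix (8- or 4-connectivity)
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  cells <- which(mask == 1)
  lab <- matrix(NA_real_, nr, nc)
  if (!length(cells)) return(list(labels = lab, sizes = integer(0)))
  id <- matrix(NA_integer_, nr, nc)
  id[cells] <- seq_along(cells)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  r <- (cells - 1L) %% nr + 1L
  cc <- (cells - 1L) %/% nr + 1L
  for (sh in shifts) {
    r2 <- r + sh[1]; c2 <- cc + sh[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- id[cbind(r2[ok], c2[ok])]
    keep <- !is.na(nb)
    if (any(keep))
      edges[[length(edges) + 1L]] <- cbind(id[cells][ok][keep], nb[keep])
  }
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  lab[cells] <- comp$membership
  list(labels = lab, sizes = as.integer(comp$csize))
}

#' Fragment sizes (log10 hectares)
#'
#' Labels habitat fragments (8-connectivity by default) and assigns every
#' habitat cell the log10 area, in hectares, of its fragment. Non-habitat
#' cells are `NA`.
#'
#' @param habitat binary `gm_raster`.
#' @param connectivity 8 (default) or 4.
#' @return list with `log10_ha` (`gm_raster`), `labels` (`gm_raster` of
#'   fragment ids) and `areas_ha` (vector of fragment areas).
#' @export
fragment_sizes <- function(habitat, connectivity = 8) {
  lc <- label_components(unclass(habitat), connectivity)
  cell_ha <- (cell_size(habitat) / 100)^2  # 1 ha = 100 m x 100 m
  areas <- lc$sizes * cell_ha
  v <- matrix(NA_real_, nrow(habitat), ncol(habitat))
  hb <- !is.na(lc$labels)
  v[hb] <- log10(areas[lc$labels[hb]])
  list(log10_ha = as_raster_like(v, habitat),
       labels = as_raster_like(lc$labels, habitat),
       areas_ha = areas)
}

#' Exact Euclidean distance transform
#'
#' Distance (meters, cell-center to cell-center) from every cell to the
#' nearest cell of a binary mask. Exact: equals brute-force nearest-mask-cell
#' search. Computed by per-row 1-D scans followed by a column-wise lower
#' envelope.
#'
#' @param mask binary `gm_raster`; must contain at least one 1.
#' @return `gm_raster` of distances, 0 on mask cells.
#' @export
distance_to <- function(mask) {
  m <- unclass(mask) == 1
  if (!any(m)) stop("empty mask")
  nr <- nrow(m); nc <- ncol(m)
  g <- matrix(Inf, nr, nc)        # per-row distance (col units) to mask
  for (i in seq_len(nr)) {
    idx <- which(m[i, ])
    if (!length(idx)) next
    g[i, ] <- vapply(seq_len(nc), function(j) min(abs(j - idx)), numeric(1))
  }
  rows <- seq_len(nr)
  M <- outer(rows, rows, function(a, b) (a - b)^2)
  d2 <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) {
    gj <- g[, j]^2
    fin <- is.finite(gj)
    d2[, j] <- apply(M[, fin, drop = FALSE] +
                       rep(gj[fin], each = nr), 1, min)
  }
  as_raster_like(sqrt(d2) * cell_size(mask), mask)
}

#' Functionally connected habitat area (log10 hectares x 100)
#'
#' Habitat fragments whose edge-to-edge gap is at most `gap_m` are merged
#' into one functional cluster; each habitat cell carries the log10 of
#' (cluster area in ha x 100). Non-habitat cells within `gap_m` of a
#' fragment inherit the value of the nearest fragment's cluster (a site just
#' off the forest edge scores as if inside). Edge-to-edge gap between two
#' fragments is the minimum center distance between their boundary cells
#' minus one cell size (floored at 0).
#'
#' @param habitat binary `gm_raster`.
#' @param gap_m maximum gap bridged by functional connectivity, meters
#'   (default 180).
#' @return list with `log10_ha100` (`gm_raster`), `cluster_areas_ha`
#'   (vector, indexed by cluster id) and `cluster_of_fragment` (vector
#'   mapping fragment id to cluster id).
#' @export
functional_connectivity <- function(habitat, gap_m = 180) {
  if (gap_m < 0) stop("gap_m must be >= 0")
  s <- cell_size(habitat)
  fr <- fragment_sizes(habitat)
  lab <- unclass(fr$labels)
  nfrag <- length(fr$areas_ha)
  cluster_of <- seq_len(max(nfrag, 1L))

  if (nfrag > 1 && gap_m > 0) {
    ## boundary cells: habitat cells with a non-habitat (or off-grid) 4-neighbor
    m <- !is.na(lab)
    nr <- nrow(m); nc <- ncol(m)
    pad <- function(shift_r, shift_c) {
      out <- matrix(FALSE, nr, nc)
      rs <- seq_len(nr) + shift_r; cs <- seq_len(nc) + shift_c
      okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
      out[okr, okc] <- m[rs[okr], cs[okc]]
      out
    }
    interior <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
    bnd <- which(m & !interior)
    bl <- lab[bnd]
    xy <- cell_centers(habitat, bnd)
    cutoff <- gap_m + s
    ## pairwise boundary-cell distances in blocks; connect fragments with
    ## edge-to-edge gap <= gap_m
    pairs <- list()
    bs <- 512L
    starts <- seq(1L, length(bnd), by = bs)
    for (a in starts) {
      ia <- a:min(a + bs - 1L, length(bnd))
      dx <- outer(xy[ia, 1], xy[, 1], "-")
      dy <- outer(xy[ia, 2], xy[, 2], "-")
      hit <- which(sqrt(dx * dx + dy * dy) - s <= gap_m, arr.ind = TRUE)
      if (nrow(hit)) {
        f1 <- bl[ia[hit[, 1]]]; f2 <- bl[hit[, 2]]
        keep <- f1 != f2
        if (any(keep))
          pairs[[length(pairs) + 1L]] <- unique(cbind(f1[keep], f2[keep]))
      }
    }
    if (length(pairs)) {
      g <- igraph::make_empty_graph(n = nfrag, directed = FALSE)
      g <- igraph::add_edges(g, t(do.call(rbind, pairs)))
      cluster_of <- igraph::components(g)$membership
    }
    rm(list = intersect(c("dx", "dy"), ls()))
  }

  cluster_areas <- as.vector(tapply(fr$areas_ha, cluster_of, sum))
  v <- matrix(NA_real_, nrow(habitat), ncol(habitat))
  hb <- !is.na(lab)
  v[hb] <- log10(cluster_areas[cluster_of[lab[hb]]] * 100)

  ## inheritance: non-habitat cells within gap_m of habitat take the value of
  ## the nearest habitat cell's cluster
  if (gap_m > 0 && any(!hb)) {
    dh <- unclass(distance_to(as_raster_like(hb * 1, habitat)))
    ring <- which(!hb & dh <= gap_m & dh > 0)
    if (length(ring)) {
      hcells <- which(hb)
      hxy <- cell_centers(habitat, hcells)
      rxy <- cell_centers(habitat, ring)
      for (k in seq_along(ring)) {
        d2 <- (hxy[, 1] - rxy[k, 1])^2 + (hxy[, 2] - rxy[k, 2])^2
        v[ring[k]] <- v[hcells[which.min(d2)]]
      }
    }
  }

  list(log10_ha100 = as_raster_like(v, habitat),
       cluster_areas_ha = cluster_areas,
       cluster_of_fragment = cluster_of)
}

#' Vegetation-index homogeneity
#'
#' Per-cell similarity of a continuous vegetation index to its 8 neighbours:
#' `1 - mean(|difference to available neighbours|) / range(index)`. A
#' constant raster (zero range) scores 1 everywhere. A transparent stand-in
#' for remote-sensing texture homogeneity measures.
#'
#' @param veg continuous `gm_raster`.
#' @return `gm_raster` with values in `[0, 1]`.
#' @export
homogeneity <- function(veg) {
  v <- unclass(veg)
  rng <- diff(range(v, na.rm = TRUE))
  if (rng == 0) return(as_raster_like(matrix(1, nrow(v), ncol(v)), veg))
  nr <- nrow(v); nc <- ncol(v)
  tot <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    r0 <- r1 - dr; c0 <- c1 - dc
    dmat <- abs(v[r0, c0, drop = FALSE] - v[r1, c1, drop = FALSE])
    tot[r0, c0] <- tot[r0, c0] + dmat
    cnt[r0, c0] <- cnt[r0, c0] + 1
  }
  h <- 1 - (tot / cnt) / rng
  as_raster_like(pmin(pmax(h, 0), 1), veg)
}

#' Compute all six per-cell landscape metrics
#'
#' Bundles proportion of habitat, fragment size, functional connectivity,
#' vegetation homogeneity and Euclidean distances to urban areas and roads.
#'
#' @param habitat,roads,urban binary `gm_raster` layers.
#' @param veg continuous vegetation-index `gm_raster`.
#' @param gap_m functional-connectivity gap, meters.
#' @param window_m habitat-proportion window, meters.
#' @return list of class `landscape_metrics` with one `gm_raster` per metric
#'   (`prop_habitat`, `fragment_size`, `connectivity`, `homogeneity`,
#'   `dist_urban`, `dist_road`). Use [metrics_table()] for a per-cell
#'   data.frame.
#' @export
landscape_metrics <- function(habitat, roads, urban, veg,
                              gap_m = 180, window_m = 1000) {
  structure(list(
    prop_habitat = proportion_habitat(habitat, window_m),
    fragment_size = fragment_sizes(habitat)$log10_ha,
    connectivity = functional_connectivity(habitat, gap_m)$log10_ha100,
    homogeneity = homogeneity(veg),
    dist_urban = distance_to(urban),
    dist_road = distance_to(roads)), class = "landscape_metrics")
}

#' @rdname landscape_metrics
#' @param metrics a `landscape_metrics` list.
#' @return `metrics_table`: data.frame with a `cell` id column (column-major
#'   linear index) and one column per metric; rows with any `NA` are kept
#'   (complete-case handling is the consumer's policy).
#' @export
metrics_table <- function(metrics) {
  vals <- lapply(metrics, function(r) as.vector(unclass(r)))
  data.frame(cell = seq_along(vals[[1]]), vals)
}
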