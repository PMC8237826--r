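# gapmeter

Sampling coverage, bias and gap analysis for species-occurrence data on an
equal-area grid.

Compiled occurrence datasets (online databases, museum digitizations,
literature checklists) are the only biodiversity evidence available at
biome scale, and they are not a probability sample: surveys cluster near
roads and cities and in large habitat remnants. gapmeter is for ecologists
and biodiversity-informatics practitioners who need to answer, before any
downstream modelling: *which grid cells of my region are genuinely
well-sampled, how spatially aggregated are they, and do they cover the
region's climate and landscape conditions?*

## What it computes

* **Record cleaning** — duplicates (same species, raw coordinates, date),
  coordinate precision on the *raw* string (≥ 3 decimals by default),
  study-polygon extent, populated-place centroids (distance rule), and
  list/synonym taxonomy, in a fixed order with an additive
  `CleaningReport`.
* **Inventory completeness** — per 1 km² cell, the sample-based species
  accumulation curve (mean over random record orders) is fitted with the
  Clench model *S(t) = a·t / (1 + b·t)*; the asymptote *a/b* predicts total
  richness and completeness is *S_obs/(a/b)*. A cell is **well-sampled**
  when it has > 50 records and completeness > 0.7, or hosts a trusted
  exhaustive local inventory.
* **Landscape metrics** — per cell: habitat proportion (moving window),
  fragment size (log₁₀ ha, 8-connectivity), 180 m functional connectivity
  (log₁₀ ha × 100), vegetation homogeneity, and exact Euclidean distances
  to roads and urban areas.
* **Environmental spaces** — standardized PCA with varimax rotation of the
  climate and landscape variables; the PC1 × PC2 plane binned into a shared
  frequency surface.
* **Coverage and bias statistics** — Schoener's
  *D = 1 − ½ Σ|pᵢ − qᵢ|* between the well-sampled surface and the
  all-cells surface, tested against 1000 uniform resamples of the same
  number of cells; the fraction of occupied environmental bins covered;
  per-cell rarity *1 − f(bin)/max f*; average-nearest-neighbour analysis
  against a randomization envelope with a per-site aggregated/overdispersed
  classification; tie-corrected Kruskal–Wallis tests of the sampled cells
  against all cells on each axis and on rarity, whole-area and per stratum.
* **Synthetic worlds** — a generator for fragmented habitat (thresholded
  Gaussian random fields), autocorrelated climate layers, roads/cities,
  environment-dependent communities and (optionally biased) surveys with
  known ground truth, used by the test suite to verify calibration and
  power of the whole pipeline.

## Worked example

An end-to-end run on a synthetic world (60 × 60 km, 50 survey sites,
120-species pool, ~250 records per site), unbiased and then biased towards
large fragments near roads:

```r
library(gapmeter)

cfg <- scenario_config(seed = 42, width = 60, height = 60, n_sites = 50,
                       n_species = 120, effort_per_site = 250,
                       n_climate_layers = 8)
rep <- run_all(run_config(scenario = cfg, n_iter = 999, n_orders = 50),
               out_dir = "runs/unbiased")
```

prints (via the persisted `report.json`):

```
n_well_sampled: 49
cleaning: 11795 of 12787 records surviving
climate:   D=0.032 p=0.605 coverage=0.022
landscape: D=0.139 p=0.873 coverage=0.125 | PC1 H=0.01 p=0.936
ANN: aggregated fraction 1.00 (n=49)
```

49 of the 50 surveyed sites qualify as well-sampled through the
completeness route (one site fell below the record threshold after
cleaning). The D tests are non-significant — the unbiased survey covers
the environmental spaces no worse than random draws — while the sites are
100% spatially aggregated simply because surveys can only happen in
habitat fragments. With `bias_fragment = 2, bias_access = 2` the same
world gives:

```
landscape: D=0.125 p=0.116 | PC1 H=41.13 p=1.4e-10 | rarity H=1.10 p=0.295
climate:   D=0.026 p=0.044 | PC1 H=15.50 p=8.2e-05
```

The landscape-PC1 Kruskal–Wallis test now detects the fragment-size bias
overwhelmingly (H = 41.1). Note the climate PC1 test also fires: in a
small, dense world the habitat mask itself is a climatically non-random,
spatially aggregated subset — the methods vignette discusses when the
climate-side tests are and are not calibrated, and the acceptance suite
demonstrates the calibrated sparse-world regime.

## Command line

```sh
GAPMETER=$(Rscript -e 'cat(system.file("cli","gapmeter",package="gapmeter"))')
Rscript $GAPMETER simulate --config scenario.json --out data/
Rscript $GAPMETER clean --records data/records.csv --polygon poly.geojson \
        --names data/names.csv --synonyms data/synonyms.csv --out cleaned/
Rscript $GAPMETER all --config run.json --out results/
```

Subcommands: `simulate`, `clean`, `landscape`, `envspace`, `completeness`,
`coverage`, `ann`, `bias`, `all`. Reruns with the same config produce
byte-identical `report.json`.

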