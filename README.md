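# tjstorm

Quantification of blood-brain-barrier tight-junction nano-architecture from
single-molecule localization microscopy (dSTORM) data.

dSTORM resolves individual antibody-labeled junctional proteins (claudin-5,
ZO1, occludin) at ~20 nm precision and exports a *molecular list*: one row
per resolved signal with x/y coordinates in nanometres. `tjstorm` is for
researchers who need to turn such lists, plus capillary cross-section
annotations, into the quantities that describe junction organization and
function:

* **Cluster analysis** - localizations are partitioned by strict
  distance-threshold single linkage: two signals are clustered when their
  distance is *strictly* below a threshold *t* (default 70 nm, admissible
  range 50-100 nm), and clusters are the transitive closure of that
  relation. Per cluster: signal count *n*, convex-hull area *A* (µm²),
  density *n/A* (signals/µm²), centroid and hull.
* **Per-capillary metrics** - total cellular signal inside the annotated
  cross-section, capillary diameter (matched-ellipse, equivalent-circle or
  max-Feret estimator), diameter-normalized abundance (signals/µm), and
  cluster counts.
* **Cluster coupling** - claudin-5 clusters classified as *coupled* to or
  *independent* of ZO1 clusters by minimum member-to-member distance
  (default 100 nm), with the coupled/independent density contrast.
* **Leakage index** - tracer signal density in the 100-300 nm abluminal
  band outside the claudin-5 ring (exact Minkowski-offset band area
  `P·Δ + π(d_out² − d_in²)` for convex rings), normalized so a reference
  group's mean defines index 1.
* **Group statistics** - two-tailed Mann-Whitney U (exact enumeration for
  small groups, tie- and continuity-corrected normal approximation
  otherwise) and Kruskal-Wallis with Dunn-Bonferroni post hoc tests.
* **Synthetic scenes** - a Neyman-Scott generator (cluster centers on a
  capillary ring, zero-truncated-Poisson molecules, geometric ≥ 1 blink
  counts for overcounting, Gaussian localization noise, Poisson background
  and tracer fields) with full ground-truth lineage, so every pipeline
  stage is testable offline.

Because each signal is an amplified proxy of its target (multivalent
labeling, fluorophore re-blinking), all quantities are designed for
*relative* comparisons between conditions, not absolute molecule counts.
See the vignette (`vignettes/tight-junction-nanoarchitecture.Rmd`) for the
model, conventions and limitations.

## Worked example

```r
library(tjstorm)

# a synthetic mature (P9-like) capillary: 5.9 um ring, 12 dense foci,
# 3x blink overcounting, 20 nm precision
sc   <- generate_scene(scene_preset("P9", seed = 7))
tab  <- sc$channels$claudin5                       # a localization_table
part <- partition_localizations(tab, threshold_nm = 70)
props <- compute_cluster_properties(tab, part, min_points = 3)
s <- cluster_summary(props)
sprintf("%d clusters (>= 3 signals); mean density %.0f +/- %.0f signals/um^2",
        s$n_clusters, s$mean_density, s$se_density)
#> "13 clusters (>= 3 signals); mean density 4390 +/- 1805 signals/um^2"
```

Thirteen clusters survive the 3-signal cutoff (the planted 12 foci plus a
background triple); mean cluster density is reported with its standard
error over non-degenerate clusters.

```r
# per-capillary metrics inside an annotation enclosing the junctional band
ring <- scene_ring_roi(sc)
ctr  <- colMeans(ring$vertices)
roi  <- capillary_roi(sweep(sweep(ring$vertices, 2, ctr) * 1.2, 2, ctr, "+"))
capillary_metrics(tab, roi, props, capillary_id = "P9-demo")[
  , c("capillary_id", "diameter_um", "total_signals",
      "normalized_signal_per_um", "n_clusters")]
#>  capillary_id diameter_um total_signals normalized_signal_per_um n_clusters
#>       P9-demo    7.079645          3712                 524.3201         13
```

A two-group tracer study (5 capillaries per group, abluminal tracer density
planted 10x higher in the immature group) recovers the leakage contrast:

```r
rows <- list()
for (i in 1:5) for (g in c("P9", "E12")) {
  si <- generate_scene(scene_preset(g, seed = 40 + 2 * i + (g == "E12"),
          tracer = list(luminal_density_um2 = 150,
                        abluminal_density_um2 = if (g == "P9") 4 else 40)))
  band <- build_abluminal_band(scene_ring_roi(si), 100, 300)
  rows[[paste(g, i)]] <- leakage_density(si$channels$tracer, band,
                                         paste0(g, "-", i), g)
}
leak <- relative_leakage_index(do.call(rbind, rows), "P9")
aggregate(relative_index ~ group, leak, mean)
#>   group relative_index
#> 1   E12       12.48017
#> 2    P9        1.00000
mann_whitney_u(leak$relative_index[leak$group == "E12"],
               leak$relative_index[leak$group == "P9"])
#> Mann-Whitney U (two-tailed): U = 0, p = 0.007937 (exact; n = 5, 5)
```

The reference group's mean index is exactly 1 by construction; the test
group's mean (12.5) scatters around the planted ratio of 10 with the
sampling noise expected from ~20 abluminal counts per reference capillary.

## Command line

```sh
Rscript -e 'tjstorm::cli_main()' simulate --preset P9 --seed 3 \
    --n-capillaries 2 --tracer-luminal 150 --tracer-abluminal 4 --out sim/
Rscript -e 'tjstorm::cli_main()' cluster --in sim/capillary_001/claudin5.csv \
    --threshold-nm 70 --min-points 3 --out out/
```

Subcommands: `simulate`, `cluster`, `capillary`, `couple`, `leakage`,
`compare`, `pipeline` (see `?cli_main`). Every run writes its resolved
configuration (all defaults included) beside the outputs.

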