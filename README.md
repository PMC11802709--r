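# flocknet

Social-network inference from RFID feeder data under three association
definitions — and the tools to find out whether the choice of definition
matters for your system.

## The problem

Studies of wild birds (and other hard-to-observe animals) routinely infer
social structure from timestamped RFID detections of PIT-tagged
individuals at feeders, under the *gambit of the group*: everyone in the
same grouping event is assumed pairwise associated. But the grouping
event itself is a modelling choice, and three definitions dominate the
literature:

1. **strict time-window** — detections chained whenever consecutive reads
   at a location fall within Δt (canonically 1 s) of each other;
2. **Gaussian-mixture gathering events** — bursts of feeder activity
   found by a 1-D mixture model over detection times, with BIC model
   selection;
3. **arrival time** — the chain rule applied to *arrivals* (first
   detection after an absence of at least Δi = 300 s), with
   Δt = 150 s: flocks travel together, so association is judged at the
   moment of arrival.

`flocknet` implements all three, builds weighted undirected networks from
the resulting group-by-individual matrices using the **simple ratio
index**, `w_ab = x / (x + y_a + y_b)` (x = events with both, y = events
with exactly one), and then quantifies how much the definition matters:

* node metrics: degree, strength, weighted betweenness (edge cost `1/w`);
* pairwise network similarity: Jaccard over edges and over closed
  triangles, single-predictor MRQAP regression, Mantel tests — each with
  pre-network permutation nulls (individual GBI columns shuffled without
  replacement, preserving per-bird detection counts);
* between-week repeatability of individual network position,
  `R = sigma^2_individual / (sigma^2_individual + sigma^2_residual)`,
  by REML random-intercept models with exact F-pivot or parametric
  bootstrap 95% CIs;
* sensitivity of all of the above to Δt (1–300 s sweep).

A fission-fusion flock-foraging simulator (latent social units, logistic
joining with a repeatable sociability trait, correlated arrivals,
open/chamber/perch feeder read models, non-social solo visits) provides
ground-truthed detection streams, so the whole pipeline is testable
without field data.

## Worked example

```r
library(flocknet)

cfg <- world_config(n_individuals = 40, n_units = 4, p_join = 0.5,
                    sigma_social = 1.0, flock_rate = 1, n_weeks = 6, seed = 1)
world   <- make_world(cfg)
streams <- simulate_weekly_panel(world)
pooled  <- detection_stream(do.call(rbind, lapply(streams, as.data.frame)))
pooled
#> <detection_stream> 182527 reads, 40 individuals, 1 location(s), span 3139037.7 s

params_arr <- association_params(delta_t = 150, delta_i = 300)
net_win <- prune_isolates(build_sri_network(
             detect_groups_window(pooled, association_params(1))))
net_arr <- prune_isolates(build_sri_network(
             detect_groups_arrival(pooled, params_arr)))
net_win
#> <social_network> V=40 E=532 D=0.682
net_arr
#> <social_network> V=40 E=773 D=0.991

compare_networks(net_win, net_arr, n_perm = 1000, seed = 1)
#> <comparison_result> Jaccard edges 0.688 | triangles 0.360 |
#>   MRQAP 0.953 (p=0.000999) | Mantel r 0.953 (p=0.001)

panel <- weekly_metric_panel(streams, "arrival", params_arr)
estimate_repeatability(panel, "strength", n_boot = 200, seed = 1)
#> <repeatability> strength (arrival): R = 0.536 [0.403, 0.676]
#>   (high; 40 individuals x 6 weeks)
```

Reading the output: the strict 1-s window produces a sparser network
(532 edges) than the arrival definition (773), yet their dyadic weights
correlate strongly (MRQAP slope / Mantel r ≈ 0.95, far beyond the
pre-network permutation null, p ≈ 0.001): network structure is largely
robust to the definition, while edge lists differ in detail
(Jaccard 0.69 on edges, 0.36 on triangles). Individual strength is
repeatable across weeks (R ≈ 0.54, "high" band) — consistent
between-individual differences that a useful association definition
should recover.

`run_flocknet()` drives the same workflow end to end from a single
config (world, weekly streams, or YAML file) and writes all tables plus a
JSON manifest; `sweep_time_window()` traces repeatability across the Δt
grid. Real data enter through `read_detections()` (CSV/TSV, ISO-8601 or
epoch-second timestamps), `map_antennas_to_locations()` and
`split_by_period()`.

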