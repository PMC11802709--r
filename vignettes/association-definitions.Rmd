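---
title: "Association definitions, SRI networks and repeatability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association definitions, SRI networks and repeatability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

Feeder-based studies of wild birds record timestamped RFID detections of
PIT-tagged individuals and must convert that stream into a social network.
The conversion rests on the *gambit of the group*: individuals detected in
the same grouping event are assumed pairwise associated. Everything then
hinges on what counts as a grouping event, and `flocknet` implements the
three definitions in common use:

* **Strict time-window.** Detections at one location are chained: whenever
  two consecutive reads are at most Δt apart they belong to the same
  event (`detect_groups_window()`). Splitting a time-sorted sequence at
  gaps exceeding Δt is exactly the transitive closure of all pairwise
  "within-Δt" links — the chain rule — and we test that equivalence
  against a union-find oracle. With Δt = 1 s this captures strict
  physical and temporal co-occurrence at the feeder.
* **Gaussian-mixture gathering events.** Detection times are modelled as a
  one-dimensional finite Gaussian mixture; each component is a burst of
  feeder activity and its assigned reads form one event
  (`detect_gathering_events()`). This adapts the window to the data:
  dense feeding bouts become single events regardless of their duration.
* **Arrival times.** A bird's *arrival* is its first detection after an
  absence longer than Δi (`detect_arrivals()`); the chain rule is then
  applied to arrivals, not raw reads, with threshold Δt
  (`detect_groups_arrival()`). Association is judged at the moment of
  arrival — flocks travel together — so a bird arriving alone stays
  unlinked even when earlier arrivals are still present, and Δi prevents
  the long chains of connection that continuous presence would create.

Canonical parameters follow field practice: Δt = 1 s for the strict
window, Δt = 150 s with Δi = 300 s for arrivals. Grouping events are
always confined to one location and one calendar date; multi-antenna
feeders (e.g. four adjacent perches) are first merged to one location with
`map_antennas_to_locations()`.

Each definition yields a group-by-individual (GBI) incidence matrix, from
which `build_sri_network()` computes simple-ratio-index weights
$w_{ab} = x / (x + y_{a} + y_{b})$, with $x$ the number of events
containing both individuals and $y_a, y_b$ those containing exactly one.
Degree-0 individuals are removed (`prune_isolates()`), and node metrics
are degree, strength and weighted betweenness with edge cost $1/w$
(betweenness is left unnormalised, with equal-cost geodesics split
fractionally; magnitudes in the tens to hundreds are therefore expected
on networks of this size).

## Comparing definitions

`compare_networks()` quantifies the similarity of two networks built from
the same stream: Jaccard similarity of edge sets and of closed-triangle
sets; a simple MRQAP regression (both adjacency matrices standardised on
their off-diagonal, slope of one on the other, significance by joint
row/column node-label permutation, two-sided); and a Mantel test (Pearson
correlation of off-diagonal weights, one-sided node-label permutation,
999 permutations by convention). With a single standardised predictor the
MRQAP slope equals the dyadic Pearson correlation, so the two tests are
expected to agree on the statistic and differ only in sidedness — we keep
both because their conventions differ and both are standard reporting.

Significance against "random group membership" uses a pre-network
permutation (`permute_gbi()`): each individual's GBI column is shuffled
without replacement, preserving how often each bird was detected in a
group while randomising composition. `permutation_null()` re-permutes both
GBIs, rebuilds both SRI networks and recomputes the statistic per
replicate (1000 by default); the empirical p-value is
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$. Permuted
replicates can produce edgeless networks whose correlation is undefined;
they are scored as similarity 0 so the null distribution is always well
defined.

## Repeatability of individual network position

Weekly sub-streams (`split_by_period()`, ISO weeks by default, with a
boundary offset for weekend-block deployments) give weekly networks and a
long panel of per-individual metrics, z-scored within each
(week, metric) cell to absorb week-to-week differences in network size
(`weekly_metric_panel()`). Individuals pruned in a week contribute no row
— absence is treated as unobserved, not as zero, consistent with degree-0
removal.

`estimate_repeatability()` fits the intercept-only random-intercept model
$y_{iw} = \mu + \alpha_i + \varepsilon_{iw}$ by REML (lme4) and reports
$R = \sigma^2_\alpha / (\sigma^2_\alpha + \sigma^2_\varepsilon)$, the
proportion of variance attributable to consistent between-individual
differences. Confidence intervals use two routes, dispatched
automatically:

* **Balanced panels** (every individual in every week): the exact F-pivot
  interval of the balanced one-way random model (Searle 1971). We prefer
  it because it is exact by construction; in our calibration simulations
  the percentile parametric bootstrap covered a 0.5 truth in only ~91% of
  nominally-95% intervals at 100 individuals × 10 weeks, while the
  F-pivot interval sat at its nominal level.
* **Unbalanced panels** (the realistic field case): parametric bootstrap —
  simulate from the fitted model, refit, take percentile quantiles
  (default 1000 replicates).

On balanced data the REML point estimate agrees with the one-way ANOVA
intraclass correlation to 1e-6 whenever the latter is positive (tested).
R is clipped to [0, 1]; estimates are banded low (< 0.3), medium
(0.3–0.5, boundaries inclusive — the conventional statement of the bands
is ambiguous at the endpoints, and we resolve both into the middle band)
and high (> 0.5).

`cross_definition_regression()` regresses one definition's z-scored
metric on another's over matched (individual, week) pairs, and
`sweep_time_window()` recomputes repeatability over a Δt grid
(1–300 s, Δi held at 300 s for arrivals) for sensitivity analysis.

## The synthetic flock-foraging world

No field data ship with the package; `world_config()` / `make_world()` /
`simulate_detections()` generate streams with the statistical structure
the analysis assumes, plus known ground truth:

* latent social units whose members visit the feeder together — unit
  visits are a Poisson process (`flock_rate` per unit-hour); member $i$
  joins a visit with probability
  $\mathrm{logit}^{-1}(\mathrm{logit}(p_{join}) + s_i)$ where
  $s_i \sim N(0, \sigma^2_{social})$ is a repeatable sociability trait;
* correlated arrivals — joiners arrive at the event time plus half-normal
  jitter (`arrival_jitter_sd`, default 30 s, well inside the 150 s
  arrival window) and stay an exponential time on the antenna
  (`stay_mean`, default 20 s);
* non-social solo visits (independent Poisson per individual,
  `solo_rate`);
* feeder architecture — open antennas emit presence reads every
  `read_interval` (0.25 s) with probability `p_read`; entry chambers
  serialise birds through a single-occupancy queue and log only entry and
  exit reads (0.5 s interval); perch feeders spread reads over k antennas
  mapped to one location;
* independent weeks sharing the same traits (the repeatable component),
  each with its own derived RNG stream so any week is reproducible in
  isolation.

The ground truth records pairwise association probabilities
($q_i q_j$ within units, a small constant background across units), so
parameter-recovery tests can compare inferred networks against
`true_network()`.

Default rates are calibrated to the read volumes of published feeder
deployments (tens of thousands of reads per observation week for a
60-bird population: 6 units, `p_join` 0.8, `flock_rate` 0.5/h,
`solo_rate` 0.3/h, 9 weeks of two 8-hour days). One generative property
deserves emphasis: with a high join baseline the weekly networks
saturate — nearly every pair co-occurs every week — which compresses
between-individual variance in degree and drives repeatability towards
zero even though sociability differences exist. Worlds meant to express
repeatable network positions therefore need a wide spread of join
propensities; we use `p_join = 0.5` with `sigma_social = 1` (join
probabilities spanning roughly 0.2–0.8) for the repeatability and
sensitivity analyses, including the shipped end-to-end acceptance run
(40 individuals, 4 units, 6 weeks of two 8-hour days — problem sizes
chosen so a full run completes in about a minute).

What the simulator does *not* emulate: spatial structure and multi-feeder
choice, dominance interactions and displacement, diurnal activity
rhythms, tag loss and read-collision artefacts. Passing tests therefore
show that the pipeline recovers the structure this generative model
encodes, not that any particular field system satisfies the model.

## Numerical and algorithmic choices

* **Chain rule.** Implemented as splitting time-sorted reads at gaps
  > Δt, provably the transitive closure of pairwise-within-Δt links;
  tested against union-find on random streams. Raw reads (not thinned
  visits) feed the window detector by default, so a continuously present
  bird can bridge chains — this mimics the naive data stream; an optional
  `thin_interval` collapses same-individual reads first.
* **Mixture event detection.** Blocks are pre-split at silences longer
  than 30 minutes, bounding the candidate component range
  (K up to min(25, n/5)); models "E"/"V" are scored by BIC (mclust).
  Fitting is deterministic: mclust initialises EM from model-based
  hierarchical clustering, on a fixed subsample above 1500 reads (the
  default initialisation is quadratic in n), with all reads then assigned
  by maximum responsibility. Two safeguards keep the segmentation
  honest: if BIC saturates the candidate range the segment holds more
  events than the mixture can resolve and is split at its largest silence
  and re-fitted; and adjacent components separated by less than
  `min_gap` (30 s) of total silence are merged, since a gathering event
  should be bounded by a genuine lull in feeder activity rather than by
  the internal shape of one dense burst. Non-convergence falls back to a
  gap-based split (with a message).
* **Arrival bookkeeping** is per individual per location, with gaps
  strictly greater than Δi starting a new arrival (a gap of exactly Δi
  does not).
* **SRI degenerate dyads.** Pairs that both occur but never co-occur get
  weight 0 (no edge), never NaN; a pair can only have an undefined
  denominator if neither individual occurs, which cannot happen inside a
  GBI.
* **Betweenness** uses igraph with weights 1/w as costs; agreement with
  exhaustive geodesic enumeration is tested on all graphs up to 7 nodes.
* **Permutation sidedness.** MRQAP two-sided on |slope|, Mantel one-sided
  (greater), both with the (1+k)/(1+n) correction; pre-network nulls are
  one-sided greater (similarity statistics).
* **Seeds.** Every stochastic stage takes a seed; a master seed expands
  into named per-stage streams (`derive_seed()`), so pipeline stages and
  simulated weeks are independently reproducible and reruns are
  byte-identical.

## Orchestration

`run_flocknet()` drives the full comparison from a config (a
`world_config`, a list of weekly streams, or a YAML file): detect under
all three definitions, build and prune SRI networks, write cardinality,
node metrics, pairwise comparisons with pre-network nulls, weekly panels,
repeatability tables and the optional Δt sweep, plus a JSON manifest of
seeds and outputs. The package is used from R (or via
`Rscript scripts/acceptance.R` for the end-to-end reproduction run);
there is deliberately no separate shell tool — the exported functions are
the interface.

## Known limitations

* The mixture event detector is a BIC-selected finite Gaussian mixture,
  interface-compatible with, but not an implementation of, the published
  variational-Bayes gathering-event algorithm; behaviour is validated on
  synthetic bursts, and on identical well-separated visits it provably
  coincides with the other definitions (tested).
* Repeatability is estimated by REML variance components rather than a
  Bayesian sampler; the estimand is the same and the two agree to
  sampling error.
* MRQAP is single-predictor only (no semi-partialling); with one
  predictor, simple Y-permutation and semi-partialling coincide in
  expectation.
* Associations are undirected and unweighted by overlap duration; no
  community detection or global clustering statistics are provided.
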