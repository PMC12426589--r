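---
title: "bruvkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bruvkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bruvkit)
```

# What the package models

`bruvkit` implements the analysis chain of a spatially balanced baited
remote underwater video (BRUV) survey: from stratified site selection to
frame-level annotation tables, MaxN-based ecological indices, biomass with
a proxy-length cascade, terrain covariates, spatially lagged GLM ranking
by AICc, and incidence-based rarefaction. A seeded synthetic-seascape
generator with recorded ground truth makes every stage testable without
field data.

The statistical backbone, stage by stage:

* **Site selection** uses generalized random tessellation stratified
  (GRTS) sampling on a discretised cell frame. Eligible cells (depth
  inside the survey envelope) receive hierarchical base-4
  quadrant-recursive addresses whose digits are scrambled with an
  independent random permutation per level; sites are drawn in
  reverse-hierarchical order, which spreads any consecutive run of draws
  across space while keeping within-stratum inclusion probabilities
  equal. A minimum-spacing rule (200 m by default, to keep bait plumes
  independent) is enforced by greedy skip-and-replace: a candidate too
  close to an accepted site is skipped and the next address is used.
* **MaxN** is the maximum, over frames, of the summed per-frame count of
  a taxon in one deployment — the standard conservative abundance metric
  that cannot double-count an individual that lingers in view.
* **Indices.** Richness is the count of taxa with MaxN ≥ 1; relative
  abundance the summed MaxN; Shannon diversity
  $H' = -\sum_i p_i \ln p_i$ in natural-log units with $p_i$ the MaxN
  share. Biomass is $\sum_i a_i \bar L_i^{b_i}\,\mathrm{MaxN}_i$ in
  grams (reported in kg), with $\bar L_i$ a mean length in mm resolved
  through a proxy cascade (below).
* **Terrain covariates.** Slope and aspect by Horn 3×3 finite
  differences (the desktop-GIS default), aggregated over a 200-m buffer;
  aspect uses the circular (vector) mean because arithmetic means are
  wrong at the 0/360° wrap. Ruggedness is the buffer depth range.
  Exposure is the circular distance of mean aspect from due west
  (0–180°, 0 = facing the prevailing westerlies). Remoteness is the
  minimum Euclidean distance to an inhabited-island point.
* **Collinearity screen.** Pairwise Pearson $r$ and VIF
  ($1/(1-R^2)$ from regressing each candidate on the rest); flags at
  $|r| > 0.55$ or VIF > 5, with an optional iterative highest-VIF drop.
* **Model ranking.** Candidate GLM sets (null, single predictors,
  single × habitat interactions, depth + relief, optionally additive
  pairs up to a target count) fitted as Poisson, negative-binomial,
  gamma (log link) or Gaussian; ranked by
  $\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with Akaike weights
  and a within-2-units confidence set. A spatially lagged dependent
  variable (equal-weight mean of the 4 nearest neighbours' responses) is
  a mandatory term by default, to absorb residual spatial
  autocorrelation, which is verified with a permutation Moran's I test.
* **Rarefaction.** Sample-based (incidence) interpolation
  $S(t) = S_{obs} - \sum_k Q_k \binom{T-k}{t}/\binom{T}{t}$, Chao2
  asymptote $S_{obs} + \frac{T-1}{T} Q_1^2 / (2 Q_2)$ (bias-corrected
  form when $Q_2 = 0$), and the standard exponential-approach
  extrapolation beyond $T$, with seeded bootstrap percentile bands.

# The proxy-length cascade

Biomass needs a mean length per taxon per deployment. Stereo measurements
are only accepted for individuals presenting a measurable profile, so the
resolver walks, in order: (1) mean of the taxon's accepted measurements
in *this* deployment; (2) pooled mean over the same sub-habitat across
the study; (3) study-wide species mean; (4) a registry reference length.
Family-level identifications resolve to the study-level family mean, and
mono-camera deployments skip tier 1 (no trusted lengths of their own).
The tier used is tallied per deployment, so the output records how much
of the biomass rests on proxies.

Mean lengths use measurements taken at (or near) the MaxN frame; when no
individual at the MaxN frame is measurable, the simulator and ingest
treat the earliest frame whose count is largest among frames with
measurable individuals as the measurement frame. This tie-break is a
package decision — field protocols describe "the next highest MaxN"
without fixing ties.

# The synthetic seascape: what it emulates, what it does not

`generate_seascape()` builds bathymetry as a radial offshore gradient
(0 m at the archipelago core to ~50 m at the rim, clamped to [0, 60])
plus smoothed Gaussian noise with a controllable length scale (default
amplitude 12 m, length scale 800 m). A second smoothed field splits rock
from soft sediment; depth then splits rock into infralittoral (≤ 15 m)
versus circalittoral and soft bottom into seagrass (≤ 8 m) versus bare
sediments. Inhabited-island points sit in the shallow core.

`species_pool()` cycles six archetypes — reef teleost, wrasse, benthic
elasmobranch, crustacean, a demersal shoaler (sand-eel-like: retained by
the demersal filter but responsible for rare hyperabundant counts via a
zero-inflated mixture, 12% probability of a ×120 hyperabundance
component), and a pelagic shoaler that the demersal filter drops. Counts
are negative binomial on a log link with per-sub-habitat affinity
multipliers and habitat-specific depth slopes; lengths are lognormal
with depth/remoteness/exposure slopes on the log scale; each individual
is measurable with a per-taxon detectability.

`simulate_annotations()` makes the MaxN statistic exact by construction:
the latent MaxN is drawn first, frame counts are binomial thinnings of
it, and one uniformly chosen frame is forced to the maximum. The
recorded latent matrix therefore *is* the ground truth that
`compute_maxn()` must recover, which is the package's strongest internal
oracle.

Deliberate defaults of the stated world: ~280 deployments split
82/99/24/75 across circalittoral rock / infralittoral rock / seagrass /
sediments (realised stratum sizes typical of a temperate archipelago
survey of this design), 60 scanned frames per standardised 60-minute
deployment (frame interval is a parameter — analysis intervals vary
between studies and are rarely reported), SST recorded in situ with a
weak north–south gradient plus noise, and baseline abundances tuned so
per-deployment demersal richness sits in the mid single digits with a
variance-to-mean ratio below 1 and summed-MaxN dispersion far above 1
(shoal-driven). What the generator does **not** emulate: observer
misidentification, bait-plume interaction between neighbouring
deployments, tides/currents, day–night behaviour, and size-selective
detectability. A green test therefore establishes statistical
correctness of the estimators on a faithful generating model, not
robustness to those field effects.

# Numerical and design choices

* **Shannon in nats** (natural log), the community-ecology default;
  stated here rather than configurable.
* **Reverse-hierarchical ordering with per-level digit permutations.**
  On a complete 4^L frame each cell's scrambled address is marginally
  uniform, so inclusion probabilities are exactly equal; on irregular
  frames, cells sharing a max-level address are cycled one-per-pass so
  that consecutive draws stay spread. Address depth is the smallest
  level count giving at least 4× as many quadrants as requested sites.
* **Minimum distance** interacts with ordering by skip-and-replace in
  reverse-hierarchical order — the simplest rule that preserves spatial
  balance; replacements are simply the next address in order.
* **Depth eligibility** is the raster value at the cell centre; tidal
  buffering is assumed folded into the envelope.
* **kNN lag weights are equal (1/k, k = 4)** — the usual default for
  k-nearest-neighbour schemes; distance-decay weighting is a config
  surface, not the default. The lag is recomputed per response from the
  observed response values (a spatially lagged *dependent* variable),
  never from fitted values.
* **Moran's I p-values** come from ≥ 999 value permutations, two-sided
  around the permutation mean; the observed arrangement counts as one
  permutation.
* **Pseudo-R²** is deviance explained, $1 - D_{model}/D_{null}$ with
  $D_{null}$ the intercept-only deviance of the same family; a McFadden
  alternative is available. This matters when comparing published
  tables, whose pseudo-R² definitions are often unstated.
* **k in AICc** counts the NB shape and the gamma dispersion as
  estimated parameters.
* **Candidate-set size.** The anchored recipe (null + singles +
  habitat interactions + depth-and-relief) gives 12 models for five
  predictors; additive pairs can extend the set to a requested size
  (e.g. 17). Published candidate lists frequently live in appendices;
  the recipe is configuration, not a hard-coded list. Interactions are
  full factorial (`a * habitat`), the conventional reading of
  "predictor × habitat".
* **Parameter-recovery checks fit lag-free candidate sets** when the
  generator has no spatial structure: including a lagged response in
  that case biases slopes slightly and is not the matching model.
* **Hexagons are flat-top**, anchored at the point-extent minimum; cell
  area (1 km² default) fixes the side length. Placement affects
  cartography only, but is pinned for reproducibility.
* **Rarefaction bootstrap** defaults to B = 200 percentile bands
  (normal-approximation switchable); the bootstrap assemblage includes
  the estimated undetected species at a common incidence rate.
* **One root seed** expands into per-stage child seeds through a fixed
  splitting rule (`split_seed()`), so any stage can be reproduced alone.
* **Rasters are exchanged as ESRI ASCII grids** and vector layers as
  GeoJSON — text formats readable anywhere, with no binary GIS
  dependency.
* **Zero-mean dispersion, all-zero Shannon rows, flat-buffer aspect**
  are all returned as missing with a warning rather than silently
  dropped or zeroed; all-tied rank tests report p = 1.

# Known limitations

* GRTS here is the equal-probability, discretised-frame variant: no
  unequal inclusion probabilities, legacy sites, or continuous frames,
  and no neighbourhood variance estimator.
* The gamma biomass model requires strictly positive responses; the
  pipeline drops zero-biomass deployments from that model with a
  warning rather than switching family.
* Diversity is computed on whichever MaxN table is supplied; the
  pipeline computes it on the full assemblage while richness, abundance
  and biomass use the demersal subset — which table feeds biomass is a
  documented switch, as conventions differ between studies.
* Exposure's orientation (0 at due west) follows the explicit 0–180°
  range convention; only its ordering matters to the GLMs, but the sign
  convention is worth checking before comparing against other surveys.
* Extrapolation beyond ~2–3× the reference sample size rests entirely
  on the Chao2 lower bound and should be read as such.
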