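---
title: "Methods: climatic niche evolution on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climatic niche evolution on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloniche)
options(phyloniche.verbose = FALSE)
```

`phyloniche` studies how the realized climatic niches of species — in the
motivating application, host-specialized herbivorous insects and their host
plants — are distributed over a time-calibrated phylogeny and over
environmental space. This vignette documents the models, their assumptions,
the tunable parameters, the numerical conventions, and what the synthetic
data generator does and does not emulate.

## From occurrences to traits

Occurrence records (`species`, `lon`, `lat`, WGS84 decimal degrees) are
deduplicated exactly on `(species, lon, lat)`; no spatial thinning is
applied. Climate is sampled at the raster cell containing each point
(nearest cell, no interpolation — bioclimatic climatologies carry no
sub-cell information), with half-open cells so a point on an interior edge
belongs to the higher-index cell. Records outside the grid or hitting
nodata in any variable are dropped with logged counts. Species with fewer
than `min_n = 5` records are removed from both the table and the tree:
below that, a median/min/max niche summary is mostly noise.

Per species and variable we keep the median, minimum and maximum. The
median (even-*n* midpoint convention) is the default trait for all
downstream analyses; min and max are fitted alongside for the signal
analysis. Before any multivariate disparity computation the trait matrix is
column-standardized with the sample (n − 1) standard deviation so every
variable carries equal weight; standardization is enforced (an error, not a
warning) because raw units would let the largest-scaled variable dominate.

Temperatures are used in the units of the input rasters; the package never
rescales (WorldClim versions differ in storing °C versus °C × 10, and
silently guessing would be worse than documenting). BIO17 follows the
standard definition, precipitation of the driest *quarter*.

## Pruning and the phylogenetic covariance

Under Brownian motion the expected covariance of two tips is the depth of
their most recent common ancestor, so `tree_vcv()` is the MRCA-depth
matrix. When the minimum-occurrence filter prunes tips, `prune_tree()`
retains the path between the original root and the retained tips' common
ancestor as a root edge, and `tree_vcv()` adds it to every entry. This
makes pruning commute exactly with taking the covariance submatrix — a
property the test suite checks against a brute-force MRCA oracle. For
mean-centred quantities (disparity, contrasts) the root edge is a common
offset and cancels.

Ultrametricity is checked with a relative tolerance of 1e-6 on the spread
of root-to-tip depths; a non-ultrametric tree is accepted with a warning
and a flag rather than an error, because real dated trees carry rounding
noise from their inference pipeline.

## Pagel's λ by maximum likelihood

For trait vector $x$ on covariance $C$, the λ transform multiplies the
off-diagonal of $C$ by $\lambda \in [0, 1]$. Conditional on λ, the root
state is the GLS mean $\hat\mu = (1^\top C_\lambda^{-1} x)/(1^\top
C_\lambda^{-1} 1)$ and the rate is the ML estimate $\hat\sigma^2 = (x -
\hat\mu 1)^\top C_\lambda^{-1} (x - \hat\mu 1)/n$; the profile
log-likelihood is the Gaussian log-density at these values, computed via
Cholesky factorization. Numerical choices:

* λ is maximized by bounded Brent search on [0, 1] with absolute tolerance
  1e-8, and the boundary values 0 and 1 are evaluated exactly afterwards so
  boundary maxima are never missed. The upper bound is fixed at 1 (not the
  tree-dependent maximum) because the definition used here caps λ at 1.
* The λ = 0 likelihood is computed exactly (diagonal covariance), and the
  LRT statistic $2(\ell_{\hat\lambda} - \ell_0)$ is clipped at 0.
* The test uses the upper tail of χ²₁ even though λ = 0 lies on the
  boundary of the parameter space; this is the conventional choice and is
  conservative (the boundary null halves the effective tail mass), which
  the type-I simulation in the test suite confirms.
* A flat profile (spread below 1e-10 across the interval — a star
  phylogeny, or a two-tip tree where λ is not identifiable) resolves to
  $\hat\lambda = 0$ with an `unidentifiable` flag.
* A zero-variance trait makes the ML rate degenerate; this is an explicit
  error, never a silent fit.

`phytools::phylosig` serves as an independent cross-check in the tests
(agreement in λ̂ and log-likelihood); the implementation itself is
self-contained.

## Disparity through time

Disparity of a species set is the **mean pairwise Euclidean distance**
between standardized trait rows. Note that some standard implementations
use the mean *squared* distance; the `metric` argument
(`"euclidean"`, default, or `"squared"`) makes the convention explicit.

The curve walks internal nodes from the root in order of age (ties broken
by node index, a fixed order). At the age of node $k$, the lineages alive
are the subtrees hanging from the nodes already passed — node $k$ itself
has not yet split, so its whole subclade counts as one lineage. The value
is the mean over lineages of subclade disparity divided by whole-clade
disparity, which forces the root point to 1. Times are reported as
relative age in [0, 1] from root to tips. Identical traits across all tips
(zero total disparity) are an error.

The null envelope simulates multivariate Brownian motion with the rate
matrix estimated from the data by phylogenetically independent contrasts
($\hat\Sigma = U^\top U/(n-1)$ for the $(n-1) \times p$ contrast matrix
$U$). Each simulated matrix is **re-standardized before its curve is
computed** — the observed curve is built from standardized traits, and
weighting simulated datasets any other way would compare curves on
different scales. The envelope is the pointwise median and 2.5%/97.5%
quantiles; the default `n_sim = 1000`.

## Niche equivalency in environmental space

The comparison of an insect with the pooled occurrences of its host plants
("host union"; for a species group, hosts of all member species) follows a
fixed pipeline:

1. **Backgrounds.** Each entity's available environment is every raster
   cell with valid data in all five variables whose centre lies in the
   entity's occurrence bounding rectangle widened by `buffer = 10°` in all
   directions (clipped to the grid and to valid latitudes). The buffer is
   deliberately generous: the background should contain climates the
   entity could plausibly reach.
2. **PCA.** One PCA (centred, unit-scaled) is calibrated per entity pair
   on the two pooled backgrounds, and the first two axes are kept. A
   single global PCA across all pairs was the design alternative;
   per-pair calibration was chosen because backgrounds are per-entity
   rectangles, so the relevant environmental contrast differs between
   pairs.
3. **Occupancy grids.** The score plane is gridded at `R = 100` over the
   range of the pooled background scores (cell-centre evaluation). Each
   cell gets the Gaussian product-kernel density of the entity's
   occurrence scores (`o`) and of its background scores (`e`), each with
   per-axis Silverman normal-reference bandwidths computed from the
   respective point set. Occupancy is `o/e` — dividing occurrence density
   by availability prevents the overlap statistic from rewarding shared
   *backgrounds* rather than shared *preferences* — zeroed where
   `e ≤ 1e-6 · max(e)` (a numeric guard against division blow-ups in
   essentially unavailable climates), then normalized to sum 1.
4. **Overlap and test.** Schoener's $D = 1 - \tfrac12\sum|z_1 - z_2|$.
   The equivalency null pools both entities' occurrence scores and
   re-splits them `reps = 100` times at the original sizes, recomputing
   both occupancy grids each time. Backgrounds, the PCA, the grid extent
   and the availability densities stay frozen across permutations — they
   describe *where the entities live geographically*, which the null
   hypothesis does not permute — while occurrence bandwidths are
   recomputed per split because subset sizes differ. The p-value is
   $(\#\{D_{null} \le D_{obs}\} + 1)/(reps + 1)$, one-sided: low observed
   overlap is the signature of non-equivalence. A `two.sided` alternative
   is available but not the default.

Permuting raw occurrence score rows (rather than densities) is the
exchangeable-unit choice; it makes the test exact under the null in the
sense that the observed D is one more draw from the permutation
distribution.

## The synthetic-data generator

The generator exists so that every stage has inputs with known truth:

* `simulate_yule_tree()` — forward pure-birth simulation conditioned on
  the tip count, with the present placed one further exponential waiting
  time after the last speciation; ultrametric by construction and a pure
  function of (parameters, seed).
* `simulate_lambda_bm()` — traits drawn from the Gaussian with tip
  covariance given by the λ-transformed tree covariance (Kronecker with
  the rate matrix).
* `make_synthetic_rasters()` — five variables as linear latitude or
  longitude gradients plus (optionally correlated) Gaussian cell noise.
  The default grid is 120 × 60 cells at 0.5° (longitude −30…30, latitude
  20…50), with poleward-declining temperatures (e.g. BIO6 from 7 to
  −20 °C across the latitude span) and longitudinally varying
  precipitation — magnitudes picked to resemble Northern-Hemisphere
  continental climatologies at desk scale.
* `sample_occurrences()` — cells drawn with probability proportional to
  Gaussian suitability around a niche optimum, points uniform within the
  cell; truncations are hard zeros.
* `make_pair_scenario()` — a host sampled from a broad niche (temperature
  breadths 4 °C, precipitation breadth 12 mm around the mid-latitude
  climate) and an insect sampled either from the identical niche
  ("equivalent") or from the niche truncated at its own BIO5 optimum
  ("truncated", i.e. the colder half), 50 occurrences per side.

These defaults are the package's working scale: large enough that the
equivalency test has clear power on truncated niches and holds its size on
equivalent ones (both measured in the acceptance tests at 100–200 scenario
replicates), small enough that the entire suite runs in minutes. What the
generator does **not** emulate: spatial autocorrelation of occurrences
beyond climate suitability, sampling bias, dispersal limitation, biotic
interactions, or disagreement between an entity's fundamental and realized
niche other than the hard truncation. Passing tests therefore demonstrate
the statistical machinery is correct and calibrated under clean
conditions, not that real occurrence data meet those conditions.

## Problem sizes and reproducibility

The test suite exercises λ recovery on 100 replicate 200-tip Yule trees
per true λ ∈ {0, 0.5, 1} (mean λ̂ within ±0.07 of truth), LRT size on 500
no-signal replicates (≤ 8% rejections at α = 0.05), DTT envelope coverage
over 50 Brownian replicates at 200 simulations each, and equivalency
size/power over 200/100 generated scenarios at 100 permutations each.
These sizes are the package's chosen working scale for routine
verification; all are driven by fixed seeds. Every stochastic function
takes a `seed` argument, restores the caller's RNG state, and is
byte-reproducible: identical seeds give identical trees, tables, grids and
JSON reports.

## File formats and orchestration

Trees are plain Newick (support annotations ignored); occurrences,
associations and species groups are headered CSV; rasters are
single-band ESRI ASCII grids in geographic coordinates (GeoTIFF input is
refused with a pointer to conversion; no reprojection is attempted);
analysis outputs are CSV and JSON. `run_config()` carries paths or
in-memory objects plus all parameters; `run_signal()`, `run_dtt()` and
`run_equivalency_batch()` are the end-to-end entry points (the batch
reports entities with fewer than `min_n` valid occurrences as NA rows and
records per-entity failures without aborting the batch). These functions
are the intended scripting interface; no shell executable is shipped.

## Known limitations

* λ is fitted per variable; a joint multivariate λ is out of scope.
* The DTT envelope is descriptive (no integrated disparity index test).
* Niche comparisons use the first two PCA axes only; strong structure in
  higher axes is invisible to the test.
* County-centroid and other location-quality heuristics are not
  implemented; input occurrence curation is the user's responsibility.
* Background rectangles ignore the antimeridian; data spanning ±180°
  longitude are not supported.
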