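---
title: "Phylogenetic regionalization under scenario change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic regionalization under scenario change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaregions)
```

## What the package computes

`betaregions` delineates *floristic regions* — clusters of equal-area grid
cells with similar plant assemblages — from presence/absence communities
and a phylogeny, and then asks how those regions, their boundaries, and
the drivers of boundary position change between a present-day community
and scenario futures.

The core statistic is pairwise Simpson dissimilarity between two cells,

$$\beta_{sim} = 1 - \frac{a}{\min(b, c) + a},$$

where $a$ is the quantity shared by the two cells and $b$, $c$ are the
quantities unique to each.  At the taxonomic level $a$, $b$, $c$ are
species counts; at the phylogenetic level they are summed branch lengths
over the cells' *branch incidences* (a branch is incident to a cell if at
least one of its descendant tips occurs there).  $\beta_{sim}$ captures
turnover only and is insensitive to richness differences; the Sorensen
index $(b+c)/(2a+b+c)$, which is richness-sensitive, is carried throughout
as a robustness alternative.  Two conventions are worth stating because
the dissimilarity formula is usually written for species counts:

* phylogenetic $a,b,c$ are **branch-length sums**, following the
  convention of branch-based phylobeta software;
* a root edge, if present, is excluded from the incidence — it subtends
  every tip, is shared by all non-empty cells, and has arbitrary length.

Pairwise matrices are computed by sparse matrix products ($a_{ij}$ is a
weighted cross-product of incidence rows) but are required — and tested —
to agree exactly with a literal set/branch enumeration.

## Regionalization

Eight hierarchical linkage algorithms (UPGMA, single, complete, ward.D,
ward.D2, WPGMA, WPGMC, UPGMC) are scored by the cophenetic correlation
between input dissimilarities and dendrogram distances; the least
distorting method wins, ties breaking by the fixed list order.  A method
whose dendrogram degenerates (all cophenetic distances equal, which single
linkage produces when zero-dissimilarity chains percolate through the
data) carries no information and is scored `NA`, so it cannot be
selected; constant *input* dissimilarities are an error.

The number of clusters is chosen by **explained dissimilarity**: the sum
of dissimilarities over cell pairs in different clusters divided by the
sum over all pairs, each unordered pair counted once (sums, not means,
matching the "sum of between-cluster dissimilarity / total" reading).
Realms are the smallest cut explaining 85% and regions the smallest
explaining 90%; both are cuts of one dendrogram, so regions refine realms
by construction.  Cuts are defined by *merge order* (undoing the last
merges first), which coincides with height cuts for monotone linkages and
resolves ties and centroid/median inversions deterministically.  The
explained curve is computed in $O(n^2)$ by accumulating, along the merge
sequence, the cross-cluster sum each merge internalizes; it is 0 at
$k = 1$, 1 at $k = n$, and non-decreasing because every accumulated term
is non-negative.

NMDS ordination (`nmds_embed`, monotone-regression via `vegan::monoMDS`)
is presentation-only and never feeds labels.

## Boundaries

Two operators are kept deliberately:

* `adjacency_boundary` is the *definition*: a cell is boundary iff at
  least one queen (8-neighbor) adjacent cell holds a different label.
* `buffer_sum_boundary` is the *headline procedure*: each region's cells
  are binarized, dilated by a Euclidean disk of
  `ceiling(buffer_km / cell_size_km)` cells (200 km → radius 2 at the
  100-km grain), and the layers summed; cells with a sum above one are
  boundary.  Reproduced literally, this yields a band roughly two buffers
  wide centred on each interface rather than a line — the band width is
  governed by `buffer_km`.  For radius ≥ 2 the adjacency boundary is
  contained in the buffer-sum boundary (dilations of adjacent regions
  always overlap on both flanking cells); the tests assert this subset
  relation on random labelings.

`distance_to_boundary` is an exact Euclidean distance transform on cell
centroids in km (brute force over boundary cells; grids here are small).

## Change statistics

**Homogenization / differentiation.**  For each present-day region, all
within-region pairwise dissimilarities are collected from the present and
from a future matrix and contrasted with a two-sided pooled-variance
t-test and Cohen's $d$ = (mean future − mean present) / pooled SD:
negative $d$ is homogenization, positive is differentiation.  The pooled
t-test (rather than Welch) is used so the t statistic and $d$ share one
variance model.  Confidence intervals come from a percentile bootstrap
that resamples *pairs* (dissimilarity values), not cells — the statistic
is defined on the pair distribution.  Pairs sharing a cell are not
independent, so this CI is approximate; that caveat is inherited from the
analysis design this package follows, not introduced by it.

**Partition congruence.**  The v-measure on the cell-count contingency
table (equal-area cells make counts proportional to areas):
$h = 1 - H(A\mid B)/H(A)$, $c = 1 - H(B\mid A)/H(B)$,
$v = (1+B)hc/(Bh + c)$, natural-log entropies (the score is
base-invariant), with $h$ (resp. $c$) defined as 1 when $H(A)$ (resp.
$H(B)$) is zero.  `B = 2` by default so completeness outweighs
homogeneity, satisfying the "B > 1" requirement; the exact value was not
stated in the source analysis and is configurable.

**Spatially corrected correlation.**  `modified_ttest` implements
Dutilleul's correction: Pearson's $r$ is unchanged, but the effective
sample size is
$\hat M = \mathrm{tr}(B\Sigma_x B)\,\mathrm{tr}(B\Sigma_y B) /
\mathrm{tr}(B\Sigma_x B \Sigma_y B)$
with $B$ the centering matrix and $\Sigma_x, \Sigma_y$ correlation
matrices assembled from Moran-type correlograms over `n_classes = 10`
equal-width distance classes (a documented tuning knob); the test is
$t = r\sqrt{(\hat M - 2)/(1 - r^2)}$ on $\hat M - 2$ df.  The double
centering is done in $O(n^2)$.  Calibration is verified by simulation
(acceptance criterion 8): on independent Gaussian fields with effective
correlation range ~5 cells on a 20×20 grid, the corrected test rejects at
the nominal 5% rate while naive Pearson rejects an order of magnitude too
often.

## Boundary determinants

Predictors per cell, mirroring the circularity-avoiding design of using
climate *heterogeneity* rather than raw climate: coefficients of
variation of the four climate fields over the focal cell plus its queen
neighbors (zero-mean neighborhoods are masked); mean absolute elevation
difference to neighbors (orographic barriers); the per-neighbor standard
deviation across time of distances to drifting neighbor positions,
averaged over neighbors (tectonic separation variability); and past
climate velocity as given.  All are standardized to mean 0, variance 1;
collinearity is checked with VIFs (warn at ≥ 2, never abort).

The response is binary: boundary cells are YES, cells inside the 200-km
buffer but off the boundary are NO, everything else is excluded.  The
fit is an **autologistic GLM**: logistic regression on the standardized
predictors plus a spatial autocovariate — the row-standardized mean of
neighbor responses within 283 km (binary within-radius weights).  This is
the package's one intentional methodological substitution: the source
design fits a hierarchical spatial-random-effect binomial model, whose
random-effect covariance family is unspecified; the autologistic form
captures the same spatial-confounding control with a fully specifiable
fixed effect (and the original predictor set itself lists spatial
autocovariates).  Coefficient t-values are converted to Fisher's
$z = \operatorname{atanh}\!\big(\operatorname{sign}(t)\sqrt{t^2/(t^2+df)}\big)$,
and 95% intervals come from 200 nonparametric bootstrap replicates over
cells; a predictor is significant when its $z$ interval excludes zero.
Quasi-separation — common here, because the autocovariate of a coherent
boundary band is nearly deterministic — triggers a small-ridge penalized
IRLS fallback with a warning.

## The synthetic world

The generator replaces downloads with a stated world:

* **Phylogeny**: pure-birth (Yule) ultrametric tree; a death rate adds
  nothing testable here.
* **Landscape**: climate fields are Gaussian-filtered white noise
  (smoothness = filter sd in cells, default 3; `Inf` gives constant
  fields).  Elevation additionally carries an axis-aligned Gaussian ridge
  of sd 1 cell and amplitude 2000 m: at a 100-km grain an orographic
  barrier spans about one cell, and a sharp ridge keeps its relief inside
  the boundary band where determinant-recovery tests need it.  Drift
  trajectories are AR(1)-velocity random walks from cell centroids
  (66 timesteps read as 1-Myr steps; velocity scale of tens of km per
  step, the order of plate motion).
* **Ranges**: the grid is split into `n_regions` contiguous rectangular
  blocks (the planted truth; straight boundaries simplify geometric
  assertions).  The tree is cut into `n_regions` clades and clades are
  mapped to regions; each species keeps its clade's region with
  probability `clade_fidelity`, else moves to a uniform random region.  A
  literal "inherit with probability f" pass down the tree degenerates to
  a single region at f = 1, so the clade-cut construction is used: it
  preserves the planted-signal property that at fidelity 1 with no
  spillover, no species (and no branch below the root) crosses a region
  boundary, making every cross-region $\beta_{sim}$ exactly 1.
* **Occupancy** defaults to 0.75 of the home region per species.  The
  range-size distribution of the emulated data is unknown, so this is a
  free parameter; the default expresses the premise of floristic
  regionalization — cells of a region share most of their flora.
  Markedly smaller values plant genuine *sub*-regional structure (at 0.5
  every species covers exactly half its region and regions split into
  disjoint half-floras), which is a different stated world than the one
  the planted-recovery tests describe.
* **Spillover** defaults to 0 (clean planted signal); a positive value
  lets species claim a few cells just across their region edge, mimicking
  transition zones.
* **Scenarios**: `contract` peels range-edge cells (farthest from the
  patch centroid first), `expand` claims adjacent cells ignoring region
  borders, `shift` translates each range in a random direction.  One
  behavior deserves emphasis: moderate expansion *differentiates*
  present-day regions (foreign species reach margin cells of otherwise
  near-identical regions, raising within-region turnover); homogenization
  emerges only when expanded ranges approach the landscape extent
  (magnitude such that range × (1 + magnitude) is of the order of the
  grid).  The directional tests therefore use large magnitudes for the
  homogenization arm, matching the hypothesis that ranges expand "to
  colonize new suitable areas" at biome scale.

What the generator does **not** emulate: realistic climate-envelope
responses, species-specific dispersal kinetics, spherical geometry, ocean
masks, or empirical range-size and richness distributions.  A green
planted-recovery test establishes that the pipeline recovers structure of
the kind it is designed to detect — not that real floristic regions are
recoverable at any particular fidelity.

## Numerical and interface choices

* All randomness descends from one integer seed through named
  per-operation substreams; reruns are bit-identical.
* Cell ids are 0-based row-major; all distances are km between centroids
  (the synthetic grid is already equal-area).
* Empty cells are dropped before dissimilarity (pairwise $\beta$ is
  undefined for empty assemblages) and tracked by id for re-insertion in
  maps.
* Dissimilarity matrices are stored dense (the contract is symmetric
  storage, not layout); cells counts here stay well below the point where
  that matters.
* Degenerate guards: `min(b,c)+a = 0` pairs, constant dissimilarities,
  empty boundaries, single-class responses, and boundary bands that fill
  their own buffer all raise typed errors rather than propagating NaNs.
* Config files are JSON with strict schema validation (unknown or missing
  keys are rejected); defaults mirror the printed settings of the
  emulated analysis: thresholds 0.85/0.90, 200-km buffers, 283-km model
  neighborhood, 1000 and 200 bootstrap replicates.

## Known limitations

* The bootstrap CI for Cohen's $d$ treats dissimilarity pairs as
  exchangeable; pair dependence through shared cells makes it
  approximate.
* The autologistic model is a contract-level stand-in for a hierarchical
  spatial model, not a replication of one; effect sizes are comparable in
  sign and significance logic, not numerically.
* The buffer-sum boundary inherits the band-not-line character of the
  literal rasterize-buffer-sum procedure.
* `neighborhood_cv` is undefined for zero-mean neighborhoods; affected
  cells are masked out of the model rather than imputed.
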