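# betaregions

Phylogenetic bioregionalization and boundary dynamics across climate
scenarios, for biogeographers and macroecologists who want the full
pipeline — communities → phylogenetic β-diversity → floristic
realms/regions → boundaries → change statistics → boundary determinants —
as tested, reusable, fully seeded code that runs on synthetic worlds
without any external downloads.

## The statistics at the core

Between two grid cells with shared quantity *a* and unique quantities
*b*, *c*:

- Simpson dissimilarity (turnover-only): `βsim = 1 − a / (min(b, c) + a)`
- Sorensen dissimilarity (richness-sensitive): `βsor = (b + c) / (2a + b + c)`

Taxonomically, *a*, *b*, *c* are species counts; phylogenetically they
are summed branch lengths over the cells' branch incidences on a shared
tree.  A dissimilarity matrix is clustered with the least-distorting of
eight linkage methods (chosen by cophenetic correlation; UPGMA in
practice), and cut at the smallest number of clusters explaining 85%
(realms) and 90% (regions) of total dissimilarity.  Region boundaries are
extracted with the rasterize–buffer(200 km)–sum procedure; scenario
change is quantified by per-region Cohen's *d* with bootstrap intervals
(negative = homogenization), v-measure partition congruence (B = 2), and
Dutilleul's spatially corrected correlation of distance-to-boundary
fields; boundary determinants are fit with an autologistic GLM (283-km
autocovariate neighborhood) summarized as Fisher's *z* with 200 bootstrap
replicates.  Details and design rationale: `vignettes/methods.Rmd`.

## Worked example

```r
library(betaregions)

tree  <- generate_phylogeny(100, seed = 42)
land  <- generate_landscape(20, 20, cell_size_km = 100, smoothness = 3, seed = 42)
world <- generate_ranges(tree, land, n_regions = 4, n_species = 80,
                         clade_fidelity = 0.9, seed = 42)
world <- apply_scenario(world, "expand", magnitude = 4, seed = 43,
                        label = "T4_SSP585")

present <- drop_empty(world$present)$community
d_now   <- pairwise_beta(present, world$phylogeny, metric = "simpson")
reg     <- regionalize(d_now)         # 0.85 / 0.90 thresholds
reg
#> <br_regionalization> UPGMA linkage; 4 realms (0.977 expl.), 4 regions (0.977 expl.) over 396 cells

v_measure(reg$labels_region, world$truth_labels[reg$cell_ids + 1])
#> <br_congruence> v = 1.0000 (h = 1.0000, c = 1.0000, B = 2)
```

UPGMA wins linkage selection (cophenetic correlation 0.931 against 0.812
for single linkage), the four planted regions are recovered exactly
(v-measure 1), and at this clean fidelity the 85% and 90% cuts coincide.
Contrasting within-region dissimilarity against the expansion future:

```r
future <- drop_empty(world$futures$T4_SSP585)$community
d_fut  <- pairwise_beta(future, world$phylogeny, metric = "simpson")
shared <- intersect(d_now$cell_ids, d_fut$cell_ids)
lab    <- reg$labels_region[match(shared, reg$cell_ids)]
within_region_beta_change(lab,
                          subset_dissim(d_now, shared),
                          subset_dissim(d_fut, shared),
                          n_boot = 1000, seed = 42)
#> <br_effects> 4 regions; global d = -0.6931 (p = 0); mean region d = -0.6972
```

Every region's Cohen's *d* is negative (−0.40 to −0.92, all 95% CIs
below zero): landscape-scale range expansion homogenizes the floras of
the present-day regions, as hypothesized.  Boundaries and their
determinants:

```r
bnd <- distance_to_boundary(
  buffer_sum_boundary(reg$labels_region, world$grid, cell_ids = reg$cell_ids))
bnd
#> <br_boundary> 140 boundary cells of 400 (region level), distances filled

fit <- fit_boundary_model(boundary_response(bnd)$response,
                          build_predictors(land), world$grid, seed = 42)
fit$coefficients[fit$coefficients$term == "altitude_var", c("term", "fisher_z", "z_ci_low", "z_ci_high")]
#>           term fisher_z z_ci_low z_ci_high
#> 5 altitude_var   0.1552   0.0961    0.3376
```

Altitude variation has a significantly positive Fisher's *z* (CI
excluding zero): one planted region interface runs along the landscape's
mountain ridge, and the model attributes boundary position to that
orographic barrier over the six competing predictors.

## Pipeline in one call

```r
run <- run_pipeline(default_config(seed = 1), "out/")   # or the CLI below
cmp <- compare_runs(run, a = "present", b = "T1_SSP126")
```

A CLI wrapper with subcommands (`synth`, `beta`, `regionalize`,
`boundaries`, `change`, `determinants`, `run`, `compare`) is installed at
`inst/cli/betaregions.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/betaregions.R", package="betaregions"))')" \
  run --out out/
```

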