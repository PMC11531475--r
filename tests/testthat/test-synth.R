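test_that("generate_phylogeny yields deterministic ultrametric Yule trees", {
  t2 <- generate_phylogeny(2, seed = 1)
  depths <- ape::node.depth.edgelength(t2)
  expect_equal(depths[1], depths[2])

  tr <- generate_phylogeny(150, seed = 7)
  expect_equal(length(tr$tip.label), 150L)
  expect_equal(nrow(tr$edge), 298L)            # 2n - 2 for rooted binary
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_false(anyDuplicated(tr$tip.label) > 0)

  expect_identical(ape::write.tree(generate_phylogeny(150, 7)),
                   ape::write.tree(generate_phylogeny(150, 7)))
  expect_error(generate_phylogeny(1, 1), "invalid-argument")
})

test_that("generate_landscape covers the grid, smooths, and reproduces", {
  land <- generate_landscape(30, 30, 100, smoothness = 3, seed = 3,
                             n_timesteps = 5)
  for (f in c("elevation", "temp_mean", "temp_seasonality", "precip_mean",
              "precip_seasonality", "past_velocity")) {
    expect_length(land[[f]], 900)
  }
  expect_true(all(land$temp_seasonality >= 0))
  expect_true(all(land$past_velocity >= 0))
  expect_equal(dim(land$drift), c(900, 5, 2))

  flat <- generate_landscape(10, 10, 100, smoothness = Inf, seed = 3,
                             n_timesteps = 2)
  expect_equal(var(flat$temp_mean), 0)
  expect_equal(var(flat$precip_mean), 0)

  l2 <- generate_landscape(30, 30, 100, smoothness = 3, seed = 3,
                           n_timesteps = 5)
  expect_identical(land$elevation, l2$elevation)
  expect_identical(land$drift, l2$drift)
  expect_error(generate_landscape(2, 10, 100, 3, 1), "invalid-argument")
})

test_that("the elevation ridge sits on its declared crest column", {
  land <- generate_landscape(21, 15, 100, smoothness = 4, seed = 5,
                             n_timesteps = 2)
  col <- (seq_len(land$grid$n_cells) - 1L) %% 21
  col_means <- tapply(land$elevation, col, mean)
  expect_equal(unname(which.max(col_means)) - 1L, land$ridge_col)
})

test_that("generate_ranges plants regions with the requested structure", {
  tr <- generate_phylogeny(60, seed = 2)
  land <- generate_landscape(12, 12, 100, smoothness = 3, seed = 2,
                             n_timesteps = 2)
  sc <- generate_ranges(tr, land, n_regions = 3, n_species = 40,
                        clade_fidelity = 1, seed = 2)
  expect_setequal(unique(sc$truth_labels), 1:3)
  expect_length(sc$truth_labels, 144)
  expect_equal(sort(sc$present$species), sc$present$species)

  # fidelity 1, spillover 0: no species occupies cells of two regions,
  # so every cross-region pair shares nothing (taxonomic beta_sim = 1)
  inc <- as.matrix(sc$present$incidence)
  regions_per_species <- apply(inc, 2, function(v) {
    length(unique(sc$truth_labels[v > 0]))
  })
  expect_true(all(regions_per_species == 1))
  # and every region holds at least one species
  expect_setequal(unique(sc$truth_labels[rowSums(inc) > 0]), 1:3)

  sc2 <- generate_ranges(tr, land, 3, 40, clade_fidelity = 1, seed = 2)
  expect_identical(as.matrix(sc$present$incidence),
                   as.matrix(sc2$present$incidence))

  expect_error(generate_ranges(tr, land, 200, 40, seed = 1),
               "invalid-argument")
  expect_error(generate_ranges(tr, land, 3, 100, seed = 1),
               "invalid-argument")
})

test_that("clade_fidelity controls the planted phylogenetic signal", {
  tr <- generate_phylogeny(80, seed = 4)
  land <- generate_landscape(14, 14, 100, smoothness = 3, seed = 4,
                             n_timesteps = 2)
  between_phylo <- function(fid) {
    sc <- generate_ranges(tr, land, 2, 60, occupancy = 0.5,
                          clade_fidelity = fid, seed = 4)
    de <- drop_empty(sc$present)
    d <- pairwise_beta(de$community, sc$phylogeny, "simpson")
    dt <- pairwise_beta(de$community, NULL, "simpson")
    truth <- sc$truth_labels[de$community$cell_ids + 1L]
    cross <- outer(truth, truth, "!=") & upper.tri(d$values)
    list(phylo = mean(d$values[cross]), tax = mean(dt$values[cross]))
  }
  b1 <- between_phylo(1)
  b0 <- between_phylo(0)
  # no spillover: species are never shared across regions at any fidelity
  expect_equal(b1$tax, 1)
  expect_equal(b0$tax, 1)
  # fidelity 1 plants deep turnover (regions = clades, no shared branches
  # below the root); fidelity 0 scatters clades, so regions still share
  # much of the tree and phylogenetic turnover drops well below 1
  expect_gt(b1$phylo, 0.95)
  expect_lt(b0$phylo, b1$phylo - 0.2)
})

test_that("apply_scenario respects identity, monotonicity and errors", {
  tr <- generate_phylogeny(40, seed = 9)
  land <- generate_landscape(10, 10, 100, smoothness = 3, seed = 9,
                             n_timesteps = 2)
  sc <- generate_ranges(tr, land, 2, 20, occupancy = 0.4, seed = 9)
  p_inc <- as.matrix(sc$present$incidence)

  s0 <- apply_scenario(sc, "contract", 0, seed = 1, label = "null")
  expect_equal(as.matrix(s0$futures$null$incidence), p_inc)

  s_con <- apply_scenario(sc, "contract", 0.5, seed = 1, label = "c")
  expect_true(all(Matrix::colSums(s_con$futures$c$incidence) <=
                    colSums(p_inc)))

  s_exp <- apply_scenario(sc, "expand", 0.5, seed = 1, label = "e")
  e_inc <- as.matrix(s_exp$futures$e$incidence)
  expect_true(all(e_inc[p_inc > 0] > 0))       # expansion is a superset
  expect_true(all(colSums(e_inc) >= colSums(p_inc)))

  s_sh <- apply_scenario(sc, "shift", 2, seed = 1, label = "s")
  expect_equal(s_sh$futures$s$species, sc$present$species)

  expect_error(apply_scenario(sc, "contract", 1, seed = 1),
               "degenerate-scenario")
  expect_error(apply_scenario(sc, "expand", -1, seed = 1),
               "invalid-argument")
})
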