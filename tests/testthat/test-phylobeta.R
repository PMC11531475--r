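test_that("beta_pair matches the closed forms and guards empty pairs", {
  expect_equal(beta_pair(5, 0, 0, "simpson"), 0)
  expect_equal(beta_pair(0, 4, 2, "simpson"), 1)
  expect_equal(beta_pair(3, 1, 2, "simpson"), 0.25)
  expect_equal(beta_pair(3, 1, 2, "sorensen"), 1 / 3)
  expect_error(beta_pair(0, 0, 0, "simpson"), "undefined-pair")
  expect_error(beta_pair(-1, 0, 1, "simpson"), "invalid-argument")
})

test_that("branch_incidence enumerates descendants correctly", {
  tree <- toy_tree()
  cm <- toy_community(list("A", c("A", "B", "C")))
  bi <- branch_incidence(cm, tree)
  # cell {A}: the A terminal plus the (A,B) stem, total length 2
  expect_equal(sum(bi$lengths[bi$incidence[1, ]]), 2)
  # cell with all tips: every branch marked
  expect_true(all(bi$incidence[2, ]))
  expect_equal(sum(bi$lengths[bi$incidence[2, ]]), sum(tree$edge.length))

  bad <- toy_community(list(c("A", "Z")))
  expect_error(branch_incidence(bad, tree), "unmatched-taxon.*Z")
})

test_that("pairwise_beta reproduces hand-enumerated phylo cases", {
  tree <- toy_tree()
  # {A} vs {B}: shared stem a = 1, unique terminals b = c = 1
  cm <- toy_community(list("A", "B"))
  d <- pairwise_beta(cm, tree, "simpson")
  expect_equal(d$values[1, 2], 0.5)
  expect_equal(d$level, "phylogenetic")

  # identical assemblages -> 0
  cm2 <- toy_community(list(c("A", "C"), c("A", "C")))
  expect_equal(pairwise_beta(cm2, tree, "simpson")$values[1, 2], 0)

  expect_error(pairwise_beta(toy_community(list("A")), tree),
               "invalid-argument")
  g <- make_grid(2, 1, 100)
  holed <- build_community(data.frame(cell_id = 0, species = "A"), g,
                           c("A", "B"))
  expect_error(pairwise_beta(holed, tree), "undefined-pair")
})

test_that("unit-branch star tree collapses phylogenetic to taxonomic beta", {
  set.seed(21)
  n_sp <- 7
  star <- ape::stree(n_sp, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- sprintf("sp%04d", seq_len(n_sp))
  for (metric in c("simpson", "sorensen")) {
    cm <- random_community(10, n_sp)
    tax <- pairwise_beta(cm, NULL, metric)
    phy <- pairwise_beta(cm, star, metric)
    expect_lt(max(abs(tax$values - phy$values)), 1e-12)
  }
})

test_that("sparse-product beta equals the literal enumeration oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n_sp <- sample(4:12, 1)
    n_cells <- sample(4:12, 1)
    cm <- random_community(n_cells, n_sp)
    tree <- ape::rtree(n_sp, tip.label = sprintf("sp%04d", seq_len(n_sp)))
    for (metric in c("simpson", "sorensen")) {
      expect_equal(unname(pairwise_beta(cm, NULL, metric)$values),
                   oracle_beta_tax(cm$incidence, metric))
      expect_equal(unname(pairwise_beta(cm, tree, metric)$values),
                   oracle_beta_phylo(cm$incidence, tree, metric))
    }
  }
})

test_that("simpson never exceeds sorensen; shared species never raise simpson", {
  set.seed(41)
  for (rep in 1:5) {
    cm <- random_community(10, 8)
    dsim <- pairwise_beta(cm, NULL, "simpson")$values
    dsor <- pairwise_beta(cm, NULL, "sorensen")$values
    expect_true(all(dsim <= dsor + 1e-12))

    # add a species present in every cell: simpson must not increase
    inc2 <- cbind(as.matrix(cm$incidence), everywhere = 1)
    pres <- which(inc2 > 0, arr.ind = TRUE)
    cm2 <- build_community(
      data.frame(cell_id = pres[, 1] - 1L,
                 species = colnames(inc2)[pres[, 2]]),
      make_grid(10, 1, 100), colnames(inc2))
    dsim2 <- pairwise_beta(cm2, NULL, "simpson")$values
    expect_true(all(dsim2 <= dsim + 1e-12))
  }
})

test_that("mean_dissimilarity averages aligned matrices and rejects others", {
  set.seed(51)
  cm <- random_community(6, 5)
  d1 <- pairwise_beta(cm, NULL, "simpson")
  expect_equal(mean_dissimilarity(list(d1))$values, d1$values)
  expect_equal(mean_dissimilarity(list(d1, d1))$values, d1$values)

  v2 <- d1$values; v2[1, 2] <- v2[2, 1] <- 0.4
  d2 <- dissim_matrix(v2, d1$cell_ids, d1$metric, d1$level)
  v_avg <- mean_dissimilarity(list(d1, d2))$values[1, 2]
  expect_equal(v_avg, (d1$values[1, 2] + 0.4) / 2)

  d_other <- dissim_matrix(d1$values, d1$cell_ids, "sorensen", d1$level)
  expect_error(mean_dissimilarity(list(d1, d_other)), "alignment")
})

test_that("dissimilarity CSV round-trips", {
  set.seed(61)
  cm <- random_community(7, 5)
  d <- pairwise_beta(cm, NULL, "simpson")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dissim_csv(d, path)
  back <- read_dissim_csv(path, metric = "simpson", level = "taxonomic")
  expect_equal(back$values, d$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$cell_ids, d$cell_ids)
})
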