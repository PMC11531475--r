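# an ultrametric distance structure: cophenetic distances of an average-
# linkage dendrogram built from random points
ultrametric_dissim <- function(n, seed = 1) {
  set.seed(seed)
  pts <- matrix(runif(n * 3), n, 3)
  hc <- hclust(dist(pts), "average")
  cc <- as.matrix(cophenetic(hc))
  dissim_matrix(cc / max(cc), seq_len(n) - 1L, "simpson", "taxonomic")
}

# planted block-diagonal dissimilarity: within `within`, between `between`
planted_dissim <- function(sizes, within = 0.05, between = 0.95) {
  lab <- rep(seq_along(sizes), sizes)
  v <- ifelse(outer(lab, lab, "=="), within, between)
  diag(v) <- 0
  list(d = dissim_matrix(v, seq_along(lab) - 1L, "simpson", "taxonomic"),
       labels = lab)
}

test_that("UPGMA is a fixed point on ultrametric distances and is selected", {
  d <- ultrametric_dissim(25, seed = 2)
  expect_equal(cophenetic_correlation(d, "UPGMA"), 1.0, tolerance = 1e-10)
  sel <- select_linkage(d)
  expect_equal(sel$method, "UPGMA")
  expect_length(sel$scores, 8)
  expect_named(sel$scores, linkage_methods())
  expect_equal(unname(sel$scores["UPGMA"]), 1.0, tolerance = 1e-10)
})

test_that("cophenetic correlation errors on constant dissimilarities", {
  v <- matrix(1, 3, 3); diag(v) <- 0
  d <- dissim_matrix(v, 0:2, "simpson", "taxonomic")
  expect_error(cophenetic_correlation(d, "UPGMA"), "undefined-correlation")
  expect_error(cophenetic_correlation(d, "nope"), "invalid-argument")
})

test_that("explained_dissimilarity matches hand sums and the brute oracle", {
  pl <- planted_dissim(c(2, 2), within = 0, between = 1)
  expect_equal(explained_dissimilarity(pl$d, pl$labels), 1.0)
  expect_equal(explained_dissimilarity(pl$d, rep(1, 4)), 0)
  expect_equal(explained_dissimilarity(pl$d, 1:4), 1)

  set.seed(5)
  v <- matrix(runif(49, 0.1, 0.9), 7, 7); v <- (v + t(v)) / 2; diag(v) <- 0
  d <- dissim_matrix(v, 0:6, "simpson", "taxonomic")
  labels <- sample(1:3, 7, replace = TRUE)
  expect_equal(explained_dissimilarity(d, labels),
               oracle_explained(d$values, labels))
  expect_error(explained_dissimilarity(d, 1:3), "invalid-argument")
})

test_that("select_k finds the smallest sufficient cut", {
  pl <- planted_dissim(c(4, 4, 4))
  hc <- hclust(as.dist(pl$d$values), "average")
  res <- select_k(hc, pl$d, 0.90)
  expect_equal(res$k, 3L)
  expect_equal(v_measure(res$labels, pl$labels)$v, 1.0)

  # explained curve: 0 at k=1, 1 at k=n, non-decreasing, oracle-checked
  expect_equal(res$curve[1], 0)
  expect_equal(res$curve[length(pl$labels)], 1)
  expect_true(all(diff(res$curve) >= -1e-12))
  for (k in c(2, 5)) {
    lab_k <- betaregions:::.cut_merge_order(hc, k)
    expect_equal(res$curve[k], oracle_explained(pl$d$values, lab_k))
  }

  expect_lte(select_k(hc, pl$d, 0.85)$k, select_k(hc, pl$d, 0.90)$k)
  expect_error(select_k(hc, pl$d, 1.2), "invalid-argument")
})

test_that("regionalize nests cuts, is deterministic, and recovers plants", {
  pl <- planted_dissim(c(5, 5, 6), within = 0.08, between = 0.9)
  r1 <- regionalize(pl$d)
  r2 <- regionalize(pl$d)
  expect_identical(r1$labels_region, r2$labels_region)
  expect_lte(r1$k_realm, r1$k_region)
  # regions refine realms: each region sits inside one realm
  expect_true(all(tapply(r1$labels_realm, r1$labels_region,
                         function(v) length(unique(v))) == 1))
  expect_equal(v_measure(r1$labels_region, pl$labels)$v, 1.0)
  expect_error(regionalize(pl$d, 0.9, 0.85), "invalid-argument")
  r3 <- regionalize(pl$d, linkage_override = "complete")
  expect_equal(r3$linkage_method, "complete")
})

test_that("cluster relabeling leaves boundaries and congruence unchanged", {
  pl <- planted_dissim(c(4, 5, 3), within = 0.1, between = 0.8)
  r <- regionalize(pl$d)
  perm <- sample(max(r$labels_region))
  relab <- perm[r$labels_region]
  expect_equal(v_measure(r$labels_region, relab)$v, 1.0)
  g <- make_grid(length(pl$labels), 1, 100)
  b1 <- adjacency_boundary(r$labels_region, g)
  b2 <- adjacency_boundary(relab, g)
  expect_identical(b1$boundary, b2$boundary)
})

test_that("nmds_embed is seeded, near-exact on planar data, and flags stress", {
  set.seed(3)
  pts <- matrix(runif(24), 12, 2)
  v <- as.matrix(dist(pts)); v <- v / max(v)
  d <- dissim_matrix(v, seq_len(12) - 1L, "simpson", "taxonomic")
  e1 <- nmds_embed(d, dims = 2, seed = 4)
  e2 <- nmds_embed(d, dims = 2, seed = 4)
  expect_identical(e1$points, e2$points)
  expect_lt(e1$stress, 0.01)     # perfect 2-D configuration

  # coincident cells land (essentially) together
  v2 <- rbind(cbind(v, v[, 1]), c(v[1, ], 0))
  d2 <- dissim_matrix(v2, seq_len(13) - 1L, "simpson", "taxonomic")
  e3 <- nmds_embed(d2, dims = 2, seed = 4)
  dup <- sqrt(sum((e3$points[13, ] - e3$points[1, ])^2))
  spread <- mean(dist(e3$points))
  expect_lt(dup, 0.05 * spread)
  expect_error(nmds_embed(d, dims = 12, seed = 1), "invalid-argument")
})
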