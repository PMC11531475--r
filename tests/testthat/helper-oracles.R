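# Independent oracles and tiny fixture builders.  The oracles deliberately
# use literal set enumeration / per-pair loops so they share no code path
# with the package's sparse-product implementations.

# literal set-based taxonomic beta between two cells of a dense 0/1 matrix
oracle_beta_tax <- function(inc, metric) {
  inc <- as.matrix(inc)
  n <- nrow(inc)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      si <- which(inc[i, ] > 0)
      sj <- which(inc[j, ] > 0)
      a <- length(intersect(si, sj))
      b <- length(setdiff(si, sj))
      c_ <- length(setdiff(sj, si))
      out[i, j] <- out[j, i] <- if (metric == "simpson") {
        1 - a / (min(b, c_) + a)
      } else {
        (b + c_) / (2 * a + b + c_)
      }
    }
  }
  out
}

# per-tip root paths -> per-cell branch sets, then literal branch-set beta
oracle_branch_sets <- function(inc, tree) {
  inc <- as.matrix(inc)
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  root <- length(tree$tip.label) + 1L
  tip_edges <- lapply(seq_along(tree$tip.label), function(tip) {
    nodes <- ape::nodepath(tree, root, tip)
    match(paste(nodes[-length(nodes)], nodes[-1]), edge_key)
  })
  lapply(seq_len(nrow(inc)), function(i) {
    sp <- which(inc[i, ] > 0)
    tips <- match(colnames(inc)[sp], tree$tip.label)
    sort(unique(unlist(tip_edges[tips])))
  })
}

oracle_beta_phylo <- function(inc, tree, metric) {
  sets <- oracle_branch_sets(inc, tree)
  len <- tree$edge.length
  n <- length(sets)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sum(len[intersect(sets[[i]], sets[[j]])])
      b <- sum(len[setdiff(sets[[i]], sets[[j]])])
      c_ <- sum(len[setdiff(sets[[j]], sets[[i]])])
      out[i, j] <- out[j, i] <- if (metric == "simpson") {
        1 - a / (min(b, c_) + a)
      } else {
        (b + c_) / (2 * a + b + c_)
      }
    }
  }
  out
}

# brute-force explained dissimilarity: loop over unordered pairs
oracle_explained <- function(values, labels) {
  n <- nrow(values)
  tot <- 0; btw <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + values[i, j]
      if (labels[i] != labels[j]) btw <- btw + values[i, j]
    }
  }
  btw / tot
}

# random community with no empty cells/species, as a br_community
random_community <- function(n_cells, n_species, fill = 0.4,
                            species = sprintf("sp%04d", seq_len(n_species))) {
  repeat {
    inc <- matrix(runif(n_cells * n_species) < fill, n_cells, n_species)
    if (all(rowSums(inc) > 0) && all(colSums(inc) > 0)) break
  }
  pres <- which(inc, arr.ind = TRUE)
  build_community(
    data.frame(cell_id = pres[, 1] - 1L, species = species[pres[, 2]]),
    make_grid(n_cells, 1, 100), species)
}

# small autocorrelated Gaussian field on an nx x ny grid (row-major vector)
helper_grf <- function(nx, ny, sigma) {
  noise <- matrix(rnorm(nx * ny), ny, nx)
  sm_r <- betaregions:::.smoother(ny, sigma)
  sm_c <- betaregions:::.smoother(nx, sigma)
  as.vector(t(sm_r %*% noise %*% t(sm_c)))
}

# ((A:1,B:1):1,C:2); the worked tree for branch-incidence examples
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_community <- function(cells) {
  species <- sort(unique(unlist(cells)))
  pres <- do.call(rbind, lapply(seq_along(cells), function(i) {
    data.frame(cell_id = i - 1L, species = cells[[i]])
  }))
  build_community(pres, make_grid(length(cells), 1, 100), species)
}
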