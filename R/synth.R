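#' @importFrom stats rnorm runif sd cor cophenetic as.dist cutree hclust
NULL

# One user-facing integer seed is fanned out to a named substream per
# operation so stages can be rerun independently yet reproducibly.
seed_substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483563) + 1L
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Generates an ultrametric pure-birth tree with unique tip labels
#' `sp0001`, `sp0002`, ... — a stand-in for a dated species-level
#' phylogeny.  Same seed, same tree, bit-identical.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @param birth Speciation rate (time units are arbitrary).
#' @return An [ape::rphylo()] `phylo` object, rooted, binary, ultrametric.
#' @examples
#' tr <- generate_phylogeny(8, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
generate_phylogeny <- function(n_tips, seed, birth = 1) {
  if (!is.numeric(n_tips) || n_tips < 2 || n_tips != round(n_tips)) {
    stop("invalid-argument: n_tips must be an integer >= 2", call. = FALSE)
  }
  set.seed(seed_substream(seed, "phylogeny"))
  tr <- ape::rphylo(as.integer(n_tips), birth = birth, death = 0)
  tr$tip.label <- sprintf("sp%04d", seq_len(n_tips))
  tr
}

# band-limited smoothing matrix: row-normalized Gaussian weights.
# sigma = Inf collapses to uniform weights, i.e. a constant field.
.smoother <- function(n, sigma) {
  idx <- seq_len(n)
  if (!is.finite(sigma)) {
    return(matrix(1 / n, n, n))
  }
  if (sigma <= 0) return(diag(n))
  w <- exp(-0.5 * (outer(idx, idx, "-") / sigma)^2)
  w / rowSums(w)
}

# spatially autocorrelated Gaussian field as an ny x nx matrix,
# standardized to mean 0 / sd 1 (unless degenerate)
smooth_field <- function(nx, ny, sigma) {
  noise <- matrix(rnorm(nx * ny), nrow = ny, ncol = nx)
  f <- .smoother(ny, sigma) %*% noise %*% t(.smoother(nx, sigma))
  s <- stats::sd(f)
  if (s > 0) f <- (f - mean(f)) / s
  f
}

#' Simulate a gridded landscape with smooth environmental fields
#'
#' Produces per-cell elevation, climate means and seasonalities, past
#' climate velocity, and per-cell tectonic drift trajectories on an
#' equal-area grid.  All fields are spatially autocorrelated
#' (Gaussian-filtered white noise); elevation additionally carries an
#' axis-aligned mountain ridge so determinant-recovery experiments have a
#' known orographic signal.  Drift trajectories are smooth (AR(1)
#' velocity) random walks from the cell centroids, one position per
#' timestep, emulating plate-motion reconstructions.
#'
#' @param nx,ny Grid dimensions (>= 3).
#' @param cell_size_km Cell side in km (default 100, the analysis grain).
#' @param smoothness Gaussian filter sd in cells; `Inf` gives constant
#'   fields.
#' @param seed Integer seed.
#' @param n_timesteps Trajectory length T (>= 2; default 66, i.e. 65
#'   intervals read as 1-Myr steps).
#' @param ridge_height Ridge amplitude in m (default 2000).
#' @return A `"br_landscape"`: `grid`, per-cell numeric fields
#'   (`elevation` m, `temp_mean` deg C, `temp_seasonality`, `precip_mean`
#'   mm, `precip_seasonality`, `past_velocity` km/yr), `ridge_col`
#'   (0-based column of the ridge crest), and `drift` (an
#'   n_cells x T x 2 array of km positions).
#' @export
generate_landscape <- function(nx, ny, cell_size_km = 100, smoothness = 3,
                               seed = 1, n_timesteps = 66,
                               ridge_height = 2000) {
  if (nx < 3 || ny < 3) {
    stop("invalid-argument: nx and ny must be >= 3", call. = FALSE)
  }
  if (n_timesteps < 2) {
    stop("invalid-argument: n_timesteps must be >= 2", call. = FALSE)
  }
  grid <- make_grid(nx, ny, cell_size_km)
  set.seed(seed_substream(seed, "landscape"))

  f <- function() as.vector(t(smooth_field(nx, ny, smoothness)))  # row-major
  # ridge sd of 1 cell: at a 100-km grain an orographic barrier spans
  # roughly one cell, concentrating relief at the crest columns
  ridge_col <- (nx - 1) %/% 2
  col <- (seq_len(grid$n_cells) - 1L) %% nx
  ridge <- ridge_height * exp(-0.5 * (col - ridge_col)^2)

  elevation <- 500 + 300 * f() + ridge
  temp_mean <- 15 + 8 * f()
  temp_seasonality <- pmax(0, 6 + 2.5 * f())
  precip_mean <- pmax(0, 1200 + 500 * f())
  precip_seasonality <- pmax(0, 40 + 15 * f())
  past_velocity <- pmax(0, 0.2 + 0.12 * f())

  # smooth random-walk drift: AR(1) velocity in km per timestep
  n <- grid$n_cells
  drift <- array(0, dim = c(n, n_timesteps, 2))
  drift[, 1, 1] <- grid$x_km
  drift[, 1, 2] <- grid$y_km
  v <- matrix(rnorm(n * 2, sd = 20), n, 2)
  for (t in seq_len(n_timesteps - 1)) {
    v <- 0.9 * v + matrix(rnorm(n * 2, sd = 8), n, 2)
    drift[, t + 1, ] <- drift[, t, ] + v
  }

  structure(list(
    grid = grid,
    elevation = elevation,
    temp_mean = temp_mean,
    temp_seasonality = temp_seasonality,
    precip_mean = precip_mean,
    precip_seasonality = precip_seasonality,
    past_velocity = past_velocity,
    ridge_col = ridge_col,
    drift = drift
  ), class = "br_landscape")
}

#' @export
print.br_landscape <- function(x, ...) {
  cat(sprintf("<br_landscape> %d x %d grid, %d drift timesteps\n",
              x$grid$nx, x$grid$ny, dim(x$drift)[2]))
  invisible(x)
}

# split the grid into n_regions contiguous rectangular blocks; returns
# per-cell 1-based region labels.  Uses the divisor pair closest to square.
planted_blocks <- function(grid, n_regions) {
  if (n_regions > grid$n_cells) {
    stop("invalid-argument: more regions than cells", call. = FALSE)
  }
  divs <- which(n_regions %% seq_len(floor(sqrt(n_regions))) == 0)
  a <- max(divs)                      # rows of blocks
  b <- n_regions %/% a                # cols of blocks
  if (a > grid$ny || b > grid$nx) { a <- 1; b <- n_regions }
  rc <- cell_rowcol(grid, seq_len(grid$n_cells) - 1L)
  rband <- pmin(a - 1, rc[, "row"] %/% ceiling(grid$ny / a))
  cband <- pmin(b - 1, rc[, "col"] %/% ceiling(grid$nx / b))
  as.integer(rband * b + cband + 1L)
}

# grow a contiguous patch of `size` cells inside `allowed` (0-based ids)
# from a random start, randomized-frontier BFS
grow_patch <- function(grid, allowed, size, nbrs) {
  start <- allowed[sample.int(length(allowed), 1)]
  allowed_set <- logical(grid$n_cells)
  allowed_set[allowed + 1L] <- TRUE
  in_patch <- logical(grid$n_cells)
  in_patch[start + 1L] <- TRUE
  patch <- start
  frontier <- start
  while (length(patch) < size && length(frontier) > 0) {
    cand <- unique(unlist(nbrs[frontier + 1L]))
    cand <- cand[allowed_set[cand + 1L] & !in_patch[cand + 1L]]
    if (!length(cand)) break
    take <- sample(cand, min(length(cand), size - length(patch)))
    in_patch[take + 1L] <- TRUE
    patch <- c(patch, take)
    frontier <- take
  }
  patch
}

#' Simulate clade-structured species ranges with planted regions
#'
#' Splits the grid into `n_regions` contiguous rectangular blocks (the
#' planted truth), cuts the phylogeny into `n_regions` clades, and maps
#' clades to regions.  Each species inherits its clade's home region with
#' probability `clade_fidelity` (otherwise a uniformly random region) and
#' occupies one contiguous patch of about `occupancy` of its home region's
#' cells.  With `spillover > 0` a species may additionally claim a few
#' cells just across its region edge, mimicking transition zones.
#'
#' @param phylo A rooted ultrametric `phylo` (e.g. [generate_phylogeny()]).
#' @param land A [generate_landscape()] landscape.
#' @param n_regions Number of planted regions (>= 2).
#' @param n_species Number of species (<= number of tips).
#' @param occupancy Fraction in (0, 1] of home-region cells per species
#'   (default 0.75: region members share most of their flora, the premise
#'   of floristic regionalization).
#' @param clade_fidelity Probability in \[0, 1\] a species stays in its
#'   clade's home region.
#' @param seed Integer seed.
#' @param spillover Probability a species spills over its region edge
#'   (default 0: clean planted signal).
#' @return A `"br_scenarios"` scenario set: `present` (`br_community`),
#'   `futures` (empty named list), `truth_labels` (per-cell planted region,
#'   1-based), `phylogeny` (pruned to the chosen species), `grid`.
#' @export
generate_ranges <- function(phylo, land, n_regions, n_species,
                            occupancy = 0.75, clade_fidelity = 1,
                            seed = 1, spillover = 0) {
  stopifnot(inherits(land, "br_landscape"), inherits(phylo, "phylo"))
  grid <- land$grid
  if (n_regions < 2) stop("invalid-argument: n_regions must be >= 2", call. = FALSE)
  if (n_species > length(phylo$tip.label)) {
    stop("invalid-argument: n_species exceeds tip count", call. = FALSE)
  }
  if (occupancy <= 0 || occupancy > 1) {
    stop("invalid-argument: occupancy must be in (0, 1]", call. = FALSE)
  }
  if (n_species < n_regions) {
    stop("invalid-argument: need at least one species per region", call. = FALSE)
  }
  set.seed(seed_substream(seed, "ranges"))

  truth <- planted_blocks(grid, n_regions)
  region_cells <- split(seq_len(grid$n_cells) - 1L, truth)

  # clade -> region map via an ultrametric-exact UPGMA cut of the tree
  coph <- stats::cophenetic(phylo)
  clades <- stats::cutree(stats::hclust(stats::as.dist(coph), "average"),
                          k = n_regions)
  clade_region <- sample.int(n_regions)   # clade i lives in region clade_region[i]

  # stratified species choice: at least one tip per clade when possible
  tips <- phylo$tip.label
  by_clade <- split(tips, clades)
  first <- vapply(by_clade, function(v) v[sample.int(length(v), 1)], "")
  rest <- setdiff(tips, first)
  extra <- if (n_species > length(first)) {
    sample(rest, n_species - length(first))
  } else character(0)
  species <- sort(c(first[seq_len(min(n_species, length(first)))], extra))

  home <- clade_region[clades[species]]
  flip <- runif(length(species)) > clade_fidelity
  home[flip] <- sample.int(n_regions, sum(flip), replace = TRUE)
  # keep every region populated
  for (r in setdiff(seq_len(n_regions), unique(home))) {
    home[sample.int(length(home), 1)] <- r
  }

  nbrs <- grid_neighbors(grid, "queen")
  rows <- integer(0); labs <- character(0)
  for (i in seq_along(species)) {
    cells_r <- region_cells[[home[i]]]
    size <- max(1L, round(occupancy * length(cells_r)))
    patch <- grow_patch(grid, cells_r, size, nbrs)
    if (spillover > 0 && runif(1) < spillover) {
      outside <- unique(unlist(nbrs[patch + 1L]))
      outside <- setdiff(outside, c(patch, cells_r))
      if (length(outside)) {
        patch <- c(patch, sample(outside, min(length(outside), max(1L, size %/% 10))))
      }
    }
    rows <- c(rows, patch)
    labs <- c(labs, rep(species[i], length(patch)))
  }
  present <- build_community(data.frame(cell_id = rows, species = labs),
                             grid, species)
  tree <- ape::keep.tip(phylo, species)
  structure(list(present = present, futures = list(),
                 truth_labels = truth, phylogeny = tree, grid = grid),
            class = "br_scenarios")
}

#' @export
print.br_scenarios <- function(x, ...) {
  cat(sprintf("<br_scenarios> %d species on %d cells; %d future scenario(s)\n",
              length(x$present$species), x$grid$n_cells, length(x$futures)))
  invisible(x)
}

#' Derive a future scenario by contracting, expanding or shifting ranges
#'
#' Applies one of the three hypothesized climate-change responses to every
#' species range: `contract` peels cells off the range edge, `expand`
#' claims adjacent cells (region borders are no barrier), `shift`
#' translates the range by a whole number of cells in a random direction
#' per species.  The resulting community is appended to `futures`; the
#' species list is unchanged.
#'
#' @param s A `br_scenarios` set.
#' @param mode `"contract"`, `"expand"` or `"shift"`.
#' @param magnitude Fraction of range cells (contract/expand) or distance
#'   in cells (shift); >= 0.  Zero reproduces the present exactly.
#' @param seed Integer seed.
#' @param label Name for the future (default `"<mode><magnitude>"`).
#' @return The scenario set with one more entry in `futures`.
#' @export
apply_scenario <- function(s, mode = c("contract", "expand", "shift"),
                           magnitude, seed = 1, label = NULL) {
  stopifnot(inherits(s, "br_scenarios"))
  mode <- match.arg(mode)
  if (magnitude < 0) stop("invalid-argument: magnitude must be >= 0", call. = FALSE)
  set.seed(seed_substream(seed, paste0("scenario-", mode)))
  grid <- s$grid
  inc <- s$present$incidence
  nbrs <- grid_neighbors(grid, "queen")
  rows <- integer(0); labs <- character(0)
  for (j in seq_along(s$present$species)) {
    cells <- which(inc[, j]) - 1L
    if (!length(cells)) next
    new_cells <- cells
    if (magnitude > 0 && mode == "contract") {
      n_drop <- min(length(cells), round(magnitude * length(cells)))
      if (n_drop > 0) {
        cx <- mean(grid$x_km[cells + 1L]); cy <- mean(grid$y_km[cells + 1L])
        d <- (grid$x_km[cells + 1L] - cx)^2 + (grid$y_km[cells + 1L] - cy)^2
        new_cells <- cells[order(d)][seq_len(length(cells) - n_drop)]
      }
    } else if (magnitude > 0 && mode == "expand") {
      n_add <- round(magnitude * length(cells))
      have <- logical(grid$n_cells); have[cells + 1L] <- TRUE
      added <- 0L
      while (added < n_add) {
        cand <- unique(unlist(nbrs[new_cells + 1L]))
        cand <- cand[!have[cand + 1L]]
        if (!length(cand)) break
        take <- if (length(cand) > n_add - added) {
          sample(cand, n_add - added)
        } else cand
        have[take + 1L] <- TRUE
        new_cells <- c(new_cells, take)
        added <- added + length(take)
      }
    } else if (magnitude > 0 && mode == "shift") {
      ang <- runif(1, 0, 2 * pi)
      dx <- round(magnitude * cos(ang)); dy <- round(magnitude * sin(ang))
      rc <- cell_rowcol(grid, cells)
      ids <- rowcol_cell(grid, rc[, "row"] + dy, rc[, "col"] + dx)
      new_cells <- ids[!is.na(ids)]
    }
    rows <- c(rows, new_cells)
    labs <- c(labs, rep(s$present$species[j], length(new_cells)))
  }
  if (!length(rows)) {
    stop("degenerate-scenario: magnitude emptied every range", call. = FALSE)
  }
  fut <- build_community(data.frame(cell_id = rows, species = labs),
                         grid, s$present$species)
  if (is.null(label)) label <- paste0(mode, magnitude)
  s$futures[[label]] <- fut
  s
}

#' Write a scenario set to plain-text artifacts
#'
#' Writes the phylogeny (newick), each community (sparse triplet CSV), the
#' planted truth labels and a JSON manifest into `dir`.
#'
#' @param s A `br_scenarios` set.
#' @param dir Output directory (created if needed).
#' @export
write_scenarios <- function(s, dir) {
  stopifnot(inherits(s, "br_scenarios"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(s$phylogeny, file.path(dir, "phylogeny.nwk"))
  write_community_csv(s$present, file.path(dir, "community_present.csv"))
  for (nm in names(s$futures)) {
    write_community_csv(s$futures[[nm]],
                        file.path(dir, paste0("community_", nm, ".csv")))
  }
  utils::write.csv(
    data.frame(cell_id = seq_len(s$grid$n_cells) - 1L, region = s$truth_labels),
    file.path(dir, "truth_labels.csv"), row.names = FALSE, quote = FALSE)
  manifest <- list(grid = list(nx = s$grid$nx, ny = s$grid$ny,
                               cell_size_km = s$grid$cell_size_km),
                   n_species = length(s$present$species),
                   futures = as.list(names(s$futures)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
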