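#' Sparse presence/absence community matrix on a grid
#'
#' Collapses an iterable of (cell_id, species) presences into a binary
#' cells x species incidence matrix bound to a grid, the gridded analogue
#' of converting range polygons to a community matrix.  Duplicate presences
#' collapse to a single 1; species declared in `species_universe` but never
#' observed are retained as all-zero columns so matrices from different
#' scenarios stay column-aligned.
#'
#' @param presences A data.frame (or two-column matrix) with columns
#'   `cell_id` (0-based grid cell id) and `species` (label).  May be empty.
#' @param grid A [make_grid()] grid.
#' @param species_universe Ordered unique species labels; every label in
#'   `presences` must appear here.
#' @return An object of class `"br_community"`: list with `grid`, `species`,
#'   and `incidence`, a [Matrix::sparseMatrix()] (ngCMatrix) of dimension
#'   n_cells x n_species with dimnames `cell<id>` / species labels.
#' @examples
#' g <- make_grid(2, 2, 100)
#' cm <- build_community(data.frame(cell_id = c(0, 0, 1), species = c("a", "a", "b")),
#'                       g, c("a", "b", "c"))
#' Matrix::rowSums(cm$incidence)
#' @export
build_community <- function(presences, grid, species_universe) {
  stopifnot(inherits(grid, "br_grid"))
  if (anyDuplicated(species_universe)) {
    stop("invalid-argument: duplicated labels in species_universe", call. = FALSE)
  }
  species_universe <- as.character(species_universe)
  if (is.matrix(presences)) presences <- as.data.frame(presences)
  if (is.null(presences) || nrow(presences) == 0) {
    cell_id <- integer(0); sp <- character(0)
  } else {
    if (!all(c("cell_id", "species") %in% names(presences))) {
      stop("invalid-argument: presences needs columns cell_id and species",
           call. = FALSE)
    }
    cell_id <- as.integer(presences$cell_id)
    sp <- as.character(presences$species)
    if (any(cell_id < 0 | cell_id >= grid$n_cells)) {
      stop("out-of-range: cell_id outside grid", call. = FALSE)
    }
    bad <- setdiff(unique(sp), species_universe)
    if (length(bad)) {
      stop("unknown-species: ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  j <- match(sp, species_universe)
  inc <- Matrix::sparseMatrix(
    i = cell_id + 1L, j = j, x = rep(1, length(j)),
    dims = c(grid$n_cells, length(species_universe)),
    dimnames = list(paste0("cell", seq_len(grid$n_cells) - 1L), species_universe)
  )
  inc <- methods::as(inc > 0, "CsparseMatrix")  # collapse duplicates to binary
  structure(list(grid = grid, species = species_universe, incidence = inc),
            class = "br_community")
}

#' @export
print.br_community <- function(x, ...) {
  cat(sprintf("<br_community> %d cells x %d species, %d presences\n",
              nrow(x$incidence), ncol(x$incidence), sum(x$incidence)))
  invisible(x)
}

#' Drop empty cells and species from a community matrix
#'
#' Pairwise dissimilarity is undefined for empty assemblages, so empty grid
#' cells (and never-observed species) are removed before analysis.  The
#' mapping back to original 0-based cell ids is kept in the result.
#'
#' @param cm A [build_community()] object.
#' @return A list with `community` (the reduced `br_community`, carrying a
#'   `cell_ids` field of retained original ids), `dropped_cells` and
#'   `dropped_species`.
#' @export
drop_empty <- function(cm) {
  stopifnot(inherits(cm, "br_community"))
  rs <- Matrix::rowSums(cm$incidence)
  cs <- Matrix::colSums(cm$incidence)
  if (all(rs == 0)) stop("empty-community: all cells are empty", call. = FALSE)
  keep_r <- which(rs > 0)
  keep_c <- which(cs > 0)
  out <- cm
  out$incidence <- cm$incidence[keep_r, keep_c, drop = FALSE]
  out$species <- cm$species[keep_c]
  out$cell_ids <- unname(keep_r) - 1L
  list(community = out,
       dropped_cells = unname(which(rs == 0)) - 1L,
       dropped_species = cm$species[cs == 0])
}

#' Read and write sparse triplet community CSV
#'
#' The on-disk format is a plain CSV `cell_id,species_id,1` (one row per
#' presence); a write/read round trip reproduces the incidence exactly.
#'
#' @param cm A `br_community`.
#' @param path File path.
#' @export
write_community_csv <- function(cm, path) {
  stopifnot(inherits(cm, "br_community"))
  tr <- Matrix::summary(methods::as(cm$incidence, "TsparseMatrix"))
  df <- data.frame(cell_id = tr$i - 1L, species_id = cm$species[tr$j],
                   presence = 1L)
  df <- df[order(df$cell_id, df$species_id), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_community_csv
#' @param grid Grid to bind the read matrix to.
#' @param species_universe Column universe (defaults to the file's species).
#' @export
read_community_csv <- function(path, grid, species_universe = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(species_universe)) {
    species_universe <- sort(unique(as.character(df$species_id)))
  }
  build_community(data.frame(cell_id = df$cell_id, species = df$species_id),
                  grid, species_universe)
}
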