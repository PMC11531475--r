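#' Equal-area analysis grid
#'
#' An `nx` by `ny` lattice of square cells of side `cell_size_km`.  Cell ids
#' are 0-based and row-major: id = row * nx + col with row 0 at the bottom.
#' All downstream distances are computed in km from cell centroids; no map
#' projection is involved because the grid is equal-area by construction.
#'
#' @param nx,ny Number of columns and rows (each >= 1).
#' @param cell_size_km Cell side length in km (> 0).
#' @return An object of class `"br_grid"` with fields `nx`, `ny`,
#'   `cell_size_km`, `n_cells`, and centroid coordinates `x_km`, `y_km`
#'   indexed by cell id + 1.
#' @examples
#' g <- make_grid(4, 3, 100)
#' g$n_cells
#' @export
make_grid <- function(nx, ny, cell_size_km = 100) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 1 || ny < 1 ||
      nx != round(nx) || ny != round(ny)) {
    stop("invalid-argument: nx and ny must be positive integers", call. = FALSE)
  }
  if (!is.numeric(cell_size_km) || cell_size_km <= 0) {
    stop("invalid-argument: cell_size_km must be positive", call. = FALSE)
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  id <- seq_len(nx * ny) - 1L
  col <- id %% nx
  row <- id %/% nx
  structure(list(
    nx = nx, ny = ny, cell_size_km = cell_size_km,
    n_cells = nx * ny,
    x_km = (col + 0.5) * cell_size_km,
    y_km = (row + 0.5) * cell_size_km
  ), class = "br_grid")
}

#' @export
print.br_grid <- function(x, ...) {
  cat(sprintf("<br_grid> %d x %d cells of %g km (%d cells)\n",
              x$nx, x$ny, x$cell_size_km, x$n_cells))
  invisible(x)
}

#' Convert between cell ids and (row, col)
#'
#' @param grid A `br_grid`.
#' @param cell_id 0-based row-major cell ids.
#' @return `cell_rowcol()`: a two-column matrix of 0-based (row, col);
#'   `rowcol_cell()`: 0-based cell ids.
#' @keywords internal
#' @export
cell_rowcol <- function(grid, cell_id) {
  stopifnot(inherits(grid, "br_grid"))
  if (any(cell_id < 0 | cell_id >= grid$n_cells)) {
    stop("out-of-range: cell_id outside grid", call. = FALSE)
  }
  cbind(row = cell_id %/% grid$nx, col = cell_id %% grid$nx)
}

#' @rdname cell_rowcol
#' @param row,col 0-based row and column indices.
#' @export
rowcol_cell <- function(grid, row, col) {
  stopifnot(inherits(grid, "br_grid"))
  ok <- row >= 0 & row < grid$ny & col >= 0 & col < grid$nx
  out <- ifelse(ok, row * grid$nx + col, NA_integer_)
  as.integer(out)
}

# queen (8-neighbor) offsets, rook subset first
.queen_offsets <- cbind(
  dr = c(0L, 0L, -1L, 1L, -1L, -1L, 1L, 1L),
  dc = c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
)

#' Neighbor lists on the grid
#'
#' @param grid A `br_grid`.
#' @param adjacency `"queen"` (8 neighbors, default) or `"rook"` (4).
#' @return A list, indexed by cell id + 1, of 0-based neighbor cell ids
#'   (edge and corner cells have fewer entries).
#' @export
grid_neighbors <- function(grid, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  off <- if (adjacency == "queen") .queen_offsets else .queen_offsets[1:4, , drop = FALSE]
  rc <- cell_rowcol(grid, seq_len(grid$n_cells) - 1L)
  lapply(seq_len(grid$n_cells), function(i) {
    r <- rc[i, 1] + off[, "dr"]
    c <- rc[i, 2] + off[, "dc"]
    ids <- rowcol_cell(grid, r, c)
    ids[!is.na(ids)]
  })
}
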