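#' Boundary map container
#'
#' Per-cell binary boundary indicator plus (optionally) the Euclidean
#' distance of every cell centroid to the nearest boundary cell centroid,
#' in km.  Distance is exactly 0 on boundary cells.
#'
#' @keywords internal
new_boundary_map <- function(grid, boundary, level = "region",
                             provenance = list()) {
  structure(list(grid = grid, boundary = as.logical(boundary),
                 distance = NULL, level = level, provenance = provenance),
            class = "br_boundary")
}

#' @export
print.br_boundary <- function(x, ...) {
  cat(sprintf("<br_boundary> %d boundary cells of %d (%s level)%s\n",
              sum(x$boundary), x$grid$n_cells, x$level,
              if (is.null(x$distance)) "" else ", distances filled"))
  invisible(x)
}

# expand per-occupied-cell labels to a full-grid vector (NA = unlabeled)
.full_labels <- function(labels, grid, cell_ids = NULL) {
  if (is.null(cell_ids)) {
    if (length(labels) != grid$n_cells) {
      stop("invalid-argument: labels must cover the grid or come with cell_ids",
           call. = FALSE)
    }
    return(labels)
  }
  full <- rep(NA_integer_, grid$n_cells)
  full[cell_ids + 1L] <- labels
  full
}

#' Region boundaries by label adjacency
#'
#' A cell is a boundary cell iff at least one adjacent cell (queen
#' 8-neighborhood by default) holds a different region label.  Unlabeled
#' (NA) cells are ignored: they neither are boundaries nor induce them.
#'
#' @param labels Integer region labels; either one per grid cell (NA for
#'   unlabeled) or one per entry of `cell_ids`.
#' @param grid A [make_grid()] grid.
#' @param cell_ids Optional 0-based ids locating `labels` on the grid.
#' @param adjacency `"queen"` (default) or `"rook"`.
#' @param level,provenance Metadata tags carried on the result.
#' @return A `br_boundary` (distance not yet filled).
#' @export
adjacency_boundary <- function(labels, grid, cell_ids = NULL,
                               adjacency = c("queen", "rook"),
                               level = "region", provenance = list()) {
  adjacency <- match.arg(adjacency)
  full <- .full_labels(labels, grid, cell_ids)
  nbrs <- grid_neighbors(grid, adjacency)
  boundary <- vapply(seq_len(grid$n_cells), function(i) {
    if (is.na(full[i])) return(FALSE)
    nb <- full[nbrs[[i]] + 1L]
    any(!is.na(nb) & nb != full[i])
  }, logical(1))
  new_boundary_map(grid, boundary, level, provenance)
}

# binary dilation by a Euclidean disk of radius r cells
.dilate_disk <- function(mask, grid, r) {
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
  rc <- cell_rowcol(grid, which(mask) - 1L)
  out <- logical(grid$n_cells)
  for (k in seq_len(nrow(off))) {
    ids <- rowcol_cell(grid, rc[, "row"] + off$dr[k], rc[, "col"] + off$dc[k])
    out[ids[!is.na(ids)] + 1L] <- TRUE
  }
  out
}

#' Region boundaries by the rasterize-buffer-sum procedure
#'
#' For each region, its cells are binarized to 1 and dilated by a
#' Euclidean disk of `ceiling(buffer_km / cell_size_km)` cells (a 200-km
#' buffer at the default 100-km grain, i.e. radius 2).  The dilated layers
#' are summed; cells with a cumulative value greater than one — reached by
#' buffers of at least two different regions — are boundary cells.  This
#' yields a band about two buffers wide centered on each interface, and
#' always contains the [adjacency_boundary()] cells (for radius >= 2).
#'
#' @inheritParams adjacency_boundary
#' @param buffer_km Buffer radius in km (default 200).
#' @return A `br_boundary` (distance not yet filled).
#' @export
buffer_sum_boundary <- function(labels, grid, cell_ids = NULL,
                                buffer_km = 200, level = "region",
                                provenance = list()) {
  full <- .full_labels(labels, grid, cell_ids)
  r <- ceiling(buffer_km / grid$cell_size_km)
  acc <- integer(grid$n_cells)
  for (lab in sort(unique(full[!is.na(full)]))) {
    layer <- .dilate_disk(!is.na(full) & full == lab, grid, r)
    acc <- acc + layer
  }
  new_boundary_map(grid, acc > 1, level, provenance)
}

#' Distance of every cell to the nearest boundary cell
#'
#' Exact Euclidean distance transform on cell centroids, in km; 0 on
#' boundary cells.
#'
#' @param b A `br_boundary` with at least one boundary cell.
#' @return The `br_boundary` with its `distance` field filled.
#' @export
distance_to_boundary <- function(b) {
  stopifnot(inherits(b, "br_boundary"))
  idx <- which(b$boundary)
  if (!length(idx)) {
    stop("all-infinite: no boundary cells; distances undefined", call. = FALSE)
  }
  g <- b$grid
  bx <- g$x_km[idx]; by <- g$y_km[idx]
  # chunked brute-force EDT: n_cells x n_boundary distances
  dist <- numeric(g$n_cells)
  step <- max(1L, 200000L %/% length(idx))
  for (s in seq(1L, g$n_cells, by = step)) {
    e <- min(g$n_cells, s + step - 1L)
    dx <- outer(g$x_km[s:e], bx, "-")
    dy <- outer(g$y_km[s:e], by, "-")
    dist[s:e] <- sqrt(apply(dx^2 + dy^2, 1, min))
  }
  b$distance <- dist
  b
}

#' Write a boundary map as per-cell CSV
#'
#' Columns `cell_id,boundary,distance_km` (distance empty if not filled).
#'
#' @param b A `br_boundary`.
#' @param path File path.
#' @export
write_boundary_csv <- function(b, path) {
  stopifnot(inherits(b, "br_boundary"))
  utils::write.csv(
    data.frame(cell_id = seq_len(b$grid$n_cells) - 1L,
               boundary = as.integer(b$boundary),
               distance_km = if (is.null(b$distance)) NA_real_ else b$distance),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
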