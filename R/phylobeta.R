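#' Pairwise cell dissimilarity container
#'
#' A symmetric n x n matrix of pairwise dissimilarities in \[0, 1\] between
#' grid cells, tagged with its metric (`simpson` or `sorensen`) and level
#' (`taxonomic` or `phylogenetic`) and carrying the 0-based grid cell id of
#' each row/column.
#'
#' @param values Symmetric numeric matrix, zero diagonal, entries in \[0,1\].
#' @param cell_ids 0-based grid cell ids, one per row.
#' @param metric `"simpson"` or `"sorensen"`.
#' @param level `"taxonomic"` or `"phylogenetic"`.
#' @return A `"br_dissim"` object.
#' @export
dissim_matrix <- function(values, cell_ids,
                          metric = c("simpson", "sorensen"),
                          level = c("taxonomic", "phylogenetic")) {
  metric <- match.arg(metric); level <- match.arg(level)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), nrow(values) == length(cell_ids))
  if (max(abs(values - t(values))) > 1e-12) {
    stop("invalid-argument: dissimilarity matrix must be symmetric", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12) {
    stop("invalid-argument: dissimilarities must lie in [0, 1]", call. = FALSE)
  }
  values <- pmin(pmax(values, 0), 1)
  dimnames(values) <- list(paste0("cell", cell_ids), paste0("cell", cell_ids))
  structure(list(values = values, cell_ids = as.integer(cell_ids),
                 metric = metric, level = level),
            class = "br_dissim")
}

#' @export
print.br_dissim <- function(x, ...) {
  cat(sprintf("<br_dissim> %d cells, %s %s dissimilarity\n",
              length(x$cell_ids), x$level, x$metric))
  invisible(x)
}

#' Branch incidence of a community on a phylogeny
#'
#' For every cell, marks every tree branch with at least one descendant tip
#' present in that cell — the construction underlying branch-based
#' phylogenetic beta diversity.  A cell's marked branch lengths sum to its
#' phylogenetic diversity (PD).  Any root edge is excluded: it subtends all
#' tips, is shared by every non-empty cell, and has arbitrary length.
#'
#' @param cm A `br_community` (all species must be tip labels of `tree`).
#' @param tree A rooted `phylo` with positive branch lengths.
#' @return A list with `incidence` (sparse cells x branches binary matrix,
#'   branches in `tree$edge` order) and `lengths` (per-branch lengths).
#' @export
branch_incidence <- function(cm, tree) {
  stopifnot(inherits(cm, "br_community"), inherits(tree, "phylo"))
  missing_sp <- setdiff(cm$species, tree$tip.label)
  if (length(missing_sp)) {
    stop("unmatched-taxon: not in tree: ",
         paste(utils::head(missing_sp, 5), collapse = ", "), call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  # postorder pass: tips-below indicator per edge, built bottom-up
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n_tip + tree$Nnode)   # tip ids below each node
  for (i in seq_len(n_tip)) desc[[i]] <- i
  edge_tips_i <- vector("list", n_edge)        # per original edge index
  ord <- match(paste(po$edge[, 1], po$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(n_edge)) {
    parent <- po$edge[k, 1]; child <- po$edge[k, 2]
    tips_below <- desc[[child]]
    edge_tips_i[[ord[k]]] <- tips_below
    desc[[parent]] <- c(desc[[parent]], tips_below)
  }
  ii <- rep.int(seq_len(n_edge), lengths(edge_tips_i))
  jj <- unlist(edge_tips_i)
  tip_by_edge <- Matrix::sparseMatrix(i = jj, j = ii, x = 1,
                                      dims = c(n_tip, n_edge))
  sp_idx <- match(cm$species, tree$tip.label)
  inc_num <- cm$incidence %*% tip_by_edge[sp_idx, , drop = FALSE]
  incidence <- methods::as(inc_num > 0, "CsparseMatrix")
  list(incidence = incidence, lengths = tree$edge.length)
}

#' Pairwise Simpson / Sorensen dissimilarity from shared and unique components
#'
#' For two assemblages with shared quantity `a` and unique quantities `b`
#' and `c` (species counts for taxonomic beta, summed branch lengths for
#' phylogenetic beta): Simpson dissimilarity is `1 - a / (min(b, c) + a)`
#' (turnover only, insensitive to richness differences) and Sorensen is
#' `(b + c) / (2a + b + c)` (richness-sensitive, includes nestedness).
#'
#' @param a,b,c Non-negative shared/unique quantities (vectorized).
#' @param metric `"simpson"` or `"sorensen"`.
#' @return Dissimilarities in \[0, 1\].
#' @examples
#' beta_pair(3, 1, 2, "simpson")   # 0.25
#' beta_pair(3, 1, 2, "sorensen")  # 1/3
#' @export
beta_pair <- function(a, b, c, metric = c("simpson", "sorensen")) {
  metric <- match.arg(metric)
  if (any(a < 0 | b < 0 | c < 0)) {
    stop("invalid-argument: a, b, c must be non-negative", call. = FALSE)
  }
  if (any(a + b + c == 0)) {
    stop("undefined-pair: a = b = c = 0 (empty assemblages)", call. = FALSE)
  }
  if (metric == "simpson") {
    denom <- pmin(b, c) + a
    if (any(denom == 0)) {
      stop("undefined-pair: min(b, c) + a = 0", call. = FALSE)
    }
    1 - a / denom
  } else {
    (b + c) / (2 * a + b + c)
  }
}

#' Pairwise taxonomic or phylogenetic beta diversity between grid cells
#'
#' With `tree = NULL` the shared/unique components a, b, c are species
#' counts; with a tree they are summed branch lengths over the branch
#' incidence ([branch_incidence()]).  Computed by sparse matrix products
#' (never per-pair set loops) but numerically identical to the literal
#' set/branch enumeration.
#'
#' @param cm A `br_community` with no empty cells (use [drop_empty()]).
#' @param tree A `phylo`, or `NULL` for taxonomic beta.
#' @param metric `"simpson"` or `"sorensen"`.
#' @return A [dissim_matrix()] on the community's cells.  Cell ids come
#'   from `cm$cell_ids` if present (post-[drop_empty()]), else 0..n-1.
#' @export
pairwise_beta <- function(cm, tree = NULL,
                          metric = c("simpson", "sorensen")) {
  metric <- match.arg(metric)
  stopifnot(inherits(cm, "br_community"))
  n <- nrow(cm$incidence)
  if (n < 2) stop("invalid-argument: need >= 2 cells", call. = FALSE)
  if (any(Matrix::rowSums(cm$incidence) == 0)) {
    stop("undefined-pair: empty cells present; apply drop_empty() first",
         call. = FALSE)
  }
  if (is.null(tree)) {
    x <- methods::as(cm$incidence, "dMatrix") * 1
    w <- rep(1, ncol(x))
    level <- "taxonomic"
  } else {
    bi <- branch_incidence(cm, tree)
    x <- methods::as(bi$incidence, "dMatrix") * 1
    w <- bi$lengths
    level <- "phylogenetic"
  }
  tot <- as.numeric(x %*% w)                        # per-cell PD / richness
  a <- as.matrix(x %*% (Matrix::t(x) * w))          # shared quantity
  tot_i <- matrix(tot, n, n)
  mn <- pmin(tot_i, t(tot_i))                       # min(b,c) + a
  d <- if (metric == "simpson") 1 - a / mn else {
    (tot_i + t(tot_i) - 2 * a) / (tot_i + t(tot_i))
  }
  ids <- if (!is.null(cm$cell_ids)) cm$cell_ids else seq_len(n) - 1L
  dissim_matrix(d, ids, metric = metric, level = level)
}

#' Elementwise mean of aligned dissimilarity matrices
#'
#' Averages matrices cell-pair by cell-pair, e.g. across emission-scenario
#' futures for one time horizon, to yield a scenario-mean dissimilarity.
#'
#' @param ms A non-empty list of `br_dissim` with identical cell ids,
#'   metric and level.
#' @return A `br_dissim` of the same shape.
#' @export
mean_dissimilarity <- function(ms) {
  if (!length(ms)) stop("invalid-argument: empty list", call. = FALSE)
  ref <- ms[[1]]
  for (m in ms) {
    if (!inherits(m, "br_dissim") ||
        !identical(m$cell_ids, ref$cell_ids) ||
        !identical(m$metric, ref$metric) ||
        !identical(m$level, ref$level)) {
      stop("alignment error: matrices differ in cells, metric or level",
           call. = FALSE)
    }
  }
  avg <- Reduce(`+`, lapply(ms, `[[`, "values")) / length(ms)
  dissim_matrix(avg, ref$cell_ids, ref$metric, ref$level)
}

#' Read and write a dissimilarity matrix as square CSV
#'
#' @param d A `br_dissim`.
#' @param path File path; the header row/column carry cell ids.
#' @export
write_dissim_csv <- function(d, path) {
  stopifnot(inherits(d, "br_dissim"))
  df <- as.data.frame(d$values)
  df <- cbind(cell_id = d$cell_ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dissim_csv
#' @param metric,level Tags for the read matrix.
#' @export
read_dissim_csv <- function(path, metric = "simpson", level = "phylogenetic") {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.integer(df$cell_id)
  vals <- as.matrix(df[, -1, drop = FALSE])
  dissim_matrix(vals, ids, metric, level)
}
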