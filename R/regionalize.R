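#' @importFrom stats pt qnorm quantile t.test var
NULL

# the eight candidate linkage algorithms, in fixed tie-break order,
# mapped to stats::hclust method names
.linkage_map <- c(
  UPGMA    = "average",
  single   = "single",
  complete = "complete",
  ward.D   = "ward.D",
  ward.D2  = "ward.D2",
  WPGMA    = "mcquitty",
  WPGMC    = "median",
  UPGMC    = "centroid"
)

#' Linkage methods considered for regionalization
#' @return Character vector of the eight linkage names, in tie-break order.
#' @export
linkage_methods <- function() names(.linkage_map)

.as_dist <- function(d) stats::as.dist(d$values)

#' Cophenetic correlation of a clustering of a dissimilarity matrix
#'
#' Builds the dendrogram for one linkage method and returns the Pearson
#' correlation between the n(n-1)/2 input dissimilarities and the
#' dendrogram's cophenetic distances — the standard measure of how little
#' the clustering distorts the data.
#'
#' @param d A `br_dissim`.
#' @param method One of [linkage_methods()].
#' @return Correlation in \[-1, 1\], or `NA` when the method's dendrogram
#'   degenerates (all cophenetic distances equal).  Constant *input*
#'   dissimilarities are an error.
#' @export
cophenetic_correlation <- function(d, method) {
  stopifnot(inherits(d, "br_dissim"))
  if (!method %in% names(.linkage_map)) {
    stop("invalid-argument: unknown linkage '", method, "'", call. = FALSE)
  }
  dd <- .as_dist(d)
  if (stats::sd(dd) == 0) {
    stop("undefined-correlation: constant dissimilarities", call. = FALSE)
  }
  hc <- stats::hclust(dd, method = .linkage_map[[method]])
  cc <- stats::cophenetic(hc)
  if (stats::sd(cc) == 0) {
    # a degenerate dendrogram (all cophenetic distances equal) carries no
    # information about the data: score NA so the method cannot be selected
    return(NA_real_)
  }
  stats::cor(as.vector(dd), as.vector(cc))
}

#' Select the least-distorting linkage method
#'
#' Scores all eight candidate linkages by cophenetic correlation and
#' returns the argmax; ties break by the fixed order of
#' [linkage_methods()].
#'
#' @param d A `br_dissim` with >= 3 cells.
#' @return List with `method` (name) and `scores` (named numeric, all 8).
#' @export
select_linkage <- function(d) {
  stopifnot(inherits(d, "br_dissim"))
  if (length(d$cell_ids) < 3) {
    stop("invalid-argument: need >= 3 cells", call. = FALSE)
  }
  scores <- vapply(linkage_methods(),
                   function(m) cophenetic_correlation(d, m), numeric(1))
  if (all(is.na(scores))) {
    stop("undefined-correlation: every linkage degenerates on this matrix",
         call. = FALSE)
  }
  best <- linkage_methods()[which.max(scores)]  # first on ties; NAs ignored
  list(method = best, scores = scores)
}

#' Explained dissimilarity of a partition
#'
#' The ratio (sum of dissimilarities over cell pairs in different clusters)
#' / (sum over all pairs), each unordered pair counted once.  0 when all
#' cells share a cluster, 1 when every cell is alone.
#'
#' @param d A `br_dissim`.
#' @param labels Integer cluster labels, one per cell of `d`.
#' @return Ratio in \[0, 1\].
#' @export
explained_dissimilarity <- function(d, labels) {
  stopifnot(inherits(d, "br_dissim"))
  if (length(labels) != length(d$cell_ids)) {
    stop("invalid-argument: labels must cover all cells", call. = FALSE)
  }
  v <- d$values
  total <- sum(v) / 2
  if (total == 0) stop("degenerate-input: total dissimilarity is 0", call. = FALSE)
  same <- outer(labels, labels, "==")
  within <- sum(v[same]) / 2
  (total - within) / total
}

# walk the hclust merge sequence once, accumulating for each merge the
# cross-cluster dissimilarity sum; yields the whole explained curve and
# (optionally) merge-order cluster memberships in O(n^2)
.merge_walk <- function(hc, values) {
  n <- nrow(values)
  members <- as.list(seq_len(n))          # indexed by merge step for clusters
  node_members <- vector("list", n - 1)
  cross <- numeric(n - 1)
  get_m <- function(code) if (code < 0) -code else node_members[[code]]
  for (m in seq_len(n - 1)) {
    a <- get_m(hc$merge[m, 1]); b <- get_m(hc$merge[m, 2])
    cross[m] <- sum(values[a, b])
    node_members[[m]] <- c(a, b)
  }
  total <- sum(values) / 2
  # within-sum at cut k = sum of cross for the first n-k merges
  within_k <- c(rev(cumsum(cross)), 0)    # index = k from 1..n
  curve <- if (total > 0) (total - within_k) / total else rep(NA_real_, n)
  list(curve = curve, node_members = node_members, total = total)
}

# cut a dendrogram into k groups by undoing merges in reverse merge order
# (ties at equal heights stay resolved by merge order, per the tie rule)
.cut_merge_order <- function(hc, k, node_members = NULL) {
  n <- length(hc$order)
  if (k >= n) return(seq_len(n))
  if (k <= 1) return(rep(1L, n))
  if (is.null(node_members)) {
    node_members <- vector("list", n - 1)
    get_m <- function(code) if (code < 0) -code else node_members[[code]]
    for (m in seq_len(n - 1)) {
      node_members[[m]] <- c(get_m(hc$merge[m, 1]), get_m(hc$merge[m, 2]))
    }
  }
  labels <- integer(n)
  # clusters after the first n-k merges: roots among merges 1..n-k plus singletons
  used <- rep(FALSE, n - 1)
  for (m in seq_len(n - k)) {
    for (code in hc$merge[m, ]) if (code > 0) used[code] <- TRUE
  }
  cl <- 0L
  for (m in seq_len(n - k)) {
    if (!used[m]) { cl <- cl + 1L; labels[node_members[[m]]] <- cl }
  }
  for (i in which(labels == 0L)) { cl <- cl + 1L; labels[i] <- cl }
  # renumber by first appearance for stable output
  as.integer(factor(labels, levels = unique(labels)))
}

#' Smallest number of clusters reaching an explained-dissimilarity threshold
#'
#' Cuts the dendrogram at k = 1...n and returns the smallest k whose
#' partition explains at least `threshold` of the total dissimilarity.
#' k = n always reaches 1, so a solution exists for any threshold < 1.
#'
#' @param hc An [stats::hclust()] dendrogram of the cells of `d`.
#' @param d The `br_dissim` the dendrogram was built from.
#' @param threshold Required explained fraction in (0, 1).
#' @return List with `k`, `labels` (1..k), and the full `curve`.
#' @export
select_k <- function(hc, d, threshold) {
  stopifnot(inherits(d, "br_dissim"), inherits(hc, "hclust"))
  if (threshold <= 0 || threshold >= 1) {
    stop("invalid-argument: threshold must be in (0, 1)", call. = FALSE)
  }
  mw <- .merge_walk(hc, d$values)
  k <- which(mw$curve >= threshold)[1]
  labels <- .cut_merge_order(hc, k, mw$node_members)
  list(k = as.integer(k), labels = labels, curve = mw$curve)
}

#' Delineate nested floristic realms and regions
#'
#' One linkage selection ([select_linkage()]), one dendrogram, two cuts:
#' realms are the smallest number of clusters explaining
#' `realm_threshold` (default 85%) of the total dissimilarity, regions the
#' smallest explaining `region_threshold` (default 90%).  Because both are
#' cuts of one dendrogram, the region partition refines the realm
#' partition.  Fully deterministic.
#'
#' @param d A `br_dissim` between occupied grid cells.
#' @param realm_threshold,region_threshold Explained-dissimilarity
#'   thresholds, `realm_threshold < region_threshold`.
#' @param linkage_override Optional linkage name to skip selection.
#' @return A `"br_regionalization"`: `linkage_method`, `cophenetic_scores`,
#'   `dendrogram` (hclust), `explained_curve`, `k_realm`, `k_region`,
#'   `labels_realm`, `labels_region`, `explained_realm`,
#'   `explained_region`, `cell_ids`.
#' @export
regionalize <- function(d, realm_threshold = 0.85, region_threshold = 0.90,
                        linkage_override = NULL) {
  stopifnot(inherits(d, "br_dissim"))
  if (!(realm_threshold < region_threshold)) {
    stop("invalid-argument: realm_threshold must be < region_threshold",
         call. = FALSE)
  }
  if (is.null(linkage_override)) {
    sel <- select_linkage(d)
  } else {
    if (!linkage_override %in% linkage_methods()) {
      stop("invalid-argument: unknown linkage '", linkage_override, "'",
           call. = FALSE)
    }
    sel <- list(method = linkage_override,
                scores = stats::setNames(rep(NA_real_, 8), linkage_methods()))
  }
  hc <- stats::hclust(.as_dist(d), method = .linkage_map[[sel$method]])
  mw <- .merge_walk(hc, d$values)
  k_realm <- which(mw$curve >= realm_threshold)[1]
  k_region <- which(mw$curve >= region_threshold)[1]
  structure(list(
    linkage_method = sel$method,
    cophenetic_scores = sel$scores,
    dendrogram = hc,
    explained_curve = mw$curve,
    k_realm = as.integer(k_realm),
    k_region = as.integer(k_region),
    labels_realm = .cut_merge_order(hc, k_realm, mw$node_members),
    labels_region = .cut_merge_order(hc, k_region, mw$node_members),
    explained_realm = mw$curve[k_realm],
    explained_region = mw$curve[k_region],
    cell_ids = d$cell_ids
  ), class = "br_regionalization")
}

#' @export
print.br_regionalization <- function(x, ...) {
  cat(sprintf(
    "<br_regionalization> %s linkage; %d realms (%.3f expl.), %d regions (%.3f expl.) over %d cells\n",
    x$linkage_method, x$k_realm, x$explained_realm,
    x$k_region, x$explained_region, length(x$cell_ids)))
  invisible(x)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Presentation-only ordination (monotone-regression NMDS via
#' [vegan::monoMDS()]); never feeds cluster labels.
#'
#' @param d A `br_dissim`.
#' @param dims Embedding dimension (default 2).
#' @param seed Integer seed fixing the start configuration.
#' @return List with `points` (n x dims), `stress`, and `converged`.
#' @export
nmds_embed <- function(d, dims = 2, seed = 1) {
  stopifnot(inherits(d, "br_dissim"))
  n <- length(d$cell_ids)
  if (n < dims + 1) stop("invalid-argument: need n >= dims + 1", call. = FALSE)
  set.seed(seed_substream(seed, "nmds"))
  fit <- vegan::monoMDS(.as_dist(d), k = dims)
  conv <- isTRUE(fit$icause != 4)   # 4 = stopped at max iterations
  if (!conv) warning("nmds_embed: iteration limit reached; best-so-far returned")
  rownames(fit$points) <- paste0("cell", d$cell_ids)
  list(points = fit$points, stress = fit$stress, converged = conv)
}

#' Write regionalization labels and dendrogram to CSV
#'
#' @param r A `br_regionalization`.
#' @param labels_path CSV `cell_id,realm,region`.
#' @param merges_path Optional CSV of the merge table
#'   (`step,left,right,height`; negative entries are leaf indices).
#' @export
write_regionalization_csv <- function(r, labels_path, merges_path = NULL) {
  stopifnot(inherits(r, "br_regionalization"))
  utils::write.csv(
    data.frame(cell_id = r$cell_ids, realm = r$labels_realm,
               region = r$labels_region),
    labels_path, row.names = FALSE, quote = FALSE)
  if (!is.null(merges_path)) {
    hc <- r$dendrogram
    utils::write.csv(
      data.frame(step = seq_len(nrow(hc$merge)), left = hc$merge[, 1],
                 right = hc$merge[, 2], height = hc$height),
      merges_path, row.names = FALSE, quote = FALSE)
  }
  invisible(labels_path)
}
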