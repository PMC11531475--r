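# pooled-SD Cohen's d between two samples (future - present orientation)
.cohens_d <- function(x_future, x_present) {
  n1 <- length(x_future); n2 <- length(x_present)
  sp2 <- ((n1 - 1) * stats::var(x_future) + (n2 - 1) * stats::var(x_present)) /
    (n1 + n2 - 2)
  if (sp2 == 0) return(0)
  (mean(x_future) - mean(x_present)) / sqrt(sp2)
}

# upper-triangle values of a dissimilarity submatrix restricted to `idx`
.pair_values <- function(d, idx) {
  v <- d$values[idx, idx, drop = FALSE]
  v[upper.tri(v)]
}

#' Homogenization / differentiation of present-day regions
#'
#' For each present-day region, collects all within-region pairwise
#' dissimilarities from the present and from a future matrix and contrasts
#' them: a two-sided pooled-variance t-test, and Cohen's d =
#' (mean_future - mean_present) / pooled SD with a bootstrap percentile
#' confidence interval (resampling dissimilarity pairs).  Negative d means
#' within-region dissimilarity falls — homogenization; positive d means
#' differentiation.  A global contrast pools the within-region pairs of
#' all regions.
#'
#' @param labels_present Integer region labels from the present-day
#'   regionalization, one per cell of the matrices.
#' @param d_present,d_future `br_dissim` on identical cells.
#' @param n_boot Bootstrap replicates for the CI (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A `"br_effects"`: `per_region` data.frame (region, d, ci_low,
#'   ci_high, t_stat, p_value, n1, n2, n_boot), the pooled `global` row,
#'   and `mean_region_d`, the unweighted mean of per-region d.  Regions
#'   with fewer than 2 cells are skipped with a warning.
#' @export
within_region_beta_change <- function(labels_present, d_present, d_future,
                                      n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(inherits(d_present, "br_dissim"), inherits(d_future, "br_dissim"))
  if (!identical(d_present$cell_ids, d_future$cell_ids)) {
    stop("alignment error: matrices must share cells", call. = FALSE)
  }
  if (length(labels_present) != length(d_present$cell_ids)) {
    stop("invalid-argument: labels must cover the matrix cells", call. = FALSE)
  }
  set.seed(seed_substream(seed, "beta-change"))
  alpha <- (1 - conf) / 2

  one_contrast <- function(vp, vf, region_id) {
    tt <- stats::t.test(vf, vp, var.equal = TRUE)
    d0 <- .cohens_d(vf, vp)
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(length(vf), replace = TRUE)
      j <- sample.int(length(vp), replace = TRUE)
      .cohens_d(vf[i], vp[j])
    }, numeric(1))
    ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    data.frame(region = region_id, d = d0,
               ci_low = min(ci[1], d0), ci_high = max(ci[2], d0),
               t_stat = unname(tt$statistic), p_value = tt$p.value,
               n1 = length(vf), n2 = length(vp), n_boot = n_boot,
               stringsAsFactors = FALSE)
  }

  rows <- list(); all_p <- list(); all_f <- list()
  for (r in sort(unique(labels_present))) {
    idx <- which(labels_present == r)
    if (length(idx) < 2) {
      warning("region ", r, " has < 2 cells; skipped")
      next
    }
    vp <- .pair_values(d_present, idx)
    vf <- .pair_values(d_future, idx)
    all_p[[length(all_p) + 1L]] <- vp
    all_f[[length(all_f) + 1L]] <- vf
    rows[[length(rows) + 1L]] <- one_contrast(vp, vf, as.character(r))
  }
  if (!length(rows)) stop("degenerate-input: no region with >= 2 cells", call. = FALSE)
  per_region <- do.call(rbind, rows)
  global <- one_contrast(unlist(all_p), unlist(all_f), "global")
  structure(list(per_region = per_region, global = global,
                 mean_region_d = mean(per_region$d)),
            class = "br_effects")
}

#' @export
print.br_effects <- function(x, ...) {
  cat(sprintf("<br_effects> %d regions; global d = %.4f (p = %.3g); mean region d = %.4f\n",
              nrow(x$per_region), x$global$d, x$global$p_value,
              x$mean_region_d))
  invisible(x)
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' V-measure congruence between two partitions of the same cells
#'
#' Entropy-based spatial congruence on the cell-count contingency table
#' (equal-area cells, so counts are areas).  Homogeneity
#' h = 1 - H(A|B)/H(A) and completeness c = 1 - H(B|A)/H(B) combine as
#' v = (1 + B) h c / (B h + c); B > 1 weights completeness more.  h (resp.
#' c) is 1 by convention when H(A) (resp. H(B)) is 0.  v is 1 iff the
#' partitions agree up to relabeling and 0 for independent partitions.
#'
#' @param labels_a,labels_b Integer labels on the same cells.
#' @param B Completeness weight (> 0, default 2).
#' @return A `"br_congruence"` list: `homogeneity`, `completeness`, `v`,
#'   `B`.
#' @export
v_measure <- function(labels_a, labels_b, B = 2.0) {
  if (length(labels_a) != length(labels_b)) {
    stop("alignment error: partitions must label the same cells", call. = FALSE)
  }
  if (B <= 0) stop("invalid-argument: B must be > 0", call. = FALSE)
  n <- length(labels_a)
  tab <- table(labels_a, labels_b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- .entropy(pa); hb <- .entropy(pb)
  # conditional entropies from the joint
  h_a_given_b <- -sum(tab[tab > 0] *
                        log(tab[tab > 0] / rep(pb, each = nrow(tab))[tab > 0]))
  h_b_given_a <- -sum(tab[tab > 0] *
                        log(tab[tab > 0] / rep(pa, times = ncol(tab))[tab > 0]))
  h <- if (ha == 0) 1 else 1 - h_a_given_b / ha
  c_ <- if (hb == 0) 1 else 1 - h_b_given_a / hb
  v <- if (h + c_ == 0) 0 else (1 + B) * h * c_ / (B * h + c_)
  structure(list(homogeneity = h, completeness = c_, v = v, B = B),
            class = "br_congruence")
}

#' @export
print.br_congruence <- function(x, ...) {
  cat(sprintf("<br_congruence> v = %.4f (h = %.4f, c = %.4f, B = %g)\n",
              x$v, x$homogeneity, x$completeness, x$B))
  invisible(x)
}

#' Dutilleul's modified t-test for the correlation of two spatial fields
#'
#' Pearson's r is unchanged, but its significance is assessed against an
#' effective sample size (ESS) estimated from the spatial autocovariance
#' of both fields over `n_classes` equal-width distance classes
#' (Moran-type correlograms).  With
#' Sx, Sy the implied correlation matrices and Bc the centering matrix,
#' ESS = tr(Bc Sx Bc) tr(Bc Sy Bc) / tr(Bc Sx Bc Sy Bc); the test is
#' t = r sqrt((ESS - 2) / (1 - r^2)) on ESS - 2 df.
#'
#' @param x,y Numeric fields on the same cells (length >= 10, finite).
#' @param coords Two-column matrix of centroid coordinates in km.
#' @param n_classes Number of distance classes (default 10).
#' @return List with `r`, `effective_df` (ESS - 2), `ess`, and `p`.
#' @export
modified_ttest <- function(x, y, coords, n_classes = 10) {
  coords <- as.matrix(coords)
  n <- length(x)
  if (length(y) != n || nrow(coords) != n) {
    stop("alignment error: x, y, coords must match", call. = FALSE)
  }
  if (n < 10) stop("invalid-argument: need >= 10 cells", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("invalid-argument: non-finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  dmat <- as.matrix(stats::dist(coords))
  brks <- seq(0, max(dmat), length.out = n_classes + 1)
  cls <- matrix(cut(dmat, breaks = brks, include.lowest = TRUE,
                    labels = FALSE), n, n)
  diag(cls) <- 0L                      # self-pairs excluded from classes
  zx <- x - mean(x); zy <- y - mean(y)
  sxx <- sum(zx^2) / n; syy <- sum(zy^2) / n
  Sx <- diag(n); Sy <- diag(n)
  for (k in seq_len(n_classes)) {
    w <- cls == k
    npairs <- sum(w)
    if (npairs == 0) next
    rho_x <- (sum(zx * (w %*% zx)) / npairs) / sxx   # Moran autocorrelation
    rho_y <- (sum(zy * (w %*% zy)) / npairs) / syy
    Sx[w] <- max(-1, min(1, rho_x))
    Sy[w] <- max(-1, min(1, rho_y))
  }
  # Bc M Bc by double centering (Bc = I - 11'/n), O(n^2)
  dcenter <- function(m) {
    rm <- rowMeans(m); cm <- colMeans(m); gm <- mean(m)
    m - outer(rm, rep(1, n)) - outer(rep(1, n), cm) + gm
  }
  cx <- dcenter(Sx); cy <- dcenter(Sy)
  ess <- sum(diag(cx)) * sum(diag(cy)) / sum(cx * t(cy))
  ess <- min(ess, n)
  df <- ess - 2
  if (df <= 0) {
    return(list(r = r, effective_df = df, ess = ess, p = NA_real_))
  }
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, effective_df = df, ess = ess, p = p)
}
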