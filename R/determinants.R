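#' Neighborhood coefficient of variation of a field
#'
#' For each cell, the coefficient of variation (sd / |mean|) over the
#' focal cell and its existing queen neighbors — a sharp-turnover
#' (heterogeneity) measure used to build climate-heterogeneity predictors
#' without feeding raw climate back into the model.  Neighborhoods whose
#' mean is (numerically) zero are flagged `NA`.
#'
#' @param field Per-cell numeric values on `grid`.
#' @param grid A [make_grid()] grid.
#' @return Per-cell CV (>= 0, or NA where undefined).
#' @export
neighborhood_cv <- function(field, grid) {
  stopifnot(inherits(grid, "br_grid"), length(field) == grid$n_cells)
  nbrs <- grid_neighbors(grid, "queen")
  vapply(seq_len(grid$n_cells), function(i) {
    v <- c(field[i], field[nbrs[[i]] + 1L])
    m <- mean(v)
    if (abs(m) < 1e-12 * max(1, max(abs(v)))) return(NA_real_)
    stats::sd(v) / abs(m)
  }, numeric(1))
}

#' Altitude variation (orographic barrier strength)
#'
#' Mean absolute elevation difference between the focal cell and its
#' existing queen neighbors, in the units of `elevation` (m).
#'
#' @param elevation Per-cell elevation.
#' @param grid A [make_grid()] grid.
#' @return Per-cell mean absolute difference (0 on flat terrain).
#' @export
altitude_variation <- function(elevation, grid) {
  stopifnot(inherits(grid, "br_grid"), length(elevation) == grid$n_cells)
  nbrs <- grid_neighbors(grid, "queen")
  vapply(seq_len(grid$n_cells), function(i) {
    mean(abs(elevation[i] - elevation[nbrs[[i]] + 1L]))
  }, numeric(1))
}

#' Tectonic separation variability
#'
#' Given per-cell drift trajectories (positions over T timesteps), computes
#' for each focal cell the distance to each existing queen neighbor at each
#' timestep, takes the standard deviation of each neighbor's distance
#' series across time, and averages these SDs over neighbors — the
#' variability of inter-cell geographic separation through time.  Rigid
#' common motion (or no motion) of a neighborhood gives 0.
#'
#' @param trajectories An n_cells x T x 2 array of positions (km), e.g.
#'   the `drift` field of [generate_landscape()].
#' @param grid A [make_grid()] grid.
#' @return Per-cell pooled SD of neighbor distances (km).
#' @export
tectonic_sd <- function(trajectories, grid) {
  stopifnot(inherits(grid, "br_grid"))
  dims <- dim(trajectories)
  if (length(dims) != 3 || dims[1] != grid$n_cells || dims[3] != 2) {
    stop("invalid-argument: trajectories must be n_cells x T x 2", call. = FALSE)
  }
  if (dims[2] < 2) stop("invalid-argument: need T >= 2 timesteps", call. = FALSE)
  nbrs <- grid_neighbors(grid, "queen")
  vapply(seq_len(grid$n_cells), function(i) {
    nb <- nbrs[[i]] + 1L
    dx <- trajectories[nb, , 1, drop = FALSE] -
      rep(trajectories[i, , 1], each = length(nb))
    dy <- trajectories[nb, , 2, drop = FALSE] -
      rep(trajectories[i, , 2], each = length(nb))
    dists <- matrix(sqrt(dx^2 + dy^2), nrow = length(nb))  # nbrs x timesteps
    mean(apply(dists, 1, stats::sd))           # SD across time, per neighbor
  }, numeric(1))
}

#' Build the standardized boundary-determinant predictor table
#'
#' Assembles the four climate-heterogeneity CVs, altitude variation,
#' tectonic separation SD, and past climate velocity from a landscape, and
#' standardizes each to mean 0 / variance 1 over cells where all
#' predictors are defined.
#'
#' @param land A [generate_landscape()] landscape.
#' @param standardize Standardize columns (default TRUE).
#' @return A `"br_predictors"`: `table` (data.frame, one row per included
#'   cell), `cell_ids` (0-based included cells), `standardized`.
#' @export
build_predictors <- function(land, standardize = TRUE) {
  stopifnot(inherits(land, "br_landscape"))
  g <- land$grid
  tab <- data.frame(
    temp_het       = neighborhood_cv(land$temp_mean, g),
    tempseas_het   = neighborhood_cv(land$temp_seasonality, g),
    precip_het     = neighborhood_cv(land$precip_mean, g),
    precipseas_het = neighborhood_cv(land$precip_seasonality, g),
    altitude_var   = altitude_variation(land$elevation, g),
    tectonic_sd    = tectonic_sd(land$drift, g),
    past_velocity  = land$past_velocity
  )
  keep <- stats::complete.cases(tab)
  tab <- tab[keep, , drop = FALSE]
  if (standardize) tab <- as.data.frame(scale(tab))
  structure(list(table = tab, cell_ids = which(keep) - 1L,
                 standardized = standardize),
            class = "br_predictors")
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on all others;
#' values below 2 indicate minimal collinearity.  Perfectly collinear
#' predictors are flagged `Inf`.
#'
#' @param p A `br_predictors` or a numeric data.frame/matrix of predictors.
#' @return Named per-predictor VIFs.
#' @export
vif <- function(p) {
  tab <- if (inherits(p, "br_predictors")) p$table else as.data.frame(p)
  if (ncol(tab) < 2) stop("invalid-argument: need >= 2 predictors", call. = FALSE)
  if (any(vapply(tab, function(v) stats::var(v) == 0, logical(1)))) {
    stop("invalid-argument: constant predictor column", call. = FALSE)
  }
  out <- vapply(seq_along(tab), function(j) {
    fit <- stats::lm(tab[[j]] ~ ., data = tab[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, names(tab))
}

#' Binary boundary response with buffer inclusion mask
#'
#' Boundary cells are coded YES (1); cells inside the `buffer_km` buffer
#' around the boundary but not on it are coded NO (0); all other cells are
#' excluded from the model (mask FALSE).
#'
#' @param b A `br_boundary` with a non-empty boundary.
#' @param buffer_km Buffer radius in km (default 200).
#' @return List with `response` (0/1, NA outside mask) and `mask`
#'   (logical inclusion).
#' @export
boundary_response <- function(b, buffer_km = 200) {
  stopifnot(inherits(b, "br_boundary"))
  if (!any(b$boundary)) stop("degenerate-response: empty boundary", call. = FALSE)
  r <- ceiling(buffer_km / b$grid$cell_size_km)
  buf <- .dilate_disk(b$boundary, b$grid, r)
  no <- buf & !b$boundary
  if (!any(no)) {
    stop("degenerate-response: boundary fills its own buffer", call. = FALSE)
  }
  resp <- rep(NA_integer_, b$grid$n_cells)
  resp[no] <- 0L
  resp[b$boundary] <- 1L
  list(response = resp, mask = buf)
}

# ridge-penalized logistic IRLS fallback for separated fits; returns
# glm-like coefficients and SEs from the penalized information matrix
.ridge_logit <- function(X, y, lambda = 1e-3, maxit = 50) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    info <- crossprod(X, X * w) + pen
    beta_new <- drop(solve(info, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  se <- sqrt(diag(solve(info)))
  list(coef = beta, se = se)
}

# design matrix + autocovariate for one fit; W is the row-standardized
# binary within-radius neighbor matrix on included cells
.autocov <- function(response, W) {
  as.numeric(W %*% response)
}

#' Fit the autologistic boundary-determinant model
#'
#' Logistic regression of the YES/NO boundary response on the standardized
#' predictors plus a spatial autocovariate: the row-standardized mean of
#' neighbor responses within `radius_km` (binary within-radius weights,
#' the `dnearneigh`-style neighborhood).  This autologistic form stands in
#' for a hierarchical spatial random-effect model: the autocovariate
#' absorbs residual spatial autocorrelation as a fixed effect.
#' Coefficients and t-values come from the full-data fit; per-predictor
#' Fisher's z and its confidence interval come from `n_boot` nonparametric
#' bootstrap replicates over cells.  A predictor is flagged significant
#' when its z interval excludes 0.
#'
#' @param response Per-grid-cell 0/1 response with NA outside the model
#'   mask (see [boundary_response()]).
#' @param predictors A `br_predictors` (standardized).
#' @param grid A [make_grid()] grid.
#' @param radius_km Neighborhood radius in km (default 283, the smallest
#'   distance keeping a 100-km grid fully connected through diagonals).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A `"br_boundary_fit"`: `coefficients` data.frame (term,
#'   estimate, se, t_value, fisher_z, z_ci_low, z_ci_high, significant),
#'   `n`, `df`, `n_boot`, `radius_km`, `separation` flag.
#' @export
fit_boundary_model <- function(response, predictors, grid, radius_km = 283,
                               n_boot = 200, seed = 1, conf = 0.95) {
  stopifnot(inherits(predictors, "br_predictors"), inherits(grid, "br_grid"))
  if (!predictors$standardized) {
    warning("predictors are not standardized; z scales will be arbitrary")
  }
  vifs <- tryCatch(vif(predictors), error = function(e) NULL)
  if (!is.null(vifs) && any(is.finite(vifs) & vifs >= 2)) {
    warning("VIF >= 2 for: ",
            paste(names(vifs)[is.finite(vifs) & vifs >= 2], collapse = ", "))
  }
  use <- intersect(which(!is.na(response)) - 1L, predictors$cell_ids)
  if (length(use) < 10) stop("invalid-argument: too few modeled cells", call. = FALSE)
  y <- response[use + 1L]
  X <- as.matrix(predictors$table[match(use, predictors$cell_ids), , drop = FALSE])
  if (length(unique(y)) < 2) {
    stop("degenerate-response: single response class", call. = FALSE)
  }
  # binary within-radius weights, row-standardized
  co <- cbind(grid$x_km[use + 1L], grid$y_km[use + 1L])
  dmat <- as.matrix(stats::dist(co))
  W <- (dmat > 0 & dmat <= radius_km) * 1
  rs <- rowSums(W)
  W <- W / ifelse(rs == 0, 1, rs)

  terms <- c("(Intercept)", colnames(X), "autocov")
  set.seed(seed_substream(seed, "boundary-model"))

  fit_once <- function(idx) {
    yy <- y[idx]
    XX <- X[idx, , drop = FALSE]
    Wi <- W[idx, idx, drop = FALSE]
    rsi <- rowSums(Wi)
    Wi <- Wi / ifelse(rsi == 0, 1, rsi)
    ac <- .autocov(yy, Wi)
    dm <- cbind(1, XX, autocov = ac)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(dm, yy, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
    if (sep || !fit$converged) {
      rf <- .ridge_logit(dm, yy)
      list(coef = rf$coef, se = rf$se, df = length(yy) - ncol(dm),
           separation = TRUE)
    } else {
      info <- crossprod(dm, dm * pmax(fit$weights, 1e-10))
      se <- sqrt(diag(solve(info)))
      list(coef = fit$coefficients, se = se, df = fit$df.residual,
           separation = FALSE)
    }
  }

  full <- fit_once(seq_along(y))
  if (full$separation) {
    warning("separation or non-convergence; ridge-penalized fallback used")
  }
  tval <- full$coef / full$se
  df <- full$df
  z_full <- vapply(tval, function(t) fisher_z(t, df)$z, numeric(1))

  boots <- matrix(NA_real_, n_boot, length(terms))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(y), replace = TRUE)
    bf <- tryCatch(fit_once(idx), error = function(e) NULL)
    if (is.null(bf)) next
    bt <- bf$coef / bf$se
    boots[b, ] <- vapply(bt, function(t) fisher_z(t, bf$df)$z, numeric(1))
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  res <- data.frame(
    term = terms, estimate = unname(full$coef), se = unname(full$se),
    t_value = unname(tval), fisher_z = z_full,
    z_ci_low = ci[1, ], z_ci_high = ci[2, ],
    stringsAsFactors = FALSE)
  res$significant <- res$z_ci_low > 0 | res$z_ci_high < 0
  structure(list(coefficients = res, n = length(y), df = df,
                 n_boot = n_boot, radius_km = radius_km,
                 separation = full$separation),
            class = "br_boundary_fit")
}

#' @export
print.br_boundary_fit <- function(x, ...) {
  cat(sprintf("<br_boundary_fit> n = %d cells, %d bootstrap reps, radius %g km%s\n",
              x$n, x$n_boot, x$radius_km,
              if (x$separation) " (penalized)" else ""))
  print(x$coefficients[, c("term", "estimate", "t_value", "fisher_z",
                           "z_ci_low", "z_ci_high", "significant")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fisher's z effect size from a t statistic
#'
#' Converts a regression t-value with `df` residual degrees of freedom to
#' a correlation r = sign(t) sqrt(t^2 / (t^2 + df)) and then to Fisher's
#' z = atanh(r), a sample-size-independent effect size; the standard error
#' is 1/sqrt(n - 3) with n = df + 2.
#'
#' @param t_value t statistic.
#' @param df Residual degrees of freedom (>= 3... the se needs n > 3).
#' @return List with `z` and `se`.
#' @examples
#' fisher_z(2, 100)
#' @export
fisher_z <- function(t_value, df) {
  if (df < 3) stop("invalid-argument: df must be >= 3", call. = FALSE)
  r <- sign(t_value) * sqrt(t_value^2 / (t_value^2 + df))
  list(z = atanh(r), se = 1 / sqrt(df + 2 - 3))
}
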