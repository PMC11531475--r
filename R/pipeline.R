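#' Default pipeline configuration
#'
#' Returns the full configuration with defaults mirroring the analysis'
#' printed settings: 0.85 / 0.90 explained-dissimilarity thresholds for
#' realms / regions, 200-km boundary buffers, a 283-km model neighborhood,
#' and 1000 / 200 bootstrap replicates for effect sizes / the boundary
#' model.  Scenario ids emulate the four SSP emission pathways over four
#' time horizons; the default list keeps one horizon per mode so the
#' default run stays small.
#'
#' @param ... Named overrides of top-level keys (unknown keys rejected).
#' @return A validated `"br_config"` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 42L,
    grid = list(nx = 20L, ny = 20L, cell_size_km = 100),
    landscape = list(smoothness = 3, n_timesteps = 66),
    phylogeny = list(n_tips = 100L),
    ranges = list(n_regions = 4L, n_species = 80L, occupancy = 0.75,
                  clade_fidelity = 0.9, spillover = 0),
    scenarios = list(
      list(mode = "expand",   magnitude = 4,   horizon = "T1", ssp = "SSP126"),
      list(mode = "shift",    magnitude = 3,   horizon = "T2", ssp = "SSP245"),
      list(mode = "contract", magnitude = 0.3, horizon = "T4", ssp = "SSP585")
    ),
    metric = "simpson",
    realm_threshold = 0.85,
    region_threshold = 0.90,
    buffer_km = 200,
    radius_km = 283,
    n_boot_effects = 1000L,
    n_boot_model = 200L
  )
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]   # whole-key replacement
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Schema validation: unknown keys (top level and nested) are rejected,
#' required keys and value ranges are checked.
#'
#' @param cfg A configuration list (e.g. from [read_config()]).
#' @return The config, classed `"br_config"`.
#' @export
validate_config <- function(cfg) {
  schema <- list(
    seed = "count", grid = c("nx", "ny", "cell_size_km"),
    landscape = c("smoothness", "n_timesteps"),
    phylogeny = "n_tips",
    ranges = c("n_regions", "n_species", "occupancy", "clade_fidelity",
               "spillover"),
    scenarios = NA, metric = "flag", realm_threshold = "unit",
    region_threshold = "unit", buffer_km = "pos", radius_km = "pos",
    n_boot_effects = "count", n_boot_model = "count")
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(names(schema), names(cfg))
  if (length(missing)) {
    stop("config error: missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (grp in c("grid", "landscape", "phylogeny", "ranges")) {
    bad <- setdiff(names(cfg[[grp]]), schema[[grp]])
    if (length(bad)) {
      stop("config error: unknown key(s) in ", grp, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    lack <- setdiff(schema[[grp]], names(cfg[[grp]]))
    if (length(lack)) {
      stop("config error: missing key(s) in ", grp, ": ",
           paste(lack, collapse = ", "), call. = FALSE)
    }
  }
  if (!cfg$metric %in% c("simpson", "sorensen")) {
    stop("config error: metric must be simpson or sorensen", call. = FALSE)
  }
  if (!(cfg$realm_threshold < cfg$region_threshold)) {
    stop("config error: realm_threshold must be < region_threshold",
         call. = FALSE)
  }
  for (sc in cfg$scenarios) {
    if (!all(c("mode", "magnitude", "horizon", "ssp") %in% names(sc))) {
      stop("config error: each scenario needs mode, magnitude, horizon, ssp",
           call. = FALSE)
    }
    if (!sc$mode %in% c("contract", "expand", "shift")) {
      stop("config error: bad scenario mode '", sc$mode, "'", call. = FALSE)
    }
  }
  structure(cfg, class = c("br_config", "list"))
}

#' Read / write a pipeline config as JSON
#'
#' @param path JSON file.
#' @return `read_config()`: a validated `br_config`.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE))
}

#' @rdname read_config
#' @param cfg A `br_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# dissimilarity + regionalization for one community (shared stage logic)
.analyze_community <- function(cm_full, tree, metric, realm_threshold,
                               region_threshold) {
  de <- drop_empty(cm_full)
  d <- pairwise_beta(de$community, tree, metric = metric)
  reg <- regionalize(d, realm_threshold, region_threshold)
  list(dissim = d, regionalization = reg, dropped = de$dropped_cells)
}

#' Run the full pipeline from one configuration
#'
#' Synthesizes the world (phylogeny, landscape, ranges), applies every
#' configured future scenario, and for the present and each future:
#' builds the community, computes phylogenetic beta diversity,
#' regionalizes (realms + regions), extracts buffer-sum boundaries and
#' distance fields.  Also fits the boundary-determinant model for the
#' present.  All artifacts are written to `outdir` as plain text plus a
#' JSON manifest; a rerun with the same config reproduces them exactly.
#'
#' @param cfg A `br_config` (see [default_config()]).
#' @param outdir Output directory.
#' @param quiet Suppress stage logging.
#' @return (Invisibly) a `"br_run"` list with all in-memory stage results
#'   and `manifest_path`.
#' @export
run_pipeline <- function(cfg, outdir, quiet = FALSE) {
  cfg <- validate_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_ <- function(...) if (!quiet) message(sprintf(...))

  log_("[synth] %d tips, %dx%d grid", cfg$phylogeny$n_tips,
       cfg$grid$nx, cfg$grid$ny)
  tree <- generate_phylogeny(cfg$phylogeny$n_tips, seed = cfg$seed)
  land <- generate_landscape(cfg$grid$nx, cfg$grid$ny, cfg$grid$cell_size_km,
                             smoothness = cfg$landscape$smoothness,
                             seed = cfg$seed,
                             n_timesteps = cfg$landscape$n_timesteps)
  sc <- generate_ranges(tree, land, cfg$ranges$n_regions,
                        cfg$ranges$n_species, cfg$ranges$occupancy,
                        cfg$ranges$clade_fidelity, seed = cfg$seed,
                        spillover = cfg$ranges$spillover)
  for (i in seq_along(cfg$scenarios)) {
    s <- cfg$scenarios[[i]]
    sc <- apply_scenario(sc, s$mode, s$magnitude, seed = cfg$seed + i,
                         label = paste(s$horizon, s$ssp, sep = "_"))
  }
  write_scenarios(sc, file.path(outdir, "synth"))

  labels <- c("present", names(sc$futures))
  comms <- c(list(present = sc$present), sc$futures)
  results <- list()
  for (nm in labels) {
    log_("[beta+regionalize] %s", nm)
    res <- .analyze_community(comms[[nm]], sc$phylogeny, cfg$metric,
                              cfg$realm_threshold, cfg$region_threshold)
    reg <- res$regionalization
    log_("  linkage %s; k_realm=%d (%.3f), k_region=%d (%.3f), %d cells",
         reg$linkage_method, reg$k_realm, reg$explained_realm,
         reg$k_region, reg$explained_region, length(reg$cell_ids))
    bnd <- list()
    for (level in c("region", "realm")) {
      lab <- if (level == "region") reg$labels_region else reg$labels_realm
      bm <- buffer_sum_boundary(lab, sc$grid, cell_ids = reg$cell_ids,
                                buffer_km = cfg$buffer_km, level = level,
                                provenance = list(scenario = nm))
      if (any(bm$boundary)) bm <- distance_to_boundary(bm)
      bnd[[level]] <- bm
    }
    write_dissim_csv(res$dissim, file.path(outdir, paste0("dissim_", nm, ".csv")))
    write_regionalization_csv(reg, file.path(outdir, paste0("labels_", nm, ".csv")),
                              file.path(outdir, paste0("merges_", nm, ".csv")))
    write_boundary_csv(bnd$region, file.path(outdir, paste0("boundary_region_", nm, ".csv")))
    write_boundary_csv(bnd$realm, file.path(outdir, paste0("boundary_realm_", nm, ".csv")))
    results[[nm]] <- list(dissim = res$dissim, regionalization = reg,
                          boundaries = bnd)
  }

  log_("[determinants] present-day boundary model")
  pred <- build_predictors(land)
  det <- tryCatch({
    resp <- boundary_response(results$present$boundaries$region,
                              buffer_km = cfg$buffer_km)
    fit_boundary_model(resp$response, pred, sc$grid,
                       radius_km = cfg$radius_km,
                       n_boot = cfg$n_boot_model, seed = cfg$seed)
  }, error = function(e) {
    log_("  determinants skipped: %s", conditionMessage(e))
    NULL
  })
  if (!is.null(det)) {
    utils::write.csv(det$coefficients,
                     file.path(outdir, "boundary_model.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    config = unclass(cfg),
    scenarios = labels,
    cells_occupied = lapply(results, function(r) length(r$regionalization$cell_ids)),
    linkage = lapply(results, function(r) r$regionalization$linkage_method),
    k_realm = lapply(results, function(r) r$regionalization$k_realm),
    k_region = lapply(results, function(r) r$regionalization$k_region),
    files = list.files(outdir, recursive = TRUE)
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(structure(list(config = cfg, scenarios = sc, landscape = land,
                           results = results, determinants = det,
                           outdir = outdir, manifest_path = manifest_path),
                      class = "br_run"))
}

#' Restrict a dissimilarity matrix to a subset of cells
#'
#' Returns the submatrix over `ids`, in the order given — the alignment
#' step before comparing matrices computed on different occupied-cell
#' sets.
#'
#' @param d A `br_dissim`.
#' @param ids 0-based cell ids, all present in `d$cell_ids`.
#' @return A `br_dissim` over `ids`.
#' @export
subset_dissim <- function(d, ids) {
  pos <- match(ids, d$cell_ids)
  if (anyNA(pos)) stop("alignment error: cells missing from matrix", call. = FALSE)
  dissim_matrix(d$values[pos, pos, drop = FALSE], ids, d$metric, d$level)
}

#' Compare two pipeline runs (present vs future analysis)
#'
#' For a pair of analyzed scenarios: v-measure congruence of the realm and
#' region partitions (on the shared occupied cells), the spatially
#' corrected correlation of the two distance-to-boundary fields
#' (Dutilleul's modified t-test), and per-region Cohen's d of
#' within-region dissimilarity change — the homogenization /
#' differentiation table.
#'
#' @param run A `br_run` from [run_pipeline()].
#' @param a,b Scenario names in the run (default `"present"` and the first
#'   future).
#' @param n_classes Distance classes for the modified t-test.
#' @return A `"br_comparison"` list: `v_region`, `v_realm`
#'   (`br_congruence`), `boundary_cor_region`, `boundary_cor_realm`
#'   (modified t-test results), `effects` (`br_effects`).
#' @export
compare_runs <- function(run, a = "present", b = NULL, n_classes = 10) {
  stopifnot(inherits(run, "br_run"))
  if (is.null(b)) b <- setdiff(names(run$results), a)[1]
  if (!a %in% names(run$results) || !b %in% names(run$results)) {
    stop("alignment error: unknown scenario name", call. = FALSE)
  }
  ra <- run$results[[a]]; rb <- run$results[[b]]
  grid <- run$scenarios$grid
  shared <- intersect(ra$regionalization$cell_ids, rb$regionalization$cell_ids)
  ia <- match(shared, ra$regionalization$cell_ids)
  ib <- match(shared, rb$regionalization$cell_ids)
  v_region <- v_measure(ra$regionalization$labels_region[ia],
                        rb$regionalization$labels_region[ib])
  v_realm <- v_measure(ra$regionalization$labels_realm[ia],
                       rb$regionalization$labels_realm[ib])
  coords <- cbind(grid$x_km, grid$y_km)
  bcor <- list()
  for (level in c("region", "realm")) {
    da <- ra$boundaries[[level]]$distance
    db <- rb$boundaries[[level]]$distance
    bcor[[level]] <- if (is.null(da) || is.null(db)) NULL else {
      tryCatch(modified_ttest(da, db, coords, n_classes = n_classes),
               error = function(e) NULL)
    }
  }
  effects <- within_region_beta_change(
    ra$regionalization$labels_region[ia],
    subset_dissim(ra$dissim, shared), subset_dissim(rb$dissim, shared),
    n_boot = run$config$n_boot_effects, seed = run$config$seed)
  structure(list(a = a, b = b, v_region = v_region, v_realm = v_realm,
                 boundary_cor_region = bcor$region,
                 boundary_cor_realm = bcor$realm, effects = effects),
            class = "br_comparison")
}

#' @export
print.br_comparison <- function(x, ...) {
  cat(sprintf("<br_comparison> %s vs %s\n", x$a, x$b))
  cat(sprintf("  v-measure: region %.3f, realm %.3f\n",
              x$v_region$v, x$v_realm$v))
  if (!is.null(x$boundary_cor_region)) {
    cat(sprintf("  boundary-distance r (region): %.3f (ESS %.1f, p %.3g)\n",
                x$boundary_cor_region$r, x$boundary_cor_region$ess,
                x$boundary_cor_region$p))
  }
  cat(sprintf("  global Cohen's d: %.4f (p %.3g)\n",
              x$effects$global$d, x$effects$global$p_value))
  invisible(x)
}
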