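test_that("neighborhood_cv matches direct computation and flags zero means", {
  g <- make_grid(5, 5, 100)
  expect_equal(neighborhood_cv(rep(3, 25), g), rep(0, 25))

  field <- rep(1, 25); field[13] <- 9         # center cell = 9
  cv <- neighborhood_cv(field, g)
  nb <- c(field[13], field[grid_neighbors(g)[[13]] + 1L])
  expect_equal(cv[13], sd(nb) / mean(nb))

  expect_true(all(is.na(neighborhood_cv(rep(0, 25), g))))  # zero-mean flag

  # step edge: CV peaks on the step columns
  step <- ifelse((seq_len(25) - 1L) %% 5 < 2, 1, 10)
  cv_s <- neighborhood_cv(step, g)
  col <- (seq_len(25) - 1L) %% 5
  expect_gt(min(cv_s[col %in% c(1, 2)]), max(cv_s[col %in% c(0, 4)]))
})

test_that("altitude_variation is a mean absolute neighbor difference", {
  g <- make_grid(5, 5, 100)
  expect_equal(altitude_variation(rep(100, 25), g), rep(0, 25))
  e <- rep(0, 25); e[13] <- 100
  expect_equal(altitude_variation(e, g)[13], 100)

  land <- generate_landscape(15, 9, 100, smoothness = Inf, seed = 1,
                             n_timesteps = 2)
  av <- altitude_variation(land$elevation, land$grid)
  col <- (seq_len(135) - 1L) %% 15
  crest <- land$ridge_col
  flank_mean <- mean(av[col %in% c(crest - 1, crest + 1)])
  far_mean <- mean(av[col %in% c(0, 1, 13, 14)])
  expect_gt(flank_mean, far_mean)
})

test_that("tectonic_sd is zero under rigid motion and matches a hand toy", {
  g <- make_grid(4, 4, 100)
  n <- 16; T_ <- 5
  base <- array(0, c(n, T_, 2))
  base[, , 1] <- g$x_km; base[, , 2] <- g$y_km
  expect_equal(tectonic_sd(base, g), rep(0, n))     # stationary

  rigid <- base
  for (t in seq_len(T_)) {
    rigid[, t, 1] <- g$x_km + 37 * t
    rigid[, t, 2] <- g$y_km - 11 * t
  }
  expect_equal(tectonic_sd(rigid, g), rep(0, n))    # common translation

  # 2x1 world, two timesteps, one neighbor moves 100 km away
  g2 <- make_grid(2, 1, 100)
  tr <- array(0, c(2, 2, 2))
  tr[1, , 1] <- c(50, 50);   tr[1, , 2] <- c(50, 50)
  tr[2, , 1] <- c(150, 250); tr[2, , 2] <- c(50, 50)
  expect_equal(tectonic_sd(tr, g2), rep(sd(c(100, 200)), 2))

  expect_error(tectonic_sd(array(0, c(16, 1, 2)), g), "invalid-argument")
  expect_error(tectonic_sd(array(0, c(3, 5, 2)), g), "invalid-argument")
})

test_that("vif matches closed forms and flags collinearity", {
  set.seed(13)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  expect_true(all(abs(vif(data.frame(x1, x2)) -
                        1 / (1 - cor(x1, x2)^2)) < 1e-12))
  # exact r = 0.6 via constructed columns
  a <- scale(rnorm(n))[, 1]
  b <- scale(resid(lm(rnorm(n) ~ a)))[, 1]
  y <- 0.6 * a + sqrt(1 - 0.36) * b
  expect_equal(unname(vif(data.frame(a, y))), rep(1 / (1 - 0.36), 2),
               tolerance = 1e-10)
  expect_true(all(is.infinite(vif(data.frame(a, a2 = 2 * a)))))
  expect_error(vif(data.frame(a)), "invalid-argument")
  expect_error(vif(data.frame(a, k = rep(1, n))), "invalid-argument")
})

test_that("boundary_response codes YES/NO bands with the right geometry", {
  g <- make_grid(16, 4, 100)
  lab <- ifelse((seq_len(64) - 1L) %% 16 < 8, 1L, 2L)
  bm <- buffer_sum_boundary(lab, g, buffer_km = 200)   # boundary cols 6..9
  resp <- boundary_response(bm, buffer_km = 200)
  yes_cols <- unique((which(resp$response == 1) - 1L) %% 16)
  no_cols <- unique((which(resp$response == 0) - 1L) %% 16)
  expect_setequal(yes_cols, 6:9)
  expect_setequal(no_cols, c(4, 5, 10, 11))
  expect_true(all(is.na(resp$response[!resp$mask])))

  all_yes <- structure(list(grid = g, boundary = rep(TRUE, 64),
                            distance = NULL, level = "region",
                            provenance = list()),
                       class = "br_boundary")
  expect_error(boundary_response(all_yes), "degenerate-response")
})

test_that("fisher_z matches its closed form and round-trips", {
  expect_equal(fisher_z(0, 10)$z, 0)
  r <- sqrt(4 / 104)
  expect_equal(fisher_z(2, 100)$z, atanh(r), tolerance = 1e-10)
  expect_equal(fisher_z(2, 100)$se, 1 / sqrt(99))
  for (t in c(-3, 0.5, 7)) {
    z <- fisher_z(t, 40)$z
    r_back <- tanh(z)
    expect_equal(r_back, sign(t) * sqrt(t^2 / (t^2 + 40)), tolerance = 1e-12)
  }
  expect_error(fisher_z(1, 2), "invalid-argument")
})

test_that("fit_boundary_model is seed-stable and finds a planted signal", {
  land <- generate_landscape(20, 12, 100, smoothness = 3, seed = 31,
                             n_timesteps = 6)
  g <- land$grid
  lab <- ifelse((seq_len(g$n_cells) - 1L) %% 20 <= land$ridge_col, 1L, 2L)
  bm <- buffer_sum_boundary(lab, g, buffer_km = 200)
  resp <- boundary_response(bm)
  pred <- build_predictors(land)
  f1 <- fit_boundary_model(resp$response, pred, g, n_boot = 60, seed = 5)
  f2 <- fit_boundary_model(resp$response, pred, g, n_boot = 60, seed = 5)
  expect_identical(f1$coefficients, f2$coefficients)

  alt <- f1$coefficients[f1$coefficients$term == "altitude_var", ]
  expect_gt(alt$fisher_z, 0)
  expect_gt(alt$z_ci_low, 0)
  expect_true(alt$significant)
})

test_that("standardization invariance: affine predictor rescaling is inert", {
  land <- generate_landscape(14, 10, 100, smoothness = 3, seed = 37,
                             n_timesteps = 4)
  lab <- ifelse((seq_len(140) - 1L) %% 14 <= land$ridge_col, 1L, 2L)
  resp <- boundary_response(buffer_sum_boundary(lab, land$grid))
  p1 <- build_predictors(land)
  land2 <- land
  land2$elevation <- 3.28 * land$elevation + 1000    # feet + offset
  p2 <- build_predictors(land2)
  f1 <- fit_boundary_model(resp$response, p1, land$grid, n_boot = 10, seed = 2)
  f2 <- fit_boundary_model(resp$response, p2, land$grid, n_boot = 10, seed = 2)
  expect_equal(f2$coefficients$fisher_z[f2$coefficients$term == "altitude_var"],
               f1$coefficients$fisher_z[f1$coefficients$term == "altitude_var"],
               tolerance = 1e-6)
})
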