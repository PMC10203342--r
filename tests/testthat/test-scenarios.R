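# shared fixture: a monocentric, sparsely vegetated (arid-type) city —
# observed NDVI well below the 0.85 cap, so increments up to 0.5 rarely
# truncate and the exposure response stays in its near-linear regime
scenario_fixture <- function(seed = 80, n = 16) {
  sc <- synthetic_city(synthetic_config(n_rows = n, n_cols = n, seed = seed,
                                        ndvi_range = c(0.05, 0.35)))
  g <- sc$grid
  rows <- !g$is_water & !is.na(g$ndvi)
  X <- cbind(intercept = 1, ndvi = g$ndvi[rows], d_w = g$d_w[rows])
  m_day <- slm_fit_ml(X, g$days_day[rows], sc$w, feature_names = colnames(X))
  m_night <- slm_fit_ml(X, g$days_night[rows], sc$w,
                        feature_names = colnames(X))
  m_day$pixels <- g$pixel_id[rows]
  m_night$pixels <- g$pixel_id[rows]
  list(grid = g, w = sc$w, m_day = m_day, m_night = m_night)
}

test_that("uniform increments respect the cap and never touch water", {
  g <- city_grid(tibble::tibble(pixel_id = 1:4, row = 1L, col = 1:4,
                                x = (1:4) * 1000 - 500, y = 500,
                                population = 10, ndvi = c(0.5, 0.7, 0.9, 0.3),
                                is_water = c(FALSE, FALSE, FALSE, TRUE)),
                 n_rows = 1, n_cols = 4)
  g1 <- apply_uniform_increment(g, 0.3, cap = 0.85)
  expect_equal(g1$ndvi, c(0.8, 0.85, 0.9, 0.3))
  expect_error(apply_uniform_increment(g, -0.1), "delta")
})

test_that("top-population selection is the minimal descending prefix", {
  g <- city_grid(tibble::tibble(pixel_id = 1:4, row = 1L, col = 1:4,
                                x = (1:4) * 1000 - 500, y = 500,
                                population = c(60, 25, 10, 5), ndvi = 0.5),
                 n_rows = 1, n_cols = 4)
  expect_identical(select_top_population(g, 0.8), 1:2)  # 85 >= 80

  gu <- city_grid(tibble::tibble(pixel_id = 1:10, row = 1L, col = 1:10,
                                 x = (1:10) * 1000 - 500, y = 500,
                                 population = 50, ndvi = 0.5),
                  n_rows = 1, n_cols = 10)
  expect_length(select_top_population(gu, 0.8), 8)

  set.seed(81)
  gr <- city_grid(tibble::tibble(pixel_id = 1:30, row = 1L, col = 1:30,
                                 x = (1:30) * 1000 - 500, y = 500,
                                 population = rpois(30, 40), ndvi = 0.5),
                  n_rows = 1, n_cols = 30)
  sel <- select_top_population(gr, 0.8)
  # oracle: every descending-population prefix shorter than the returned
  # set misses the share; the returned set reaches it
  ord <- order(-gr$population, gr$pixel_id)
  cum <- cumsum(gr$population[ord])
  total <- sum(gr$population)
  expect_identical(sort(sel), sort(gr$pixel_id[ord[seq_along(sel)]]))
  expect_gte(cum[length(sel)], 0.8 * total)
  expect_lt(cum[length(sel) - 1], 0.8 * total)
})

test_that("predicted exposure vanishes without population and matches longhand at rho 0", {
  fx <- scenario_fixture()
  g0 <- fx$grid
  g0$population <- 0
  g0 <- set_city_meta(g0, city_meta(g0))
  expect_equal(predicted_total_exposure(g0, fx$m_day, fx$m_night, fx$w), 0)

  # 4-pixel longhand check with rho = 0 models
  g4 <- city_grid(tibble::tibble(pixel_id = 1:4, row = c(1, 1, 2, 2),
                                 col = c(1, 2, 1, 2),
                                 x = c(500, 1500, 500, 1500),
                                 y = c(500, 500, 1500, 1500),
                                 population = c(10, 20, 30, 40),
                                 ndvi = c(0.2, 0.4, 0.6, 0.8),
                                 d_w = c(1, 0.5, 0.25, 0.1)),
                  n_rows = 2, n_cols = 2)
  w4 <- knn_weights(cbind(g4$x, g4$y), k = 3)
  bd <- c(10, -4, -1)
  bn <- c(8, -2, -0.5)
  md <- structure(list(beta = bd, rho = 0, pixels = 1:4), class = "slm_model")
  mn <- structure(list(beta = bn, rho = 0, pixels = 1:4), class = "slm_model")
  te <- predicted_total_exposure(g4, md, mn, w4)
  X <- cbind(1, g4$ndvi, g4$d_w)
  manual <- sum(g4$population * (X %*% bd + X %*% bn) / 2)
  expect_equal(te, manual, tolerance = 1e-10)
})

test_that("greening any pixel lowers predicted exposure under negative beta", {
  fx <- scenario_fixture()
  te0 <- predicted_total_exposure(fx$grid, fx$m_day, fx$m_night, fx$w)
  g1 <- fx$grid
  pick <- which(!g1$is_water & g1$ndvi < 0.8)[10]
  g1$ndvi[pick] <- g1$ndvi[pick] + 0.05
  g1 <- set_city_meta(g1, city_meta(g1))
  te1 <- predicted_total_exposure(g1, fx$m_day, fx$m_night, fx$w)
  expect_lt(te1, te0)
})

test_that("relative exposure change follows its defining formula", {
  expect_equal(delta_te(164e6, 144e6), 100 * (144 - 164) / 164)
  expect_equal(round(abs(delta_te(164e6, 144e6)), 1), 12.2)
  expect_equal(delta_te(200, 150), -25)
  expect_equal(delta_te(7, 7), 0)
  expect_true(is.na(delta_te(0, 5)))
})

test_that("the targeted solver hits a null target, a linear closed form, and a dense scan", {
  fx <- scenario_fixture()
  target <- select_top_population(fx$grid, 0.8)

  sol0 <- solve_targeted_increment(fx$grid, fx$m_day, fx$m_night, fx$w,
                                   target, 0)
  expect_equal(sol0$delta_local, 0)

  # rho = 0, no pixel hits the cap: TE is exactly linear in delta, so
  # delta* = (pct/100) * TE0 / sum_target(pop * (bd_ndvi + bn_ndvi) / 2)
  g4 <- city_grid(tibble::tibble(pixel_id = 1:4, row = c(1, 1, 2, 2),
                                 col = c(1, 2, 1, 2),
                                 x = c(500, 1500, 500, 1500),
                                 y = c(500, 500, 1500, 1500),
                                 population = c(10, 20, 30, 40),
                                 ndvi = c(0.2, 0.3, 0.4, 0.2),
                                 d_w = c(1, 0.5, 0.25, 0.1)),
                  n_rows = 2, n_cols = 2)
  w4 <- knn_weights(cbind(g4$x, g4$y), k = 3)
  md <- structure(list(beta = c(10, -4, -1), rho = 0, pixels = 1:4),
                  class = "slm_model")
  mn <- structure(list(beta = c(8, -2, -0.5), rho = 0, pixels = 1:4),
                  class = "slm_model")
  te0 <- predicted_total_exposure(g4, md, mn, w4)
  tgt <- 4L  # single target pixel
  pct <- -2
  sol <- solve_targeted_increment(g4, md, mn, w4, tgt, pct)
  delta_closed <- (pct / 100) * te0 / (40 * (-4 + -2) / 2)
  expect_equal(sol$delta_local, delta_closed, tolerance = 1e-4)

  # dense scan oracle on the monocentric city
  uni <- scenario_uniform(fx$grid, fx$m_day, fx$m_night, fx$w, 0.2)
  sol2 <- solve_targeted_increment(fx$grid, fx$m_day, fx$m_night, fx$w,
                                   target, uni$delta_te_pct)
  deltas <- seq(0, 0.85, by = 1e-4)
  te_at <- function(d) {
    g1 <- apply_uniform_increment(fx$grid, d, 0.85, target)
    predicted_total_exposure(g1, fx$m_day, fx$m_night, fx$w)
  }
  te0m <- predicted_total_exposure(fx$grid, fx$m_day, fx$m_night, fx$w)
  scan <- vapply(deltas, function(d) delta_te(te0m, te_at(d)), numeric(1))
  first_cross <- deltas[which(scan <= uni$delta_te_pct)[1]]
  expect_lt(abs(sol2$delta_local - first_cross), 2e-4)

  # achieved change within 1e-4 percentage points of the target
  expect_lt(abs(sol2$result$delta_te_pct - uni$delta_te_pct), 1e-4)
})

test_that("an unreachable target returns an infeasibility result, not an error", {
  fx <- scenario_fixture()
  target <- select_top_population(fx$grid, 0.8)
  sol <- solve_targeted_increment(fx$grid, fx$m_day, fx$m_night, fx$w,
                                  target, -95)
  expect_false(sol$feasible)
  expect_true(is.na(sol$delta_local))
  expect_lt(sol$best_achievable_pct, 0)
  expect_false(sol$result$feasible)
})

test_that("NDVI savings follow the printed formula with the magnitude alongside", {
  mk <- function(nd) city_grid(tibble::tibble(pixel_id = 1:2, row = 1L,
                                              col = 1:2, x = c(500, 1500),
                                              y = 500, population = 1,
                                              ndvi = nd),
                               n_rows = 1, n_cols = 2)
  s <- ndvi_savings(mk(c(100, 100)), mk(c(80, 80)))
  expect_equal(s$savings_formula_pct, -20)
  expect_equal(s$savings_pct, 20)
  s0 <- ndvi_savings(mk(c(0.4, 0.6)), mk(c(0.4, 0.6)))
  expect_equal(s0$savings_formula_pct, 0)
})

test_that("targeted greening saves vegetation on a monocentric city", {
  fx <- scenario_fixture()
  target <- select_top_population(fx$grid, 0.8)
  uni <- scenario_uniform(fx$grid, fx$m_day, fx$m_night, fx$w, 0.3)
  sol <- solve_targeted_increment(fx$grid, fx$m_day, fx$m_night, fx$w,
                                  target, uni$delta_te_pct)
  expect_true(sol$feasible)
  g_uni <- apply_uniform_increment(fx$grid, 0.3)
  g_tar <- apply_uniform_increment(fx$grid, sol$delta_local, 0.85, target)
  sav <- ndvi_savings(g_uni, g_tar)
  expect_gt(sav$savings_pct, 0)
  expect_lt(sav$savings_formula_pct, 0)  # targeting adds less total NDVI
})

test_that("the scenario engine never touches population, water or distances", {
  fx <- scenario_fixture()
  g1 <- apply_uniform_increment(fx$grid, 0.4)
  expect_identical(g1$population, fx$grid$population)
  expect_identical(g1$d_w, fx$grid$d_w)
  expect_identical(g1$D_w, fx$grid$D_w)
  expect_identical(g1$is_water, fx$grid$is_water)
  expect_identical(g1$ndvi[g1$is_water], fx$grid$ndvi[fx$grid$is_water])
})

test_that("targeting every pixel reduces to the uniform scenario", {
  fx <- scenario_fixture()
  g_uni <- apply_uniform_increment(fx$grid, 0.25)
  g_all <- apply_uniform_increment(fx$grid, 0.25,
                                   target_pixels = fx$grid$pixel_id)
  expect_identical(tibble::as_tibble(g_uni), tibble::as_tibble(g_all))
})

test_that("the increment sweep is monotone, near-linear and self-consistent", {
  fx <- scenario_fixture()
  sw <- sweep_increments(fx$grid, fx$m_day, fx$m_night, fx$w,
                         deltas = seq(0.1, 0.5, by = 0.1))
  expect_true(all(sw$feasible))
  # stronger treatments reduce exposure at least as much
  expect_true(all(diff(abs(sw$delta_te_pct)) >= 0))
  # near-linear exposure response to the increment
  expect_gt(cor(sw$delta_global, sw$delta_te_pct)^2, 0.99)
  # a single-delta sweep row agrees with the individual operations
  one <- sweep_increments(fx$grid, fx$m_day, fx$m_night, fx$w, deltas = 0.1)
  uni <- scenario_uniform(fx$grid, fx$m_day, fx$m_night, fx$w, 0.1)
  expect_equal(one$delta_te_pct, uni$delta_te_pct)
  sol <- solve_targeted_increment(fx$grid, fx$m_day, fx$m_night, fx$w,
                                  select_top_population(fx$grid, 0.8),
                                  uni$delta_te_pct)
  expect_equal(one$delta_local, sol$delta_local, tolerance = 1e-8)
})
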