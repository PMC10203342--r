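#' Apply a uniform NDVI increment
#'
#' Counterfactual greening: every eligible pixel's NDVI rises by `delta`,
#' capped at `cap` (default 0.85 — a practical ceiling on how green a
#' 1 km cell can get). Pixels already at or above the cap, water pixels,
#' and pixels with missing NDVI are untouched. Population and the
#' distance-to-water features are never modified by the scenario engine.
#'
#' @param grid A `city_grid`.
#' @param delta NDVI increment, >= 0 (decrements are out of scope).
#' @param cap NDVI ceiling in (0, 1].
#' @param target_pixels Optional vector of pixel ids; when supplied the
#'   increment applies only there (targeted greening).
#' @return The modified `city_grid`.
#' @export
#' @examples
#' g <- synthetic_city(synthetic_config(n_rows = 8, n_cols = 8, seed = 1))$grid
#' g1 <- apply_uniform_increment(g, 0.3)
apply_uniform_increment <- function(grid, delta, cap = 0.85,
                                    target_pixels = NULL) {
  stopifnot(inherits(grid, "city_grid"))
  if (delta < 0) abort("apply_uniform_increment: delta must be >= 0")
  if (cap <= 0 || cap > 1) abort("apply_uniform_increment: cap must be in (0, 1]")
  eligible <- !grid$is_water & !is.na(grid$ndvi) & grid$ndvi < cap
  if (!is.null(target_pixels)) {
    eligible <- eligible & grid$pixel_id %in% target_pixels
  }
  grid$ndvi[eligible] <- pmin(grid$ndvi[eligible] + delta, cap)
  set_city_meta(grid, city_meta(grid))
}

#' Pixels holding a population share
#'
#' Sorts pixels by population descending (ties broken by ascending pixel
#' id) and returns the smallest prefix whose cumulative population
#' reaches `share` of the city total — the "most populated areas" used by
#' targeted greening, with the default 80% share.
#'
#' @param grid A `city_grid`.
#' @param share Cumulative population share in (0, 1] (default 0.8).
#' @return Integer vector of pixel ids.
#' @export
select_top_population <- function(grid, share = 0.8) {
  stopifnot(inherits(grid, "city_grid"))
  if (share <= 0 || share > 1) {
    abort("select_top_population: share must be in (0, 1]")
  }
  total <- sum(grid$population)
  if (total <= 0) abort("select_top_population: total population is zero")
  ord <- order(-grid$population, grid$pixel_id)
  cum <- cumsum(grid$population[ord])
  n_keep <- which(cum >= share * total)[1]
  grid$pixel_id[ord[seq_len(n_keep)]]
}

#' Model-predicted total exposure of a (counterfactual) grid
#'
#' Predicts day and night exceedance counts for the grid's modelling
#' pixels through the fitted spatial lag models' reduced form (clipped to
#' the physical count range) and returns the total exposure
#' TE_T = sum over pixels of population x (yhat_day + yhat_night) / 2,
#' in person-days.
#'
#' Both models must have been fitted on the same pixel set, in the order
#' of `w`; the grid may be any counterfactual modification of that city
#' that leaves pixel ids in place.
#'
#' @param grid A `city_grid` (observed or modified).
#' @param model_day,model_night Fitted `slm_model`s with a `pixels`
#'   element (as returned by [fit_exceedance_slm()]).
#' @param w The `spatial_weights` the models were fitted with.
#' @param verbose Report prediction clipping (default FALSE).
#' @return Scalar TE_T in person-days.
#' @export
predicted_total_exposure <- function(grid, model_day, model_night, w,
                                     verbose = FALSE) {
  ids <- model_day$pixels %||% grid$pixel_id[!grid$is_water & !is.na(grid$ndvi)]
  rows <- match(ids, grid$pixel_id)
  use_dw <- length(model_day$beta) == 3
  X <- slm_design(grid, rows, use_dw = use_dw)
  L <- city_meta(grid)$season_length
  yd <- slm_predict(model_day, X, w, clip = c(0, L), verbose = verbose)
  yn <- slm_predict(model_night, X, w, clip = c(0, L), verbose = verbose)
  sum(grid$population[rows] * (yd + yn) / 2)
}

#' Relative exposure change
#'
#' Delta TE (%) = 100 (TE1 - TE0) / TE0: negative for a reduction.
#' Summaries usually quote the magnitude.
#'
#' @param te0 Exposure before the intervention (> 0).
#' @param te1 Exposure after.
#' @return Signed percent change, `NA` when `te0` is zero.
#' @export
delta_te <- function(te0, te1) {
  if (is.na(te0) || te0 == 0) return(NA_real_)
  100 * (te1 - te0) / te0
}

new_scenario_result <- function(mode, delta, cap, target_pixels,
                                te0, te1, grid0, grid1, feasible = TRUE) {
  s0 <- sum(grid0$ndvi, na.rm = TRUE)
  s1 <- sum(grid1$ndvi, na.rm = TRUE)
  out <- tibble::tibble(
    mode = mode,
    delta_applied = delta,
    ndvi_cap = cap,
    n_target = if (is.null(target_pixels)) NA_integer_ else length(target_pixels),
    te0 = te0, te1 = te1,
    delta_te_pct = delta_te(te0, te1),
    ndvi_sum_before = s0, ndvi_sum_after = s1,
    global_increment_pct = if (s0 > 0) 100 * (s1 - s0) / s0 else NA_real_,
    feasible = feasible)
  attr(out, "target_pixels") <- target_pixels
  class(out) <- c("scenario_result", class(out))
  out
}

#' Uniform greening scenario
#'
#' Scenario 1: raise NDVI by `delta` at every eligible pixel (cap rule of
#' [apply_uniform_increment()]) and evaluate the exposure change through
#' the fitted models. The baseline TE0 is the model-predicted exposure on
#' the observed features, so the reported change reflects only the
#' counterfactual, not residual offsets.
#'
#' @inheritParams predicted_total_exposure
#' @param delta NDVI increment.
#' @param cap NDVI ceiling (default 0.85).
#' @return A `scenario_result` tibble row (with the target pixel set as
#'   an attribute for targeted runs).
#' @export
scenario_uniform <- function(grid, model_day, model_night, w, delta,
                             cap = 0.85) {
  te0 <- predicted_total_exposure(grid, model_day, model_night, w)
  g1 <- apply_uniform_increment(grid, delta, cap)
  te1 <- predicted_total_exposure(g1, model_day, model_night, w)
  new_scenario_result("uniform", delta, cap, NULL, te0, te1, grid, g1)
}

#' Targeted increment matching a reference exposure reduction
#'
#' Scenario 2: finds the increment `delta_local`, applied only on
#' `target_pixels` (cap rule unchanged), whose exposure change equals
#' `target_delta_te`. Because predicted exposure is monotone
#' non-increasing in the increment, the root is isolated up to flat
#' cap-saturated stretches; bisection on \[0, cap\] returns the smallest
#' root, to relative tolerance 1e-6. An unreachable target (even at the
#' full cap) yields an infeasibility result reporting the best achievable
#' change — never an exception.
#'
#' @inheritParams scenario_uniform
#' @param target_pixels Pixel ids eligible for greening (typically
#'   [select_top_population()]).
#' @param target_delta_te Required signed exposure change in percent
#'   (negative: a reduction).
#' @param tol Relative bisection tolerance on delta (default 1e-6).
#' @return List with `delta_local`, `feasible`, `best_achievable_pct`,
#'   and `result` (a `scenario_result` at the returned increment).
#' @export
solve_targeted_increment <- function(grid, model_day, model_night, w,
                                     target_pixels, target_delta_te,
                                     cap = 0.85, tol = 1e-6) {
  if (target_delta_te > 0) {
    abort("solve_targeted_increment: target must be a reduction (<= 0)")
  }
  te0 <- predicted_total_exposure(grid, model_day, model_night, w)
  change_at <- function(delta) {
    g1 <- apply_uniform_increment(grid, delta, cap, target_pixels)
    list(grid = g1,
         te1 = predicted_total_exposure(g1, model_day, model_night, w))
  }
  eval_pct <- function(delta) delta_te(te0, change_at(delta)$te1)

  if (target_delta_te == 0) {
    at <- change_at(0)
    return(list(delta_local = 0, feasible = TRUE,
                best_achievable_pct = eval_pct(cap),
                result = new_scenario_result("targeted", 0, cap,
                                             target_pixels, te0, at$te1,
                                             grid, at$grid)))
  }

  best <- eval_pct(cap)
  if (best > target_delta_te) {
    at <- change_at(cap)
    return(list(delta_local = NA_real_, feasible = FALSE,
                best_achievable_pct = best,
                result = new_scenario_result("targeted", cap, cap,
                                             target_pixels, te0, at$te1,
                                             grid, at$grid,
                                             feasible = FALSE)))
  }

  lo <- 0      # change(lo) >= target
  hi <- cap    # change(hi) <= target
  while (hi - lo > tol * max(cap, 1e-12)) {
    mid <- (lo + hi) / 2
    if (eval_pct(mid) <= target_delta_te) hi <- mid else lo <- mid
  }
  delta_local <- hi  # smallest increment achieving the target
  at <- change_at(delta_local)
  list(delta_local = delta_local, feasible = TRUE,
       best_achievable_pct = best,
       result = new_scenario_result("targeted", delta_local, cap,
                                    target_pixels, te0, at$te1,
                                    grid, at$grid))
}

#' Vegetation savings of targeted versus uniform greening
#'
#' Computes 100 (NDVI_80 - NDVI_all) / NDVI_all on the city-wide NDVI
#' sums after the two interventions, where NDVI_all is the sum after
#' greening the whole city and NDVI_80 the sum after greening only the
#' most populated pixels to the same exposure reduction. The formula
#' yields a negative value when targeting adds less total vegetation; the
#' magnitude is reported alongside as the savings.
#'
#' @param grid_uniform_after `city_grid` after the uniform increment.
#' @param grid_targeted_after `city_grid` after the targeted increment.
#' @return Tibble with `savings_formula_pct` (signed, as printed) and
#'   `savings_pct` (magnitude).
#' @export
ndvi_savings <- function(grid_uniform_after, grid_targeted_after) {
  s_all <- sum(grid_uniform_after$ndvi, na.rm = TRUE)
  s_80 <- sum(grid_targeted_after$ndvi, na.rm = TRUE)
  if (s_all == 0) {
    return(tibble::tibble(savings_formula_pct = NA_real_,
                          savings_pct = NA_real_))
  }
  v <- 100 * (s_80 - s_all) / s_all
  tibble::tibble(savings_formula_pct = v, savings_pct = abs(v))
}

#' Increment sweep: uniform versus targeted greening
#'
#' For each global increment delta, evaluates the uniform scenario,
#' solves the targeted increment matching its exposure reduction on the
#' top-population pixel set, and tabulates the exposure change, the local
#' increment, the vegetation savings and the local-minus-global increment
#' difference. Infeasible targets carry the infeasibility flag rather
#' than silent `NA`s.
#'
#' @inheritParams scenario_uniform
#' @param deltas Global increments to sweep (default 0.1-0.5 in steps of
#'   0.1).
#' @param share Population share defining the targeted pixel set
#'   (default 0.8).
#' @return A tibble of class `sweep_table`, one row per delta, with
#'   `city`, `climate_zone`, `delta_global`, `delta_te_pct`,
#'   `delta_local`, `savings_formula_pct`, `savings_pct`,
#'   `local_minus_global`, `feasible`.
#' @export
sweep_increments <- function(grid, model_day, model_night, w,
                             deltas = seq(0.1, 0.5, by = 0.1),
                             share = 0.8, cap = 0.85) {
  stopifnot(all(deltas > 0), all(deltas <= cap))
  meta <- city_meta(grid)
  target <- select_top_population(grid, share)
  rows <- purrr::map(deltas, function(d) {
    uni <- scenario_uniform(grid, model_day, model_night, w, d, cap)
    sol <- solve_targeted_increment(grid, model_day, model_night, w,
                                    target, uni$delta_te_pct, cap)
    g_uni <- apply_uniform_increment(grid, d, cap)
    g_tar <- if (sol$feasible) {
      apply_uniform_increment(grid, sol$delta_local, cap, target)
    } else {
      apply_uniform_increment(grid, cap, cap, target)
    }
    sav <- ndvi_savings(g_uni, g_tar)
    tibble::tibble(
      city = meta$city_name, climate_zone = meta$climate_zone,
      delta_global = d,
      delta_te_pct = uni$delta_te_pct,
      delta_local = sol$delta_local,
      savings_formula_pct = sav$savings_formula_pct,
      savings_pct = sav$savings_pct,
      local_minus_global = sol$delta_local - d,
      feasible = sol$feasible)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_table", class(out))
  out
}
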