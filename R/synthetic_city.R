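#' Configuration for the synthetic city generator
#'
#' Collects every knob of the synthetic data-generating process: grid
#' geometry, a monocentric exponential population surface, a spatially
#' autocorrelated NDVI field, a water body, and the spatial-lag process
#' that produces warm-season exceedance counts from (NDVI, d_w). The
#' default day coefficients (-4.7, -1.2) and night coefficients
#' (-2.7, -0.6) are the fold-averaged values the exposure model recovers
#' on real multi-city data; the spatial autoregressive parameter defaults
#' to 0.5 and the noise SD to 0.5 days (repository defaults for the
#' simulation, not externally reported values).
#'
#' @param n_rows,n_cols Grid dimensions (default 40 x 40).
#' @param cell_size Cell edge in metres (default 1000).
#' @param seed Integer seed; all generator randomness flows from it.
#' @param population_total Total residents (default 1e6), conserved
#'   exactly after integerization.
#' @param population_decay_length e-folding length of the monocentric
#'   exponential population surface, metres (default 5000).
#' @param ndvi_field_length_scale Correlation length of the NDVI random
#'   field, metres (default 5000).
#' @param ndvi_range Range the NDVI field is rescaled to (default
#'   `c(0.1, 0.8)`), within \[0, 1\].
#' @param water_geometry `"edge_strip"` (one-cell strip along the left
#'   edge), `"blob"` (disc in the lower-left quadrant) or `"none"`.
#' @param dgp_beta_day,dgp_beta_night Generating coefficients
#'   `(intercept, beta_NDVI, beta_dw)` for the day and night counts.
#' @param dgp_rho Spatial autoregressive parameter, |rho| < 1.
#' @param dgp_sigma Noise SD of the count process, days.
#' @param season_length Warm-season length in days (default 92, i.e. a
#'   3-month June--August season).
#' @param n_years Years of daily LST series when one is generated.
#' @param k Neighbours of the weights used by the generating process.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 40, n_cols = 40, cell_size = 1000,
                             seed = 1L,
                             population_total = 1e6,
                             population_decay_length = 5000,
                             ndvi_field_length_scale = 5000,
                             ndvi_range = c(0.1, 0.8),
                             water_geometry = c("edge_strip", "blob", "none"),
                             dgp_beta_day = c(10, -4.7, -1.2),
                             dgp_beta_night = c(10, -2.7, -0.6),
                             dgp_rho = 0.5,
                             dgp_sigma = 0.5,
                             season_length = 92,
                             n_years = 3,
                             k = 8) {
  water_geometry <- match.arg(water_geometry)
  stopifnot(ndvi_range[1] >= 0, ndvi_range[2] <= 1,
            ndvi_range[1] < ndvi_range[2],
            abs(dgp_rho) < 1, dgp_sigma >= 0, season_length >= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Spatially autocorrelated Gaussian random field
#'
#' Smooths white noise with a Gaussian kernel by circular FFT convolution
#' and standardizes the result to zero mean and unit variance. The exact
#' covariance form is not load-bearing; only smoothness at the requested
#' length scale and bit-reproducibility under a seed are. Length scales
#' below half a cell return standardized white noise.
#'
#' @param n_rows,n_cols Field dimensions.
#' @param length_scale Correlation length in cells (> 0).
#' @param seed Integer seed.
#' @return `n_rows` x `n_cols` matrix, empirically mean 0 / SD 1.
#' @export
gaussian_random_field <- function(n_rows, n_cols, length_scale, seed) {
  if (!is.numeric(length_scale) || length_scale <= 0) {
    abort("gaussian_random_field: length_scale must be positive")
  }
  set.seed(seed)
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (length_scale < 0.5) {
    return((z - mean(z)) / sd(z))
  }
  # circularly wrapped Gaussian kernel
  dr <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dc <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * length_scale^2))
  sm <- Re(fft(fft(z) * fft(k), inverse = TRUE)) / (n_rows * n_cols)
  (sm - mean(sm)) / sd(sm)
}

#' Simulate responses from the spatial lag process
#'
#' Draws y solving (I - rho W) y = X beta + eps with eps iid
#' Normal(0, sigma^2), by sparse linear solve (never a dense inverse).
#'
#' @param X Design matrix including the intercept column.
#' @param w A row-standardized `spatial_weights` object.
#' @param beta Coefficient vector matching `ncol(X)`.
#' @param rho Spatial autoregressive parameter, |rho| < 1.
#' @param sigma Noise SD (days).
#' @param seed Integer seed.
#' @return Numeric response vector.
#' @export
slm_dgp <- function(X, w, beta, rho, sigma, seed) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(beta), nrow(X) == w$n)
  if (abs(rho) >= 1) {
    abort("slm_dgp: |rho| must be < 1 for a row-standardized W")
  }
  set.seed(seed)
  eps <- rnorm(w$n, 0, sigma)
  as.numeric(Matrix::solve(Diagonal(w$n) - rho * w$W,
                           as.numeric(X %*% beta) + eps))
}

# integerize a non-negative vector conserving its (integer) total:
# floor, then distribute the remainder to the largest fractional parts,
# ties broken by index.
integerize_conserving <- function(x, total) {
  base <- floor(x)
  deficit <- as.integer(round(total - sum(base)))
  if (deficit > 0) {
    frac_order <- order(-(x - base), seq_along(x))
    base[frac_order[seq_len(deficit)]] <- base[frac_order[seq_len(deficit)]] + 1
  }
  base
}

#' Generate a synthetic city
#'
#' Builds a complete `city_grid` with the statistical structure the
#' exposure analysis assumes: a monocentric exponential population
#' surface integerized to conserve the configured total exactly; NDVI as
#' a Gaussian random field min-max rescaled into `ndvi_range`; a water
#' body with the distance features from [distance_to_water()] and
#' [dw_feature()]; an urban-core flag (interior cells, with a 5-cell
#' buffer ring standing for the 5 km rural surround); and day/night
#' exceedance counts drawn from the spatial lag process over
#' k-nearest-neighbour weights on the land pixels, clipped to
#' \[0, season_length\] (clipping is reported — heavy clipping distorts
#' parameter recovery).
#'
#' @param config A [synthetic_config()].
#' @param lst_series Also generate a daily LST series consistent with the
#'   counts (see [synthetic_lst_series()]); default FALSE.
#' @return List with elements `grid` (a `city_grid`), `w` (the
#'   `spatial_weights` over land pixels used by the generating process)
#'   and, when requested, `lst` (an `lst_series`).
#' @export
synthetic_city <- function(config, lst_series = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$n_rows
  nc <- config$n_cols
  cs <- config$cell_size

  base <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  base <- dplyr::arrange(base, .data$row, .data$col)
  base$pixel_id <- seq_len(nrow(base))
  base$x <- (base$col - 0.5) * cs
  base$y <- (base$row - 0.5) * cs

  # water geometry
  is_water <- rep(FALSE, nrow(base))
  if (config$water_geometry == "edge_strip") {
    is_water <- base$col == 1L
  } else if (config$water_geometry == "blob") {
    cx <- 0.25 * nc * cs
    cy <- 0.25 * nr * cs
    r <- 0.12 * min(nr, nc) * cs
    is_water <- (base$x - cx)^2 + (base$y - cy)^2 <= r^2
  }
  base$is_water <- is_water

  # monocentric population, zero on water, total conserved exactly
  cx <- nc * cs / 2
  cy <- nr * cs / 2
  dist_centre <- sqrt((base$x - cx)^2 + (base$y - cy)^2)
  raw <- exp(-dist_centre / config$population_decay_length)
  raw[is_water] <- 0
  scaled <- config$population_total * raw / sum(raw)
  base$population <- integerize_conserving(scaled, config$population_total)

  # NDVI: smooth random field rescaled into ndvi_range
  fld <- gaussian_random_field(nr, nc, config$ndvi_field_length_scale / cs,
                               seed = config$seed)
  f <- fld[cbind(base$row, base$col)]
  lo <- config$ndvi_range[1]
  hi <- config$ndvi_range[2]
  ndvi <- lo + (hi - lo) * (f - min(f)) / (max(f) - min(f))
  base$ndvi <- pmin(pmax(ndvi, 0), 1)

  grid <- city_grid(base, n_rows = nr, n_cols = nc, cell_size = cs,
                    city_name = sprintf("synthetic-%d", config$seed),
                    season_length = config$season_length)
  grid <- add_water_distance(grid)

  # urban core: interior cells, leaving a 5-cell buffer ring (5 km at the
  # default cell size) as the rural reference surround
  ring <- 5L
  grid$in_urban_core <- grid$row > ring & grid$row <= nr - ring &
    grid$col > ring & grid$col <= nc - ring

  # exceedance counts from the spatial lag process over land pixels
  land <- !grid$is_water
  use_dw <- !isTRUE(city_meta(grid)$dw_excluded)
  X <- slm_design(grid, land, use_dw = use_dw)
  w <- knn_weights(cbind(grid$x, grid$y)[land, ], k = config$k)
  take <- function(beta) if (use_dw) beta else beta[1:2]
  y_day <- slm_dgp(X, w, take(config$dgp_beta_day), config$dgp_rho,
                   config$dgp_sigma, seed = config$seed + 1L)
  y_night <- slm_dgp(X, w, take(config$dgp_beta_night), config$dgp_rho,
                     config$dgp_sigma, seed = config$seed + 2L)
  clip_count <- sum(y_day < 0 | y_day > config$season_length) +
    sum(y_night < 0 | y_night > config$season_length)
  if (clip_count > 0) {
    inform(sprintf("synthetic_city: clipped %d generated count(s) to [0, %d]",
                   clip_count, config$season_length))
  }
  grid$days_day <- 0
  grid$days_night <- 0
  grid$days_day[land] <- pmin(pmax(y_day, 0), config$season_length)
  grid$days_night[land] <- pmin(pmax(y_night, 0), config$season_length)
  grid <- set_city_meta(grid, city_meta(grid))

  out <- list(grid = grid, w = w, config = config)
  if (lst_series) out$lst <- synthetic_lst_series(grid, config)
  out
}

#' Daily LST series consistent with a grid's exceedance counts
#'
#' Back-fills a daily day/night LST series whose exceedance counts, as
#' computed by [compute_thresholds()] and [count_exceedances()] at the
#' percentile stored in the result, reproduce the grid's `days_day` /
#' `days_night` up to integer rounding. Per pixel and year an integer
#' number of "hot" days is placed (the multi-year mean of the integers
#' matching the target to < 1 day); hot values are drawn well above,
#' cool values well below, a designed cut, and the reporting percentile
#' `q` is chosen so the pooled-distribution threshold falls in the gap.
#' This is a construction for exercising the exposure stack, not a
#' physical LST simulation.
#'
#' @param grid A `city_grid` with `days_day` / `days_night` filled.
#' @param config The [synthetic_config()] that produced the grid.
#' @return An `lst_series` (see [lst_series()]) with attribute `q` — the
#'   percentile at which thresholds reproduce the counts.
#' @export
synthetic_lst_series <- function(grid, config) {
  L <- config$season_length
  n_years <- config$n_years
  n_pix <- nrow(grid)
  n_dates <- L * n_years
  year <- rep(seq_len(n_years), each = L)

  set.seed(config$seed + 10L)
  fill_channel <- function(days, t_cut, spread) {
    target_total <- round(days * n_years)
    vals <- matrix(0, n_pix, n_dates)
    for (i in seq_len(n_pix)) {
      per_year <- integerize_conserving(rep(target_total[i] / n_years, n_years),
                                        target_total[i])
      hot <- logical(n_dates)
      for (yy in seq_len(n_years)) {
        if (per_year[yy] > 0) hot[(yy - 1) * L + seq_len(per_year[yy])] <- TRUE
      }
      n_hot <- sum(hot)
      vals[i, hot] <- t_cut + 1 + stats::runif(n_hot, 0, spread)
      vals[i, !hot] <- t_cut - 1 - stats::runif(n_dates - n_hot, 0, spread)
    }
    vals
  }
  day <- fill_channel(grid$days_day, t_cut = 40, spread = 4)
  night <- fill_channel(grid$days_night, t_cut = 25, spread = 4)

  # choose q so that the pooled percentile lands in the (cool, hot) gap:
  # rank r = 1 + (N - 1) q / 100 strictly between N - K and N - K + 1
  N <- length(day)
  K_day <- sum(day > 40)
  K_night <- sum(night > 25)
  q_of <- function(K) 100 * (N - K - 0.5) / (N - 1)
  q <- (q_of(K_day) + q_of(K_night)) / 2
  # per-channel exactness requires equal K; when they differ the shared q
  # must still cut both gaps, which holds when |K_day - K_night| small
  # relative to N; thresholds are computed per channel so each cut only
  # needs q to fall inside its own gap rank interval
  ser <- lst_series(day, night, year = year,
                    season = rep(TRUE, n_dates))
  attr(ser, "q_day") <- q_of(K_day)
  attr(ser, "q_night") <- q_of(K_night)
  attr(ser, "q") <- q
  ser
}
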