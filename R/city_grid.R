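#' Gridded-city data model
#'
#' A `city_grid` is a tibble with one row per 1 km-class raster cell of a
#' city, carrying the variables the exposure analysis consumes: resident
#' population, NDVI greenness, distance to the nearest water body and its
#' normalized inverse-square transform, mean warm-season exceedance counts,
#' and the water / urban-core flags. Grid geometry and city metadata travel
#' as attributes so the object pipes through dplyr verbs like any tibble
#' (use [city_meta()] to read them back, [set_city_meta()] to re-attach
#' after verbs that drop attributes).
#'
#' Required columns (fixed names, used by every downstream stage):
#' `pixel_id`, `row`, `col`, `x`, `y`, `population`, `ndvi`, `D_w`, `d_w`,
#' `days_day`, `days_night`, `is_water`, `in_urban_core`.
#'
#' @param pixels A data frame holding the per-pixel columns above. Missing
#'   optional columns (`D_w`, `d_w`, `days_day`, `days_night`,
#'   `in_urban_core`) are filled with `NA`; `is_water` defaults to `FALSE`.
#' @param n_rows,n_cols Grid dimensions.
#' @param cell_size Cell edge length in metres (default 1000).
#' @param city_name City label.
#' @param climate_zone One of `"Arid"`, `"Continental"`, `"Temperate"`,
#'   `"Tropical"` or an additional cluster label.
#' @param season_length Number of days in the warm season (default 92,
#'   a June--August season).
#' @param dw_excluded Flag: `TRUE` when the city has no water pixel so the
#'   distance-to-water feature is undefined and must be left out of models.
#'
#' @return A tibble of class `city_grid`.
#' @export
#' @examples
#' g <- synthetic_city(synthetic_config(n_rows = 8, n_cols = 8, seed = 1))$grid
#' city_meta(g)$cell_size
city_grid <- function(pixels, n_rows, n_cols, cell_size = 1000,
                      city_name = "synthetic", climate_zone = "Temperate",
                      season_length = 92, dw_excluded = FALSE) {
  pixels <- tibble::as_tibble(pixels)
  required <- c("pixel_id", "row", "col", "x", "y", "population", "ndvi")
  missing <- setdiff(required, names(pixels))
  if (length(missing) > 0) {
    abort(paste0("city_grid: missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  optional <- c("D_w", "d_w", "days_day", "days_night", "in_urban_core")
  for (col in optional) {
    if (!col %in% names(pixels)) pixels[[col]] <- NA_real_
  }
  if (!"is_water" %in% names(pixels)) pixels$is_water <- FALSE
  pixels$in_urban_core <- as.logical(pixels$in_urban_core)
  pixels <- pixels[, c(required, "D_w", "d_w", "days_day", "days_night",
                       "is_water", "in_urban_core")]

  if (anyDuplicated(pixels$pixel_id) > 0) {
    abort("city_grid: pixel_id must be unique")
  }
  if (anyDuplicated(pixels[, c("row", "col")]) > 0) {
    abort("city_grid: (row, col) pairs must be unique")
  }
  if (any(pixels$population < 0, na.rm = TRUE)) {
    abort("city_grid: population must be non-negative")
  }
  bad_days <- function(v) any(v < 0 | v > season_length, na.rm = TRUE)
  if (bad_days(pixels$days_day) || bad_days(pixels$days_night)) {
    abort("city_grid: exceedance days must lie in [0, season_length]")
  }

  structure(pixels,
            class = c("city_grid", class(tibble::tibble())),
            city_name = city_name,
            climate_zone = climate_zone,
            n_rows = as.integer(n_rows),
            n_cols = as.integer(n_cols),
            cell_size = cell_size,
            season_length = season_length,
            dw_excluded = isTRUE(dw_excluded))
}

#' Read or restore city-grid metadata
#'
#' @param grid A `city_grid`.
#' @return `city_meta()` returns a named list of the grid attributes
#'   (`city_name`, `climate_zone`, `n_rows`, `n_cols`, `cell_size`,
#'   `season_length`, `dw_excluded`).
#' @export
city_meta <- function(grid) {
  list(city_name = attr(grid, "city_name"),
       climate_zone = attr(grid, "climate_zone"),
       n_rows = attr(grid, "n_rows"),
       n_cols = attr(grid, "n_cols"),
       cell_size = attr(grid, "cell_size"),
       season_length = attr(grid, "season_length"),
       dw_excluded = attr(grid, "dw_excluded"))
}

#' @rdname city_meta
#' @param pixels A data frame of per-pixel records.
#' @param meta A list as returned by [city_meta()].
#' @export
set_city_meta <- function(pixels, meta) {
  city_grid(pixels,
            n_rows = meta$n_rows, n_cols = meta$n_cols,
            cell_size = meta$cell_size, city_name = meta$city_name,
            climate_zone = meta$climate_zone,
            season_length = meta$season_length,
            dw_excluded = meta$dw_excluded)
}

#' @export
print.city_grid <- function(x, ...) {
  m <- city_meta(x)
  cat(sprintf("# city_grid: %s (%s), %d x %d cells of %g m, season %d days%s\n",
              m$city_name, m$climate_zone, m$n_rows, m$n_cols, m$cell_size,
              m$season_length,
              if (isTRUE(m$dw_excluded)) ", d_w excluded (no water)" else ""))
  NextMethod()
}

#' Aggregate native-resolution point observations onto the city grid
#'
#' Bins point samples (e.g. 250 m NDVI retrievals, population points) into
#' grid cells. Population points are summed per cell; NDVI points are
#' averaged; exceedance-count points (`days_day`, `days_night`) are
#' averaged. Cells receiving no NDVI point carry `NA` and are excluded from
#' model fitting downstream.
#'
#' @param points A data frame with columns `x`, `y` (planar metres),
#'   `variable` (one of `"population"`, `"ndvi"`, `"days_day"`,
#'   `"days_night"`) and `value`.
#' @param grid_spec A list with `n_rows`, `n_cols`, `cell_size` and
#'   optionally `origin = c(x0, y0)` (default `c(0, 0)`), plus any
#'   metadata fields accepted by [city_grid()].
#' @return A `city_grid` tibble. Points falling outside the grid are
#'   dropped with a warning reporting the count.
#' @export
aggregate_to_grid <- function(points, grid_spec) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x", "y", "variable", "value") %in% names(points)))
  schema <- c("population", "ndvi", "days_day", "days_night")
  unknown <- setdiff(unique(points$variable), schema)
  if (length(unknown) > 0) {
    abort(paste0("aggregate_to_grid: unknown variable(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    abort("aggregate_to_grid: point coordinates must be finite")
  }

  nr <- grid_spec$n_rows
  nc <- grid_spec$n_cols
  cs <- grid_spec$cell_size %||% 1000
  origin <- grid_spec$origin %||% c(0, 0)

  col <- floor((points$x - origin[1]) / cs) + 1L
  row <- floor((points$y - origin[2]) / cs) + 1L
  inside <- col >= 1L & col <= nc & row >= 1L & row <= nr
  n_out <- sum(!inside)
  if (n_out > 0) {
    warn(sprintf("aggregate_to_grid: dropped %d point(s) outside the grid",
                 n_out))
  }
  pts <- points[inside, ]
  pts$row <- row[inside]
  pts$col <- col[inside]

  base <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  base$pixel_id <- seq_len(nrow(base))
  base$x <- origin[1] + (base$col - 0.5) * cs
  base$y <- origin[2] + (base$row - 0.5) * cs

  agg_one <- function(var, fun, default) {
    sub <- pts[pts$variable == var, ]
    if (nrow(sub) == 0) return(rep(default, nrow(base)))
    cell <- dplyr::summarise(dplyr::group_by(sub, .data$row, .data$col),
                             value = fun(.data$value), .groups = "drop")
    out <- rep(default, nrow(base))
    idx <- (cell$col - 1L) * nr + cell$row
    pos <- match(paste(cell$row, cell$col), paste(base$row, base$col))
    out[pos] <- cell$value
    out
  }

  base$population <- agg_one("population", sum, 0)
  base$ndvi <- agg_one("ndvi", mean, NA_real_)
  base$days_day <- agg_one("days_day", mean, NA_real_)
  base$days_night <- agg_one("days_night", mean, NA_real_)

  n_missing <- sum(is.na(base$ndvi))
  if (n_missing > 0) {
    inform(sprintf("aggregate_to_grid: %d cell(s) without an NDVI point (kept as NA)",
                   n_missing))
  }

  city_grid(base, n_rows = nr, n_cols = nc, cell_size = cs,
            city_name = grid_spec$city_name %||% "aggregated",
            climate_zone = grid_spec$climate_zone %||% "Temperate",
            season_length = grid_spec$season_length %||% 92)
}

# Exact 1-D squared Euclidean distance transform (lower envelope of
# parabolas); f is the squared-distance seed: 0 at sources, a large finite
# sentinel elsewhere (must exceed any attainable squared distance so it
# never wins the envelope where a source exists).
edt_1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L
  z[1] <- -Inf
  z[2] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    while (k > 1L && s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  j <- 1L
  for (q in 1:n) {
    while (z[j + 1] < q) j <- j + 1L
    d[q] <- (q - v[j])^2 + f[v[j]]
  }
  d
}

#' Euclidean distance to the nearest water pixel
#'
#' Exact centroid-to-centroid Euclidean distance transform on the raster
#' grid (two-pass separable parabola algorithm), in metres. Water cells
#' have distance zero. No geodesic correction is applied: at city scale
#' the planar approximation is exact enough and synthetic grids are planar
#' by construction.
#'
#' @param water_mask Logical matrix (`n_rows` x `n_cols`), `TRUE` on water.
#' @param cell_size Cell edge length in metres.
#' @return Numeric matrix of distances in metres, or an all-`NA` matrix
#'   (with a warning) when the mask holds no water cell.
#' @export
distance_to_water <- function(water_mask, cell_size = 1000) {
  stopifnot(is.matrix(water_mask))
  mask <- water_mask
  storage.mode(mask) <- "logical"
  if (!any(mask)) {
    warn("distance_to_water: no water cell in mask; D_w undefined (all NA)")
    out <- matrix(NA_real_, nrow(mask), ncol(mask))
    return(out)
  }
  big <- nrow(mask)^2 + ncol(mask)^2 + 1  # exceeds any attainable squared cell distance
  f <- ifelse(mask, 0, big)
  g <- apply(f, 2, edt_1d)        # pass 1: along columns
  d2 <- t(apply(g, 1, edt_1d))    # pass 2: along rows
  cell_size * sqrt(d2)
}

#' Inverse-square distance-to-water feature
#'
#' Computes the raw feature 1 / D_w^2 on land cells, assigns water cells
#' the maximum land raw value (the transform diverges at D_w = 0; this
#' keeps the "closest to water = largest" ordering without infinities),
#' and divides by the overall maximum so the feature lies in \[0, 1\] with
#' max exactly 1. Normalization is per city.
#'
#' @param D_w Numeric matrix of distances in metres (from
#'   [distance_to_water()]).
#' @param is_water Logical matrix flagging water cells; defaults to
#'   `D_w == 0`.
#' @return Numeric matrix `d_w` in \[0, 1\]; all-`NA` when `D_w` is
#'   all-`NA`.
#' @export
dw_feature <- function(D_w, is_water = NULL) {
  stopifnot(is.matrix(D_w))
  if (all(is.na(D_w))) {
    return(matrix(NA_real_, nrow(D_w), ncol(D_w)))
  }
  if (is.null(is_water)) is_water <- !is.na(D_w) & D_w == 0
  raw <- matrix(NA_real_, nrow(D_w), ncol(D_w))
  land <- !is_water & !is.na(D_w)
  raw[land] <- 1 / D_w[land]^2
  if (!any(land)) {
    # city entirely water: feature is 1 everywhere by convention
    raw[is_water] <- 1
    return(raw)
  }
  max_land <- max(raw[land])
  raw[is_water] <- max_land
  raw / max_land
}

#' Attach water-distance features to a city grid
#'
#' Convenience wrapper: derives the water mask from the grid's `is_water`
#' column, runs [distance_to_water()] and [dw_feature()], and writes the
#' `D_w` / `d_w` columns back. With no water pixel the grid's
#' `dw_excluded` flag is set and both columns are `NA`.
#'
#' @param grid A `city_grid`.
#' @return The grid with `D_w` and `d_w` filled in.
#' @export
add_water_distance <- function(grid) {
  meta <- city_meta(grid)
  mask <- matrix(FALSE, meta$n_rows, meta$n_cols)
  mask[cbind(grid$row, grid$col)] <- grid$is_water
  if (!any(mask)) {
    grid$D_w <- NA_real_
    grid$d_w <- NA_real_
    meta$dw_excluded <- TRUE
    return(set_city_meta(grid, meta))
  }
  D <- distance_to_water(mask, meta$cell_size)
  d <- dw_feature(D, mask)
  grid$D_w <- D[cbind(grid$row, grid$col)]
  grid$d_w <- d[cbind(grid$row, grid$col)]
  meta$dw_excluded <- FALSE
  set_city_meta(grid, meta)
}

#' Extract a grid column as a row-by-column matrix
#'
#' @param grid A `city_grid`.
#' @param var Column name.
#' @return Matrix of dimension `n_rows` x `n_cols`.
#' @export
grid_matrix <- function(grid, var) {
  meta <- city_meta(grid)
  m <- matrix(NA_real_, meta$n_rows, meta$n_cols)
  m[cbind(grid$row, grid$col)] <- grid[[var]]
  m
}
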