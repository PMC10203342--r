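#' Daily land-surface-temperature series for a gridded city
#'
#' Container for per-pixel daily daytime and nighttime LST. Values are
#' stored as pixel x date matrices with a date index, the year of each
#' date, and a logical warm-season mask (the 3 warmest months, supplied
#' by configuration for synthetic cities).
#'
#' @param day,night Numeric matrices, pixels in rows and dates in
#'   columns; `NA` marks missing retrievals.
#' @param year Integer vector, length `ncol(day)`: year of each date.
#' @param season Logical vector, length `ncol(day)`: `TRUE` for dates in
#'   the warm season.
#' @param dates Optional `Date` vector.
#' @return An object of class `lst_series`.
#' @export
lst_series <- function(day, night, year, season, dates = NULL) {
  stopifnot(is.matrix(day), is.matrix(night),
            all(dim(day) == dim(night)),
            length(year) == ncol(day), length(season) == ncol(day))
  structure(list(day = day, night = night,
                 year = as.integer(year), season = as.logical(season),
                 dates = dates),
            class = "lst_series")
}

#' @export
print.lst_series <- function(x, ...) {
  cat(sprintf("# lst_series: %d pixels x %d dates (%d in warm season), years %s\n",
              nrow(x$day), ncol(x$day), sum(x$season),
              paste(range(x$year), collapse = "-")))
  invisible(x)
}

#' Tidy an LST series into long form
#'
#' @param x An `lst_series`.
#' @param ... Unused.
#' @return Long tibble with `pixel_id`, `date_index`, `year`, `in_season`,
#'   `channel`, `lst`.
#' @export
tidy.lst_series <- function(x, ...) {
  nd <- ncol(x$day)
  np <- nrow(x$day)
  base <- tidyr::expand_grid(date_index = seq_len(nd), pixel_id = seq_len(np))
  dplyr::bind_rows(
    dplyr::mutate(base, year = x$year[.data$date_index],
                  in_season = x$season[.data$date_index],
                  channel = "day",
                  lst = as.vector(x$day)[(base$date_index - 1L) * np + base$pixel_id]),
    dplyr::mutate(base, year = x$year[.data$date_index],
                  in_season = x$season[.data$date_index],
                  channel = "night",
                  lst = as.vector(x$night)[(base$date_index - 1L) * np + base$pixel_id]))
}

#' Exposure thresholds from the pooled LST distribution
#'
#' The day (night) threshold is the q-th percentile of the pooled
#' distribution of all daytime (nighttime) LST values over all pixels and
#' all dates of the reference period — pooling across the whole city, not
#' per pixel. Percentiles use the linear-interpolation convention between
#' order statistics ([stats::quantile()] type 7).
#'
#' @param lst An `lst_series`.
#' @param q Percentile in (0, 100); a scalar applied to both channels or
#'   a length-2 vector `c(q_day, q_night)`. Default 90.
#' @param reference_years Optional integer vector restricting the pooled
#'   distribution to those years (default: all years in the series).
#' @return Tibble with `t_day`, `t_night`, `q_day`, `q_night` and the
#'   reference-year range.
#' @export
compute_thresholds <- function(lst, q = 90, reference_years = NULL) {
  stopifnot(inherits(lst, "lst_series"), all(q > 0), all(q < 100))
  q <- rep(q, length.out = 2)
  keep <- if (is.null(reference_years)) rep(TRUE, ncol(lst$day))
          else lst$year %in% reference_years
  pooled_day <- lst$day[, keep, drop = FALSE]
  pooled_night <- lst$night[, keep, drop = FALSE]
  if (all(is.na(pooled_day)) || all(is.na(pooled_night))) {
    abort("compute_thresholds: no valid observation in the reference period")
  }
  tibble::tibble(
    t_day = unname(quantile(pooled_day, q[1] / 100, na.rm = TRUE, type = 7)),
    t_night = unname(quantile(pooled_night, q[2] / 100, na.rm = TRUE, type = 7)),
    q_day = q[1], q_night = q[2],
    year_min = min(lst$year[keep]), year_max = max(lst$year[keep]))
}

#' Count warm-season threshold exceedances
#'
#' For each pixel and year, counts the warm-season dates whose LST
#' strictly exceeds the threshold ("exceeds": ties do not count).
#' Missing observations never count. Years whose season mask is empty are
#' excluded from the multi-year mean with a warning.
#'
#' @param lst An `lst_series`.
#' @param thresholds A row from [compute_thresholds()] (or any list with
#'   `t_day`, `t_night`).
#' @return List with `per_year` (tibble: `pixel_id`, `year`,
#'   `count_day`, `count_night`) and `mean` (tibble: `pixel_id`,
#'   `days_day`, `days_night` — the per-year counts averaged over years).
#' @export
count_exceedances <- function(lst, thresholds) {
  stopifnot(inherits(lst, "lst_series"))
  years <- sort(unique(lst$year))
  np <- nrow(lst$day)
  rows <- vector("list", length(years))
  kept <- logical(length(years))
  for (i in seq_along(years)) {
    sel <- lst$year == years[i] & lst$season
    if (!any(sel)) {
      warn(sprintf("count_exceedances: year %d has an empty season mask; excluded",
                   years[i]))
      next
    }
    kept[i] <- TRUE
    d <- lst$day[, sel, drop = FALSE]
    n <- lst$night[, sel, drop = FALSE]
    rows[[i]] <- tibble::tibble(
      pixel_id = seq_len(np), year = years[i],
      count_day = as.integer(rowSums(d > thresholds$t_day, na.rm = TRUE)),
      count_night = as.integer(rowSums(n > thresholds$t_night, na.rm = TRUE)))
  }
  per_year <- dplyr::bind_rows(rows[kept])
  mean_tbl <- dplyr::summarise(dplyr::group_by(per_year, .data$pixel_id),
                               days_day = mean(.data$count_day),
                               days_night = mean(.data$count_night),
                               .groups = "drop")
  list(per_year = per_year, mean = mean_tbl)
}

#' Person-day exposure from exceedance counts
#'
#' Per pixel, the daytime exposure TE_D is the mean warm-season
#' exceedance days multiplied by the resident population (person-days per
#' season); TE_N analogously for nights; the total exposure averages the
#' two, TE_T = (TE_D + TE_N) / 2. City totals sum over pixels, and the
#' per-capita exposure divides the city total by the city population.
#'
#' @param grid A `city_grid` with `population`, `days_day`, `days_night`.
#' @return List of class `exposure_result`: `pixels` (tibble with per-pixel
#'   `te_day`, `te_night`, `te_total`) and `city` (one-row tibble with the
#'   totals, total population and per-capita exposure in days; per-capita
#'   is `NA` for an unpopulated city).
#' @export
exposure_from_counts <- function(grid) {
  stopifnot(inherits(grid, "city_grid"))
  dd <- ifelse(is.na(grid$days_day), 0, grid$days_day)
  dn <- ifelse(is.na(grid$days_night), 0, grid$days_night)
  te_day <- dd * grid$population
  te_night <- dn * grid$population
  pixels <- tibble::tibble(pixel_id = grid$pixel_id,
                           te_day = te_day, te_night = te_night,
                           te_total = (te_day + te_night) / 2)
  pop <- sum(grid$population)
  te_d_c <- sum(te_day)
  te_n_c <- sum(te_night)
  te_t_c <- (te_d_c + te_n_c) / 2  # the city identity TE_T = (TE_D + TE_N)/2, exactly
  city <- tibble::tibble(
    te_day = te_d_c, te_night = te_n_c, te_total = te_t_c,
    population = pop,
    per_capita_days = if (pop > 0) te_t_c / pop else NA_real_)
  structure(list(pixels = pixels, city = city), class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  c <- x$city
  cat(sprintf("# exposure: TE_D = %.4g, TE_N = %.4g, TE_T = %.4g person-days; per capita %.2f days\n",
              c$te_day, c$te_night, c$te_total, c$per_capita_days))
  invisible(x)
}

#' @export
tidy.exposure_result <- function(x, ...) x$pixels

#' @rdname tidy.slm_model
#' @export
glance.exposure_result <- function(x, ...) x$city

#' Surface urban heat island intensity
#'
#' SUHI is the mean LST of the urban-core pixels minus the mean LST of
#' the rural ring (buffer pixels outside the core). The ring's mean NDVI
#' is reported alongside, since across cities SUHI correlates negatively
#' with the greenness of the rural surround.
#'
#' @param grid A `city_grid` with `in_urban_core` set.
#' @param lst_mean Numeric vector: per-pixel mean LST, in grid row order.
#' @return Tibble with `suhi` (degrees), `core_mean`, `ring_mean`,
#'   `rural_ndvi_mean`, `n_core`, `n_ring`.
#' @export
suhi <- function(grid, lst_mean) {
  stopifnot(inherits(grid, "city_grid"), length(lst_mean) == nrow(grid))
  core <- grid$in_urban_core & !grid$is_water
  ring <- !grid$in_urban_core & !grid$is_water
  if (!any(core) || !any(ring)) {
    abort("suhi: need non-empty urban core and rural ring")
  }
  tibble::tibble(
    suhi = mean(lst_mean[core]) - mean(lst_mean[ring]),
    core_mean = mean(lst_mean[core]),
    ring_mean = mean(lst_mean[ring]),
    rural_ndvi_mean = mean(grid$ndvi[ring], na.rm = TRUE),
    n_core = sum(core), n_ring = sum(ring))
}

#' Write exceedance counts back into the grid
#'
#' @param grid A `city_grid`.
#' @param counts Result of [count_exceedances()].
#' @return The grid with `days_day` / `days_night` replaced by the
#'   multi-year mean counts.
#' @export
set_exceedance_days <- function(grid, counts) {
  m <- counts$mean[match(grid$pixel_id, counts$mean$pixel_id), ]
  grid$days_day <- m$days_day
  grid$days_night <- m$days_night
  set_city_meta(grid, city_meta(grid))
}
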