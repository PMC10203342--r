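#' Plot a city-grid variable as a raster map
#'
#' @param object A `city_grid`.
#' @param var Column to map (default `"ndvi"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.city_grid <- function(object, var = "ndvi", ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data[[var]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("%s — %s", city_meta(object)$city_name, var),
                  x = NULL, y = NULL)
}

#' Plot an increment sweep
#'
#' Exposure reduction against the global NDVI increment (near-linear by
#' construction of the model) together with the targeted local increment
#' required for the same reduction.
#'
#' @param object A `sweep_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(
    dplyr::transmute(df, delta_global = .data$delta_global,
                     `delta TE (%)` = .data$delta_te_pct,
                     `local increment` = .data$delta_local,
                     `NDVI savings (%)` = .data$savings_pct),
    -"delta_global", names_to = "panel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$delta_global, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "global NDVI increment", y = NULL)
}

#' Plot cross-validation performance
#'
#' Test R-squared per fold for the spatial lag model and the OLS
#' baseline.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(factor(.data$fold), .data$r2_test,
                               fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "fold", y = expression(test ~ R^2), fill = NULL)
}
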