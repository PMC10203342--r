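#' Assemble a city grid from raster layers
#'
#' Takes co-registered single-band rasters as plain matrices (one per
#' variable, as read from per-variable raster files) and builds the
#' per-pixel table. All layers must share the grid shape; `population`
#' and `ndvi` are mandatory. Water-distance features are derived from the
#' water mask via [add_water_distance()].
#'
#' @param layers Named list of matrices: `population`, `ndvi` (mandatory),
#'   optionally `water` (nonzero = water), `days_day`, `days_night`,
#'   `urban_core` (nonzero = inside the urban boundary).
#' @param cell_size Cell edge in metres.
#' @param ... Metadata passed to [city_grid()].
#' @return A `city_grid`.
#' @export
city_from_layers <- function(layers, cell_size = 1000, ...) {
  mandatory <- c("population", "ndvi")
  for (nm in mandatory) {
    if (is.null(layers[[nm]])) {
      abort(paste0("city_from_layers: missing mandatory layer: ", nm))
    }
  }
  ref <- dim(layers$population)
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), ref)) {
      abort(sprintf("city_from_layers: layer '%s' has shape %s, expected %s",
                    nm, paste(dim(layers[[nm]]), collapse = "x"),
                    paste(ref, collapse = "x")))
    }
  }
  nr <- ref[1]
  nc <- ref[2]
  base <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  base <- dplyr::arrange(base, .data$row, .data$col)
  base$pixel_id <- seq_len(nrow(base))
  base$x <- (base$col - 0.5) * cell_size
  base$y <- (base$row - 0.5) * cell_size
  at <- cbind(base$row, base$col)
  base$population <- layers$population[at]
  base$ndvi <- layers$ndvi[at]
  base$is_water <- if (!is.null(layers$water)) layers$water[at] != 0 else FALSE
  if (!is.null(layers$days_day)) base$days_day <- layers$days_day[at]
  if (!is.null(layers$days_night)) base$days_night <- layers$days_night[at]
  if (!is.null(layers$urban_core)) base$in_urban_core <- layers$urban_core[at] != 0
  grid <- city_grid(base, n_rows = nr, n_cols = nc, cell_size = cell_size, ...)
  add_water_distance(grid)
}

#' Write / read a city bundle on disk
#'
#' A city bundle is a directory holding `meta.yaml` (grid geometry and
#' metadata), `pixels.csv` (the per-pixel table with the fixed column
#' schema `pixel_id,row,col,x,y,population,ndvi,D_w,d_w,days_day,
#' days_night,is_water,in_urban_core`), optionally `pixels.parquet`
#' (same table, columnar; written when the arrow package is available)
#' and optionally `lst.csv` (long per-pixel daily day/night LST).
#' CSVs round-trip doubles at full precision, so write-then-read
#' reproduces the table exactly.
#'
#' @param grid A `city_grid`.
#' @param path Bundle directory (created if needed).
#' @param lst Optional `lst_series` to include.
#' @return `write_city()` returns `path` invisibly; `read_city()` returns
#'   a list with `grid` and `lst` (NULL when the bundle has no series).
#' @export
write_city <- function(grid, path, lst = NULL) {
  stopifnot(inherits(grid, "city_grid"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- city_meta(grid)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  readr::write_csv(tibble::as_tibble(grid), file.path(path, "pixels.csv"))
  if (requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_parquet(tibble::as_tibble(grid),
                         file.path(path, "pixels.parquet"))
  }
  if (!is.null(lst)) {
    long <- tidy(lst)
    wide <- tidyr::pivot_wider(long, names_from = "channel",
                               values_from = "lst")
    readr::write_csv(wide, file.path(path, "lst.csv"))
    yaml::write_yaml(list(q = attr(lst, "q"),
                          q_day = attr(lst, "q_day"),
                          q_night = attr(lst, "q_night")),
                     file.path(path, "lst_meta.yaml"))
  }
  invisible(path)
}

#' @rdname write_city
#' @export
read_city <- function(path) {
  meta_path <- file.path(path, "meta.yaml")
  csv_path <- file.path(path, "pixels.csv")
  if (!file.exists(meta_path) || !file.exists(csv_path)) {
    abort(paste0("read_city: not a city bundle (missing meta.yaml or pixels.csv): ",
                 path))
  }
  meta <- yaml::read_yaml(meta_path)
  pixels <- readr::read_csv(csv_path, show_col_types = FALSE,
                            col_types = readr::cols(
                              pixel_id = readr::col_integer(),
                              row = readr::col_integer(),
                              col = readr::col_integer(),
                              is_water = readr::col_logical(),
                              in_urban_core = readr::col_logical(),
                              .default = readr::col_double()))
  grid <- set_city_meta(pixels, meta)
  lst <- NULL
  lst_path <- file.path(path, "lst.csv")
  if (file.exists(lst_path)) {
    long <- readr::read_csv(lst_path, show_col_types = FALSE)
    np <- max(long$pixel_id)
    nd <- max(long$date_index)
    day <- matrix(NA_real_, np, nd)
    night <- matrix(NA_real_, np, nd)
    day[cbind(long$pixel_id, long$date_index)] <- long$day
    night[cbind(long$pixel_id, long$date_index)] <- long$night
    first <- long[!duplicated(long$date_index), ]
    first <- first[order(first$date_index), ]
    lst <- lst_series(day, night, year = first$year, season = first$in_season)
    lm_path <- file.path(path, "lst_meta.yaml")
    if (file.exists(lm_path)) {
      lm <- yaml::read_yaml(lm_path)
      attr(lst, "q") <- lm$q
      attr(lst, "q_day") <- lm$q_day
      attr(lst, "q_night") <- lm$q_night
    }
  }
  list(grid = grid, lst = lst)
}

#' Read or write a single-band raster layer as TIFF
#'
#' Thin wrappers over the tiff package for exchanging per-variable raster
#' layers. The payload is stored as 32-bit samples min-max scaled to
#' \[0, 1\]; the affine scale travels in a YAML sidecar next to the file
#' (grid geometry lives in the bundle's `meta.yaml`). Round-trip accuracy
#' is float precision (~7 significant digits) — the CSV table, not the
#' TIFF, is the exact serialization.
#'
#' @param m Numeric matrix.
#' @param path File path (sidecar written to `<path>.yaml`).
#' @return `read_layer_tiff()` returns the rescaled numeric matrix.
#' @export
write_layer_tiff <- function(m, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("write_layer_tiff: the tiff package is not installed")
  }
  lo <- min(m, na.rm = TRUE)
  hi <- max(m, na.rm = TRUE)
  payload <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
  tiff::writeTIFF(payload, path, bits.per.sample = 32L, reduce = TRUE)
  yaml::write_yaml(list(lo = lo, hi = hi), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_layer_tiff
#' @export
read_layer_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("read_layer_tiff: the tiff package is not installed")
  }
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  sc <- yaml::read_yaml(paste0(path, ".yaml"))
  sc$lo + m * (sc$hi - sc$lo)
}

#' Serialize a fitted model or scenario result to JSON
#'
#' @param x An `slm_model`, `cv_report` or `scenario_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(x, path) {
  payload <- if (inherits(x, "slm_model")) {
    list(type = "slm_model", beta = as.list(x$beta), rho = x$rho,
         sigma2 = x$sigma2, loglik = x$loglik, n = x$n,
         converged = x$converged)
  } else if (inherits(x, "cv_report")) {
    list(type = "cv_report", beta_avg = as.list(x$beta_avg),
         rho_avg = x$rho_avg, n_folds = x$n_folds, seed = x$seed,
         folds = x$folds)
  } else if (inherits(x, "scenario_result")) {
    list(type = "scenario_result", as.list(tibble::as_tibble(x)[1, ]))
  } else {
    abort("write_model_json: unsupported object")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
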