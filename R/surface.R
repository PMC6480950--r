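# Applying a fitted model at points and over regular grids.

#' Specify a regular prediction grid
#'
#' @param origin (x, y) of the lower-left corner, metres.
#' @param cellsize cell edge length, metres.
#' @param ncol,nrow grid dimensions, at least 1.
#' @param period year the surface represents (annotation only).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(origin, cellsize, ncol, nrow, period = NA_integer_) {
  if (!is_scalar_number(cellsize) || cellsize <= 0) stopf("cellsize must be positive")
  if (ncol < 1 || nrow < 1) stopf("grid dimensions must be at least 1")
  structure(list(origin = as.numeric(origin), cellsize = as.numeric(cellsize),
                 ncol = as.integer(ncol), nrow = as.integer(nrow),
                 period = period),
            class = "grid_spec")
}

#' Predict from a fitted LUR model at supplied rows
#'
#' Computes `intercept + sum(coefficient * value)` for each row,
#' back-transforming when the model was fitted on a log10 response.
#'
#' @param model a `lur_model`.
#' @param newdata data frame containing every column the model uses.
#' @return numeric vector of predictions in response units.
#' @export
predict_at_points <- function(model, newdata) {
  stopifnot(inherits(model, "lur_model"))
  newdata <- as.data.frame(newdata)
  cols <- model$terms$column
  missing_cols <- setdiff(cols, names(newdata))
  if (length(missing_cols) > 0) {
    stopf("newdata is missing model column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  pred <- rep(model$intercept, nrow(newdata))
  for (i in seq_along(cols)) {
    pred <- pred + model$terms$coefficient[i] * as.numeric(newdata[[cols[i]]])
  }
  if (model$response_transform == "log10") pred <- 10^pred
  pred
}

#' @export
predict.lur_model <- function(object, newdata, ...) {
  predict_at_points(object, newdata)
}

#' Inverse-distance-weighted covariate raster from station values
#'
#' Builds a covariate raster (e.g. NOx, temperature, relative humidity) over
#' a grid from station-level values by inverse-distance weighting over all
#' stations (power 2 by default). A grid cell coinciding with a station takes
#' that station's value. This is a transparent modelling choice for carrying
#' station-measured covariates onto a prediction grid, not an attempt at
#' geostatistical interpolation.
#'
#' @param stations validated station data frame.
#' @param values numeric vector of station values, aligned with `stations`.
#' @param grid a [grid_spec()].
#' @param power IDW exponent (default 2).
#' @return a [raster_grid()].
#' @export
idw_raster <- function(stations, values, grid, power = 2) {
  stations <- validate_stations(stations)
  if (length(values) != nrow(stations)) {
    stopf("values must align with stations")
  }
  xs <- grid$origin[1] + (seq_len(grid$ncol) - 0.5) * grid$cellsize
  ys <- grid$origin[2] + (grid$nrow - seq_len(grid$nrow) + 0.5) * grid$cellsize
  vals <- matrix(NA_real_, grid$nrow, grid$ncol)
  for (i in seq_len(grid$nrow)) {
    d2 <- outer(rep(ys[i], grid$ncol), stations$y, function(a, b) (a - b)^2) +
      outer(xs, stations$x, function(a, b) (a - b)^2)
    d <- sqrt(d2)
    hit <- d == 0
    w <- 1 / d^power
    num <- as.numeric(w %*% values)
    den <- rowSums(w)
    v <- num / den
    if (any(hit)) {
      idx <- which(rowSums(hit) > 0)
      v[idx] <- values[apply(hit[idx, , drop = FALSE], 1, which.max)]
    }
    vals[i, ] <- v
  }
  raster_grid(grid$origin, grid$cellsize, vals)
}

#' Predict a gridded concentration surface
#'
#' Evaluates a fitted model at every grid-cell centre: buffer and distance
#' terms are extracted from the supplied layers at each centre via the
#' buffer-extraction engine, and covariate terms (NOx, temperature, relative
#' humidity, altitude, ...) are sampled from user-supplied covariate rasters.
#' Cells where any input is missing receive `NA`. Layers are treated as
#' complete: margin cells whose buffers extend beyond the supplied geometry
#' are still computed (an `edge_mask` flags cells within the maximum model
#' radius of the grid edge for users who want to blank them).
#'
#' @param model a `lur_model`.
#' @param layers named list of `geo_layer` objects covering every buffer or
#'   distance term of the model (names must match the column stems).
#' @param covariate_rasters named list of [raster_grid()]s, one per covariate
#'   column used by the model.
#' @param grid a [grid_spec()].
#' @param edge_mask logical; if `TRUE`, also return the edge flag matrix.
#' @return list of class `prediction_raster`: `grid`, `values` (matrix, row 1
#'   = north), and optionally `edge` (logical matrix).
#' @export
predict_surface <- function(model, layers = list(),
                            covariate_rasters = list(), grid,
                            edge_mask = FALSE) {
  stopifnot(inherits(model, "lur_model"), inherits(grid, "grid_spec"))
  cols <- model$terms$column
  layer_names <- vapply(layers, function(l) l$name, character(1))
  names(layers) <- layer_names

  # split model columns into layer-derived and covariate columns
  is_layer_col <- grepl("@", cols)
  stems <- sub("@.*$", "", cols[is_layer_col])
  missing_layers <- setdiff(unique(stems), layer_names)
  if (length(missing_layers) > 0) {
    stopf("no layer supplied for model column stem(s): %s",
          paste(missing_layers, collapse = ", "))
  }
  cov_cols <- cols[!is_layer_col]
  missing_cov <- setdiff(cov_cols, names(covariate_rasters))
  if (length(missing_cov) > 0) {
    stopf("no covariate raster supplied for model column(s): %s",
          paste(missing_cov, collapse = ", "))
  }

  xs <- grid$origin[1] + (seq_len(grid$ncol) - 0.5) * grid$cellsize
  ys <- grid$origin[2] + (grid$nrow - seq_len(grid$nrow) + 0.5) * grid$cellsize
  centers <- cbind(rep(xs, times = grid$nrow),
                   rep(ys, each = grid$ncol))   # row-major over the grid

  newdata <- data.frame(row.names = seq_len(nrow(centers)))
  for (cn in cols[is_layer_col]) {
    stem <- sub("@.*$", "", cn)
    layer <- layers[[stem]]
    if (grepl("@dist$", cn)) {
      newdata[[cn]] <- vapply(seq_len(nrow(centers)), function(i) {
        nearest_distance(layer, centers[i, ])
      }, numeric(1))
    } else {
      r <- as.numeric(sub("^.*@", "", cn))
      newdata[[cn]] <- extract_column_at(layer, centers, r)
    }
  }
  for (cn in cov_cols) {
    newdata[[cn]] <- raster_sample(covariate_rasters[[cn]], centers)
  }

  pred <- rep(NA_real_, nrow(centers))
  ok <- stats::complete.cases(newdata) | ncol(newdata) == 0
  if (any(ok)) {
    pred[ok] <- predict_at_points(model, newdata[ok, , drop = FALSE])
  }
  values <- matrix(pred, nrow = grid$nrow, ncol = grid$ncol, byrow = TRUE)
  out <- list(grid = grid, values = values)
  if (edge_mask) {
    radii <- suppressWarnings(as.numeric(sub("^.*@", "", cols[is_layer_col])))
    rmax <- if (any(is.finite(radii))) max(radii, na.rm = TRUE) else 0
    xmax <- grid$origin[1] + grid$ncol * grid$cellsize
    ymax <- grid$origin[2] + grid$nrow * grid$cellsize
    edge <- outer(ys, xs, function(y, x) {
      x - grid$origin[1] < rmax | xmax - x < rmax |
        y - grid$origin[2] < rmax | ymax - y < rmax
    })
    out$edge <- edge
  }
  class(out) <- "prediction_raster"
  out
}

# one buffer column for a matrix of centres
extract_column_at <- function(layer, centers, radius) {
  n <- nrow(centers)
  vapply(seq_len(n), function(i) {
    switch(layer$kind,
      points = as.numeric(count_points_in_buffer(layer, centers[i, ], radius)),
      lines = line_length_in_buffer(layer, centers[i, ], radius),
      polygons = polygon_area_in_buffer(layer, centers[i, ], radius),
      raster = raster_mean_in_buffer(layer, centers[i, ], radius)
    )
  }, numeric(1))
}

#' @export
print.prediction_raster <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<prediction_raster> %d x %d cells of %gm, values %.4g..%.4g (%d missing)\n",
              x$grid$nrow, x$grid$ncol, x$grid$cellsize, rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' Write a prediction raster as an ESRI ASCII grid
#'
#' @param surface a `prediction_raster` from [predict_surface()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  write_ascii_grid(raster_grid(surface$grid$origin, surface$grid$cellsize,
                               surface$values), path)
}
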