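# Circular-buffer and nearest-distance predictor extraction.
#
# All geometry is Euclidean on planar metre coordinates. Disk boundaries are
# closed: a feature exactly at distance r from the centre counts.

check_center <- function(center) {
  center <- as.numeric(center)
  if (length(center) != 2 || !all(is.finite(center))) {
    stopf("center must be a finite (x, y) pair")
  }
  center
}

#' Count layer points inside a circular buffer
#'
#' Number of points of a point layer with Euclidean distance <= `radius`
#' (closed disk) from `center`.
#'
#' @param layer a point `geo_layer`.
#' @param center numeric (x, y) in metres.
#' @param radius buffer radius in metres, positive.
#' @return integer count; an empty layer yields 0.
#' @export
count_points_in_buffer <- function(layer, center, radius) {
  if (layer$kind != "points") stopf("layer '%s' is not a point layer", layer$name)
  center <- check_center(center)
  if (!is_scalar_number(radius) || radius <= 0) stopf("radius must be positive")
  pts <- layer$geometry
  if (nrow(pts) == 0) return(0L)
  d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2
  sum(d2 <= radius^2)
}

# flatten a list of polylines into parallel segment-endpoint vectors
flatten_segments <- function(lines) {
  if (length(lines) == 0) {
    return(list(x1 = numeric(0), y1 = numeric(0),
                x2 = numeric(0), y2 = numeric(0)))
  }
  segs <- lapply(lines, function(g) {
    n <- nrow(g)
    cbind(g[-n, 1], g[-n, 2], g[-1, 1], g[-1, 2])
  })
  m <- do.call(rbind, segs)
  list(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4])
}

# exact segment-circle clipping: total in-disk length for each radius
segment_lengths_in_disk <- function(seg, cx, cy, radii) {
  px <- seg$x1 - cx; py <- seg$y1 - cy
  dx <- seg$x2 - seg$x1; dy <- seg$y2 - seg$y1
  a <- dx * dx + dy * dy           # zero for degenerate segments
  b <- 2 * (px * dx + py * dy)
  c0 <- px * px + py * py
  len <- sqrt(a)
  out <- numeric(length(radii))
  pos <- a > 0
  for (i in seq_along(radii)) {
    r2 <- radii[i]^2
    disc <- b * b - 4 * a * (c0 - r2)
    ok <- pos & disc > 0
    sq <- sqrt(pmax(disc, 0))
    t1 <- (-b - sq) / (2 * a)
    t2 <- (-b + sq) / (2 * a)
    frac <- pmin(t2, 1) - pmax(t1, 0)
    frac[!ok] <- 0
    out[i] <- sum(pmax(frac, 0) * len)
  }
  out
}

#' Total polyline length inside a circular buffer
#'
#' Total length of the geometric intersection of a line layer with the closed
#' disk of radius `radius` around `center`, by exact segment-circle clipping
#' (entry/exit parameters solve the quadratic per segment).
#'
#' @inheritParams count_points_in_buffer
#' @param layer a line `geo_layer`.
#' @return length in metres; degenerate zero-length segments contribute 0.
#' @export
line_length_in_buffer <- function(layer, center, radius) {
  if (layer$kind != "lines") stopf("layer '%s' is not a line layer", layer$name)
  center <- check_center(center)
  if (!is_scalar_number(radius) || radius <= 0) stopf("radius must be positive")
  seg <- flatten_segments(layer$geometry)
  segment_lengths_in_disk(seg, center[1], center[2], radius)
}

#' Polygon area inside a circular buffer
#'
#' Area of the intersection between the union of the layer's polygons and the
#' disk of radius `radius` around `center`. The disk is represented as a
#' regular inscribed 256-gon (relative area error about 1e-4); overlapping
#' polygons are unioned before intersection so no area is double-counted.
#'
#' @inheritParams count_points_in_buffer
#' @param layer a polygon `geo_layer` (rings validated as simple at
#'   construction).
#' @param ngon number of disk-polygon vertices.
#' @return area in square metres.
#' @export
polygon_area_in_buffer <- function(layer, center, radius, ngon = 256L) {
  if (layer$kind != "polygons") {
    stopf("layer '%s' is not a polygon layer", layer$name)
  }
  center <- check_center(center)
  if (!is_scalar_number(radius) || radius <= 0) stopf("radius must be positive")
  if (length(layer$geometry) == 0) return(0)
  poly_union_area_in_disk_cpp(layer$geometry, center[1], center[2], radius,
                              as.integer(ngon))
}

#' Mean raster value inside a circular buffer
#'
#' Arithmetic mean of the raster cells whose centres lie within the closed
#' disk (cell-centre inclusion, the common zonal-statistics default; no area
#' weighting). Returns `NA` when no cell centre qualifies; a buffer entirely
#' outside the raster extent additionally raises a warning.
#'
#' @inheritParams count_points_in_buffer
#' @param layer a raster `geo_layer`.
#' @return mean cell value (raster units) or `NA`.
#' @export
raster_mean_in_buffer <- function(layer, center, radius) {
  if (layer$kind != "raster") stopf("layer '%s' is not a raster layer", layer$name)
  center <- check_center(center)
  if (!is_scalar_number(radius) || radius <= 0) stopf("radius must be positive")
  grid <- layer$geometry
  xmax <- grid$origin[1] + grid$ncol * grid$cellsize
  ymax <- grid$origin[2] + grid$nrow * grid$cellsize
  if (center[1] + radius < grid$origin[1] || center[1] - radius > xmax ||
      center[2] + radius < grid$origin[2] || center[2] - radius > ymax) {
    warning(sprintf("buffer at (%.0f, %.0f) r=%.0f lies outside raster '%s'",
                    center[1], center[2], radius, layer$name))
    return(NA_real_)
  }
  cc <- raster_cell_centers(grid)
  ci <- which(abs(cc$x - center[1]) <= radius)
  ri <- which(abs(cc$y - center[2]) <= radius)
  if (length(ci) == 0 || length(ri) == 0) return(NA_real_)
  d2 <- outer((cc$y[ri] - center[2])^2, (cc$x[ci] - center[1])^2, "+")
  inside <- d2 <= radius^2
  if (!any(inside)) return(NA_real_)
  vals <- grid$values[ri, ci, drop = FALSE][inside]
  mean(vals, na.rm = TRUE)
}

#' Distance to the nearest point of a layer
#'
#' @inheritParams count_points_in_buffer
#' @param layer a non-empty point `geo_layer`.
#' @return minimum Euclidean distance in metres.
#' @export
nearest_distance <- function(layer, center) {
  if (layer$kind != "points") stopf("layer '%s' is not a point layer", layer$name)
  center <- check_center(center)
  pts <- layer$geometry
  if (nrow(pts) == 0) {
    stopf("nearest_distance is undefined for empty layer '%s'", layer$name)
  }
  sqrt(min((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2))
}

# per-layer extraction for a matrix of centres; returns a named value matrix
extract_layer_values <- function(layer, centers) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  n <- nrow(centers)
  if (layer$mode == "nearest_distance") {
    vals <- vapply(seq_len(n), function(i) nearest_distance(layer, centers[i, ]),
                   numeric(1))
    out <- matrix(vals, ncol = 1)
    colnames(out) <- paste0(layer$name, "@dist")
    return(out)
  }
  radii <- layer$radii
  out <- matrix(NA_real_, nrow = n, ncol = length(radii))
  colnames(out) <- paste0(layer$name, "@", format(radii, trim = TRUE,
                                                  scientific = FALSE))
  if (layer$kind == "points") {
    pts <- layer$geometry
    for (i in seq_len(n)) {
      if (nrow(pts) == 0) { out[i, ] <- 0; next }
      d <- sort(sqrt((pts[, 1] - centers[i, 1])^2 +
                     (pts[, 2] - centers[i, 2])^2))
      out[i, ] <- findInterval(radii, d, left.open = FALSE)
    }
  } else if (layer$kind == "lines") {
    seg <- flatten_segments(layer$geometry)
    for (i in seq_len(n)) {
      out[i, ] <- segment_lengths_in_disk(seg, centers[i, 1], centers[i, 2],
                                          radii)
    }
  } else if (layer$kind == "polygons") {
    for (i in seq_len(n)) {
      out[i, ] <- if (length(layer$geometry) == 0) 0 else
        poly_union_area_in_disk_multi_cpp(layer$geometry, centers[i, 1],
                                          centers[i, 2], radii, 256L)
    }
  } else { # raster
    grid <- layer$geometry
    usable <- radii >= grid$cellsize / 2
    for (i in seq_len(n)) {
      for (j in which(usable)) {
        out[i, j] <- raster_mean_in_buffer(layer, centers[i, ], radii[j])
      }
    }
    out <- out[, usable, drop = FALSE]
  }
  out
}

layer_unit <- function(layer) {
  if (layer$mode == "nearest_distance") return("m")
  switch(layer$kind, points = "count", lines = "m", polygons = "m2",
         raster = "raster")
}

#' Default sign priors for station covariates
#'
#' A-priori directions of effect on ozone for the pass-through covariates:
#' NOx negative (titration of ozone by fresh NO near sources), relative
#' humidity negative, temperature positive (photochemical production),
#' altitude positive, UV unconstrained.
#'
#' @return named character vector of priors.
#' @export
default_covariate_priors <- function() {
  c(nox = "negative", relative_humidity = "negative",
    temperature = "positive", altitude = "positive", uv = "unconstrained")
}

#' Build the candidate design matrix
#'
#' Extracts every layer's buffer/distance predictors at each station location
#' and joins them with the period-varying covariates (NOx, temperature,
#' relative humidity) and station altitude, producing one row per
#' (station, period). Buffer and distance columns are static across periods
#' for a station; covariate columns vary by period. Columns that are constant
#' across all rows are flagged in the column metadata and excluded from
#' selection.
#'
#' @param stations validated station data frame.
#' @param periods period table from [aggregate_to_periods()] (or any data
#'   frame with `station_id`, `period` and `mean_*` covariate columns).
#' @param layers list of `geo_layer` objects.
#' @param covariate_priors named character vector of sign priors for the
#'   covariate columns; see [default_covariate_priors()].
#' @return a `predictor_table`: a data frame with key columns `station_id`,
#'   `period` plus predictor columns, carrying a `column_info` attribute
#'   (data frame: column, layer, radius, kind, unit, sign_prior, constant).
#' @export
build_design_matrix <- function(stations, periods, layers = list(),
                                covariate_priors = default_covariate_priors()) {
  stations <- validate_stations(stations)
  missing_ids <- setdiff(unique(periods$station_id), stations$station_id)
  if (length(missing_ids) > 0) {
    stopf("station(s) in period table but not in station table: %s",
          paste(missing_ids, collapse = ", "))
  }
  sidx <- match(periods$station_id, stations$station_id)
  out <- data.frame(station_id = periods$station_id, period = periods$period,
                    stringsAsFactors = FALSE)
  if ("year" %in% names(periods)) out$year <- periods$year

  info <- data.frame(column = character(), layer = character(),
                     radius = numeric(), kind = character(),
                     unit = character(), sign_prior = character(),
                     stringsAsFactors = FALSE)

  centers <- as.matrix(stations[, c("x", "y")])
  for (layer in layers) {
    vals <- extract_layer_values(layer, centers)  # one row per station
    rows <- vals[sidx, , drop = FALSE]
    for (j in seq_len(ncol(vals))) out[[colnames(vals)[j]]] <- rows[, j]
    rad <- if (layer$mode == "buffer") {
      as.numeric(sub(".*@", "", colnames(vals)))
    } else {
      rep(NA_real_, ncol(vals))
    }
    info <- rbind(info, data.frame(
      column = colnames(vals), layer = layer$name, radius = rad,
      kind = ifelse(layer$mode == "buffer", "buffer", "distance"),
      unit = layer_unit(layer), sign_prior = layer$sign_prior,
      stringsAsFactors = FALSE
    ))
  }

  cov_map <- c(nox = "mean_nox", temperature = "mean_temperature",
               relative_humidity = "mean_rh", uv = "mean_uv")
  for (cv in names(cov_map)) {
    src <- cov_map[[cv]]
    if (src %in% names(periods) && !all(is.na(periods[[src]]))) {
      out[[cv]] <- periods[[src]]
      info <- rbind(info, data.frame(
        column = cv, layer = NA_character_, radius = NA_real_,
        kind = "covariate",
        unit = switch(cv, nox = "ppb", temperature = "degC",
                      relative_humidity = "percent", uv = "unitless"),
        sign_prior = unname(covariate_priors[cv] %|na|% "unconstrained"),
        stringsAsFactors = FALSE
      ))
    }
  }
  out$altitude <- stations$altitude[sidx]
  info <- rbind(info, data.frame(
    column = "altitude", layer = NA_character_, radius = NA_real_,
    kind = "covariate", unit = "m",
    sign_prior = unname(covariate_priors["altitude"] %|na|% "unconstrained"),
    stringsAsFactors = FALSE
  ))

  info$constant <- vapply(info$column, function(cn) {
    v <- out[[cn]]
    v <- v[!is.na(v)]
    length(unique(v)) <= 1
  }, logical(1))
  rownames(info) <- NULL
  attr(out, "column_info") <- info
  class(out) <- c("predictor_table", "data.frame")
  out
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Column metadata of a predictor table
#'
#' @param design a `predictor_table` from [build_design_matrix()].
#' @return the `column_info` data frame (column, layer, radius, kind, unit,
#'   sign_prior, constant).
#' @export
column_info <- function(design) {
  ci <- attr(design, "column_info")
  if (is.null(ci)) stopf("design has no column_info attribute")
  ci
}

# candidate columns eligible for selection (non-constant predictors)
candidate_columns <- function(design) {
  ci <- column_info(design)
  ci$column[!ci$constant]
}

# named vector of sign priors for all predictor columns
design_priors <- function(design) {
  ci <- column_info(design)
  stats::setNames(ci$sign_prior, ci$column)
}

#' Restrict a predictor table to selected predictor columns
#'
#' Keeps the key columns (`station_id`, `period`, `year`) plus the requested
#' predictor columns, with the column metadata filtered accordingly. Useful
#' for fitting or validating against a fixed candidate set.
#'
#' @param design a `predictor_table`.
#' @param columns predictor column names to keep.
#' @return a `predictor_table`.
#' @export
keep_columns <- function(design, columns) {
  ci <- column_info(design)
  missing_cols <- setdiff(columns, ci$column)
  if (length(missing_cols) > 0) {
    stopf("column(s) not in design: %s", paste(missing_cols, collapse = ", "))
  }
  keys <- intersect(c("station_id", "period", "year"), names(design))
  out <- as.data.frame(design)[, c(keys, columns), drop = FALSE]
  attr(out, "column_info") <- ci[ci$column %in% columns, , drop = FALSE]
  class(out) <- c("predictor_table", "data.frame")
  out
}
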