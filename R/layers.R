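DEFAULT_RADII <- c(25, 50, 100, 250, 500, 750, 1000, 1250, 1500, 1750, 2000,
                   2500, 3000, 3500, 4000, 4500, 5000)

#' Default circular-buffer radius ladder
#'
#' Radii in metres at which buffer predictors are extracted. The coarse
#' default covers every radius used by published buffer-based LUR models on
#' the 25 m to 5000 m range; `dense = TRUE` yields the full 25 m step grid
#' (200 radii).
#'
#' @param dense logical; return every 25 m from 25 to 5000.
#' @return numeric vector of radii (m), strictly increasing.
#' @export
buffer_radii <- function(dense = FALSE) {
  if (dense) seq(25, 5000, by = 25) else DEFAULT_RADII
}

#' Construct a geospatial predictor layer
#'
#' A `geo_layer` bundles one predictor source (point, line or polygon
#' geometry, or a regular raster grid) with the metadata the selection
#' algorithm needs: its a-priori direction of effect (`sign_prior`) and how it
#' is turned into predictor columns (`mode = "buffer"` at a ladder of radii,
#' or `mode = "nearest_distance"`).
#'
#' Coordinates are planar metres in a single projected CRS throughout; no
#' geodesic computation is performed anywhere in the package.
#'
#' @param name layer name; used as the column-name stem.
#' @param kind `"points"`, `"lines"`, `"polygons"` or `"raster"`.
#' @param geometry for points: an n x 2 numeric matrix; for lines: a list of
#'   polyline matrices (each m x 2); for polygons: a list of simple-ring
#'   matrices (each m x 2, not necessarily closed); for rasters: a
#'   [raster_grid()].
#' @param sign_prior `"positive"`, `"negative"` or `"unconstrained"`.
#' @param mode `"buffer"` or `"nearest_distance"` (points only).
#' @param radii buffer radii in metres, strictly increasing, within
#'   \[25, 5000\]; required iff `mode = "buffer"`.
#' @return an object of class `geo_layer`.
#' @export
geo_layer <- function(name, kind = c("points", "lines", "polygons", "raster"),
                      geometry, sign_prior = "unconstrained",
                      mode = c("buffer", "nearest_distance"),
                      radii = buffer_radii()) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  sign_prior <- check_sign_prior(sign_prior)
  if (mode == "nearest_distance" && kind != "points") {
    stopf("nearest_distance mode requires a point layer")
  }
  if (mode == "buffer") {
    if (!is.numeric(radii) || length(radii) == 0) {
      stopf("buffer mode requires a non-empty radii vector")
    }
    if (any(diff(radii) <= 0)) stopf("radii must be strictly increasing")
    if (any(radii < 25 | radii > 5000)) stopf("radii must lie in [25, 5000] m")
  } else {
    radii <- numeric(0)
  }
  geometry <- switch(kind,
    points = {
      m <- as.matrix(geometry)
      if (length(m) == 0) m <- matrix(numeric(0), ncol = 2)
      if (ncol(m) != 2) stopf("point geometry must be an n x 2 matrix")
      storage.mode(m) <- "double"
      dimnames(m) <- NULL
      m
    },
    lines = {
      if (!is.list(geometry)) stopf("line geometry must be a list of matrices")
      lapply(geometry, function(g) {
        g <- as.matrix(g)
        if (ncol(g) != 2 || nrow(g) < 2) {
          stopf("each polyline must be an m x 2 matrix with m >= 2")
        }
        storage.mode(g) <- "double"
        dimnames(g) <- NULL
        g
      })
    },
    polygons = {
      if (!is.list(geometry)) {
        stopf("polygon geometry must be a list of ring matrices")
      }
      lapply(seq_along(geometry), function(i) {
        g <- as.matrix(geometry[[i]])
        if (ncol(g) != 2 || nrow(g) < 3) {
          stopf("polygon %d: ring must be an m x 2 matrix with m >= 3", i)
        }
        # drop an explicit closing vertex
        if (all(g[1, ] == g[nrow(g), ])) g <- g[-nrow(g), , drop = FALSE]
        storage.mode(g) <- "double"
        dimnames(g) <- NULL
        if (!is_simple_polygon_cpp(g)) {
          stopf("polygon %d is not simple (self-intersecting)", i)
        }
        g
      })
    },
    raster = {
      if (!inherits(geometry, "raster_grid")) {
        stopf("raster geometry must be a raster_grid object")
      }
      geometry
    }
  )
  structure(
    list(name = name, kind = kind, geometry = geometry,
         sign_prior = sign_prior, mode = mode, radii = radii),
    class = "geo_layer"
  )
}

#' @export
print.geo_layer <- function(x, ...) {
  n <- switch(x$kind,
    points = nrow(x$geometry),
    lines = length(x$geometry),
    polygons = length(x$geometry),
    raster = paste0(x$geometry$nrow, "x", x$geometry$ncol)
  )
  cat(sprintf("<geo_layer> %s: %s (%s features), prior %s, mode %s\n",
              x$name, x$kind, paste(n, collapse = ""), x$sign_prior, x$mode))
  invisible(x)
}

#' Construct a regular raster grid
#'
#' A north-up regular grid of cell values on a planar metre CRS. `values` is
#' stored with row 1 at the top (largest y), matching the ESRI ASCII grid
#' layout; `origin` is the lower-left corner of the grid.
#'
#' @param origin numeric length-2, (x, y) of the lower-left corner in metres.
#' @param cellsize cell edge length in metres, positive.
#' @param values numeric matrix of cell values, row 1 = northernmost row.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(origin, cellsize, values) {
  if (length(origin) != 2 || !all(is.finite(origin))) {
    stopf("origin must be a finite (x, y) pair")
  }
  if (!is_scalar_number(cellsize) || cellsize <= 0) {
    stopf("cellsize must be positive")
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(
    list(origin = as.numeric(origin), cellsize = as.numeric(cellsize),
         nrow = nrow(values), ncol = ncol(values), values = values),
    class = "raster_grid"
  )
}

# cell-centre coordinates; row 1 is the top (north) row
raster_cell_centers <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$ncol) - 0.5) * grid$cellsize
  ys <- grid$origin[2] + (grid$nrow - seq_len(grid$nrow) + 0.5) * grid$cellsize
  list(x = xs, y = ys)
}

#' Sample a raster at arbitrary points
#'
#' Returns the value of the cell containing each point, or `NA` for points
#' outside the grid extent.
#'
#' @param grid a [raster_grid()].
#' @param xy n x 2 matrix of point coordinates (metres).
#' @return numeric vector of length n.
#' @export
raster_sample <- function(grid, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  col <- floor((xy[, 1] - grid$origin[1]) / grid$cellsize) + 1
  row_from_bottom <- floor((xy[, 2] - grid$origin[2]) / grid$cellsize) + 1
  row <- grid$nrow - row_from_bottom + 1
  ok <- col >= 1 & col <= grid$ncol & row >= 1 & row <= grid$nrow
  out <- rep(NA_real_, nrow(xy))
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out
}

#' Write a raster grid as an ESRI ASCII grid
#'
#' @param grid a [raster_grid()].
#' @param path output path (conventionally `.asc`).
#' @param nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  vals <- grid$values
  vals[is.na(vals)] <- nodata
  writeLines(apply(vals, 1, function(r) paste(format(r, digits = 17,
                                                     trim = TRUE,
                                                     scientific = FALSE),
                                              collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to an ESRI ASCII grid file.
#' @return a [raster_grid()]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  ncols <- as.integer(hdr$ncols)
  nrows <- as.integer(hdr$nrows)
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  raster_grid(c(xll, yll), hdr$cellsize, m)
}

#' Write vector layer geometry as GeoJSON
#'
#' Serializes a point, line or polygon `geo_layer`'s geometry as a GeoJSON
#' FeatureCollection (coordinates in planar metres, not longitude/latitude).
#' Layer metadata (sign prior, mode, radii) is stored in the collection's
#' `properties` member so the file round-trips through [read_layer_geojson()].
#'
#' @param layer a vector `geo_layer`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layer_geojson <- function(layer, path) {
  if (layer$kind == "raster") stopf("use write_ascii_grid() for rasters")
  coords <- switch(layer$kind,
    points = lapply(seq_len(nrow(layer$geometry)),
                    function(i) as.numeric(layer$geometry[i, ])),
    lines = lapply(layer$geometry, function(g) {
      lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
    }),
    polygons = lapply(layer$geometry, function(g) {
      g <- rbind(g, g[1, ])  # close the ring per GeoJSON
      list(lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ])))
    })
  )
  gtype <- switch(layer$kind, points = "Point", lines = "LineString",
                  polygons = "Polygon")
  features <- lapply(coords, function(cc) {
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = gtype, coordinates = cc))
  })
  fc <- list(
    type = "FeatureCollection",
    properties = list(name = layer$name, sign_prior = layer$sign_prior,
                      mode = layer$mode, radii = as.numeric(layer$radii),
                      kind = layer$kind),
    features = features
  )
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a vector layer from GeoJSON
#'
#' Reads Point/MultiPoint, LineString/MultiLineString and
#' Polygon/MultiPolygon features (outer rings only; coordinates in planar
#' metres). Layer metadata is taken from the collection `properties` written
#' by [write_layer_geojson()] unless overridden by the arguments.
#'
#' @param path GeoJSON file path.
#' @param name,sign_prior,mode,radii optional overrides of the stored
#'   metadata.
#' @return a `geo_layer`.
#' @export
read_layer_geojson <- function(path, name = NULL, sign_prior = NULL,
                               mode = NULL, radii = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    stopf("expected a GeoJSON FeatureCollection")
  }
  meta <- fc$properties %||% list()
  name <- name %||% meta$name %||% tools::file_path_sans_ext(basename(path))
  sign_prior <- sign_prior %||% meta$sign_prior %||% "unconstrained"
  mode <- mode %||% meta$mode %||% "buffer"
  radii <- radii %||% (if (length(meta$radii) > 0) unlist(meta$radii)
                       else buffer_radii())

  to_mat <- function(cc) {
    do.call(rbind, lapply(cc, function(p) as.numeric(unlist(p)[1:2])))
  }
  pts <- list(); lns <- list(); pls <- list()
  for (f in fc$features) {
    g <- f$geometry
    switch(g$type,
      Point = { pts[[length(pts) + 1]] <- as.numeric(unlist(g$coordinates)[1:2]) },
      MultiPoint = { for (p in g$coordinates)
        pts[[length(pts) + 1]] <- as.numeric(unlist(p)[1:2]) },
      LineString = { lns[[length(lns) + 1]] <- to_mat(g$coordinates) },
      MultiLineString = { for (l in g$coordinates)
        lns[[length(lns) + 1]] <- to_mat(l) },
      Polygon = { pls[[length(pls) + 1]] <- to_mat(g$coordinates[[1]]) },
      MultiPolygon = { for (p in g$coordinates)
        pls[[length(pls) + 1]] <- to_mat(p[[1]]) },
      stopf("unsupported GeoJSON geometry type: %s", g$type)
    )
  }
  if (length(pts) > 0) {
    geo_layer(name, "points", do.call(rbind, pts), sign_prior, mode,
              radii = radii)
  } else if (length(lns) > 0) {
    geo_layer(name, "lines", lns, sign_prior, "buffer", radii = radii)
  } else if (length(pls) > 0) {
    geo_layer(name, "polygons", pls, sign_prior, "buffer", radii = radii)
  } else {
    # empty collection: default to an empty point layer
    geo_layer(name, "points", matrix(numeric(0), ncol = 2), sign_prior, mode,
              radii = radii)
  }
}
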