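test_that("point counting uses a closed disk and matches brute force", {
  empty <- geo_layer("p", "points", matrix(numeric(0), ncol = 2))
  expect_identical(count_points_in_buffer(empty, c(0, 0), 1000), 0L)

  ring <- geo_layer("p", "points",
                    cbind(c(100, 400, 600), c(0, 0, 0)))
  expect_equal(count_points_in_buffer(ring, c(0, 0), 500), 2)

  center_pt <- geo_layer("p", "points", cbind(0, 0))
  expect_equal(count_points_in_buffer(center_pt, c(0, 0), 25), 1)

  # boundary point exactly at distance r is included
  bd <- geo_layer("p", "points", cbind(300, 400))  # distance 500
  expect_equal(count_points_in_buffer(bd, c(0, 0), 500), 1)

  set.seed(21)
  for (i in 1:20) {
    pts <- cbind(runif(80, -2000, 2000), runif(80, -2000, 2000))
    lay <- geo_layer("p", "points", pts)
    ctr <- runif(2, -500, 500)
    r <- runif(1, 50, 1500)
    brute <- sum(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2) <= r)
    expect_equal(count_points_in_buffer(lay, ctr, r), brute)
  }
})

test_that("line clipping is exact on closed forms and matches dense sampling", {
  through <- geo_layer("l", "lines", list(cbind(c(-5000, 5000), c(0, 0))))
  expect_equal(line_length_in_buffer(through, c(0, 0), 500), 1000,
               tolerance = 1e-12)
  outside <- geo_layer("l", "lines", list(cbind(c(-5000, 5000), c(600, 600))))
  expect_equal(line_length_in_buffer(outside, c(0, 0), 500), 0)
  # chord at offset d has length 2*sqrt(r^2 - d^2)
  chord <- geo_layer("l", "lines", list(cbind(c(-5000, 5000), c(300, 300))))
  expect_equal(line_length_in_buffer(chord, c(0, 0), 500), 2 * sqrt(500^2 - 300^2),
               tolerance = 1e-12)
  # degenerate zero-length segment contributes nothing
  degen <- geo_layer("l", "lines", list(cbind(c(10, 10), c(10, 10))))
  expect_equal(line_length_in_buffer(degen, c(0, 0), 500), 0)

  set.seed(31)
  for (i in 1:5) {
    lines <- replicate(6, {
      p <- runif(2, -800, 800)
      q <- p + runif(2, -1200, 1200)
      rbind(p, q)
    }, simplify = FALSE)
    lay <- geo_layer("l", "lines", lines)
    r <- runif(1, 200, 700)
    got <- line_length_in_buffer(lay, c(0, 0), r)
    want <- oracle_line_length(lines, c(0, 0), r, step = 0.01)
    expect_equal(got, want, tolerance = 5e-3)
  }
})

test_that("polygon clipping matches closed forms, the Monte-Carlo oracle, and unions overlaps", {
  big <- geo_layer("g", "polygons", list(random_ring(0, 0, 1e4, 1e4)))
  expect_equal(polygon_area_in_buffer(big, c(0, 0), 500), pi * 500^2,
               tolerance = 5e-4)
  half <- geo_layer("g", "polygons", list(random_ring(1e4, 0, 1e4, 2e4)))
  expect_equal(polygon_area_in_buffer(half, c(0, 0), 500), pi * 500^2 / 2,
               tolerance = 5e-4)

  set.seed(41)
  for (i in 1:4) {
    rings <- replicate(3, random_ring(runif(1, -400, 400), runif(1, -400, 400),
                                      runif(1, 100, 600), runif(1, 100, 600)),
                       simplify = FALSE)
    r <- runif(1, 300, 800)
    lay <- geo_layer("g", "polygons", rings)
    got <- polygon_area_in_buffer(lay, c(0, 0), r)
    mc <- oracle_polygon_area_mc(rings, c(0, 0), r, n = 2e5)
    expect_lt(abs(got - mc$area), 3 * mc$se + 1e-9)
  }

  # duplicated polygon must not double the area
  ring <- random_ring(0, 0, 600, 100)
  one <- polygon_area_in_buffer(geo_layer("g", "polygons", list(ring)),
                                c(0, 0), 5000)
  two <- polygon_area_in_buffer(geo_layer("g", "polygons", list(ring, ring)),
                                c(0, 0), 5000)
  expect_equal(one, 1200 * 200, tolerance = 1e-9)
  expect_equal(two, one, tolerance = 1e-12)
})

test_that("self-intersecting polygons are rejected with their index", {
  bowtie <- cbind(c(0, 100, 0, 100), c(0, 100, 100, 0))
  expect_error(geo_layer("g", "polygons", list(random_ring(0, 0, 1, 1), bowtie)),
               "polygon 2")
})

test_that("raster buffer means are exact against cell-centre enumeration", {
  const <- raster_grid(c(0, 0), 100, matrix(3.5, 20, 20))
  lay <- geo_layer("r", "raster", const, radii = c(250, 500))
  expect_equal(raster_mean_in_buffer(lay, c(1000, 1000), 300), 3.5)
  expect_equal(raster_mean_in_buffer(lay, c(1000, 1000), 900), 3.5)

  # radius capturing exactly one cell centre returns that cell's value
  set.seed(51)
  vals <- matrix(runif(400), 20, 20)
  g <- raster_grid(c(0, 0), 100, vals)
  lay2 <- geo_layer("r", "raster", g, radii = c(250, 500))
  # cell centre at (950, 950): row 11 from top (y), col 10
  expect_equal(raster_mean_in_buffer(lay2, c(950, 950), 49), vals[11, 10])

  for (i in 1:10) {
    ctr <- runif(2, 200, 1800)
    r <- runif(1, 60, 700)
    expect_equal(raster_mean_in_buffer(lay2, ctr, r),
                 oracle_raster_mean(g, ctr, r), tolerance = 1e-12)
  }

  # entirely outside the extent: NA with a warning
  expect_warning(v <- raster_mean_in_buffer(lay2, c(10000, 10000), 100),
                 "outside")
  expect_true(is.na(v))
})

test_that("nearest distance matches brute force and rejects empty layers", {
  single <- geo_layer("p", "points", cbind(1234.5, 0), mode = "nearest_distance")
  expect_equal(nearest_distance(single, c(0, 0)), 1234.5, tolerance = 1e-12)
  expect_equal(nearest_distance(single, c(1234.5, 0)), 0)

  set.seed(61)
  pts <- cbind(runif(100, -5000, 5000), runif(100, -5000, 5000))
  lay <- geo_layer("p", "points", pts, mode = "nearest_distance")
  ctr <- c(123, -456)
  brute <- min(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2))
  expect_equal(nearest_distance(lay, ctr), brute, tolerance = 1e-12)

  empty <- geo_layer("p", "points", matrix(numeric(0), ncol = 2),
                     mode = "nearest_distance")
  expect_error(nearest_distance(empty, c(0, 0)), "empty")
})

test_that("buffer values are monotone in radius and translation invariant", {
  set.seed(71)
  pts <- cbind(runif(60, 0, 4000), runif(60, 0, 4000))
  lines <- replicate(10, {
    p <- runif(2, 0, 4000); rbind(p, p + runif(2, -1500, 1500))
  }, simplify = FALSE)
  rings <- replicate(6, random_ring(runif(1, 0, 4000), runif(1, 0, 4000),
                                    runif(1, 100, 900), runif(1, 100, 900)),
                     simplify = FALSE)
  radii <- buffer_radii()
  pl <- geo_layer("p", "points", pts)
  ll <- geo_layer("l", "lines", lines)
  gl <- geo_layer("g", "polygons", rings)
  for (ctr in list(c(2000, 2000), c(500, 3500))) {
    counts <- vapply(radii, function(r) count_points_in_buffer(pl, ctr, r) + 0,
                     numeric(1))
    lens <- vapply(radii, function(r) line_length_in_buffer(ll, ctr, r),
                   numeric(1))
    areas <- vapply(radii, function(r) polygon_area_in_buffer(gl, ctr, r),
                    numeric(1))
    expect_true(all(diff(counts) >= 0))
    expect_true(all(diff(lens) >= -1e-9))
    expect_true(all(diff(areas) >= -1e-6))
  }

  shift <- c(12345.6, -9876.5)
  pl2 <- geo_layer("p", "points", sweep(pts, 2, -shift))
  ll2 <- geo_layer("l", "lines", lapply(lines, function(g) sweep(g, 2, -shift)))
  gl2 <- geo_layer("g", "polygons", lapply(rings, function(g) sweep(g, 2, -shift)))
  ctr <- c(2000, 2000)
  expect_equal(count_points_in_buffer(pl2, ctr + shift, 1500),
               count_points_in_buffer(pl, ctr, 1500))
  expect_equal(line_length_in_buffer(ll2, ctr + shift, 1500),
               line_length_in_buffer(ll, ctr, 1500), tolerance = 1e-9)
  expect_equal(polygon_area_in_buffer(gl2, ctr + shift, 1500),
               polygon_area_in_buffer(gl, ctr, 1500), tolerance = 1e-9)
})

test_that("buffer values are local: geometry beyond r + eps is irrelevant", {
  set.seed(81)
  ctr <- c(0, 0)
  r <- 800
  pts <- cbind(runif(80, -3000, 3000), runif(80, -3000, 3000))
  keep_p <- sqrt(rowSums(sweep(pts, 2, ctr)^2)) <= r + 1
  expect_equal(
    count_points_in_buffer(geo_layer("p", "points", pts), ctr, r),
    count_points_in_buffer(geo_layer("p", "points", pts[keep_p, , drop = FALSE]),
                           ctr, r)
  )
  lines <- replicate(12, {
    p <- runif(2, -2500, 2500); rbind(p, p + runif(2, -1000, 1000))
  }, simplify = FALSE)
  keep_l <- vapply(lines, function(g) {
    point_segment_dist(ctr, g[1, ], g[2, ]) <= r + 1
  }, logical(1))
  expect_equal(
    line_length_in_buffer(geo_layer("l", "lines", lines), ctr, r),
    line_length_in_buffer(geo_layer("l", "lines", lines[keep_l]), ctr, r),
    tolerance = 1e-9
  )
})

test_that("design matrix composes per-operation extractions and repeats static layers", {
  stations <- data.frame(
    station_id = c("A", "B"), x = c(1000, 3000), y = c(1000, 2500),
    altitude = c(10, 200), station_class = "general",
    stringsAsFactors = FALSE
  )
  periods <- data.frame(
    station_id = rep(c("A", "B"), each = 3),
    period = rep(as.character(2010:2012), 2), year = rep(2010:2012, 2),
    mean_nox = c(20, 21, 22, 10, 11, 12), mean_temperature = 23,
    mean_rh = 70, stringsAsFactors = FALSE
  )
  set.seed(91)
  pts <- cbind(runif(40, 0, 4000), runif(40, 0, 4000))
  temple <- geo_layer("temple", "points", pts, "negative", radii = c(500, 1000))
  roads <- geo_layer("road", "lines",
                     replicate(8, {
                       p <- runif(2, 0, 4000); rbind(p, p + runif(2, -2000, 2000))
                     }, simplify = FALSE), "negative", radii = c(500, 1000))
  plant <- geo_layer("power_plant", "points", cbind(c(100, 3900), c(100, 3900)),
                     "unconstrained", mode = "nearest_distance")

  design <- build_design_matrix(stations, periods, list(temple, roads, plant))
  expect_equal(nrow(design), 6)
  expect_true(all(c("temple@500", "temple@1000", "road@500", "road@1000",
                    "power_plant@dist", "nox", "altitude") %in% names(design)))

  # static layers repeat across years within a station
  for (cn in c("temple@500", "road@1000", "power_plant@dist")) {
    expect_equal(length(unique(design[[cn]][design$station_id == "A"])), 1)
  }
  # cell-by-cell match with individually invoked operations
  for (si in 1:2) {
    ctr <- c(stations$x[si], stations$y[si])
    row <- design[design$station_id == stations$station_id[si], ][1, ]
    expect_equal(row[["temple@500"]], count_points_in_buffer(temple, ctr, 500) + 0)
    expect_equal(row[["temple@1000"]], count_points_in_buffer(temple, ctr, 1000) + 0)
    expect_equal(row[["road@500"]], line_length_in_buffer(roads, ctr, 500),
                 tolerance = 1e-12)
    expect_equal(row[["power_plant@dist"]], nearest_distance(plant, ctr),
                 tolerance = 1e-12)
  }
  expect_equal(design$nox, periods$mean_nox)
  expect_equal(design$altitude, stations$altitude[rep(1:2, each = 3)])

  # zero layers: only covariate columns
  d0 <- build_design_matrix(stations, periods, list())
  expect_equal(sort(column_info(d0)$column),
               sort(c("nox", "temperature", "relative_humidity", "altitude")))

  # station referenced by periods but missing from the table
  bad <- periods
  bad$station_id[1] <- "ZZ"
  expect_error(build_design_matrix(stations, bad, list()), "ZZ")
})

test_that("constant columns are flagged and excluded from candidacy", {
  stations <- data.frame(station_id = c("A", "B", "C"), x = c(0, 10000, 20000),
                         y = 0, altitude = 5, station_class = "general",
                         stringsAsFactors = FALSE)
  periods <- data.frame(station_id = c("A", "B", "C"), period = "2010",
                        year = 2010, mean_nox = c(1, 2, 3),
                        stringsAsFactors = FALSE)
  far <- geo_layer("temple", "points", cbind(1e6, 1e6), "negative",
                   radii = c(500))
  d <- build_design_matrix(stations, periods, list(far))
  ci <- column_info(d)
  expect_true(ci$constant[ci$column == "temple@500"])   # all-zero counts
  expect_true(ci$constant[ci$column == "altitude"])     # identical altitudes
  expect_false("temple@500" %in% lurkit:::candidate_columns(d))
})
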