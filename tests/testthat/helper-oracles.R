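# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's own geometry code paths.

# dense-sampling oracle for line length inside a disk: sample each segment at
# `step` metre intervals and count in-disk samples
oracle_line_length <- function(lines, center, radius, step = 0.01) {
  total <- 0
  for (g in lines) {
    for (i in seq_len(nrow(g) - 1)) {
      p <- g[i, ]; q <- g[i + 1, ]
      len <- sqrt(sum((q - p)^2))
      if (len == 0) next
      n <- max(ceiling(len / step), 1)
      t <- (seq_len(n) - 0.5) / n
      x <- p[1] + t * (q[1] - p[1]); y <- p[2] + t * (q[2] - p[2])
      inside <- (x - center[1])^2 + (y - center[2])^2 <= radius^2
      total <- total + sum(inside) * (len / n)
    }
  }
  total
}

# even-odd point-in-polygon test, vectorized over points
points_in_ring <- function(x, y, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Monte-Carlo oracle for the area of (union of rings) intersected with a disk
oracle_polygon_area_mc <- function(rings, center, radius, n = 1e6) {
  u <- runif(n); th <- runif(n, 0, 2 * pi)
  r <- radius * sqrt(u)
  x <- center[1] + r * cos(th); y <- center[2] + r * sin(th)
  hit <- rep(FALSE, n)
  for (ring in rings) hit <- hit | points_in_ring(x, y, ring)
  p <- mean(hit)
  disk <- pi * radius^2
  list(area = p * disk, se = disk * sqrt(p * (1 - p) / n))
}

# exhaustive cell-centre enumeration oracle for raster buffer means
oracle_raster_mean <- function(grid, center, radius) {
  vals <- c()
  for (i in seq_len(grid$nrow)) {
    for (j in seq_len(grid$ncol)) {
      cx <- grid$origin[1] + (j - 0.5) * grid$cellsize
      cy <- grid$origin[2] + (grid$nrow - i + 0.5) * grid$cellsize
      if ((cx - center[1])^2 + (cy - center[2])^2 <= radius^2) {
        vals <- c(vals, grid$values[i, j])
      }
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# true point-to-segment distance (for locality tests)
point_segment_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

# a reduced scene for fast module tests: same processes, smaller region
tiny_scene_config <- function(seed = 1, ...) {
  scene_config(
    seed = seed,
    region = c(20000, 20000), n_stations = 30, years = 2010:2012,
    intensities = list(
      n_roads = 40, n_main_roads = 8,
      n_residential = 25, n_mixed_residential = 15, n_industrial = 10,
      n_forest = 12, n_crop = 12, n_water = 8,
      n_power_plants = 4, n_incinerators = 3
    ),
    ...
  )
}

random_ring <- function(cx, cy, w, h) {
  cbind(c(cx - w, cx + w, cx + w, cx - w), c(cy - h, cy - h, cy + h, cy + h))
}
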