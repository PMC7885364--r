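# Fixture builders shared across test files.

# n x n grid of unit segments with given spacing; returns road_segments
grid_segments <- function(n, spacing = 100, accessible = TRUE) {
  geoms <- list()
  for (j in seq_len(n + 1L)) for (i in seq_len(n)) {
    geoms[[length(geoms) + 1L]] <-
      rbind(c((i - 1) * spacing, (j - 1) * spacing),
            c(i * spacing, (j - 1) * spacing))
  }
  for (i in seq_len(n + 1L)) for (j in seq_len(n)) {
    geoms[[length(geoms) + 1L]] <-
      rbind(c((i - 1) * spacing, (j - 1) * spacing),
            c((i - 1) * spacing, j * spacing))
  }
  road_segments(geoms, segment_id = sprintf("g%03d", seq_along(geoms)),
                accessible = accessible)
}

# rectangular parcel covering [x0,x1] x [y0,y1]
rect_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# wall-to-wall checkerboard mosaic of cell_m-sized parcels over an extent
checkerboard_parcels <- function(extent, cell_m, classes, year = 2003,
                                 scheme = lum_default_scheme()) {
  nx <- ceiling((extent[2] - extent[1]) / cell_m)
  ny <- ceiling((extent[4] - extent[3]) / cell_m)
  geoms <- list(); cls <- character(0)
  k <- 0
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    x0 <- extent[1] + (i - 1) * cell_m
    y0 <- extent[3] + (j - 1) * cell_m
    geoms[[length(geoms) + 1L]] <- rect_ring(x0, y0, x0 + cell_m, y0 + cell_m)
    cls <- c(cls, classes[((i + j) %% length(classes)) + 1L])
    k <- k + 1
  }
  land_parcels(geoms, cls, valid_year = year, scheme = scheme)
}

# balanced toy panel with known within/between structure, no covariates
balanced_panel <- function(n_persons = 40, waves = 3, beta_w = -5,
                           beta_b = 10, sd_v = 30, sd_e = 40, seed = 1) {
  set.seed(seed)
  id <- rep(sprintf("p%03d", seq_len(n_persons)), each = waves)
  xbar <- rep(rnorm(n_persons, 3, 1), each = waves)
  dm <- matrix(rnorm(n_persons * waves), n_persons, waves)
  dm <- dm - rowMeans(dm)
  dev <- as.vector(t(dm)) # person-major, matching id
  x <- xbar + dev
  v <- rep(rnorm(n_persons, 0, sd_v), each = waves)
  y <- 100 + beta_w * dev + beta_b * xbar + v + rnorm(n_persons * waves, 0, sd_e)
  data.frame(person_id = id, wave_id = rep(seq_len(waves), n_persons),
             x = x, y = y)
}

# small complete synthetic panel for harmonize/impute tests
tiny_config <- function(seed = 42, ...) {
  world_config(seed = seed, grid_n = 10L, n_persons_a = 30L,
               n_persons_b = 20L, ...)
}
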