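# Land-use clipping, the entropy score and exposure linkage.

make_buffer <- function(d = 200, w = 25, center = c(500, 500), n = 4) {
  net <- build_network(grid_segments(n, spacing = 250))
  org <- snap_to_network(center, net, max_snap_m = 100)
  sausage_buffer(reachable_subnetwork(net, org, d), w)
}

test_that("clip_land_use computes per-class shares over the covered area", {
  buf <- make_buffer()
  # one giant residential parcel: share 1
  big <- land_parcels(list(rect_ring(-500, -500, 1500, 1500)), "residential",
                      valid_year = 2003)
  tab <- clip_land_use(buf, big)
  expect_equal(unname(tab$share["residential"]), 1)
  expect_equal(sum(tab$share), 1)
  expect_equal(attr(tab, "gap_fraction"), 0, tolerance = 1e-9)

  # two half-planes split through the buffer's symmetric center: 50/50
  halves <- land_parcels(list(rect_ring(-500, -500, 500, 1500),
                              rect_ring(500, -500, 1500, 1500)),
                         c("residential", "retail"), valid_year = 2003)
  tab2 <- clip_land_use(buf, halves)
  expect_equal(unname(tab2$share["residential"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(tab2$share["retail"]), 0.5, tolerance = 1e-6)

  # absent classes carry share 0
  expect_equal(unname(tab2$share["water"]), 0)
})

test_that("checkerboard clip matches the 0.5-m rasterization oracle", {
  buf <- make_buffer(d = 300)
  classes <- c("residential", "retail", "parks_green")
  parc <- checkerboard_parcels(c(-100, 1100, -100, 1100), 150, classes)
  tab <- clip_land_use(buf, parc)

  # oracle: raster over the reachable segments dilated by w
  net <- build_network(grid_segments(4, spacing = 250))
  org <- snap_to_network(c(500, 500), net, max_snap_m = 100)
  re <- reachable_subnetwork(net, org, 300)
  segs <- do.call(rbind, lapply(re, function(p)
    cbind(p[-nrow(p), 1], p[-nrow(p), 2], p[-1, 1], p[-1, 2])))
  rects <- do.call(rbind, lapply(seq_along(parc$parcel_id), function(k) {
    r <- parc$geometry[[k]][[1]]
    data.frame(x0 = min(r[, 1]), y0 = min(r[, 2]), x1 = max(r[, 1]),
               y1 = max(r[, 2]), class = parc$class_label[k])
  }))
  oracle <- raster_class_areas(segs, 25, rects, cell = 0.5)
  for (cl in classes) {
    expect_lt(abs(tab$area_m2[cl] / oracle[cl] - 1), 0.005)
  }
})

test_that("clip_land_use flags gaps and rejects zero coverage", {
  buf <- make_buffer()
  partial <- land_parcels(list(rect_ring(-500, -500, 520, 1500)),
                          "residential", valid_year = 2003)
  expect_warning(clip_land_use(buf, partial), "gap")
  far <- land_parcels(list(rect_ring(5000, 5000, 6000, 6000)), "water",
                      valid_year = 2003)
  expect_error(clip_land_use(buf, far), "no land-use coverage")
})

test_that("entropy matches the printed anchor values", {
  # perfectly even mix over all 11 classes: exactly 1
  expect_equal(entropy_lum(class_area_table(rep(1, 11))), 1)
  # single class: exactly 0 (0 * ln 0 convention)
  expect_equal(entropy_lum(class_area_table(c(residential = 7))), 0)
  # two classes at 0.5/0.5 under N = 11: ln 2 / ln 11
  tab <- class_area_table(c(residential = 5, retail = 5))
  expect_equal(entropy_lum(tab), log(2) / log(11), tolerance = 1e-12)
  expect_equal(log(2) / log(11), 0.289065, tolerance = 1e-5)
})

test_that("entropy properties hold on randomized share vectors", {
  set.seed(7)
  N <- 11
  for (i in 1:200) {
    k <- sample(1:N, 1)
    a <- numeric(N)
    a[sample(N, k)] <- rgamma(k, 1)
    e <- entropy_lum(class_area_table(setNames(a, lum_default_scheme())))
    expect_gte(e, 0)
    expect_lte(e, 1)
    # 1 iff all shares equal over all N classes; 0 iff a point mass
    if (k < N) expect_lt(e, 1)
    if (k > 1 && sd(a[a > 0]) > 1e-9) expect_lt(e, 1)
    if (k == 1) expect_equal(e, 0)
    # permutation invariance
    expect_equal(e, entropy_lum(class_area_table(
      setNames(sample(a), lum_default_scheme()))))
    # merging two classes never increases entropy
    if (k >= 2) {
      nz <- which(a > 0)
      pick <- sample(nz, 2)
      a2 <- a
      a2[pick[1]] <- a[pick[1]] + a[pick[2]]
      a2[pick[2]] <- 0
      e2 <- entropy_lum(class_area_table(setNames(a2, lum_default_scheme())))
      expect_lte(e2, e + 1e-12)
    }
  }
  expect_equal(entropy_lum(class_area_table(rep(1, 11))), 1)
  expect_error(entropy_lum(rep(1, 1)), "N < 2")
})

test_that("exposure records carry lum_scaled = 10 x entropy exactly", {
  buf <- make_buffer()
  halves <- land_parcels(list(rect_ring(-500, -500, 500, 1500),
                              rect_ring(500, -500, 1500, 1500)),
                         c("residential", "retail"), valid_year = 2003)
  rec <- exposure_records(list(buf), halves, person_id = "p1", wave_id = 1)
  expect_equal(rec$lum_scaled, 10 * rec$lum_entropy)
  expect_equal(rec$exposure_year, 2003)
})

test_that("link_exposure enforces chronology and counts exclusions", {
  panel <- data.frame(person_id = rep(c("p1", "p2"), each = 2),
                      wave_id = rep(1:2, 2),
                      fieldwork_year = rep(c(2004, 2011), 2))
  expo <- expand.grid(person_id = c("p1", "p2"), wave_id = 1:2,
                      buffer_size_m = 1000, stringsAsFactors = FALSE)
  expo$exposure_year <- ifelse(expo$wave_id == 1, 2003, 2010)
  expo$lum_entropy <- seq(0.1, 0.4, length.out = 4)
  expo$lum_scaled <- 10 * expo$lum_entropy
  linked <- link_exposure(panel, expo, c("1" = 2003, "2" = 2010))
  expect_equal(nrow(linked), 4L)
  expect_true(all(c("lum_entropy_1000", "lum_scaled_1000") %in% names(linked)))
  expect_equal(attr(linked, "n_excluded_no_exposure"), 0L)

  # a person-wave without an exposure record is excluded and counted
  expo2 <- expo[-2, ]
  linked2 <- suppressMessages(link_exposure(panel, expo2,
                                            c("1" = 2003, "2" = 2010)))
  expect_equal(nrow(linked2), 3L)
  expect_equal(attr(linked2, "n_excluded_no_exposure"), 1L)

  # mapping a wave to a year after fieldwork violates chronology
  expect_error(link_exposure(panel, expo, c("1" = 2005, "2" = 2010)),
               "exposure must precede outcome")
  # a wave without a mapping is a configuration error
  expect_error(link_exposure(panel, expo, c("1" = 2003)),
               "no exposure year mapped")
})
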