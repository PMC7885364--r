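# Road network construction, snapping, reachability, sausage buffers.

test_that("build_network merges endpoints and drops inaccessible roads", {
  # two segments sharing an endpoint: 3 nodes, 2 edges
  segs <- road_segments(list(rbind(c(0, 0), c(100, 0)),
                             rbind(c(100, 0), c(100, 100))),
                        segment_id = c("a", "b"))
  net <- build_network(segs)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)

  # highways (accessible = FALSE) are excluded
  segs2 <- road_segments(list(rbind(c(0, 0), c(100, 0)),
                              rbind(c(0, 50), c(100, 50))),
                         segment_id = c("street", "highway"),
                         accessible = c(TRUE, FALSE))
  net2 <- build_network(segs2)
  expect_equal(net2$edges$segment_id, "street")

  # 10x10 grid of unit segments: (10+1)^2 nodes, 2*10*11 edges
  net3 <- build_network(grid_segments(10))
  expect_equal(nrow(net3$nodes), 121L)
  expect_equal(nrow(net3$edges), 220L)

  # endpoints within the snap tolerance are merged into one node
  segs4 <- road_segments(list(rbind(c(0, 0), c(100, 0)),
                              rbind(c(100.004, 0.003), c(200, 0))))
  expect_equal(nrow(build_network(segs4, snap_tolerance_m = 0.01)$nodes), 3L)
})

test_that("build_network rejects empty accessible sets and degree input", {
  segs <- road_segments(list(rbind(c(0, 0), c(100, 0))), accessible = FALSE)
  expect_error(build_network(segs), "no accessible segments")
  expect_error(road_segments(list(rbind(c(4.89, 52.37), c(4.90, 52.38)))),
               "geographic")
  a <- road_segments(list(rbind(c(0, 0), c(500, 0))), crs = "EPSG:28992")
  b <- road_segments(list(rbind(c(500, 0), c(900, 0))), crs = "EPSG:32631")
  expect_error(build_network(list(a, b)), "mix coordinate reference")
})

test_that("snap_to_network finds the nearest on-edge point", {
  net <- build_network(road_segments(list(rbind(c(0, 0), c(1000, 0))),
                                     segment_id = "road"))
  # point on the edge interior
  loc0 <- snap_to_network(c(300, 0), net, max_snap_m = 50)
  expect_equal(loc0$snap_distance_m, 0)
  expect_equal(loc0$offset_m, 300)

  # 10 m perpendicular offset: snap distance 10, offset at the foot;
  # cross-checked against brute-force sampling along the edge
  loc <- snap_to_network(c(250, 10), net, max_snap_m = 50)
  expect_equal(loc$snap_distance_m, 10, tolerance = 1e-9)
  expect_equal(loc$offset_m, 250, tolerance = 1e-9)
  s <- seq(0, 1000, by = 0.01)
  expect_equal(min(sqrt((s - 250)^2 + 100)),
               loc$snap_distance_m, tolerance = 1e-3)

  # beyond max_snap_m: typed error carrying the distance
  err <- tryCatch(snap_to_network(c(500, 100), net, max_snap_m = 50),
                  lumrewb_unlocatable = function(e) e)
  expect_s3_class(err, "lumrewb_unlocatable")
  expect_equal(err$distance_m, 100, tolerance = 1e-9)
})

test_that("snap tie-break is deterministic towards the lowest segment_id", {
  net <- build_network(road_segments(
    list(rbind(c(0, 10), c(100, 10)), rbind(c(0, -10), c(100, -10))),
    segment_id = c("b", "a")))
  loc <- snap_to_network(c(50, 0), net, max_snap_m = 50)
  expect_equal(loc$segment_id, "a")
})

test_that("reachable_subnetwork cuts edges exactly at distance d", {
  # isolated 3000 m road, origin at midpoint, d = 1000: one 2000 m piece
  net <- build_network(road_segments(list(rbind(c(0, 0), c(3000, 0)))))
  org <- snap_to_network(c(1500, 0), net, max_snap_m = 10)
  re <- reachable_subnetwork(net, org, 1000)
  expect_equal(attr(re, "total_length_m"), 2000)
  expect_equal(length(re), 1L)
  expect_equal(range(re[[1]][, 1]), c(500, 2500))

  # d = 0: empty edge set
  expect_equal(length(reachable_subnetwork(net, org, 0)), 0L)
})

test_that("reachable length matches the 1-m subdivision Dijkstra oracle", {
  net <- build_network(grid_segments(10))
  center <- which(net$nodes$x == 500 & net$nodes$y == 500)
  org <- snap_to_network(c(500, 500), net, max_snap_m = 10)
  nodes <- net$nodes
  edges <- data.frame(from = net$edges$from, to = net$edges$to,
                      length = net$edges$length_m)
  for (d in c(250, 520)) {
    got <- attr(reachable_subnetwork(net, org, d), "total_length_m")
    want <- subdivision_reach_length(nodes, edges, nodes$id[center], d,
                                     step = 1)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("sausage buffer area matches closed forms and the raster oracle", {
  w <- 25
  # straight 2000 m road, d = 1000 from midpoint: area = 4dw + pi w^2
  net <- build_network(road_segments(list(rbind(c(0, 0), c(2000, 0)))))
  org <- snap_to_network(c(1000, 0), net, max_snap_m = 10)
  buf <- sausage_buffer(reachable_subnetwork(net, org, 1000), w)
  expect_equal(buf$area_m2, 4 * 1000 * w + pi * w^2, tolerance = 0.005)

  # empty reachable set: disk of radius w, flagged degenerate
  buf0 <- sausage_buffer(reachable_subnetwork(net, org, 0), w)
  expect_true(buf0$degenerate)
  expect_equal(buf0$area_m2, pi * w^2, tolerance = 0.005)

  # cross of two perpendicular 1000 m roads meeting at the origin
  # (four arms sharing the center node): 0.5-m raster oracle, 0.5%
  netx <- build_network(road_segments(list(
    rbind(c(-500, 0), c(0, 0)), rbind(c(0, 0), c(500, 0)),
    rbind(c(0, -500), c(0, 0)), rbind(c(0, 0), c(0, 500)))))
  orgx <- snap_to_network(c(0, 0), netx, max_snap_m = 10)
  bufx <- sausage_buffer(reachable_subnetwork(netx, orgx, 500), w)
  oracle <- raster_buffer_area(rbind(c(-500, 0, 500, 0), c(0, -500, 0, 500)),
                               w, cell = 0.5)
  expect_lt(abs(bufx$area_m2 / oracle - 1), 0.005)
  # and strictly less than the double-counted sum of the two capsules
  expect_lt(bufx$area_m2, 2 * (1000 * 2 * w + pi * w^2))
})

test_that("buffers are monotone in d, disk-contained, and highway-blind", {
  net <- build_network(grid_segments(10))
  pt <- c(480, 515)
  org <- snap_to_network(pt, net, max_snap_m = 100)
  sizes <- c(500, 1000, 1600)
  bufs <- lapply(sizes, function(d)
    sausage_buffer(reachable_subnetwork(net, org, d), 25))
  # monotone: area(smaller \ larger) == 0 via intersection areas
  for (i in 1:2) {
    inter <- lumrewb:::overlay_areas(bufs[[i]]$rings,
                                     list(bufs[[i + 1]]$rings))
    expect_equal(inter$area_b, bufs[[i]]$area_m2, tolerance = 1e-9)
    expect_gt(bufs[[i + 1]]$area_m2, bufs[[i]]$area_m2)
  }
  # containment in the euclidean disk of radius d + w + snap distance
  for (i in seq_along(sizes)) {
    r_max <- sizes[i] + 25 + org$snap_distance_m
    verts <- do.call(rbind, bufs[[i]]$rings)
    dist <- sqrt((verts[, 1] - pt[1])^2 + (verts[, 2] - pt[2])^2)
    expect_lte(max(dist), r_max + 1e-6)
  }
  # adding inaccessible highways changes nothing
  hw <- road_segments(list(rbind(c(-50, 505), c(1050, 505)),
                           rbind(c(505, -50), c(505, 1050))),
                      segment_id = c("h1", "h2"), accessible = FALSE)
  base <- grid_segments(10)
  both <- road_segments(c(base$geometry, hw$geometry),
                        segment_id = c(base$segment_id, hw$segment_id),
                        accessible = c(base$accessible, hw$accessible))
  net2 <- build_network(both)
  org2 <- snap_to_network(pt, net2, max_snap_m = 100)
  buf2 <- sausage_buffer(reachable_subnetwork(net2, org2, 1000), 25)
  expect_equal(buf2$area_m2, bufs[[2]]$area_m2, tolerance = 1e-9)
})
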