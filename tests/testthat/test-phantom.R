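# Synthetic scene generator: determinism, geometry contracts and the
# self-consistency of the generated ground truth.

test_that("phantom configs are validated", {
  expect_error(phantom_config(field_of_view = c(-1, 100)), "positive")
  expect_error(phantom_config(superficial_diam_range = c(30, 40),
                              deep_diam_range = c(35, 50)), "overlap")
  expect_error(phantom_config(voxel = c(10, 10, 10),
                              superficial_diam_range = c(12, 30)),
               "unresolvable vessel")
})

test_that("empty scenes and determinism contracts hold", {
  cfg <- small_phantom_config(seed = 9)
  cfg$vessel_counts <- c(superficial = 0, deep = 0)
  cfg$noise_sigma <- 0
  ph <- make_vessel_phantom(cfg)
  expect_length(ph$truth$vessels, 0)
  expect_true(all(ph$volume$data == 0))

  cfg2 <- small_phantom_config(seed = 31)
  a <- make_vessel_phantom(cfg2)
  b <- make_vessel_phantom(cfg2)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$metrics, b$truth$metrics)
})

test_that("rendered tube cross-section matches the analytic area", {
  # straight horizontal tube, radius 20 um, on a fine 5 um grid
  v <- array(0, dim = c(120, 60, 40))
  pts <- cbind(x = seq(0, 595, by = 1), y = 150, z = 100, sigma = 10)
  v <- woundvasc:::cpp_render_tubes(v, dim(v), c(5, 5, 5), pts)
  dim(v) <- c(120, 60, 40)
  # cross-section at mid-length; vessel voxels at the 1/e^2 amplitude level
  area <- sum(v[60, , ] >= exp(-2)) * 25
  expect_lt(abs(area - pi * 20^2) / (pi * 20^2), 0.10)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("layer geometry: centerlines never cross the true surface", {
  ph <- make_vessel_phantom(small_phantom_config(seed = 17))
  cfg <- small_phantom_config(seed = 17)
  for (v in ph$truth$vessels) {
    s <- woundvasc:::phantom_surface(cfg, v$points[, 1], v$points[, 2])
    if (v$layer == "superficial") expect_true(all(v$points[, 3] < s))
    else expect_true(all(v$points[, 3] > s))
  }
})

test_that("ground-truth metrics are computed from the polylines", {
  set.seed(33)
  # straight polyline: zero tortuosity, exact length and angle
  xy <- cbind(x = seq(100, 600, by = 10), y = seq(100, 600, by = 10))
  m <- woundvasc:::polyline_metrics(xy)
  expect_identical(m$tortuosity, 0)
  expect_equal(m$length, 500 * sqrt(2))
  expect_equal(m$angle, 45)
  # circular arc: turning rate (180/pi)/r within 1%
  th <- seq(0, pi * 0.8, length.out = 500)
  arc <- cbind(x = 200 * cos(th), y = 200 * sin(th))
  ma <- woundvasc:::polyline_metrics(arc)
  expect_lt(abs(ma$tortuosity - (180 / pi) / 200) / ((180 / pi) / 200), 0.01)
})

test_that("random-walk tortuosity hits its target turning rate", {
  set.seed(44)
  tort <- replicate(40, {
    xy <- woundvasc:::walk_centerline(c(3000, 3000), runif(1, 0, 2 * pi),
                                      1500, 10, 0.65, c(0, 6000, 0, 6000))
    woundvasc:::polyline_metrics(xy)$tortuosity
  })
  expect_lt(abs(mean(tort) - 0.65) / 0.65, 0.10)
})

test_that("wound series: closure limits, monotone radii, alignment target", {
  pc <- small_phantom_config(seed = 2)
  pc$vessel_counts <- c(superficial = 10, deep = 2)
  # far before / after the logistic midpoint
  wc <- wound_series_config(timepoints = c(-20, 0.1, 0.2, 40),
                            closure_logistic = c(k = 1.2, t0 = 5.5),
                            initial_radius = 600,
                            n_ring = 8, n_inwound = 20, phantom = pc, seed = 5)
  ser <- make_wound_series(wc)
  area0 <- pi * 600^2
  px_area <- prod(pc$voxel[1:2])
  expect_gt(sum(ser[[1]]$truth$wound_mask) * px_area / area0, 0.95)
  expect_lt(sum(ser[[4]]$truth$wound_mask) * px_area / area0, 0.01)
  radii <- vapply(ser, function(s) s$truth$wound_radius, 0)
  expect_true(all(diff(radii) <= 0))

  # alignment_schedule 1.0 -> perfectly radial in-wound vessels (the late
  # healing stage: radially aligned, straight regrowth)
  wc2 <- wound_series_config(timepoints = c(8, 10), closure_targets = c(0.9, 0.95),
                             alignment_schedule = 1.0, tortuosity_schedule = 0.05,
                             initial_radius = 800,
                             n_ring = 0, n_inwound = 60, phantom = pc, seed = 6)
  ser2 <- make_wound_series(wc2)
  tm <- do.call(rbind, lapply(ser2, function(s) s$truth$metrics))
  inw <- tm$kind == "inwound"
  expect_gt(sum(inw), 50)
  expect_lt(abs(mean(tm$align[inw]) - 1.0), 0.02)
})

test_that("wound series configs are validated", {
  expect_error(wound_series_config(timepoints = c(5, 5, 7)), "increasing")
  expect_error(wound_series_config(closure_targets = c(0.5, 0.4, 0.6, 0.7)),
               "non-decreasing")
  expect_error(wound_series_config(closure_logistic = c(k = -1, t0 = 5)),
               "positive")
})

test_that("edge target samples the logistic with exact limits", {
  es <- make_edge_target(k = 0.5, x0 = 80, step = 1)
  expect_equal(es$y[which.min(abs(es$x - 80))], 0.5, tolerance = 1e-12)
  expect_gt(max(es$y), 0.999)
  expect_lt(min(es$y), 0.001)
  # seeded noise is reproducible and zero-mean
  e1 <- make_edge_target(0.5, 80, 1, noise_sigma = 0.05, seed = 3)
  e2 <- make_edge_target(0.5, 80, 1, noise_sigma = 0.05, seed = 3)
  expect_identical(e1$y, e2$y)
  expect_lt(abs(mean(e1$y - es$y)), 0.02)
})

test_that("raw scans reproduce the volume and cover the grid", {
  vol <- render_tubes(c(50, 40, 20), c(10, 10, 10),
                      tube_points(c(50, 200, 100), c(450, 200, 100), sigma = 10))
  raw <- make_raw_scan(vol, trajectory = "raster")
  expect_identical(regrid(raw, list(nx = 50, ny = 40, dx = 10, dy = 10))$data,
                   vol$data)
  # sinusoidal trajectory at default density: every MAP pixel receives signal
  raw2 <- make_raw_scan(vol, trajectory = "sinusoidal")
  vol2 <- regrid(raw2, list(nx = 50, ny = 40, dx = 10, dy = 10))
  expect_lt(mean(attr(vol2, "filled")), 0.05)
  m <- max_amplitude_projection(vol2)$map
  expect_identical(dim(m), c(50L, 40L))
  expect_error(make_raw_scan(vol, energy_jitter = 1.2), "jitter")
})
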