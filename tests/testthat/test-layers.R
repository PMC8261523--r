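# Vesselness filtering, support-point gating, separation-surface fitting and
# volume splitting.

test_that("vesselness vanishes on constant images and selects the tube scale", {
  expect_true(all(multiscale_vesselness(matrix(1, 60, 60), c(5, 10), 10) == 0))

  # tube of radius 20 um (Gaussian sigma 10) at 5 um pixels
  vol <- render_tubes(c(120, 80, 10), c(5, 5, 5),
                      tube_points(c(50, 200, 25), c(550, 200, 25), sigma = 10))
  m <- max_amplitude_projection(vol)$map
  on_axis <- cbind(30:90, 41)
  v_match <- multiscale_vesselness(m, 10, 5)   # scale ~ w/2
  v_off <- multiscale_vesselness(m, 80, 5,     # 4x too coarse, same footing
                                 c_norm = attr(v_match, "c_norm"))
  expect_gt(median(v_match[on_axis]), median(v_off[on_axis]))

  # isolated impulse (blob) must respond less than a matched tube
  imp <- matrix(0, 120, 80); imp[60, 41] <- 1
  k <- woundvasc:::gauss_deriv_kernels(2)
  imp <- woundvasc:::cpp_sep_conv2(imp, k$g0, k$g0)  # soften to a blob
  v_imp <- multiscale_vesselness(imp / max(imp), 10, 5)
  expect_lt(v_imp[60, 41], median(v_match[on_axis]))

  expect_error(multiscale_vesselness(matrix(0, 20, 20), 200, 10), "quarter")
})

test_that("support points gate on small-not-large vessel structure", {
  # only deep vessels: gating leaves (nearly) nothing
  cfg_deep <- small_phantom_config(seed = 7)
  cfg_deep$vessel_counts <- c(superficial = 0, deep = 6)
  ph <- make_vessel_phantom(cfg_deep)
  proj <- max_amplitude_projection(ph$volume)
  vn <- vesselness_maps(proj)
  n_deep <- tryCatch(nrow(select_support_points(vn, proj)),
                     error = function(e) 0)
  expect_lt(n_deep, 50)

  # only superficial vessels: support depths sit on the capillaries
  cfg_sup <- small_phantom_config(seed = 8)
  cfg_sup$vessel_counts <- c(superficial = 15, deep = 0)
  ph2 <- make_vessel_phantom(cfg_sup)
  proj2 <- max_amplitude_projection(ph2$volume)
  pts <- select_support_points(vesselness_maps(proj2), proj2)
  expect_gte(nrow(pts), 50)
  ij <- cbind(round(pts$x / 10) + 1, round(pts$y / 10) + 1)
  surf_at <- ph2$truth$surface[ij]
  clear_mid <- mean(cfg_sup$superficial_clearance)
  # capillary centerlines ride `clearance` above the surface
  expect_lt(abs(median(pts$depth - (surf_at - clear_mid))), 2 * 10)

  # two layers: support stays above the true surface
  ph3 <- make_vessel_phantom(small_phantom_config(seed = 9))
  proj3 <- max_amplitude_projection(ph3$volume)
  pts3 <- select_support_points(vesselness_maps(proj3), proj3)
  surf3 <- ph3$truth$surface[cbind(round(pts3$x / 10) + 1, round(pts3$y / 10) + 1)]
  expect_lt(mean(pts3$depth > surf3), 0.05)
})

test_that("surface fit: planes are exact, quadratics within 1 um, offset applied", {
  set.seed(20)
  n <- 400
  x <- runif(n, 0, 1990); y <- runif(n, 0, 1990)
  grid <- list(nx = 200, ny = 200, dx = 10, dy = 10)

  # plane
  pl <- fit_separation_surface(data.frame(x = x, y = y, depth = 300 + 0.02 * x),
                               grid, offset = 0)
  truth <- outer((0:199) * 10, rep(1, 200)) * 0.02 + 300
  expect_lt(max(abs(pl$depth - truth)[50:150, 50:150]), 0.5)

  # gentle quadratic (clamping keeps extrapolation inside the depth band)
  f <- function(x, y) 400 + 30 * ((x - 1000) / 1000)^2 - 20 * ((y - 1000) / 1000)^2
  q <- fit_separation_surface(data.frame(x = x, y = y, depth = f(x, y)),
                              grid, offset = 0)
  qt <- outer((0:199) * 10, (0:199) * 10, f)
  expect_lt(max(abs(q$depth - qt)[20:180, 20:180]), 1)

  # offset shifts the surface deeper
  q2 <- fit_separation_surface(data.frame(x = x, y = y, depth = f(x, y)),
                               grid, offset = 25)
  expect_equal(q2$depth, q$depth + 25, tolerance = 1e-9)
})

test_that("surface fit preconditions and rank fallback", {
  grid <- list(nx = 100, ny = 100, dx = 10, dy = 10)
  few <- data.frame(x = runif(10, 0, 990), y = runif(10, 0, 990), depth = 100)
  expect_error(fit_separation_surface(few, grid), "50")
  set.seed(1)
  narrow <- data.frame(x = runif(100, 0, 200), y = runif(100, 0, 990), depth = 100)
  expect_error(fit_separation_surface(narrow, grid), "span")
  # collinear-degenerate support still returns a surface (degree lowered)
  set.seed(2)
  colin <- data.frame(x = runif(200, 0, 990), y = 0, depth = 150)
  colin$y <- colin$x  # exactly collinear diagonal
  expect_message(
    s <- fit_separation_surface(colin, grid, offset = 0),
    "lowering degree")
  expect_true(all(is.finite(s$depth)))
})

test_that("split_volume partitions exactly and respects the surface", {
  ph <- make_vessel_phantom(small_phantom_config(seed = 12))
  d <- dim(ph$volume$data)
  # degenerate surfaces
  top <- list(depth = matrix(0, d[1], d[2]))
  sp <- split_volume(ph$volume, top)
  expect_equal(sum(abs(sp$superficial$data)), 0)
  expect_identical(sp$deep$data, ph$volume$data)
  bottom <- list(depth = matrix(1e6, d[1], d[2]))
  sp2 <- split_volume(ph$volume, bottom)
  expect_identical(sp2$superficial$data, ph$volume$data)

  # fitted surface: exact conservation
  proj <- max_amplitude_projection(ph$volume)
  pts <- select_support_points(vesselness_maps(proj), proj)
  surf <- fit_separation_surface(pts, list(nx = d[1], ny = d[2], dx = 10, dy = 10))
  sp3 <- split_volume(ph$volume, surf)
  expect_identical(sp3$superficial$data + sp3$deep$data, ph$volume$data)

  expect_error(split_volume(ph$volume, list(depth = matrix(0, 2, 2))), "grid")
})

test_that("superficial and deep layers separate by diameter on a default phantom", {
  ph <- make_vessel_phantom(small_phantom_config(seed = 14))
  d <- dim(ph$volume$data)
  proj <- max_amplitude_projection(ph$volume)
  pts <- select_support_points(vesselness_maps(proj), proj)
  surf <- fit_separation_surface(pts, list(nx = d[1], ny = d[2], dx = 10, dy = 10))
  sp <- split_volume(ph$volume, surf)
  tab_s <- analyze_vessels(max_amplitude_projection(sp$superficial))
  tab_d <- analyze_vessels(max_amplitude_projection(sp$deep))
  expect_gt(nrow(tab_s), 0)
  expect_gt(nrow(tab_d), 0)
  expect_lt(median(tab_s$diameter_um), median(tab_d$diameter_um))
})

test_that("surface recovery degrades gracefully with noise", {
  rms_at <- function(noise, seed) {
    cfg <- small_phantom_config(seed = seed)
    cfg$noise_sigma <- noise
    ph <- make_vessel_phantom(cfg)
    proj <- max_amplitude_projection(ph$volume)
    pts <- tryCatch(select_support_points(vesselness_maps(proj), proj),
                    error = function(e) NULL)
    if (is.null(pts)) return(NA_real_)
    d <- dim(ph$volume$data)
    surf <- fit_separation_surface(pts, list(nx = d[1], ny = d[2],
                                             dx = 10, dy = 10))
    sqrt(mean((surf$depth - ph$truth$surface)^2))
  }
  noise <- c(0.01, 0.05, 0.15)
  rms <- sapply(noise, function(ns) mean(sapply(41:43, function(s)
    rms_at(ns, s)), na.rm = TRUE))
  expect_gt(cor(noise, rms, method = "spearman"), 0)
})
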