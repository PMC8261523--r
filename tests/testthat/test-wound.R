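# Wound-level aggregation: center, scores, kinetics, heat maps, radial
# profiles, layer comparison.

disk_mask <- function(n, cx, cy, r) {
  outer(seq_len(n), seq_len(n), function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
}

test_that("wound center is the centroid of the largest avascular component", {
  vasc <- !disk_mask(101, 40, 60, 15)
  ctr <- wound_center(vasc, pixel = c(10, 10))
  expect_lt(abs(ctr[1] - 39 * 10), 10)
  expect_lt(abs(ctr[2] - 59 * 10), 10)

  two <- !(disk_mask(101, 30, 30, 18) | disk_mask(101, 75, 75, 5))
  ctr2 <- wound_center(two, pixel = c(1, 1))
  expect_lt(sqrt(sum((ctr2 - c(29, 29))^2)), 1.5)

  expect_error(wound_center(matrix(TRUE, 10, 10)), "no wound region")
  # border-touching avascular areas are not wounds
  border <- matrix(TRUE, 50, 50); border[1:3, ] <- FALSE
  expect_error(wound_center(border), "no wound region")
})

test_that("healing and vascularization scores follow the area ratios", {
  expect_equal(healing_score(100, 100), 0)
  expect_equal(healing_score(100, 0), 1)
  expect_equal(healing_score(100, 25), 0.75)
  expect_warning(h <- healing_score(100, 120), "expansion")
  expect_equal(h, 0)
  expect_equal(vascularization_score(100, 0), 0)
  expect_equal(vascularization_score(100, 100), 1)
  expect_error(healing_score(0, 10), "initial_area")
})

test_that("vascularized mask closes gaps but preserves the wound bed", {
  m <- matrix(FALSE, 200, 200)
  for (j in seq(10, 190, by = 25)) m[10:190, j] <- TRUE   # grid of vessels
  wound <- disk_mask(200, 100, 100, 60)                   # 1.2 mm avascular disk
  m[wound] <- FALSE
  v <- vascularized_mask(m, c(10, 10))
  expect_gt(mean(v[!wound]), 0.8)
  inner <- disk_mask(200, 100, 100, 25)  # core stays avascular after closing
  expect_lt(mean(v[inner]), 0.05)
})

test_that("healing kinetics: exact recovery, peak rate at t0, degenerate input", {
  t <- c(2, 4, 5, 6, 8, 11)
  s <- 1 / (1 + exp(-1.2 * (t - 5.5)))
  hc <- fit_healing_curve(t, s)
  expect_equal(hc$k, 1.2, tolerance = 1e-6)
  expect_equal(hc$t0, 5.5, tolerance = 1e-6)
  expect_equal(hc$peak_rate_time, hc$t0)
  expect_equal(max(hc$rate_curve$rate), 1)
  expect_equal(unname(coef(hc)), c(hc$k, hc$t0))

  expect_error(fit_healing_curve(t, rep(0, 6)), "degenerate")
  expect_error(fit_healing_curve(1:3, c(0, 0.5, 1)), "4 timepoints")
  expect_error(fit_healing_curve(t, s + 1), "\\[0, 1\\]")
})

test_that("noisy kinetics recover the midpoint within half a day", {
  t <- c(2, 4, 5, 6, 8, 11)
  s0 <- 1 / (1 + exp(-1.2 * (t - 5.5)))
  set.seed(99)
  t0_hat <- replicate(60, {
    s <- pmin(pmax(s0 + rnorm(6, 0, 0.03), 0), 1)
    fit_healing_curve(t, s)$t0
  })
  expect_lt(median(abs(t0_hat - 5.5)), 0.5)
})

test_that("heat maps bin relative positions and are translation-invariant", {
  tab <- data.frame(id = 1, mid_x = 1500, mid_y = 1500,
                    length_um = 120, diameter_um = 18, angle_deg = 0,
                    tortuosity_deg_per_um = 0.5, align = 0.2,
                    depth_um = 100, n_points = 10)
  hm <- make_heatmaps(list(tab), list(c(1000, 1000)))
  expect_equal(sum(hm$count), 1L)  # vessel at relative (+500, +500): one bin
  occupied <- which(hm$count == 1, arr.ind = TRUE)
  expect_equal(hm$centers_rel[occupied[1]], 400)  # +500 falls in bin [200, 600)
  expect_equal(hm$diameter[occupied], 18)
  expect_true(all(is.na(hm$diameter[hm$count == 0])))

  shift <- tab; shift$mid_x <- shift$mid_x + 1234; shift$mid_y <- shift$mid_y - 87
  hm2 <- make_heatmaps(list(shift), list(c(1000 + 1234, 1000 - 87)))
  expect_identical(hm$count, hm2$count)
  expect_identical(hm$diameter, hm2$diameter)
})

test_that("heat-map counts conserve the in-extent vessel total", {
  set.seed(5)
  n <- 500
  tab <- data.frame(id = seq_len(n),
                    mid_x = runif(n, -4000, 4000), mid_y = runif(n, -4000, 4000),
                    length_um = runif(n, 50, 300), diameter_um = runif(n, 10, 40),
                    angle_deg = runif(n, 0, 180),
                    tortuosity_deg_per_um = runif(n, 0, 1),
                    align = runif(n, -1, 1), depth_um = 100, n_points = 10)
  hm <- make_heatmaps(list(tab), list(c(0, 0)), bin = 400, extent = 6000)
  in_ext <- sum(abs(tab$mid_x) <= 3000 & abs(tab$mid_y) <= 3000)
  expect_equal(sum(hm$count), in_ext)
})

test_that("radial profiles: flat for uniform tables, NA for empty annuli", {
  set.seed(6)
  n <- 4000
  r <- sqrt(runif(n)) * 2800
  phi <- runif(n, 0, 2 * pi)
  tab <- data.frame(id = seq_len(n),
                    mid_x = r * cos(phi), mid_y = r * sin(phi),
                    length_um = rnorm(n, 150, 10), diameter_um = rnorm(n, 20, 1),
                    angle_deg = runif(n, 0, 180),
                    tortuosity_deg_per_um = rnorm(n, 0.6, 0.05),
                    align = 0, depth_um = 100, n_points = 10)
  rp <- radial_profiles(list(tab), list(c(0, 0)), bin_width = 400,
                        max_radius = 2800)
  expect_true(all(rp$n > 0))
  expect_lt(diff(range(rp$diameter_um)), 1)    # flat within sampling error
  expect_lt(diff(range(rp$length_um)), 12)

  # an annulus with no vessels reports NA, not zero
  far <- tab[r > 2000, ]
  rp2 <- radial_profiles(list(far), list(c(0, 0)), bin_width = 400,
                         max_radius = 2800)
  expect_true(any(rp2$n == 0))
  expect_true(all(is.na(rp2$diameter_um[rp2$n == 0])))
})

test_that("layer diameter comparison matches hand-computed Student's t", {
  # a = (1,2,3), b = (2,4,6): pooled s^2 = 2.5, t = -2 / sqrt(2.5 * 2/3)
  res <- compare_layer_diameters(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$t, -2 / sqrt(2.5 * (2 / 3)), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(res$t, 4), tolerance = 1e-12)
  expect_equal(unname(res$means), c(2, 4))

  # identical groups: t = 0, p = 1
  same <- compare_layer_diameters(c(10, 12, 14), c(10, 12, 14))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # the layer regimes separate decisively at the study's sample size
  set.seed(77)
  sup <- rnorm(28, 16, 1); deep <- rnorm(28, 43, 5)
  big <- compare_layer_diameters(sup, deep)
  expect_lt(big$p, 1e-20)
  expect_true(big$ci["superficial", "hi"] < big$ci["deep", "lo"])

  expect_error(compare_layer_diameters(1, c(2, 3)), "at least 2")
})
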