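# A-scan preprocessing: band-pass, energy correction, regridding, MAP,
# CLAHE and depth encoding.

make_tone_scan <- function(freqs, n = 250, fs = 250e6, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  ascans <- t(vapply(freqs, function(f)
    if (f == 0) rep(amp, n) else amp * sin(2 * pi * f * t), numeric(n)))
  structure(list(ascans = ascans, sample_rate = fs,
                 positions = cbind(seq_along(freqs) - 1, 0),
                 energies = rep(1, length(freqs)), depth_spacing = 5),
            class = "oa_rawscan")
}

test_that("band-pass response: DC removed, passband unity, stopband attenuated", {
  # frequencies chosen with an integer number of periods in the window
  fs <- 250e6; n <- 250
  raw <- make_tone_scan(c(0, 10e6, 100e6), n = n, fs = fs)
  out <- bandpass_filter(raw)
  rms <- function(x) sqrt(mean(x^2))
  # DC: attenuation > 40 dB (here exactly zero by construction)
  expect_lt(rms(out$ascans[1, ]) / rms(raw$ascans[1, ]), 10^(-40 / 20))
  # 10 MHz (geometric mean of 2-50 MHz): within 1 dB
  expect_gt(rms(out$ascans[2, ]) / rms(raw$ascans[2, ]), 10^(-1 / 20))
  expect_lt(rms(out$ascans[2, ]) / rms(raw$ascans[2, ]), 10^(1 / 20))
  # 100 MHz: attenuated by more than 15 dB
  expect_lt(rms(out$ascans[3, ]) / rms(raw$ascans[3, ]), 10^(-15 / 20))
})

test_that("band edges outside Nyquist are rejected", {
  raw <- make_tone_scan(10e6)
  expect_error(bandpass_filter(raw, low = 2e6, high = 130e6), "Nyquist")
  expect_error(bandpass_filter(raw, low = 60e6, high = 50e6), "Nyquist")
})

test_that("filtering is linear", {
  set.seed(3)
  fs <- 250e6; n <- 128
  r1 <- make_tone_scan(10e6, n = n); r2 <- make_tone_scan(30e6, n = n)
  r1$ascans[] <- rnorm(n); r2$ascans[] <- rnorm(n)
  mix <- r1; mix$ascans <- 2.5 * r1$ascans - 1.3 * r2$ascans
  lhs <- bandpass_filter(mix)$ascans
  rhs <- 2.5 * bandpass_filter(r1)$ascans - 1.3 * bandpass_filter(r2)$ascans
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("energy correction inverts per-pulse scaling", {
  raw <- make_tone_scan(c(10e6, 20e6, 30e6))
  expect_equal(energy_correct(raw)$ascans, raw$ascans)  # unit energies

  scaled <- raw
  scaled$energies <- c(2, 2, 2)
  scaled$ascans <- scaled$ascans * 2
  cor2 <- energy_correct(scaled)
  expect_equal(cor2$ascans, raw$ascans, tolerance = 1e-12)
  expect_equal(cor2$energies, rep(1, 3))

  bad <- raw; bad$energies[2] <- 0
  expect_error(energy_correct(bad), "pulse index 2")
})

test_that("jittered phantom stream round-trips through energy_correct + regrid", {
  set.seed(10)
  vol <- render_tubes(c(60, 50, 30), c(10, 10, 10),
                      tube_points(c(50, 250, 150), c(550, 250, 150), sigma = 10))
  raw <- make_raw_scan(vol, energy_jitter = 0.2, trajectory = "raster", seed = 4)
  cor <- energy_correct(raw)
  back <- regrid(cor, list(nx = 60, ny = 50, dx = 10, dy = 10))
  denom <- pmax(abs(vol$data), 1e-12)
  expect_lt(max(abs(back$data - vol$data) / denom), 1e-6)
})

test_that("regrid averages duplicate nodes and flags/fills empty ones", {
  raw <- structure(list(
    ascans = rbind(c(1, 1), c(3, 3), c(5, 5)),
    sample_rate = 250e6,
    positions = rbind(c(0, 0), c(0, 0), c(10, 0)),
    energies = rep(1, 3), depth_spacing = 5), class = "oa_rawscan")
  expect_warning(vol <- regrid(raw, list(nx = 3, ny = 1, dx = 10, dy = 10)),
                 "no pulse")
  expect_equal(vol$data[1, 1, ], c(2, 2))   # (1+3)/2
  expect_equal(vol$data[2, 1, ], c(5, 5))
  expect_equal(vol$data[3, 1, ], c(5, 5))   # filled from neighbor
  expect_true(attr(vol, "filled")[3, 1])
  expect_false(attr(vol, "filled")[1, 1])
  # >50% empty is an error
  raw$positions <- rbind(c(0, 0), c(0, 0), c(0, 0))
  expect_error(regrid(raw, list(nx = 4, ny = 2, dx = 10, dy = 10)), "cover")
  # positions outside the grid are rejected
  raw$positions <- rbind(c(0, 0), c(200, 0), c(10, 0))
  expect_error(regrid(raw, list(nx = 3, ny = 1, dx = 10, dy = 10)), "outside")
})

test_that("MAP takes the first (shallowest) maximum and records zero depth", {
  v <- array(0, dim = c(4, 3, 50))
  v[2, 2, 38] <- 0.7   # 0-based depth index 37
  vol <- oa_volume(v, c(10, 10, 5))
  p <- max_amplitude_projection(vol)
  expect_equal(p$map[2, 2], 0.7)
  expect_equal(p$depth_index[2, 2], 37)
  expect_equal(p$zero_depth, 37 * 5)

  # all-equal columns: tie breaks to the first slice
  vol2 <- oa_volume(array(1, dim = c(3, 3, 5)), c(1, 1, 1))
  expect_true(all(max_amplitude_projection(vol2)$depth_index == 0))

  # amplitude is |signal|: a negative lobe can carry the maximum
  v3 <- array(0, dim = c(1, 1, 10)); v3[1, 1, 4] <- -2; v3[1, 1, 8] <- 1
  p3 <- max_amplitude_projection(oa_volume(v3, c(1, 1, 1)))
  expect_equal(p3$depth_index[1, 1], 3)
  expect_equal(p3$map[1, 1], 2)
})

test_that("CLAHE is range-bounded, constant-preserving, contrast-enhancing", {
  expect_equal(diff(range(clahe(matrix(0.37, 64, 64)))), 0)
  set.seed(8)
  img <- matrix(runif(96 * 96)^4, 96, 96)
  out <- clahe(img)
  expect_true(all(out >= 0 & out <= 1))
  # bimodal map with a compressed dynamic range (dim background, slightly
  # brighter vessels): equalization stretches the separation, so the
  # relative contrast (std/mean) must not decrease
  lowhigh <- matrix(0.45 + abs(rnorm(256 * 256, 0, 0.005)), 256, 256)
  lowhigh[, seq(8, 256, by = 32)] <- 0.55
  expect_gte(sd(clahe(lowhigh)) / mean(clahe(lowhigh)),
             sd(lowhigh) / mean(lowhigh))
  expect_message(clahe(matrix(runif(25), 5, 5), tile_size = 10), "global")
  expect_error(clahe(matrix(c(NA, 1:15), 4, 4)), "finite")
})

test_that("depth encoding maps depth to hue and is deterministic", {
  v <- array(0, dim = c(8, 8, 20))
  v[1:4, , 3] <- 1   # shallow structure
  v[5:8, , 15] <- 1  # deep structure
  p <- max_amplitude_projection(oa_volume(v, c(10, 10, 10)))
  rgb1 <- depth_encode(p)
  rgb2 <- depth_encode(p)
  expect_identical(rgb1, rgb2)
  # two depths -> two distinct hues
  h1 <- rgb1[2, 2, ] / max(rgb1[2, 2, ])
  h2 <- rgb1[6, 2, ] / max(rgb1[6, 2, ])
  expect_gt(max(abs(h1 - h2)), 0.1)
  # flat depth -> single hue
  vf <- array(0, dim = c(6, 6, 10)); vf[, , 4] <- matrix(runif(36), 6, 6) + 0.5
  pf <- max_amplitude_projection(oa_volume(vf, c(10, 10, 10)))
  rgbf <- depth_encode(pf)
  ratio <- rgbf[, , 1] / pmax(rgbf[, , 2], 1e-9)
  expect_lt(diff(range(ratio)), 1e-6)
})

test_that("raw -> volume -> MAP equals direct MAP on a clean phantom", {
  vol <- render_tubes(c(40, 40, 20), c(10, 10, 10),
                      tube_points(c(50, 200, 100), c(350, 200, 100), sigma = 10))
  raw <- make_raw_scan(vol, energy_jitter = 0, trajectory = "raster")
  vol2 <- regrid(raw, list(nx = 40, ny = 40, dx = 10, dy = 10))
  expect_identical(vol2$data, vol$data)
  expect_identical(max_amplitude_projection(vol2)$map,
                   max_amplitude_projection(vol)$map)
})
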