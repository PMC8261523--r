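# Small scene builders shared across tests. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

# Rasterize a straight line of given angle (deg) into a logical mask.
line_mask <- function(angle_deg, n = 300, pixel = 10, start = c(500, 1500),
                      length_um = 2000, step = 2) {
  a <- angle_deg * pi / 180
  m <- matrix(FALSE, n, n)
  tpar <- seq(0, length_um, by = step)
  i <- round((start[1] + tpar * cos(a)) / pixel) + 1
  j <- round((start[2] + tpar * sin(a)) / pixel) + 1
  ok <- i >= 1 & i <= n & j >= 1 & j <= n
  m[cbind(i[ok], j[ok])] <- TRUE
  m
}

# Render Gaussian tubes directly into a volume from a (x, y, z, sigma) point
# matrix (um), bypassing the phantom generator.
render_tubes <- function(dims, voxel, points, noise = 0) {
  v <- array(0, dim = dims)
  v <- woundvasc:::cpp_render_tubes(v, dims, voxel, points)
  dim(v) <- dims
  if (noise > 0) v <- v + stats::rnorm(length(v), 0, noise)
  oa_volume(v, voxel)
}

# Dense samples along a straight 3D tube.
tube_points <- function(from, to, sigma, spacing = NULL) {
  if (is.null(spacing)) spacing <- max(sigma / 2, 0.5)
  n <- max(2, ceiling(sqrt(sum((to - from)^2)) / spacing))
  t <- seq(0, 1, length.out = n)
  cbind(x = from[1] + t * (to[1] - from[1]),
        y = from[2] + t * (to[2] - from[2]),
        z = from[3] + t * (to[3] - from[3]),
        sigma = sigma)
}

# A small but complete two-layer phantom configuration (2 x 2 mm).
small_phantom_config <- function(seed = 5, ...) {
  phantom_config(field_of_view = c(2000, 2000), depth = 1000,
                 voxel = c(10, 10, 10),
                 superficial_diam_range = c(20, 30),
                 deep_clearance = c(60, 120),
                 vessel_counts = c(superficial = 12, deep = 4),
                 noise_sigma = 0.02, seed = seed, ...)
}
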