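#' Configuration of a synthetic two-layer vascular scene
#'
#' Describes the ground-truthed phantom the generator renders: a superficial
#' plexus of tortuous capillaries above a smooth, non-planar separation
#' surface, and straighter, larger cutaneous vessels below it. Defaults mirror
#' the dorsal mouse skin regime the pipeline is built for: capillary diameters
#' of 10-30 um over deep vessels of 35-50 um, a 7 x 7 mm field of view and
#' 1.5 mm depth range, rendered at 10 um lateral / 5 um axial voxels (a
#' downscaled version of the instrument's 5 um step size, to keep runtimes
#' practical; pass finer `voxel` for full resolution).
#'
#' @param field_of_view lateral extent `(x, y)` in um.
#' @param depth axial extent in um.
#' @param voxel voxel spacing `(dx, dy, dz)` in um.
#' @param superficial_diam_range,deep_diam_range vessel diameter ranges (um);
#'   must not overlap.
#' @param surface_coeffs coefficients `(c0, cx, cy, cxx, cxy, cyy)` of the
#'   true separation surface, a quadratic in lateral coordinates scaled to
#'   `[-1, 1]`; values in um depth.
#' @param capillary_tortuosity target turning rate of capillary random walks,
#'   degrees per um.
#' @param vessel_counts named vector `c(superficial=, deep=)`.
#' @param superficial_clearance range (um) of capillary centerline heights
#'   above the separation surface.
#' @param deep_clearance range (um) of deep-vessel centerline depths below
#'   the separation surface.
#' @param capillary_length_range,step length range of capillaries and walk
#'   step size, um.
#' @param noise_sigma additive Gaussian amplitude noise (volume amplitudes
#'   are in `[0, 1]` before noise).
#' @param psf_fwhm optional `(lateral, axial)` Gaussian PSF FWHM in um
#'   (e.g. `c(7.5, 35)` for the instrument), or `NULL` for no blur.
#' @param seed integer seed; identical configs give bit-identical scenes.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(field_of_view = c(7000, 7000),
                           depth = 1500,
                           voxel = c(10, 10, 5),
                           superficial_diam_range = c(10, 30),
                           deep_diam_range = c(35, 50),
                           surface_coeffs = c(450, 20, -30, 80, 0, 60),
                           capillary_tortuosity = 0.65,
                           vessel_counts = c(superficial = 30, deep = 10),
                           superficial_clearance = c(10, 40),
                           deep_clearance = c(60, 140),
                           capillary_length_range = c(500, 2000),
                           step = 10,
                           noise_sigma = 0.02,
                           psf_fwhm = NULL,
                           seed = 1L) {
  cfg <- list(field_of_view = as.numeric(field_of_view), depth = as.numeric(depth),
              voxel = as.numeric(voxel),
              superficial_diam_range = as.numeric(superficial_diam_range),
              deep_diam_range = as.numeric(deep_diam_range),
              surface_coeffs = as.numeric(surface_coeffs),
              capillary_tortuosity = as.numeric(capillary_tortuosity),
              vessel_counts = vessel_counts,
              superficial_clearance = as.numeric(superficial_clearance),
              deep_clearance = as.numeric(deep_clearance),
              capillary_length_range = as.numeric(capillary_length_range),
              step = as.numeric(step),
              noise_sigma = as.numeric(noise_sigma),
              psf_fwhm = if (!is.null(psf_fwhm)) as.numeric(psf_fwhm),
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (any(field_of_view <= 0) || depth <= 0 || any(voxel <= 0))
      stop("extents and voxel sizes must be positive")
    if (length(surface_coeffs) != 6)
      stop("surface_coeffs must have 6 coefficients (c0, cx, cy, cxx, cxy, cyy)")
    sdr <- superficial_diam_range; ddr <- deep_diam_range
    if (any(sdr <= 0) || any(ddr <= 0) || sdr[1] > sdr[2] || ddr[1] > ddr[2])
      stop("diameter ranges must be positive and ordered")
    if (max(sdr) >= min(ddr))
      stop("superficial and deep diameter ranges must not overlap")
    if (min(sdr) < 2 * min(voxel))
      stop("unresolvable vessel: diameter ", min(sdr),
           " um is below twice the finest voxel spacing (", 2 * min(voxel), " um)")
    if (capillary_tortuosity < 0 || noise_sigma < 0 || step <= 0)
      stop("tortuosity, noise_sigma and step must be non-negative")
    if (!all(c("superficial", "deep") %in% names(vessel_counts)))
      stop("vessel_counts needs named entries 'superficial' and 'deep'")
  })
  invisible(cfg)
}

# Evaluate the true separation surface (um depth) at lateral positions (um).
phantom_surface <- function(cfg, x, y) {
  u <- 2 * x / cfg$field_of_view[1] - 1
  v <- 2 * y / cfg$field_of_view[2] - 1
  cc <- cfg$surface_coeffs
  cc[1] + cc[2] * u + cc[3] * v + cc[4] * u^2 + cc[5] * u * v + cc[6] * v^2
}

# True surface sampled on the volume's lateral voxel grid.
phantom_surface_grid <- function(cfg) {
  nx <- ceiling(cfg$field_of_view[1] / cfg$voxel[1])
  ny <- ceiling(cfg$field_of_view[2] / cfg$voxel[2])
  outer(axis_coords(nx, cfg$voxel[1]), axis_coords(ny, cfg$voxel[2]),
        function(x, y) phantom_surface(cfg, x, y))
}

# von Mises(0, kappa) sampler (Best & Fisher 1979 rejection scheme).
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(clamp(f, -1, 1))
      i <- i + 1L
    }
  }
  out
}

# Turning-rate target (deg/um) -> von Mises concentration for a given step.
# E|theta| ~ sqrt(2 / (pi * kappa)) for a concentrated von Mises.
tortuosity_kappa <- function(tort_deg_per_um, step) {
  t_rad <- tort_deg_per_um * step * pi / 180
  2 / (pi * t_rad^2)
}

# Random-walk centerline in the lateral plane. Returns an (n x 2) matrix of
# positions (um), truncated where it leaves `bounds` (xmin,xmax,ymin,ymax) or
# enters the optional forbidden region `avoid(x, y) -> logical`.
walk_centerline <- function(start, heading, length, step, tort_deg_per_um,
                            bounds, avoid = NULL) {
  n <- max(2L, ceiling(length / step))
  turns <- if (tort_deg_per_um > 0)
    rvonmises(n - 1L, tortuosity_kappa(tort_deg_per_um, step)) else numeric(n - 1L)
  headings <- heading + cumsum(c(0, turns[-length(turns)]))
  xs <- start[1] + c(0, cumsum(step * cos(headings)))
  ys <- start[2] + c(0, cumsum(step * sin(headings)))
  ok <- xs >= bounds[1] & xs <= bounds[2] & ys >= bounds[3] & ys <= bounds[4]
  if (!is.null(avoid)) ok <- ok & !avoid(xs, ys)
  bad <- which(!ok)
  keep <- if (length(bad)) seq_len(bad[1] - 1L) else seq_along(xs)
  if (length(keep) < 2L) return(NULL)
  cbind(x = xs[keep], y = ys[keep])
}

# Planar ground-truth metrics of a centerline polyline, matching the
# conventions of measure_segment(): length = sum of chord lengths,
# tortuosity = total absolute turning (deg) / length, angle = end-to-end
# orientation folded to [0, 180).
polyline_metrics <- function(xy) {
  dxy <- diff(xy)
  seglen <- sqrt(rowSums(dxy^2))
  len <- sum(seglen)
  ang <- atan2(xy[nrow(xy), 2] - xy[1, 2], xy[nrow(xy), 1] - xy[1, 1])
  ang_deg <- unname((ang * 180 / pi) %% 180)
  tort <- 0
  if (nrow(dxy) >= 2) {
    h <- atan2(dxy[, 2], dxy[, 1])
    dh <- diff(h)
    dh <- atan2(sin(dh), cos(dh))  # wrap to (-pi, pi]
    tort <- sum(abs(dh)) * 180 / pi / len
  }
  mid <- xy[ceiling(nrow(xy) / 2), ]
  list(length = len, tortuosity = tort, angle = ang_deg,
       mid = c(mid[1], mid[2]))
}

# Undirected alignment of an orientation (deg) at a midpoint w.r.t. a center:
# cos(2 * delta) with delta the acute angle to the radial direction.
alignment_score <- function(angle_deg, mid, center) {
  radial <- atan2(mid[2] - center[2], mid[1] - center[1]) * 180 / pi
  d <- (angle_deg - radial) * pi / 180
  unname(cos(2 * d))
}

# Resample a 3D polyline (x, y, z) to roughly uniform spacing (um) by linear
# interpolation along arclength.
resample_polyline <- function(pts, spacing) {
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  stot <- s[length(s)]
  if (stot <= 0) return(pts[1, , drop = FALSE])
  si <- seq(0, stot, by = spacing)
  if (si[length(si)] < stot) si <- c(si, stot)
  apply(pts, 2, function(col) stats::approx(s, col, xout = si)$y)
}

# Build one ground-truth vessel record: lateral centerline `xy`, depth from
# `zfun(x, y)`, constant radius. Returns list(points3 = (x,y,z), radius, ...).
make_vessel <- function(xy, zfun, radius, layer, kind, center = NULL) {
  z <- zfun(xy[, 1], xy[, 2])
  m <- polyline_metrics(xy)
  align <- if (!is.null(center)) alignment_score(m$angle, m$mid, center) else NA_real_
  list(points = cbind(xy, z = z), radius = radius, layer = layer, kind = kind,
       length = m$length, diameter = 2 * radius, tortuosity = m$tortuosity,
       angle = m$angle, align = align, mid = m$mid)
}

vessel_metrics_table <- function(vessels) {
  if (!length(vessels)) {
    return(data.frame(id = integer(), layer = character(), kind = character(),
                      length_um = numeric(), diameter_um = numeric(),
                      tortuosity_deg_per_um = numeric(), angle_deg = numeric(),
                      align = numeric(), mid_x = numeric(), mid_y = numeric()))
  }
  data.frame(
    id = seq_along(vessels),
    layer = vapply(vessels, `[[`, "", "layer"),
    kind = vapply(vessels, `[[`, "", "kind"),
    length_um = vapply(vessels, `[[`, 0, "length"),
    diameter_um = vapply(vessels, `[[`, 0, "diameter"),
    tortuosity_deg_per_um = vapply(vessels, `[[`, 0, "tortuosity"),
    angle_deg = vapply(vessels, `[[`, 0, "angle"),
    align = vapply(vessels, `[[`, 0, "align"),
    mid_x = vapply(vessels, function(v) v$mid[1], 0),
    mid_y = vapply(vessels, function(v) v$mid[2], 0))
}

# Rasterize ground-truth vessels into an amplitude volume. Vessels are
# Gaussian-profile tubes, amplitude = exp(-d^2 / (2 sigma^2)) with
# sigma = radius / 2, composited by per-voxel maximum (band-limited
# optoacoustic amplitudes rather than hard cylinders).
render_phantom_volume <- function(cfg, vessels) {
  nx <- ceiling(cfg$field_of_view[1] / cfg$voxel[1])
  ny <- ceiling(cfg$field_of_view[2] / cfg$voxel[2])
  nz <- ceiling(cfg$depth / cfg$voxel[3])
  vol <- array(0, dim = c(nx, ny, nz))
  if (length(vessels)) {
    pts <- do.call(rbind, lapply(vessels, function(v) {
      sigma <- v$radius / 2
      spacing <- min(min(cfg$voxel) / 2, sigma / 2)
      p <- resample_polyline(v$points, spacing)
      cbind(p, sigma = sigma)
    }))
    vol <- cpp_render_tubes(vol, dim(vol), cfg$voxel, pts)
    dim(vol) <- c(nx, ny, nz)
  }
  if (!is.null(cfg$psf_fwhm)) vol <- blur_volume(vol, cfg$voxel, cfg$psf_fwhm)
  if (cfg$noise_sigma > 0)
    vol <- vol + stats::rnorm(length(vol), 0, cfg$noise_sigma)
  oa_volume(vol, cfg$voxel)
}

# Gaussian PSF blur, separable: lateral FWHM in x/y, axial FWHM in z.
blur_volume <- function(vol, voxel, psf_fwhm) {
  sig <- psf_fwhm / (2 * sqrt(2 * log(2)))
  kx <- gauss_kernel(sig[1] / voxel[1])
  ky <- gauss_kernel(sig[1] / voxel[2])
  kz <- gauss_kernel(sig[2] / voxel[3])
  d <- dim(vol)
  for (k in seq_len(d[3])) vol[, , k] <- cpp_sep_conv2(vol[, , k], kx, ky)
  m <- matrix(vol, nrow = d[1] * d[2], ncol = d[3])
  m <- cpp_sep_conv2(m, 1, kz)  # kernel of length 1 on dim 1 = identity
  array(m, dim = d)
}

gauss_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma_px^2))
  k / sum(k)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a two-layer vascular phantom with ground truth
#'
#' Renders a seeded synthetic scene: tortuous superficial capillaries riding
#' just above the true separation surface, and large, nearly straight deep
#' vessels below it. Returns both the rendered amplitude volume and the
#' generating ground truth (centerlines, per-segment metrics computed from
#' the polylines themselves, and the true surface) for parameter-recovery
#' testing.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `volume` (an [oa_volume]) and `truth` (class
#'   `phantom_truth`: `vessels`, `metrics`, `surface` matrix in um on the
#'   lateral voxel grid, `pixel`).
#' @export
make_vessel_phantom <- function(config) {
  validate_phantom_config(config)
  with_seed(config$seed, {
    vessels <- gen_baseline_vessels(config)
    truth <- structure(list(
      vessels = vessels,
      metrics = vessel_metrics_table(vessels),
      surface = phantom_surface_grid(config),
      pixel = config$voxel[1:2],
      wound_mask = NULL, wound_center = NULL),
      class = "phantom_truth")
    list(volume = render_phantom_volume(config, vessels), truth = truth)
  })
}

# Stratified (jittered-lattice) start points: capillary beds are
# space-filling, so pure Poisson placement would leave unrealistic voids.
# Points inside the forbidden region are re-drawn by rejection.
stratified_starts <- function(n, fov, avoid = NULL) {
  if (n < 1) return(matrix(numeric(0), 0, 2))
  n_side <- ceiling(sqrt(n))
  cells <- utils::head(expand.grid(i = seq_len(n_side), j = seq_len(n_side))[
    sample.int(n_side^2), ], n)
  pts <- cbind((cells$i - stats::runif(n)) * fov[1] / n_side,
               (cells$j - stats::runif(n)) * fov[2] / n_side)
  if (!is.null(avoid)) {
    for (i in which(avoid(pts[, 1], pts[, 2]))) {
      for (tries in 1:50) {
        cand <- stats::runif(2) * fov
        if (!avoid(cand[1], cand[2])) { pts[i, ] <- cand; break }
      }
    }
    pts <- pts[!avoid(pts[, 1], pts[, 2]), , drop = FALSE]
  }
  pts
}

# Baseline (unwounded) scene: capillaries above the surface, straight deep
# vessels below, walks truncated at the field-of-view boundary.
gen_baseline_vessels <- function(cfg, avoid = NULL, center = NULL) {
  fov <- cfg$field_of_view
  bounds <- c(0, fov[1], 0, fov[2])
  vessels <- list()
  n_sup <- cfg$vessel_counts[["superficial"]]
  n_deep <- cfg$vessel_counts[["deep"]]
  starts <- stratified_starts(n_sup, fov, avoid)
  for (i in seq_len(nrow(starts))) {
    start <- starts[i, ]
    xy <- walk_centerline(start, stats::runif(1, 0, 2 * pi),
                          stats::runif(1, cfg$capillary_length_range[1],
                                       cfg$capillary_length_range[2]),
                          cfg$step, cfg$capillary_tortuosity, bounds, avoid)
    if (is.null(xy)) next
    clr <- stats::runif(1, cfg$superficial_clearance[1], cfg$superficial_clearance[2])
    r <- stats::runif(1, cfg$superficial_diam_range[1], cfg$superficial_diam_range[2]) / 2
    vessels[[length(vessels) + 1L]] <- make_vessel(
      xy, function(x, y) phantom_surface(cfg, x, y) - clr, r,
      "superficial", "background", center)
  }
  for (i in seq_len(n_deep)) {
    # long, nearly straight vessels spanning the field of view
    edge_pt <- stats::runif(2) * fov
    xy <- walk_centerline(edge_pt, stats::runif(1, 0, 2 * pi),
                          2 * max(fov), cfg$step, 0.05, bounds)
    if (is.null(xy) || nrow(xy) < 10) next
    clr <- stats::runif(1, cfg$deep_clearance[1], cfg$deep_clearance[2])
    r <- stats::runif(1, cfg$deep_diam_range[1], cfg$deep_diam_range[2]) / 2
    vessels[[length(vessels) + 1L]] <- make_vessel(
      xy, function(x, y) phantom_surface(cfg, x, y) + clr, r,
      "deep", "background", center)
  }
  vessels
}
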