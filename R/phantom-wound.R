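#' Configuration of a synthetic healing-wound time series
#'
#' Describes a circular full-thickness excisional wound (default 5 mm
#' diameter) whose avascular area shrinks over days post wounding (dpw)
#' following a logistic closure curve, surrounded by a peri-wound ring of
#' tortuous, dilated sprouts at early timepoints and refilled by radially
#' aligned, straighter vessels as healing progresses. Default kinetics put
#' the peak re-vascularization rate at 5.5 dpw; default tortuosity declines
#' to 0.35 deg/um by the latest timepoints, and alignment rises toward the
#' wound center, the regimes reported for healing mouse skin.
#'
#' @param timepoints strictly increasing dpw values.
#' @param initial_radius initial wound radius, um (2500 = 5 mm diameter).
#' @param closure_logistic `c(k, t0)`: steepness (1/day) and midpoint (day)
#'   of the closure logistic. The avascular *area* at time t is
#'   `(1 - logistic(t)) * initial area`.
#' @param closure_targets optional explicit per-timepoint closure fractions
#'   in `[0, 1]` (non-decreasing); overrides `closure_logistic`.
#' @param sprout_ring_width width (um) of the peri-wound sprout annulus.
#' @param sprout_tortuosity turning rate (deg/um) of early sprouts.
#' @param sprout_dilation diameter multiplier of sprouts vs baseline
#'   capillaries (edema/active sprouting).
#' @param sprout_until_closure sprout ring present while closure is below
#'   this fraction.
#' @param alignment_schedule per-timepoint target mean angular alignment of
#'   in-wound vessels (`cos(2*delta)` scale, 1 = perfectly radial).
#' @param tortuosity_schedule per-timepoint turning rate (deg/um) of
#'   in-wound vessels.
#' @param n_ring,n_inwound vessel counts for the sprout ring and the fully
#'   revascularized wound (in-wound count is scaled by the revascularized
#'   area fraction).
#' @param phantom a [phantom_config()] for the surrounding baseline scene.
#'   The default raises the capillary count to 150 so the peri-wound skin is
#'   densely vascularized (inter-capillary spacing of a few hundred um, as
#'   in dorsal mouse skin); sparser scenes make the vascularized-area mask
#'   ill-defined. The default also samples depth at 10 um (still well below
#'   the 35 um axial resolution) over 1 mm so a four-timepoint series of
#'   7 x 7 mm volumes fits comfortably in memory, and accordingly restricts
#'   capillary diameters to the population resolvable at that sampling
#'   (20-30 um).
#' @param seed integer seed for the whole series.
#' @return A validated list of class `wound_series_config`.
#' @export
wound_series_config <- function(timepoints = c(5, 7, 10, 13),
                                initial_radius = 2500,
                                closure_logistic = c(k = 1.2, t0 = 5.5),
                                closure_targets = NULL,
                                sprout_ring_width = 500,
                                sprout_tortuosity = 1.5,
                                sprout_dilation = 1.5,
                                sprout_until_closure = 0.9,
                                alignment_schedule = c(0.1, 0.4, 0.7, 0.9),
                                tortuosity_schedule = c(1.2, 0.8, 0.5, 0.35),
                                n_ring = 60,
                                n_inwound = 150,
                                phantom = phantom_config(
                                  depth = 1000, voxel = c(10, 10, 10),
                                  superficial_diam_range = c(20, 30),
                                  vessel_counts = c(superficial = 150, deep = 10)),
                                seed = 7L) {
  cfg <- list(timepoints = as.numeric(timepoints),
              initial_radius = as.numeric(initial_radius),
              closure_logistic = closure_logistic,
              closure_targets = closure_targets,
              sprout_ring_width = sprout_ring_width,
              sprout_tortuosity = sprout_tortuosity,
              sprout_dilation = sprout_dilation,
              sprout_until_closure = sprout_until_closure,
              alignment_schedule = rep_len(alignment_schedule, length(timepoints)),
              tortuosity_schedule = rep_len(tortuosity_schedule, length(timepoints)),
              n_ring = n_ring, n_inwound = n_inwound,
              phantom = phantom, seed = as.integer(seed))
  nt <- length(cfg$timepoints)
  if (nt < 1 || any(diff(cfg$timepoints) <= 0))
    stop("timepoints must be strictly increasing")
  if (cfg$initial_radius <= 0) stop("initial_radius must be positive")
  if (!is.null(cfg$closure_targets)) {
    ct <- cfg$closure_targets
    if (length(ct) != nt || any(ct < 0 | ct > 1) || any(diff(ct) < 0))
      stop("closure_targets must be per-timepoint, in [0,1], non-decreasing")
  } else if (cfg$closure_logistic[["k"]] <= 0) {
    stop("closure steepness k must be positive")
  }
  validate_phantom_config(cfg$phantom)
  class(cfg) <- "wound_series_config"
  cfg
}

logistic <- function(t, k, t0) 1 / (1 + exp(-k * (t - t0)))

series_closure <- function(cfg) {
  if (!is.null(cfg$closure_targets)) return(cfg$closure_targets)
  logistic(cfg$timepoints, cfg$closure_logistic[["k"]], cfg$closure_logistic[["t0"]])
}

# Rotate a polyline about its midpoint so that its end-to-end chord has the
# requested orientation (radians). Keeps arclength and turning unchanged.
rotate_to_chord <- function(xy, target_rad) {
  chord <- atan2(xy[nrow(xy), 2] - xy[1, 2], xy[nrow(xy), 1] - xy[1, 1])
  a <- target_rad - chord
  ctr <- colMeans(xy[c(1, nrow(xy)), , drop = FALSE])
  rot <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)  # row-vector convention
  sweep(sweep(xy, 2, ctr) %*% rot, 2, ctr, `+`)
}

#' Generate a healing-wound phantom time series
#'
#' For each timepoint, renders a scene with (i) the fixed deep vessel network,
#' (ii) baseline capillaries outside the original wound area, (iii) a
#' peri-wound ring of tortuous, dilated sprouts while closure is still
#' incomplete, and (iv) radially aligned vessels filling the revascularized
#' annulus between the shrinking avascular disk and the original wound
#' border. Each element carries full ground truth including the avascular
#' `wound_mask` and `wound_center`.
#'
#' @param config a [wound_series_config()].
#' @return A list with one element per timepoint: `list(volume, truth, dpw)`.
#' @export
make_wound_series <- function(config) {
  stopifnot(inherits(config, "wound_series_config"))
  pc <- config$phantom
  fov <- pc$field_of_view
  center <- fov / 2
  r0 <- config$initial_radius
  closure <- series_closure(config)
  r_t <- r0 * sqrt(pmax(0, 1 - closure))
  nx <- ceiling(fov[1] / pc$voxel[1]); ny <- ceiling(fov[2] / pc$voxel[2])
  xs <- axis_coords(nx, pc$voxel[1]); ys <- axis_coords(ny, pc$voxel[2])
  surf <- phantom_surface_grid(pc)
  with_seed(config$seed, {
    deep <- Filter(function(v) v$layer == "deep",
                   gen_baseline_vessels(
                     modifyList_cfg(pc, vessel_counts = c(superficial = 0,
                                                          deep = pc$vessel_counts[["deep"]])),
                     center = center))
    out <- vector("list", length(config$timepoints))
    for (i in seq_along(config$timepoints)) {
      vessels <- c(deep,
                   gen_wound_superficial(config, i, center, r_t[i]))
      dsq <- outer(xs, ys, function(x, y) (x - center[1])^2 + (y - center[2])^2)
      truth <- structure(list(
        vessels = vessels,
        metrics = vessel_metrics_table(vessels),
        surface = surf,
        pixel = pc$voxel[1:2],
        wound_mask = dsq <= r_t[i]^2,
        wound_radius = r_t[i],
        initial_radius = r0,
        closure = closure[i],
        wound_center = center),
        class = "phantom_truth")
      out[[i]] <- list(volume = render_phantom_volume(pc, vessels),
                       truth = truth, dpw = config$timepoints[i])
    }
    out
  })
}

# shallow config edit that keeps the class and re-validates
modifyList_cfg <- function(cfg, ...) {
  out <- utils::modifyList(unclass(cfg), list(...))
  class(out) <- class(cfg)
  out
}

# Stratified sample of ~n midpoints in an annulus: jittered rings of jittered
# angular positions. Returns a matrix (x, y, radial angle).
stratified_annulus <- function(n, center, r_in, r_out) {
  if (n < 1) return(matrix(numeric(0), 0, 3))
  n_rings <- max(1L, round(sqrt(n * (r_out - r_in) / (pi * (r_out + r_in)))))
  edges <- seq(r_in, r_out, length.out = n_rings + 1)
  out <- NULL
  for (k in seq_len(n_rings)) {
    rmid <- (edges[k] + edges[k + 1]) / 2
    nk <- max(1L, round(n * (edges[k + 1]^2 - edges[k]^2) / (r_out^2 - r_in^2)))
    phi0 <- stats::runif(1, 0, 2 * pi)
    phis <- phi0 + (seq_len(nk) - 1) * 2 * pi / nk +
      stats::runif(nk, -0.4, 0.4) * 2 * pi / nk
    rhos <- stats::runif(nk, edges[k], edges[k + 1])
    out <- rbind(out, cbind(center[1] + rhos * cos(phis),
                            center[2] + rhos * sin(phis), phis %% (2 * pi)))
  }
  out
}

# Superficial compartment of one wound timepoint.
gen_wound_superficial <- function(cfg, i, center, r_cur) {
  pc <- cfg$phantom
  fov <- pc$field_of_view
  bounds <- c(0, fov[1], 0, fov[2])
  r0 <- cfg$initial_radius
  in_disk <- function(r) function(x, y)
    (x - center[1])^2 + (y - center[2])^2 <= r^2
  vessels <- Filter(function(v) v$layer == "superficial",
                    gen_baseline_vessels(
                      modifyList_cfg(pc, vessel_counts = c(
                        superficial = pc$vessel_counts[["superficial"]], deep = 0)),
                      avoid = in_disk(r0), center = center))
  closure <- series_closure(cfg)[i]
  zfun_at <- function(clr) function(x, y) phantom_surface(pc, x, y) - clr
  # peri-wound sprout ring just outside the avascular margin while the
  # wound is still open (sprouts surround the margin and grow toward it,
  # but the wound bed itself stays avascular)
  if (closure < cfg$sprout_until_closure && r_cur > 0) {
    w <- cfg$sprout_ring_width
    ann_lo <- r_cur; ann_hi <- r_cur + w
    outside_ring <- function(x, y) {
      d2 <- (x - center[1])^2 + (y - center[2])^2
      d2 < ann_lo^2 | d2 > (ann_hi + w / 2)^2
    }
    for (s in seq_len(cfg$n_ring)) {
      phi <- stats::runif(1, 0, 2 * pi)
      rho <- stats::runif(1, ann_lo, ann_hi)
      start <- center + rho * c(cos(phi), sin(phi))
      xy <- walk_centerline(start, stats::runif(1, 0, 2 * pi),
                            stats::runif(1, 200, 500), pc$step,
                            cfg$sprout_tortuosity, bounds, outside_ring)
      if (is.null(xy)) next
      clr <- stats::runif(1, pc$superficial_clearance[1], pc$superficial_clearance[2])
      r <- cfg$sprout_dilation *
        stats::runif(1, pc$superficial_diam_range[1], pc$superficial_diam_range[2]) / 2
      vessels[[length(vessels) + 1L]] <-
        make_vessel(xy, zfun_at(clr), r, "superficial", "sprout", center)
    }
  }
  # radially aligned vessels filling the revascularized annulus [r_cur, r0];
  # placement is stratified (jittered polar grid) -- capillary beds are
  # space-filling, and Poisson placement would leave unrealistic voids
  frac <- max(0, 1 - (r_cur / r0)^2)
  n_in <- round(cfg$n_inwound * frac)
  if (n_in > 0) {
    m <- cfg$alignment_schedule[i]
    s_dev <- if (m >= 1) 0 else if (m <= 0) NA else sqrt(-log(m) / 2)
    mids <- stratified_annulus(n_in, center, r_cur, r0)
    for (s in seq_len(nrow(mids))) {
      mid <- mids[s, 1:2]
      phi <- mids[s, 3]
      len <- stats::runif(1, 200, 600)
      xy <- walk_centerline(mid - len / 2 * c(cos(phi), sin(phi)), phi, len,
                            pc$step, cfg$tortuosity_schedule[i], bounds)
      if (is.null(xy)) next
      delta <- if (is.na(s_dev)) stats::runif(1, -pi / 2, pi / 2)
               else stats::rnorm(1, 0, s_dev)
      # align the chord to (radial + delta) at the polyline's own mid vertex,
      # where the alignment metric is evaluated; for tortuous walks the mid
      # vertex moves slightly under rotation, so iterate to a fixed point
      for (it in 1:3) {
        mv <- xy[ceiling(nrow(xy) / 2), ]
        phi_m <- atan2(mv[2] - center[2], mv[1] - center[1])
        xy <- rotate_to_chord(xy, phi_m + delta)
      }
      # clip anything the rotation swung into the avascular disk or out of
      # the field of view (collinear truncation keeps the chord direction)
      keep <- (xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2 > r_cur^2 &
        xy[, 1] >= 0 & xy[, 1] <= fov[1] & xy[, 2] >= 0 & xy[, 2] <= fov[2]
      bad <- which(!keep)
      if (length(bad)) {
        runs <- split(seq_len(nrow(xy))[keep], cumsum(!keep)[keep])
        if (!length(runs)) next
        xy <- xy[runs[[which.max(lengths(runs))]], , drop = FALSE]
        if (nrow(xy) < 2) next
      }
      clr <- stats::runif(1, pc$superficial_clearance[1], pc$superficial_clearance[2])
      r <- stats::runif(1, pc$superficial_diam_range[1], pc$superficial_diam_range[2]) / 2
      vessels[[length(vessels) + 1L]] <-
        make_vessel(xy, zfun_at(clr), r, "superficial", "inwound", center)
    }
  }
  vessels
}

#' Simulate an edge-target resolution scan
#'
#' Samples the edge-spread function `y(x) = 1 / (1 + exp(-k (x - x0)))` of a
#' sharp absorbing edge, plus optional zero-mean Gaussian noise, as recorded
#' when scanning across an edge target.
#'
#' @param k edge steepness, 1/um.
#' @param x0 edge location, um.
#' @param step sample spacing, um.
#' @param noise_sigma amplitude noise standard deviation.
#' @param span half-width of the scan around `x0`, um (default covers both
#'   plateaus generously).
#' @param seed optional seed for the noise.
#' @return An object of class `edge_scan`: list with `x` (um) and `y`.
#' @export
make_edge_target <- function(k, x0, step, noise_sigma = 0, span = NULL,
                             seed = NULL) {
  stopifnot(k > 0, step > 0, noise_sigma >= 0)
  if (is.null(span)) span <- max(12 / k, 10 * step)
  x <- seq(x0 - span, x0 + span, by = step)
  y <- logistic(x, k, x0)
  if (noise_sigma > 0) {
    if (!is.null(seed)) return(with_seed(seed, {
      structure(list(x = x, y = y + stats::rnorm(length(x), 0, noise_sigma)),
                class = "edge_scan")
    }))
    y <- y + stats::rnorm(length(x), 0, noise_sigma)
  }
  structure(list(x = x, y = y), class = "edge_scan")
}

#' Simulate a raw A-scan stream from a volume
#'
#' Emulates pulse-by-pulse acquisition: the scan head visits lateral
#' positions along a raster or sinusoidal trajectory (fast sinusoidal x-axis
#' sweep, slow linear y-axis motion); each laser pulse records the volume's
#' depth column at the nearest lateral voxel, scaled by a per-pulse relative
#' energy drawn uniformly from `1 +/- energy_jitter`.
#'
#' @param volume an [oa_volume].
#' @param energy_jitter relative per-pulse energy fluctuation, in `[0, 1)`.
#' @param trajectory `"raster"` (one pulse per grid node, in grid order) or
#'   `"sinusoidal"`.
#' @param seed seed for energy jitter.
#' @param oversample pulses per grid node for the sinusoidal trajectory; the
#'   default 4 covers every lateral grid column.
#' @param sample_rate digitizer rate, Hz (metadata; default 250 MS/s).
#' @return An object of class `oa_rawscan`: `ascans` (pulse x depth-sample
#'   matrix), `sample_rate`, `positions` (pulse x 2, um), `energies`,
#'   `depth_spacing` (um).
#' @export
make_raw_scan <- function(volume, energy_jitter = 0,
                          trajectory = c("raster", "sinusoidal"),
                          seed = 1L, oversample = 4, sample_rate = 250e6) {
  stopifnot(inherits(volume, "oa_volume"),
            energy_jitter >= 0, energy_jitter < 1)
  trajectory <- match.arg(trajectory)
  d <- dim(volume$data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  dx <- volume$voxel[1]; dy <- volume$voxel[2]
  if (trajectory == "raster") {
    ix <- rep(seq_len(nx), times = ny)
    iy <- rep(seq_len(ny), each = nx)
    pos <- cbind((ix - 1) * dx, (iy - 1) * dy)
  } else {
    n <- oversample * nx * ny
    t <- (seq_len(n) - 1) / n
    x <- (nx - 1) * dx * (1 - cos(2 * pi * ny * t)) / 2
    y <- (ny - 1) * dy * t
    pos <- cbind(x, y)
    ix <- clamp(round(x / dx), 0, nx - 1) + 1L
    iy <- clamp(round(y / dy), 0, ny - 1) + 1L
  }
  cols <- matrix(volume$data, nrow = nx * ny, ncol = nz)
  ascans <- cols[ix + nx * (iy - 1L), , drop = FALSE]
  energies <- rep(1, nrow(ascans))
  if (energy_jitter > 0) {
    energies <- with_seed(seed,
      stats::runif(nrow(ascans), 1 - energy_jitter, 1 + energy_jitter))
    ascans <- ascans * energies
  }
  structure(list(ascans = ascans, sample_rate = sample_rate,
                 positions = unname(pos), energies = energies,
                 depth_spacing = volume$voxel[3]),
            class = "oa_rawscan")
}

#' @export
print.oa_rawscan <- function(x, ...) {
  cat(sprintf("<oa_rawscan> %d pulses x %d depth samples, %.0f MS/s\n",
              nrow(x$ascans), ncol(x$ascans), x$sample_rate / 1e6))
  invisible(x)
}
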