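#' Binarize a vessel map by hysteresis thresholding
#'
#' Produces the binary vessel mask the skeletonization works on. Weak
#' candidate pixels are taken from the amplitude map at `low` times its
#' robust maximum (the default 0.135, `exp(-2)`, matches the 1/e^2 width
#' convention for Gaussian-profile vessel cross-sections, keeping
#' distance-transform diameters unbiased); strong seed pixels additionally
#' require a high vesselness-weighted amplitude. Weak components are kept
#' only if they contain a seed (hysteresis), and objects smaller than
#' `min_size` pixels are removed. Raising `high` can only remove pixels,
#' never add them.
#'
#' @param map amplitude matrix (maximum-amplitude projection).
#' @param vesselness matching tubularity response (same shape), e.g. the
#'   small-scale map of [vesselness_maps()].
#' @param low weak threshold, fraction of the map's robust maximum.
#' @param high strong-seed threshold on the vesselness-weighted map.
#' @param min_size minimum object size in pixels.
#' @return Logical matrix. An empty result triggers a warning.
#' @export
binarize_vessels <- function(map, vesselness, low = exp(-2), high = 0.3,
                             min_size = 5) {
  stopifnot(is.matrix(map), all(dim(map) == dim(vesselness)))
  m0 <- stats::quantile(map, 0.999)
  if (m0 <= 0) {
    warning("empty vessel mask: map has no signal")
    return(matrix(FALSE, nrow(map), ncol(map)))
  }
  mapn <- clamp(map / m0, 0, 1)
  vmax <- max(vesselness)
  w <- if (vmax > 0) mapn * (vesselness / vmax) else mapn * 0
  # the weak (outline) threshold acts on a lightly denoised map: a 3x3 box
  # cuts pixel noise threefold while barely moving the 1/e^2 outline
  k3 <- rep(1 / 3, 3)
  weak <- cpp_sep_conv2(mapn, k3, k3) >= low
  strong <- w >= high
  lab <- cpp_label(weak, 8L)
  keep <- unique(lab[strong & lab > 0])
  mask <- matrix(lab %in% keep & lab > 0, nrow(map), ncol(map))
  if (any(mask)) {
    # close pinholes and boundary notches left by noise (1.5 px disk; a
    # closing this small cannot expand the vessel outline)
    dil <- cpp_edt2(!mask, 1, 1, FALSE) <= 1.5
    mask <- (cpp_edt2(dil, 1, 1, FALSE) > 1.5) | mask
  }
  if (any(mask)) {
    lab2 <- cpp_label(mask, 8L)
    sizes <- tabulate(lab2[lab2 > 0])
    mask <- matrix(lab2 > 0 & sizes[pmax(lab2, 1)] >= min_size,
                   nrow(map), ncol(map))
  }
  if (!any(mask)) warning("empty vessel mask")
  # companion mask for diameter measurement: the denoised outline is wider
  # than the true 1/e^2 contour, so distances are measured on the raw
  # amplitude contour within the detected vessels
  attr(mask, "measure") <- mask & mapn >= low
  mask
}

# 8-neighbor count of TRUE pixels (borders treated as background)
neighbor_count <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  p <- matrix(0L, nx + 2, ny + 2)
  p[2:(nx + 1), 2:(ny + 1)] <- mask
  acc <- matrix(0L, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    acc <- acc + p[(2:(nx + 1)) + di, (2:(ny + 1)) + dj]
  }
  acc
}

# 3x3 binary dilation
dilate1 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  p <- matrix(FALSE, nx + 2, ny + 2)
  p[2:(nx + 1), 2:(ny + 1)] <- mask
  acc <- matrix(FALSE, nx, ny)
  for (di in -1:1) for (dj in -1:1)
    acc <- acc | p[(2:(nx + 1)) + di, (2:(ny + 1)) + dj]
  acc
}

# Crossing number: 0->1 transitions around the 8-neighborhood in cyclic
# order. Counts the distinct branches meeting at a pixel; >= 3 marks a true
# junction. (A plain neighbor count misclassifies the staircase-redundant
# pixels Zhang-Suen leaves on diagonal runs.)
crossing_number <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  p <- matrix(0L, nx + 2, ny + 2)
  p[2:(nx + 1), 2:(ny + 1)] <- mask
  offs <- list(c(0, -1), c(1, -1), c(1, 0), c(1, 1),
               c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  ri <- 2:(nx + 1); rj <- 2:(ny + 1)
  acc <- matrix(0L, nx, ny)
  for (t in seq_along(offs)) {
    a <- offs[[t]]; b <- offs[[if (t == 8) 1 else t + 1]]
    acc <- acc + (p[ri + a[1], rj + a[2]] == 0L & p[ri + b[1], rj + b[2]] == 1L)
  }
  acc
}

#' Skeletonize a vessel mask and decompose it into centerlines
#'
#' Thins the mask to a one-pixel, topology-preserving skeleton (Zhang-Suen),
#' splits it at junction pixels (three or more skeleton neighbors), orders
#' each remaining branch into a pixel path, and converts paths to
#' micrometre coordinates. Branches shorter than `min_length` (spurs and
#' fragments) are discarded.
#'
#' @param mask logical matrix.
#' @param min_length minimum centerline length in um (default 30, about four
#'   times the lateral resolution).
#' @param pixel lateral pixel size `(dx, dy)` in um.
#' @return List of centerline matrices (columns `x`, `y` in um), each with
#'   attribute `pixels` (the corresponding `(i, j)` pixel indices).
#' @export
skeletonize_and_segment <- function(mask, min_length = 30, pixel = c(1, 1)) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(mask)) return(list())
  skel <- cpp_thin(mask)
  cn <- crossing_number(skel)
  junction <- skel & cn >= 3
  # drop junctions with their 3x3 neighborhood: branch ends are diagonal
  # neighbors of each other around a removed junction pixel and would
  # otherwise reconnect under 8-connectivity
  branches <- skel & !dilate1(junction)
  lab <- cpp_label(branches, 8L)
  nx <- nrow(mask)
  segs <- list()
  nlab <- max(lab)
  if (nlab == 0) return(list())
  idx_all <- which(lab > 0)
  by_lab <- split(idx_all, lab[idx_all])
  for (ids in by_lab) {
    path <- order_path(ids, nx)
    if (length(path) < 2) next
    i <- (path - 1) %% nx + 1
    j <- (path - 1) %/% nx + 1
    cl <- cbind(x = (i - 1) * pixel[1], y = (j - 1) * pixel[2])
    len <- sum(sqrt(rowSums(diff(cl)^2)))
    if (len < min_length) next
    attr(cl, "pixels") <- cbind(i, j)
    segs[[length(segs) + 1L]] <- cl
  }
  segs
}

# Order the linear indices of a thin 8-connected branch into a path by
# greedy walking from an endpoint (or an arbitrary pixel for loops).
order_path <- function(ids, nx) {
  if (length(ids) <= 2) return(ids)
  pos <- new.env(hash = TRUE, size = length(ids))
  for (id in ids) assign(as.character(id), TRUE, envir = pos)
  offs <- c(-1, 1, -nx, nx, -nx - 1, -nx + 1, nx - 1, nx + 1)
  nbrs <- function(id) {
    cand <- id + offs
    # guard row wrap-around: neighbor must stay within +-1 row
    ri <- (id - 1) %% nx
    rc <- (cand - 1) %% nx
    cand <- cand[abs(rc - ri) <= 1]
    cand[vapply(as.character(cand), exists, FALSE, envir = pos, inherits = FALSE)]
  }
  deg <- vapply(ids, function(id) length(nbrs(id)), 0L)
  start <- if (any(deg <= 1)) ids[which(deg <= 1)[1]] else ids[1]
  path <- integer(length(ids))
  visited <- new.env(hash = TRUE, size = length(ids))
  cur <- start
  for (t in seq_along(ids)) {
    path[t] <- cur
    assign(as.character(cur), TRUE, envir = visited)
    nn <- nbrs(cur)
    nn <- nn[!vapply(as.character(nn), exists, FALSE, envir = visited,
                     inherits = FALSE)]
    if (!length(nn)) { path <- path[seq_len(t)]; break }
    # prefer 4-connected continuation (tighter path through the raster)
    d4 <- abs(nn - cur) %in% c(1, nx)
    cur <- if (any(d4)) nn[d4][1] else nn[1]
  }
  path
}

# centered moving-average smoothing (full windows only) for turning angles;
# raster skeletons of straight lines otherwise accumulate staircase turning
smooth_centerline <- function(cl, window = 3) {
  n <- nrow(cl)
  if (window <= 1 || n < window + 2) return(cl)
  k <- rep(1 / window, window)
  xs <- stats::filter(cl[, 1], k, sides = 2)
  ys <- stats::filter(cl[, 2], k, sides = 2)
  keep <- !is.na(xs)
  cbind(x = as.numeric(xs[keep]), y = as.numeric(ys[keep]))
}

#' Morphometrics of one vessel centerline
#'
#' Computes the per-segment measures: path length (sum of chord lengths),
#' diameter (twice the median distance-to-background along the centerline),
#' end-to-end orientation folded to `[0, 180)` degrees, and tortuosity, the
#' accumulated absolute turning angle between consecutive chords of the
#' (lightly smoothed) centerline divided by path length, in degrees per um.
#' Two-point centerlines get tortuosity 0 by convention.
#'
#' @param centerline matrix with columns `x`, `y` in um (attribute `pixels`
#'   used for the distance-map lookup when present).
#' @param distance_map optional Euclidean distance transform of the vessel
#'   mask in um (per-pixel distance to the nearest background pixel).
#' @param pixel lateral pixel size in um (used to index `distance_map` when
#'   the centerline has no `pixels` attribute).
#' @param smooth_window moving-average window (points) applied before
#'   turning-angle summation.
#' @param chord_um target physical chord length (um) of the turning-angle
#'   stencil; the centerline is strided so consecutive chords span about
#'   this distance. On rasterized skeletons, single-pixel chords alias the
#'   staircase into spurious turning; ~30 um chords (four lateral resolution
#'   elements) suppress it while leaving genuine curvature intact (for a
#'   circular arc the turning-per-length ratio is chord-length invariant).
#' @param depth_map optional matrix of depths (um) to annotate the segment.
#' @return Object of class `vessel_segment`: list with `length`, `diameter`,
#'   `angle`, `tortuosity`, `midpoint`, `depth`, `n_points`.
#' @export
measure_segment <- function(centerline, distance_map = NULL, pixel = c(1, 1),
                            smooth_window = 3, chord_um = 30,
                            depth_map = NULL) {
  n <- nrow(centerline)
  stopifnot(n >= 2)
  steps <- diff(centerline[, 1:2, drop = FALSE])
  seglen <- sqrt(rowSums(steps^2))
  len <- sum(seglen)
  dvec <- centerline[n, 1:2] - centerline[1, 1:2]
  angle <- (atan2(dvec[2], dvec[1]) * 180 / pi) %% 180
  diameter <- NA_real_
  if (!is.null(distance_map)) {
    px <- attr(centerline, "pixels")
    if (is.null(px))
      px <- cbind(pmin(pmax(round(centerline[, 1] / pixel[1]) + 1, 1),
                       nrow(distance_map)),
                  pmin(pmax(round(centerline[, 2] / pixel[2]) + 1, 1),
                       ncol(distance_map)))
    diameter <- 2 * stats::median(distance_map[px])
  }
  depth <- NA_real_
  if (!is.null(depth_map)) {
    px <- attr(centerline, "pixels")
    if (!is.null(px)) depth <- stats::median(depth_map[px])
  }
  tortuosity <- 0
  if (n >= 3) {
    sm <- smooth_centerline(centerline[, 1:2, drop = FALSE], smooth_window)
    stride <- max(1L, round(chord_um / stats::median(
      sqrt(rowSums(diff(sm)^2)))))
    sm <- sm[seq(1, nrow(sm), by = stride), , drop = FALSE]
    if (nrow(sm) >= 3) {
      v <- diff(sm)
      v1 <- v[-nrow(v), , drop = FALSE]
      v2 <- v[-1, , drop = FALSE]
      cross <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
      dot <- v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2]
      turn <- abs(atan2(cross, dot)) * 180 / pi
      # each turning vertex is paired with the mean length of its two
      # chords; the ratio is then exact for circular arcs independent of
      # chord count (no end-effect bias)
      lens <- sqrt(rowSums(v^2))
      assoc <- (lens[-length(lens)] + lens[-1]) / 2
      tortuosity <- sum(turn) / sum(assoc)
    }
  }
  mid <- centerline[ceiling(n / 2), 1:2]
  structure(list(length = len, diameter = diameter, angle = unname(angle),
                 tortuosity = tortuosity,
                 midpoint = c(x = unname(mid[1]), y = unname(mid[2])),
                 depth = depth, n_points = n),
            class = "vessel_segment")
}

#' Angular alignment of a vessel toward the wound center
#'
#' Scores how closely a segment's (undirected) orientation matches the
#' radial direction from the wound center through its midpoint:
#' `cos(2 * delta)` with `delta` the acute angle between the two directions.
#' +1 means radially aligned, -1 circumferential, and isotropically oriented
#' vessels average 0.
#'
#' @param segment a [measure_segment()] result (or list with `angle` in
#'   degrees and `midpoint` in um).
#' @param wound_center `(x, y)` in um.
#' @return Score in `[-1, 1]`, or `NA` (with a warning) if the midpoint
#'   coincides with the center.
#' @export
angular_alignment <- function(segment, wound_center) {
  mid <- segment$midpoint
  if (all(abs(mid - wound_center) < .Machine$double.eps * 100)) {
    warning("segment midpoint at wound center; alignment undefined, excluded")
    return(NA_real_)
  }
  alignment_score(segment$angle, mid, wound_center)
}

#' Full vessel analysis of a projection
#'
#' Convenience wrapper running the morphometry stage end to end: vesselness,
#' hysteresis binarization, skeletonization with branch decomposition,
#' per-segment measures and (when a wound center is given) angular
#' alignment.
#'
#' @param projection an `oa_projection` (typically of the superficial
#'   volume).
#' @param wound_center optional `(x, y)` in um.
#' @param min_length minimum segment length in um.
#' @param scales_small vesselness scales in um.
#' @param ... passed to [binarize_vessels()].
#' @return A `data.frame` (one row per retained segment) with columns
#'   `id`, `mid_x`, `mid_y`, `length_um`, `diameter_um`, `angle_deg`,
#'   `tortuosity_deg_per_um`, `align`, `depth_um`, `n_points`; the binary
#'   mask and skeleton segment list are attached as attributes.
#' @export
analyze_vessels <- function(projection, wound_center = NULL, min_length = 30,
                            scales_small = c(5, 10, 15), ...) {
  stopifnot(inherits(projection, "oa_projection"))
  vn <- multiscale_vesselness(clahe(projection$map), scales_small,
                              projection$pixel)
  mask <- binarize_vessels(projection$map, vn, ...)
  px <- projection$pixel
  segs <- skeletonize_and_segment(mask, min_length = min_length, pixel = px)
  meas <- attr(mask, "measure")
  if (is.null(meas)) meas <- mask
  dmap <- if (any(mask)) cpp_edt2(meas, px[1], px[2]) else NULL
  depth_map <- projection$depth_index * projection$dz
  rows <- lapply(seq_along(segs), function(i) {
    s <- measure_segment(segs[[i]], distance_map = dmap, pixel = px,
                         depth_map = depth_map)
    al <- if (!is.null(wound_center)) angular_alignment(s, wound_center)
          else NA_real_
    data.frame(id = i, mid_x = s$midpoint[1], mid_y = s$midpoint[2],
               length_um = s$length, diameter_um = s$diameter,
               angle_deg = s$angle, tortuosity_deg_per_um = s$tortuosity,
               align = al, depth_um = s$depth, n_points = s$n_points)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), mid_x = numeric(), mid_y = numeric(),
               length_um = numeric(), diameter_um = numeric(),
               angle_deg = numeric(), tortuosity_deg_per_um = numeric(),
               align = numeric(), depth_um = numeric(), n_points = integer())
  rownames(out) <- NULL
  attr(out, "mask") <- mask
  attr(out, "segments") <- segs
  out
}
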