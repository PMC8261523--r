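# Sampled Gaussian and Gaussian-derivative kernels sharing one normalization
gauss_deriv_kernels <- function(sigma_px) {
  h <- max(2L, ceiling(3 * sigma_px))
  t <- seq(-h, h)
  g <- exp(-t^2 / (2 * sigma_px^2))
  nrm <- sum(g)
  g2 <- ((t^2 - sigma_px^2) / sigma_px^4) * g / nrm
  # enforce an exactly zero-sum second-derivative kernel: sampling roundoff
  # otherwise turns constant images into nonzero (if tiny) responses that the
  # self-normalizing Frangi measure then amplifies
  g2 <- g2 - sum(g2) / length(g2)
  list(g0 = g / nrm,
       g1 = (-t / sigma_px^2) * g / nrm,
       g2 = g2)
}

#' Multiscale Frangi vesselness of a 2D amplitude map
#'
#' Hessian-eigenvalue tubularity for bright curvilinear structures on a dark
#' background, computed at several Gaussian scales and combined by per-pixel
#' maximum. At each scale the image is filtered with scale-normalized
#' Gaussian second derivatives; with ordered eigenvalues `|l1| <= |l2|`, the
#' response is `exp(-(l1/l2)^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`
#' for `l2 < 0` (bright ridge) and 0 otherwise, with `S` the Frobenius norm
#' and `c` half its per-scale maximum. Constant images give an all-zero
#' response.
#'
#' @param map numeric matrix (e.g. a CLAHE-equalized maximum-amplitude
#'   projection).
#' @param scales Gaussian scales in um (approximately the vessel radius to
#'   enhance).
#' @param pixel lateral pixel size in um (length 1 or 2; lateral pixels are
#'   assumed near-isotropic and the mean is used).
#' @param beta Frangi blobness sensitivity.
#' @param c_norm optional structure-sensitivity constant (the Frangi `c`);
#'   by default half the maximum Frobenius norm over all requested scales.
#'   Pass a shared value to compare responses across separate calls on a
#'   common footing.
#' @return Matrix of the same size, response `>= 0`, with the constant used
#'   attached as attribute `c_norm`.
#' @export
multiscale_vesselness <- function(map, scales, pixel, beta = 0.5,
                                  c_norm = NULL) {
  stopifnot(is.matrix(map), length(scales) >= 1, all(scales > 0))
  px <- mean(pixel)
  if (any(scales >= min(dim(map)) * px / 4))
    stop("scales must be below a quarter of the image extent")
  out <- matrix(0, nrow(map), ncol(map))
  if (diff(range(map)) == 0) return(out)  # no structure, no response
  per_scale <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    s <- max(scales[i] / px, 0.5)
    k <- gauss_deriv_kernels(s)
    Lxx <- cpp_sep_conv2(map, k$g2, k$g0) * s^2
    Lyy <- cpp_sep_conv2(map, k$g0, k$g2) * s^2
    Lxy <- cpp_sep_conv2(map, k$g1, k$g1) * s^2
    # eigenvalues m +/- tmp with tmp >= 0; a bright ridge needs the
    # larger-magnitude eigenvalue negative, which happens exactly when m < 0
    # (then l2 = m - tmp, l1 = m + tmp with |l1| <= |l2|)
    tmp <- sqrt(((Lxx - Lyy) / 2)^2 + Lxy^2)
    m <- (Lxx + Lyy) / 2
    S2 <- 2 * (m^2 + tmp^2)  # squared Frobenius norm l1^2 + l2^2
    l2 <- m - tmp
    rb2 <- ((m + tmp) / (l2 + (l2 == 0)))^2
    per_scale[[i]] <- list(S2 = S2, rb2 = rb2, bright = m < 0)
  }
  # the structure-sensitivity constant is shared across scales (half the
  # maximum Frobenius norm over all of them): per-scale normalization would
  # equalize responses across scales and destroy scale selectivity
  c2 <- if (!is.null(c_norm)) c_norm^2
        else max(vapply(per_scale, function(p) max(p$S2), 0)) / 4
  if (c2 <= 0) return(out)
  for (p in per_scale) {
    v <- exp(-p$rb2 / (2 * beta^2)) * (1 - exp(-p$S2 / (2 * c2))) * p$bright
    out <- pmax(out, v)
  }
  attr(out, "c_norm") <- sqrt(c2)
  out
}

#' Small- and large-vessel response maps of a projection
#'
#' Convenience wrapper computing the two multiscale vesselness responses the
#' layer separation gates on, from the CLAHE-equalized maximum-amplitude
#' projection. Default scale sets match the superficial (10-30 um diameter)
#' and deep (35-50 um) vessel regimes.
#'
#' @param projection an `oa_projection`.
#' @param scales_small,scales_large Gaussian scales in um.
#' @param equalize apply [clahe()] to the map first.
#' @return Object of class `vesselness_maps`: `small`, `large`,
#'   `scales_small`, `scales_large`.
#' @export
vesselness_maps <- function(projection, scales_small = c(5, 10, 15),
                            scales_large = c(25, 40, 60), equalize = TRUE) {
  stopifnot(inherits(projection, "oa_projection"))
  m <- if (equalize) clahe(projection$map) else projection$map
  structure(list(
    small = multiscale_vesselness(m, scales_small, projection$pixel),
    large = multiscale_vesselness(m, scales_large, projection$pixel),
    scales_small = scales_small, scales_large = scales_large),
    class = "vesselness_maps")
}

#' Select surface support points from vesselness-gated depth indices
#'
#' Depth indices of pixels containing small but not large vessels serve as
#' support for the separation-surface fit: a pixel qualifies when its
#' small-vessel response exceeds the `q_small` quantile (and a noise floor of
#' `floor_frac` times the map maximum) while its large-vessel response stays
#' below the `q_large` quantile.
#'
#' @param vn a [vesselness_maps()] object.
#' @param projection the matching `oa_projection`.
#' @param q_small,q_large gating quantiles in (0, 1), taken over *structure*
#'   pixels (pixels whose small or large response exceeds `floor_frac` of
#'   the respective maximum). Quantiles over the full image would be
#'   dominated by the empty background and gate on noise instead of on
#'   vessels.
#' @param floor_frac response floor defining structure pixels, as a fraction
#'   of each map's maximum.
#' @return data.frame with `x`, `y`, `depth` (um).
#' @export
select_support_points <- function(vn, projection, q_small = 0.9,
                                  q_large = 0.7, floor_frac = 0.2) {
  stopifnot(inherits(vn, "vesselness_maps"), inherits(projection, "oa_projection"))
  stopifnot(q_small > 0, q_small < 1, q_large > 0, q_large < 1)
  struct <- vn$small > floor_frac * max(vn$small) |
            vn$large > floor_frac * max(vn$large)
  if (!any(struct)) stop("insufficient support: no vessel structure detected")
  ts <- stats::quantile(vn$small[struct], q_small)
  tl <- stats::quantile(vn$large[struct], q_large)
  sel <- vn$small > ts & vn$large < tl
  idx <- which(sel, arr.ind = TRUE)
  pts <- data.frame(
    x = (idx[, 1] - 1) * projection$pixel[1],
    y = (idx[, 2] - 1) * projection$pixel[2],
    depth = projection$depth_index[sel] * projection$dz)
  if (nrow(pts) < 50)
    stop("insufficient support: only ", nrow(pts), " support points")
  pts
}

# bilinear upsampling of a coarse grid (coords xs/ys, um) to target coords
bilinear_upsample <- function(m, xs, ys, xt, yt) {
  tmp <- apply(m, 2, function(col) stats::approx(xs, col, xout = xt, rule = 2)$y)
  t(apply(tmp, 1, function(row) stats::approx(ys, row, xout = yt, rule = 2)$y))
}

# TRUE for grid points inside the convex hull of (px, py)
in_hull <- function(gx, gy, px, py) {
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h]
  n <- length(h)
  if (n < 3) return(rep(FALSE, length(gx)))
  # chull returns clockwise; make the test sign-agnostic by orienting once
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  s <- sign(area2)
  inside <- rep(TRUE, length(gx))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (gy - hy[i]) - (hy[j] - hy[i]) * (gx - hx[i])
    inside <- inside & (s * cr >= 0)
  }
  inside
}

#' Fit the superficial/deep separation surface
#'
#' Combines two complementary surface estimates through the vesselness-gated
#' support points: a local linear (moving-least-squares plane) interpolation,
#' accurate but noisy, and a smooth fifth-order bivariate polynomial
#' least-squares fit. The returned surface is their average, shifted deeper
#' by `offset` (support points sit on capillaries; the separation plane lies
#' below them). Outside the convex hull of the support points the polynomial
#' alone is used (the local interpolant does not extrapolate).
#'
#' @param points data.frame with `x`, `y`, `depth` in um
#'   (from [select_support_points()]).
#' @param grid target grid: list/vector with `nx`, `ny`, `dx`, `dy`.
#' @param offset downward shift in um applied after averaging.
#' @param coarse number of moving-least-squares evaluation nodes per axis.
#' @param degree polynomial degree (lowered automatically, with a message,
#'   if the fit is rank-deficient).
#' @return Object of class `separation_surface`: `depth` (nx x ny matrix,
#'   um), `support_points`, `method`, `offset`, `pixel`.
#' @export
fit_separation_surface <- function(points, grid, offset = 30, coarse = 32,
                                   degree = 5) {
  grid <- as.list(grid)
  nx <- as.integer(grid$nx); ny <- as.integer(grid$ny)
  dx <- grid$dx; dy <- grid$dy
  if (nrow(points) < 50) stop("need at least 50 support points")
  ext_x <- (nx - 1) * dx; ext_y <- (ny - 1) * dy
  if (diff(range(points$x)) < 0.5 * ext_x || diff(range(points$y)) < 0.5 * ext_y)
    stop("support points must span at least half the grid extent in x and y")
  xt <- axis_coords(nx, dx); yt <- axis_coords(ny, dy)
  # --- smooth component: bivariate polynomial least squares on scaled coords
  mx <- mean(points$x); sx <- max(stats::sd(points$x), 1)
  my <- mean(points$y); sy <- max(stats::sd(points$y), 1)
  u <- (points$x - mx) / sx; v <- (points$y - my) / sy
  poly_design <- function(u, v, deg) {
    cols <- list()
    for (i in 0:deg) for (j in 0:(deg - i)) cols[[length(cols) + 1L]] <- u^i * v^j
    do.call(cbind, cols)
  }
  deg <- degree
  repeat {
    X <- poly_design(u, v, deg)
    qrX <- qr(X)
    if (qrX$rank == ncol(X) || deg == 1) break
    deg <- deg - 1
    message("rank-deficient polynomial fit; lowering degree to ", deg)
  }
  beta <- qr.coef(qrX, points$depth)
  beta[is.na(beta)] <- 0
  ug <- (rep(xt, times = ny) - mx) / sx
  vg <- (rep(yt, each = nx) - my) / sy
  poly_grid <- matrix(poly_design(ug, vg, deg) %*% beta, nx, ny)
  # --- data-faithful component: moving-least-squares plane on a coarse grid
  ncx <- min(coarse, nx); ncy <- min(coarse, ny)
  xs <- seq(0, ext_x, length.out = ncx)
  ys <- seq(0, ext_y, length.out = ncy)
  r0 <- 2 * max(ext_x / ncx, ext_y / ncy)
  interp_c <- matrix(NA_real_, ncx, ncy)
  for (j in seq_len(ncy)) {
    dy2 <- (points$y - ys[j])^2
    for (i in seq_len(ncx)) {
      d2 <- (points$x - xs[i])^2 + dy2
      r <- r0
      repeat {
        sel <- d2 <= r^2
        if (sum(sel) >= 8 || r > max(ext_x, ext_y)) break
        r <- r * 1.5
      }
      if (sum(sel) < 3) next
      X <- cbind(1, points$x[sel] - xs[i], points$y[sel] - ys[j])
      fitc <- tryCatch(qr.coef(qr(X), points$depth[sel]), error = function(e) NULL)
      if (!is.null(fitc) && is.finite(fitc[1])) interp_c[i, j] <- fitc[1]
    }
  }
  poly_c <- matrix(poly_design((rep(xs, times = ncy) - mx) / sx,
                               (rep(ys, each = ncx) - my) / sy, deg) %*% beta,
                   ncx, ncy)
  interp_c[is.na(interp_c)] <- poly_c[is.na(interp_c)]
  interp_grid <- bilinear_upsample(interp_c, xs, ys, xt, yt)
  # --- average inside the support hull, polynomial alone outside
  avg <- (interp_grid + poly_grid) / 2
  gx <- rep(xt, times = ny); gy <- rep(yt, each = nx)
  inside <- matrix(in_hull(gx, gy, points$x, points$y), nx, ny)
  depth <- ifelse(inside, avg, poly_grid)
  # a high-degree polynomial extrapolates without bound; the separation
  # surface cannot leave the observed capillary depth band
  depth <- clamp(depth, min(points$depth), max(points$depth)) + offset
  structure(list(depth = depth, support_points = points, method = "average",
                 offset = offset, pixel = c(dx, dy), poly_degree = deg),
            class = "separation_surface")
}

#' @export
print.separation_surface <- function(x, ...) {
  cat(sprintf(
    "<separation_surface> %d x %d grid, depth %.0f-%.0f um (%d support points, offset %g um)\n",
    nrow(x$depth), ncol(x$depth), min(x$depth), max(x$depth),
    nrow(x$support_points), x$offset))
  invisible(x)
}

#' Split a volume at a separation surface
#'
#' Assigns every voxel strictly above the surface (depth < surface depth at
#' its lateral position) to the superficial volume and the rest to the deep
#' volume. The two outputs partition the input exactly:
#' superficial + deep = original, voxel-wise.
#'
#' @param volume an [oa_volume].
#' @param surface a [fit_separation_surface()] result (or any list with a
#'   `depth` matrix in um matching the volume's lateral grid).
#' @return list with `superficial` and `deep` [oa_volume]s.
#' @export
split_volume <- function(volume, surface) {
  stopifnot(inherits(volume, "oa_volume"))
  d <- dim(volume$data)
  if (!all(dim(surface$depth) == d[1:2]))
    stop("surface grid does not match the volume's lateral grid")
  sup <- array(0, dim = d)
  deep <- array(0, dim = d)
  dz <- volume$voxel[3]
  for (k in seq_len(d[3])) {
    above <- (k - 1) * dz < surface$depth
    slice <- volume$data[, , k]
    sup[, , k] <- slice * above
    deep[, , k] <- slice * !above
  }
  list(superficial = oa_volume(sup, volume$voxel),
       deep = oa_volume(deep, volume$voxel))
}
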