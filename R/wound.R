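#' Derive a vascularized-area mask from a vessel mask
#'
#' Vessels are sparse curves; the vascularized *area* is obtained by
#' morphological closing of the binary vessel mask with a disk (default
#' 300 um radius, bridging the typical inter-capillary spacing) followed by
#' filling of enclosed holes smaller than `max_hole_area`. Large enclosed
#' voids -- the avascular wound bed -- are preserved.
#'
#' @param vessel_mask logical matrix.
#' @param pixel pixel size `(dx, dy)` in um.
#' @param closing_radius disk radius for closing, um.
#' @param max_hole_area holes up to this area (um^2) are filled; defaults to
#'   the closing-disk area.
#' @return Logical matrix: TRUE where tissue is vascularized.
#' @export
vascularized_mask <- function(vessel_mask, pixel, closing_radius = 300,
                              max_hole_area = pi * closing_radius^2) {
  stopifnot(is.logical(vessel_mask))
  if (!any(vessel_mask)) return(vessel_mask)
  # closing = dilation then erosion, both via the Euclidean distance transform
  dil <- cpp_edt2(!vessel_mask, pixel[1], pixel[2], FALSE) <= closing_radius
  # erosion: keep pixels farther than the radius from the dilated set's complement
  clo <- cpp_edt2(dil, pixel[1], pixel[2], FALSE) > closing_radius
  clo <- clo | vessel_mask  # closing never removes original foreground
  # fill small enclosed holes
  holes <- cpp_label(!clo, 4L)
  if (max(holes) > 0) {
    px_area <- pixel[1] * pixel[2]
    nx <- nrow(clo); ny <- ncol(clo)
    border_labs <- unique(c(holes[1, ], holes[nx, ], holes[, 1], holes[, ny]))
    sizes <- tabulate(holes[holes > 0])
    fill <- which(sizes * px_area <= max_hole_area)
    fill <- setdiff(fill, border_labs)
    if (length(fill)) clo[holes %in% fill] <- TRUE
  }
  clo
}

#' Wound center from the non-vascularized area
#'
#' The apparent wound center is the center of mass of the largest
#' non-vascularized connected component of the mask.
#'
#' @param mask logical matrix, TRUE = vascularized (from
#'   [vascularized_mask()] or ground truth).
#' @param pixel pixel size `(dx, dy)` in um.
#' @param exclude_border ignore non-vascularized components touching the
#'   image border (default): a wound bed is an enclosed avascular region,
#'   while border-touching components are peripheral coverage gaps of the
#'   field of view.
#' @return `(x, y)` in um.
#' @export
wound_center <- function(mask, pixel = c(1, 1), exclude_border = TRUE) {
  stopifnot(is.logical(mask))
  nonvasc <- !mask
  if (!any(nonvasc)) stop("no wound region: mask is fully vascularized")
  lab <- cpp_label(nonvasc, 4L)
  sizes <- tabulate(lab[lab > 0])
  if (exclude_border) {
    nx <- nrow(mask); ny <- ncol(mask)
    border <- setdiff(unique(c(lab[1, ], lab[nx, ], lab[, 1], lab[, ny])), 0L)
    sizes[border] <- 0L
  }
  if (!any(sizes > 0)) stop("no wound region: mask is fully vascularized")
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  c(x = (mean(idx[, 1]) - 1) * pixel[1],
    y = (mean(idx[, 2]) - 1) * pixel[2])
}

#' Healing and re-vascularization scores
#'
#' `healing_score` is the ratio of healed to initially wounded area,
#' `(initial - current) / initial`; `vascularization_score` the ratio of
#' re-vascularized area to the original wound area. Both are clipped to
#' `[0, 1]`; values close to 0 mean no healing, close to 1 full closure /
#' full re-vascularization. Apparent wound expansion beyond 5% warns.
#'
#' @param initial_area original wound area (um^2), > 0.
#' @param current_wound_area current (avascular) wound area (um^2).
#' @return Score in `[0, 1]`.
#' @export
healing_score <- function(initial_area, current_wound_area) {
  stopifnot(initial_area > 0, current_wound_area >= 0)
  if (current_wound_area > 1.05 * initial_area)
    warning("current wound area exceeds initial area by more than 5% (wound expansion); clipped")
  clamp((initial_area - current_wound_area) / initial_area, 0, 1)
}

#' @param revascularized_area re-vascularized area within the original wound
#'   (um^2).
#' @rdname healing_score
#' @export
vascularization_score <- function(initial_area, revascularized_area) {
  stopifnot(initial_area > 0, revascularized_area >= 0)
  if (revascularized_area > 1.05 * initial_area)
    warning("re-vascularized area exceeds the initial wound area by more than 5%; clipped")
  clamp(revascularized_area / initial_area, 0, 1)
}

#' Fit logistic healing kinetics
#'
#' Fits the logistic `score(t) = 1 / (1 + exp(-k (t - t0)))` to per-wound
#' closure or re-vascularization scores by least squares
#' (Levenberg-Marquardt), and derives the healing-rate curve as the
#' normalized numerical gradient of the fit; by the symmetry of the
#' logistic, the peak rate occurs at `t0`.
#'
#' @param times dpw values (at least 4).
#' @param scores matching scores in `[0, 1]`.
#' @param rate_grid_n number of grid points for the rate curve.
#' @return Object of class `healing_curve`: `k` (1/day), `t0` (day),
#'   `fitted`, `residual`, `rate_curve` (data.frame `t`, `rate` with max 1),
#'   `peak_rate_time`, plus the data.
#' @export
fit_healing_curve <- function(times, scores, rate_grid_n = 200) {
  stopifnot(length(times) == length(scores))
  if (length(times) < 4) stop("need at least 4 timepoints")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (diff(range(scores)) < 0.05)
    stop("degenerate healing data: scores show no progression; cannot fit kinetics")
  # initial values: midpoint crossing and a slope-matched steepness
  t0_0 <- stats::approx(scores, times, xout = 0.5, ties = mean)$y
  if (!is.finite(t0_0)) t0_0 <- mean(times)
  k0 <- 4 * max(diff(scores) / diff(times))
  if (!is.finite(k0) || k0 <= 0) k0 <- 1
  fn <- function(p) logistic(times, p[1], p[2])
  jac <- function(p) {
    L <- logistic(times, p[1], p[2])
    cbind(k = L * (1 - L) * (times - p[2]), t0 = -L * (1 - L) * p[1])
  }
  fit <- lm_core(c(k = k0, t0 = t0_0), scores, fn, jac)
  if (!fit$converged || !is.finite(fit$ssr))
    stop("healing-curve fit did not converge; residual sum of squares = ",
         signif(fit$ssr, 4))
  k <- unname(fit$par[1]); t0 <- unname(fit$par[2])
  tg <- seq(min(times), max(times), length.out = rate_grid_n)
  rate <- diff(logistic(tg, k, t0)) / diff(tg)
  tc <- (tg[-1] + tg[-length(tg)]) / 2
  rate <- rate / max(rate)
  structure(list(k = k, t0 = t0, fitted = fn(fit$par),
                 residual = sqrt(fit$ssr / length(times)),
                 rate_curve = data.frame(t = tc, rate = rate),
                 peak_rate_time = t0,
                 data = list(times = times, scores = scores)),
            class = "healing_curve")
}

#' @export
print.healing_curve <- function(x, ...) {
  cat("Logistic healing kinetics\n")
  cat(sprintf("  k  = %.3f / day\n  t0 = %.2f dpw (peak rate)\n  RMS residual = %.4f\n",
              x$k, x$t0, x$residual))
  invisible(x)
}

#' @export
coef.healing_curve <- function(object, ...) c(k = object$k, t0 = object$t0)

#' @export
predict.healing_curve <- function(object, times = object$data$times, ...) {
  logistic(times, object$k, object$t0)
}

#' Spatial heat maps of vessel parameters
#'
#' Re-expresses vessel positions relative to each wound's center, pools the
#' vessels of all supplied wounds, and bins them into square areas (default
#' 400 um over a 6 mm extent). Each bin holds the mean of the member
#' vessels' length, diameter, tortuosity and alignment; empty bins are `NA`,
#' not zero, and per-bin counts are retained.
#'
#' @param tables list of vessel tables (from [analyze_vessels()]).
#' @param centers list/matrix of matching wound centers `(x, y)` in um.
#' @param bin bin side, um.
#' @param extent full heat-map side, um.
#' @return Object of class `vessel_heatmap`: list of matrices `length`,
#'   `diameter`, `tortuosity`, `align`, `count`, plus `bin`, `extent` and
#'   the bin-center coordinates `centers_rel`.
#' @export
make_heatmaps <- function(tables, centers, bin = 400, extent = 6000) {
  stopifnot(length(tables) >= 1, length(tables) == NROW(centers))
  if (is.matrix(centers)) centers <- asplit(centers, 1)
  rel <- do.call(rbind, Map(function(tb, ct) {
    if (!nrow(tb)) return(NULL)
    data.frame(rx = tb$mid_x - ct[1], ry = tb$mid_y - ct[2],
               length_um = tb$length_um, diameter_um = tb$diameter_um,
               tortuosity = tb$tortuosity_deg_per_um, align = tb$align)
  }, tables, centers))
  nb <- floor(extent / bin)
  edges <- seq(-nb / 2 * bin, nb / 2 * bin, by = bin)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  empty <- matrix(NA_real_, nb, nb)
  out <- list(length = empty, diameter = empty, tortuosity = empty,
              align = empty, count = matrix(0L, nb, nb))
  if (!is.null(rel)) {
    bi <- findInterval(rel$rx, edges, rightmost.closed = TRUE)
    bj <- findInterval(rel$ry, edges, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= nb & bj >= 1 & bj <= nb
    if (any(ok)) {
      g <- interaction(bi[ok], bj[ok], drop = TRUE)
      cells <- cbind(as.integer(sub("\\..*", "", levels(g))),
                     as.integer(sub(".*\\.", "", levels(g))))
      out$count[cells] <- as.integer(table(g))
      for (v in c("length_um", "diameter_um", "tortuosity", "align")) {
        nm <- switch(v, length_um = "length", diameter_um = "diameter",
                     tortuosity = "tortuosity", align = "align")
        out[[nm]][cells] <- as.numeric(tapply(rel[[v]][ok], g, mean))
      }
    }
  }
  structure(c(out, list(bin = bin, extent = extent, centers_rel = mids)),
            class = "vessel_heatmap")
}

#' Radial profiles of vessel parameters
#'
#' Mean vessel length, diameter, tortuosity and alignment per annulus of
#' distance from the wound center, pooled over the supplied wounds (one
#' profile per group, e.g. per dpw). Annuli without vessels are reported as
#' `NA`, not zero.
#'
#' @param tables list of vessel tables.
#' @param centers matching wound centers `(x, y)` in um.
#' @param bin_width annulus width in um.
#' @param max_radius outermost annulus edge, um.
#' @param group optional per-table grouping label (e.g. dpw); defaults to a
#'   single pooled group.
#' @return data.frame with `group`, `r_mid` (annulus mid-radius, um), `n`,
#'   and mean `length_um`, `diameter_um`, `tortuosity_deg_per_um`, `align`.
#' @export
radial_profiles <- function(tables, centers, bin_width = 250,
                            max_radius = 3000, group = NULL) {
  stopifnot(bin_width > 0, length(tables) == NROW(centers))
  if (is.matrix(centers)) centers <- asplit(centers, 1)
  if (is.null(group)) group <- rep("all", length(tables))
  pooled <- do.call(rbind, Map(function(tb, ct, g) {
    if (!nrow(tb)) return(NULL)
    data.frame(g = g, r = sqrt((tb$mid_x - ct[1])^2 + (tb$mid_y - ct[2])^2),
               length_um = tb$length_um, diameter_um = tb$diameter_um,
               tortuosity_deg_per_um = tb$tortuosity_deg_per_um,
               align = tb$align)
  }, tables, centers, as.list(group)))
  edges <- seq(0, max_radius, by = bin_width)
  out <- do.call(rbind, lapply(split(pooled, pooled$g), function(dd) {
    bi <- findInterval(dd$r, edges, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= length(edges) - 1
    res <- data.frame(group = dd$g[1],
                      r_mid = (edges[-1] + edges[-length(edges)]) / 2,
                      n = 0L, length_um = NA_real_, diameter_um = NA_real_,
                      tortuosity_deg_per_um = NA_real_, align = NA_real_)
    if (any(ok)) {
      tb <- table(factor(bi[ok], levels = seq_len(length(edges) - 1)))
      res$n <- as.integer(tb)
      for (v in c("length_um", "diameter_um", "tortuosity_deg_per_um", "align")) {
        m <- tapply(dd[[v]][ok], factor(bi[ok], levels = seq_len(length(edges) - 1)),
                    mean, na.rm = TRUE)
        res[[v]] <- as.numeric(m)
      }
    }
    res
  }))
  rownames(out) <- NULL
  out
}

#' Compare superficial and deep vessel diameters across wounds
#'
#' Two-sample Student's t-test (equal variances by default, matching the
#' classical analysis; Welch optional) on per-wound median vessel diameters,
#' with group means and normal-theory 95% confidence intervals.
#'
#' @param superficial_medians,deep_medians per-wound median diameters, um
#'   (at least 2 each).
#' @param var_equal use the pooled-variance Student's test (default).
#' @return list with `t`, `p`, `df`, `means`, `ci` (2 x 2 matrix of 95%
#'   CIs), and the underlying `htest`.
#' @export
compare_layer_diameters <- function(superficial_medians, deep_medians,
                                    var_equal = TRUE) {
  if (length(superficial_medians) < 2 || length(deep_medians) < 2)
    stop("need at least 2 wounds per group")
  ht <- stats::t.test(superficial_medians, deep_medians, var.equal = var_equal)
  ci_of <- function(x) {
    n <- length(x)
    se <- stats::sd(x) / sqrt(n)
    mean(x) + c(-1, 1) * stats::qt(0.975, n - 1) * se
  }
  ci <- rbind(superficial = ci_of(superficial_medians),
              deep = ci_of(deep_medians))
  colnames(ci) <- c("lo", "hi")
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       means = c(superficial = mean(superficial_medians),
                 deep = mean(deep_medians)),
       ci = ci, htest = ht)
}
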