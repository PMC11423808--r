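# resample a closed polygon (n x 2) to m points uniformly spaced by arc length
.resample_closed <- function(p, m) {
  p <- as.matrix(p)
  n <- nrow(p)
  q <- rbind(p, p[1, ])
  seg <- sqrt(diff(q[, 1])^2 + diff(q[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[n + 1]
  target <- seq(0, total, length.out = m + 1L)[-(m + 1L)]
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx <- pmin(idx, n)
  f <- (target - s[idx]) / pmax(seg[idx], 1e-12)
  cbind(q[idx, 1] + f * (q[idx + 1, 1] - q[idx, 1]),
        q[idx, 2] + f * (q[idx + 1, 2] - q[idx, 2]))
}

# signed area; positive for counter-clockwise orientation
.polygon_area <- function(p) {
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]) / 2
}

# smallest positive ray-polygon intersection distance; NA when none <= smax
.ray_polygon_distance <- function(origin, dir, poly, smax) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1L), ]
  ex <- b[, 1] - a[, 1]
  ey <- b[, 2] - a[, 2]
  denom <- dir[1] * ey - dir[2] * ex
  wx <- a[, 1] - origin[1]
  wy <- a[, 2] - origin[2]
  s <- (wx * ey - wy * ex) / denom
  u <- (wx * dir[2] - wy * dir[1]) / (-denom)
  ok <- is.finite(s) & s > 1e-9 & u >= -1e-9 & u <= 1 + 1e-9 & s <= smax
  if (!any(ok)) return(NA_real_)
  min(s[ok])
}

#' Inter-edge distance between paired contours
#'
#' Measures local thickness between a closed inner and outer contour: at
#' `n_samples` points uniformly spaced by arc length along the inner contour,
#' the outward normal is cast and the distance to its first crossing of the
#' outer contour is recorded. Sample points whose polar angle (about the inner
#' contour centroid) falls inside an exclusion arc are dropped from the
#' summary, mirroring the manual exclusion of the interosseous membrane;
#' normals that fail to reach the outer contour within the search length are
#' flagged and dropped with a warning, and the measurement errors out if more
#' than half of the retained points fail.
#'
#' @param contour_inner,contour_outer data frames or matrices with columns
#'   `x_um`, `y_um`; ordered closed contours.
#' @param exclusion_arcs list of `c(lo_deg, hi_deg)` angular arcs (degrees, in
#'   `(-180, 180]`; `lo > hi` wraps), or a single such vector.
#' @param n_samples number of inner-contour sample points (>= 16).
#' @param max_search_um normal search length; default twice the bounding-box
#'   diagonal of the outer contour.
#' @return list of class `thickness_measurement`: `samples` (data frame with
#'   `x_um`, `y_um`, `theta_deg`, `distance_um`, `excluded`, `failed`),
#'   `mean_um`, `sd_um`, `n`, `n_excluded`, `n_failed`, `exclusion_arcs`.
#' @export
interedge_distance <- function(contour_inner, contour_outer,
                               exclusion_arcs = NULL, n_samples = 100L,
                               max_search_um = NULL) {
  if (n_samples < 16L) stop("n_samples must be at least 16")
  inner <- as.matrix(as.data.frame(contour_inner)[, 1:2])
  outer <- as.matrix(as.data.frame(contour_outer)[, 1:2])
  if (nrow(inner) < 3L || nrow(outer) < 3L) stop("contours need at least 3 points")
  if (.polygon_area(inner) < 0) inner <- inner[rev(seq_len(nrow(inner))), ]
  if (is.null(max_search_um)) {
    bb <- apply(outer, 2, range)
    max_search_um <- 2 * sqrt(sum((bb[2, ] - bb[1, ])^2))
  }
  if (!is.null(exclusion_arcs) && !is.list(exclusion_arcs))
    exclusion_arcs <- list(exclusion_arcs)

  pts <- .resample_closed(inner, n_samples)
  nrm <- .vertex_normals(pts)
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1]) * 180 / pi
  excl <- rep(FALSE, n_samples)
  for (arc in exclusion_arcs %||% list())
    excl <- excl | .theta_in_sector(ang, arc)

  dist <- rep(NA_real_, n_samples)
  for (i in seq_len(n_samples)) {
    if (excl[i]) next
    dist[i] <- .ray_polygon_distance(pts[i, ], nrm[i, ], outer, max_search_um)
  }
  failed <- !excl & is.na(dist)
  n_retained <- sum(!excl)
  if (n_retained == 0) stop("all sample points excluded")
  if (sum(failed) > 0)
    warning(sprintf("%d of %d normals failed to reach the outer contour",
                    sum(failed), n_retained))
  if (sum(failed) > n_retained / 2)
    stop("more than half of the retained normals failed to reach the outer contour")
  good <- dist[!excl & !failed]
  structure(list(
    samples = data.frame(x_um = pts[, 1], y_um = pts[, 2], theta_deg = ang,
                         distance_um = dist, excluded = excl, failed = failed),
    mean_um = mean(good),
    sd_um = if (length(good) > 1) sd(good) else 0,
    n = length(good),
    n_excluded = sum(excl),
    n_failed = sum(failed),
    exclusion_arcs = exclusion_arcs
  ), class = "thickness_measurement")
}

#' @export
print.thickness_measurement <- function(x, ...) {
  cat(sprintf(
    "<thickness_measurement> mean %.3f um, sd %.3f um, n = %d (%d excluded, %d failed)\n",
    x$mean_um, x$sd_um, x$n, x$n_excluded, x$n_failed))
  invisible(x)
}
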