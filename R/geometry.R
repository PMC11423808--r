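#' Compute the marrow-cavity z-axis
#'
#' The axis is the line through the area centroids of the marrow region in the
#' first (most proximal) and last (most distal) slices. Per-slice centroids are
#' also returned for diagnostics (they are not used as reference points).
#'
#' @param marrow a [mask_volume()] with role `"marrow"`.
#' @return list of class `marrow_axis` with `endpoint_proximal`,
#'   `endpoint_distal` (3D points, micrometres, `(x, y, z)`) and
#'   `per_slice_centers` (data frame `z_um`, `x_um`, `y_um`; `NA` where the
#'   marrow is absent).
#' @export
compute_marrow_axis <- function(marrow) {
  stopifnot(inherits(marrow, "mask_volume"))
  v <- marrow$voxel_size_um
  dims <- dim(marrow$values)
  nz <- dims[3]
  centers <- matrix(NA_real_, nz, 2)
  for (k in seq_len(nz)) {
    idx <- which(marrow$values[, , k], arr.ind = TRUE)
    if (nrow(idx) > 0) {
      centers[k, ] <- c(mean(idx[, 2] - 1) * v, mean(idx[, 1] - 1) * v)  # (x, y)
    }
  }
  if (anyNA(centers[1, ]) || anyNA(centers[nz, ]))
    stop("axis undefined: marrow absent in an end slice")
  structure(list(
    endpoint_proximal = c(centers[1, ], 0),
    endpoint_distal = c(centers[nz, ], (nz - 1) * v),
    per_slice_centers = data.frame(
      z_um = (seq_len(nz) - 1) * v, x_um = centers[, 1], y_um = centers[, 2])
  ), class = "marrow_axis")
}

#' Point on the marrow axis at a given z-level
#'
#' @param axis a [compute_marrow_axis()] result.
#' @param z_um height(s) in micrometres.
#' @return matrix with columns `x_um`, `y_um`.
#' @export
axis_point_at_z <- function(axis, z_um) {
  p0 <- axis$endpoint_proximal
  p1 <- axis$endpoint_distal
  dz <- p1[3] - p0[3]
  if (dz <= 0) stop("axis has no z-extent")
  f <- (z_um - p0[3]) / dz
  cbind(x_um = p0[1] + f * (p1[1] - p0[1]),
        y_um = p0[2] + f * (p1[2] - p0[2]))
}

#' Canal diameter from the canal-perpendicular cross-section
#'
#' The component's tube axis is taken from the eigenvectors of the second
#' central moments of its voxel coordinates. All component voxels are then
#' projected onto the plane through the centroid perpendicular to that axis --
#' for a straight tube this projection is exactly the cross-section, and using
#' every voxel (rather than a thin slab) suppresses voxelization noise. The
#' moment-matched ellipse of the projected point set gives the minor-axis
#' length: for a uniform elliptical region the moment-matched semi-axes are
#' twice the coordinate standard deviations along the principal directions,
#' with the per-voxel cell variance (voxel^2 / 12) added to the coordinate
#' variance of the voxel centres. Components below 4 voxels, or projections
#' below 3 distinct points, fall back to the equivalent-circle diameter of the
#' largest single-slice section and are flagged.
#'
#' For stubby components whose length through the wall is comparable to their
#' width (the nutrient foramen), the largest-variance eigenvector no longer
#' tracks the tube axis; an optional `axis_hint` (for a trans-cortical void,
#' the outward radial direction at its centroid) selects the eigenvector most
#' aligned with the expected piercing direction instead.
#'
#' @param coords_um numeric matrix of voxel-centre coordinates (columns
#'   `x, y, z`, micrometres).
#' @param voxel_size_um voxel edge length, micrometres.
#' @param axis_hint optional 3-vector; the principal direction with the
#'   largest absolute cosine to it is used as the tube axis.
#' @return list with `diameter_um` and logical `flagged`.
#' @export
canal_diameter <- function(coords_um, voxel_size_um, axis_hint = NULL) {
  coords_um <- as.matrix(coords_um)
  n <- nrow(coords_um)
  if (n < 4) return(.diameter_fallback(coords_um, voxel_size_um))
  ctr <- colMeans(coords_um)
  cc <- sweep(coords_um, 2, ctr)
  ev <- eigen(crossprod(cc) / n, symmetric = TRUE)
  pick <- if (is.null(axis_hint)) 1L else
    which.max(abs(as.vector(axis_hint %*% ev$vectors)))
  basis <- ev$vectors[, -pick, drop = FALSE]
  plane <- cc %*% basis
  if (nrow(unique(round(plane / voxel_size_um))) < 3)
    return(.diameter_fallback(coords_um, voxel_size_um))
  pc <- sweep(plane, 2, colMeans(plane))
  m2 <- crossprod(pc) / nrow(pc) + diag(voxel_size_um^2 / 12, 2)
  lam <- eigen(m2, symmetric = TRUE, only.values = TRUE)$values
  minor <- 4 * sqrt(max(min(lam), 0))
  if (minor <= 0) return(.diameter_fallback(coords_um, voxel_size_um))
  list(diameter_um = minor, flagged = FALSE)
}

.diameter_fallback <- function(coords_um, voxel_size_um) {
  z <- round(coords_um[, 3] / voxel_size_um)
  n_max <- max(tabulate(as.integer(z - min(z) + 1)))
  list(diameter_um = 2 * sqrt(n_max / pi) * voxel_size_um, flagged = TRUE)
}

# coordinates (um) of the voxels of one labeled component
component_coords <- function(voids, id) {
  dims <- dim(voids$labels)
  w <- which(voids$labels == id)
  if (!length(w)) stop("no component with id ", id)
  k <- (w - 1L) %/% (dims[1] * dims[2])
  rem <- (w - 1L) %% (dims[1] * dims[2])
  cbind(x = (rem %/% dims[1]) * voids$voxel_size_um,
        y = (rem %% dims[1]) * voids$voxel_size_um,
        z = k * voids$voxel_size_um)
}

#' Add per-component diameters to a void-component set
#'
#' @param voids a [extract_void_components()] result.
#' @param only_ids optional ids to measure; others get `NA` (saves work when
#'   only trans-cortical components need diameters).
#' @param axis optional [compute_marrow_axis()] result; when given, each
#'   trans-cortical component is measured with the outward radial direction at
#'   its centroid as the tube-axis hint (see [canal_diameter()]).
#' @return the component data frame with `diameter_um` and `diam_flagged`.
#' @export
annotate_diameters <- function(voids, only_ids = NULL, axis = NULL) {
  df <- voids$components
  df$diameter_um <- NA_real_
  df$diam_flagged <- NA
  ids <- only_ids %||% df$id
  for (id in ids) {
    row <- which(df$id == id)
    hint <- NULL
    if (!is.null(axis) && df$touches_periosteum[row] && df$touches_endosteum[row]) {
      ref <- axis_point_at_z(axis, df$z_um[row])
      hint <- c(df$x_um[row] - ref[1], df$y_um[row] - ref[2], 0)
      hint <- hint / sqrt(sum(hint^2))
    }
    res <- canal_diameter(component_coords(voids, id), voids$voxel_size_um, hint)
    df$diameter_um[row] <- res$diameter_um
    df$diam_flagged[row] <- res$flagged
  }
  df
}

#' Polar orientation of a canal about the marrow axis
#'
#' The reference point is the point on the two-point z-axis line at the
#' canal's z-level. Theta is the signed angle in the slice plane between the
#' anterior direction and the vector from the reference point to the canal
#' centroid, in `(-180, 180]`, positive turning towards `+y`. A canal is
#' posterior when `|theta| > 90` (the boundary itself counts as anterior).
#'
#' @param centroid_um 3D point or n x 3 matrix (`x, y, z`, micrometres).
#' @param axis a [compute_marrow_axis()] result.
#' @param anterior_direction unit 2-vector; default `+x`.
#' @return numeric vector of angles in degrees.
#' @export
canal_orientation <- function(centroid_um, axis, anterior_direction = c(1, 0)) {
  p <- if (is.matrix(centroid_um)) centroid_um else matrix(centroid_um, 1)
  ref <- axis_point_at_z(axis, p[, 3])
  vx <- p[, 1] - ref[, 1]
  vy <- p[, 2] - ref[, 2]
  if (any(vx^2 + vy^2 < 1e-12))
    stop("undefined orientation: centroid lies on the axis")
  a <- anterior_direction / sqrt(sum(anterior_direction^2))
  # components along anterior and its +90-degree rotation (towards +y)
  u <- vx * a[1] + vy * a[2]
  w <- -vx * a[2] + vy * a[1]
  theta <- atan2(w, u) * 180 / pi
  # atan2 returns (-180, 180]; map -180 to 180 for the convention
  theta[theta <= -180] <- 180
  unname(theta)
}

#' Assemble per-canal records from voids, axis and configuration
#'
#' Computes diameters for components above the lacuna volume cutoff, classifies
#' every component, and attaches polar orientation and the posterior flag.
#'
#' @param voids a [extract_void_components()] result.
#' @param axis a [compute_marrow_axis()] result.
#' @param config a [run_config()].
#' @return data frame with columns `id`, `class`, `x_um`, `y_um`, `z_um`,
#'   `volume_um3`, `diameter_um`, `theta_deg`, `is_posterior`,
#'   `touches_periosteum`, `touches_endosteum`, `diam_flagged`.
#' @export
build_canal_records <- function(voids, axis, config = run_config()) {
  df <- voids$components
  if (nrow(df) == 0) {
    df <- cbind(df, data.frame(diameter_um = double(), diam_flagged = logical(),
                               class = character(), theta_deg = double(),
                               is_posterior = logical()))
    return(df[, c("id", "class", "x_um", "y_um", "z_um", "volume_um3",
                  "diameter_um", "theta_deg", "is_posterior",
                  "touches_periosteum", "touches_endosteum", "diam_flagged")])
  }
  measure <- df$id[df$volume_um3 > config$lacuna_max_volume_um3]
  df <- annotate_diameters(voids, only_ids = measure, axis = axis)
  df <- classify_components(df, config$lacuna_max_volume_um3,
                            config$foramen_min_diameter_um)
  df$theta_deg <- canal_orientation(as.matrix(df[, c("x_um", "y_um", "z_um")]),
                                    axis, config$anterior_direction)
  df$is_posterior <- abs(df$theta_deg) > 90
  df[, c("id", "class", "x_um", "y_um", "z_um", "volume_um3", "diameter_um",
         "theta_deg", "is_posterior", "touches_periosteum", "touches_endosteum",
         "diam_flagged")]
}

#' Endosteal surface area of an angular sector
#'
#' For each slice, rays are cast from the axis point and the endosteal radius
#' is the first marrow-to-wall crossing (sub-voxel, by linear interpolation).
#' The polar arc length over the sector is integrated per slice and multiplied
#' by the slice thickness, then summed over slices.
#'
#' @param marrow a [mask_volume()] with role `"marrow"`.
#' @param axis a [compute_marrow_axis()] result.
#' @param sector_deg angular window `c(lo, hi)` in degrees; `lo > hi` wraps
#'   through 180.
#' The per-slice radius profile is smoothed with a short circular moving
#' average before differentiation: the raw profile carries half-voxel
#' digitization steps whose finite-difference derivative would otherwise
#' inflate the arc length by several percent.
#'
#' @param n_theta angular sampling of the full circle.
#' @return area in mm^2.
#' @export
endosteal_sector_area <- function(marrow, axis, sector_deg = c(-180, 180),
                                  n_theta = 720L) {
  v <- marrow$voxel_size_um
  dims <- dim(marrow$values)
  dtheta <- 360 / n_theta
  theta <- seq(-180 + dtheta / 2, 180 - dtheta / 2, by = dtheta)
  keep <- .theta_in_sector(theta, sector_deg)
  rmax <- max(dims[1:2]) * v
  total <- 0
  for (k in seq_len(dims[3])) {
    ctr <- axis_point_at_z(axis, (k - 1) * v)
    r <- .first_crossing_radii(marrow$values[, , k] * 1.0, ctr, theta, v, rmax,
                               falling = TRUE)
    if (anyNA(r)) next
    r <- .smooth_circular(r, max(3L, round(n_theta / 60)))
    dr <- (r[c(2:n_theta, 1)] - r[c(n_theta, 1:(n_theta - 1))]) / (2 * dtheta * pi / 180)
    seg <- sqrt(r^2 + dr^2) * (dtheta * pi / 180)
    total <- total + sum(seg[keep]) * v
  }
  total / 1e6
}

# circular moving average with an odd window
.smooth_circular <- function(x, w) {
  if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  xx <- c(x[(n - h + 1L):n], x, x[1:h])
  as.vector(stats::filter(xx, rep(1 / w, w), sides = 2))[(h + 1L):(h + n)]
}

.theta_in_sector <- function(theta, sector_deg) {
  lo <- sector_deg[1]; hi <- sector_deg[2]
  if (lo <= hi) theta >= lo & theta <= hi else theta >= lo | theta <= hi
}

#' Canal density over an angular sector
#'
#' Counts `class == "canal"` records whose orientation falls in the sector and
#' divides by the endocortical (endosteal) surface area of that sector. Supply
#' `area_mm2` directly, or `marrow` and `axis` to have it computed by
#' [endosteal_sector_area()].
#'
#' @param records canal records from [build_canal_records()].
#' @param sector_deg angular window `c(lo, hi)` in degrees (wraps when
#'   `lo > hi`).
#' @param area_mm2 reference area; computed from `marrow`/`axis` when `NULL`.
#' @param marrow,axis used when `area_mm2` is `NULL`.
#' @param label region label carried into the result.
#' @return list of class `density_result` with `label`, `canal_count`,
#'   `reference_area_mm2`, `density_per_mm2`.
#' @export
canal_density <- function(records, sector_deg = c(-180, 180), area_mm2 = NULL,
                          marrow = NULL, axis = NULL, label = "whole") {
  if (is.null(area_mm2)) {
    if (is.null(marrow) || is.null(axis))
      stop("supply area_mm2 or both marrow and axis")
    area_mm2 <- endosteal_sector_area(marrow, axis, sector_deg)
  }
  if (!is.finite(area_mm2) || area_mm2 <= 0) stop("reference area must be positive")
  canals <- records[records$class == "canal", , drop = FALSE]
  count <- sum(.theta_in_sector(canals$theta_deg, sector_deg))
  structure(list(label = label, canal_count = count,
                 reference_area_mm2 = area_mm2,
                 density_per_mm2 = count / area_mm2),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("<density_result:%s> %d canals / %.5f mm^2 = %.2f per mm^2\n",
              x$label, x$canal_count, x$reference_area_mm2, x$density_per_mm2))
  invisible(x)
}

#' Fraction of canals in the posterior half
#'
#' Posterior means absolute polar angle greater than 90 degrees from the
#' anterior direction.
#'
#' @param records canal records; only `class == "canal"` rows are counted.
#' @return list with `fraction`, `n_posterior`, `n_total`.
#' @export
posterior_fraction <- function(records) {
  canals <- records[records$class == "canal", , drop = FALSE]
  if (nrow(canals) == 0) stop("no canals")
  n_post <- sum(abs(canals$theta_deg) > 90)
  list(fraction = n_post / nrow(canals), n_posterior = n_post,
       n_total = nrow(canals))
}
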