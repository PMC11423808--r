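# Bilinear interpolation of a (y, x) slice at physical points (um).
# Out-of-grid points return `outside`.
.bilinear_slice <- function(slice, x_um, y_um, voxel, outside = 0) {
  fx <- x_um / voxel + 1
  fy <- y_um / voxel + 1
  ny <- nrow(slice); nx <- ncol(slice)
  x0 <- floor(fx); y0 <- floor(fy)
  wx <- fx - x0; wy <- fy - y0
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  out <- rep(outside, length(fx))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; wxo <- wx[ok]; wyo <- wy[ok]
  i00 <- y0 + (x0 - 1) * ny
  v00 <- slice[i00]; v01 <- slice[i00 + ny]
  v10 <- slice[i00 + 1]; v11 <- slice[i00 + ny + 1]
  out[ok] <- v00 * (1 - wxo) * (1 - wyo) + v01 * wxo * (1 - wyo) +
    v10 * (1 - wxo) * wyo + v11 * wxo * wyo
  out
}

# Radius of the first 0.5-crossing of an interpolated binary slice along rays
# from `center_um` at angles `theta_deg`. `falling = FALSE` finds the first
# rise to >= 0.5 (e.g. first bone contact); `falling = TRUE` the first drop
# below 0.5 (e.g. marrow boundary). Sub-voxel refinement by linear
# interpolation between the bracketing samples. NA where no crossing occurs
# within `rmax_um`.
.first_crossing_radii <- function(slice, center_um, theta_deg, voxel, rmax_um,
                                  falling = FALSE) {
  step <- voxel / 2
  radii <- seq(step, rmax_um, by = step)
  nt <- length(theta_deg)
  nr <- length(radii)
  th <- theta_deg * pi / 180
  px <- center_um[1] + outer(radii, cos(th))
  py <- center_um[2] + outer(radii, sin(th))
  vals <- matrix(.bilinear_slice(slice, as.vector(px), as.vector(py), voxel,
                                 outside = if (falling) 0 else 0), nr, nt)
  hit <- if (falling) vals < 0.5 else vals >= 0.5
  # first TRUE per column
  first <- rep(NA_integer_, nt)
  w <- which(hit)
  if (length(w)) {
    rr <- ((w - 1L) %% nr) + 1L
    cc <- ((w - 1L) %/% nr) + 1L
    ord <- rev(seq_along(w))
    first[cc[ord]] <- rr[ord]
  }
  out <- rep(NA_real_, nt)
  ok <- !is.na(first)
  if (any(ok)) {
    f <- first[ok]
    col <- which(ok)
    v1 <- vals[cbind(f, col)]
    v0 <- ifelse(f > 1, vals[cbind(pmax(f - 1, 1), col)], if (falling) 1 else 0)
    r1 <- radii[f]
    r0 <- ifelse(f > 1, radii[f - 1], 0)
    dv <- v1 - v0
    frac <- ifelse(abs(dv) > 1e-12, (0.5 - v0) / dv, 0)
    out[col] <- r0 + pmin(pmax(frac, 0), 1) * (r1 - r0)
  }
  out
}

.panoramic_image <- function(values, depth_um, gap, theta_deg, z_um, mode,
                             views_generated = NA_integer_, voxel_size_um) {
  structure(list(values = values, depth_um = depth_um, gap = gap,
                 theta_deg = theta_deg, z_um = z_um, mode = mode,
                 views_generated = views_generated,
                 voxel_size_um = voxel_size_um),
            class = "panoramic_image")
}

#' @export
print.panoramic_image <- function(x, ...) {
  cat(sprintf("<panoramic_image:%s> %d x %d (z x theta), %s gaps%s\n",
              x$mode, nrow(x$values), ncol(x$values), sum(x$gap),
              if (!is.na(x$views_generated))
                sprintf(", %d views", x$views_generated) else ""))
  invisible(x)
}

# shared ray-cast unwrapping over a theta grid
.unwrap_grid <- function(volume, bone_mask, axis, theta_deg, z_idx) {
  v <- volume$voxel_size_um
  dims <- dim(volume$values)
  rmax <- max(dims[1:2]) * v
  nz <- length(z_idx)
  nt <- length(theta_deg)
  depth <- matrix(NA_real_, nz, nt)
  surf <- matrix(NA_real_, nz, nt)
  for (i in seq_len(nz)) {
    k <- z_idx[i]
    ctr <- axis_point_at_z(axis, (k - 1) * v)
    bslice <- bone_mask$values[, , k] * 1.0
    r <- .first_crossing_radii(bslice, ctr, theta_deg, v, rmax, falling = FALSE)
    depth[i, ] <- r
    ok <- !is.na(r)
    if (any(ok)) {
      th <- theta_deg[ok] * pi / 180
      surf[i, ok] <- .bilinear_slice(volume$values[, , k],
                                     ctr[1] + r[ok] * cos(th),
                                     ctr[2] + r[ok] * sin(th), v,
                                     outside = NA_real_)
    }
  }
  list(depth = depth, surf = surf)
}

#' Unwrap the endocortical surface by direct (theta, z) resampling
#'
#' For each (theta, z) sample a ray is cast outward from the marrow-axis point
#' at that z-level, perpendicular to the axis; the radius of first bone contact
#' gives the depth map and the volume intensity at the contact point gives the
#' surface image. Rays exiting the grid without bone contact (as through a
#' canal opening) yield gap pixels, not errors. The horizontal axis is exactly
#' linear in theta over `[-180, 180)`.
#'
#' @param volume a [voxel_volume()].
#' @param bone_mask a [mask_volume()] with role `"bone"`.
#' @param axis a [compute_marrow_axis()] result.
#' @param theta_samples angular samples over the full circle (>= 8).
#' @param z_samples slice indices to render; default all slices.
#' @return A `panoramic_image` (fields `values`, `depth_um`, `gap`,
#'   `theta_deg`, `z_um`, `mode = "resample"`).
#' @export
unwrap_resample <- function(volume, bone_mask, axis, theta_samples = 360L,
                            z_samples = NULL) {
  if (theta_samples < 8L) stop("theta_samples must be at least 8")
  z_idx <- z_samples %||% seq_len(dim(volume$values)[3])
  if (length(z_idx) < 8L && is.null(z_samples)) stop("volume too shallow")
  dtheta <- 360 / theta_samples
  theta <- seq(-180, 180 - dtheta, by = dtheta)
  g <- .unwrap_grid(volume, bone_mask, axis, theta, z_idx)
  .panoramic_image(g$surf, g$depth, is.na(g$depth), theta,
                   (z_idx - 1) * volume$voxel_size_um, "resample",
                   voxel_size_um = volume$voxel_size_um)
}

#' Unwrap the endocortical surface by rotate-and-stitch
#'
#' Emulates the rotate/crop/stitch procedure: the bone is viewed from its
#' central longitudinal axis at successive rotation steps; each rendered view
#' is cropped to its central `crop_fraction` and the crops are stitched
#' left-to-right in angle order. With a 20-degree step a full revolution
#' produces 18 views. Rays are cylindrical (perpendicular to the z-axis), so
#' each view's horizontal axis is linear in theta and the stitched panorama
#' spans `[-180, 180)`.
#'
#' @param volume a [voxel_volume()].
#' @param bone_mask a [mask_volume()] with role `"bone"`.
#' @param axis a [compute_marrow_axis()] result.
#' @param theta_step_deg rotation step; must divide 360 evenly.
#' @param crop_fraction central fraction of each view retained (default 1/4,
#'   so each view is rendered over `theta_step / crop_fraction` degrees).
#' @param samples_per_deg horizontal resolution of each view.
#' @return A `panoramic_image` with `mode = "stitch"` and `views_generated`.
#' @export
unwrap_stitch <- function(volume, bone_mask, axis, theta_step_deg = 20,
                          crop_fraction = 0.25, samples_per_deg = 1) {
  if (theta_step_deg <= 0 || 360 %% theta_step_deg != 0)
    stop("theta_step_deg must divide 360 evenly")
  n_views <- as.integer(360 / theta_step_deg)
  z_idx <- seq_len(dim(volume$values)[3])
  nt_keep <- max(1L, round(theta_step_deg * samples_per_deg))
  view_width <- min(360, theta_step_deg / crop_fraction)
  nt_view <- max(nt_keep, round(view_width * samples_per_deg))
  strips_v <- vector("list", n_views)
  strips_d <- vector("list", n_views)
  theta_all <- numeric(0)
  for (vw in seq_len(n_views)) {
    center <- -180 + (vw - 0.5) * theta_step_deg
    th_view <- center + seq(-view_width / 2, view_width / 2, length.out = nt_view)
    keep <- seq.int(from = (nt_view - nt_keep) %/% 2 + 1L, length.out = nt_keep)
    th_keep <- th_view[keep]
    g <- .unwrap_grid(volume, bone_mask, axis, th_keep, z_idx)
    strips_v[[vw]] <- g$surf
    strips_d[[vw]] <- g$depth
    theta_all <- c(theta_all, th_keep)
  }
  vals <- do.call(cbind, strips_v)
  depth <- do.call(cbind, strips_d)
  .panoramic_image(vals, depth, is.na(depth), theta_all,
                   (z_idx - 1) * volume$voxel_size_um, "stitch",
                   views_generated = n_views,
                   voxel_size_um = volume$voxel_size_um)
}

#' Write a panoramic image as 16-bit TIFF with a JSON axis sidecar
#'
#' Gap pixels are written as 0; the sidecar records the theta/z calibration,
#' the mode and the view count.
#'
#' @param pano a `panoramic_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_panorama <- function(pano, path) {
  vals <- pano$values
  vals[is.na(vals)] <- 0
  vals <- pmin(pmax(round(vals), 0), 65535) / 65535
  tiff::writeTIFF(vals, path, bits.per.sample = 16L)
  jsonlite::write_json(list(
    mode = pano$mode, views_generated = pano$views_generated,
    theta_deg = pano$theta_deg, z_um = pano$z_um
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
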