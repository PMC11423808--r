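#' Phantom specification for a synthetic long-bone cortex
#'
#' Describes a hollow, elliptic-cylindrical cortical shell carrying straight
#' trans-cortical canals, ellipsoidal osteocyte lacunae and (optionally) one
#' large nutrient foramen, plus the acquisition model (partial-volume blur and
#' additive Gaussian noise). The defaults emulate a nano-CT scan of a developing
#' mouse fibula diaphysis at the instrument's native sampling of 1.27 um/voxel:
#' a thin elliptic cortex around a single marrow cavity, canals of 15-24 um
#' diameter concentrated in the anterior (endosteal-forming) half.
#'
#' @param grid_shape integer vector `(nx, ny, nz)` of voxel counts.
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @param outer_radii_um,inner_radii_um semi-axes `(x, y)` of the periosteal and
#'   endosteal surfaces of the elliptic shell, in micrometres. Inner must be
#'   strictly less than outer on both axes.
#' @param axis_tilt_um_per_slice lateral drift `(x, y)` of the shell centre per
#'   z-slice, in micrometres (models a bone not perfectly aligned with the
#'   scanner axis).
#' @param canal_specs data frame with columns `theta_deg` (polar angle from the
#'   anterior `+x` direction, in `(-180, 180]`), `z_frac` (fractional height in
#'   `(0, 1)`), `diameter_um` and `inclination_deg` (tilt of the canal axis out
#'   of the slice plane).
#' @param lacuna_count number of ellipsoidal lacunae carved fully inside the
#'   cortical wall.
#' @param lacuna_semiaxes_um semi-axes of each lacuna, micrometres.
#' @param foramen optional named vector `c(theta_deg, z_frac, diameter_um)` for
#'   the nutrient foramen (a wide trans-cortical channel).
#' @param bone_intensity,background_intensity grey values assigned to bone and
#'   to marrow/background before blur and noise.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param blur_sigma_um Gaussian blur applied before noise (partial-volume
#'   model); default half a voxel.
#' @param seed integer seed; every stochastic element of the phantom (lacuna
#'   placement, noise) derives from it. Required.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(256L, 256L, 160L),
                         voxel_size_um = 1.27,
                         outer_radii_um = c(130, 105),
                         inner_radii_um = c(75, 60),
                         axis_tilt_um_per_slice = c(0, 0),
                         canal_specs = default_canal_specs(),
                         lacuna_count = 30L,
                         lacuna_semiaxes_um = c(4, 2.5, 2.5),
                         foramen = NULL,
                         bone_intensity = 200,
                         background_intensity = 50,
                         noise_sd = 8,
                         blur_sigma_um = 0.5 * voxel_size_um,
                         seed) {
  if (missing(seed)) stop("phantom_spec requires an explicit seed")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three voxel counts >= 8")
  if (voxel_size_um <= 0) stop("voxel_size_um must be positive")
  if (length(outer_radii_um) != 2L || length(inner_radii_um) != 2L)
    stop("shell radii must be (x, y) pairs")
  if (any(inner_radii_um >= outer_radii_um))
    stop("inner radii must be strictly less than outer radii on both semi-axes")
  if (any(inner_radii_um <= 0)) stop("inner radii must be positive")

  canal_specs <- as.data.frame(canal_specs)
  if (nrow(canal_specs) > 0) {
    need <- c("theta_deg", "z_frac", "diameter_um")
    if (!all(need %in% names(canal_specs)))
      stop("canal_specs needs columns theta_deg, z_frac, diameter_um")
    if (is.null(canal_specs$inclination_deg)) canal_specs$inclination_deg <- 0
    if (any(canal_specs$theta_deg <= -180 | canal_specs$theta_deg > 180))
      stop("canal theta_deg must lie in (-180, 180]")
    if (any(canal_specs$z_frac <= 0 | canal_specs$z_frac >= 1))
      stop("canal z_frac must lie in (0, 1)")
    if (any(canal_specs$diameter_um < 2 * voxel_size_um))
      stop("every canal diameter must be at least 2 voxels")
  }
  if (!is.null(foramen)) {
    foramen <- as.list(foramen)
    if (!all(c("theta_deg", "z_frac", "diameter_um") %in% names(foramen)))
      stop("foramen needs theta_deg, z_frac, diameter_um")
    if (nrow(canal_specs) > 0 && any(canal_specs$diameter_um >= foramen$diameter_um))
      stop("every canal diameter must be smaller than the foramen diameter")
  }
  if (lacuna_count < 0) stop("lacuna_count must be >= 0")
  if (noise_sd < 0 || blur_sigma_um < 0) stop("noise_sd and blur_sigma_um must be >= 0")

  structure(list(
    grid_shape = grid_shape, voxel_size_um = voxel_size_um,
    outer_radii_um = outer_radii_um, inner_radii_um = inner_radii_um,
    axis_tilt_um_per_slice = axis_tilt_um_per_slice,
    canal_specs = canal_specs, lacuna_count = as.integer(lacuna_count),
    lacuna_semiaxes_um = lacuna_semiaxes_um, foramen = foramen,
    bone_intensity = bone_intensity, background_intensity = background_intensity,
    noise_sd = noise_sd, blur_sigma_um = blur_sigma_um,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Default canal layout: a control-like fibula
#'
#' Twelve trans-cortical canals, eleven in the anterior half (wider,
#' endosteal-forming cortex) and one posterior, mirroring the control-limb
#' pattern in which only a small fraction of canals sits at absolute polar
#' angles beyond 90 degrees.
#'
#' @return data frame usable as `canal_specs` in [phantom_spec()].
#' @export
default_canal_specs <- function() {
  data.frame(
    theta_deg = c(-75, -52, -30, -12, 4, 18, 33, 49, 62, 78, 86, 150),
    z_frac = c(0.22, 0.64, 0.41, 0.77, 0.30, 0.55, 0.20, 0.70, 0.45, 0.60, 0.33, 0.50),
    diameter_um = c(24, 22, 25, 23, 24, 26, 22, 24, 23, 25, 24, 15),
    inclination_deg = c(5, -8, 0, 10, -5, 3, 0, -10, 6, -3, 8, 0)
  )
}

# ellipse radius at polar angle theta (radians) for semi-axes (a, b)
.ellipse_radius <- function(theta, a, b) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# squared distance from points (n x 3) to segment P0 + t*d, t in [0, tmax]
.seg_dist2 <- function(px, py, pz, p0, d, tmax) {
  vx <- px - p0[1]; vy <- py - p0[2]; vz <- pz - p0[3]
  t <- pmin(pmax(vx * d[1] + vy * d[2] + vz * d[3], 0), tmax)
  (vx - t * d[1])^2 + (vy - t * d[2])^2 + (vz - t * d[3])^2
}

# carve a tube (canal/foramen) into the logical void array; returns modified array
.carve_tube <- function(void, spec, theta_deg, z_frac, diameter_um, inclination_deg) {
  v <- spec$voxel_size_um
  d <- dim(void)  # (ny, nx, nz)
  th <- theta_deg * pi / 180
  inc <- inclination_deg * pi / 180
  z0 <- z_frac * (d[3] - 1) * v
  ctr <- .shell_center(spec, z0)
  p0 <- c(ctr[1], ctr[2], z0)
  dir <- c(cos(th) * cos(inc), sin(th) * cos(inc), sin(inc))
  tmax <- 2.2 * max(spec$outer_radii_um) / max(cos(inc), 0.5)
  r <- diameter_um / 2
  p1 <- p0 + tmax * dir
  pad <- r + 2 * v
  xr <- .um_range_to_idx(c(min(p0[1], p1[1]) - pad, max(p0[1], p1[1]) + pad), v, d[2])
  yr <- .um_range_to_idx(c(min(p0[2], p1[2]) - pad, max(p0[2], p1[2]) + pad), v, d[1])
  zr <- .um_range_to_idx(c(min(p0[3], p1[3]) - pad, max(p0[3], p1[3]) + pad), v, d[3])
  if (any(vapply(list(xr, yr, zr), length, 1L) == 0)) return(void)
  xs <- .idx_to_um(xr, v); ys <- .idx_to_um(yr, v); zs <- .idx_to_um(zr, v)
  ny <- length(yr); nx <- length(xr); nz <- length(zr)
  py <- rep(ys, times = nx * nz)
  px <- rep(rep(xs, each = ny), times = nz)
  pz <- rep(zs, each = ny * nx)
  hit <- .seg_dist2(px, py, pz, p0, dir, tmax) <= r^2
  sub <- void[yr, xr, zr, drop = FALSE]
  void[yr, xr, zr] <- sub | array(hit, dim = c(ny, nx, nz))
  void
}

.um_range_to_idx <- function(range_um, voxel, n) {
  lo <- max(1L, floor(range_um[1] / voxel) + 1L)
  hi <- min(n, ceiling(range_um[2] / voxel) + 1L)
  if (lo > hi) integer(0) else lo:hi
}

# shell centre (x_um, y_um) at height z_um (possibly fractional slice)
.shell_center <- function(spec, z_um) {
  d <- spec$grid_shape  # (nx, ny, nz)
  v <- spec$voxel_size_um
  base <- c((d[1] - 1) / 2, (d[2] - 1) / 2) * v
  base + spec$axis_tilt_um_per_slice * (z_um / v)
}

#' Generate a synthetic cortical-bone volume with ground truth
#'
#' Rasterizes the shell of a [phantom_spec()], carves the canals, lacunae and
#' nutrient foramen as voids (carving is masking: a voxel is void if any void
#' structure covers it, so structure order is irrelevant), then applies the
#' partial-volume blur and additive Gaussian noise. Identical seeds give
#' bit-identical volumes. Canals are straight tubes running from beyond the
#' periosteal surface through the marrow cavity, so every canal is
#' trans-cortical by construction; lacunae are rejection-sampled to sit fully
#' inside the wall, clear of both surfaces and of every tube.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [voxel_volume()]) and `truth`, a
#'   `phantom_truth` object: `$canals` (id, theta_deg, z_um, diameter_um,
#'   inclination_deg, is_foramen), `$lacunae` (centroids and semi-axes),
#'   `$shell` (geometry echo) and `$anterior_direction` (unit 2-vector).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  v <- spec$voxel_size_um
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  dims <- c(ny, nx, nz)
  xs <- .idx_to_um(seq_len(nx), v)
  ys <- .idx_to_um(seq_len(ny), v)

  bone <- array(FALSE, dims)
  for (k in seq_len(nz)) {
    ctr <- .shell_center(spec, (k - 1) * v)
    X <- matrix(xs - ctr[1], ny, nx, byrow = TRUE)
    Y <- matrix(ys - ctr[2], ny, nx)
    q_out <- (X / spec$outer_radii_um[1])^2 + (Y / spec$outer_radii_um[2])^2
    q_in <- (X / spec$inner_radii_um[1])^2 + (Y / spec$inner_radii_um[2])^2
    bone[, , k] <- q_out <= 1 & q_in > 1
  }

  void <- array(FALSE, dims)
  tubes <- spec$canal_specs
  n_canal <- nrow(tubes)
  for (i in seq_len(n_canal)) {
    void <- .carve_tube(void, spec, tubes$theta_deg[i], tubes$z_frac[i],
                        tubes$diameter_um[i], tubes$inclination_deg[i])
  }
  if (!is.null(spec$foramen)) {
    void <- .carve_tube(void, spec, spec$foramen$theta_deg, spec$foramen$z_frac,
                        spec$foramen$diameter_um, 0)
  }

  # tube axes for lacuna clearance checks
  tube_geoms <- list()
  cols <- c("theta_deg", "z_frac", "diameter_um", "inclination_deg")
  all_tubes <- if (n_canal > 0) tubes[, cols] else
    data.frame(theta_deg = double(), z_frac = double(),
               diameter_um = double(), inclination_deg = double())
  if (!is.null(spec$foramen)) {
    all_tubes <- rbind(
      all_tubes,
      data.frame(theta_deg = spec$foramen$theta_deg, z_frac = spec$foramen$z_frac,
                 diameter_um = spec$foramen$diameter_um, inclination_deg = 0)
    )
  }
  for (i in seq_len(nrow(all_tubes))) {
    th <- all_tubes$theta_deg[i] * pi / 180
    inc <- all_tubes$inclination_deg[i] * pi / 180
    z0 <- all_tubes$z_frac[i] * (nz - 1) * v
    ctr <- .shell_center(spec, z0)
    tube_geoms[[i]] <- list(
      p0 = c(ctr, z0),
      dir = c(cos(th) * cos(inc), sin(th) * cos(inc), sin(inc)),
      tmax = 2.2 * max(spec$outer_radii_um) / max(cos(inc), 0.5),
      r = all_tubes$diameter_um[i] / 2
    )
  }

  lac <- data.frame(id = integer(), x_um = double(), y_um = double(),
                    z_um = double(), a_um = double(), b_um = double(), c_um = double())
  noise <- NULL
  run <- function() {
    if (spec$lacuna_count > 0) {
      sa <- spec$lacuna_semiaxes_um
      margin <- 1.6 * max(sa) + v
      zmar <- max(sa) + 2 * v
      height <- (nz - 1) * v
      placed <- 0L
      tries <- 0L
      while (placed < spec$lacuna_count) {
        tries <- tries + 1L
        if (tries > 500L * spec$lacuna_count)
          stop("could not place lacunae clear of surfaces and canals")
        th <- runif(1, -pi, pi)
        zc <- runif(1, zmar, height - zmar)
        ctr <- .shell_center(spec, zc)
        r_in <- .ellipse_radius(th, spec$inner_radii_um[1], spec$inner_radii_um[2])
        r_out <- .ellipse_radius(th, spec$outer_radii_um[1], spec$outer_radii_um[2])
        span <- r_out - r_in - 2 * margin
        if (span <= 0) stop("cortical wall too thin for the requested lacunae")
        rr <- r_in + margin + runif(1) * span
        cen <- c(ctr[1] + rr * cos(th), ctr[2] + rr * sin(th), zc)
        clear <- TRUE
        for (g in tube_geoms) {
          d2 <- .seg_dist2(cen[1], cen[2], cen[3], g$p0, g$dir, g$tmax)
          if (sqrt(d2) <= g$r + max(sa) + 3 * v) { clear <- FALSE; break }
        }
        if (clear && placed > 0L) {
          prev <- as.matrix(lac[seq_len(placed), c("x_um", "y_um", "z_um")])
          d2p <- (prev[, 1] - cen[1])^2 + (prev[, 2] - cen[2])^2 + (prev[, 3] - cen[3])^2
          if (min(d2p) <= (2 * max(sa) + 3 * v)^2) clear <- FALSE
        }
        if (!clear) next
        placed <- placed + 1L
        lac[placed, ] <<- list(placed, cen[1], cen[2], cen[3], sa[1], sa[2], sa[3])
        xr <- .um_range_to_idx(cen[1] + c(-1, 1) * (sa[1] + v), v, nx)
        yr <- .um_range_to_idx(cen[2] + c(-1, 1) * (sa[2] + v), v, ny)
        zr <- .um_range_to_idx(cen[3] + c(-1, 1) * (sa[3] + v), v, nz)
        pxs <- .idx_to_um(xr, v); pys <- .idx_to_um(yr, v); pzs <- .idx_to_um(zr, v)
        nyb <- length(yr); nxb <- length(xr); nzb <- length(zr)
        py <- rep(pys, times = nxb * nzb)
        px <- rep(rep(pxs, each = nyb), times = nzb)
        pz <- rep(pzs, each = nyb * nxb)
        inside <- ((px - cen[1]) / sa[1])^2 + ((py - cen[2]) / sa[2])^2 +
          ((pz - cen[3]) / sa[3])^2 <= 1
        sub <- void[yr, xr, zr, drop = FALSE]
        void[yr, xr, zr] <<- sub | array(inside, dim = c(nyb, nxb, nzb))
      }
    }
    if (spec$noise_sd > 0) noise <<- rnorm(prod(dims), 0, spec$noise_sd)
    invisible(NULL)
  }
  with_seed(spec$seed, run())

  # ambiguity guard: each carved structure must remain its own void component
  void_in_wall <- bone & void
  n_struct <- n_canal + (!is.null(spec$foramen)) + spec$lacuna_count
  if (n_struct > 0) {
    labs <- cpp_label3d(void_in_wall, dims, 26L)
    n_found <- max(labs)
    if (n_found != n_struct)
      stop(sprintf(
        "overlapping void structures: carved %d but found %d connected components; truth would be ambiguous",
        n_struct, n_found))
  }

  vol <- array(spec$background_intensity, dims)
  vol[bone & !void] <- spec$bone_intensity
  if (spec$blur_sigma_um > 0)
    vol <- array(cpp_blur3(vol, dims, spec$blur_sigma_um / v), dims)
  if (!is.null(noise)) vol <- vol + array(noise, dims)

  canals <- data.frame(
    id = seq_len(n_canal + (!is.null(spec$foramen))),
    theta_deg = c(tubes$theta_deg, if (!is.null(spec$foramen)) spec$foramen$theta_deg),
    z_um = c(tubes$z_frac, if (!is.null(spec$foramen)) spec$foramen$z_frac) * (nz - 1) * v,
    diameter_um = c(tubes$diameter_um, if (!is.null(spec$foramen)) spec$foramen$diameter_um),
    inclination_deg = c(tubes$inclination_deg, if (!is.null(spec$foramen)) 0),
    is_foramen = c(rep(FALSE, n_canal), if (!is.null(spec$foramen)) TRUE)
  )

  truth <- structure(list(
    canals = canals,
    lacunae = lac,
    shell = list(outer_radii_um = spec$outer_radii_um,
                 inner_radii_um = spec$inner_radii_um,
                 axis_tilt_um_per_slice = spec$axis_tilt_um_per_slice,
                 grid_shape = spec$grid_shape, voxel_size_um = v),
    anterior_direction = c(1, 0)
  ), class = "phantom_truth")

  list(volume = voxel_volume(vol, v), truth = truth)
}

#' Random well-separated phantom specification
#'
#' Samples `n_canals` canals with prescribed anterior/posterior split, enforcing
#' enough angular or axial separation that no two tubes merge inside the wall
#' (which [generate_phantom()] would reject). Posterior canals are drawn from
#' absolute angles in (92.5, 177.5) degrees and anterior ones from
#' (-87.5, 87.5), keeping every canal at least 2.5 degrees away from the
#' anterior/posterior boundary so truth classifications are unambiguous.
#'
#' @param seed integer seed for both the layout and the phantom.
#' @param n_canals total number of canals.
#' @param n_posterior how many canals fall in the posterior half
#'   (`|theta| > 90` degrees).
#' @param diameter_range_um range canal diameters are drawn from.
#' @param noise_sd,blur_sigma_um acquisition model, passed through.
#' @param lacuna_count passed through.
#' @param foramen passed through.
#' @param grid_shape,voxel_size_um passed through.
#' @inheritParams phantom_spec
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, n_canals = 8L, n_posterior = 1L,
                                diameter_range_um = c(15, 25),
                                noise_sd = 0, blur_sigma_um = 0,
                                lacuna_count = 0L, foramen = NULL,
                                grid_shape = c(170L, 170L, 110L),
                                voxel_size_um = 2,
                                outer_radii_um = c(130, 105),
                                inner_radii_um = c(75, 60)) {
  stopifnot(n_posterior <= n_canals)
  layout <- with_seed(seed, {
    # seed the separation check with the foramen so no canal collides with it
    if (!is.null(foramen)) {
      fo <- as.list(foramen)
      theta <- fo$theta_deg; zf <- fo$z_frac; dia <- fo$diameter_um
      incl <- 0
    } else {
      theta <- numeric(0); zf <- numeric(0); dia <- numeric(0); incl <- numeric(0)
    }
    n_fixed <- length(theta)
    height <- (grid_shape[3] - 1) * voxel_size_um
    tries <- 0L
    while (length(theta) < n_canals + n_fixed) {
      tries <- tries + 1L
      if (tries > 5000L) stop("could not place well-separated canals")
      posterior <- (length(theta) - n_fixed) < n_posterior
      th <- if (posterior) {
        sample(c(-1, 1), 1) * runif(1, 92.5, 177.5)
      } else {
        runif(1, -87.5, 87.5)
      }
      z <- runif(1, 0.18, 0.82)
      d <- runif(1, diameter_range_um[1], diameter_range_um[2])
      # points along the candidate tube axis spanning the cortical wall
      wall_pts <- function(th_deg, z_frac, inc_deg) {
        rr <- seq(min(inner_radii_um) - 12, max(outer_radii_um) + 12, length.out = 24)
        thr <- th_deg * pi / 180
        incr <- inc_deg * pi / 180
        cbind(rr * cos(thr), rr * sin(thr), z_frac * height + rr * tan(incr))
      }
      inc <- runif(1, -12, 12)
      cand <- wall_pts(th, z, inc)
      ok <- TRUE
      for (i in seq_along(theta)) {
        other <- wall_pts(theta[i], zf[i], incl[i])
        d2 <- outer(cand[, 1], other[, 1], "-")^2 +
          outer(cand[, 2], other[, 2], "-")^2 +
          outer(cand[, 3], other[, 3], "-")^2
        clearance <- (d + dia[i]) / 2 + 6 * voxel_size_um
        if (min(d2) < clearance^2) { ok <- FALSE; break }
      }
      if (!ok) next
      theta <- c(theta, th); zf <- c(zf, z); dia <- c(dia, d); incl <- c(incl, inc)
    }
    new <- seq.int(n_fixed + 1L, length.out = n_canals)
    data.frame(theta_deg = theta[new], z_frac = zf[new], diameter_um = dia[new],
               inclination_deg = incl[new])
  })
  phantom_spec(
    grid_shape = grid_shape, voxel_size_um = voxel_size_um,
    outer_radii_um = outer_radii_um, inner_radii_um = inner_radii_um,
    canal_specs = layout, lacuna_count = lacuna_count, foramen = foramen,
    noise_sd = noise_sd, blur_sigma_um = blur_sigma_um, seed = seed
  )
}

#' Generate a matched inner/outer contour pair
#'
#' Builds a closed inner contour from a radius profile and offsets it outward
#' along vertex normals by a thickness profile, producing the paired-edge
#' fixture used to validate the periosteal thickness measurement. Profiles are
#' functions of the polar angle in radians (constants are accepted).
#'
#' @param radius_inner_um scalar radius or function of angle (radians) giving
#'   the inner contour radius in micrometres.
#' @param thickness_profile scalar or nonnegative function of angle (radians),
#'   micrometres.
#' @param n_points number of contour vertices, at least 16.
#' @param exclusion_arc optional numeric `c(lo_deg, hi_deg)` recorded for
#'   downstream masking (e.g. an interosseous-membrane attachment).
#' @return list of class `contour_pair` with data frames `inner` and `outer`
#'   (columns `x_um`, `y_um`) and the recorded `exclusion_arc`.
#' @export
generate_contour_pair <- function(radius_inner_um, thickness_profile,
                                  n_points = 256L, exclusion_arc = NULL) {
  if (n_points < 16L) stop("n_points must be at least 16")
  th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  rfun <- if (is.function(radius_inner_um)) radius_inner_um else function(t) rep(radius_inner_um, length(t))
  tfun <- if (is.function(thickness_profile)) thickness_profile else function(t) rep(thickness_profile, length(t))
  r <- rfun(th)
  tk <- tfun(th)
  if (any(r <= 0)) stop("inner radius profile must be positive")
  if (any(tk < 0)) stop("thickness profile must be nonnegative")
  inner <- cbind(x_um = r * cos(th), y_um = r * sin(th))
  nrm <- .vertex_normals(inner)
  outer <- inner + tk * nrm
  if (.polygon_self_intersects(outer))
    stop("offset contour self-intersects: thickness too large for the local curvature")
  structure(list(
    inner = as.data.frame(inner),
    outer = as.data.frame(outer),
    exclusion_arc = exclusion_arc
  ), class = "contour_pair")
}

# outward unit normals at the vertices of a closed CCW polygon (n x 2)
.vertex_normals <- function(p) {
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  tx <- p[nxt, 1] - p[prv, 1]
  ty <- p[nxt, 2] - p[prv, 2]
  len <- sqrt(tx^2 + ty^2)
  # rotate tangent -90 degrees: outward for counter-clockwise orientation
  cbind(ty / len, -tx / len)
}

# brute-force non-adjacent segment intersection test for a closed polygon
.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), ]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    if (any(.segments_cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2],
                            a[js, 1], a[js, 2], b[js, 1], b[js, 2]))) return(TRUE)
  }
  FALSE
}

# vectorized proper-crossing test of segment (x1,y1)-(x2,y2) vs segments p3-p4
.segments_cross <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  d1 <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
  d2 <- (x2 - x1) * (y4 - y1) - (y2 - y1) * (x4 - x1)
  d3 <- (x4 - x3) * (y1 - y3) - (y4 - y3) * (x1 - x3)
  d4 <- (x4 - x3) * (y2 - y3) - (y4 - y3) * (x2 - x3)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}
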