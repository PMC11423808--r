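test_that("marrow axis of a coaxial shell runs through the grid centre", {
  ph <- generate_phantom(shell_spec(seed = 1, grid = c(90L, 90L, 40L),
                                    outer = c(70, 58), inner = c(44, 34)))
  bone <- threshold_bone(ph$volume, "fixed", 125)
  axis <- compute_marrow_axis(extract_marrow(bone))
  centre <- (90 - 1) / 2 * 2
  expect_equal(axis$endpoint_proximal[1:2], c(centre, centre), tolerance = 0.5,
               ignore_attr = TRUE)
  expect_equal(axis$endpoint_distal[1:2], c(centre, centre), tolerance = 0.5,
               ignore_attr = TRUE)
})

test_that("marrow axis follows a drifting shell centre", {
  voxel <- 2
  ph <- generate_phantom(shell_spec(seed = 2, grid = c(110L, 90L, 40L),
                                    outer = c(60, 50), inner = c(38, 30),
                                    axis_tilt_um_per_slice = c(0.5, 0)))
  bone <- threshold_bone(ph$volume, "fixed", 125)
  marrow <- extract_marrow(bone)
  axis <- compute_marrow_axis(marrow)
  # oracle: brute-force centroids of the end slices
  for (k in c(1, 40)) {
    idx <- which(marrow$values[, , k], arr.ind = TRUE)
    cx <- mean(idx[, 2] - 1) * voxel
    cy <- mean(idx[, 1] - 1) * voxel
    ep <- if (k == 1) axis$endpoint_proximal else axis$endpoint_distal
    expect_equal(ep[1:2], c(cx, cy), tolerance = 0.5 * voxel, ignore_attr = TRUE)
  }
  # total drift across the stack is 0.5 um/slice * 39 slices
  expect_equal(axis$endpoint_distal[1] - axis$endpoint_proximal[1], 0.5 * 39,
               tolerance = 1)
})

test_that("marrow axis requires marrow in both end slices", {
  m <- array(FALSE, dim = c(10, 10, 5))
  m[4:6, 4:6, 2:4] <- TRUE
  expect_error(compute_marrow_axis(mask_volume(m, 1, "marrow")),
               "axis undefined")
})

test_that("canal diameter recovers analytic cylinders at any inclination", {
  # axis-aligned tube: voxels within radius 5 of the z-axis line
  g <- expand.grid(x = -8:8, y = -8:8, z = 0:40)
  tube <- g[g$x^2 + g$y^2 <= 25, ]
  res <- canal_diameter(as.matrix(tube), 1)
  expect_false(res$flagged)
  expect_equal(res$diameter_um, 10, tolerance = 1)
  # the same tube inclined 45 degrees to the slice plane
  g2 <- expand.grid(x = -10:40, y = -8:8, z = -10:40)
  d <- c(1, 0, 1) / sqrt(2)
  t <- g2$x * d[1] + g2$z * d[3]
  r2 <- (g2$x - t * d[1])^2 + g2$y^2 + (g2$z - t * d[3])^2
  tube2 <- g2[r2 <= 25 & t >= 0 & t <= 40, ]
  res2 <- canal_diameter(as.matrix(tube2), 1)
  expect_false(res2$flagged)
  expect_equal(res2$diameter_um, 10, tolerance = 1)
})

test_that("degenerate components fall back to a flagged slice-based diameter", {
  res <- canal_diameter(matrix(c(0, 0, 0), 1), 1)
  expect_true(res$flagged)
  expect_equal(res$diameter_um, 2 / sqrt(pi), tolerance = 1e-6)
})

test_that("canal orientation follows the anterior reference convention", {
  axis <- structure(list(endpoint_proximal = c(0, 0, 0),
                         endpoint_distal = c(0, 0, 100),
                         per_slice_centers = NULL), class = "marrow_axis")
  expect_equal(canal_orientation(c(10, 0, 50), axis), 0)
  th180 <- canal_orientation(c(-10, 0, 50), axis)
  expect_equal(th180, 180)
  expect_true(abs(th180) > 90)
  expect_equal(canal_orientation(c(7, 7, 50), axis), 45)
  expect_equal(canal_orientation(c(0, -3, 50), axis), -90)
  expect_error(canal_orientation(c(0, 0, 50), axis), "undefined orientation")
  # arbitrary displacements agree with the planar arctangent oracle
  set.seed(8)
  for (i in 1:20) {
    p <- c(rnorm(2), runif(1, 0, 100))
    if (sum(p[1:2]^2) < 1e-6) next
    expect_equal(canal_orientation(p, axis),
                 atan2(p[2], p[1]) * 180 / pi, tolerance = 1e-10)
  }
})

test_that("canal density divides counts by the sector area", {
  rec <- data.frame(class = rep("canal", 12), theta_deg = seq(-80, 80, length.out = 12))
  dens <- canal_density(rec, c(-90, 90), area_mm2 = 0.2)
  expect_equal(dens$canal_count, 12)
  expect_equal(dens$density_per_mm2, 60)
  expect_error(canal_density(rec, c(-90, 90), area_mm2 = 0), "positive")
  none <- canal_density(rec[0, ], c(-90, 90), area_mm2 = 0.5)
  expect_equal(none$density_per_mm2, 0)
})

test_that("endosteal sector area matches the analytic ellipse arc", {
  grid <- c(160L, 160L, 60L); voxel <- 2
  inner <- c(75, 60)
  ph <- generate_phantom(shell_spec(seed = 7, grid = grid, voxel = voxel,
                                    outer = inner + 40, inner = inner))
  bone <- threshold_bone(ph$volume, "fixed", 125)
  marrow <- extract_marrow(bone)
  axis <- compute_marrow_axis(marrow)
  height <- grid[3] * voxel
  arc_analytic <- function(lo, hi) {
    th <- seq(lo, hi, length.out = 4001) * pi / 180
    r <- inner[1] * inner[2] /
      sqrt((inner[2] * cos(th))^2 + (inner[1] * sin(th))^2)
    dth <- diff(th)[1]
    dr <- c(diff(r) / dth, NA)
    sum(sqrt(r[-4001]^2 + dr[-4001]^2) * dth)
  }
  full <- endosteal_sector_area(marrow, axis, c(-180, 180))
  expect_equal(full, arc_analytic(-180, 180) * height / 1e6, tolerance = 0.02)
  ant <- endosteal_sector_area(marrow, axis, c(-45, 45))
  expect_equal(ant, arc_analytic(-45, 45) * height / 1e6, tolerance = 0.02)
})

test_that("posterior fraction implements the 90-degree rule", {
  rec <- data.frame(class = "canal", theta_deg = c(0, 45, 91, 179, -135))
  pf <- posterior_fraction(rec)
  expect_equal(pf$fraction, 0.6)
  expect_equal(pf$n_posterior, 3)
  all_ant <- data.frame(class = "canal", theta_deg = seq(-89, 89, by = 10))
  expect_equal(posterior_fraction(all_ant)$fraction, 0)
  expect_error(posterior_fraction(all_ant[0, ]), "no canals")
  # uniform angles: fraction near 1/2 within 3 binomial standard deviations
  set.seed(123)
  th <- runif(1000, -180, 180)
  pf2 <- posterior_fraction(data.frame(class = "canal", theta_deg = th))
  expect_lt(abs(pf2$fraction - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("diameters scale exactly with the voxel size", {
  canals <- data.frame(theta_deg = c(30, -100), z_frac = c(0.4, 0.6),
                       diameter_um = c(20, 24), inclination_deg = c(0, 6))
  ph <- generate_phantom(shell_spec(seed = 23, canals = canals))
  bone <- threshold_bone(ph$volume, "fixed", 125)
  cortex <- define_cortex_region(bone, 35)
  marrow <- extract_marrow(bone, cortex)
  voids1 <- extract_void_components(cortex, bone, marrow)
  voids2 <- voids1
  voids2$voxel_size_um <- voids1$voxel_size_um * 2
  for (id in voids1$components$id) {
    d1 <- canal_diameter(canalmorph:::component_coords(voids1, id), voids1$voxel_size_um)
    d2 <- canal_diameter(canalmorph:::component_coords(voids2, id), voids2$voxel_size_um)
    expect_equal(d2$diameter_um, 2 * d1$diameter_um, tolerance = 1e-12)
  }
})

test_that("posterior classification is robust to one-voxel axis jitter", {
  canals <- data.frame(theta_deg = c(30, -120, 84, -96), z_frac = c(0.3, 0.45, 0.6, 0.75),
                       diameter_um = c(20, 22, 18, 20), inclination_deg = 0)
  ph <- generate_phantom(shell_spec(seed = 29, canals = canals))
  q <- quantify_volume(ph$volume, run_config(threshold_method = "fixed",
                                             fixed_threshold = 125,
                                             closing_radius_um = 35))
  base <- q$records[q$records$class == "canal", ]
  base <- base[order(base$theta_deg), ]
  set.seed(5)
  for (i in 1:5) {
    jit <- q$axis
    jit$endpoint_proximal[1:2] <- jit$endpoint_proximal[1:2] + runif(2, -2, 2)
    jit$endpoint_distal[1:2] <- jit$endpoint_distal[1:2] + runif(2, -2, 2)
    th <- canal_orientation(as.matrix(base[, c("x_um", "y_um", "z_um")]), jit)
    expect_identical(abs(th) > 90, base$is_posterior)
  }
})
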