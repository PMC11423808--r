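test_that("phantom generation is deterministic and order-independent", {
  canals <- data.frame(theta_deg = c(20, -110, 75), z_frac = c(0.3, 0.5, 0.7),
                       diameter_um = c(20, 18, 22), inclination_deg = c(0, 5, -5))
  s1 <- shell_spec(seed = 11, canals = canals, lacunae = 5, noise_sd = 4, blur = 1)
  s2 <- shell_spec(seed = 11, canals = canals[c(3, 1, 2), ], lacunae = 5,
                   noise_sd = 4, blur = 1)
  p1 <- generate_phantom(s1)
  p2 <- generate_phantom(s1)
  p3 <- generate_phantom(s2)
  expect_identical(p1$volume$values, p2$volume$values)
  expect_identical(p1$volume$values, p3$volume$values)
  s3 <- shell_spec(seed = 12, canals = canals, lacunae = 5, noise_sd = 4, blur = 1)
  expect_false(identical(p1$volume$values, generate_phantom(s3)$volume$values))
})

test_that("empty phantom yields no truth entries and no void components", {
  ph <- generate_phantom(shell_spec(seed = 3))
  expect_equal(nrow(ph$truth$canals), 0)
  expect_equal(nrow(ph$truth$lacunae), 0)
  bone <- threshold_bone(ph$volume, "fixed", 125)
  cortex <- define_cortex_region(bone, 30)
  marrow <- extract_marrow(bone, cortex)
  voids <- extract_void_components(cortex, bone, marrow)
  expect_equal(nrow(voids$components), 0)
})

test_that("phantom defaults use the nano-CT sampling of 1.27 um per voxel", {
  spec <- phantom_spec(seed = 1)
  expect_equal(spec$voxel_size_um, 1.27)
})

test_that("phantom specification enforces its invariants", {
  expect_error(phantom_spec(), "seed")
  expect_error(shell_spec(inner = c(120, 95)), "strictly less")
  expect_error(shell_spec(canals = data.frame(theta_deg = 200, z_frac = 0.5,
                                              diameter_um = 20)), "theta")
  expect_error(shell_spec(canals = data.frame(theta_deg = 0, z_frac = 1.2,
                                              diameter_um = 20)), "z_frac")
  expect_error(shell_spec(canals = data.frame(theta_deg = 0, z_frac = 0.5,
                                              diameter_um = 1)), "2 voxels")
  expect_error(shell_spec(canals = data.frame(theta_deg = 0, z_frac = 0.5,
                                              diameter_um = 60),
                          foramen = c(theta_deg = 90, z_frac = 0.5,
                                      diameter_um = 55)),
               "smaller than the foramen")
})

test_that("overlapping canal specifications are rejected as ambiguous", {
  canals <- data.frame(theta_deg = c(30, 33), z_frac = c(0.5, 0.5),
                       diameter_um = c(20, 20), inclination_deg = c(0, 0))
  expect_error(generate_phantom(shell_spec(seed = 5, canals = canals)),
               "overlapping")
})

test_that("noise-free thresholding reproduces the carved geometry exactly", {
  grid <- c(100L, 100L, 50L); voxel <- 2
  outer <- c(80, 64); inner <- c(50, 38)
  canals <- data.frame(theta_deg = 40, z_frac = 0.5, diameter_um = 20,
                       inclination_deg = 0)
  ph <- generate_phantom(shell_spec(seed = 9, grid = grid, voxel = voxel,
                                    outer = outer, inner = inner,
                                    canals = canals))
  bone <- threshold_bone(ph$volume, "fixed", 125)
  # independent rasterization: shell minus the analytic tube
  shell <- rasterize_shell(grid, voxel, outer, inner)
  cx <- (grid[1] - 1) / 2 * voxel; cy <- (grid[2] - 1) / 2 * voxel
  z0 <- 0.5 * (grid[3] - 1) * voxel
  co <- which(shell, arr.ind = TRUE)
  px <- (co[, 2] - 1) * voxel; py <- (co[, 1] - 1) * voxel; pz <- (co[, 3] - 1) * voxel
  # distance to ray from the shell centre along theta = 40 degrees
  d <- c(cos(40 * pi / 180), sin(40 * pi / 180), 0)
  vx <- px - cx; vy <- py - cy; vz <- pz - z0
  t <- pmax(vx * d[1] + vy * d[2] + vz * d[3], 0)
  dist2 <- (vx - t * d[1])^2 + (vy - t * d[2])^2 + (vz - t * d[3])^2
  expected <- shell
  expected[co[dist2 <= 100, , drop = FALSE]] <- FALSE
  expect_identical(bone$values, expected)
})

test_that("automatic segmentation of a noise-free phantom matches the fixed threshold", {
  ph <- generate_phantom(shell_spec(seed = 21, lacunae = 10))
  auto <- threshold_bone(ph$volume, "otsu")
  fixed <- threshold_bone(ph$volume, "fixed", 125)
  expect_identical(auto$values, fixed$values)
})

test_that("contour pair generator offsets along normals and validates input", {
  cp <- generate_contour_pair(10, 4, n_points = 64)
  r_in <- sqrt(cp$inner$x_um^2 + cp$inner$y_um^2)
  r_out <- sqrt(cp$outer$x_um^2 + cp$outer$y_um^2)
  expect_equal(r_in, rep(10, 64), tolerance = 1e-10)
  expect_equal(r_out, rep(14, 64), tolerance = 1e-3)
  expect_error(generate_contour_pair(10, 4, n_points = 8), "at least 16")
  expect_error(generate_contour_pair(10, -1), "nonnegative")
  # offset larger than the local curvature radius of a wavy contour
  expect_error(
    generate_contour_pair(function(t) 10 + 3 * cos(8 * t), 25, n_points = 256),
    "self-intersect")
})
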