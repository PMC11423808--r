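test_that("automatic threshold matches exhaustive intra-class variance search", {
  set.seed(42)
  x <- c(rnorm(20000, 100, 10), rnorm(20000, 200, 10))
  vol <- voxel_volume(array(x, dim = c(40, 50, 20)), 1)
  thr <- attr(threshold_bone(vol, "otsu"), "threshold")
  expect_gte(thr, 140)
  expect_lte(thr, 160)
  # oracle: brute-force minimization of the weighted intra-class variance
  cands <- seq(min(x), max(x), length.out = 512)
  intra <- vapply(cands, function(t) {
    lo <- x[x < t]; hi <- x[x >= t]
    if (!length(lo) || !length(hi)) return(Inf)
    (length(lo) * var(lo) * (length(lo) - 1) / length(lo) +
       length(hi) * var(hi) * (length(hi) - 1) / length(hi)) / length(x)
  }, 1)
  best <- cands[which.min(intra)]
  expect_equal(thr, best, tolerance = 2 * diff(range(x)) / 256)
})

test_that("fixed thresholding of a binary volume is the identity", {
  m <- array(runif(8 * 8 * 4) > 0.5, dim = c(8, 8, 4))
  vol <- voxel_volume(m * 1, 1)
  expect_identical(threshold_bone(vol, "fixed", 0.5)$values, m)
})

test_that("constant-intensity volumes are rejected by the automatic threshold", {
  vol <- voxel_volume(array(7, dim = c(8, 8, 4)), 1)
  expect_error(threshold_bone(vol, "otsu"), "degenerate histogram")
})

test_that("automatic segmentation is invariant to intensity shifts", {
  ph <- generate_phantom(shell_spec(seed = 31, lacunae = 8, noise_sd = 5, blur = 1))
  m1 <- threshold_bone(ph$volume, "otsu")
  shifted <- voxel_volume(ph$volume$values + 500, ph$volume$voxel_size_um)
  m2 <- threshold_bone(shifted, "otsu")
  expect_identical(m1$values, m2$values)
})

test_that("cortex closing captures pierced tubes and validates its radius", {
  grid <- c(100L, 100L, 50L)
  canals <- data.frame(theta_deg = -60, z_frac = 0.5, diameter_um = 20,
                       inclination_deg = 0)
  ph <- generate_phantom(shell_spec(seed = 13, grid = grid, outer = c(80, 64),
                                    inner = c(50, 38), canals = canals))
  bone <- threshold_bone(ph$volume, "fixed", 125)
  cortex <- define_cortex_region(bone, 30)
  # every voxel carved out of the wall must lie inside the cortex region
  shell <- rasterize_shell(grid, 2, c(80, 64), c(50, 38))
  tube_in_wall <- shell & !bone$values
  # the closed region contains the pierced tube and all of the bone; at the
  # tube mouths the rolling ball shaves a film whose depth is bounded by the
  # closing sagitta (r - sqrt(r^2 - a^2), about one voxel here), so the
  # assertion of full capture applies to voxels deeper than two voxels into
  # the wall
  wall_depth2 <- canalmorph:::cpp_edt3d_sq(!shell, dim(shell))
  interior <- tube_in_wall & array(wall_depth2 > 4.01, dim(shell))
  expect_true(all(cortex$values[interior]))
  expect_gt(mean(cortex$values[tube_in_wall]), 0.9)
  expect_true(all(cortex$values[bone$values]))
  marrow <- extract_marrow(bone, cortex)
  voids <- extract_void_components(cortex, bone, marrow)
  trans <- voids$components$touches_periosteum & voids$components$touches_endosteum
  expect_equal(sum(trans), 1)
  expect_error(define_cortex_region(bone, 0), "at least one voxel")
})

test_that("closing a void-free solid is (near) idempotent", {
  # convex block: digitally exact
  block <- array(FALSE, dim = c(40, 40, 24))
  block[10:30, 8:32, 8:16] <- TRUE
  bone <- mask_volume(block, 1, "bone")
  expect_identical(define_cortex_region(bone, 5)$values, block)
  # curved shell: any extra voxels are confined to the one-voxel surface rind
  ph <- generate_phantom(shell_spec(seed = 2, grid = c(90L, 90L, 40L)))
  bone2 <- threshold_bone(ph$volume, "fixed", 125)
  cortex <- define_cortex_region(bone2, 20)
  expect_true(all(cortex$values[bone2$values]))
  extra <- cortex$values & !bone2$values
  if (any(extra)) {
    d2 <- canalmorph:::cpp_edt3d_sq(bone2$values, dim(extra))
    expect_lte(max(d2[extra]), 1.01)
  }
})

test_that("marrow extraction recovers the carved interior exactly", {
  grid <- c(90L, 90L, 40L); voxel <- 2
  outer <- c(70, 58); inner <- c(44, 34)
  ph <- generate_phantom(shell_spec(seed = 4, grid = grid, voxel = voxel,
                                    outer = outer, inner = inner))
  bone <- threshold_bone(ph$volume, "fixed", 125)
  marrow <- extract_marrow(bone)
  nx <- grid[1]; ny <- grid[2]
  xs <- (seq_len(nx) - 1) * voxel - (nx - 1) / 2 * voxel
  ys <- (seq_len(ny) - 1) * voxel - (ny - 1) / 2 * voxel
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  cavity <- (X / inner[1])^2 + (Y / inner[2])^2 <= 1
  expected <- array(rep(cavity, grid[3]), dim = dim(bone$values))
  expect_identical(marrow$values, expected)
})

test_that("marrow extraction rejects solid volumes and ambiguous ties", {
  solid <- mask_volume(array(TRUE, dim = c(20, 20, 10)), 1, "bone")
  expect_error(extract_marrow(solid), "no marrow cavity")
  # two congruent rectangular cavities
  m <- array(TRUE, dim = c(30, 30, 10))
  m[5:10, 5:10, ] <- FALSE
  m[20:25, 20:25, ] <- FALSE
  expect_error(extract_marrow(mask_volume(m, 1, "bone")), "ambiguous marrow")
})

test_that("void extraction finds tubes plus lacunae with correct contact flags", {
  canals <- data.frame(theta_deg = c(0, 120, -120), z_frac = c(0.3, 0.5, 0.7),
                       diameter_um = c(20, 22, 18), inclination_deg = c(0, 4, -4))
  ph <- generate_phantom(shell_spec(seed = 17, canals = canals, lacunae = 20))
  bone <- threshold_bone(ph$volume, "fixed", 125)
  cortex <- define_cortex_region(bone, 35)
  marrow <- extract_marrow(bone, cortex)
  voids <- extract_void_components(cortex, bone, marrow)
  expect_equal(nrow(voids$components), 23)
  trans <- voids$components$touches_periosteum & voids$components$touches_endosteum
  expect_equal(sum(trans), 3)
})

test_that("void labeling agrees with a brute-force flood fill at one-voxel gaps", {
  # two 3-voxel-wide tubes separated by a single bone plane
  dims <- c(15L, 15L, 9L)
  bone <- array(TRUE, dims)
  bone[4:6, 3:13, 4:6] <- FALSE
  bone[8:10, 3:13, 4:6] <- FALSE
  cortex <- mask_volume(array(TRUE, dims), 1, "cortex_region")
  marrow <- mask_volume(array(FALSE, dims), 1, "marrow")
  voids <- extract_void_components(cortex, mask_volume(bone, 1, "bone"), marrow)
  expect_equal(nrow(voids$components), 2)
  oracle <- flood_fill_labels(!bone, 26)
  expect_equal(max(oracle), 2)
  # diagonal contact: shifting one tube to touch corner-to-corner merges them
  bone2 <- array(TRUE, dims)
  bone2[4:6, 3:13, 4:6] <- FALSE
  bone2[7:9, 3:13, 7:9] <- FALSE
  voids2 <- extract_void_components(cortex, mask_volume(bone2, 1, "bone"), marrow)
  expect_equal(nrow(voids2$components), max(flood_fill_labels(!bone2, 26)))
  expect_equal(nrow(voids2$components), 1)
})

test_that("void extraction is idempotent", {
  canals <- data.frame(theta_deg = 45, z_frac = 0.5, diameter_um = 20,
                       inclination_deg = 0)
  ph <- generate_phantom(shell_spec(seed = 19, canals = canals, lacunae = 6))
  bone <- threshold_bone(ph$volume, "fixed", 125)
  cortex <- define_cortex_region(bone, 35)
  marrow <- extract_marrow(bone, cortex)
  v1 <- extract_void_components(cortex, bone, marrow)
  v2 <- extract_void_components(cortex, bone, marrow)
  expect_identical(v1$labels, v2$labels)
  expect_identical(v1$components, v2$components)
})

test_that("component classification applies the volume and diameter cutoffs", {
  df <- data.frame(
    id = 1:5,
    n_voxels = c(10, 3000, 3000, 3000, 3000),
    volume_um3 = c(500, 24000, 24000, 24000, 24000),
    x_um = 0, y_um = 0, z_um = 0,
    touches_periosteum = c(FALSE, TRUE, TRUE, TRUE, FALSE),
    touches_endosteum = c(FALSE, TRUE, TRUE, TRUE, FALSE),
    diameter_um = c(NA, 20, 50, 80, 30)
  )
  out <- classify_components(df, lacuna_max_volume_um3 = 2000,
                             foramen_min_diameter_um = 50)
  expect_equal(out$class, c("lacuna", "canal", "foramen", "foramen", "partial"))
  # all components below the lacuna cutoff: no canals
  small <- df[1, ]
  expect_equal(classify_components(small, 2000, 50)$class, "lacuna")
  expect_error(classify_components(df[, setdiff(names(df), "diameter_um")], 2000, 50),
               "diameters")
})
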