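# Shared fixtures: small phantoms and brute-force oracles.

# small hollow elliptic shell spec; canal_specs as given (default none)
shell_spec <- function(seed = 7, grid = c(140L, 140L, 80L), voxel = 2,
                       outer = c(110, 90), inner = c(70, 55),
                       canals = data.frame(theta_deg = numeric(),
                                           z_frac = numeric(),
                                           diameter_um = numeric()),
                       lacunae = 0L, noise_sd = 0, blur = 0, ...) {
  phantom_spec(grid_shape = grid, voxel_size_um = voxel,
               outer_radii_um = outer, inner_radii_um = inner,
               canal_specs = canals, lacuna_count = lacunae,
               noise_sd = noise_sd, blur_sigma_um = blur, seed = seed, ...)
}

# analytic shell rasterization, independent of generate_phantom internals
rasterize_shell <- function(grid, voxel, outer, inner) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  xs <- (seq_len(nx) - 1) * voxel - (nx - 1) / 2 * voxel
  ys <- (seq_len(ny) - 1) * voxel - (ny - 1) / 2 * voxel
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  sl <- (X / outer[1])^2 + (Y / outer[2])^2 <= 1 &
    (X / inner[1])^2 + (Y / inner[2])^2 > 1
  array(rep(sl, nz), dim = c(ny, nx, nz))
}

# brute-force 3D flood fill (26- or 6-connectivity) used as labeling oracle
flood_fill_labels <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dy) + abs(offs$dx) + abs(offs$dz) == 1, ]
  lab <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (labels[p[1], p[2], p[3]] > 0) next
    lab <- lab + 1L
    stack <- list(p)
    labels[p[1], p[2], p[3]] <- lab
    while (length(stack)) {
      q <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        n <- q + c(offs$dy[o], offs$dx[o], offs$dz[o])
        if (any(n < 1) || any(n > dims)) next
        if (mask[n[1], n[2], n[3]] && labels[n[1], n[2], n[3]] == 0) {
          labels[n[1], n[2], n[3]] <- lab
          stack[[length(stack) + 1L]] <- n
        }
      }
    }
  }
  labels
}

# rotate a (y, x, z) volume array by +90 degrees about the z-axis
rotate90_z <- function(arr) {
  d <- dim(arr)
  stopifnot(d[1] == d[2])
  out <- aperm(arr, c(2, 1, 3))
  out[, d[1]:1, , drop = FALSE]
}

# recovered canal table joined to truth by nearest theta
match_to_truth <- function(records, truth) {
  canals <- records[records$class == "canal", ]
  tr <- truth$canals[!truth$canals$is_foramen, ]
  canals <- canals[order(canals$theta_deg), ]
  tr <- tr[order(tr$theta_deg), ]
  list(recovered = canals, truth = tr)
}
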