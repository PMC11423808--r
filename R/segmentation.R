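#' Segment bone by thresholding
#'
#' Bone is the set of voxels at or above the threshold. The automatic method
#' selects the grey level minimizing the intra-class intensity variance over a
#' 256-bin histogram of the volume (the classic bimodal criterion); because the
#' bins are placed over the observed intensity range, the automatic threshold
#' is invariant to adding a constant to all voxels. The threshold actually
#' used is attached as attribute `"threshold"`.
#'
#' @param volume a [voxel_volume()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold when `method = "fixed"`.
#' @return A [mask_volume()] with role `"bone"` and attribute `"threshold"`.
#' @export
threshold_bone <- function(volume, method = c("otsu", "fixed"), fixed_value = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  method <- match.arg(method)
  vals <- volume$values
  if (method == "fixed") {
    if (is.null(fixed_value) || !is.finite(fixed_value))
      stop("fixed threshold value required")
    thr <- fixed_value
  } else {
    rng <- range(vals)
    if (diff(rng) <= 0) stop("degenerate histogram: constant-intensity volume")
    thr <- otsu_threshold(vals, n_bins = 256L)
  }
  m <- mask_volume(vals >= thr, volume$voxel_size_um, "bone")
  attr(m, "threshold") <- thr
  m
}

#' Minimal intra-class variance threshold of a numeric sample
#'
#' Histogram-based: candidate thresholds are the bin edges; the one minimizing
#' the mass-weighted sum of the two class variances (equivalently maximizing
#' the between-class variance) is returned.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins number of histogram bins.
#' @return threshold value; voxels `>= threshold` form the upper class.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) <= 0) stop("degenerate histogram: constant input")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  mu <- w * mids
  w0 <- cumsum(w)
  m0 <- cumsum(mu)
  mT <- m0[n_bins]
  w1 <- 1 - w0
  # between-class variance for cut after bin t
  bc <- (mT * w0 - m0)^2 / (w0 * w1)
  bc[!is.finite(bc)] <- -Inf
  t <- which.max(bc[-n_bins])
  edges[t + 1L]
}

#' Define the cortex region by morphological closing
#'
#' Closes the bone mask with a Euclidean ball of the given radius (computed by
#' distance transform, so arbitrarily large radii are cheap), producing the
#' filled cortical wall inside which canal and lacunar voids fall. The closing
#' radius must exceed the largest void radius to be captured but stay below
#' the minimum curvature radius of the endosteal surface: a ball that cannot
#' roll inside the cavity leaves slivers of it in the closed set. Border
#' handling reflects a diaphysis cut perpendicular to its axis: the z faces
#' are treated as a continuation of the specimen (a shell running through the
#' full z-extent keeps its full extent), while the lateral x/y faces are
#' treated as air, so a dilation that reaches them is eroded back rather than
#' leaving border pockets. Bone voxels are always retained, and only the
#' largest connected component of the closed set is kept.
#'
#' @param bone a [mask_volume()] with role `"bone"`.
#' @param closing_radius_um ball radius in micrometres; at least one voxel.
#' @return A [mask_volume()] with role `"cortex_region"`.
#' @export
define_cortex_region <- function(bone, closing_radius_um) {
  stopifnot(inherits(bone, "mask_volume"))
  r_vox <- closing_radius_um / bone$voxel_size_um
  if (r_vox < 1) stop("closing radius must be at least one voxel")
  dims <- dim(bone$values)
  r2 <- r_vox^2 + 1e-9
  dil <- array(cpp_edt3d_sq(bone$values, dims) <= r2, dims)
  comp <- !dil
  # lateral faces are air: seed the erosion there
  comp[1, , ] <- TRUE; comp[dims[1], , ] <- TRUE
  comp[, 1, ] <- TRUE; comp[, dims[2], ] <- TRUE
  closed <- array(cpp_edt3d_sq(comp, dims) > r2, dims) | bone$values
  labs <- cpp_label3d(closed, dims, 6L)
  if (max(labs) > 1) {
    sizes <- tabulate(labs, nbins = max(labs))
    closed <- array(labs == which.max(sizes), dims)
  }
  mask_volume(closed, bone$voxel_size_um, "cortex_region")
}

#' Extract the marrow cavity
#'
#' The marrow is the largest connected (6-connectivity) non-bone component
#' that does not touch the lateral (x/y) faces of the grid. When trans-cortical
#' canals pierce the shell the raw non-bone complement leaks to the exterior
#' through the tubes; pass the closed `cortex_region` to take the complement of
#' the filled wall instead, which restores the cavity.
#'
#' @param bone a [mask_volume()] with role `"bone"`.
#' @param cortex_region optional [mask_volume()] from [define_cortex_region()];
#'   when supplied, cavities are components of its complement.
#' @return A [mask_volume()] with role `"marrow"`.
#' @export
extract_marrow <- function(bone, cortex_region = NULL) {
  stopifnot(inherits(bone, "mask_volume"))
  solid <- if (is.null(cortex_region)) bone$values else cortex_region$values
  dims <- dim(solid)
  labs <- cpp_label3d(!solid, dims, 6L)
  n <- max(labs)
  if (n == 0) stop("no marrow cavity")
  # labels touching a lateral (y or x) face are exterior
  lateral <- unique(c(labs[1, , ], labs[dims[1], , ], labs[, 1, ], labs[, dims[2], ]))
  lateral <- lateral[lateral > 0]
  sizes <- tabulate(labs, nbins = n)
  sizes[lateral] <- 0L
  if (all(sizes == 0)) stop("no marrow cavity")
  best <- max(sizes)
  cands <- which(sizes == best)
  if (length(cands) > 1) stop("ambiguous marrow: multiple equal-size cavities")
  mask_volume(array(labs == cands, dims), bone$voxel_size_um, "marrow")
}

#' Extract intracortical void components
#'
#' Voids are connected components (26-connectivity) of
#' `cortex_region \ bone \ marrow`. Because the digitized closing can leave
#' sub-voxel slivers of the cavity or exterior inside the cortex region along
#' its surfaces, candidate void voxels that are simultaneously face-adjacent
#' to bone and to a free surface (marrow or exterior) are ascribed to that
#' surface and dropped; this removes sliver chains that would otherwise
#' bridge distinct canal mouths along the endosteal surface while leaving
#' pore interiors untouched. Components living entirely within two voxels of
#' a free surface (detached mouth collars of the same digitization origin)
#' are likewise discarded as surface films -- a real pore at this resolution
#' has interior voxels deeper than that. Each component is annotated with surface contact
#' flags evaluated within a two-voxel neighbourhood: periosteal contact means
#' proximity to the exterior space, endosteal contact proximity to the
#' marrow.
#'
#' @param cortex_region,bone,marrow congruent [mask_volume()]s.
#' @return list of class `void_components` with `labels` (integer array),
#'   `components` (data frame: `id`, `n_voxels`, `volume_um3`, centroid
#'   `x_um`/`y_um`/`z_um`, `touches_periosteum`, `touches_endosteum`) and
#'   `voxel_size_um`.
#' @export
extract_void_components <- function(cortex_region, bone, marrow) {
  dims <- dim(bone$values)
  stopifnot(identical(dims, dim(cortex_region$values)),
            identical(dims, dim(marrow$values)))
  v <- bone$voxel_size_um
  void <- cortex_region$values & !bone$values & !marrow$values
  exterior <- !cortex_region$values & !marrow$values
  near_bone <- cpp_edt3d_sq(bone$values, dims) <= 1.01
  d2_surf <- cpp_edt3d_sq(marrow$values | exterior, dims)
  void <- void & !(near_bone & d2_surf <= 1.01)
  labs <- cpp_label3d(void, dims, 26L)
  n <- max(labs)
  if (n > 0) {
    w0 <- which(labs > 0)
    depth_max <- tapply(d2_surf[w0], labs[w0], max)
    film <- as.integer(names(depth_max))[depth_max <= 4.01]
    if (length(film)) {
      labs[labs %in% film] <- 0L
      keep <- sort(unique(labs[labs > 0]))
      relab <- integer(n)
      relab[keep] <- seq_along(keep)
      labs[labs > 0] <- relab[labs[labs > 0]]
      n <- length(keep)
    }
  }
  if (n == 0) {
    comps <- data.frame(id = integer(), n_voxels = integer(), volume_um3 = double(),
                        x_um = double(), y_um = double(), z_um = double(),
                        touches_periosteum = logical(), touches_endosteum = logical())
    return(structure(list(labels = labs, components = comps, voxel_size_um = v),
                     class = "void_components"))
  }
  near_marrow <- array(cpp_edt3d_sq(marrow$values, dims) <= 1.01, dims)
  near_exterior <- array(cpp_edt3d_sq(exterior, dims) <= 1.01, dims)
  flags <- cpp_contact_flags(labs, near_exterior, near_marrow, dims, n)
  w <- which(labs > 0)
  lab <- labs[w]
  k <- (w - 1L) %/% (dims[1] * dims[2])
  rem <- (w - 1L) %% (dims[1] * dims[2])
  iy <- rem %% dims[1]
  ix <- rem %/% dims[1]
  counts <- tabulate(lab, nbins = n)
  comps <- data.frame(
    id = seq_len(n),
    n_voxels = counts,
    volume_um3 = counts * v^3,
    x_um = as.vector(rowsum(ix * v, lab)) / counts,
    y_um = as.vector(rowsum(iy * v, lab)) / counts,
    z_um = as.vector(rowsum(k * v, lab)) / counts,
    touches_periosteum = flags[, 1],
    touches_endosteum = flags[, 2]
  )
  structure(list(labels = labs, components = comps, voxel_size_um = v),
            class = "void_components")
}

#' @export
print.void_components <- function(x, ...) {
  cat(sprintf("<void_components> %d components, %.4g um/voxel\n",
              nrow(x$components), x$voxel_size_um))
  if (nrow(x$components)) print(head(x$components, 10))
  invisible(x)
}

#' Classify void components as canal, lacuna, foramen or partial
#'
#' A component is a lacuna if its volume is at or below
#' `lacuna_max_volume_um3`; otherwise, if trans-cortical (touching both the
#' periosteal and endosteal surface) it is the nutrient foramen when its
#' diameter is at or above `foramen_min_diameter_um` (the cutoff is inclusive)
#' and a canal when below; components that are neither are `"partial"`. Only
#' canals enter downstream statistics.
#'
#' @param components data frame from [extract_void_components()] with a
#'   `diameter_um` column added (see [annotate_diameters()]).
#' @param lacuna_max_volume_um3,foramen_min_diameter_um class cutoffs.
#' @return the data frame with a `class` column.
#' @export
classify_components <- function(components, lacuna_max_volume_um3 = 2000,
                                foramen_min_diameter_um = 50) {
  df <- components
  if (nrow(df) == 0) {
    df$class <- character(0)
    return(df)
  }
  if (is.null(df$diameter_um))
    stop("diameters must be computed before classification (annotate_diameters)")
  trans <- df$touches_periosteum & df$touches_endosteum
  cls <- rep("partial", nrow(df))
  cls[df$volume_um3 <= lacuna_max_volume_um3] <- "lacuna"
  big <- df$volume_um3 > lacuna_max_volume_um3
  cls[big & trans & df$diameter_um >= foramen_min_diameter_um] <- "foramen"
  cls[big & trans & df$diameter_um < foramen_min_diameter_um] <- "canal"
  df$class <- cls
  df
}
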