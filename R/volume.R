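#' Voxel volume container
#'
#' A 3D scalar image with an isotropic voxel size in micrometres. The value
#' array is stored with dimensions `(y, x, z)`: `values[, , k]` is the k-th
#' z-slice (proximal to distal) as a matrix with rows along y and columns along
#' x, matching multi-page TIFF layout. Physical coordinates are micrometres
#' from the centre of the voxel at index `(1, 1, 1)`; the anatomical anterior
#' direction is `+x` by convention and positive polar angles turn towards `+y`.
#'
#' @param values numeric 3D array, dimensions `(ny, nx, nz)`.
#' @param voxel_size_um isotropic voxel edge length in micrometres (> 0).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, voxel_size_um) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (any(dim(values) < 1L)) stop("grid non-empty required")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L || voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number")
  structure(
    list(values = values, voxel_size_um = as.numeric(voxel_size_um)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels (y,x,z), %.4g um/voxel, range [%.4g, %.4g]\n",
    d[1], d[2], d[3], x$voxel_size_um, min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Binary mask volume
#'
#' A logical 3D grid congruent with its source [voxel_volume()], tagged with
#' the region it represents.
#'
#' @param values logical 3D array, dimensions `(ny, nx, nz)`.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param role one of `"bone"`, `"cortex_region"`, `"marrow"`, `"void"`.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(values, voxel_size_um,
                        role = c("bone", "cortex_region", "marrow", "void")) {
  role <- match.arg(role)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  storage.mode(values) <- "logical"
  structure(
    list(values = values, voxel_size_um = as.numeric(voxel_size_um), role = role),
    class = "mask_volume"
  )
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<mask_volume:%s> %d x %d x %d voxels, %.4g um/voxel, %d set\n",
    x$role, d[1], d[2], d[3], x$voxel_size_um, sum(x$values)
  ))
  invisible(x)
}

# physical coordinate (um) of voxel index along one axis
.idx_to_um <- function(idx, voxel_size_um) (idx - 1) * voxel_size_um

# voxel-index coordinates (y,x,z matrix) of the TRUE voxels of a mask array
.mask_coords <- function(values) which(values, arr.ind = TRUE)
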