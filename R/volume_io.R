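#' Run configuration for the quantification pipeline
#'
#' Collects every tunable the pipeline uses, with the defaults documented at
#' each stage. Angular parameters must divide 360 evenly.
#'
#' @param threshold_method `"otsu"` (minimal intra-class variance) or `"fixed"`.
#' @param fixed_threshold grey value used when `threshold_method = "fixed"`.
#' @param closing_radius_um ball radius for the morphological closing that
#'   defines the cortex region; must exceed the largest expected void radius
#'   (including the foramen, if it is to be captured) while staying below the
#'   minimum radius of curvature of the endosteal surface, or the closing
#'   leaves slivers of the cavity inside the region (and, at the extreme,
#'   fills the cavity).
#' @param lacuna_max_volume_um3 voids at or below this volume are classified as
#'   osteocyte lacunae (default 2000 um^3, a generous lacunar upper bound).
#' @param foramen_min_diameter_um trans-cortical voids with diameter at or
#'   above this are classified as the nutrient foramen and excluded from canal
#'   statistics (default 50 um).
#' @param theta_step_deg rotation step of the panoramic stitch mode (default
#'   20 degrees, giving 18 views per revolution).
#' @param histogram_bin_deg polar histogram bin width (default 15 degrees).
#' @param anterior_direction unit 2-vector of the anatomical anterior in the
#'   slice plane; default `+x`.
#' @param output_dir where pipeline artifacts are written.
#' @param seed integer seed echoed into outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(threshold_method = c("otsu", "fixed"),
                       fixed_threshold = NA_real_,
                       closing_radius_um = 35,
                       lacuna_max_volume_um3 = 2000,
                       foramen_min_diameter_um = 50,
                       theta_step_deg = 20,
                       histogram_bin_deg = 15,
                       anterior_direction = c(1, 0),
                       output_dir = ".",
                       seed = 1L) {
  threshold_method <- match.arg(threshold_method)
  if (360 %% theta_step_deg != 0) stop("theta_step_deg must divide 360 evenly")
  if (360 %% histogram_bin_deg != 0) stop("histogram_bin_deg must divide 360 evenly")
  structure(list(
    threshold_method = threshold_method, fixed_threshold = fixed_threshold,
    closing_radius_um = closing_radius_um,
    lacuna_max_volume_um3 = lacuna_max_volume_um3,
    foramen_min_diameter_um = foramen_min_diameter_um,
    theta_step_deg = theta_step_deg, histogram_bin_deg = histogram_bin_deg,
    anterior_direction = anterior_direction, output_dir = output_dir,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON")
  )
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

#' Read a 3D volume from multi-page TIFF or NIfTI-1
#'
#' NIfTI voxel sizes are taken from the header (`pixdim`, interpreted in
#' micrometres as written by [write_volume()]); TIFF carries no calibrated
#' voxel size, so a JSON sidecar (`<path>.json` with field `voxel_size_um`)
#' written by [write_volume()] is consulted, and otherwise
#' `voxel_size_override` is required. Anisotropic voxels are rejected: all
#' downstream geometry assumes isotropy. Axis order is normalized to the
#' package convention (`values[y, x, z]`).
#'
#' @param path input file (`.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param voxel_size_override voxel size in micrometres, used when the file
#'   carries none.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, voxel_size_override = NULL) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3]
    if (max(pd) - min(pd) > 1e-6 * max(pd))
      stop("anisotropic voxels are not supported")
    vs <- pd[1]
    if (!is.finite(vs) || vs <= 0) {
      if (is.null(voxel_size_override)) stop("voxel size required")
      vs <- voxel_size_override
    }
    arr <- aperm(unclass(img)[, , , drop = FALSE], c(2, 1, 3))  # (x,y,z) -> (y,x,z)
    return(voxel_volume(arr, vs))
  }
  if (grepl("\\.tiff?$", lower)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    sidecar <- paste0(path, ".json")
    vs <- voxel_size_override
    if (is.null(vs) && file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      vs <- meta$voxel_size_um
    }
    if (is.null(vs)) stop("voxel size required: supply voxel_size_override or a JSON sidecar")
    return(voxel_volume(arr, vs))
  }
  stop("unsupported volume format: ", path)
}

#' Write a 3D volume as multi-page TIFF or NIfTI-1
#'
#' TIFF output is 16-bit (values are rounded to integers and must fit in
#' 0..65535) with a JSON sidecar carrying `voxel_size_um`; NIfTI output stores
#' the voxel size in the header `pixdim`, in micrometres.
#'
#' @param volume a [voxel_volume()].
#' @param path output file (`.tif`/`.tiff` or `.nii`/`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    arr <- aperm(volume$values, c(2, 1, 3))  # (y,x,z) -> (x,y,z)
    attr(arr, "pixdim") <- rep(volume$voxel_size_um, 3)
    RNifti::writeNifti(RNifti::asNifti(arr), path)
    return(invisible(path))
  }
  if (grepl("\\.tiff?$", lower)) {
    vals <- volume$values
    if (min(vals) < 0 || max(vals) > 65535)
      stop("TIFF output requires values in [0, 65535]")
    nz <- dim(vals)[3]
    pages <- lapply(seq_len(nz), function(k) round(vals[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    jsonlite::write_json(list(voxel_size_um = volume$voxel_size_um),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  stop("unsupported volume format: ", path)
}

.canal_table_cols <- c("id", "class", "x_um", "y_um", "z_um", "volume_um3",
                       "diameter_um", "theta_deg", "is_posterior")

#' Write the per-canal record table as CSV
#'
#' Deterministic output: rows ordered by id, floats fixed to 4 decimals.
#'
#' @param records data frame of canal records (see [build_canal_records()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_canal_table <- function(records, path) {
  cols <- .canal_table_cols
  if (nrow(records) == 0) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  miss <- setdiff(cols, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  out <- records[order(records$id), cols]
  for (nm in c("x_um", "y_um", "z_um", "volume_um3", "diameter_um", "theta_deg"))
    out[[nm]] <- sprintf("%.4f", out[[nm]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a canal record table written by [write_canal_table()]
#'
#' @param path CSV path.
#' @return data frame of canal records.
#' @export
read_canal_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) > 0) df$is_posterior <- as.logical(df$is_posterior)
  df
}

#' Read a 2D contour from a two-column CSV point list
#'
#' @param path CSV with columns `x_um`, `y_um` (ordered closed contour).
#' @return data frame with columns `x_um`, `y_um`.
#' @export
read_contour_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("contour CSV needs columns x_um, y_um")
  df[, c("x_um", "y_um")]
}
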