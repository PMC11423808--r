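#' Quantify trans-cortical canals in a volume
#'
#' Runs the full in-memory pipeline: bone thresholding, cortex-region closing,
#' marrow extraction, marrow-axis computation, void-component extraction,
#' diameter measurement, classification, polar orientation and the polar
#' summary.
#'
#' @param volume a [voxel_volume()].
#' @param config a [run_config()].
#' @return list of class `canal_quantification`: `records` (per-component
#'   table), `axis`, `threshold`, `polar` (a `polar_summary` over canals, or
#'   NULL when none), `posterior` (list from [posterior_fraction()], or NULL),
#'   plus the intermediate `bone`, `cortex`, `marrow`, `voids`, and the
#'   `config` echo.
#' @export
quantify_volume <- function(volume, config = run_config()) {
  bone <- threshold_bone(volume, config$threshold_method, config$fixed_threshold)
  cortex <- define_cortex_region(bone, config$closing_radius_um)
  marrow <- extract_marrow(bone, cortex)
  axis <- compute_marrow_axis(marrow)
  voids <- extract_void_components(cortex, bone, marrow)
  records <- build_canal_records(voids, axis, config)
  n_canal <- sum(records$class == "canal")
  polar <- if (n_canal > 0)
    polar_histogram(records, config$histogram_bin_deg) else NULL
  posterior <- if (n_canal > 0) posterior_fraction(records) else NULL
  structure(list(
    records = records, axis = axis, threshold = attr(bone, "threshold"),
    polar = polar, posterior = posterior,
    bone = bone, cortex = cortex, marrow = marrow, voids = voids,
    config = config
  ), class = "canal_quantification")
}

#' @export
print.canal_quantification <- function(x, ...) {
  tab <- table(x$records$class)
  cat(sprintf("<canal_quantification> threshold %.4g; components: %s\n",
              x$threshold,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  if (!is.null(x$posterior))
    cat(sprintf("  posterior fraction: %d/%d = %.1f%%\n",
                x$posterior$n_posterior, x$posterior$n_total,
                100 * x$posterior$fraction))
  invisible(x)
}

#' Simulate a phantom and write its artifacts
#'
#' Writes the volume (16-bit multi-page TIFF with JSON voxel-size sidecar), the
#' truth tables (canals and lacunae, CSV) and a JSON echo of the specification,
#' then returns a manifest of output paths with content hashes. Identical
#' specs give identical manifests.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @return list with `paths`, `md5`, and the `truth` ledger, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- generate_phantom(spec)
  vol_path <- file.path(out_dir, "phantom.tif")
  write_volume(ph$volume, vol_path)
  canals_path <- file.path(out_dir, "truth_canals.csv")
  tc <- ph$truth$canals
  for (nm in c("theta_deg", "z_um", "diameter_um", "inclination_deg"))
    tc[[nm]] <- sprintf("%.4f", tc[[nm]])
  write.csv(tc, canals_path, row.names = FALSE, quote = FALSE)
  lac_path <- file.path(out_dir, "truth_lacunae.csv")
  write.csv(ph$truth$lacunae, lac_path, row.names = FALSE, quote = FALSE)
  spec_path <- file.path(out_dir, "spec.json")
  jsonlite::write_json(unclass(spec)[!vapply(unclass(spec), is.null, TRUE)],
                       spec_path, auto_unbox = TRUE, digits = NA)
  paths <- c(volume = vol_path, sidecar = paste0(vol_path, ".json"),
             truth_canals = canals_path, truth_lacunae = lac_path,
             spec = spec_path)
  md5 <- tools::md5sum(paths)
  names(md5) <- names(paths)
  invisible(list(paths = paths, md5 = md5, truth = ph$truth))
}

#' Quantify a volume from disk and write all artifacts
#'
#' Reads the volume, runs [quantify_volume()], and writes the canal record
#' table (CSV), the polar summary (JSON), a human-readable report, and
#' optionally the stitched panorama (TIFF + JSON sidecar).
#'
#' @param volume_path path to a TIFF/NIfTI volume, or a [voxel_volume()].
#' @param config a [run_config()]; `config$output_dir` receives the artifacts.
#' @param voxel_size_override passed to [read_volume()].
#' @param write_panorama_tiff also render and write the stitched panorama.
#' @return list with `result` (the `canal_quantification`), `paths` and `md5`,
#'   invisibly.
#' @export
run_quantify <- function(volume_path, config = run_config(),
                         voxel_size_override = NULL,
                         write_panorama_tiff = FALSE) {
  volume <- if (inherits(volume_path, "voxel_volume")) volume_path
    else read_volume(volume_path, voxel_size_override)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- quantify_volume(volume, config)

  table_path <- file.path(out_dir, "canal_records.csv")
  write_canal_table(res$records, table_path)

  polar_path <- file.path(out_dir, "polar_summary.json")
  pol <- res$polar
  jsonlite::write_json(list(
    bin_deg = config$histogram_bin_deg,
    breaks_deg = if (!is.null(pol)) pol$breaks_deg else numeric(0),
    counts = if (!is.null(pol)) pol$counts else integer(0),
    anterior_pct = if (!is.null(pol)) pol$anterior_pct else NA,
    posterior_pct = if (!is.null(pol)) pol$posterior_pct else NA,
    threshold_used = res$threshold,
    n_canals = sum(res$records$class == "canal")
  ), polar_path, auto_unbox = TRUE, digits = NA, na = "null")

  report_path <- file.path(out_dir, "report.txt")
  cls <- table(res$records$class)
  lines <- c(
    "canalmorph quantification report",
    sprintf("threshold used: %.6g", res$threshold),
    sprintf("components by class: %s",
            paste(sprintf("%s=%d", names(cls), cls), collapse = ", ")),
    if (!is.null(res$posterior))
      sprintf("posterior canals: %d/%d (%.2f%%)",
              res$posterior$n_posterior, res$posterior$n_total,
              100 * res$posterior$fraction)
    else "posterior canals: none detected"
  )
  writeLines(lines, report_path)

  paths <- c(canal_table = table_path, polar_summary = polar_path,
             report = report_path)
  if (write_panorama_tiff) {
    pano <- unwrap_stitch(volume, res$bone, res$axis, config$theta_step_deg)
    pano_path <- file.path(out_dir, "panorama.tif")
    write_panorama(pano, pano_path)
    paths <- c(paths, panorama = pano_path,
               panorama_sidecar = paste0(pano_path, ".json"))
  }
  md5 <- tools::md5sum(paths)
  names(md5) <- names(paths)
  invisible(list(result = res, paths = paths, md5 = md5))
}
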