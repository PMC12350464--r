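#' Export a point cloud as ASCII PLY
#'
#' Optionally labels section membership in a `uchar` property `section`
#' (0 = other, 1 = stenosis section, 2 = reference section).
#'
#' @param cloud A `point_cloud`.
#' @param path Output `.ply` path.
#' @param section Optional integer vector (one value per point).
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, section = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$points)
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", n),
              "property float x", "property float y", "property float z")
  if (!is.null(section)) {
    stopifnot(length(section) == n)
    header <- c(header, "property uchar section")
  }
  header <- c(header, "end_header")
  body <- if (is.null(section)) {
    sprintf("%.6g %.6g %.6g",
            cloud$points[, 1], cloud$points[, 2], cloud$points[, 3])
  } else {
    sprintf("%.6g %.6g %.6g %d",
            cloud$points[, 1], cloud$points[, 2], cloud$points[, 3],
            as.integer(section))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Serialize a stenosis report to JSON
#'
#' Percentages are rounded to 2 decimals in the file; full precision is
#' retained in the in-memory object.
#'
#' @param report A `stenosis_report`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "stenosis_report"))
  out <- list(
    psa = round(report$psa, 2), psd = round(report$psd, 2),
    area_stenosis = report$area_stenosis,
    area_reference = report$area_reference,
    diameter_stenosis = report$diameter_stenosis,
    diameter_reference = report$diameter_reference,
    reference_plane_index = report$reference_plane_index,
    keyframe_index = report$keyframe_index,
    flags = as.list(report$flags))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "list")
  invisible(path)
}
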