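#' 3D contour of the stenotic region
#'
#' Takes the morphological outer edge of the stenosis mask (pixels
#' adjacent to, but outside, the dark region - the visible rim of the
#' narrowing) and returns the 3D points whose provenance pixels lie on it.
#' Mask-edge pixels with invalid depth are dropped with a warning count.
#'
#' @param cloud A `point_cloud` from [backproject()].
#' @param stenosis_mask Logical matrix (same frame dimensions) marking the
#'   dark stenotic region.
#' @return n x 3 matrix of contour points (a subset of the cloud), with
#'   attribute `pixel_index`.
#' @export
stenosis_contour_3d <- function(cloud, stenosis_mask) {
  stopifnot(inherits(cloud, "point_cloud"), is.logical(stenosis_mask))
  if (!identical(dim(stenosis_mask), as.integer(cloud$dim)) &&
      !identical(dim(stenosis_mask), cloud$dim))
    stop("mask dimensions do not match the cloud's frame")
  edge <- mask_outer_edge(stenosis_mask)
  edge_idx <- which(edge)
  hit <- match(edge_idx, cloud$pixel_index)
  dropped <- sum(is.na(hit))
  if (dropped > 0)
    warning(dropped, " contour pixel(s) had no valid depth and were dropped")
  hit <- hit[!is.na(hit)]
  if (length(hit) < 3)
    stop("fewer than 3 contour points with valid depth; plane undefined")
  pts <- cloud$points[hit, , drop = FALSE]
  attr(pts, "pixel_index") <- cloud$pixel_index[hit]
  pts
}

# pixels adjacent (8-connectivity) to the mask but not in it
mask_outer_edge <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  dil <- matrix(FALSE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    dil[rs, cs] <- dil[rs, cs] | mask[rs - dr, cs - dc]
  }
  dil & !mask
}

#' Total-least-squares plane fit
#'
#' Centers the points, takes the eigenvector of the smallest eigenvalue of
#' the covariance as the normal, and orients it with a positive z
#' component (away from the camera). Points `X` on the plane satisfy
#' `normal . X = offset`.
#'
#' @param points n x 3 matrix, `n >= 3`, not collinear.
#' @return A `section_plane`: unit `normal` and scalar `offset`.
#' @export
fit_plane <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  if (nrow(points) < 3) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300))
    stop("points are collinear or coincident; plane undefined")
  nrm <- ev$vectors[, 3]
  if (nrm[3] < 0) nrm <- -nrm
  structure(list(normal = nrm, offset = sum(nrm * ctr)),
            class = "section_plane")
}

#' Algebraic least-squares circle fit (Kasa)
#'
#' Solves the linear system `2*cx*x + 2*cy*y + (r^2 - cx^2 - cy^2) = x^2 + y^2`
#' for the centre and radius. Exact for points on a circle; for three
#' non-collinear points it returns the circumscribed circle.
#'
#' @param boundary_2d n x 2 matrix of in-plane points, `n >= 3`.
#' @return List with `center` (length 2), `diameter`, `rms_residual` (RMS
#'   of radial residuals) and logical `poor_fit` (residual above 10% of
#'   the radius).
#' @export
fit_circle <- function(boundary_2d) {
  stopifnot(is.matrix(boundary_2d), ncol(boundary_2d) == 2)
  if (nrow(boundary_2d) < 3) stop("need at least 3 points to fit a circle")
  x <- boundary_2d[, 1]; y <- boundary_2d[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  if (qr(A)$rank < 3) stop("points are collinear; circle undefined")
  sol <- qr.solve(A, x^2 + y^2)
  ctr <- sol[1:2]
  r2 <- sol[3] + sum(ctr^2)
  if (r2 <= 0) stop("degenerate circle fit")
  r <- sqrt(r2)
  resid <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2) - r
  rms <- sqrt(mean(resid^2))
  list(center = unname(ctr), diameter = 2 * r, rms_residual = rms,
       poor_fit = rms > 0.1 * r)
}

# shoelace area of an ordered polygon (n x 2)
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# orthonormal in-plane basis for a unit normal
plane_basis <- function(normal) {
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  cbind(e1, e2)
}

#' Cross-section of the cloud with a plane
#'
#' Selects cloud points within `slab_tolerance` of the plane, projects
#' them into an orthonormal in-plane basis, takes the 2D convex hull as
#' the section boundary (ordered counter-clockwise), computes its
#' shoelace area and fits a circle to the hull vertices.
#'
#' @param cloud A `point_cloud`.
#' @param plane A `section_plane` from [fit_plane()].
#' @param slab_tolerance Half-thickness of the slab, in cloud units
#'   (`> 0`).
#' @return A `cross_section`: `plane`, `boundary_2d`, `area`,
#'   `circle_center`, `circle_diameter`, `n_points`, `flags` (may contain
#'   `"sparse_section"` for < 50 slab points and/or `"circle_fit_poor"`).
#' @export
cross_section <- function(cloud, plane, slab_tolerance) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(plane, "section_plane"))
  if (slab_tolerance <= 0) stop("slab_tolerance must be positive")
  dist <- abs(cloud$points %*% plane$normal - plane$offset)
  keep <- which(dist <= slab_tolerance)
  if (length(keep) < 3)
    stop("fewer than 3 points in the slab; section undefined")
  flags <- character(0)
  if (length(keep) < 50) flags <- c(flags, "sparse_section")
  B <- plane_basis(plane$normal)
  p2 <- cloud$points[keep, , drop = FALSE] %*% B
  hull_idx <- grDevices::chull(p2)       # clockwise in standard orientation
  hull <- p2[rev(hull_idx), , drop = FALSE]  # counter-clockwise
  circ <- fit_circle(hull)
  if (circ$poor_fit) flags <- c(flags, "circle_fit_poor")
  structure(list(plane = plane, boundary_2d = hull,
                 area = polygon_area(hull),
                 circle_center = circ$center,
                 circle_diameter = circ$diameter,
                 circle_rms_residual = circ$rms_residual,
                 n_points = length(keep), flags = flags),
            class = "cross_section")
}

#' Sweep camera-perpendicular planes for the reference section
#'
#' Generates `n_planes` planes with normal `(0, 0, 1)` at evenly spaced
#' offsets in `[z_min, z_max]`, computes each cross-section area and
#' returns the plane of maximum area - the widest airway section between
#' the vocal cords and the stenosis, which serves as the healthy
#' reference. Ties resolve to the plane nearest the camera. Planes with
#' fewer than 3 slab points contribute zero area.
#'
#' @param cloud A `point_cloud`.
#' @param z_min,z_max Sweep range along z (cloud units), `z_min < z_max`.
#' @param n_planes Number of planes (`>= 2`).
#' @param slab_tolerance Slab half-thickness.
#' @return List with `index` (1-based index of the winning plane),
#'   `section` (its [cross_section()]), `offsets` and `areas`.
#' @export
sweep_reference_plane <- function(cloud, z_min, z_max, n_planes = 50,
                                  slab_tolerance) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!(z_min < z_max)) stop("need z_min < z_max")
  if (n_planes < 2) stop("need at least 2 planes")
  offsets <- seq(z_min, z_max, length.out = n_planes)
  areas <- numeric(n_planes)
  for (k in seq_len(n_planes)) {
    pl <- structure(list(normal = c(0, 0, 1), offset = offsets[k]),
                    class = "section_plane")
    areas[k] <- tryCatch(cross_section(cloud, pl, slab_tolerance)$area,
                         error = function(e) 0)
  }
  if (all(areas == 0)) stop("all swept planes are degenerate")
  best <- which.max(areas)               # which.max takes the first maximum
  pl <- structure(list(normal = c(0, 0, 1), offset = offsets[best]),
                  class = "section_plane")
  list(index = best, section = cross_section(cloud, pl, slab_tolerance),
       offsets = offsets, areas = areas)
}

#' Stenosis indices from section areas and diameters
#'
#' `PSA = (1 - A_stenosis / A_reference) * 100` and
#' `PSD = (1 - d_stenosis / d_reference) * 100`, reported unclamped:
#' negative values (reference smaller than the stenosis section) are
#' flagged rather than silently clipped.
#'
#' @param area_stenosis,area_reference Section areas (squared cloud units,
#'   `> 0`).
#' @param diameter_stenosis,diameter_reference Fitted-circle diameters
#'   (cloud units, `> 0`).
#' @param reference_plane_index Optional index of the winning reference
#'   plane.
#' @param keyframe_index Optional 0-based keyframe index.
#' @param extra_flags Additional flags to carry into the report.
#' @return A `stenosis_report`.
#' @export
compute_indices <- function(area_stenosis, area_reference,
                            diameter_stenosis, diameter_reference,
                            reference_plane_index = NA_integer_,
                            keyframe_index = NA_integer_,
                            extra_flags = character(0)) {
  vals <- c(area_stenosis, area_reference, diameter_stenosis, diameter_reference)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("areas and diameters must be positive")
  psa <- (1 - area_stenosis / area_reference) * 100
  psd <- (1 - diameter_stenosis / diameter_reference) * 100
  flags <- extra_flags
  if (psa < 0 || psd < 0) flags <- c(flags, "reference_smaller_than_stenosis")
  structure(list(psa = psa, psd = psd,
                 area_stenosis = area_stenosis,
                 area_reference = area_reference,
                 diameter_stenosis = diameter_stenosis,
                 diameter_reference = diameter_reference,
                 reference_plane_index = reference_plane_index,
                 keyframe_index = keyframe_index,
                 flags = unique(flags)),
            class = "stenosis_report")
}

#' @export
print.stenosis_report <- function(x, ...) {
  cat(sprintf("stenosis_report: PSA %.2f%%, PSD %.2f%%\n", x$psa, x$psd))
  cat(sprintf("  A_stenosis %.4g, A_reference %.4g (plane %s)\n",
              x$area_stenosis, x$area_reference, x$reference_plane_index))
  cat(sprintf("  d_stenosis %.4g, d_reference %.4g\n",
              x$diameter_stenosis, x$diameter_reference))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Measure stenosis indices on a 3D point cloud
#'
#' The geometric half of [measure_keyframe()], operating on an existing
#' cloud and stenosis mask: contour of the dark region, total-least-squares
#' stenosis plane, slab cross-section, reference-plane sweep between the
#' camera and the stenosis, and the PSA/PSD indices. Useful on its own for
#' scale-invariance checks and for depth maps from external estimators.
#'
#' The slab half-thickness defaults to 2% of the median point distance
#' (scale-free), widened to twice the median plane-fit residual of the
#' contour when the reconstruction is noisy so the stenosis slab is never
#' empty.
#'
#' @param cloud A `point_cloud`.
#' @param stenosis_mask Logical matrix marking the dark stenotic region.
#' @param slab_tolerance Slab half-thickness; `NULL` for the default rule.
#' @param n_planes Number of reference sweep planes.
#' @return A `stenosis_report`.
#' @export
measure_cloud <- function(cloud, stenosis_mask, slab_tolerance = NULL,
                          n_planes = 50) {
  contour <- stenosis_contour_3d(cloud, stenosis_mask)
  plane <- fit_plane(contour)
  if (is.null(slab_tolerance)) {
    med_d <- stats::median(sqrt(rowSums(cloud$points^2)))
    resid <- abs(contour %*% plane$normal - plane$offset)
    slab_tolerance <- max(0.02 * med_d, 2 * stats::median(resid))
  }
  cs_sten <- cross_section(cloud, plane, slab_tolerance)
  slab_pts <- abs(cloud$points %*% plane$normal - plane$offset) <= slab_tolerance
  z_sten <- mean(cloud$points[slab_pts, 3])
  z_min <- stats::quantile(cloud$points[, 3], 0.05, names = FALSE)
  if (!(z_min < z_sten)) stop("no depth range between camera and stenosis")
  sw <- sweep_reference_plane(cloud, z_min, z_sten, n_planes, slab_tolerance)
  compute_indices(cs_sten$area, sw$section$area,
                  cs_sten$circle_diameter, sw$section$circle_diameter,
                  reference_plane_index = sw$index,
                  extra_flags = unique(c(cs_sten$flags, sw$section$flags)))
}

#' Measure stenosis severity at a keyframe
#'
#' End-to-end single-frame measurement: segment the stenotic region as the
#' darkest image area (same intensity rule as the tracker), estimate
#' up-to-scale depth, backproject through the camera intrinsics, and
#' derive PSA and PSD from the stenosis cross-section and the
#' maximum-area reference section between the vocal cords and the
#' stenosis. Stage failures are reported with a stage label.
#'
#' @param image Grayscale matrix or RGB array (the keyframe).
#' @param camera A [camera_model()].
#' @param config A [tracker_config()] supplying the dark threshold.
#' @param estimator_id Depth estimator (see [estimate_depth()]); defaults
#'   to `"tube_shading"`, the shading-corrected analytic estimator.
#' @param keyframe_index Optional 0-based index recorded in the report.
#' @param ... Passed to the depth estimator.
#' @return A `stenosis_report`.
#' @export
measure_keyframe <- function(image, camera, config = tracker_config(),
                             estimator_id = "tube_shading",
                             keyframe_index = NA_integer_, ...) {
  gray <- to_grayscale(image)
  seg <- segment_dark_region(gray, config)
  if (is.null(seg))
    stop("segmentation stage: no dark region below threshold ",
         config$intensity_threshold, " in the keyframe")
  est <- tryCatch(
    estimate_depth(gray, camera, estimator_id, ...),
    error = function(e) stop("depth stage: ", conditionMessage(e), call. = FALSE))
  cloud <- backproject(est$depth, camera)
  report <- tryCatch(
    measure_cloud(cloud, seg$mask),
    error = function(e) stop("measurement stage: ", conditionMessage(e), call. = FALSE))
  report$keyframe_index <- keyframe_index
  report
}
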