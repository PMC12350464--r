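#' Depth map container
#'
#' Per-pixel positive depths on an arbitrary (up-to-scale) scale, with a
#' validity mask. Invalid pixels are those whose intensity carries no
#' reliable photometric information (noise floor) or is saturated
#' (specular highlights).
#'
#' @param values Numeric matrix of depths.
#' @param valid Logical matrix of the same dimension.
#' @return An object of class `depth_map`.
#' @export
depth_map <- function(values, valid = is.finite(values) & values > 0) {
  stopifnot(is.matrix(values), identical(dim(values), dim(valid)))
  structure(list(values = values, valid = valid), class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("depth_map: %dx%d, %.1f%% valid, range [%.3g, %.3g] (arbitrary scale)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$valid),
              min(x$values[x$valid]), max(x$values[x$valid])))
  invisible(x)
}

#' Analytic depth from the illumination-decline relation
#'
#' In endoscopy the camera and light source are co-located, so image
#' intensity falls with distance following the inverse square law and the
#' camera's gamma correction, `I ~ (1/d^2)^(1/gamma)`. Inverting this
#' relation gives an up-to-scale depth `d = max(I, floor_epsilon)^(-gamma/2)`
#' per pixel. Pixels at or below the noise floor (too dark for reliable
#' photometric information) or at/above the saturation level (specular)
#' are marked invalid; their depth is clamped at the floor inversion.
#'
#' @param gray Single-channel image: 8-bit integers or `[0, 1]` intensities.
#' @param camera A [camera_model()] supplying `gamma`.
#' @param floor_epsilon Noise floor on the `[0, 1]` intensity scale.
#' @param saturation_level 8-bit level at and above which pixels are
#'   treated as specular.
#' @return A [depth_map].
#' @export
depth_from_intensity <- function(gray, camera, floor_epsilon = 0.02,
                                 saturation_level = 250) {
  stopifnot(is.matrix(gray))
  if (camera$gamma <= 0) stop("gamma must be positive")
  if (floor_epsilon <= 0 || floor_epsilon >= 1)
    stop("floor_epsilon must be in (0, 1)")
  Inorm <- if (max(gray, na.rm = TRUE) > 1) gray / 255 else gray
  d <- pmax(Inorm, floor_epsilon)^(-camera$gamma / 2)
  valid <- Inorm > floor_epsilon & Inorm < saturation_level / 255
  depth_map(d, valid)
}

#' Backproject a depth map to a 3D point cloud
#'
#' Each valid pixel `(u, v)` spawns the unit ray
#' `normalize((u-cx)/fx, (v-cy)/fy, 1)` scaled by its depth. Depth is
#' interpreted as Euclidean distance along the ray (not z-depth), matching
#' the inverse-square physics of a light source at the camera centre.
#' Camera frame: x right, y down, z forward.
#'
#' @param depth A [depth_map].
#' @param camera A [camera_model()] with matching dimensions.
#' @return A `point_cloud`: `points` (n x 3 matrix), `pixel_index` (linear
#'   index of each point's source pixel in the `height x width` grid) and
#'   `dim`.
#' @export
backproject <- function(depth, camera) {
  stopifnot(inherits(depth, "depth_map"))
  if (!identical(dim(depth$values), c(camera$height, camera$width)))
    stop("depth and camera dimensions disagree")
  rays <- camera_rays(camera)
  keep <- which(depth$valid)
  d <- depth$values[keep]
  pts <- cbind(x = d * rays$dx[keep], y = d * rays$dy[keep],
               z = d * rays$dz[keep])
  structure(list(points = pts, pixel_index = keep,
                 dim = c(camera$height, camera$width)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points from a %dx%d frame, z in [%.3g, %.3g]\n",
              nrow(x$points), x$dim[1], x$dim[2],
              min(x$points[, 3]), max(x$points[, 3])))
  invisible(x)
}

#' Project cloud points back to pixel coordinates
#'
#' The inverse of [backproject()]; used to verify round-trip consistency.
#'
#' @param points n x 3 matrix of camera-frame points (z > 0).
#' @param camera A [camera_model()].
#' @return n x 2 matrix of `(u, v)` pixel coordinates.
#' @export
project_points <- function(points, camera) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  if (any(points[, 3] <= 0)) stop("points must have z > 0")
  cbind(u = camera$fx * points[, 1] / points[, 3] + camera$cx,
        v = camera$fy * points[, 2] / points[, 3] + camera$cy)
}

#' Surface normals from a depth map
#'
#' Backprojects the depth map and takes finite-difference tangent vectors
#' along rows and columns; the normal is their normalized cross product,
#' oriented to face the camera (`n . (-X) > 0`). Pixels without enough
#' valid neighbours get an invalid normal.
#'
#' @param depth A [depth_map].
#' @param camera A [camera_model()].
#' @return A `normal_map`: matrices `nx, ny, nz` and a `valid` mask.
#' @export
normals_from_depth <- function(depth, camera) {
  stopifnot(inherits(depth, "depth_map"))
  h <- camera$height; w <- camera$width
  rays <- camera_rays(camera)
  dv <- depth$values
  dv[!depth$valid] <- NA_real_
  X <- dv * rays$dx; Y <- dv * rays$dy; Z <- dv * rays$dz
  gx <- function(M) {
    G <- matrix(NA_real_, h, w)
    G[, 2:(w - 1)] <- (M[, 3:w] - M[, 1:(w - 2)]) / 2
    G[, 1] <- M[, 2] - M[, 1]; G[, w] <- M[, w] - M[, w - 1]
    G
  }
  gy <- function(M) {
    G <- matrix(NA_real_, h, w)
    G[2:(h - 1), ] <- (M[3:h, ] - M[1:(h - 2), ]) / 2
    G[1, ] <- M[2, ] - M[1, ]; G[h, ] <- M[h, ] - M[h - 1, ]
    G
  }
  tx1 <- gx(X); ty1 <- gx(Y); tz1 <- gx(Z)
  tx2 <- gy(X); ty2 <- gy(Y); tz2 <- gy(Z)
  nx <- ty1 * tz2 - tz1 * ty2
  ny <- tz1 * tx2 - tx1 * tz2
  nz <- tx1 * ty2 - ty1 * tx2
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  valid <- is.finite(nn) & nn > 0 & depth$valid
  nn[!valid] <- 1
  nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
  # orient toward the camera: n . X < 0
  s <- sign(nx * X + ny * Y + nz * Z)
  s[!is.finite(s) | s == 0] <- 1
  flip <- s > 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]; nz[flip] <- -nz[flip]
  nx[!valid] <- NA_real_; ny[!valid] <- NA_real_; nz[!valid] <- NA_real_
  structure(list(nx = nx, ny = ny, nz = nz, valid = valid),
            class = "normal_map")
}

# ---- depth estimator registry ------------------------------------------

.estimators <- new.env(parent = emptyenv())

#' Register a depth estimator
#'
#' Estimators are functions `f(gray, camera, ...)` returning a list with a
#' `depth` ([depth_map]), and optionally `albedo` and `normals`; missing
#' components are filled in by [estimate_depth()]. The registry is how a
#' learned single-frame model (trained elsewhere) can be plugged into the
#' pipeline in place of the analytic estimators.
#'
#' @param id Estimator name.
#' @param fn Estimator function.
#' @return `id`, invisibly.
#' @export
register_depth_estimator <- function(id, fn) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fn))
  assign(id, fn, envir = .estimators)
  invisible(id)
}

#' List registered depth estimators
#' @return Character vector of estimator ids.
#' @export
list_depth_estimators <- function() sort(ls(.estimators))

#' Estimate depth, albedo and normals from a single frame
#'
#' Dispatches to a registered estimator. Two analytic estimators ship with
#' the package:
#'
#' * `"photometric"` - the pure illumination-decline inversion of
#'   [depth_from_intensity()] (albedo and Lambert shading ignored).
#' * `"tube_shading"` - a shading-corrected variant for tubular scenes
#'   viewed along the axis ([tube_shading_depth()]); it solves a 1-D
#'   shape-from-shading equation over ray angle and is markedly more
#'   accurate near the stenosis rim, where the Lambert term collapses.
#'
#' Output depth is always up-to-scale with a validity mask; the albedo map
#' defaults to a constant 1.
#'
#' @param image Single-channel matrix or RGB array.
#' @param camera A [camera_model()].
#' @param estimator_id Registered estimator name.
#' @param ... Passed to the estimator.
#' @return List with `depth` ([depth_map]), `albedo` (matrix in `(0, 1]`)
#'   and `normals` (`normal_map`).
#' @export
estimate_depth <- function(image, camera, estimator_id = "photometric", ...) {
  if (!exists(estimator_id, envir = .estimators))
    stop("unknown estimator '", estimator_id, "'; registered: ",
         paste(list_depth_estimators(), collapse = ", "))
  gray <- to_grayscale(image)
  fn <- get(estimator_id, envir = .estimators)
  out <- fn(gray, camera, ...)
  if (is.null(out$albedo))
    out$albedo <- matrix(1, camera$height, camera$width)
  if (is.null(out$normals))
    out$normals <- normals_from_depth(out$depth, camera)
  out
}

#' Tube-prior shading-corrected photometric depth
#'
#' For a tubular surface of revolution viewed from a camera on its axis,
#' the Lambert shading term has the closed form
#' `n.l = t / sqrt(t^2 + t'^2)` where `t(theta)` is the ray-distance as a
#' function of ray angle `theta` from the optical axis. Substituting into
#' the co-located light model `I^gamma = g * (n.l) / t^2` and writing
#' `q = log t` yields the ordinary differential equation
#' `q'(theta) = -sqrt(exp(4 * (q0(theta) - q(theta))) - 1)` where
#' `q0 = -log(I^gamma) / 2` is the pure inverse-square inversion.
#' Integrating inward from the image periphery (where a straight wall
#' gives the initial condition `n.l = sin(theta)`) is a contracting
#' direction, so initialization error decays and the estimate remains
#' stable down to the stenosis rim.
#'
#' The intensity profile is computed over annular bins of `theta` around
#' the principal point, restricted to the contiguous bright annulus (the
#' wall); bins dominated by dark pixels (the lumen interior, where
#' photometric information is insufficient) terminate the annulus.
#' Per-pixel depth is interpolated from the profile; bright pixels just
#' inside the annulus (the stenosis rim) receive the extrapolated rim
#' depth.
#'
#' @param gray Single-channel 8-bit image (matrix).
#' @param camera A [camera_model()].
#' @param floor_epsilon,saturation_level As in [depth_from_intensity()].
#' @param reliable_level `[0, 1]`-scale intensity below which a pixel is
#'   considered too dark to constrain the profile (default matches the
#'   dark-segmentation threshold, 50/255).
#' @param n_bins Number of annular bins.
#' @return List with `depth` (a [depth_map]).
#' @export
tube_shading_depth <- function(gray, camera, floor_epsilon = 0.02,
                               saturation_level = 250,
                               reliable_level = 50 / 255, n_bins = 160) {
  stopifnot(is.matrix(gray))
  Inorm <- if (max(gray, na.rm = TRUE) > 1) gray / 255 else gray
  h <- camera$height; w <- camera$width
  rays <- camera_rays(camera)
  theta <- asin(pmin(as.vector(rays$s), 1))
  Iv <- as.vector(Inorm)
  valid <- Iv > floor_epsilon & Iv < saturation_level / 255
  Ilin <- pmax(Iv, floor_epsilon)^camera$gamma

  grid <- seq(min(theta), max(theta), length.out = n_bins + 1)
  centers <- (grid[-1] + grid[-(n_bins + 1)]) / 2
  bw <- grid[2] - grid[1]
  bin <- pmin(pmax(findInterval(theta, grid, all.inside = TRUE), 1L), n_bins)
  q0 <- rep(NA_real_, n_bins)
  dark_frac <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    ia <- which(bin == b)
    if (!length(ia)) next
    dark_frac[b] <- mean(Iv[ia] < reliable_level)
    iv <- ia[valid[ia] & Iv[ia] >= reliable_level]
    if (length(iv) >= 3) q0[b] <- -0.5 * log(stats::median(Ilin[iv]))
  }
  # the wall annulus: scan inward from the periphery; empty bins (pixel
  # radii are discrete near the centre) are skipped, populated mostly-dark
  # bins (lumen interior) stop the scan
  bend <- n_bins
  while (bend > 1L && (is.na(q0[bend]) ||
                       (!is.na(dark_frac[bend]) && dark_frac[bend] > 0.5)))
    bend <- bend - 1L
  bstart <- bend
  while (bstart > 1L && (is.na(dark_frac[bstart - 1L]) ||
                         dark_frac[bstart - 1L] <= 0.5))
    bstart <- bstart - 1L
  while (bstart <= bend && is.na(q0[bstart])) bstart <- bstart + 1L
  if (bend - bstart < 5L)
    stop("tube_shading_depth: no usable wall annulus in this frame")
  use <- bstart:bend
  g <- centers[use]
  q0u <- q0[use]
  if (anyNA(q0u)) {
    ok <- !is.na(q0u)
    q0u <- stats::approx(g[ok], q0u[ok], xout = g, rule = 2)$y
  }
  q0s <- running_mean(q0u, 3)

  n <- length(g)
  q <- numeric(n)
  q[n] <- q0s[n] + 0.5 * log(sin(g[n]))   # straight-wall initial condition
  slope <- function(qv, q0v) -sqrt(max(exp(4 * (q0v - qv)) - 1, 0))
  for (b in (n - 1L):1L) {                # midpoint rule, integrating inward
    k1 <- slope(q[b + 1L], q0s[b + 1L])
    k2 <- slope(q[b + 1L] - bw / 2 * k1, (q0s[b] + q0s[b + 1L]) / 2)
    q[b] <- q[b + 1L] - bw * k2
  }
  d <- exp(stats::approx(g, q, xout = theta, rule = 2)$y)
  pix_valid <- valid & Iv >= reliable_level & theta <= g[n] + bw
  list(depth = depth_map(matrix(d, h, w), matrix(pix_valid, h, w)))
}

running_mean <- function(x, k) {
  f <- stats::filter(x, rep(1 / k, k), sides = 2)
  f[is.na(f)] <- x[is.na(f)]
  as.numeric(f)
}

# built-in estimators
register_depth_estimator("photometric", function(gray, camera, ...) {
  list(depth = depth_from_intensity(gray, camera, ...))
})
register_depth_estimator("tube_shading", function(gray, camera, ...) {
  tube_shading_depth(gray, camera, ...)
})
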