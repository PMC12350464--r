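#' Synthetic stenotic-airway phantom
#'
#' Builds a tubular airway model used to render synthetic bronchoscopy
#' sequences with known geometry. The tube is a surface of revolution
#' around a straight axis: radius `base_radius` everywhere except a smooth
#' (Gaussian) narrowing to `stenosis_radius` at `stenosis_z`. The vocal
#' cords are modelled as a thin membrane at `vocal_cord_z` pierced by a
#' circular aperture of radius `vocal_cord_radius` whose edge passes
#' through the tube axis (the aperture centre sits one radius off-axis).
#' A membrane, rather than a smooth funnel in the radius profile, is what
#' makes the appearance of the darkest image region change abruptly when
#' the camera crosses the cords: before the crossing the aperture occludes
#' half of the distal view, after it the full stenotic lumen is visible.
#'
#' All lengths are in millimetres.
#'
#' @param base_radius Healthy airway radius (mm).
#' @param stenosis_radius Minimal radius at the stenosis (mm),
#'   `0 < stenosis_radius < base_radius`.
#' @param stenosis_z Axial position of the stenosis (mm).
#' @param vocal_cord_radius Aperture radius of the cords membrane (mm),
#'   `0 < vocal_cord_radius < base_radius`.
#' @param vocal_cord_z Axial position of the cords membrane (mm),
#'   `0 < vocal_cord_z < stenosis_z < axis_length`.
#' @param axis_length Total tube length (mm).
#' @param stenosis_sigma Width (standard deviation, mm) of the Gaussian
#'   radius dip at the stenosis.
#' @param albedo Uniform surface reflectance in `(0, 1]`.
#' @return An object of class `airway_phantom` with a queryable
#'   `radius_profile(z)` function.
#' @examples
#' ph <- make_stenotic_airway(base_radius = 10, stenosis_radius = 5,
#'                            stenosis_z = 40, vocal_cord_radius = 3,
#'                            vocal_cord_z = 20, axis_length = 80)
#' ph$radius_profile(c(0, 40, 80))
#' @export
make_stenotic_airway <- function(base_radius = 10, stenosis_radius = 5,
                                 stenosis_z = 40, vocal_cord_radius = 3,
                                 vocal_cord_z = 20, axis_length = 80,
                                 stenosis_sigma = 4, albedo = 1) {
  if (base_radius <= 0 || stenosis_radius <= 0 || vocal_cord_radius <= 0)
    stop("radii must be positive")
  if (stenosis_radius >= base_radius)
    stop("stenosis_radius must be smaller than base_radius (non-stenotic phantom)")
  if (vocal_cord_radius >= base_radius)
    stop("vocal_cord_radius must be smaller than base_radius")
  if (!(0 < vocal_cord_z && vocal_cord_z < stenosis_z && stenosis_z < axis_length))
    stop("need 0 < vocal_cord_z < stenosis_z < axis_length")
  if (stenosis_sigma <= 0) stop("stenosis_sigma must be positive")
  if (albedo <= 0 || albedo > 1) stop("albedo must be in (0, 1]")
  depth_amp <- base_radius - stenosis_radius
  radius_profile <- function(z)
    base_radius - depth_amp * exp(-0.5 * ((z - stenosis_z) / stenosis_sigma)^2)
  radius_profile_deriv <- function(z)
    depth_amp * ((z - stenosis_z) / stenosis_sigma^2) *
      exp(-0.5 * ((z - stenosis_z) / stenosis_sigma)^2)
  structure(
    list(base_radius = base_radius, stenosis_radius = stenosis_radius,
         stenosis_z = stenosis_z, stenosis_sigma = stenosis_sigma,
         vocal_cord_radius = vocal_cord_radius, vocal_cord_z = vocal_cord_z,
         vocal_cord_offset = vocal_cord_radius,  # aperture edge on the axis
         axis_length = axis_length, albedo = albedo,
         radius_profile = radius_profile,
         radius_profile_deriv = radius_profile_deriv),
    class = "airway_phantom")
}

#' @export
print.airway_phantom <- function(x, ...) {
  cat(sprintf(paste0(
    "airway_phantom: length %.0f mm, base radius %.1f mm\n",
    "  vocal cords: membrane aperture r=%.1f mm at z=%.0f mm\n",
    "  stenosis:    r=%.1f mm at z=%.0f mm (sigma %.1f mm)\n"),
    x$axis_length, x$base_radius, x$vocal_cord_radius, x$vocal_cord_z,
    x$stenosis_radius, x$stenosis_z, x$stenosis_sigma))
  invisible(x)
}

#' Rendering configuration for the phantom
#'
#' @param camera A [camera_model()]; its `gamma` is the encoding gamma.
#' @param gain Light-source intensity factor. `NULL` (default) picks the
#'   gain at render time so that the median wall pixel of the first pose
#'   encodes near 0.5, keeping both the dark-threshold and non-saturated
#'   regimes present in the frames.
#' @param noise_sigma Additive Gaussian noise, standard deviation on the
#'   `[0, 1]` intensity scale (applied after gamma encoding).
#' @param specular_strength Strength of the optional co-located Phong lobe
#'   (0 disables it).
#' @param specular_shininess Phong exponent of the specular lobe.
#' @param quantization Bit depth of the output frames, 8 or 16.
#' @param noise_floor Intensity at which lumen pixels (rays that exit the
#'   far end of the tube) are rendered; default 5/255.
#' @param seed Integer seed controlling the noise; the same configuration
#'   always renders bit-identical frames.
#' @return An object of class `render_config`.
#' @export
render_config <- function(camera = default_camera(), gain = NULL,
                          noise_sigma = 0.01, specular_strength = 0,
                          specular_shininess = 32, quantization = 8,
                          noise_floor = 5 / 255, seed = 1L) {
  stopifnot(inherits(camera, "camera_model"))
  if (camera$gamma <= 0) stop("gamma must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (!quantization %in% c(8, 16)) stop("quantization must be 8 or 16")
  if (specular_strength < 0) stop("specular_strength must be non-negative")
  structure(
    list(camera = camera, gain = gain, noise_sigma = noise_sigma,
         specular_strength = specular_strength,
         specular_shininess = specular_shininess,
         quantization = quantization, noise_floor = noise_floor,
         seed = as.integer(seed)),
    class = "render_config")
}

#' Forward on-axis camera trajectory
#'
#' Poses are camera positions (mm) along the tube axis, forward-facing.
#' The ground-truth `transition_index` is the (0-based) index of the first
#' pose past the vocal-cord membrane.
#'
#' @param phantom An [make_stenotic_airway()] phantom.
#' @param from,to First and last camera position (mm); must be strictly
#'   increasing and inside the tube.
#' @param n_frames Number of poses.
#' @return An object of class `airway_trajectory` with fields `positions`
#'   and `transition_index`.
#' @export
axial_trajectory <- function(phantom, from = 2, to = 30, n_frames = 100) {
  stopifnot(inherits(phantom, "airway_phantom"))
  if (!(from < to)) stop("trajectory positions must be strictly increasing")
  if (from <= 0 || to >= phantom$axis_length)
    stop("trajectory must stay inside the tube")
  if (n_frames < 2) stop("need at least 2 poses")
  pos <- seq(from, to, length.out = n_frames)
  past <- which(pos > phantom$vocal_cord_z)
  transition <- if (length(past)) past[1] - 1L else NA_integer_
  structure(list(positions = pos, transition_index = transition),
            class = "airway_trajectory")
}

#' Ray-cast ground-truth depth for one pose
#'
#' Casts one ray per pixel from an on-axis, forward-facing camera at axial
#' position `pose` and intersects it with the phantom: the revolve wall
#' (base radius with the stenotic dip) and, when the camera is proximal to
#' the cords, the cords membrane. Depth is the Euclidean distance from the
#' camera centre to the first hit (the illumination model is driven by
#' distance from the co-located source, not by z-depth). Rays that leave
#' the far end of the tube without hitting the wall are lumen pixels.
#'
#' @param phantom An [make_stenotic_airway()] phantom.
#' @param pose Camera position on the axis (mm); must lie strictly inside
#'   the tube.
#' @param camera A [camera_model()].
#' @param n_steps Number of axial samples used to bracket the wall
#'   intersection before local linear refinement.
#' @return A list with `depth` (a [depth_map]: `values`, `valid`), `normals`
#'   (unit camera-frame normals `nx, ny, nz`), `hit_z` (axial coordinate of
#'   each hit) and `lumen_mask` (TRUE where the ray exits the far end).
#' @export
ray_cast_depth <- function(phantom, pose, camera = default_camera(),
                           n_steps = 250) {
  stopifnot(inherits(phantom, "airway_phantom"))
  if (pose <= 0 || pose >= phantom$axis_length)
    stop("camera must be inside the tube (0 < pose < axis_length)")
  h <- camera$height; w <- camera$width
  rays <- camera_rays(camera)
  a <- as.vector(rays$s / rays$dz)            # tan(angle from axis)
  zg <- seq(pose, phantom$axis_length, length.out = n_steps)
  Rz <- phantom$radius_profile(zg)
  # f(z) = rho(z) - R(z); first sign change marks the wall hit
  Fm <- outer(a, zg - pose) - rep(Rz, each = length(a))
  hit <- Fm >= 0
  anyhit <- rowSums(hit) > 0L
  j <- max.col(hit, ties.method = "first")
  j[!anyhit] <- NA_integer_
  j[!is.na(j) & j == 1L] <- 2L                # camera strictly inside the tube
  np <- length(a); idx <- seq_len(np)
  f1 <- Fm[cbind(idx, pmax(j - 1L, 1L))]
  f2 <- Fm[cbind(idx, pmin(j, n_steps))]
  z1 <- zg[pmax(j - 1L, 1L)]; z2 <- zg[pmin(j, n_steps)]
  zstar <- z1 - f1 * (z2 - z1) / (f2 - f1)
  zstar[!anyhit] <- NA_real_
  dz <- as.vector(rays$dz)
  d <- (zstar - pose) / dz                    # Euclidean: rays are unit vectors
  # inward normal of the revolve surface: (-x/rho, -y/rho, R'(z)), normalised
  xh <- d * as.vector(rays$dx); yh <- d * as.vector(rays$dy)
  rho <- sqrt(xh^2 + yh^2)
  dR <- phantom$radius_profile_deriv(zstar)
  nx <- -xh / rho; ny <- -yh / rho; nz <- dR
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nx <- nx / nn; ny <- ny / nn; nz <- nz / nn

  if (pose < phantom$vocal_cord_z) {
    # cords membrane: block rays that miss its off-axis aperture
    tp <- (phantom$vocal_cord_z - pose) / dz
    xp <- tp * as.vector(rays$dx); yp <- tp * as.vector(rays$dy)
    inside_aperture <- sqrt(xp^2 + (yp - phantom$vocal_cord_offset)^2) <=
      phantom$vocal_cord_radius
    rhop <- sqrt(xp^2 + yp^2)
    blocked <- !inside_aperture &
      rhop < phantom$radius_profile(phantom$vocal_cord_z) &
      (is.na(d) | tp < d)
    d[blocked] <- tp[blocked]
    zstar[blocked] <- phantom$vocal_cord_z
    anyhit[blocked] <- TRUE
    nx[blocked] <- 0; ny[blocked] <- 0; nz[blocked] <- -1
  }

  list(depth = depth_map(matrix(d, h, w), matrix(anyhit, h, w)),
       normals = list(nx = matrix(nx, h, w), ny = matrix(ny, h, w),
                      nz = matrix(nz, h, w)),
       hit_z = matrix(zstar, h, w),
       lumen_mask = matrix(!anyhit, h, w))
}

#' Render a frame from depth and normals
#'
#' Implements the co-located spotlight model: linear radiance
#' `L = gain * albedo * max(n.l, 0) / d^2` with `l` the unit vector from
#' the surface point back to the camera (so intensity declines with the
#' inverse square of distance), gamma-encoded as `I = clip(L, 0, 1)^(1/gamma)`,
#' with optional specular lobe, additive Gaussian noise and quantization.
#' Lumen pixels (invalid depth) render at the configured noise floor.
#'
#' @param depth A [depth_map] (positive values where valid).
#' @param normals List of `nx, ny, nz` matrices (unit camera-frame normals).
#' @param albedo Scalar reflectance in `(0, 1]` or a matrix of per-pixel
#'   reflectance.
#' @param config A [render_config()]. `config$gain` must be set (use
#'   [auto_gain()] or [render_sequence()] for the automatic choice).
#' @param add_noise Logical; set `FALSE` to skip the noise term regardless
#'   of `noise_sigma` (the noise stream is otherwise drawn from the current
#'   RNG state).
#' @return A `height x width` matrix of intensities in `[0, 1]`, quantized
#'   to the configured bit depth.
#' @export
render_frame <- function(depth, normals, albedo, config, add_noise = TRUE) {
  stopifnot(inherits(depth, "depth_map"), inherits(config, "render_config"))
  cam <- config$camera
  if (cam$gamma <= 0) stop("gamma must be positive")
  gain <- config$gain
  if (is.null(gain)) stop("config$gain is NULL; use auto_gain() or render_sequence()")
  rays <- camera_rays(cam)
  nl <- -(normals$nx * rays$dx + normals$ny * rays$dy + normals$nz * rays$dz)
  nl <- pmax(nl, 0)
  ok <- depth$valid & is.finite(depth$values)
  L <- matrix(0, cam$height, cam$width)
  L[ok] <- gain * nl[ok] / depth$values[ok]^2
  if (is.matrix(albedo)) L <- L * albedo else L <- L * albedo
  if (config$specular_strength > 0) {
    # Phong lobe with co-located source/viewer: r.v = 2 (n.l)^2 - 1
    rv <- pmax(2 * nl^2 - 1, 0)
    L[ok] <- L[ok] + config$specular_strength *
      rv[ok]^config$specular_shininess / depth$values[ok]^2
  }
  I <- pmin(pmax(L, 0), 1)^(1 / cam$gamma)
  I[!ok] <- config$noise_floor
  if (add_noise && config$noise_sigma > 0)
    I <- I + matrix(stats::rnorm(length(I), 0, config$noise_sigma),
                    cam$height, cam$width)
  levels <- 2^config$quantization - 1
  round(pmin(pmax(I, 0), 1) * levels) / levels
}

#' Automatic light gain for a phantom sequence
#'
#' Picks the gain so that the median wall pixel of the given pose encodes
#' near 0.5 after gamma correction. The gain is then held fixed for the
#' whole sequence, as a real light source would be.
#'
#' @inheritParams ray_cast_depth
#' @param config A [render_config()].
#' @return The gain (scalar).
#' @export
auto_gain <- function(phantom, pose, config) {
  rc <- ray_cast_depth(phantom, pose, config$camera)
  rays <- camera_rays(config$camera)
  nl <- pmax(-(rc$normals$nx * rays$dx + rc$normals$ny * rays$dy +
                 rc$normals$nz * rays$dz), 0)
  ok <- rc$depth$valid
  L1 <- phantom$albedo * nl[ok] / rc$depth$values[ok]^2
  0.5^config$camera$gamma / stats::median(L1)
}

#' Render a full synthetic bronchoscopy sequence
#'
#' Renders one frame per trajectory pose and bundles the ground truth
#' needed to evaluate every downstream stage. Fully reproducible: the
#' configured seed drives all noise, and the RNG state of the caller is
#' restored on exit.
#'
#' @param phantom An [make_stenotic_airway()] phantom.
#' @param trajectory An [axial_trajectory()].
#' @param config A [render_config()].
#' @param keep_depth Logical; store per-frame ground-truth depth maps
#'   (memory-heavy for long sequences, default `FALSE`).
#' @return A list with `frames` (list of intensity matrices),
#'   `ground_truth` (list: `transition_index`, `stenosis_radius`,
#'   `base_radius`, `positions`, `gain`, optionally `depth`), and `config`.
#' @export
render_sequence <- function(phantom, trajectory, config = render_config(),
                            keep_depth = FALSE) {
  stopifnot(inherits(phantom, "airway_phantom"),
            inherits(trajectory, "airway_trajectory"),
            inherits(config, "render_config"))
  pos <- trajectory$positions
  if (!length(pos)) stop("empty trajectory")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  gain <- config$gain
  if (is.null(gain)) gain <- auto_gain(phantom, pos[1], config)
  config$gain <- gain
  frames <- vector("list", length(pos))
  depths <- if (keep_depth) vector("list", length(pos)) else NULL
  for (i in seq_along(pos)) {
    rc <- ray_cast_depth(phantom, pos[i], config$camera)
    frames[[i]] <- render_frame(rc$depth, rc$normals, phantom$albedo, config)
    if (keep_depth) depths[[i]] <- rc$depth
  }
  list(frames = frames,
       ground_truth = list(
         transition_index = trajectory$transition_index,
         stenosis_radius = phantom$stenosis_radius,
         base_radius = phantom$base_radius,
         true_psa = 100 * (1 - (phantom$stenosis_radius / phantom$base_radius)^2),
         true_psd = 100 * (1 - phantom$stenosis_radius / phantom$base_radius),
         positions = pos, gain = gain, depth = depths),
       config = config)
}

#' Write a rendered sequence to disk
#'
#' Frames are written as 8-bit (or 16-bit) grayscale PNGs with zero-padded
#' numeric filenames, plus a single JSON sidecar `ground_truth.json` with
#' the transition index, radii and render parameters.
#'
#' @param sequence Result of [render_sequence()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_sequence <- function(sequence, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(sequence$frames)
  fmt <- paste0("%0", max(4, nchar(n)), "d.png")
  for (i in seq_len(n)) {
    png::writePNG(sequence$frames[[i]], file.path(dir, sprintf(fmt, i - 1)))
  }
  gt <- sequence$ground_truth
  gt$depth <- NULL
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
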