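#' Pinhole camera model
#'
#' A pinhole camera with focal lengths and principal point in pixels, plus
#' the gamma correction applied by the sensor pipeline. Integer pixel
#' coordinates address pixel centres and are 0-based, so the pixel grid
#' spans `[0, width-1] x [0, height-1]`.
#'
#' @param fx,fy Focal lengths in pixels (`> 0`).
#' @param cx,cy Principal point in pixels (0-based pixel-centre convention).
#' @param width,height Image size in pixels.
#' @param gamma Gamma correction exponent (`> 0`); intensities are encoded
#'   as `I = L^(1/gamma)` for linear radiance `L`.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(fx = 40, fy = 40, cx = 47.5, cy = 47.5,
#'                     width = 96, height = 96, gamma = 2.2)
#' cam
#' @export
camera_model <- function(fx, fy, cx, cy, width, height, gamma = 2.2) {
  stopifnot(is.numeric(fx), is.numeric(fy), length(fx) == 1L, length(fy) == 1L)
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  width <- as.integer(width); height <- as.integer(height)
  if (width < 2L || height < 2L) stop("image size must be at least 2x2")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point must lie inside the image")
  structure(
    list(fx = fx, fy = fy, cx = cx, cy = cy,
         width = width, height = height, gamma = gamma),
    class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: %dx%d px, fx=%.2f fy=%.2f, c=(%.2f, %.2f), gamma=%.2f\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy, x$gamma))
  invisible(x)
}

#' Default phantom camera
#'
#' The camera used throughout the synthetic experiments: 96x96 pixels,
#' focal length 40 px (a wide field of view of about 100 degrees,
#' typical of endoscopes), centred principal point, gamma 2.2.
#'
#' @return A [camera_model()].
#' @export
default_camera <- function() {
  camera_model(fx = 40, fy = 40, cx = 47.5, cy = 47.5,
               width = 96, height = 96, gamma = 2.2)
}

#' Read / write camera calibration files
#'
#' Calibration files are YAML or JSON with keys `fx, fy, cx, cy, width,
#' height, gamma`. The format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @return `read_calibration()` returns a [camera_model()];
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("fx", "fy", "cx", "cy", "width", "height")
  miss <- setdiff(need, names(vals))
  if (length(miss)) stop("calibration file missing keys: ", paste(miss, collapse = ", "))
  camera_model(vals$fx, vals$fy, vals$cx, vals$cy, vals$width, vals$height,
               if (is.null(vals$gamma)) 2.2 else vals$gamma)
}

#' @param camera A [camera_model()].
#' @rdname read_calibration
#' @export
write_calibration <- function(camera, path) {
  stopifnot(inherits(camera, "camera_model"))
  vals <- unclass(camera)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

# Unit ray direction per pixel, camera frame (x right, y down, z forward).
# Returns height x width matrices dx, dy, dz plus s = sin(angle to axis).
# Cached per camera geometry since every stage needs it.
camera_rays <- function(camera) {
  key <- paste(camera$fx, camera$fy, camera$cx, camera$cy,
               camera$width, camera$height, sep = "/")
  hit <- .ray_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- camera$height; w <- camera$width
  u <- matrix(rep(seq_len(w) - 1, each = h), h)
  v <- matrix(rep(seq_len(h) - 1, w), h)
  x <- (u - camera$cx) / camera$fx
  y <- (v - camera$cy) / camera$fy
  n <- sqrt(x^2 + y^2 + 1)
  out <- list(dx = x / n, dy = y / n, dz = 1 / n,
              s = sqrt(x^2 + y^2) / n, u = u, v = v)
  .ray_cache[[key]] <- out
  out
}

.ray_cache <- new.env(parent = emptyenv())
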