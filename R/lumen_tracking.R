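#' Convert an RGB image to 8-bit grayscale luma
#'
#' BT.601 weights (0.299, 0.587, 0.114), rounded half-up. Accepts either a
#' `h x w x 3` array or an already single-channel matrix (returned
#' unchanged). Inputs may be on the `[0, 1]` scale (as read by
#' [png::readPNG()]) or 8-bit integers; the output is always integer
#' intensities in `[0, 255]`.
#'
#' @param image Numeric matrix (`h x w`) or array (`h x w x 3`).
#' @return Integer-valued matrix of 8-bit luma.
#' @export
to_grayscale <- function(image) {
  as_levels <- function(m) {
    if (max(m, na.rm = TRUE) <= 1) m <- m * 255
    floor(m + 0.5)  # round half-up, not banker's rounding
  }
  if (is.matrix(image)) return(as_levels(image))
  if (length(dim(image)) == 3L) {
    nc <- dim(image)[3]
    if (nc == 1L) return(as_levels(image[, , 1]))
    if (nc %in% c(3L, 4L)) {
      y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
      if (max(image[, , 1:3], na.rm = TRUE) <= 1) y <- y * 255
      return(floor(y + 0.5))
    }
  }
  stop("expected a single-channel matrix or an RGB(A) array")
}

#' Tracker configuration
#'
#' Defaults follow the operating point used for real bronchoscopy: dark
#' pixels are those with 8-bit intensity below 50, the tracker requires a
#' minimum IoU of 50% between consecutive detections, and tolerates up to
#' 25 consecutive failed frames before declaring the track lost.
#'
#' @param intensity_threshold 8-bit threshold; pixels strictly below it are
#'   dark.
#' @param min_iou Minimum intersection-over-union for a detection to match
#'   the tracked segment.
#' @param patience_frames Number of consecutive misses tolerated before the
#'   track is lost.
#' @param min_area_fraction Minimum segment area as a fraction of the frame
#'   area.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(intensity_threshold = 50, min_iou = 0.5,
                           patience_frames = 25, min_area_fraction = 0.001) {
  if (intensity_threshold <= 0 || intensity_threshold >= 255)
    stop("intensity_threshold must be in (0, 255)")
  if (min_iou <= 0 || min_iou > 1) stop("min_iou must be in (0, 1]")
  if (patience_frames < 0) stop("patience_frames must be >= 0")
  structure(list(intensity_threshold = intensity_threshold,
                 min_iou = min_iou,
                 patience_frames = as.integer(patience_frames),
                 min_area_fraction = min_area_fraction),
            class = "tracker_config")
}

# 8-connected component labelling of a logical matrix via igraph.
# Returns an integer matrix of labels (0 = background).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  r <- (idx - 1L) %% h + 1L
  cc <- (idx - 1L) %/% h + 1L
  pixid <- match(idx, idx)          # 1..n in mask order
  pos <- matrix(0L, h, w); pos[idx] <- pixid
  edges <- NULL
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + sh[1]; c2 <- cc + sh[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- pos[cbind(r2[ok], c2[ok])]
    here <- pixid[ok]
    keep <- nb > 0L
    if (any(keep)) edges <- rbind(edges, cbind(here[keep], nb[keep]))
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_along(idx)]
  }
  lab[idx] <- as.integer(comp)
  lab
}

#' Segment the largest dark region of a frame
#'
#' Binarizes the grayscale frame at the configured intensity threshold
#' (`gray < threshold`), labels 8-connected components and returns the
#' largest one, provided it covers at least `min_area_fraction` of the
#' frame. Components touching the image border are eligible. Absence of a
#' qualifying dark region returns `NULL` (a valid outcome, not an error).
#'
#' @param gray Single-channel image: 8-bit integers or intensities in
#'   `[0, 1]` (rescaled internally).
#' @param config A [tracker_config()].
#' @param frame_index Optional 0-based frame index stored in the result.
#' @return A `lumen_segment` (fields `frame_index`, `mask`, `area_px`,
#'   `bbox` as 0-based half-open `(row_min, col_min, row_max, col_max)`,
#'   `centroid` as `(row, col)`), or `NULL`.
#' @export
segment_dark_region <- function(gray, config = tracker_config(),
                                frame_index = NA_integer_) {
  stopifnot(is.matrix(gray))
  if (max(gray, na.rm = TRUE) <= 1) gray <- gray * 255
  dark <- gray < config$intensity_threshold
  min_area <- config$min_area_fraction * length(dark)
  if (sum(dark) < max(1, min_area)) return(NULL)
  lab <- label_components(dark)
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  if (sizes[best] < min_area) return(NULL)
  mask <- lab == best
  rows <- row(mask)[mask]; cols <- col(mask)[mask]
  structure(
    list(frame_index = frame_index, mask = mask, area_px = sizes[best],
         bbox = c(row_min = min(rows) - 1L, col_min = min(cols) - 1L,
                  row_max = max(rows), col_max = max(cols)),
         centroid = c(row = mean(rows) - 1, col = mean(cols) - 1)),
    class = "lumen_segment")
}

#' Intersection over union of two binary masks
#'
#' Defined as 0 when both masks are empty; errors on shape mismatch.
#'
#' @param mask_a,mask_b Logical matrices of identical dimensions.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes differ: ", paste(dim(mask_a), collapse = "x"),
         " vs ", paste(dim(mask_b), collapse = "x"))
  u <- sum(mask_a | mask_b)
  if (u == 0) return(0)
  sum(mask_a & mask_b) / u
}

#' Track the dark lumen segment and select the measurement keyframe
#'
#' Initializes on the first frame with a valid dark segment and then, for
#' each subsequent frame, compares the current largest dark segment to the
#' last successfully tracked one. A match (IoU at or above `min_iou`)
#' resets the miss counter and updates the reference mask; a miss (low IoU
#' or no segment) increments it without touching the reference, which
#' keeps the tracker robust to sudden illumination changes. Once misses
#' exceed `patience_frames`, tracking is declared lost and the keyframe is
#' the first frame of the terminal miss run: the frame where the darkest
#' segment first changed, i.e. where the camera has just passed the vocal
#' cords (waiting out the patience window would select a frame
#' `patience_frames` late).
#'
#' @param frames List of grayscale frames (matrices), in temporal order,
#'   or a directory path of PNG frames in lexicographic order.
#' @param config A [tracker_config()].
#' @return A `keyframe_result`: `keyframe_index` and `loss_start_index`
#'   (0-based), `reason` (one of `"tracking_lost"`,
#'   `"sequence_end_no_loss"`, `"never_initialized"`), and `track_history`
#'   (a data frame with per-frame `frame`, `segment_area`, `iou`,
#'   `miss_count`, `state`).
#' @export
track_sequence <- function(frames, config = tracker_config()) {
  if (is.character(frames)) frames <- read_frames(frames)
  n <- length(frames)
  if (n < 1) stop("need at least one frame")
  ref <- NULL
  miss <- 0L
  loss_start <- NA_integer_
  hist <- data.frame(frame = seq_len(n) - 1L, segment_area = NA_integer_,
                     iou = NA_real_, miss_count = 0L,
                     state = "uninitialized", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    gray <- to_grayscale(frames[[i]])
    seg <- segment_dark_region(gray, config, frame_index = i - 1L)
    if (!is.null(seg)) hist$segment_area[i] <- seg$area_px
    if (is.null(ref)) {
      if (!is.null(seg)) {
        ref <- seg$mask
        hist$state[i] <- "tracking"
      }
      next
    }
    ov <- if (is.null(seg)) 0 else iou(seg$mask, ref)
    hist$iou[i] <- ov
    if (ov >= config$min_iou) {
      ref <- seg$mask
      miss <- 0L
      loss_start <- NA_integer_
      hist$state[i] <- "tracking"
    } else {
      if (miss == 0L) loss_start <- i - 1L
      miss <- miss + 1L
      hist$miss_count[i] <- miss
      hist$state[i] <- "miss"
      if (miss > config$patience_frames) {
        hist$state[i] <- "lost"
        hist <- hist[seq_len(i), ]
        return(structure(list(keyframe_index = loss_start,
                              loss_start_index = loss_start,
                              reason = "tracking_lost",
                              track_history = hist),
                         class = "keyframe_result"))
      }
    }
  }
  if (is.null(ref)) {
    return(structure(list(keyframe_index = NA_integer_,
                          loss_start_index = NA_integer_,
                          reason = "never_initialized",
                          track_history = hist),
                     class = "keyframe_result"))
  }
  structure(list(keyframe_index = n - 1L,
                 loss_start_index = loss_start,
                 reason = "sequence_end_no_loss",
                 track_history = hist),
            class = "keyframe_result")
}

#' @export
print.keyframe_result <- function(x, ...) {
  cat(sprintf("keyframe_result: keyframe %s (%s), %d frames examined\n",
              x$keyframe_index, x$reason, nrow(x$track_history)))
  invisible(x)
}

#' Write the per-frame tracking log as CSV
#'
#' @param result A `keyframe_result` from [track_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_log <- function(result, path) {
  stopifnot(inherits(result, "keyframe_result"))
  utils::write.csv(result$track_history, path, row.names = FALSE)
  invisible(path)
}

#' Read a directory of frames
#'
#' PNG (or JPEG-decoded-to-PNG) frames in lexicographic filename order;
#' RGB frames are kept as arrays for [to_grayscale()] to handle.
#'
#' @param dir Directory containing `.png` frames.
#' @return List of image matrices/arrays.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", dir)
  lapply(files, png::readPNG)
}
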