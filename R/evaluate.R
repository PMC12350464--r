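#' Run the full pipeline on one sequence
#'
#' Tracks the dark lumen segment to the measurement keyframe, then
#' measures PSA/PSD at that keyframe. Accepts in-memory frames or a frame
#' directory; the calibration may be a [camera_model()] or a calibration
#' file path.
#'
#' @param frames List of grayscale matrices / RGB arrays, or a directory
#'   of PNG frames.
#' @param camera A [camera_model()] or path to a YAML/JSON calibration.
#' @param config A [tracker_config()].
#' @param estimator_id Depth estimator for the measurement stage.
#' @param sequence_id Optional identifier used in error messages.
#' @return List with `keyframe` (a `keyframe_result`) and `report`
#'   (a `stenosis_report`).
#' @export
run_pipeline <- function(frames, camera, config = tracker_config(),
                         estimator_id = "tube_shading",
                         sequence_id = NULL) {
  if (is.character(camera)) camera <- read_calibration(camera)
  if (is.character(frames)) frames <- read_frames(frames)
  tag <- if (is.null(sequence_id)) "" else paste0("[", sequence_id, "] ")
  kf <- track_sequence(frames, config)
  if (kf$reason == "never_initialized")
    stop(tag, "tracking stage: no frame ever produced a dark segment ",
         "(never_initialized)", call. = FALSE)
  report <- tryCatch(
    measure_keyframe(frames[[kf$keyframe_index + 1L]], camera, config,
                     estimator_id, keyframe_index = kf$keyframe_index),
    error = function(e) stop(tag, conditionMessage(e), call. = FALSE))
  list(keyframe = kf, report = report)
}

#' Is the selected keyframe inside the annotated optimal interval?
#'
#' The optimal interval spans from when the bronchoscope is just below
#' the vocal cords to just before reaching the stenosis; bounds are
#' inclusive.
#'
#' @param selected_index Selected keyframe index.
#' @param keyframe_interval Length-2 vector `(first_ok, last_ok)`.
#' @return Logical.
#' @export
keyframe_correct <- function(selected_index, keyframe_interval) {
  stopifnot(length(keyframe_interval) == 2)
  if (keyframe_interval[1] > keyframe_interval[2])
    stop("invalid interval: first_ok > last_ok")
  selected_index >= keyframe_interval[1] & selected_index <= keyframe_interval[2]
}

#' Mean absolute error between reference and estimated indices
#'
#' `MAE = sum(|GT_i - ce_i|) / N` over sequences with a reference value.
#' Pairs with missing ground truth must be excluded before the call.
#'
#' @param ground_truths,estimates Equal-length numeric vectors.
#' @return The MAE (same percent units as the inputs).
#' @export
mae <- function(ground_truths, estimates) {
  if (length(ground_truths) != length(estimates))
    stop("ground truth and estimate lengths differ")
  if (!length(ground_truths)) stop("empty input")
  if (anyNA(ground_truths) || anyNA(estimates))
    stop("missing values must be excluded before calling mae()")
  mean(abs(ground_truths - estimates))
}

#' Same-patient consistency of repeated estimations
#'
#' For each patient with at least two estimations under the same
#' condition, reports the estimation range (min, max) and the absolute
#' difference `diff = max - min`, plus the mean difference across
#' patients. Patients with a single estimate are excluded with a warning.
#'
#' @param estimates Numeric vector of PSA or PSD estimates (percent).
#' @param patient Factor/character vector of patient ids, same length.
#' @return List with `per_patient` (data frame: `patient`, `n`, `min`,
#'   `max`, `diff`) and `mean_diff`.
#' @export
consistency <- function(estimates, patient) {
  if (length(estimates) != length(patient)) stop("length mismatch")
  keep <- !is.na(estimates)
  estimates <- estimates[keep]; patient <- as.character(patient)[keep]
  counts <- table(patient)
  single <- names(counts)[counts < 2]
  if (length(single))
    warning("excluded patient(s) with a single estimate: ",
            paste(single, collapse = ", "))
  use <- patient %in% names(counts)[counts >= 2]
  if (!any(use)) stop("no patient has two or more estimates")
  sp <- split(estimates[use], patient[use])
  per <- data.frame(
    patient = names(sp),
    n = vapply(sp, length, 1L),
    min = vapply(sp, min, 1),
    max = vapply(sp, max, 1),
    stringsAsFactors = FALSE)
  per$diff <- per$max - per$min
  rownames(per) <- NULL
  list(per_patient = per, mean_diff = mean(per$diff))
}

#' Published repeated-procedure estimates
#'
#' Per-sequence PSA/PSD estimates for the patients with repeated
#' bronchoscopies under unchanged condition (B, D and E), as produced by
#' the automated pipeline on the clinical recordings, together with the
#' expert PSD estimates available for patients B and D. Used to exercise
#' the consistency arithmetic on real reported values.
#'
#' @return Data frame with columns `patient`, `sequence`, `method`
#'   (`"pipeline"` or `"expert"`), `psa`, `psd`.
#' @export
repeated_procedure_estimates <- function() {
  path <- system.file("extdata", "repeated_procedure_estimates.csv",
                      package = "stenoscope")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Evaluate the pipeline over a set of sequences
#'
#' Computes the evaluation metrics given per-sequence results and ground
#' truth: percentage of correct keyframes, PSA/PSD mean absolute errors
#' (over sequences with the respective reference), and same-patient
#' consistency.
#'
#' @param results Data frame with columns `sequence_id`, `patient`,
#'   `keyframe_index`, `psa`, `psd`.
#' @param ground_truth Data frame with columns `sequence_id`,
#'   `first_ok`, `last_ok`, and optional `psa_reference`, `psd_reference`
#'   (NA where unavailable).
#' @return List with `correct_keyframe_pct`, `per_sequence` (data frame
#'   incl. absolute errors), `mae_psa`, `mae_psd`, `consistency_psa`,
#'   `consistency_psd`.
#' @export
evaluate_sequences <- function(results, ground_truth) {
  m <- merge(results, ground_truth, by = "sequence_id", sort = TRUE)
  if (!nrow(m)) stop("no overlapping sequence ids")
  m$keyframe_ok <- m$keyframe_index >= m$first_ok &
    m$keyframe_index <= m$last_ok
  m$ae_psa <- if ("psa_reference" %in% names(m))
    abs(m$psa_reference - m$psa) else NA_real_
  m$ae_psd <- if ("psd_reference" %in% names(m))
    abs(m$psd_reference - m$psd) else NA_real_
  has_psa <- !is.na(m$ae_psa); has_psd <- !is.na(m$ae_psd)
  cons_psa <- tryCatch(suppressWarnings(consistency(m$psa, m$patient)),
                       error = function(e) NULL)
  cons_psd <- tryCatch(suppressWarnings(consistency(m$psd, m$patient)),
                       error = function(e) NULL)
  list(correct_keyframe_pct = 100 * mean(m$keyframe_ok),
       per_sequence = m,
       mae_psa = if (any(has_psa))
         mae(m$psa_reference[has_psa], m$psa[has_psa]) else NA_real_,
       mae_psd = if (any(has_psd))
         mae(m$psd_reference[has_psd], m$psd[has_psd]) else NA_real_,
       consistency_psa = cons_psa,
       consistency_psd = cons_psd)
}
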