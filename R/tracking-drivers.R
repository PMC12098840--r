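#' Track a light-dark video
#'
#' Runs the ROI-threshold pipeline over a frame sequence from a camera
#' imaging the light box: binarise each frame's ROI, count target pixels,
#' and apply the light-dark rule.
#'
#' @param frames List of 8-bit frame matrices.
#' @param roi Optional [roi()] (default: whole frame).
#' @param config A [detection_config()]; its `pixel_count_threshold` is
#'   the in-ROI decision threshold.
#' @param fps Frame rate for the returned timeline.
#' @return List with `timeline` (a [chamber_timeline()]) and `counts`
#'   (per-frame target-pixel counts).
#' @export
track_lightdark <- function(frames, roi = NULL, config = detection_config(),
                            fps = 20) {
  counts <- vapply(frames, function(fr)
    count_target_pixels(binarize(fr, roi, config), config$target_color),
    numeric(1))
  labels <- classify_light_dark(counts, config$pixel_count_threshold)
  list(timeline = chamber_timeline(labels, fps), counts = counts)
}

#' Track a three-chamber video
#'
#' Runs the two-ROI pipeline over a frame sequence from a camera imaging
#' the middle chamber, carrying the side memory across frames.
#'
#' @param frames List of 8-bit frame matrices.
#' @param roi_left,roi_right [roi()]s covering the two halves of the
#'   middle chamber.
#' @param config A [detection_config()].
#' @param thresholds Length-2 pixel-count thresholds `(left, right)`;
#'   default repeats `config$pixel_count_threshold`.
#' @param fps Frame rate for the returned timeline.
#' @return List with `timeline`, `counts_left`, `counts_right`.
#' @export
track_three_chamber <- function(frames, roi_left, roi_right,
                                config = detection_config(),
                                thresholds = NULL, fps = 20) {
  if (is.null(thresholds))
    thresholds <- rep(config$pixel_count_threshold, 2)
  n <- length(frames)
  labels <- character(n)
  cl <- numeric(n); cr <- numeric(n)
  memory <- "unknown"
  for (i in seq_len(n)) {
    cl[i] <- count_target_pixels(binarize(frames[[i]], roi_left, config),
                                 config$target_color)
    cr[i] <- count_target_pixels(binarize(frames[[i]], roi_right, config),
                                 config$target_color)
    res <- classify_three_chamber(cl[i], cr[i], thresholds, memory)
    labels[i] <- res$chamber
    memory <- res$side_memory
  }
  list(timeline = chamber_timeline(labels, fps), counts_left = cl,
       counts_right = cr)
}

#' Extract a centroid trajectory from frames
#'
#' Binarises each frame and takes the target-pixel centroid; frames with
#' no target pixels yield NA positions, later bridged by
#' [locomotion_metrics()].
#'
#' @param frames List of 8-bit frame matrices.
#' @param config A [detection_config()].
#' @param fps Frame rate.
#' @param mm_per_px Spatial scale from arena calibration, mm per pixel.
#' @param roi Optional [roi()].
#' @return A [trajectory()].
#' @export
track_centroids <- function(frames, config = detection_config(), fps = 20,
                            mm_per_px = 1, roi = NULL) {
  xy <- vapply(frames, function(fr)
    mask_centroid(binarize(fr, roi, config), config$target_color),
    numeric(2))
  trajectory(xy["x", ], xy["y", ], fps = fps, mm_per_px = mm_per_px)
}
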