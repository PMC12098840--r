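#' Frames where the ROI-threshold rule is decisive
#'
#' Marks the frames of a simulated walk on which the chamber of the
#' subject is unambiguous for the detector: the rendered disc (with one
#' pixel of margin) lies entirely within a single decision zone — a
#' visible detection ROI or an unimaged chamber. For the three-chamber
#' paradigm, side-chamber frames additionally require that the walk has
#' already passed fully through one of the middle-chamber ROIs, since
#' before that the classifier's side memory is legitimately undefined.
#' Frames straddling zone boundaries are ambiguous by construction and
#' excluded from recovery guarantees.
#'
#' @param walk Output of [simulate_walk()].
#' @param arena The matching [arena_spec()].
#' @return Logical vector, one element per frame.
#' @export
frame_unambiguous <- function(walk, arena) {
  m <- arena$blob_radius + 1
  x <- walk$x
  inside <- function(rg) x - m >= rg[1] & x + m <= rg[2]
  if (arena$paradigm == "lightdark") {
    inside(arena$regions$light) | inside(arena$regions$dark)
  } else if (arena$paradigm == "threechamber") {
    mid <- arena$regions$middle
    half <- mean(mid)
    in_roi <- inside(c(mid[1], half)) | inside(c(half, mid[2]))
    memory_known <- cumsum(in_roi) > 0
    side <- inside(arena$regions$left) | inside(arena$regions$right)
    in_roi | (side & memory_known)
  } else {
    rep(TRUE, length(x))
  }
}

#' Run a full virtual experiment
#'
#' End-to-end emulation of a closed-loop behavioural session: a seeded
#' random walk is rendered into camera frames, the tracking pipeline
#' detects the chamber per frame, the detections become the controller's
#' position stream, synthetic sensor traces (with any injected anomalies)
#' become its sensor stream, and the three-gate controller produces the
#' experiment log. Frame rate is locked to the controller poll rate so
#' every poll has a fresh position.
#'
#' @param protocol A [stimulation_protocol()]; its duration sets the
#'   session length.
#' @param arena An [arena_spec()].
#' @param walk Optional [walk_params()]; must use `dt = 1/poll_rate` and
#'   cover the protocol duration. Default: a seeded walk of the right
#'   length.
#' @param anomalies List of [anomaly_spec()]s injected into the sensor
#'   traces.
#' @param thresholds A [sensor_thresholds()].
#' @param config A [controller_config()].
#' @param detection A [detection_config()].
#' @param pixel_noise_sd Gaussian pixel noise added to rendered frames.
#' @param seed Master seed; the walk and trace seeds derive from it.
#' @return List of class `virtual_rig_result`: `log` (the controller's
#'   [experiment_log][run_closed_loop()]), `truth` (the walk with
#'   ground-truth chambers), `detected` (per-frame detected chambers),
#'   `unambiguous` (see [frame_unambiguous()]), `position_stream`,
#'   `sensor_stream`.
#' @export
virtual_rig <- function(protocol, arena, walk = NULL, anomalies = list(),
                        thresholds = sensor_thresholds(),
                        config = controller_config(),
                        detection = detection_config(
                          pixel_count_threshold = 200),
                        pixel_noise_sd = 0, seed = 1) {
  stopifnot(inherits(protocol, "stimulation_protocol"),
            inherits(arena, "arena_spec"))
  duration <- protocol_duration(protocol)
  dt <- 1 / config$poll_rate
  n_frames <- round(duration * config$poll_rate) + 1
  if (is.null(walk)) {
    walk <- walk_params(steps = n_frames, dt = dt, seed = seed)
  } else {
    if (abs(walk$dt - dt) > 1e-12)
      stop("walk dt must equal the controller poll interval", call. = FALSE)
    if (walk$steps < n_frames)
      stop("walk too short for the protocol duration", call. = FALSE)
  }
  truth <- simulate_walk(arena, walk)
  frames <- render_frames(truth, arena, noise_sd = pixel_noise_sd,
                          seed = seed + 1)

  if (arena$paradigm == "lightdark") {
    tr <- track_lightdark(frames, arena$rois$main, detection,
                          fps = config$poll_rate)
    detected <- tr$timeline$labels
  } else if (arena$paradigm == "threechamber") {
    tr <- track_three_chamber(frames, arena$rois$left, arena$rois$right,
                              detection, fps = config$poll_rate)
    detected <- tr$timeline$labels
  } else {
    counts <- vapply(frames, function(fr)
      count_target_pixels(binarize(fr, arena$rois$main, detection),
                          detection$target_color), numeric(1))
    detected <- rep("arena", length(frames))
    tr <- list(counts = counts)
  }
  position_stream <- data.frame(
    time_s = truth$time_s, chamber = detected,
    in_target = detected == arena$target_chamber,
    stringsAsFactors = FALSE)

  sensor_stream <- simulate_sensor_traces(duration + dt,
                                          poll_rate = config$poll_rate,
                                          anomalies = anomalies,
                                          seed = seed + 2)
  log <- run_closed_loop(protocol, sensor_stream, position_stream,
                         thresholds, config)
  structure(list(log = log, truth = truth, detected = detected,
                 unambiguous = frame_unambiguous(truth, arena),
                 position_stream = position_stream,
                 sensor_stream = sensor_stream, tracking = tr),
            class = "virtual_rig_result")
}
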