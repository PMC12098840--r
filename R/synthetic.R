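#' Virtual behavioural arena
#'
#' Geometry of a synthetic arena for one of the three behavioural
#' paradigms, in pixels at a configurable scale (default 10 px/cm, so the
#' 14 cm chambers map to 140 px). The camera images only part of the
#' arena, as in the physical rigs where coils or covers obstruct the other
#' chambers:
#'
#' * `lightdark` - light and dark boxes of 14 x 10 cm side by side; only
#'   the light box is visible. Target (stimulation) chamber: dark.
#' * `threechamber` - 20 cm middle chamber flanked by 14 cm side
#'   chambers; only the middle chamber is visible, split into left/right
#'   detection ROIs. Target chamber: configurable side (default left).
#' * `openfield` - a single 10 x 10 cm arena, fully visible; the subject
#'   is always in target.
#'
#' The subject is rendered as a black disc of `blob_radius` pixels
#' (default 12 px = 2.4 cm, the scale of a crouched mouse body seen from
#' above).
#'
#' @param paradigm One of `"lightdark"`, `"threechamber"`, `"openfield"`.
#' @param px_per_cm Pixel scale (default 10).
#' @param blob_radius Subject disc radius, pixels.
#' @param target_chamber Chamber whose occupancy opens the position gate;
#'   defaults per paradigm as above.
#' @return An object of class `arena_spec` with fields `width`, `height`
#'   (arena pixels), `visible` (x-range imaged by the camera), `regions`
#'   (named x-ranges of the chambers), `rois` (detection ROIs in frame
#'   coordinates, where applicable).
#' @export
arena_spec <- function(paradigm = c("lightdark", "threechamber", "openfield"),
                       px_per_cm = 10, blob_radius = 12,
                       target_chamber = NULL) {
  paradigm <- match.arg(paradigm)
  if (px_per_cm <= 0 || blob_radius <= 0)
    stop("'px_per_cm' and 'blob_radius' must be positive", call. = FALSE)
  s <- function(cm) as.integer(round(cm * px_per_cm))
  if (paradigm == "lightdark") {
    width <- s(28); height <- s(10)
    regions <- list(light = c(0, s(14)), dark = c(s(14), width))
    visible <- c(0, s(14))
    rois <- list(main = roi(0, 0, s(14), height))
    target <- target_chamber %||% "dark"
  } else if (paradigm == "threechamber") {
    width <- s(48); height <- s(10)
    regions <- list(left = c(0, s(14)), middle = c(s(14), s(34)),
                    right = c(s(34), width))
    visible <- c(s(14), s(34))
    rois <- list(left = roi(0, 0, s(10), height),
                 right = roi(s(10), 0, s(10), height))
    target <- target_chamber %||% "left"
  } else {
    width <- s(10); height <- s(10)
    regions <- list(arena = c(0, width))
    visible <- c(0, width)
    rois <- list(main = roi(0, 0, width, height))
    target <- target_chamber %||% "arena"
  }
  if (!target %in% names(regions))
    stop("'target_chamber' must name an arena region", call. = FALSE)
  structure(list(paradigm = paradigm, px_per_cm = px_per_cm,
                 blob_radius = as.integer(blob_radius), width = width,
                 height = height, visible = visible, regions = regions,
                 rois = rois, target_chamber = target),
            class = "arena_spec")
}

# geometric chamber label of a position
.arena_zone <- function(arena, x) {
  for (nm in names(arena$regions)) {
    rg <- arena$regions[[nm]]
    if (x >= rg[1] && x < rg[2]) return(nm)
  }
  names(arena$regions)[length(arena$regions)]
}

#' Random-walk parameters
#'
#' A reflected correlated random walk: the heading receives Gaussian
#' noise each step, the speed is constant, and the subject reflects off
#' the arena walls (with a margin of one blob radius so the rendered disc
#' stays inside).
#'
#' @param steps Number of frames.
#' @param dt Frame interval, seconds.
#' @param speed Step length, pixels per frame (>= 0).
#' @param turn_sd Heading noise standard deviation, radians per step.
#' @param seed RNG seed; every generator is a pure function of it.
#' @param start Optional starting position `c(x, y)` in arena pixels.
#' @return An object of class `walk_params`.
#' @export
walk_params <- function(steps, dt = 0.05, speed = 3, turn_sd = 0.4,
                        seed = 1, start = NULL) {
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (speed < 0) stop("'speed' must be non-negative", call. = FALSE)
  structure(list(steps = as.integer(steps), dt = dt, speed = speed,
                 turn_sd = turn_sd, seed = as.integer(seed), start = start),
            class = "walk_params")
}

#' Simulate a subject walk with ground-truth labels
#'
#' @param arena An [arena_spec()].
#' @param params A [walk_params()].
#' @return Data frame with columns `frame`, `time_s`, `x`, `y` (arena
#'   pixels, continuous) and `chamber` (geometric ground truth).
#' @export
simulate_walk <- function(arena, params) {
  stopifnot(inherits(arena, "arena_spec"), inherits(params, "walk_params"))
  if (arena$width <= 2 * arena$blob_radius ||
      arena$height <= 2 * arena$blob_radius)
    stop("arena too small for the blob", call. = FALSE)
  set.seed(params$seed)
  m <- arena$blob_radius
  lox <- m; hix <- arena$width - m
  loy <- m; hiy <- arena$height - m
  x <- numeric(params$steps); y <- numeric(params$steps)
  p <- params$start %||% c(mean(c(lox, hix)), mean(c(loy, hiy)))
  th <- stats::runif(1, 0, 2 * pi)
  reflect <- function(v, lo, hi) {
    # fold back into [lo, hi]
    while (v < lo || v > hi) {
      if (v < lo) v <- 2 * lo - v
      if (v > hi) v <- 2 * hi - v
    }
    v
  }
  for (i in seq_len(params$steps)) {
    x[i] <- p[1]; y[i] <- p[2]
    th <- th + stats::rnorm(1, 0, params$turn_sd)
    p2 <- p + params$speed * c(cos(th), sin(th))
    if (p2[1] < lox || p2[1] > hix) th <- pi - th
    if (p2[2] < loy || p2[2] > hiy) th <- -th
    p <- c(reflect(p2[1], lox, hix), reflect(p2[2], loy, hiy))
  }
  chamber <- vapply(x, function(xx) .arena_zone(arena, xx), character(1))
  data.frame(frame = seq_len(params$steps) - 1L,
             time_s = (seq_len(params$steps) - 1L) * params$dt,
             x = x, y = y, chamber = chamber, stringsAsFactors = FALSE)
}

#' Render arena frames from a walk
#'
#' Draws the subject as a filled black disc on a white background over the
#' camera's visible window only; positions outside the visible window
#' yield blank frames, emulating the camera losing sight of the subject
#' in covered chambers. Optional i.i.d. Gaussian pixel noise is added and
#' clipped to `[0, 255]`.
#'
#' @param walk Output of [simulate_walk()].
#' @param arena The same [arena_spec()].
#' @param noise_sd Pixel-noise standard deviation (0 for clean frames).
#' @param seed RNG seed for the noise.
#' @return List of integer frame matrices (`height x visible width`).
#' @export
render_frames <- function(walk, arena, noise_sd = 0, seed = 1) {
  stopifnot(inherits(arena, "arena_spec"))
  set.seed(seed)
  w <- arena$visible[2] - arena$visible[1]
  h <- arena$height
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
  r2 <- arena$blob_radius^2
  lapply(seq_len(nrow(walk)), function(i) {
    fr <- matrix(255L, h, w)
    cx <- walk$x[i] - arena$visible[1]
    cy <- walk$y[i]
    if (cx > -arena$blob_radius && cx < w + arena$blob_radius) {
      fr[(xs - cx)^2 + (ys - cy)^2 <= r2] <- 0L
    }
    if (noise_sd > 0) {
      fr <- fr + as.integer(round(stats::rnorm(h * w, 0, noise_sd)))
      fr <- pmin(pmax(fr, 0L), 255L)
    }
    storage.mode(fr) <- "integer"
    fr
  })
}

#' Sensor anomaly specification
#'
#' A transient disturbance added to one sensor trace, used to exercise
#' threshold interrupts.
#'
#' @param kind Sensor kind (see [sensor_table()]).
#' @param onset Start time, seconds (>= 0).
#' @param duration Length, seconds (> 0).
#' @param magnitude Added value in the sensor's units.
#' @return An object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(kind, onset, duration, magnitude) {
  .sensor_range(kind)  # validates the kind
  if (onset < 0) stop("'onset' must be non-negative", call. = FALSE)
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  structure(list(kind = kind, onset = onset, duration = duration,
                 magnitude = magnitude),
            class = "anomaly_spec")
}

#' Simulate sensor traces with injectable anomalies
#'
#' Per-kind baseline plus seeded Gaussian noise, sampled at the poll
#' rate; anomalies add their magnitude over their time windows. The
#' sample count per kind is `ceiling(duration * poll_rate)`.
#'
#' @param duration Trace length, seconds (> 0).
#' @param poll_rate Sampling rate, Hz.
#' @param baselines Named numeric baselines per kind.
#' @param noise_sd Named numeric noise SDs per kind (0 allowed).
#' @param anomalies List of [anomaly_spec()]s.
#' @param seed RNG seed.
#' @return Long data frame `time_s`, `kind`, `value`.
#' @export
simulate_sensor_traces <- function(duration, poll_rate = 20,
                                   baselines = c(magnetic = 0,
                                                 temperature = 24,
                                                 sound = 45,
                                                 vibration = 0.02),
                                   noise_sd = c(magnetic = 0.5,
                                                temperature = 0.05,
                                                sound = 1,
                                                vibration = 0.005),
                                   anomalies = list(), seed = 1) {
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  set.seed(seed)
  n <- ceiling(duration * poll_rate)
  t <- (seq_len(n) - 1) / poll_rate
  out <- lapply(names(baselines), function(k) {
    v <- baselines[[k]] + stats::rnorm(n, 0, noise_sd[[k]])
    data.frame(time_s = t, kind = k, value = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  for (an in anomalies) {
    stopifnot(inherits(an, "anomaly_spec"))
    if (an$onset >= duration) {
      warning(sprintf("%s anomaly at %g s lies outside the %g s trace",
                      an$kind, an$onset, duration), call. = FALSE)
      next
    }
    win <- out$kind == an$kind & out$time_s >= an$onset &
      out$time_s < an$onset + an$duration
    out$value[win] <- out$value[win] + an$magnitude
  }
  out
}
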