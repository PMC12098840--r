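#' Pixel rectangle (region of interest)
#'
#' Image-convention ROI: `x` is the column and `y` the row of the top-left
#' corner, 0-based, origin at the top-left of the frame; the rectangle is
#' half-open, covering pixels `[x, x + width) x [y, y + height)`.
#'
#' @param x,y Top-left corner, 0-based pixels.
#' @param width,height Extents in pixels (> 0).
#' @return An object of class `roi`.
#' @export
roi <- function(x, y, width, height) {
  if (width <= 0 || height <= 0) stop("ROI extents must be positive",
                                      call. = FALSE)
  if (x < 0 || y < 0) stop("ROI origin must be non-negative", call. = FALSE)
  structure(list(x = as.integer(x), y = as.integer(y),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi")
}

#' Detection configuration
#'
#' Parameters of the ROI-threshold detector: frames are median-blurred,
#' thresholded at `intensity_threshold` (intensity above the threshold
#' maps to white 255, at or below to black 0), and the subject is detected
#' from the count of target-coloured pixels against
#' `pixel_count_threshold`.
#'
#' @param intensity_threshold Binarisation threshold, 0-255 (default 127).
#' @param blur_kernel Median-blur kernel width in pixels, odd and >= 1
#'   (default 5); 1 disables blurring.
#' @param pixel_count_threshold Minimum target-pixel count for the subject
#'   to be considered inside an ROI; a count exactly at the threshold
#'   counts as in-ROI.
#' @param target_color Colour of the subject on the background, `"black"`
#'   (default; dark mouse on white floor) or `"white"`.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(intensity_threshold = 127, blur_kernel = 5,
                             pixel_count_threshold = 100,
                             target_color = c("black", "white")) {
  if (intensity_threshold < 0 || intensity_threshold > 255)
    stop("'intensity_threshold' must be in [0, 255]", call. = FALSE)
  if (blur_kernel < 1 || blur_kernel %% 2 == 0)
    stop("'blur_kernel' must be odd and >= 1", call. = FALSE)
  if (pixel_count_threshold < 0)
    stop("'pixel_count_threshold' must be non-negative", call. = FALSE)
  structure(list(intensity_threshold = intensity_threshold,
                 blur_kernel = as.integer(blur_kernel),
                 pixel_count_threshold = pixel_count_threshold,
                 target_color = match.arg(target_color)),
            class = "detection_config")
}

.crop <- function(frame, r) {
  if (r$x + r$width > ncol(frame) || r$y + r$height > nrow(frame))
    stop("ROI extends outside the frame", call. = FALSE)
  frame[(r$y + 1):(r$y + r$height), (r$x + 1):(r$x + r$width), drop = FALSE]
}

# Median blur with replicate-padded borders. The frame is padded by the
# kernel radius with edge replication, filtered, and cropped back, so the
# border rule is pinned down independently of the filter backend.
.median_blur <- function(m, kernel) {
  if (kernel == 1) return(m)
  rad <- (kernel - 1L) %/% 2L
  ri <- pmin(pmax(seq_len(nrow(m) + 2 * rad) - rad, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2 * rad) - rad, 1L), ncol(m))
  pad <- m[ri, ci, drop = FALSE]
  f <- EBImage::medianFilter(pad / 255, rad)
  out <- round(f[(rad + 1):(rad + nrow(m)), (rad + 1):(rad + ncol(m)),
                 drop = FALSE] * 255)
  storage.mode(out) <- "integer"
  out
}

#' Binarise a frame region
#'
#' Crop to the ROI, median-blur, then threshold: intensity strictly above
#' `intensity_threshold` becomes white (255), at or below becomes black
#' (0). With `blur_kernel = 1` no smoothing is applied, so binarisation is
#' idempotent on already-binary input.
#'
#' @param frame Integer matrix of 8-bit intensities (rows = y, cols = x).
#' @param roi Optional [roi()]; default is the whole frame.
#' @param config A [detection_config()].
#' @return Binary integer matrix with values 0 and 255.
#' @export
binarize <- function(frame, roi = NULL, config = detection_config()) {
  stopifnot(is.matrix(frame))
  if (any(frame < 0 | frame > 255)) stop("frame values must be in [0, 255]",
                                         call. = FALSE)
  m <- if (is.null(roi)) frame else .crop(frame, roi)
  if (config$blur_kernel > min(dim(m)))
    stop("blur kernel larger than the ROI", call. = FALSE)
  m <- .median_blur(m, config$blur_kernel)
  out <- ifelse(m > config$intensity_threshold, 255L, 0L)
  storage.mode(out) <- "integer"
  out
}

#' Count target-coloured pixels in a binary mask
#'
#' @param mask Binary matrix with values 0 and 255 (e.g. from
#'   [binarize()]).
#' @param target_color `"black"` counts zeros, `"white"` counts 255s.
#' @return Integer pixel count.
#' @export
count_target_pixels <- function(mask, target_color = c("black", "white")) {
  target_color <- match.arg(target_color)
  if (!all(mask %in% c(0L, 255L)))
    stop("mask is not binary (values must be 0 or 255)", call. = FALSE)
  if (target_color == "black") sum(mask == 0L) else sum(mask == 255L)
}

#' Light-dark chamber rule
#'
#' The camera images only the light box. If the target-pixel count in the
#' ROI reaches the pixel threshold the subject is visible, hence in the
#' light chamber; below the threshold it is out of view, hence in the dark
#' chamber. A count exactly at the threshold counts as in-ROI.
#'
#' @param target_count Target-pixel count from [count_target_pixels()].
#' @param pixel_count_threshold Detection threshold (count >= threshold
#'   means in-ROI).
#' @return `"light"` or `"dark"` (vectorised over `target_count`).
#' @export
classify_light_dark <- function(target_count, pixel_count_threshold) {
  if (any(target_count < 0)) stop("counts must be non-negative", call. = FALSE)
  ifelse(target_count >= pixel_count_threshold, "light", "dark")
}

#' Three-chamber rule with side memory
#'
#' The camera images the middle chamber, split into a left and a right
#' ROI. If either ROI's target-pixel count reaches its threshold the
#' subject is in the middle chamber and the side memory records which ROI
#' it occupies (the fuller one when both trigger). If both counts are
#' below threshold the subject has left the middle chamber towards the
#' side recorded in memory; with no memory yet the position is
#' `"undetermined"` rather than guessed.
#'
#' @param count_left,count_right Target-pixel counts of the two ROIs.
#' @param thresholds Length-2 numeric `(left, right)` pixel thresholds.
#' @param previous_side `"left"`, `"right"` or `"unknown"`: the last
#'   remembered ROI side.
#' @return List with `chamber` (`"middle"`, `"left"`, `"right"` or
#'   `"undetermined"`) and `side_memory` (updated memory).
#' @export
classify_three_chamber <- function(count_left, count_right, thresholds,
                                   previous_side = "unknown") {
  stopifnot(length(thresholds) == 2)
  if (!previous_side %in% c("left", "right", "unknown"))
    stop("'previous_side' must be left, right or unknown", call. = FALSE)
  in_left <- count_left >= thresholds[1]
  in_right <- count_right >= thresholds[2]
  if (in_left || in_right) {
    side <- if (in_left && in_right) {
      if (count_right > count_left) "right" else "left"
    } else if (in_left) "left" else "right"
    list(chamber = "middle", side_memory = side)
  } else if (previous_side == "unknown") {
    list(chamber = "undetermined", side_memory = "unknown")
  } else {
    list(chamber = previous_side, side_memory = previous_side)
  }
}

#' Centroid of the target pixels in a binary mask
#'
#' Arithmetic mean of the target pixels' image coordinates (`x` = column,
#' `y` = row, 0-based, origin top-left), in float pixels.
#'
#' @inheritParams count_target_pixels
#' @return Named numeric `c(x, y)`, or `c(NA, NA)` when the mask holds no
#'   target pixel.
#' @export
mask_centroid <- function(mask, target_color = c("black", "white")) {
  target_color <- match.arg(target_color)
  if (!all(mask %in% c(0L, 255L)))
    stop("mask is not binary (values must be 0 or 255)", call. = FALSE)
  hit <- which(mask == if (target_color == "black") 0L else 255L,
               arr.ind = TRUE)
  if (nrow(hit) == 0) return(c(x = NA_real_, y = NA_real_))
  c(x = mean(hit[, "col"]) - 1, y = mean(hit[, "row"]) - 1)
}

#' Centroid trajectory container
#'
#' @param x,y Per-frame centroid coordinates in pixels (NA where the
#'   subject was not detected).
#' @param fps Frame rate, frames per second (> 0).
#' @param mm_per_px Spatial scale, millimetres per pixel (> 0); this must
#'   come from the user's arena calibration.
#' @return A data frame of class `trajectory` with columns `frame`,
#'   `x_px`, `y_px` and attributes `fps`, `mm_per_px`.
#' @export
trajectory <- function(x, y, fps, mm_per_px) {
  if (fps <= 0 || mm_per_px <= 0)
    stop("'fps' and 'mm_per_px' must be positive", call. = FALSE)
  stopifnot(length(x) == length(y))
  out <- data.frame(frame = seq_along(x) - 1L, x_px = x, y_px = y)
  class(out) <- c("trajectory", "data.frame")
  attr(out, "fps") <- fps
  attr(out, "mm_per_px") <- mm_per_px
  out
}

#' Locomotion metrics from a centroid trajectory
#'
#' Total path length and mean speed from per-frame centroid displacements.
#' Frames without a detected centroid are bridged: the displacement is
#' measured from the last detected position to the next one. Elapsed time
#' runs from the first to the last detected frame.
#'
#' @param traj A [trajectory()] with at least two detected centroids.
#' @return List with `distance_m` (metres) and `mean_speed_mm_s` (mm/s).
#' @export
locomotion_metrics <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  ok <- !is.na(traj$x_px) & !is.na(traj$y_px)
  if (sum(ok) < 2)
    stop("need at least two detected centroids", call. = FALSE)
  x <- traj$x_px[ok]; y <- traj$y_px[ok]; f <- traj$frame[ok]
  step_px <- sqrt(diff(x)^2 + diff(y)^2)
  dist_mm <- sum(step_px) * attr(traj, "mm_per_px")
  elapsed <- (f[length(f)] - f[1]) / attr(traj, "fps")
  list(distance_m = dist_mm / 1000, mean_speed_mm_s = dist_mm / elapsed)
}

#' Per-frame chamber labels over time
#'
#' @param labels Character vector of per-frame chamber labels; frames the
#'   detector could not resolve are `"undetermined"`.
#' @param fps Frame rate (> 0).
#' @return An object of class `chamber_timeline`.
#' @export
chamber_timeline <- function(labels, fps) {
  if (fps <= 0) stop("'fps' must be positive", call. = FALSE)
  structure(list(labels = as.character(labels), fps = fps),
            class = "chamber_timeline")
}

#' Time spent per chamber
#'
#' Each frame contributes `1 / fps` seconds to its chamber. Undetermined
#' frames are accumulated separately and excluded from the fraction
#' denominator, so the reported fractions are over resolved frames only.
#'
#' @param timeline A [chamber_timeline()].
#' @return List with `seconds` (named, per chamber), `fractions` (named,
#'   summing to 1 over resolved chambers), `undetermined_s` and `total_s`.
#' @export
chamber_times <- function(timeline) {
  stopifnot(inherits(timeline, "chamber_timeline"))
  lab <- timeline$labels
  dt <- 1 / timeline$fps
  und <- sum(lab == "undetermined") * dt
  lab <- lab[lab != "undetermined"]
  secs <- if (length(lab)) dt * table(lab) else table(character(0))
  secs <- stats::setNames(as.numeric(secs), names(secs))
  fr <- if (length(secs) && sum(secs) > 0) secs / sum(secs) else secs
  list(seconds = secs, fractions = fr, undetermined_s = und,
       total_s = length(timeline$labels) * dt)
}

#' Read / write a plain PGM image
#'
#' Minimal PGM support for frame fixtures: reads P2 (ASCII) and P5
#' (binary, maxval <= 255) files, writes P2.
#'
#' @param path File path.
#' @param frame Integer matrix of 8-bit intensities.
#' @return `read_pgm` returns the integer matrix; `write_pgm` returns
#'   `path` invisibly.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file", call. = FALSE)
  tokens <- character(0)
  buf <- character(0)
  # read header tokens (width, height, maxval), skipping comments
  while (length(tokens) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0 || nchar(ch) == 0) stop("truncated PGM", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (!length(ch) || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxv <- as.integer(tokens[3])
  if (maxv > 255) stop("only 8-bit PGM supported", call. = FALSE)
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    as.integer(scan(con, what = integer(), n = w * h, quiet = TRUE))
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(frame, path) {
  stopifnot(is.matrix(frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(frame), nrow(frame)), "255"), con)
  utils::write.table(frame, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
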