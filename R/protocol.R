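#' One phase of a stimulation protocol
#'
#' A phase is a stimulation period followed by a rest period, repeated
#' `repeats` times. During stimulation the H-bridge either alternates field
#' direction every half-period (`bidirectional`) or gates a single
#' direction on and off at 50% duty (`unidirectional`). `dead_time` is the
#' enforced both-switches-off interval inserted before every direction
#' change to prevent H-bridge shoot-through; it must be shorter than the
#' half-period.
#'
#' @param stim_duration Stimulation time per repeat, seconds (>= 0).
#' @param rest_duration Rest time per repeat, seconds (>= 0).
#' @param frequency Field frequency, Hz (> 0 when `stim_duration > 0`).
#' @param dead_time Dead time, seconds (default 1 ms).
#' @param mode `"bidirectional"` (default) or `"unidirectional"`.
#' @param repeats Number of stim+rest cycles (>= 1).
#' @return An object of class `protocol_phase`.
#' @export
protocol_phase <- function(stim_duration, rest_duration = 0, frequency = 10,
                           dead_time = 0.001,
                           mode = c("bidirectional", "unidirectional"),
                           repeats = 1) {
  mode <- match.arg(mode)
  if (stim_duration < 0 || rest_duration < 0)
    stop("durations must be non-negative", call. = FALSE)
  if (stim_duration > 0 && frequency <= 0)
    stop("'frequency' must be positive when stimulating", call. = FALSE)
  if (dead_time < 0) stop("'dead_time' must be non-negative", call. = FALSE)
  if (stim_duration > 0 && dead_time >= 1 / (2 * frequency))
    stop(sprintf("dead_time (%g s) must be below the half-period (%g s)",
                 dead_time, 1 / (2 * frequency)), call. = FALSE)
  if (repeats < 1) stop("'repeats' must be >= 1", call. = FALSE)
  structure(list(stim_duration = stim_duration, rest_duration = rest_duration,
                 frequency = frequency, dead_time = dead_time, mode = mode,
                 repeats = as.integer(repeats)),
            class = "protocol_phase")
}

#' A stimulation protocol
#'
#' An ordered list of [protocol_phase()]s executed back to back, for up to
#' six independently driven channels (the console drives at most six
#' solenoids).
#'
#' @param phases A `protocol_phase` or list of them.
#' @param channel_count Number of driven channels, 1-6.
#' @return An object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(phases, channel_count = 1) {
  if (inherits(phases, "protocol_phase")) phases <- list(phases)
  ok <- vapply(phases, inherits, logical(1), what = "protocol_phase")
  if (length(phases) && !all(ok))
    stop("'phases' must be protocol_phase objects", call. = FALSE)
  if (channel_count < 1 || channel_count > 6)
    stop("'channel_count' must be between 1 and 6", call. = FALSE)
  structure(list(phases = phases, channel_count = as.integer(channel_count)),
            class = "stimulation_protocol")
}

#' Intended stimulation timeline of a protocol
#'
#' The piecewise-constant commanded-ON timeline, ignoring any gating: each
#' repeat contributes a stimulation interval followed by a rest interval,
#' phases concatenate without gap or overlap, and every repeat begins with
#' the stimulation period. Total ON duration equals the sum of
#' `stim_duration * repeats` over phases.
#'
#' @param protocol A [stimulation_protocol()].
#' @return Data frame with columns `start_s`, `end_s`, `stim_on`.
#' @export
protocol_timeline <- function(protocol) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  start <- numeric(0); end <- numeric(0); on <- logical(0)
  t <- 0
  for (ph in protocol$phases) {
    for (k in seq_len(ph$repeats)) {
      if (ph$stim_duration > 0) {
        start <- c(start, t); end <- c(end, t + ph$stim_duration)
        on <- c(on, TRUE)
        t <- t + ph$stim_duration
      }
      if (ph$rest_duration > 0) {
        start <- c(start, t); end <- c(end, t + ph$rest_duration)
        on <- c(on, FALSE)
        t <- t + ph$rest_duration
      }
    }
  }
  data.frame(start_s = start, end_s = end, stim_on = on)
}

#' Total protocol duration in seconds
#' @param protocol A [stimulation_protocol()].
#' @return Duration in seconds.
#' @export
protocol_duration <- function(protocol) {
  sum(vapply(protocol$phases,
             function(ph) ph$repeats * (ph$stim_duration + ph$rest_duration),
             numeric(1)))
}

#' Compile a protocol into H-bridge pin-pair events
#'
#' Turns a protocol into the channel's switching timeline. Events are state
#' changes `(time_s, pin_a, pin_b)`; `pin_a` high drives the forward
#' direction, `pin_b` high the reverse, both low is off. In bidirectional
#' mode every half-period opens with a both-low dead-time gap, then holds
#' the (alternating) direction for `1/(2f) - dead_time`; unidirectional
#' mode emits an on/off square wave at 50% duty. Rest periods are all-off.
#' By construction `pin_a` and `pin_b` are never simultaneously high and
#' every direction change is separated by at least `dead_time`.
#'
#' Stimulation windows are compiled in whole half-periods (whole periods
#' for unidirectional mode); a fractional trailing remainder is left off.
#'
#' @param protocol A [stimulation_protocol()].
#' @param channel Channel index (1-based), recorded in the events.
#' @return A data frame of class `waveform_events` with columns `time_s`,
#'   `channel`, `pin_a`, `pin_b`, plus attribute `t_end` (total protocol
#'   duration).
#' @export
compile_waveform <- function(protocol, channel = 1) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  if (channel < 1 || channel > protocol$channel_count)
    stop("'channel' outside the protocol's channel_count", call. = FALSE)
  times <- numeric(0); pa <- integer(0); pb <- integer(0)
  emit <- function(t, a, b) {
    times <<- c(times, t); pa <<- c(pa, a); pb <<- c(pb, b)
  }
  t <- 0
  emit(0, 0L, 0L)
  for (ph in protocol$phases) {
    for (k in seq_len(ph$repeats)) {
      if (ph$stim_duration > 0) {
        if (ph$mode == "bidirectional") {
          half <- 1 / (2 * ph$frequency)
          n_half <- floor(ph$stim_duration / half + 1e-9)
          for (h in seq_len(n_half)) {
            t_h <- t + (h - 1) * half
            if (ph$dead_time > 0) emit(t_h, 0L, 0L)
            if (h %% 2 == 1) emit(t_h + ph$dead_time, 1L, 0L)
            else             emit(t_h + ph$dead_time, 0L, 1L)
          }
          # the whole-half-period count may overshoot stim_duration by a
          # rounding sliver; never emit past the stimulation window
          emit(t + min(ph$stim_duration, n_half * half), 0L, 0L)
        } else {
          period <- 1 / ph$frequency
          n_cyc <- floor(ph$stim_duration / period + 1e-9)
          for (h in seq_len(n_cyc)) {
            t_c <- t + (h - 1) * period
            emit(t_c, 1L, 0L)
            emit(t_c + period / 2, 0L, 0L)
          }
        }
        t <- t + ph$stim_duration
      }
      t <- t + ph$rest_duration
    }
  }
  # coincident events (e.g. a block-end off meeting the next repeat's
  # first edge with zero dead time) resolve to the later state, then
  # consecutive duplicate states collapse so times strictly increase
  last <- !duplicated(times, fromLast = TRUE)
  times <- times[last]; pa <- pa[last]; pb <- pb[last]
  keep <- c(TRUE, pa[-1] != pa[-length(pa)] | pb[-1] != pb[-length(pb)])
  out <- data.frame(time_s = times[keep], channel = as.integer(channel),
                    pin_a = pa[keep], pin_b = pb[keep])
  class(out) <- c("waveform_events", "data.frame")
  attr(out, "t_end") <- t
  out
}

#' Energized intervals and total energized time of a compiled waveform
#'
#' `waveform_intervals` returns every maximal interval during which a
#' direction pin is high; `energized_time` is their summed duration. For a
#' bidirectional phase the conservation law
#' `energized = stim_time - transitions * dead_time` holds by construction.
#'
#' @param events A `waveform_events` data frame from [compile_waveform()].
#' @return `waveform_intervals`: data frame `start_s`, `end_s`,
#'   `direction` (`"forward"`/`"reverse"`); `energized_time`: seconds.
#' @export
waveform_intervals <- function(events) {
  stopifnot(inherits(events, "waveform_events"))
  t_end <- attr(events, "t_end")
  on <- events$pin_a == 1L | events$pin_b == 1L
  starts <- which(on)
  if (!length(starts))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      direction = character(0)))
  ends <- vapply(starts, function(i) {
    if (i < nrow(events)) events$time_s[i + 1] else t_end
  }, numeric(1))
  data.frame(start_s = events$time_s[starts], end_s = ends,
             direction = ifelse(events$pin_a[starts] == 1L,
                                "forward", "reverse"))
}

#' @rdname waveform_intervals
#' @export
energized_time <- function(events) {
  iv <- waveform_intervals(events)
  sum(iv$end_s - iv$start_s)
}

#' Check timing feasibility of a protocol
#'
#' With sensor detection enabled the firmware's 20 Hz polling plus the two
#' extra per-cycle reads keep switching timing stable only below 200 Hz;
#' with sensing disabled the output stage itself remains stable at higher
#' rates. The 200 Hz bound is applied as a strict inequality.
#'
#' @param protocol A [stimulation_protocol()].
#' @param sensing_enabled Logical; is continuous sensor detection active?
#' @return An object of class `timing_report`: list with
#'   `requested_frequency` (max over stimulating phases, Hz),
#'   `sensing_enabled`, `feasible`, `note`.
#' @export
validate_protocol <- function(protocol, sensing_enabled = TRUE) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  freqs <- vapply(protocol$phases, function(ph)
    if (ph$stim_duration > 0) ph$frequency else NA_real_, numeric(1))
  fmax <- if (all(is.na(freqs))) 0 else max(freqs, na.rm = TRUE)
  if (isTRUE(sensing_enabled) && fmax >= 200) {
    feasible <- FALSE
    note <- sprintf(paste0(
      "%g Hz with sensor detection enabled: per-cycle sensor reads ",
      "perturb switching timing at 200 Hz and above; disable sensing or ",
      "stay below 200 Hz"), fmax)
  } else {
    feasible <- TRUE
    note <- "timing stable for the requested configuration"
  }
  structure(list(requested_frequency = fmax,
                 sensing_enabled = isTRUE(sensing_enabled),
                 feasible = feasible, note = note),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf("%g Hz, sensing %s: %s\n  %s\n", x$requested_frequency,
              if (x$sensing_enabled) "on" else "off",
              if (x$feasible) "feasible" else "NOT feasible", x$note))
  invisible(x)
}

#' Read / write a protocol table
#'
#' CSV mirror of the protocol page: one row per phase with columns
#' `stim_s`, `rest_s`, `frequency_hz`, `dead_time_s`, `mode`, `repeats`.
#'
#' @param protocol A [stimulation_protocol()].
#' @param path File path.
#' @param channel_count Channels for the reconstructed protocol.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns a [stimulation_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  df <- do.call(rbind, lapply(protocol$phases, function(ph)
    data.frame(stim_s = ph$stim_duration, rest_s = ph$rest_duration,
               frequency_hz = ph$frequency, dead_time_s = ph$dead_time,
               mode = ph$mode, repeats = ph$repeats)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path, channel_count = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stim_s", "rest_s", "frequency_hz", "dead_time_s", "mode",
            "repeats")
  if (!all(need %in% names(df)))
    stop("protocol file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  phases <- lapply(seq_len(nrow(df)), function(i)
    protocol_phase(df$stim_s[i], df$rest_s[i], df$frequency_hz[i],
                   df$dead_time_s[i], df$mode[i], df$repeats[i]))
  stimulation_protocol(phases, channel_count)
}
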