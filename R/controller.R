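#' Sensor gating thresholds
#'
#' Limits applied to live sensor feedback during a run. Stimulation is
#' gated off while any enabled sensor is at or beyond its limit (ties
#' count as a breach). The magnetic channel takes a lower and an upper
#' limit; temperature, sound and vibration take upper limits only. All
#' limits must lie within the sensor detection ranges of [sensor_table()].
#'
#' @param magnetic Length-2 numeric `(lower, upper)` in mT.
#' @param temperature Upper limit, degC.
#' @param sound Upper limit, dB.
#' @param vibration Upper limit, g.
#' @param enabled Named logical vector selecting active sensors; names
#'   from `magnetic`, `temperature`, `sound`, `vibration`.
#' @return An object of class `sensor_thresholds`.
#' @export
sensor_thresholds <- function(magnetic = c(-67, 67), temperature = 40,
                              sound = 90, vibration = 2,
                              enabled = c(magnetic = TRUE, temperature = TRUE,
                                          sound = TRUE, vibration = TRUE)) {
  stopifnot(length(magnetic) == 2, magnetic[1] < magnetic[2])
  check <- function(kind, vals) {
    rg <- .sensor_range(kind)
    if (any(vals < rg[1] | vals > rg[2]))
      stop(sprintf("%s limit outside the sensor detection range [%g, %g]",
                   kind, rg[1], rg[2]), call. = FALSE)
  }
  check("magnetic", magnetic); check("temperature", temperature)
  check("sound", sound); check("vibration", vibration)
  kinds <- c("magnetic", "temperature", "sound", "vibration")
  en <- stats::setNames(rep(TRUE, 4), kinds)
  en[names(enabled)] <- enabled
  structure(list(magnetic = magnetic, temperature = temperature,
                 sound = sound, vibration = vibration, enabled = en),
            class = "sensor_thresholds")
}

#' Controller configuration
#'
#' @param poll_rate Sensor/gate polling rate, Hz (default 20, the
#'   firmware's continuous detection rate).
#' @param extra_reads_per_cycle Extra sensor reads scheduled per
#'   stimulation cycle at direction changes (default 2).
#' @param breach_action `"pause"` (resume when readings return within
#'   limits) or `"abort"` (latch stimulation off for the rest of the run).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(poll_rate = 20, extra_reads_per_cycle = 2,
                              breach_action = c("pause", "abort")) {
  if (poll_rate <= 0) stop("'poll_rate' must be positive", call. = FALSE)
  structure(list(poll_rate = poll_rate,
                 extra_reads_per_cycle = as.integer(extra_reads_per_cycle),
                 breach_action = match.arg(breach_action)),
            class = "controller_config")
}

#' Evaluate the three stimulation gates
#'
#' Stimulation is commanded if and only if the protocol is in an ON
#' interval, all enabled sensors are within limits, and the subject is in
#' the target area: a plain conjunction, vectorised over polls.
#'
#' @param protocol_on,sensors_ok,in_target Logical vectors (recycled to a
#'   common length).
#' @return Logical vector: stimulate or not.
#' @export
evaluate_gates <- function(protocol_on, sensors_ok, in_target) {
  n <- max(length(protocol_on), length(sensors_ok), length(in_target))
  rep_len(as.logical(protocol_on), n) &
    rep_len(as.logical(sensors_ok), n) &
    rep_len(as.logical(in_target), n)
}

# latest-value lookup: value of the most recent reading at or before each
# poll time; NA (and stale = TRUE) where none or where the reading is older
# than max_age.
.latest_at <- function(read_times, read_values, t_poll, max_age) {
  idx <- findInterval(t_poll + 1e-12, read_times)
  val <- ifelse(idx >= 1, read_values[pmax(idx, 1)], NA_real_)
  age <- t_poll - ifelse(idx >= 1, read_times[pmax(idx, 1)], -Inf)
  list(value = val, stale = idx < 1 | age > max_age + 1e-12)
}

#' Run the closed-loop controller over recorded streams
#'
#' Sampled-control emulation of the rig's gating engine: at every poll
#' instant (`poll_rate` Hz) the controller evaluates the three gates
#' against the protocol timeline, the most recent sensor readings and the
#' most recent tracked position, and commands stimulation only when all
#' three hold. A sensor at or beyond a limit, or one whose latest reading
#' is older than two poll intervals (stale, fail-safe), gates stimulation
#' off within one poll interval. With `breach_action = "pause"` the
#' stimulation resumes as soon as readings return within limits and the
#' other gates hold; with `"abort"` a breach latches stimulation off.
#'
#' @param protocol A [stimulation_protocol()].
#' @param sensor_stream Data frame `time_s`, `kind`, `value` with kinds
#'   from [sensor_table()].
#' @param position_stream Data frame `time_s`, `chamber`, `in_target`.
#' @param thresholds A [sensor_thresholds()].
#' @param config A [controller_config()].
#' @return An `experiment_log`: data frame with one row per poll and
#'   columns `time_s`, `mf_mT`, `temp_c`, `sound_db`, `accel_g`,
#'   `stim_state` (`"on"`/`"off"`), `chamber`, `in_target`, plus the gate
#'   columns `protocol_on` and `sensors_ok`.
#' @export
run_closed_loop <- function(protocol, sensor_stream, position_stream,
                            thresholds = sensor_thresholds(),
                            config = controller_config()) {
  stopifnot(inherits(protocol, "stimulation_protocol"),
            inherits(thresholds, "sensor_thresholds"),
            inherits(config, "controller_config"))
  duration <- protocol_duration(protocol)
  if (nrow(sensor_stream) == 0 || max(sensor_stream$time_s) < duration - 1e-9)
    stop("sensor stream ends before the protocol does", call. = FALSE)
  if (nrow(position_stream) == 0 ||
      max(position_stream$time_s) < duration - 1e-9)
    stop("position stream ends before the protocol does", call. = FALSE)

  n <- round(duration * config$poll_rate)
  t_poll <- (seq_len(n) - 1) / config$poll_rate
  max_age <- 2 / config$poll_rate

  tl <- protocol_timeline(protocol)
  on_tl <- tl[tl$stim_on, , drop = FALSE]
  protocol_on <- rep(FALSE, n)
  for (i in seq_len(nrow(on_tl)))
    protocol_on <- protocol_on |
      (t_poll >= on_tl$start_s[i] - 1e-12 & t_poll < on_tl$end_s[i] - 1e-12)

  kinds <- c("magnetic", "temperature", "sound", "vibration")
  latest <- lapply(kinds, function(k) {
    s <- sensor_stream[sensor_stream$kind == k, , drop = FALSE]
    s <- s[order(s$time_s), , drop = FALSE]
    .latest_at(s$time_s, s$value, t_poll, max_age)
  })
  names(latest) <- kinds

  breach_of <- function(kind) {
    lv <- latest[[kind]]
    if (!thresholds$enabled[[kind]]) return(rep(FALSE, n))
    lim_hit <- if (kind == "magnetic") {
      lv$value <= thresholds$magnetic[1] | lv$value >= thresholds$magnetic[2]
    } else {
      lv$value >= thresholds[[kind]]
    }
    lv$stale | (!is.na(lv$value) & lim_hit)
  }
  breach <- Reduce(`|`, lapply(kinds, breach_of))
  sensors_ok <- !breach
  if (config$breach_action == "abort" && any(breach))
    sensors_ok[seq_len(n) >= which(breach)[1]] <- FALSE

  ps <- position_stream[order(position_stream$time_s), , drop = FALSE]
  pidx <- findInterval(t_poll + 1e-12, ps$time_s)
  in_target <- ifelse(pidx >= 1, as.logical(ps$in_target[pmax(pidx, 1)]),
                      FALSE)
  chamber <- ifelse(pidx >= 1, as.character(ps$chamber[pmax(pidx, 1)]),
                    NA_character_)

  stim <- evaluate_gates(protocol_on, sensors_ok, in_target)
  val <- function(k) round(latest[[k]]$value, 6)
  out <- data.frame(
    time_s = t_poll, mf_mT = val("magnetic"), temp_c = val("temperature"),
    sound_db = val("sound"), accel_g = val("vibration"),
    stim_state = ifelse(stim, "on", "off"), chamber = chamber,
    in_target = in_target, protocol_on = protocol_on,
    sensors_ok = sensors_ok, stringsAsFactors = FALSE)
  class(out) <- c("experiment_log", "data.frame")
  out
}

#' Write / read an experiment log as CSV
#'
#' Lossless CSV round trip of the controller log. `read_log` validates the
#' schema and that poll times are strictly increasing, reporting the first
#' offending row on failure.
#'
#' @param log An `experiment_log` from [run_closed_loop()].
#' @param path File path.
#' @return `write_log` returns `path` invisibly; `read_log` the log.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "experiment_log"))
  df <- as.data.frame(log)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "mf_mT", "temp_c", "sound_db", "accel_g", "stim_state",
            "chamber", "in_target", "protocol_on", "sensors_ok")
  if (!all(need %in% names(df)))
    stop("experiment log must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) > 1) {
    bad <- which(diff(df$time_s) <= 0)
    if (length(bad))
      stop(sprintf("log times not strictly increasing at row %d", bad[1] + 1),
           call. = FALSE)
  }
  if (!all(df$stim_state %in% c("on", "off")))
    stop(sprintf("invalid stim_state at row %d",
                 which(!df$stim_state %in% c("on", "off"))[1]), call. = FALSE)
  class(df) <- c("experiment_log", "data.frame")
  df
}
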