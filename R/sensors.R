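#' Sensor catalogue
#'
#' The four feedback sensors the rig integrates, with supply requirements
#' and detection ranges. These ranges bound both threshold settings and
#' the clipping applied by the voltage conversions.
#'
#' @return A data frame with one row per sensor kind: `kind`,
#'   `part_number`, `supply_v_min`, `supply_v_max`, `supply_ma`,
#'   `range_min`, `range_max`, `unit`.
#' @export
sensor_table <- function() {
  data.frame(
    kind = c("magnetic", "temperature", "sound", "vibration"),
    part_number = c("SS495A", "TMP36GT9Z", "SEN0232", "ADXL345"),
    supply_v_min = c(4.5, 2.7, 3.3, 2.0),
    supply_v_max = c(10.5, 5.0, 5.0, 3.6),
    supply_ma = c(7, 0.05, 14, 0.14),
    range_min = c(-67, -40, 30, -16),
    range_max = c(67, 125, 130, 16),
    unit = c("mT", "degC", "dB", "g"),
    stringsAsFactors = FALSE
  )
}

.sensor_range <- function(kind) {
  tab <- sensor_table()
  row <- tab[tab$kind == kind, ]
  if (nrow(row) != 1) stop("unknown sensor kind: ", kind, call. = FALSE)
  c(row$range_min, row$range_max)
}

.clip_to_range <- function(value, kind) {
  rg <- .sensor_range(kind)
  clipped <- value < rg[1] | value > rg[2]
  out <- pmin(pmax(value, rg[1]), rg[2])
  attr(out, "clipped") <- clipped
  out
}

#' Convert a ratiometric Hall-sensor voltage to field density
#'
#' The Hall element is ratiometric: the null point sits at half the supply
#' voltage and the sensitivity is 3.125 mV per gauss (31.25 mV/mT) at a
#' 5 V supply, scaling proportionally with supply. Output is clipped to
#' the sensor's +/- 67 mT detection range, with a `clipped` attribute
#' flagging saturated samples. The transfer constants are nominal part
#' behaviour and should be treated as replaceable calibration values.
#'
#' @param voltage Sensor output voltage(s), V (within `[0, supply]`).
#' @param supply Supply voltage, V (> 0).
#' @return Field density in millitesla with logical attribute `clipped`.
#' @export
convert_hall <- function(voltage, supply = 5) {
  if (supply <= 0) stop("'supply' must be positive", call. = FALSE)
  if (any(voltage < 0 | voltage > supply))
    stop("'voltage' must lie within [0, supply]", call. = FALSE)
  sens <- 0.03125 * supply / 5   # V per mT, ratiometric
  .clip_to_range((voltage - supply / 2) / sens, "magnetic")
}

#' Convert sensor voltages to physical units
#'
#' `convert_temperature` applies the 10 mV/degC transfer with 0.5 V offset
#' at 0 degC; `convert_sound` applies the 50 dB/V linear mapping. Both
#' clip to the sensor detection range with a `clipped` attribute. As for
#' [convert_hall()], the constants are nominal calibration values.
#'
#' @param voltage Sensor output voltage(s), V (>= 0).
#' @return Physical value(s) with logical attribute `clipped`.
#' @export
convert_temperature <- function(voltage) {
  if (any(voltage < 0)) stop("'voltage' must be non-negative", call. = FALSE)
  .clip_to_range((voltage - 0.5) / 0.010, "temperature")
}

#' @rdname convert_temperature
#' @export
convert_sound <- function(voltage) {
  if (any(voltage < 0)) stop("'voltage' must be non-negative", call. = FALSE)
  .clip_to_range(voltage * 50, "sound")
}
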