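# Nominal resistance of solid copper wire at 20 degrees C, ohm per metre.
.awg_ohm_per_m <- c(
  `10` = 0.003276, `12` = 0.005211, `14` = 0.008286, `16` = 0.013174,
  `18` = 0.020948, `20` = 0.033292, `22` = 0.052946, `24` = 0.084197,
  `26` = 0.133890, `28` = 0.212872, `30` = 0.338496
)

#' Estimate winding resistance from the AWG wire table
#'
#' Wire length is `turns` times the mean-turn circumference (mean radius =
#' inner radius + radial build / 2); resistance is length times the nominal
#' per-metre resistance of the gauge. This is a nominal-wire estimator:
#' as-built coils routinely deviate through packing, lead length and
#' temperature.
#'
#' @param coil A [coil_spec()] with `wire_gauge` set, unless `ohm_per_m`
#'   is supplied directly.
#' @param ohm_per_m Optional explicit per-metre resistance, overriding the
#'   gauge table.
#' @return Estimated resistance in ohms.
#' @export
estimate_resistance <- function(coil, ohm_per_m = NULL) {
  stopifnot(inherits(coil, "coil_spec"))
  if (is.null(ohm_per_m)) {
    if (is.null(coil$wire_gauge))
      stop("set 'wire_gauge' on the coil or supply 'ohm_per_m'", call. = FALSE)
    key <- as.character(coil$wire_gauge)
    if (!key %in% names(.awg_ohm_per_m))
      stop(sprintf("unknown wire gauge %s; supported AWG gauges: %s",
                   key, paste(names(.awg_ohm_per_m), collapse = ", ")),
           call. = FALSE)
    ohm_per_m <- .awg_ohm_per_m[[key]]
  }
  mean_r <- coil$inner_radius + coil$radial_build / 2
  coil$turns * 2 * pi * mean_r * ohm_per_m
}

#' Estimate inductance with Wheeler's multilayer approximation
#'
#' \deqn{L \approx \frac{31.6\, N^2 a^2}{6a + 9b + 10c}\ \mu\mathrm{H}}
#' with mean radius \eqn{a}, axial length \eqn{b} and radial build \eqn{c}
#' in metres. Accuracy is a few percent for ordinary multilayer air coils;
#' like [estimate_resistance()] this is an engineering estimator, not a
#' field computation.
#'
#' @param coil A [coil_spec()].
#' @return Estimated inductance in henries.
#' @export
estimate_inductance <- function(coil) {
  stopifnot(inherits(coil, "coil_spec"))
  a <- coil$inner_radius + coil$radial_build / 2
  b <- coil$axial_length
  cc <- coil$radial_build
  31.6 * coil$turns^2 * a^2 / (6 * a + 9 * b + 10 * cc) * 1e-6
}
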