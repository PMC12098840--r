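#' Physical constants
#'
#' Vacuum permeability, 4 * pi * 1e-7 T m/A. Used throughout the field
#' engine; exposed so downstream code and tests share one value.
#'
#' @format A named list with element `mu0` (T m/A).
#' @export
physical_constants <- list(mu0 = 4e-7 * pi)

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("'%s' must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

#' Single circular current loop
#'
#' The elementary filament of the field engine: a circular loop of given
#' radius carrying a steady current, lying in a plane perpendicular to the
#' shared z axis.
#'
#' @param radius Loop radius in metres (> 0).
#' @param current Current in amperes. Positive current circulates
#'   counterclockwise viewed from +z.
#' @param z_position Axial position of the loop plane in metres.
#' @return An object of class `loop_spec`.
#' @export
loop_spec <- function(radius, current = 1, z_position = 0) {
  stop_if_not_scalar_pos(radius, "radius")
  stopifnot(is.numeric(current), length(current) == 1L,
            is.numeric(z_position), length(z_position) == 1L)
  structure(list(radius = radius, current = current, z_position = z_position),
            class = "loop_spec")
}

#' Axisymmetric thick coil
#'
#' A multi-turn winding with rectangular cross-section, coaxial with the z
#' axis. The winding occupies radii `[inner_radius, inner_radius +
#' radial_build]` and the axial interval `axial_center +/- axial_length/2`.
#' Current is assumed uniformly distributed over the cross-section, the
#' same assumption a 2-D axisymmetric finite-element model makes.
#'
#' @param inner_radius Inner (bore) radius in metres.
#' @param radial_build Radial thickness of the winding in metres.
#' @param axial_length Axial extent of the winding in metres.
#' @param turns Number of turns (>= 1).
#' @param current Current per turn in amperes.
#' @param axial_center Axial position of the winding centre in metres.
#' @param wire_gauge Optional AWG gauge (integer) used by
#'   [estimate_resistance()] and [estimate_inductance()].
#' @return An object of class `coil_spec`.
#' @export
coil_spec <- function(inner_radius, radial_build, axial_length, turns,
                      current, axial_center = 0, wire_gauge = NULL) {
  stop_if_not_scalar_pos(inner_radius, "inner_radius")
  stop_if_not_scalar_pos(radial_build, "radial_build")
  stop_if_not_scalar_pos(axial_length, "axial_length")
  if (!is.numeric(turns) || length(turns) != 1L || turns < 1)
    stop("'turns' must be >= 1", call. = FALSE)
  stopifnot(is.numeric(current), length(current) == 1L)
  if (!is.null(wire_gauge)) stopifnot(is.numeric(wire_gauge), length(wire_gauge) == 1L)
  structure(list(inner_radius = inner_radius, radial_build = radial_build,
                 axial_length = axial_length, turns = turns, current = current,
                 axial_center = axial_center, wire_gauge = wire_gauge),
            class = "coil_spec")
}

#' Coaxial array of thick coils
#'
#' An ordered stack of [coil_spec()] windings sharing one axis. Overlapping
#' axial extents are physically impossible for a real stack but are allowed
#' with a warning so exploratory configurations still evaluate.
#'
#' @param ... `coil_spec` objects, or a single list of them.
#' @return An object of class `coil_array_spec`.
#' @export
coil_array <- function(...) {
  coils <- list(...)
  if (length(coils) == 1L && is.list(coils[[1]]) &&
      !inherits(coils[[1]], "coil_spec")) coils <- coils[[1]]
  if (length(coils) == 0L) stop("coil array must contain at least one coil", call. = FALSE)
  ok <- vapply(coils, inherits, logical(1), what = "coil_spec")
  if (!all(ok)) stop("all elements must be coil_spec objects", call. = FALSE)
  if (length(coils) > 1L) {
    lo <- vapply(coils, function(cl) cl$axial_center - cl$axial_length / 2, numeric(1))
    hi <- vapply(coils, function(cl) cl$axial_center + cl$axial_length / 2, numeric(1))
    ord <- order(lo)
    if (any(lo[ord][-1] < hi[ord][-length(hi)] - 1e-12))
      warning("coil axial extents overlap", call. = FALSE)
  }
  structure(list(coils = coils), class = "coil_array_spec")
}

#' Stack equal coils along the axis with given gaps
#'
#' Convenience constructor for the arena-style apparatus: `n` identical
#' coils separated by `gaps` (length `n - 1`), centred as a whole on
#' `center`.
#'
#' @param n Number of coils.
#' @param gaps Axial gaps between successive coils, metres (length `n - 1`).
#' @param center Axial centre of the whole stack, metres.
#' @inheritParams coil_spec
#' @return A `coil_array_spec`.
#' @export
coil_stack <- function(n, gaps, inner_radius, radial_build, axial_length,
                       turns, current, center = 0, wire_gauge = NULL) {
  stopifnot(n >= 1, length(gaps) == n - 1)
  total <- n * axial_length + sum(gaps)
  z <- center - total / 2
  coils <- vector("list", n)
  for (i in seq_len(n)) {
    coils[[i]] <- coil_spec(inner_radius, radial_build, axial_length, turns,
                            current, axial_center = z + axial_length / 2,
                            wire_gauge = wire_gauge)
    z <- z + axial_length + if (i < n) gaps[i] else 0
  }
  coil_array(coils)
}

#' Rectangular air-core coil
#'
#' A winding around a rectangular cuboid core, axis along z. The inner
#' window is `inner_width x inner_height`, the outer envelope
#' `outer_width x outer_height`, and the winding extends `length` along the
#' axis. Fields are computed by discretising the winding volume into
#' rectangular filament loops (finite-segment Biot-Savart per side).
#'
#' @param inner_width,inner_height Inner window dimensions, metres.
#' @param outer_width,outer_height Outer envelope dimensions, metres.
#' @param length Axial length of the winding, metres.
#' @param turns Number of turns.
#' @param current Current per turn, amperes.
#' @param axial_center Axial centre, metres.
#' @return An object of class `rect_coil_spec`.
#' @export
rect_coil_spec <- function(inner_width, inner_height, outer_width,
                           outer_height, length, turns, current,
                           axial_center = 0) {
  stop_if_not_scalar_pos(inner_width, "inner_width")
  stop_if_not_scalar_pos(inner_height, "inner_height")
  stop_if_not_scalar_pos(length, "length")
  if (outer_width <= inner_width) stop("outer_width must exceed inner_width", call. = FALSE)
  if (outer_height <= inner_height) stop("outer_height must exceed inner_height", call. = FALSE)
  if (turns < 1) stop("'turns' must be >= 1", call. = FALSE)
  structure(list(inner_width = inner_width, inner_height = inner_height,
                 outer_width = outer_width, outer_height = outer_height,
                 length = length, turns = turns, current = current,
                 axial_center = axial_center),
            class = "rect_coil_spec")
}

#' Evaluation region for homogeneity statistics
#'
#' A cylinder (axis along z) or an axis-aligned box, used to select field
#' samples for [homogeneity()].
#'
#' @param shape `"cylinder"` or `"box"`.
#' @param center Region centre, a length-3 numeric `(x, y, z)` in metres.
#'   For axisymmetric field maps only the z component is used and the
#'   region must be on-axis.
#' @param radius Cylinder radius, metres (cylinder only).
#' @param height Cylinder height (axial extent), metres (cylinder only).
#' @param half_widths Length-3 numeric of box half-extents, metres (box only).
#' @param name Optional label used in messages.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(shape = c("cylinder", "box"), center = c(0, 0, 0),
                        radius = NULL, height = NULL, half_widths = NULL,
                        name = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(center), length(center) == 3L)
  if (shape == "cylinder") {
    stop_if_not_scalar_pos(radius, "radius")
    stop_if_not_scalar_pos(height, "height")
  } else {
    stopifnot(is.numeric(half_widths), length(half_widths) == 3L)
    if (any(half_widths <= 0)) stop("half_widths must be positive", call. = FALSE)
  }
  structure(list(shape = shape, center = center, radius = radius,
                 height = height, half_widths = half_widths,
                 name = name %||% shape),
            class = "region_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coil_spec <- function(x, ...) {
  cat(sprintf(
    "Thick coil: bore r=%g m, build %g m, length %g m @ z=%g m, %g turns x %g A\n",
    x$inner_radius, x$radial_build, x$axial_length, x$axial_center,
    x$turns, x$current))
  invisible(x)
}

#' @export
print.coil_array_spec <- function(x, ...) {
  cat(sprintf("Coaxial array of %d coils:\n", length(x$coils)))
  for (cl in x$coils) print(cl)
  invisible(x)
}
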