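#' Reference apparatus designs
#'
#' Constructors for the coil apparatuses the toolkit was designed around,
#' as used for in vitro stimulation and rodent behavioural arenas. Each
#' returns a ready-to-evaluate geometry; pass a different `current` to
#' rescale the drive.
#'
#' * `microscopy_coil()` - single thick coil for on-microscope
#'   stimulation: 3.5 cm bore (inner radius 1.75 cm), 5 cm radial build,
#'   4 cm axial length, 2000 turns of 18 AWG wire, 2.2 A.
#' * `arena10_array()` - four-coil stack for a 10 cm diameter behavioural
#'   arena: each coil 11 cm bore, 5 cm build, 4 cm length, 500 turns of
#'   12 AWG; axial gaps 1, 2, 1 cm; 6 A.
#' * `arena20_array()` - six-coil stack for a 20 cm diameter arena: each
#'   coil 21 cm bore, 4 cm build, 5 cm length, 500 turns of 12 AWG; axial
#'   gaps 1, 2, 1, 2, 1 cm; 7 A.
#' * `multiwell_coil()` - rectangular air-core coil for a 24-well culture
#'   dish: inner window 9.5 x 3.5 cm, outer envelope 12.5 x 7.5 cm, 20 cm
#'   long, 3000 turns of 18 AWG, 3.2 A.
#'
#' All stacks are centred on z = 0.
#'
#' @param current Drive current in amperes (defaults above).
#' @return A [coil_spec()], [coil_array_spec][coil_array()] or
#'   [rect_coil_spec()].
#' @name apparatus_presets
NULL

#' @rdname apparatus_presets
#' @export
microscopy_coil <- function(current = 2.2) {
  coil_spec(inner_radius = 0.0175, radial_build = 0.05, axial_length = 0.04,
            turns = 2000, current = current, wire_gauge = 18)
}

#' @rdname apparatus_presets
#' @export
arena10_array <- function(current = 6) {
  coil_stack(n = 4, gaps = c(0.01, 0.02, 0.01), inner_radius = 0.055,
             radial_build = 0.05, axial_length = 0.04, turns = 500,
             current = current, wire_gauge = 12)
}

#' @rdname apparatus_presets
#' @export
arena20_array <- function(current = 7) {
  coil_stack(n = 6, gaps = c(0.01, 0.02, 0.01, 0.02, 0.01),
             inner_radius = 0.105, radial_build = 0.04, axial_length = 0.05,
             turns = 500, current = current, wire_gauge = 12)
}

#' @rdname apparatus_presets
#' @export
multiwell_coil <- function(current = 3.2) {
  rect_coil_spec(inner_width = 0.095, inner_height = 0.035,
                 outer_width = 0.125, outer_height = 0.075,
                 length = 0.20, turns = 3000, current = current)
}
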