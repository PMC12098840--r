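#' Load a run configuration
#'
#' Reads a YAML configuration describing an apparatus, evaluation
#' regions and/or a stimulation protocol, validates it against the
#' schema, fills defaults and builds the corresponding package objects.
#' Unknown keys are rejected by name, so typos fail loudly instead of
#' silently using defaults.
#'
#' Schema (all sections optional unless a command needs them):
#' \preformatted{
#' seed: 1
#' grid_mm: 1                    # evaluation grid spacing
#' coil:                         # single thick coil ...
#'   preset: microscopy          #   one of the reference apparatuses
#'   current_a: 2.2              #   optional drive override
#' array:                        # ... or a coaxial stack
#'   preset: arena10 | arena20
#' regions:
#'   center: {shape: cylinder, radius_m: 0.05, height_m: 0.05,
#'            center_z_m: 0}
#' protocol:
#'   channel_count: 1
#'   phases:
#'     - {stim_s: 30, rest_s: 30, frequency_hz: 10, dead_time_s: 0.001,
#'        mode: bidirectional, repeats: 5}
#' }
#' A `coil` section may instead give the full geometry
#' (`inner_radius_m`, `radial_build_m`, `axial_length_m`, `turns`,
#' `current_a`, optional `axial_center_m`, `wire_gauge`).
#'
#' @param path YAML file path.
#' @return List of class `run_config` with elements `seed`, `grid_mm`,
#'   `apparatus` (coil or array spec or NULL), `regions` (named list of
#'   [region_spec()]), `protocol` ([stimulation_protocol()] or NULL).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  allowed <- c("seed", "grid_mm", "coil", "array", "regions", "protocol")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  parse_coil <- function(cc) {
    if (!is.null(cc$preset)) {
      cur <- cc$current_a
      switch(cc$preset,
             microscopy = if (is.null(cur)) microscopy_coil()
                          else microscopy_coil(cur),
             stop("unknown coil preset: ", cc$preset, call. = FALSE))
    } else {
      coil_spec(cc$inner_radius_m, cc$radial_build_m, cc$axial_length_m,
                cc$turns, cc$current_a, cc$axial_center_m %||% 0,
                cc$wire_gauge)
    }
  }
  parse_array <- function(aa) {
    if (!is.null(aa$preset)) {
      cur <- aa$current_a
      switch(aa$preset,
             arena10 = if (is.null(cur)) arena10_array() else arena10_array(cur),
             arena20 = if (is.null(cur)) arena20_array() else arena20_array(cur),
             stop("unknown array preset: ", aa$preset, call. = FALSE))
    } else {
      coil_array(lapply(aa$coils, parse_coil))
    }
  }
  parse_region <- function(rr, nm) {
    shape <- rr$shape %||% "cylinder"
    if (shape == "cylinder") {
      region_spec("cylinder", center = c(0, 0, rr$center_z_m %||% 0),
                  radius = rr$radius_m, height = rr$height_m, name = nm)
    } else {
      region_spec("box", center = c(0, 0, rr$center_z_m %||% 0),
                  half_widths = unlist(rr$half_widths_m), name = nm)
    }
  }
  parse_protocol <- function(pp) {
    phases <- lapply(pp$phases, function(ph)
      protocol_phase(ph$stim_s, ph$rest_s %||% 0, ph$frequency_hz %||% 10,
                     ph$dead_time_s %||% 0.001,
                     ph$mode %||% "bidirectional", ph$repeats %||% 1))
    stimulation_protocol(phases, pp$channel_count %||% 1)
  }

  apparatus <- if (!is.null(raw$coil)) parse_coil(raw$coil)
    else if (!is.null(raw$array)) parse_array(raw$array) else NULL
  regions <- if (!is.null(raw$regions))
    stats::setNames(lapply(names(raw$regions), function(nm)
      parse_region(raw$regions[[nm]], nm)), names(raw$regions))
    else list()
  protocol <- if (!is.null(raw$protocol)) parse_protocol(raw$protocol)
    else NULL

  structure(list(seed = raw$seed %||% 1L, grid_mm = raw$grid_mm %||% 1,
                 apparatus = apparatus, regions = regions,
                 protocol = protocol, path = path),
            class = "run_config")
}

# Evaluation grid covering a cylindrical region at grid_mm spacing,
# for an axisymmetric apparatus.
.region_grid <- function(region, grid_mm) {
  stopifnot(region$shape == "cylinder")
  st <- grid_mm / 1000
  field_grid(r = seq(0, region$radius, by = st),
             z = seq(region$center[3] - region$height / 2,
                     region$center[3] + region$height / 2, by = st))
}

#' Evaluate a field map over a configured region
#'
#' Convenience wrapper used by the command-line interface and the
#' worked examples: samples the configured apparatus on a regular grid
#' covering the named region and returns the map (and, via
#' [homogeneity()], its report).
#'
#' @param config A [load_config()] result (or an apparatus spec plus a
#'   region).
#' @param region_name Name of the region in the config.
#' @return A `field_map`.
#' @export
config_field_map <- function(config, region_name) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$apparatus))
    stop("config has no coil or array section", call. = FALSE)
  region <- config$regions[[region_name]]
  if (is.null(region))
    stop("config has no region named '", region_name, "'", call. = FALSE)
  pts <- .region_grid(region, config$grid_mm)
  if (inherits(config$apparatus, "coil_array_spec"))
    array_field(config$apparatus, pts)
  else coil_field(config$apparatus, pts)
}

#' Save a run configuration
#'
#' Writes the canonical YAML form of a [load_config()] result, with
#' apparatus geometry spelled out in full (presets are expanded), so a
#' save/load round trip reproduces the same objects.
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  coil_yaml <- function(cl) {
    out <- list(inner_radius_m = cl$inner_radius,
                radial_build_m = cl$radial_build,
                axial_length_m = cl$axial_length, turns = cl$turns,
                current_a = cl$current, axial_center_m = cl$axial_center)
    if (!is.null(cl$wire_gauge)) out$wire_gauge <- cl$wire_gauge
    out
  }
  out <- list(seed = config$seed, grid_mm = config$grid_mm)
  ap <- config$apparatus
  if (inherits(ap, "coil_spec")) out$coil <- coil_yaml(ap)
  if (inherits(ap, "coil_array_spec"))
    out$array <- list(coils = lapply(ap$coils, coil_yaml))
  if (length(config$regions))
    out$regions <- lapply(config$regions, function(rg) {
      if (rg$shape == "cylinder")
        list(shape = "cylinder", radius_m = rg$radius, height_m = rg$height,
             center_z_m = rg$center[3])
      else
        list(shape = "box", half_widths_m = as.list(rg$half_widths),
             center_z_m = rg$center[3])
    })
  if (!is.null(config$protocol))
    out$protocol <- list(
      channel_count = config$protocol$channel_count,
      phases = lapply(config$protocol$phases, function(ph)
        list(stim_s = ph$stim_duration, rest_s = ph$rest_duration,
             frequency_hz = ph$frequency, dead_time_s = ph$dead_time,
             mode = ph$mode, repeats = ph$repeats)))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
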