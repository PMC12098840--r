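#' Homogeneity report for the reference apparatus designs
#'
#' Recomputes, with the analytic field engine, the design-stage field
#' statistics of the axisymmetric reference apparatuses over their stated
#' evaluation regions:
#'
#' * the microscopy coil (2.2 A) over the central 2 cm (axial) x 2 cm
#'   (diametral) sagittal region;
#' * the four-coil 10 cm arena (6 A) over central cylinders of 10 cm
#'   diameter and 5, 10 and 15 cm height;
#' * the six-coil 20 cm arena (7 A) over central cylinders of 20 cm
#'   diameter and 5, 10, 15 and 20 cm height.
#'
#' Regions are centred on the array mid-plane and sampled at `grid_mm`
#' spacing (default 1 mm); statistics are on the field magnitude |B|.
#'
#' @param grid_mm Evaluation grid spacing in millimetres.
#' @param n_r,n_z Filament discretisation per coil cross-section.
#' @return A data frame with columns `apparatus`, `region`, `B_min_mT`,
#'   `B_max_mT`, `B_mean_mT`, `homogeneity_pct`, `n_points`.
#' @export
design_report <- function(grid_mm = 1, n_r = 20, n_z = 20) {
  cases <- list(
    list(app = "microscopy", spec = microscopy_coil(), radius = 0.01,
         heights = 0.02),
    list(app = "arena10", spec = arena10_array(), radius = 0.05,
         heights = c(0.05, 0.10, 0.15)),
    list(app = "arena20", spec = arena20_array(), radius = 0.10,
         heights = c(0.05, 0.10, 0.15, 0.20))
  )
  rows <- list()
  for (cs in cases) {
    st <- grid_mm / 1000
    zmax <- max(cs$heights) / 2
    pts <- field_grid(r = seq(0, cs$radius, by = st),
                      z = seq(-zmax, zmax, by = st))
    map <- if (inherits(cs$spec, "coil_array_spec"))
      array_field(cs$spec, pts, n_r = n_r, n_z = n_z)
    else coil_field(cs$spec, pts, n_r = n_r, n_z = n_z)
    for (h in cs$heights) {
      reg <- region_spec("cylinder", radius = cs$radius, height = h,
                         name = sprintf("%s h=%g cm", cs$app, h * 100))
      rep <- homogeneity(map, reg)
      rows[[length(rows) + 1]] <- data.frame(
        apparatus = cs$app, region = sprintf("h%gcm", h * 100),
        B_min_mT = rep$B_min, B_max_mT = rep$B_max, B_mean_mT = rep$B_mean,
        homogeneity_pct = rep$homogeneity, n_points = rep$n_points,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
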