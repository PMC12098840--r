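#' Off-axis field of a circular current loop
#'
#' Exact magnetostatic field of a filamentary circular loop, expressed with
#' complete elliptic integrals K and E. This is the kernel every thick-coil
#' and array computation superposes.
#'
#' With loop radius \eqn{a}, current \eqn{I} and the field point at
#' cylindrical coordinates \eqn{(r, z)} relative to the loop plane:
#' \deqn{k^2 = \frac{4 a r}{(a + r)^2 + z^2}}
#' \deqn{B_z = \frac{\mu_0 I}{2\pi\sqrt{(a+r)^2+z^2}}
#'       \left[K(k^2) + \frac{a^2 - r^2 - z^2}{(a-r)^2+z^2} E(k^2)\right]}
#' \deqn{B_r = \frac{\mu_0 I z}{2\pi r \sqrt{(a+r)^2+z^2}}
#'       \left[-K(k^2) + \frac{a^2 + r^2 + z^2}{(a-r)^2+z^2} E(k^2)\right]}
#' On the axis (\eqn{r = 0}) the radial component is identically zero.
#'
#' @param loop A [loop_spec()].
#' @param r,z Field point cylindrical coordinates in metres (vectors of
#'   equal length; `r >= 0`). `z` is absolute, not relative to the loop.
#' @return A list with numeric vectors `B_r` and `B_z` in tesla.
#' @export
loop_field <- function(loop, r, z) {
  stopifnot(inherits(loop, "loop_spec"))
  if (any(r < 0)) stop("'r' must be non-negative", call. = FALSE)
  n <- max(length(r), length(z))
  r <- rep_len(r, n); z <- rep_len(z, n)
  zr <- z - loop$z_position
  a <- loop$radius
  if (any(abs(r - a) < 1e-12 & abs(zr) < 1e-12))
    stop("singular evaluation: field point lies on the loop filament",
         call. = FALSE)
  .loop_field_num(a, loop$current, r, zr)
}

# unchecked numeric kernel, zr relative to the loop plane
.loop_field_num <- function(a, current, r, zr) {
  mu0 <- physical_constants$mu0
  Q <- (a + r)^2 + zr^2
  m <- 4 * a * r / Q
  ke <- pracma::ellipke(m)
  K <- ke$k; E <- ke$e
  denom <- (a - r)^2 + zr^2
  C <- mu0 * current / (2 * pi)
  Bz <- C / sqrt(Q) * (K + (a^2 - r^2 - zr^2) / denom * E)
  Br <- numeric(length(r))
  off <- r > 0
  Br[off] <- C * zr[off] / (r[off] * sqrt(Q[off])) *
    (-K[off] + (a^2 + r[off]^2 + zr[off]^2) / denom[off] * E[off])
  list(B_r = Br, B_z = Bz)
}

#' Build a sagittal-plane evaluation grid
#'
#' Regular grid in the (r, z) half-plane, ordered lexicographically by
#' (r, z). This is the sampling layout the homogeneity reports use.
#'
#' @param r,z Numeric vectors of radial / axial coordinates, metres.
#' @return A data frame with columns `r` and `z`, one row per grid point.
#' @export
field_grid <- function(r, z) {
  g <- expand.grid(z = z, r = r, KEEP.OUT.ATTRS = FALSE)
  data.frame(r = g$r, z = g$z)
}

.new_field_map <- function(points, B, in_winding, frame) {
  B_mT <- sqrt(Reduce(`+`, lapply(B, function(b) b^2))) * 1e3
  out <- cbind(points, as.data.frame(B), B_mT = B_mT,
               in_winding = in_winding)
  class(out) <- c("field_map", "data.frame")
  attr(out, "frame") <- frame
  out
}

#' Field map of an axisymmetric thick coil
#'
#' Discretises the rectangular winding cross-section into `n_r x n_z`
#' filamentary loops carrying equal shares `turns * current / (n_r * n_z)`
#' of the total ampere-turns (the uniform-current-density assumption of an
#' axisymmetric finite-element model) and superposes [loop_field()] over
#' all sample points.
#'
#' @param coil A [coil_spec()].
#' @param points Data frame with columns `r` and `z` (metres), e.g. from
#'   [field_grid()].
#' @param n_r,n_z Filament discretisation of the cross-section (default
#'   20 x 20).
#' @return A `field_map`: a data frame with columns `r`, `z`, `B_r`, `B_z`
#'   (tesla), `B_mT` (field magnitude, millitesla) and `in_winding`
#'   (logical; samples inside the winding volume, excluded from region
#'   statistics).
#' @export
coil_field <- function(coil, points, n_r = 20, n_z = 20) {
  stopifnot(inherits(coil, "coil_spec"))
  if (n_r < 1 || n_z < 1)
    stop("filament discretisation must be positive", call. = FALSE)
  pts <- as.data.frame(points)
  stopifnot(all(c("r", "z") %in% names(pts)))
  f <- .coil_field_num(coil, pts$r, pts$z, n_r, n_z)
  .new_field_map(pts[c("r", "z")], f, .in_winding_coil(coil, pts$r, pts$z),
                 "axisymmetric")
}

.coil_field_num <- function(coil, r, z, n_r, n_z) {
  a_s <- coil$inner_radius + (seq_len(n_r) - 0.5) / n_r * coil$radial_build
  z_s <- coil$axial_center - coil$axial_length / 2 +
    (seq_len(n_z) - 0.5) / n_z * coil$axial_length
  I_fil <- coil$turns * coil$current / (n_r * n_z)
  Br <- numeric(length(r)); Bz <- numeric(length(r))
  for (a in a_s) {
    for (z0 in z_s) {
      f <- .loop_field_num(a, I_fil, r, z - z0)
      Br <- Br + f$B_r; Bz <- Bz + f$B_z
    }
  }
  list(B_r = Br, B_z = Bz)
}

.in_winding_coil <- function(coil, r, z) {
  r >= coil$inner_radius & r <= coil$inner_radius + coil$radial_build &
    abs(z - coil$axial_center) <= coil$axial_length / 2
}

#' Field map of a coaxial coil array
#'
#' Pointwise vector sum of [coil_field()] over every coil in the stack.
#'
#' @param array A [coil_array_spec()] (see also [coil_stack()]).
#' @inheritParams coil_field
#' @return A `field_map` as for [coil_field()].
#' @export
array_field <- function(array, points, n_r = 20, n_z = 20) {
  stopifnot(inherits(array, "coil_array_spec"))
  pts <- as.data.frame(points)
  stopifnot(all(c("r", "z") %in% names(pts)))
  Br <- numeric(nrow(pts)); Bz <- numeric(nrow(pts))
  inw <- rep(FALSE, nrow(pts))
  for (cl in array$coils) {
    f <- .coil_field_num(cl, pts$r, pts$z, n_r, n_z)
    Br <- Br + f$B_r; Bz <- Bz + f$B_z
    inw <- inw | .in_winding_coil(cl, pts$r, pts$z)
  }
  .new_field_map(pts[c("r", "z")], list(B_r = Br, B_z = Bz), inw,
                 "axisymmetric")
}

# Field of a straight finite current segment from p1 to p2 at points X
# (n x 3 matrix), numerically stable vector form.
.segment_field <- function(p1, p2, X, current) {
  mu0 <- physical_constants$mu0
  r1 <- sweep(X, 2, p1)
  r2 <- sweep(X, 2, p2)
  n1 <- sqrt(rowSums(r1^2)); n2 <- sqrt(rowSums(r2^2))
  cr <- cbind(r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2],
              r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3],
              r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1])
  dot <- rowSums(r1 * r2)
  denom <- n1 * n2 * (n1 * n2 + dot)
  if (any(denom <= .Machine$double.eps * (n1 * n2 + 1)))
    stop("singular evaluation: field point lies on a coil segment",
         call. = FALSE)
  cr * (mu0 * current / (4 * pi)) * ((n1 + n2) / denom)
}

# One rectangular filament loop: half-widths wx, wy in the plane z = z0,
# counterclockwise seen from +z.
.rect_loop_field <- function(wx, wy, z0, current, X) {
  corners <- rbind(c( wx, -wy, z0), c( wx,  wy, z0),
                   c(-wx,  wy, z0), c(-wx, -wy, z0))
  B <- matrix(0, nrow(X), 3)
  for (i in 1:4) {
    j <- if (i == 4) 1 else i + 1
    B <- B + .segment_field(corners[i, ], corners[j, ], X, current)
  }
  B
}

#' Field map of a rectangular air-core coil
#'
#' The winding volume is discretised into `n_build x n_axial` rectangular
#' filament loops whose in-plane dimensions interpolate between the inner
#' window and the outer envelope; each straight side contributes through
#' the finite-segment Biot-Savart formula.
#'
#' @param rect A [rect_coil_spec()].
#' @param points Data frame with columns `x`, `y`, `z` (metres).
#' @param n_build,n_axial Filament discretisation (default 10 x 10).
#' @return A `field_map` with columns `x`, `y`, `z`, `B_x`, `B_y`, `B_z`
#'   (tesla), `B_mT` and `in_winding`.
#' @export
rect_coil_field <- function(rect, points, n_build = 10, n_axial = 10) {
  stopifnot(inherits(rect, "rect_coil_spec"))
  if (n_build < 1 || n_axial < 1)
    stop("filament discretisation must be positive", call. = FALSE)
  pts <- as.data.frame(points)
  stopifnot(all(c("x", "y", "z") %in% names(pts)))
  X <- as.matrix(pts[c("x", "y", "z")])
  I_fil <- rect$turns * rect$current / (n_build * n_axial)
  B <- matrix(0, nrow(X), 3)
  for (i in seq_len(n_build)) {
    fr <- (i - 0.5) / n_build
    wx <- (rect$inner_width + fr * (rect$outer_width - rect$inner_width)) / 2
    wy <- (rect$inner_height + fr * (rect$outer_height - rect$inner_height)) / 2
    for (j in seq_len(n_axial)) {
      z0 <- rect$axial_center - rect$length / 2 +
        (j - 0.5) / n_axial * rect$length
      B <- B + .rect_loop_field(wx, wy, z0, I_fil, X)
    }
  }
  inw <- abs(pts$z - rect$axial_center) <= rect$length / 2 &
    abs(pts$x) <= rect$outer_width / 2 & abs(pts$y) <= rect$outer_height / 2 &
    (abs(pts$x) >= rect$inner_width / 2 | abs(pts$y) >= rect$inner_height / 2)
  .new_field_map(pts[c("x", "y", "z")],
                 list(B_x = B[, 1], B_y = B[, 2], B_z = B[, 3]), inw,
                 "cartesian")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("Field map (%s frame): %d samples, |B| %.3f - %.3f mT\n",
              attr(x, "frame"), nrow(x), min(x$B_mT), max(x$B_mT)))
  invisible(x)
}
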