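# Independent reference implementations used as oracles. These share no
# code with the package: loops are integrated by brute-force quadrature,
# image operations are computed pixel by pixel.

MU0 <- 4e-7 * pi

# Biot-Savart line-integral field of a circular loop (radius a, current I,
# plane z = z0) at the point (r, 0, z), by direct segment summation.
quad_loop_field <- function(a, I, r, z, z0 = 0, n = 2e4) {
  th <- (seq_len(n) - 0.5) / n * 2 * pi
  dl <- 2 * pi * a / n
  sx <- a * cos(th); sy <- a * sin(th)
  dlx <- -sin(th) * dl; dly <- cos(th) * dl
  rx <- r - sx; ry <- -sy; rz <- z - z0
  R3 <- (rx^2 + ry^2 + rz^2)^1.5
  c(B_r = MU0 * I / (4 * pi) * sum(dly * rz / R3),
    B_z = MU0 * I / (4 * pi) * sum((dlx * ry - dly * rx) / R3))
}

# Biot-Savart quadrature field of an arbitrary closed polyline at a 3-D
# point, n segments per side.
quad_polyline_field <- function(verts, I, pt, n = 5000) {
  B <- c(0, 0, 0)
  for (i in seq_len(nrow(verts))) {
    p1 <- verts[i, ]
    p2 <- verts[if (i == nrow(verts)) 1 else i + 1, ]
    tseq <- (seq_len(n) - 0.5) / n
    seg <- p2 - p1
    src <- outer(tseq, seg) + matrix(p1, n, 3, byrow = TRUE)
    dl <- matrix(seg / n, n, 3, byrow = TRUE)
    rv <- matrix(pt, n, 3, byrow = TRUE) - src
    R3 <- (rowSums(rv^2))^1.5
    cr <- cbind(dl[, 2] * rv[, 3] - dl[, 3] * rv[, 2],
                dl[, 3] * rv[, 1] - dl[, 1] * rv[, 3],
                dl[, 1] * rv[, 2] - dl[, 2] * rv[, 1])
    B <- B + MU0 * I / (4 * pi) * colSums(cr / R3)
  }
  B
}

# Thick-coil on-axis centre field closed form (uniform current density):
# B = mu0 J b ln[(a2 + sqrt(a2^2 + b^2)) / (a1 + sqrt(a1^2 + b^2))]
# with a1/a2 inner/outer radius, b the half-length, J the current density.
thick_coil_center_field <- function(a1, a2, len, turns, I) {
  b <- len / 2
  J <- turns * I / ((a2 - a1) * len)
  MU0 * J * b * log((a2 + sqrt(a2^2 + b^2)) / (a1 + sqrt(a1^2 + b^2)))
}

# Pixel-by-pixel median blur with replicate-padded borders.
brute_median_blur <- function(m, k) {
  if (k == 1) return(m)
  rad <- (k - 1) %/% 2
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      ri <- pmin(pmax((i - rad):(i + rad), 1), nrow(m))
      ci <- pmin(pmax((j - rad):(j + rad), 1), ncol(m))
      out[i, j] <- stats::median(m[ri, ci])
    }
  }
  out
}

brute_binarize <- function(m, k, thr) {
  b <- brute_median_blur(m, k)
  ifelse(b > thr, 255L, 0L)
}

# A tiny valid bidirectional protocol, reused across controller tests:
# one 30 s stimulation + 30 s rest cycle at 10 Hz.
simple_protocol <- function(repeats = 1) {
  stimulation_protocol(protocol_phase(30, 30, frequency = 10,
                                      dead_time = 0.001, repeats = repeats))
}

# Constant clean sensor stream covering `duration` seconds at `rate` Hz.
flat_sensor_stream <- function(duration, rate = 20,
                               baselines = c(magnetic = 0, temperature = 24,
                                             sound = 45, vibration = 0.02)) {
  simulate_sensor_traces(duration + 1 / rate, poll_rate = rate,
                         baselines = baselines,
                         noise_sd = c(magnetic = 0, temperature = 0,
                                      sound = 0, vibration = 0),
                         seed = 1)
}

always_in_target <- function(duration, rate = 20, chamber = "dark") {
  t <- seq(0, duration, by = 1 / rate)
  data.frame(time_s = t, chamber = chamber, in_target = TRUE,
             stringsAsFactors = FALSE)
}

# Wrap bare |B| samples (mT) into a minimal axisymmetric map at on-axis
# points, with a region that contains them all.
fake_map <- function(B_mT) {
  n <- length(B_mT)
  magnetokit:::.new_field_map(
    data.frame(r = rep(0, n), z = seq(0, 0.001, length.out = n)),
    list(B_r = rep(0, n), B_z = B_mT / 1e3), rep(FALSE, n), "axisymmetric")
}
unit_region <- region_spec("cylinder", radius = 0.01, height = 0.01,
                           center = c(0, 0, 0.0005), name = "test")
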