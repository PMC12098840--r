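.region_mask <- function(map, region) {
  frame <- attr(map, "frame")
  ctr <- region$center
  if (frame == "axisymmetric") {
    if (region$shape == "cylinder") {
      if (any(abs(ctr[1:2]) > 1e-12))
        stop("cylinder region must be on-axis for axisymmetric maps",
             call. = FALSE)
      map$r <= region$radius + 1e-12 &
        abs(map$z - ctr[3]) <= region$height / 2 + 1e-12
    } else {
      # box in the sagittal plane: half_widths[1] bounds r, [3] bounds z
      map$r <= region$half_widths[1] + 1e-12 &
        abs(map$z - ctr[3]) <= region$half_widths[3] + 1e-12
    }
  } else {
    if (region$shape == "cylinder") {
      sqrt((map$x - ctr[1])^2 + (map$y - ctr[2])^2) <= region$radius + 1e-12 &
        abs(map$z - ctr[3]) <= region$height / 2 + 1e-12
    } else {
      abs(map$x - ctr[1]) <= region$half_widths[1] + 1e-12 &
        abs(map$y - ctr[2]) <= region$half_widths[2] + 1e-12 &
        abs(map$z - ctr[3]) <= region$half_widths[3] + 1e-12
    }
  }
}

#' Field homogeneity over a region
#'
#' Computes the extrema and mean of the field magnitude over the samples of
#' a [field_map] falling inside a [region_spec()], and the homogeneity
#' figure of merit
#' \deqn{H = \frac{B_{max} - B_{min}}{B_{mean}} \times 100\%.}
#' `H = 0` exactly when the field is uniform on the region, and `H` is
#' invariant under uniform current scaling.
#'
#' Samples inside a winding volume (flagged `in_winding` in the map) are
#' excluded from the statistics rather than raising an error; the number
#' excluded is reported.
#'
#' @param map A `field_map` from [coil_field()], [array_field()] or
#'   [rect_coil_field()].
#' @param region A [region_spec()].
#' @return An object of class `homogeneity_report`: list with `B_max`,
#'   `B_min`, `B_mean` (millitesla), `homogeneity` (percent), `n_points`
#'   (samples used) and `n_excluded` (in-winding samples dropped).
#' @export
homogeneity <- function(map, region) {
  stopifnot(inherits(map, "field_map"), inherits(region, "region_spec"))
  sel <- .region_mask(map, region)
  n_excluded <- sum(sel & map$in_winding)
  sel <- sel & !map$in_winding
  if (sum(sel) < 2)
    stop(sprintf("region '%s' contains fewer than 2 usable field samples",
                 region$name), call. = FALSE)
  B <- map$B_mT[sel]
  structure(list(B_max = max(B), B_min = min(B), B_mean = mean(B),
                 homogeneity = (max(B) - min(B)) / mean(B) * 100,
                 n_points = sum(sel), n_excluded = n_excluded),
            class = "homogeneity_report")
}

#' @export
print.homogeneity_report <- function(x, ...) {
  cat(sprintf(
    "|B|: %.2f - %.2f mT (mean %.2f), homogeneity %.2f%% [%d samples%s]\n",
    x$B_min, x$B_max, x$B_mean, x$homogeneity, x$n_points,
    if (x$n_excluded > 0) sprintf(", %d in-winding excluded", x$n_excluded)
    else ""))
  invisible(x)
}

#' Write / read a field map as delimited text
#'
#' One row per sample: coordinates in metres and the field components in
#' tesla plus `B_mT`. Values are written with 17 significant digits so a
#' read round-trip reproduces the doubles bit-exactly.
#'
#' @param map A `field_map`.
#' @param path Output file path.
#' @return `export_field_map` returns `path` invisibly; `read_field_map`
#'   returns the `field_map`.
#' @export
export_field_map <- function(map, path) {
  stopifnot(inherits(map, "field_map"))
  if (nrow(map) == 0) stop("field map is empty", call. = FALSE)
  df <- as.data.frame(map)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17, format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# frame=", attr(map, "frame")), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_field_map
#' @export
read_field_map <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# frame="))
    stop("not a field map file: missing frame header", call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  df$in_winding <- as.logical(df$in_winding)
  class(df) <- c("field_map", "data.frame")
  attr(df, "frame") <- sub("# frame=", "", first, fixed = TRUE)
  df
}
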