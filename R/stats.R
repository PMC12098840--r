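#' Pearson correlation between two measurement series
#'
#' Thin validated wrapper around the sample Pearson correlation, used for
#' device-agreement checks (e.g. integrated sensor vs handheld meter).
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a series has zero variance", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Bland-Altman agreement analysis
#'
#' Method-agreement statistics for paired measurements: the bias is the
#' mean difference `mean(x - y)` and the limits of agreement (LoA) are
#' `bias +/- 1.96 * s`, with `s` the sample (n-1) standard deviation of
#' the differences.
#'
#' @param x,y Numeric vectors of equal length (>= 3); differences are
#'   taken as `x - y`.
#' @return An object of class `agreement_result`: list with `bias`,
#'   `loa_lower`, `loa_upper`, `sd_diff`, `n`, and the per-pair `means`
#'   and `differences` for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s, sd_diff = s, n = length(d),
                 means = (x + y) / 2, differences = d),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n=%d): bias %.4g, LoA [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' System Usability Scale score
#'
#' Scores one completed 10-item SUS questionnaire (Likert 1-5). Odd items
#' contribute `item - 1`, even items `5 - item`; the sum is multiplied by
#' 2.5 for a 0-100 score. Above 68 is conventionally read as
#' above-average usability.
#'
#' @param items Integer vector of exactly 10 responses in `[1, 5]`.
#' @return The SUS score, 0-100.
#' @export
sus_score <- function(items) {
  if (length(items) != 10) stop("a SUS response has exactly 10 items",
                                call. = FALSE)
  if (any(items != round(items)) || any(items < 1 | items > 5))
    stop("SUS items must be integers in [1, 5]", call. = FALSE)
  odd <- items[c(1, 3, 5, 7, 9)]
  even <- items[c(2, 4, 6, 8, 10)]
  (sum(odd - 1) + sum(5 - even)) * 2.5
}
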