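#' Fit an isotope-dilution calibration curve
#'
#' Weighted least-squares line of response ratio (analyte quant-ion area /
#' ISTD area) against amount ratio (native mass / ISTD mass). The default
#' weighting of 1/x is the usual choice for calibrations spanning more than
#' two orders of magnitude, as this one does (0.5\% to 100\% of the top
#' standard); \code{"none"} and \code{"1/x2"} are available. The
#' coefficient of determination is computed on the weighted fit, and a
#' back-calculated relative error is reported per level.
#'
#' @param amount_ratio calibrant amount ratios (x).
#' @param response_ratio measured response ratios (y).
#' @param weighting one of \code{"1/x"}, \code{"none"}, \code{"1/x2"}.
#' @param analyte analyte name carried into the object (optional).
#' @return An object of class \code{vna_calibration} with components
#'   \code{analyte}, \code{slope}, \code{intercept}, \code{weighting},
#'   \code{r_squared}, \code{level_residuals} (data frame: level,
#'   back-calculated level, relative error \%), \code{n}, \code{data} and
#'   the underlying \code{fit}. Errors: fewer than 3 distinct levels, or a
#'   non-positive fitted slope (curve rejected).
#' @examples
#' x <- c(0.004, 0.2, 0.4, 1)
#' cal <- fit_calibration(x, 0.5 * x)
#' coef(cal)                  # intercept 0, slope 0.5
#' predict(cal, response_ratio = 0.25)  # amount ratio 0.5
#' @seealso \code{\link{quantitate}}, \code{\link{solution_accuracy_check}}
#' @export
fit_calibration <- function(amount_ratio, response_ratio,
                            weighting = c("1/x", "none", "1/x2"),
                            analyte = "") {
  weighting <- match.arg(weighting)
  keep <- is.finite(amount_ratio) & is.finite(response_ratio)
  x <- amount_ratio[keep]
  y <- response_ratio[keep]
  if (length(unique(x)) < 3)
    stop("calibration requires at least 3 distinct levels with valid ",
         "response ratios (got ", length(unique(x)), ")")
  if (weighting != "none" && any(x <= 0))
    stop("1/x-type weighting requires strictly positive amount ratios")
  w <- switch(weighting, none = rep(1, length(x)), `1/x` = 1 / x,
              `1/x2` = 1 / x^2)
  fit <- stats::lm(y ~ x, weights = w)
  b <- unname(stats::coef(fit)[1])
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m <= 0)
    stop("calibration rejected for ", if (nzchar(analyte)) analyte else
         "analyte", ": fitted slope ", format(m),
         " is not positive; check calibrant responses")
  wmean <- sum(w * y) / sum(w)
  sst <- sum(w * (y - wmean)^2)
  sse <- sum(w * stats::residuals(fit)^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  lev <- sort(unique(x))
  back <- vapply(lev, function(l) (mean(y[x == l]) - b) / m, 0)
  level_residuals <- data.frame(
    level = lev, back_calc = back,
    rel_error_pct = (back - lev) / lev * 100)
  structure(list(analyte = analyte, slope = m, intercept = b,
                 weighting = weighting, r_squared = r2,
                 level_residuals = level_residuals,
                 n = length(x), data = data.frame(x = x, y = y, w = w),
                 fit = fit),
            class = "vna_calibration")
}

#' @export
coef.vna_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Invert a calibration curve
#'
#' @param object a \code{vna_calibration}.
#' @param response_ratio response ratios to back-calculate.
#' @param ... unused.
#' @return Amount ratios \code{(response_ratio - intercept) / slope}.
#' @export
predict.vna_calibration <- function(object, response_ratio, ...) {
  (response_ratio - object$intercept) / object$slope
}

#' @export
residuals.vna_calibration <- function(object, ...) {
  stats::residuals(object$fit)
}

#' @export
print.vna_calibration <- function(x, ...) {
  cat("Isotope-dilution calibration",
      if (nzchar(x$analyte)) paste0("(", x$analyte, ")"), "\n")
  cat(sprintf("  response_ratio = %.6g + %.6g * amount_ratio   [weights: %s]\n",
              x$intercept, x$slope, x$weighting))
  cat(sprintf("  weighted r-squared: %.6f   levels: %d   points: %d\n",
              x$r_squared, nrow(x$level_residuals), x$n))
  invisible(x)
}

#' @export
summary.vna_calibration <- function(object, ...) {
  structure(list(cal = object), class = "summary.vna_calibration")
}

#' @export
print.summary.vna_calibration <- function(x, ...) {
  print(x$cal)
  cat("  per-level back-calculation:\n")
  lr <- x$cal$level_residuals
  for (i in seq_len(nrow(lr)))
    cat(sprintf("    level %-10.4g back %-10.4g rel err %+.3f%%\n",
                lr$level[i], lr$back_calc[i], lr$rel_error_pct[i]))
  invisible(x)
}

#' @export
plot.vna_calibration <- function(x, ...) {
  d <- x$data
  graphics::plot(d$x, d$y, log = if (all(d$x > 0)) "xy" else "",
                 xlab = "amount ratio", ylab = "response ratio",
                 main = paste("Calibration", x$analyte), ...)
  ab <- x$intercept + x$slope * sort(d$x)
  graphics::lines(sort(d$x), ab, col = "steelblue")
  invisible(x)
}
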