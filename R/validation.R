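#' Limit of detection by the 3*S0 method
#'
#' S0 is the standard deviation extrapolated to zero concentration:
#' per-pool SDs are regressed on nominal pool concentration by ordinary
#' least squares and the fitted intercept is S0; the LOD is exactly
#' 3 * S0. Appropriate for analytes with positive blank detections. A
#' non-positive extrapolated intercept is an estimation error — the CLSI
#' procedure (\code{\link{estimate_lod_clsi}}) should be used instead.
#'
#' @param pool_results either a named list mapping nominal concentration
#'   (coercible to numeric) to measured values, or a data frame with
#'   columns \code{nominal_pg_ml} and \code{measured_pg_ml}.
#' @param analyte analyte name carried into the result.
#' @return List of class \code{vna_lod}: \code{analyte}, \code{method}
#'   ("three_s0"), \code{s0}, \code{lod} (= 3 * s0), \code{n_runs},
#'   \code{pool_sds} (per-pool SD table).
#' @examples
#' pools <- list(`0` = c(-2, 0, 2), `2.5` = c(0.4, 2.5, 4.6),
#'               `5` = c(2.8, 5, 7.2), `7.5` = c(5.2, 7.5, 9.8))
#' estimate_lod_3s0(pools)
#' @export
estimate_lod_3s0 <- function(pool_results, analyte = "") {
  tab <- .pool_table(pool_results)
  if (nrow(tab) < 3)
    stop("3*S0 needs at least 3 pools with at least 2 values each")
  fit <- stats::lm(sd ~ conc, data = tab)
  s0 <- unname(stats::coef(fit)[1])
  if (!is.finite(s0) || s0 <= 0)
    stop("extrapolated SD at zero concentration is not positive (",
         format(s0), "); use the CLSI method instead")
  structure(list(analyte = analyte, method = "three_s0", s0 = s0,
                 lod = 3 * s0, n_runs = min(tab$n), pool_sds = tab),
            class = "vna_lod")
}

.pool_table <- function(pool_results) {
  if (is.data.frame(pool_results)) {
    conc <- pool_results$nominal_pg_ml
    val <- pool_results$measured_pg_ml
  } else {
    conc <- rep(as.numeric(names(pool_results)),
                lengths(pool_results))
    val <- unlist(pool_results, use.names = FALSE)
  }
  groups <- split(val, conc)
  if (any(lengths(groups) < 2))
    stop("every pool needs at least 2 values to estimate its SD")
  data.frame(conc = as.numeric(names(groups)),
             sd = vapply(groups, stats::sd, 0),
             n = lengths(groups), row.names = NULL)
}

#' Limit of detection by the CLSI (EP17-style) parametric procedure
#'
#' Limit of blank: \code{LoB = mean(blanks) + q * sd(blanks)}; limit of
#' detection: \code{LoD = LoB + q * sd_pooled(low pools)}, with q the
#' one-sided normal quantile (1.645 for 5\% alpha/beta). Used for analytes
#' without reliable positive blank detections.
#'
#' @param blank_values measured blank concentrations.
#' @param low_pool_values measured values of the low pool(s): a numeric
#'   vector or a list of vectors (one per pool, pooled SD across them).
#' @param beta_quantile the normal quantile (default 1.645).
#' @param analyte analyte name carried into the result.
#' @return List of class \code{vna_lod}: \code{analyte}, \code{method}
#'   ("clsi"), \code{lob}, \code{lod}, \code{n_runs}.
#' @examples
#' estimate_lod_clsi(c(0.5, 1.0, 1.5), rnorm(20, 2.5, 1))
#' @export
estimate_lod_clsi <- function(blank_values, low_pool_values,
                              beta_quantile = 1.645, analyte = "") {
  if (length(blank_values) < 2)
    stop("CLSI LoB needs at least 2 blank values")
  if (!is.list(low_pool_values)) low_pool_values <- list(low_pool_values)
  if (any(lengths(low_pool_values) < 2))
    stop("CLSI LoD needs at least 2 values per low pool")
  lob <- mean(blank_values) + beta_quantile * stats::sd(blank_values)
  dfs <- lengths(low_pool_values) - 1
  sds <- vapply(low_pool_values, stats::sd, 0)
  sd_pooled <- sqrt(sum(dfs * sds^2) / sum(dfs))
  structure(list(analyte = analyte, method = "clsi", lob = lob,
                 lod = lob + beta_quantile * sd_pooled,
                 n_runs = length(blank_values)),
            class = "vna_lod")
}

#' @export
print.vna_lod <- function(x, ...) {
  cat(sprintf("LOD (%s%s): %.3f pg/mL", x$method,
              if (nzchar(x$analyte)) paste0(", ", x$analyte) else "",
              x$lod))
  if (x$method == "three_s0") cat(sprintf("  [S0 = %.3f]", x$s0))
  if (x$method == "clsi") cat(sprintf("  [LoB = %.3f]", x$lob))
  cat("\n")
  invisible(x)
}

#' Intra-run and inter-run precision
#'
#' Intra-run CV is \code{100 * sd / mean} within each run; inter-run CV is
#' the CV of the run means, with n equal to the number of runs (run means,
#' not a pooled ANOVA decomposition). CVs are invariant to positive
#' rescaling of all values.
#'
#' @param values data frame with columns \code{run} and a value column
#'   (default \code{measured_pg_ml}).
#' @param value_col name of the value column.
#' @return List with \code{intra} (data frame: run, n, mean, cv_pct) and
#'   \code{inter} (list: n_runs, mean, cv_pct). A zero mean anywhere is an
#'   error (CV undefined).
#' @examples
#' d <- data.frame(run = rep(1:2, each = 3),
#'                 measured_pg_ml = c(48, 50, 52, 47, 49, 51))
#' precision_summary(d)
#' @export
precision_summary <- function(values, value_col = "measured_pg_ml") {
  v <- values[[value_col]]
  runs <- split(v, values$run)
  if (length(runs) < 2 || any(lengths(runs) < 2))
    stop("precision needs at least 2 runs with at least 2 replicates each")
  means <- vapply(runs, mean, 0)
  if (any(means == 0) || mean(means) == 0)
    stop("CV undefined: a run mean is zero")
  intra <- data.frame(run = names(runs), n = lengths(runs), mean = means,
                      cv_pct = 100 * vapply(runs, stats::sd, 0) / means,
                      row.names = NULL)
  inter <- list(n_runs = length(runs), mean = mean(means),
                cv_pct = 100 * stats::sd(means) / mean(means))
  list(intra = intra, inter = inter)
}

#' Spike-recovery accuracy in matrix
#'
#' Recovery of each spiked measurement is
#' \code{(measured - mean(baseline)) / nominal * 100}; the summary reports
#' the mean and CV of the recoveries per spike level (n = 9 in the 3
#' triplicate-days design).
#'
#' @param spiked data frame with columns \code{nominal_pg_ml} (spike level)
#'   and \code{measured_pg_ml}.
#' @param baseline measured values of the unspiked aliquots (their mean is
#'   the endogenous level subtracted from every spiked measurement).
#' @param value_col name of the measured-value column.
#' @return Data frame: \code{nominal_pg_ml}, \code{n},
#'   \code{mean_recovery_pct}, \code{cv_pct}.
#' @examples
#' sp <- data.frame(nominal_pg_ml = rep(100, 3),
#'                  measured_pg_ml = c(104, 110, 113))
#' accuracy_summary(sp, baseline = c(9, 10, 11))
#' @export
accuracy_summary <- function(spiked, baseline,
                             value_col = "measured_pg_ml") {
  if (any(spiked$nominal_pg_ml == 0))
    stop("nominal spike level must be non-zero")
  base <- mean(baseline)
  rec <- (spiked[[value_col]] - base) / spiked$nominal_pg_ml * 100
  lev <- split(rec, spiked$nominal_pg_ml)
  if (any(lengths(lev) < 2))
    stop("accuracy needs at least 2 measurements per spike level")
  data.frame(nominal_pg_ml = as.numeric(names(lev)),
             n = lengths(lev),
             mean_recovery_pct = vapply(lev, mean, 0),
             cv_pct = 100 * vapply(lev, stats::sd, 0) /
               vapply(lev, mean, 0),
             row.names = NULL)
}

#' Second-source accuracy of the calibration curve
#'
#' Independently prepared calibrators (typically at 0.5\%, 25\% and 50\% of
#' the top standard) are back-calculated through the working curve;
#' per-level accuracy is the mean of back-calculated / nominal * 100 over
#' the triplicates, compared against a pass floor.
#'
#' @param measurements data frame with columns \code{nominal_ratio}
#'   (nominal amount ratio) and \code{response_ratio}.
#' @param curve the working \code{\link{vna_calibration}}.
#' @param expected_levels nominal ratios that must all be present (default:
#'   the distinct levels found; supply explicitly to enforce a design).
#' @param floor_pct minimum acceptable mean accuracy per level (90).
#' @return Data frame: \code{nominal_ratio}, \code{n},
#'   \code{mean_accuracy_pct}, \code{pass}.
#' @export
solution_accuracy_check <- function(measurements, curve,
                                    expected_levels = NULL,
                                    floor_pct = 90) {
  if (!is.null(expected_levels)) {
    missing_lev <- setdiff(expected_levels,
                           unique(measurements$nominal_ratio))
    if (length(missing_lev))
      stop("missing calibrator level(s): ",
           paste(format(missing_lev), collapse = ", "))
  }
  back <- predict(curve, measurements$response_ratio)
  acc <- back / measurements$nominal_ratio * 100
  lev <- split(acc, measurements$nominal_ratio)
  out <- data.frame(nominal_ratio = as.numeric(names(lev)),
                    n = lengths(lev),
                    mean_accuracy_pct = vapply(lev, mean, 0),
                    row.names = NULL)
  out$pass <- out$mean_accuracy_pct >= floor_pct
  out
}
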