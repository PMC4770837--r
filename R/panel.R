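#' The six-analyte volatile nitrosamine panel
#'
#' Returns the default analyte panel: the six urinary volatile nitrosamines
#' with their deuterated internal-standard pairing, expected retention
#' times, expected confirmation-ion ratio, per-analyte limit of detection
#' and blank limit, and whether the analyte is prone to injection carryover
#' (NDMA, NMEA and NDEA only).
#'
#' Expected retention times, ion ratios and the minimum acceptable ISTD
#' area are lab- and instrument-specific; the shipped values are plausible
#' placeholders for a ~12-minute polar-column GC-MS/MS method and are meant
#' to be replaced from a lab's own configuration (see
#' \code{\link{load_config}}). The shipped blank limits are set to twice
#' the shipped LODs, again as documented placeholders: a production lab
#' derives blank limits from its own long-term blank characterisation.
#'
#' @return A data frame of class \code{vna_panel} with one row per analyte
#'   and columns \code{name}, \code{istd_name}, \code{expected_rt_min},
#'   \code{expected_rt_istd_min}, \code{expected_ion_ratio},
#'   \code{lod_pg_ml}, \code{blank_limit_pg_ml}, \code{carryover_prone}.
#' @examples
#' default_panel()
#' @export
default_panel <- function() {
  lods <- c(NDMA = 6.54, NMEA = 3.64, NDEA = 5.02,
            NPIP = 5.08, NPYR = 8.15, NMOR = 7.84)
  panel <- data.frame(
    name = names(lods),
    istd_name = c("NDMA-d6", "NMEA-d3", "NDEA-d10",
                  "NPIP-d10", "NPYR-d8", "NMOR-d8"),
    expected_rt_min = c(5.21, 5.88, 6.47, 8.09, 8.72, 9.38),
    expected_rt_istd_min = c(5.21, 5.88, 6.47, 8.09, 8.72, 9.38) - 0.02,
    expected_ion_ratio = c(0.62, 0.48, 0.55, 0.44, 0.51, 0.38),
    lod_pg_ml = unname(lods),
    blank_limit_pg_ml = unname(2 * lods),
    carryover_prone = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  as_vna_panel(panel)
}

#' Validate and class an analyte panel
#'
#' @param x a data frame with the columns of \code{\link{default_panel}}.
#' @return \code{x} with class \code{vna_panel}, or an error describing the
#'   first violated invariant (missing ISTD pairing names the analyte;
#'   non-positive ratios or limits are rejected).
#' @export
as_vna_panel <- function(x) {
  needed <- c("name", "istd_name", "expected_rt_min", "expected_rt_istd_min",
              "expected_ion_ratio", "lod_pg_ml", "blank_limit_pg_ml",
              "carryover_prone")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols))
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(x$name))
    stop("panel has duplicated analyte names")
  no_istd <- is.na(x$istd_name) | !nzchar(x$istd_name)
  if (any(no_istd))
    stop("analyte ", x$name[which(no_istd)[1]],
         " has no internal-standard pairing")
  for (col in c("expected_ion_ratio", "lod_pg_ml", "blank_limit_pg_ml")) {
    bad <- !is.finite(x[[col]]) | x[[col]] <= 0
    if (any(bad))
      stop("panel column ", col, " must be strictly positive (analyte ",
           x$name[which(bad)[1]], ")")
  }
  if (!is.logical(x$carryover_prone))
    stop("carryover_prone must be logical")
  rownames(x) <- NULL
  class(x) <- c("vna_panel", "data.frame")
  x
}

#' Method constants for the isotope-dilution assay
#'
#' Fixed quantities of the assay: internal-standard mass spiked per sample,
#' urine aliquot volume, the top calibration standard, the concentration
#' above which the following injection must be flagged for possible
#' carryover, and the tiered repeatability criterion (maximum relative
#' difference between duplicate injections: one threshold below the cut
#' concentration, a tighter one at or above it).
#'
#' Both unit systems of the assay meet in amount-ratio space (native mass /
#' ISTD mass): a urine-phase concentration c pg/mL corresponds to the ratio
#' \code{c * sample_volume_ml / istd_mass_pg}, and a solution-phase
#' calibrator at c ng/mL (in the final extract) to
#' \code{c * 1000 * extract_volume_ml / istd_mass_pg}. With the defaults, 1
#' ng/mL in solution equals 50 pg/mL in urine, and the 400 ng/mL top
#' standard is amount ratio 80.
#'
#' @param istd_mass_pg internal standard mass per sample, pg (500).
#' @param sample_volume_ml urine aliquot volume, mL (2).
#' @param extract_volume_ml final extract volume in the GC vial, mL (0.1).
#' @param top_standard_ng_ml highest calibration standard, ng/mL (400).
#' @param carryover_flag_threshold_pg_ml concentration above which the next
#'   injection is flagged, pg/mL (200).
#' @param repeatability_low_pct allowed duplicate difference below the cut,
#'   percent (20).
#' @param repeatability_high_pct allowed duplicate difference at or above
#'   the cut, percent (10).
#' @param repeatability_cut_pg_ml concentration separating the two tiers,
#'   pg/mL (50).
#' @return A list of class \code{vna_constants}.
#' @examples
#' method_constants()
#' @export
method_constants <- function(istd_mass_pg = 500,
                             sample_volume_ml = 2,
                             extract_volume_ml = 0.1,
                             top_standard_ng_ml = 400,
                             carryover_flag_threshold_pg_ml = 200,
                             repeatability_low_pct = 20,
                             repeatability_high_pct = 10,
                             repeatability_cut_pg_ml = 50) {
  vals <- list(istd_mass_pg = istd_mass_pg,
               sample_volume_ml = sample_volume_ml,
               extract_volume_ml = extract_volume_ml,
               top_standard_ng_ml = top_standard_ng_ml,
               carryover_flag_threshold_pg_ml = carryover_flag_threshold_pg_ml,
               repeatability_low_pct = repeatability_low_pct,
               repeatability_high_pct = repeatability_high_pct,
               repeatability_cut_pg_ml = repeatability_cut_pg_ml)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("method constant ", nm, " must be a single strictly positive number")
  }
  if (repeatability_high_pct >= repeatability_low_pct)
    stop("repeatability_high_pct must be smaller than repeatability_low_pct ",
         "(the tighter criterion applies to higher concentrations)")
  structure(vals, class = "vna_constants")
}

#' QA rule configuration
#'
#' Tolerances for the per-sample QA rules: retention-time window for the
#' quant-ion and ISTD peaks, relative tolerance on the confirmation ion
#' ratio, minimum acceptable ISTD peak area, and whether the leading ACN
#' blank is held to the same blank limits as the DCM blanks.
#'
#' @param rt_tolerance_min allowed absolute RT deviation, minutes.
#' @param ion_ratio_tolerance_pct allowed relative deviation of
#'   confirmation/quant area ratio from the expected ratio, percent.
#' @param istd_area_min minimum ISTD peak area, counts.
#' @param check_leading_acn_blank also apply blank limits to the batch's
#'   leading ACN blank.
#' @return A list of class \code{vna_qa_config}.
#' @export
qa_rule_config <- function(rt_tolerance_min = 0.1,
                           ion_ratio_tolerance_pct = 20,
                           istd_area_min = 2e4,
                           check_leading_acn_blank = TRUE) {
  if (rt_tolerance_min <= 0 || ion_ratio_tolerance_pct <= 0 ||
      istd_area_min <= 0)
    stop("QA tolerances must be strictly positive")
  structure(list(rt_tolerance_min = rt_tolerance_min,
                 ion_ratio_tolerance_pct = ion_ratio_tolerance_pct,
                 istd_area_min = istd_area_min,
                 check_leading_acn_blank = isTRUE(check_leading_acn_blank)),
            class = "vna_qa_config")
}

#' Rule identifiers of the per-sample QA engine
#' @keywords internal
QA_RULES <- c("rt_quant", "rt_istd", "ion_ratio", "istd_area", "blank_limit",
              "carryover_follow", "repeat_fail", "unquantifiable")

#' Westgard multirule set
#'
#' Configuration of the multirule QC engine. Each rule can be enabled or
#' disabled and assigned an action (\code{"warn"} or \code{"reject"}).
#' Default: 1_2s warns; 1_3s, 2_2s and R_4s reject; 4_1s and 10_x are
#' available but disabled. 2_2s is evaluated both across pools within the
#' run and within a pool against the previous run; 4_1s and 10_x consume a
#' window of recent historical values per pool.
#'
#' @param enabled character vector of enabled rules, a subset of
#'   \code{c("1_2s","1_3s","2_2s","R_4s","4_1s","10_x")}.
#' @param actions named character vector mapping rules to "warn"/"reject";
#'   unnamed rules keep their default action.
#' @return A list of class \code{vna_westgard_rules}.
#' @examples
#' westgard_ruleset()
#' westgard_ruleset(enabled = c("1_3s", "10_x"))
#' @export
westgard_ruleset <- function(enabled = c("1_2s", "1_3s", "2_2s", "R_4s"),
                             actions = NULL) {
  all_rules <- c("1_2s", "1_3s", "2_2s", "R_4s", "4_1s", "10_x")
  default_action <- c(`1_2s` = "warn", `1_3s` = "reject", `2_2s` = "reject",
                      R_4s = "reject", `4_1s` = "reject", `10_x` = "reject")
  unknown <- setdiff(enabled, all_rules)
  if (length(unknown))
    stop("unknown Westgard rule(s): ", paste(unknown, collapse = ", "))
  act <- default_action
  if (!is.null(actions)) {
    bad <- setdiff(names(actions), all_rules)
    if (length(bad)) stop("unknown Westgard rule(s): ",
                          paste(bad, collapse = ", "))
    if (!all(actions %in% c("warn", "reject")))
      stop("rule actions must be 'warn' or 'reject'")
    act[names(actions)] <- actions
  }
  en <- stats::setNames(all_rules %in% enabled, all_rules)
  if (!any(en & act == "reject"))
    stop("at least one rejection rule must be enabled")
  structure(list(enabled = en, action = act),
            class = "vna_westgard_rules")
}

#' @export
print.vna_panel <- function(x, ...) {
  cat("Volatile nitrosamine panel (", nrow(x), " analytes)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' @export
print.vna_constants <- function(x, ...) {
  cat("Method constants:\n")
  for (nm in names(x)) cat(sprintf("  %-32s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Default calibration design
#'
#' Amount ratios (native mass / ISTD mass) of the shipped calibration
#' design: levels log-spaced from 0.5\% to 100\% of the top standard. The
#' top standard's amount ratio comes from its native mass in the final
#' extract: \code{top_ng_ml * 1000 * extract_volume_ml / istd_mass}, i.e.
#' 80 for 400 ng/mL, 100 uL and 500 pg. The lowest level (0.5\%) is then 2
#' ng/mL in solution, 100 pg/mL urine-equivalent — the bottom of the range
#' routine samples occupy.
#'
#' @param constants a \code{\link{method_constants}} object.
#' @param n_levels number of levels (8).
#' @param low_frac lowest level as a fraction of the top standard (0.005).
#' @return Numeric vector of ascending amount ratios.
#' @export
default_calibration_levels <- function(constants = method_constants(),
                                       n_levels = 8, low_frac = 0.005) {
  top_ratio <- constants$top_standard_ng_ml * 1000 *
    constants$extract_volume_ml / constants$istd_mass_pg
  fracs <- 10^seq(log10(low_frac), 0, length.out = n_levels)
  top_ratio * fracs
}

#' Convert between amount ratio and urine-phase concentration
#'
#' An amount ratio r (native mass / ISTD mass) corresponds to a urine
#' concentration of \code{r * istd_mass_pg / sample_volume_ml} pg/mL.
#'
#' @param ratio amount ratio(s).
#' @param conc_pg_ml concentration(s), pg/mL.
#' @param constants a \code{\link{method_constants}} object.
#' @return The converted numeric vector.
#' @export
ratio_to_conc <- function(ratio, constants = method_constants()) {
  ratio * constants$istd_mass_pg / constants$sample_volume_ml
}

#' @rdname ratio_to_conc
#' @export
conc_to_ratio <- function(conc_pg_ml, constants = method_constants()) {
  conc_pg_ml * constants$sample_volume_ml / constants$istd_mass_pg
}
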