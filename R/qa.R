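#' Per-sample QA rules
#'
#' Every evaluated injection receives exactly one flag per rule and analyte.
#' The rules, mirroring the custom LIMS checks of the assay:
#' \describe{
#'   \item{rt_quant / rt_istd}{retention times of the quant-ion and ISTD
#'     peaks within \code{rt_tolerance_min} of the expected values.}
#'   \item{ion_ratio}{confirmation/quant area ratio within a relative
#'     tolerance of the expected ratio (closed interval); no quant peak
#'     fails.}
#'   \item{istd_area}{ISTD area at or above the configured minimum.}
#'   \item{blank_limit}{blank samples (the two DCM blanks, and the leading
#'     ACN blank when configured) must not exceed the per-analyte blank
#'     limit; passes trivially for other roles.}
#'   \item{carryover_follow}{an unknown immediately following an injection
#'     whose blank-subtracted concentration (any analyte) exceeds the
#'     carryover threshold must be reinjected.}
#'   \item{repeat_fail}{when a reinjection value exists, original and
#'     reinjection must satisfy the tiered repeatability criterion.}
#'   \item{unquantifiable}{the response ratio must be computable (ISTD
#'     peak present).}
#' }
#'
#' @name qa_rules
NULL

#' Retention-time rule
#'
#' @param records injection records (needs \code{analyte},
#'   \code{rt_quant_min}, \code{rt_istd_min}, and identifier columns).
#' @param panel analyte panel with expected retention times.
#' @param cfg a \code{\link{qa_rule_config}}.
#' @return Two flag rows per record (rules \code{rt_quant} and
#'   \code{rt_istd}): \code{sample_id}, \code{well}, \code{analyte},
#'   \code{rule_id}, \code{passed}, \code{detail}.
#' @export
check_retention_times <- function(records, panel = default_panel(),
                                  cfg = qa_rule_config()) {
  j <- match(records$analyte, panel$name)
  dev_q <- records$rt_quant_min - panel$expected_rt_min[j]
  dev_i <- records$rt_istd_min - panel$expected_rt_istd_min[j]
  rbind(
    .flag(records, "rt_quant", abs(dev_q) <= cfg$rt_tolerance_min,
          sprintf("quant RT deviation %+.3f min (tol %.3f)",
                  dev_q, cfg$rt_tolerance_min)),
    .flag(records, "rt_istd", abs(dev_i) <= cfg$rt_tolerance_min,
          sprintf("ISTD RT deviation %+.3f min (tol %.3f)",
                  dev_i, cfg$rt_tolerance_min)))
}

#' Confirmation ion ratio rule
#'
#' @inheritParams check_retention_times
#' @return One flag row per record (rule \code{ion_ratio}).
#' @export
check_ion_ratio <- function(records, panel = default_panel(),
                            cfg = qa_rule_config()) {
  j <- match(records$analyte, panel$name)
  expd <- panel$expected_ion_ratio[j]
  obs <- ifelse(records$quant_area > 0,
                records$confirm_area / records$quant_area, NA_real_)
  rel <- abs(obs - expd) / expd * 100
  pass <- !is.na(obs) & rel <= cfg$ion_ratio_tolerance_pct
  detail <- ifelse(is.na(obs), "no quant peak",
                   sprintf("ion ratio %.3f vs expected %.3f (%.1f%%, tol %.1f%%)",
                           obs, expd, rel, cfg$ion_ratio_tolerance_pct))
  .flag(records, "ion_ratio", pass, detail)
}

#' ISTD peak area rule
#'
#' @inheritParams check_retention_times
#' @return One flag row per record (rule \code{istd_area}).
#' @export
check_istd_area <- function(records, cfg = qa_rule_config()) {
  pass <- records$istd_area >= cfg$istd_area_min
  .flag(records, "istd_area",
        pass, sprintf("ISTD area %.0f (min %.0f)",
                      records$istd_area, cfg$istd_area_min))
}

.flag <- function(records, rule_id, passed, detail) {
  data.frame(sample_id = records$sample_id,
             well = records$well,
             analyte = records$analyte,
             rule_id = rule_id,
             passed = as.logical(passed),
             detail = detail,
             stringsAsFactors = FALSE)
}

#' Run rejection on blank results
#'
#' The run is rejected if any DCM blank's raw concentration strictly
#' exceeds the established blank limit for any analyte (a blank exactly at
#' the limit is accepted). When configured, the leading ACN blank is held
#' to the same limits. A missing blank rejects the run outright.
#'
#' @param results quantitation results for the batch (raw concentrations).
#' @param panel analyte panel with \code{blank_limit_pg_ml}.
#' @param cfg a \code{\link{qa_rule_config}}.
#' @return List with \code{accept} (logical), \code{verdict}
#'   ("accept"/"reject"), \code{offending} (data frame of blank sample,
#'   analyte, concentration, limit) and \code{reasons}.
#' @export
check_run_blanks <- function(results, panel = default_panel(),
                             cfg = qa_rule_config()) {
  reasons <- character(0)
  bl <- results[results$role == "dcm_blank", ]
  if (cfg$check_leading_acn_blank) {
    lead <- results[results$role == "acn_blank" &
                      results$injection_index ==
                      min(results$injection_index), ]
    bl <- rbind(bl, lead)
  }
  limits <- panel$blank_limit_pg_ml[match(bl$analyte, panel$name)]
  n_dcm <- length(unique(bl$sample_id[bl$role == "dcm_blank"]))
  if (n_dcm < 2)
    reasons <- c(reasons, "missing blank")
  miss <- !is.finite(bl$raw_conc_pg_ml)
  if (any(miss))
    reasons <- c(reasons, paste0("blank unquantifiable: ",
                                 paste(unique(bl$sample_id[miss]),
                                       collapse = ", ")))
  over <- !miss & bl$raw_conc_pg_ml > limits
  offending <- data.frame(sample_id = bl$sample_id[over],
                          well = bl$well[over],
                          analyte = bl$analyte[over],
                          raw_conc_pg_ml = bl$raw_conc_pg_ml[over],
                          blank_limit_pg_ml = limits[over],
                          stringsAsFactors = FALSE)
  if (nrow(offending))
    reasons <- c(reasons, sprintf("%s in blank %s exceeds limit (%.2f > %.2f pg/mL)",
                                  offending$analyte, offending$sample_id,
                                  offending$raw_conc_pg_ml,
                                  offending$blank_limit_pg_ml))
  accept <- length(reasons) == 0
  list(accept = accept, verdict = if (accept) "accept" else "reject",
       offending = offending, reasons = reasons)
}

#' Carryover follow-up flags
#'
#' Flags any unknown whose immediate predecessor in the injection sequence
#' has a blank-subtracted concentration above the carryover threshold for
#' any analyte (the most conservative reading of "a high concentration
#' sample"). The first injection of a batch is never flagged. Flagged
#' samples require reinjection.
#'
#' @param results blank-subtracted quantitation results, sorted by
#'   \code{injection_index}.
#' @param constants method constants (carryover threshold).
#' @return One flag row per (result row) with rule
#'   \code{carryover_follow}.
#' @export
flag_carryover_follow <- function(results, constants = method_constants()) {
  if (is.unsorted(results$injection_index))
    stop("results must be sorted by injection_index")
  idx <- sort(unique(results$injection_index))
  max_conc <- vapply(idx, function(i)
    suppressWarnings(max(results$blank_sub_conc_pg_ml[
      results$injection_index == i], na.rm = TRUE)), 0)
  pred <- c(NA_real_, max_conc[-length(max_conc)])[
    match(results$injection_index, idx)]
  thr <- constants$carryover_flag_threshold_pg_ml
  fails <- results$role == "unknown" & !is.na(pred) & pred > thr
  .flag(results, "carryover_follow", !fails,
        ifelse(is.na(pred), "first injection (no predecessor)",
               sprintf("predecessor max %.1f pg/mL (threshold %.0f)%s",
                       pred, thr,
                       ifelse(fails, "; reinjection required", ""))))
}

#' Tiered repeatability criterion for duplicate injections
#'
#' The relative difference of the two concentrations to their mean must not
#' exceed 20\% when the mean is below the 50 pg/mL cut, or 10\% at or above
#' it. A pair of exact zeros passes.
#'
#' @param conc_a,conc_b the duplicate concentrations, pg/mL (vectorized).
#' @param constants method constants (tier thresholds and cut).
#' @return Logical vector: \code{TRUE} where the pair passes.
#' @examples
#' check_repeatability(40, 46)    # TRUE  (13.95% vs 20% tier)
#' check_repeatability(100, 115)  # FALSE (13.95% vs 10% tier)
#' @export
check_repeatability <- function(conc_a, conc_b,
                                constants = method_constants()) {
  m <- (conc_a + conc_b) / 2
  thr <- ifelse(m < constants$repeatability_cut_pg_ml,
                constants$repeatability_low_pct,
                constants$repeatability_high_pct)
  rel <- ifelse(m == 0, ifelse(conc_a == conc_b, 0, Inf),
                abs(conc_a - conc_b) / m * 100)
  rel <= thr
}

# Full flags table for a batch: one row per (injection, analyte, rule).
.qa_flags_table <- function(results, records, panel, cfg, constants,
                            reinjections = NULL) {
  key <- function(d) paste(d$injection_index, d$analyte)
  rec <- records[match(key(results), key(records)), ]
  flags <- rbind(
    check_retention_times(rec, panel, cfg),
    check_ion_ratio(rec, panel, cfg),
    check_istd_area(rec, cfg))

  # blank_limit: real check for blank roles, trivially passing otherwise
  limits <- panel$blank_limit_pg_ml[match(results$analyte, panel$name)]
  is_blank <- results$role == "dcm_blank" |
    (cfg$check_leading_acn_blank & results$role == "acn_blank" &
       results$injection_index == min(results$injection_index))
  bl_pass <- ifelse(is_blank,
                    is.finite(results$raw_conc_pg_ml) &
                      results$raw_conc_pg_ml <= limits, TRUE)
  bl_detail <- ifelse(is_blank,
                      sprintf("blank %.2f pg/mL vs limit %.2f",
                              results$raw_conc_pg_ml, limits),
                      "not a blank (rule not applicable)")
  flags <- rbind(flags, .flag(results, "blank_limit", bl_pass, bl_detail))

  flags <- rbind(flags, flag_carryover_follow(results, constants))

  flags <- rbind(flags, .flag(results, "unquantifiable",
                              !results$unquantifiable,
                              ifelse(results$unquantifiable,
                                     "no ISTD peak; response ratio undefined",
                                     "response ratio computable")))

  # repeat_fail: evaluated where a reinjection value exists
  rp_pass <- rep(TRUE, nrow(results))
  rp_detail <- rep("no reinjection (rule not applicable)", nrow(results))
  if (!is.null(reinjections) && nrow(reinjections)) {
    k <- paste(results$sample_id, results$analyte)
    rk <- paste(reinjections$sample_id, reinjections$analyte)
    hit <- match(k, rk)
    has <- !is.na(hit)
    a <- results$blank_sub_conc_pg_ml[has]
    b <- reinjections$conc_pg_ml[hit[has]]
    ok <- check_repeatability(a, b, constants)
    rp_pass[has] <- ok
    m <- (a + b) / 2
    rp_detail[has] <- sprintf(
      "original %.1f vs reinjection %.1f pg/mL: %.1f%% (tier %s%%)",
      a, b, ifelse(m == 0, 0, abs(a - b) / m * 100),
      ifelse(m < constants$repeatability_cut_pg_ml,
             constants$repeatability_low_pct,
             constants$repeatability_high_pct))
  }
  flags <- rbind(flags, .flag(results, "repeat_fail", rp_pass, rp_detail))
  rownames(flags) <- NULL
  flags
}

#' Evaluate one sample's QA report
#'
#' Aggregates all QA flags for one sample and derives its disposition:
#' \code{"report"} when all rules pass (a carryover flag resolved by a
#' reinjection passing repeatability reports the reinjection value),
#' \code{"reinject"} when the carryover rule fired and no reinjection is
#' available yet, \code{"repeat"} when a reinjection failed repeatability
#' (the sample must be re-prepared), and \code{"fail_qa"} otherwise.
#'
#' @param sample_id the sample to evaluate.
#' @param results blank-subtracted batch results.
#' @param records the batch's injection records.
#' @param panel,cfg,constants configuration objects.
#' @param reinjections optional data frame \code{(sample_id, analyte,
#'   conc_pg_ml)} of reinjection measurements.
#' @return List with \code{flags} (this sample's flag rows),
#'   \code{reportable}, \code{disposition} and \code{value_source}
#'   ("original" or "reinjection").
#' @export
evaluate_sample <- function(sample_id, results, records,
                            panel = default_panel(),
                            cfg = qa_rule_config(),
                            constants = method_constants(),
                            reinjections = NULL) {
  flags <- .qa_flags_table(results, records, panel, cfg, constants,
                           reinjections)
  .sample_disposition(sample_id, flags, reinjections)
}

.sample_disposition <- function(sid, flags, reinjections) {
  f <- flags[flags$sample_id == sid, ]
  core <- f[!(f$rule_id %in% c("carryover_follow", "repeat_fail")), ]
  core_ok <- all(core$passed)
  carry_fail <- any(!f$passed[f$rule_id == "carryover_follow"])
  has_reinj <- !is.null(reinjections) &&
    sid %in% reinjections$sample_id
  repeat_ok <- all(f$passed[f$rule_id == "repeat_fail"])
  if (!carry_fail) {
    list(flags = f, reportable = core_ok,
         disposition = if (core_ok) "report" else "fail_qa",
         value_source = "original")
  } else if (!has_reinj) {
    list(flags = f, reportable = FALSE, disposition = "reinject",
         value_source = "original")
  } else if (repeat_ok) {
    list(flags = f, reportable = core_ok,
         disposition = if (core_ok) "report" else "fail_qa",
         value_source = "reinjection")
  } else {
    list(flags = f, reportable = FALSE, disposition = "repeat",
         value_source = "original")
  }
}

#' Evaluate QA for every injection of a batch
#'
#' @inheritParams evaluate_sample
#' @return List with \code{flags} (full flag table: sample_id, well,
#'   analyte, rule_id, passed, detail) and \code{dispositions} (one row per
#'   sample: reportable, disposition, value_source).
#' @export
evaluate_batch_qa <- function(results, records, panel = default_panel(),
                              cfg = qa_rule_config(),
                              constants = method_constants(),
                              reinjections = NULL) {
  flags <- .qa_flags_table(results, records, panel, cfg, constants,
                           reinjections)
  sids <- unique(results$sample_id[order(results$injection_index)])
  disp <- lapply(sids, function(s)
    .sample_disposition(s, flags, reinjections))
  dispositions <- data.frame(
    sample_id = sids,
    reportable = vapply(disp, `[[`, TRUE, "reportable"),
    disposition = vapply(disp, `[[`, "", "disposition"),
    value_source = vapply(disp, `[[`, "", "value_source"),
    stringsAsFactors = FALSE)
  list(flags = flags, dispositions = dispositions)
}
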