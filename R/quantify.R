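#' Response ratio of an injection
#'
#' Analyte quant-ion area divided by ISTD area. A zero (or missing) ISTD
#' area makes the injection unquantifiable: the ratio is returned as
#' \code{NA} and the QA engine raises the corresponding flag — no error is
#' thrown here.
#'
#' @param quant_area quant-ion peak area(s).
#' @param istd_area ISTD peak area(s).
#' @return Numeric vector of response ratios (NA where unquantifiable).
#' @examples
#' response_ratio(5000, 10000)  # 0.5
#' response_ratio(5000, 0)      # NA (unquantifiable)
#' @export
response_ratio <- function(quant_area, istd_area) {
  ifelse(is.finite(istd_area) & istd_area > 0 & is.finite(quant_area),
         quant_area / istd_area, NA_real_)
}

#' Quantitate injection records against a calibration curve
#'
#' Back-calculates the amount ratio through the curve and converts it to a
#' urine-phase concentration: \code{amount_ratio * istd_mass_pg /
#' sample_volume_ml}, multiplied by the dilution factor when present. With
#' the method's 500 pg ISTD in a 2 mL aliquot, a unit amount ratio is 250
#' pg/mL.
#'
#' @param records injection records for one analyte (data frame with at
#'   least \code{sample_id}, \code{well}, \code{injection_index},
#'   \code{role}, \code{quant_area}, \code{istd_area}; optional
#'   \code{dilution}).
#' @param curve a \code{\link{vna_calibration}} for the same analyte.
#' @param constants method constants.
#' @return Data frame of raw quantitation results: \code{sample_id},
#'   \code{well}, \code{injection_index}, \code{role}, \code{analyte},
#'   \code{response_ratio}, \code{raw_conc_pg_ml} (NA where
#'   unquantifiable), \code{unquantifiable}.
#' @export
quantitate <- function(records, curve, constants = method_constants()) {
  rr <- response_ratio(records$quant_area, records$istd_area)
  dil <- if ("dilution" %in% names(records)) records$dilution else 1
  amount_ratio <- predict(curve, rr)
  data.frame(sample_id = records$sample_id,
             well = records$well,
             injection_index = records$injection_index,
             role = records$role,
             analyte = if ("analyte" %in% names(records)) records$analyte
                       else curve$analyte,
             response_ratio = rr,
             raw_conc_pg_ml = ratio_to_conc(amount_ratio, constants) * dil,
             unquantifiable = !is.finite(rr),
             stringsAsFactors = FALSE)
}

#' In-batch DCM blank subtraction
#'
#' Per analyte, the mean raw concentration of the two designated DCM blanks
#' (first and last plate wells) is subtracted from every other result in
#' the batch. The blanks themselves keep their raw values (they are what
#' the run-rejection check inspects). Negative blank-subtracted
#' concentrations are reported as-is — never clamped — and flagged below
#' the LOD, which keeps batch statistics unbiased.
#'
#' @param results quantitation results for one batch (all analytes), as
#'   produced by \code{\link{quantitate}}.
#' @param panel analyte panel (supplies per-analyte LODs for the
#'   \code{below_lod} flag).
#' @return The results with columns \code{blank_sub_conc_pg_ml} and
#'   \code{below_lod} added, plus an attribute \code{blank_means} (named
#'   per-analyte blank means). Errors if either DCM blank is missing or
#'   unquantifiable for any analyte: the batch cannot be reported.
#' @export
blank_subtract <- function(results, panel = default_panel()) {
  results$blank_sub_conc_pg_ml <- NA_real_
  results$below_lod <- NA
  blank_means <- stats::setNames(numeric(0), character(0))
  for (an in unique(results$analyte)) {
    i <- which(results$analyte == an)
    bl <- i[results$role[i] == "dcm_blank"]
    if (length(bl) != 2)
      stop("batch must contain exactly the two designated DCM blank ",
           "results for ", an, " (found ", length(bl), ")")
    if (any(!is.finite(results$raw_conc_pg_ml[bl])))
      stop("DCM blank unquantifiable for ", an,
           "; batch cannot be reported")
    bmean <- mean(results$raw_conc_pg_ml[bl])
    blank_means[an] <- bmean
    results$blank_sub_conc_pg_ml[i] <- results$raw_conc_pg_ml[i] - bmean
    results$blank_sub_conc_pg_ml[bl] <- results$raw_conc_pg_ml[bl]
    lod <- panel$lod_pg_ml[match(an, panel$name)]
    results$below_lod[i] <- !is.na(results$blank_sub_conc_pg_ml[i]) &
      results$blank_sub_conc_pg_ml[i] < lod
  }
  attr(results, "blank_means") <- blank_means
  results
}

#' Calibrate and quantitate a whole batch
#'
#' Fits one calibration per analyte from the batch's calibrant injections,
#' quantitates every injection, and applies the in-batch DCM blank
#' subtraction.
#'
#' @param batch a \code{\link{vna_batch}} with records.
#' @param panel analyte panel.
#' @param constants method constants.
#' @param weighting calibration weighting (see
#'   \code{\link{fit_calibration}}).
#' @return List with \code{calibrations} (named list of
#'   \code{vna_calibration}) and \code{results} (blank-subtracted
#'   quantitation table).
#' @export
quantify_batch <- function(batch, panel = default_panel(),
                           constants = method_constants(),
                           weighting = "1/x") {
  rec <- batch$records
  if (is.null(rec) || !nrow(rec)) stop("batch has no injection records")
  cals <- list()
  res <- vector("list", nrow(panel))
  for (j in seq_len(nrow(panel))) {
    an <- panel$name[j]
    r <- rec[rec$analyte == an, ]
    calr <- r[r$role == "calibrant", ]
    cals[[an]] <- fit_calibration(
      calr$calibrant_amount_ratio,
      response_ratio(calr$quant_area, calr$istd_area),
      weighting = weighting, analyte = an)
    res[[j]] <- quantitate(r, cals[[an]], constants)
  }
  results <- do.call(rbind, res)
  results <- results[order(results$injection_index, results$analyte), ]
  rownames(results) <- NULL
  list(calibrations = cals,
       results = blank_subtract(results, panel))
}
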