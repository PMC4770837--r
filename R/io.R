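#' Read a plate-map worklist CSV
#'
#' Columns: \code{batch_id}, \code{well}, \code{sample_id}, \code{role}
#' (one of dcm_blank, qc_low, qc_high, unknown). Parse problems are
#' reported with their line numbers (header is line 1): a file must have
#' exactly 48 rows, no duplicate wells and only known roles.
#'
#' @param path path to the worklist CSV.
#' @return A \code{\link{vna_batch}} skeleton.
#' @export
read_worklist <- function(path) {
  if (!file.exists(path)) stop("worklist file not found: ", path)
  w <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  needed <- c("batch_id", "well", "sample_id", "role")
  missing_cols <- setdiff(needed, names(w))
  if (length(missing_cols))
    stop("worklist is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  errs <- character(0)
  line <- function(i) i + 1L  # header occupies line 1
  if (nrow(w) != 48)
    errs <- c(errs, sprintf("expected 48 rows, found %d", nrow(w)))
  dup <- which(duplicated(w$well))
  if (length(dup))
    errs <- c(errs, sprintf("line %d: duplicate well %s",
                            line(dup), w$well[dup]))
  badrole <- which(!(w$role %in% WELL_ROLES))
  if (length(badrole))
    errs <- c(errs, sprintf("line %d: unknown role '%s' (allowed: %s)",
                            line(badrole), w$role[badrole],
                            paste(WELL_ROLES, collapse = ", ")))
  badwell <- which(!(w$well %in% plate_wells()))
  if (length(badwell))
    errs <- c(errs, sprintf("line %d: unknown well coordinate '%s'",
                            line(badwell), w$well[badwell]))
  if (length(errs))
    stop("worklist parse errors:\n  ", paste(errs, collapse = "\n  "))
  if (length(unique(w$batch_id)) != 1)
    stop("worklist mixes batch ids: ",
         paste(unique(w$batch_id), collapse = ", "))
  vna_batch(w$batch_id[1], w[, c("well", "sample_id", "role")])
}

#' Write a plate-map worklist CSV
#'
#' @param batch a \code{\link{vna_batch}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_worklist <- function(batch, path) {
  out <- cbind(batch_id = batch$batch_id, batch$wells)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a plate batch to an injection sequence
#'
#' The instrument sequence of one analytical batch: a leading ACN blank (to
#' verify the system is clean before analysis), the calibrants in ascending
#' order, three ACN solvent blanks immediately after the top standard (to
#' wash out carryover of the prone analytes), then the 48 plate wells in
#' processing order. Injection indices are contiguous from 1 and sample ids
#' are preserved verbatim.
#'
#' @param batch a validated \code{\link{vna_batch}}.
#' @param cal_ratios calibrant amount ratios (at least one; sorted
#'   ascending internally).
#' @return Data frame of sequence entries: \code{injection_index},
#'   \code{position} (well or \code{VIAL:} coordinate), \code{sample_id},
#'   \code{role}, \code{sample_type} (blank/calibrant/qc/unknown),
#'   \code{dilution}, \code{calibrant_amount_ratio}.
#' @examples
#' s <- worklist_to_sequence(default_layout(), default_calibration_levels())
#' nrow(s)  # 1 + 8 + 3 + 48 = 60
#' @export
worklist_to_sequence <- function(batch, cal_ratios) {
  if (length(cal_ratios) == 0)
    stop("at least one calibrant level is required (a curve is mandatory)")
  viol <- validate_batch(batch)
  if (length(viol))
    stop("batch fails structural validation: ", paste(viol, collapse = "; "))
  cal_ratios <- sort(cal_ratios)
  L <- length(cal_ratios)
  bid <- batch$batch_id
  entry <- function(position, sample_id, role, ratio = NA_real_)
    data.frame(position = position, sample_id = sample_id, role = role,
               calibrant_amount_ratio = ratio, stringsAsFactors = FALSE)
  parts <- list(
    entry("VIAL:ACN", paste0(bid, "-ACNBLK0"), "acn_blank"),
    entry(sprintf("VIAL:CAL%02d", seq_len(L)),
          sprintf("%s-CAL%02d", bid, seq_len(L)), "calibrant", cal_ratios),
    entry("VIAL:ACN", paste0(bid, "-ACNBLK", 1:3), "acn_blank"))
  w <- batch$wells[match(plate_wells(), batch$wells$well), ]
  parts <- c(parts, list(
    data.frame(position = w$well, sample_id = w$sample_id, role = w$role,
               calibrant_amount_ratio = NA_real_, stringsAsFactors = FALSE)))
  out <- do.call(rbind, parts)
  out$sample_type <- c(dcm_blank = "blank", acn_blank = "blank",
                       calibrant = "calibrant", qc_low = "qc",
                       qc_high = "qc", unknown = "unknown")[out$role]
  out$dilution <- 1
  out <- cbind(injection_index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out[, c("injection_index", "position", "sample_id", "role",
          "sample_type", "dilution", "calibrant_amount_ratio")]
}

#' Read / write a per-injection peak table CSV
#'
#' The peak-table dialect the pipeline consumes: one row per injection and
#' analyte with columns \code{sample_id}, \code{well},
#' \code{injection_index}, \code{role}, \code{dilution}, \code{analyte},
#' \code{quant_area}, \code{confirm_area}, \code{istd_area},
#' \code{rt_quant_min}, \code{rt_istd_min}, \code{calibrant_amount_ratio}
#' (empty except for calibrants).
#'
#' @param path CSV path.
#' @param records the records data frame (for writing).
#' @return \code{read_peak_table}: the records data frame; a missing
#'   required column aborts naming the column.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "well", "injection_index", "role", "analyte",
              "quant_area", "confirm_area", "istd_area", "rt_quant_min",
              "rt_istd_min", "calibrant_amount_ratio")
  for (col in needed)
    if (!col %in% names(rec))
      stop("peak table is missing required column: ", col)
  if (!"dilution" %in% names(rec)) rec$dilution <- 1
  rec[order(rec$injection_index, rec$analyte), ]
}

#' @rdname read_peak_table
#' @export
write_peak_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Export the LIMS import file
#'
#' One row per plate sample and analyte, carrying the blank-subtracted
#' concentration (fixed at 3 decimal places, which makes
#' export-reimport-export byte-stable), the below-LOD flag, the QA
#' disposition, and the batch verdict. A batch rejected by the blank-limit
#' or QC rules exports with the reject marker and no reportable
#' concentrations. Exporting before QC evaluation is a sequencing error.
#'
#' @param results blank-subtracted quantitation results.
#' @param dispositions per-sample QA dispositions
#'   (\code{\link{evaluate_batch_qa}}).
#' @param run_blanks run-rejection verdict (\code{\link{check_run_blanks}}).
#' @param qc_eval Westgard verdict (\code{\link{evaluate_batch_qc}}).
#' @param batch the \code{\link{vna_batch}}.
#' @param path optional CSV output path.
#' @return The LIMS table (invisibly when \code{path} is given).
#' @export
export_lims <- function(results, dispositions, run_blanks, qc_eval,
                        batch, path = NULL) {
  if (is.null(qc_eval))
    stop("sequencing error: batch QC must be evaluated before LIMS export")
  if (is.null(run_blanks))
    stop("sequencing error: run blanks must be checked before LIMS export")
  accepted <- run_blanks$accept && qc_eval$verdict != "reject"
  plate <- results[results$well %in% batch$wells$well, ]
  d <- dispositions[match(plate$sample_id, dispositions$sample_id), ]
  reportable <- accepted & plate$role == "unknown" &
    d$disposition == "report"
  conc <- if (accepted) plate$blank_sub_conc_pg_ml
          else rep(NA_real_, nrow(plate))
  reject_reason <- if (accepted) "" else
    paste(c(run_blanks$reasons,
            if (qc_eval$verdict == "reject")
              paste0("QC rule ", qc_eval$violations$rule, " (",
                     qc_eval$violations$analyte, ")")),
          collapse = "; ")
  out <- data.frame(
    batch_id = batch$batch_id,
    sample_id = plate$sample_id,
    well = plate$well,
    analyte = plate$analyte,
    conc_pg_ml = ifelse(is.na(conc), "", sprintf("%.3f", conc)),
    below_lod = plate$below_lod,
    qa_disposition = d$disposition,
    value_source = d$value_source,
    reportable = reportable,
    batch_verdict = if (accepted) "accept" else "reject",
    reject_reason = reject_reason,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Read a LIMS import file back
#'
#' @param path the exported CSV.
#' @return Data frame with \code{conc_pg_ml} parsed back to numeric.
#' @export
read_lims <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(conc_pg_ml = "character"))
  d$conc_pg_ml <- suppressWarnings(as.numeric(d$conc_pg_ml))
  d
}

#' Run the full batch pipeline
#'
#' Orchestrates the sample data flow of one batch: worklist to sequence,
#' peak table (measured or simulated) to calibrated, blank-subtracted
#' concentrations, per-sample QA, run-blank rejection, Westgard batch QC,
#' and the LIMS export. The pipeline is a pure function of (configuration,
#' inputs, seed): repeated runs produce identical bundles.
#'
#' @param config a \code{\link{vna_config}} (or a path to a JSON config).
#' @param worklist a \code{\link{vna_batch}} skeleton, a worklist CSV path,
#'   or \code{NULL} for the default layout.
#' @param peak_table an injection-record data frame or CSV path (ignored
#'   when \code{simulate = TRUE}).
#' @param simulate when \code{TRUE} the peak table is generated by the
#'   synthetic-data module under \code{config$sim}; the truth table is kept
#'   and a recovery report is added.
#' @param reinjections optional reinjection table \code{(sample_id,
#'   analyte, conc_pg_ml)} consumed by the repeatability rule.
#' @param out_dir optional directory; when given, the sequence, results,
#'   QA, QC, LIMS (and with \code{simulate} the truth/recovery) CSVs are
#'   written there.
#' @return List with \code{batch}, \code{sequence}, \code{calibrations},
#'   \code{results}, \code{qa}, \code{run_blanks}, \code{qc},
#'   \code{lims}, \code{accepted}, and (simulated runs) \code{truth} and
#'   \code{recovery}.
#' @export
run_pipeline <- function(config = default_config(), worklist = NULL,
                         peak_table = NULL, simulate = FALSE,
                         reinjections = NULL, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  layout <- if (is.null(worklist)) default_layout()
  else if (is.character(worklist)) read_worklist(worklist)
  else worklist
  cal_ratios <- default_calibration_levels(config$constants)
  sequence <- worklist_to_sequence(layout, cal_ratios)

  batch <- if (simulate) {
    generate_batch(config$sim, layout, config$panel, config$constants,
                   cal_ratios)
  } else {
    if (is.null(peak_table))
      stop("either a peak table or simulate = TRUE is required")
    rec <- if (is.character(peak_table)) read_peak_table(peak_table)
    else peak_table
    b <- layout
    b$records <- rec
    viol <- validate_batch(b, config$panel)
    if (length(viol))
      stop("quantify stage: batch fails validation: ",
           paste(viol, collapse = "; "))
    b
  }

  q <- quantify_batch(batch, config$panel, config$constants)
  run_blanks <- check_run_blanks(q$results, config$panel, config$qa)
  qa <- evaluate_batch_qa(q$results, batch$records, config$panel,
                          config$qa, config$constants, reinjections)
  qc_rows <- q$results[q$results$role %in% c("qc_low", "qc_high"), ]
  current_qc <- data.frame(analyte = qc_rows$analyte, pool = qc_rows$role,
                           value = qc_rows$blank_sub_conc_pg_ml,
                           stringsAsFactors = FALSE)
  qc <- evaluate_batch_qc(current_qc, config$qc_char, config$westgard)
  lims <- export_lims(q$results, qa$dispositions, run_blanks, qc, batch)
  accepted <- run_blanks$accept && qc$verdict != "reject"

  bundle <- list(batch = batch, sequence = sequence,
                 calibrations = q$calibrations, results = q$results,
                 qa = qa, run_blanks = run_blanks, qc = qc, lims = lims,
                 accepted = accepted)
  if (simulate) {
    bundle$truth <- batch$truth
    unk <- q$results[q$results$role == "unknown", ]
    tk <- paste(batch$truth$sample_id, batch$truth$analyte)
    truth_conc <- batch$truth$true_conc_pg_ml[
      match(paste(unk$sample_id, unk$analyte), tk)]
    ok <- truth_conc > 0
    bundle$recovery <- data.frame(
      sample_id = unk$sample_id[ok], analyte = unk$analyte[ok],
      true_conc_pg_ml = truth_conc[ok],
      measured_pg_ml = unk$blank_sub_conc_pg_ml[ok],
      recovery_pct = unk$blank_sub_conc_pg_ml[ok] / truth_conc[ok] * 100,
      stringsAsFactors = FALSE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
    wr(sequence, "sequence.csv")
    wr(q$results, "results.csv")
    wr(qa$flags, "qa_flags.csv")
    wr(qa$dispositions, "qa_dispositions.csv")
    wr(qc$violations, "qc_violations.csv")
    wr(lims, "lims_import.csv")
    if (simulate) {
      wr(bundle$truth, "truth.csv")
      wr(bundle$recovery, "recovery.csv")
    }
  }
  bundle
}
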