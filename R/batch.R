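#' Plate well coordinates in processing order
#'
#' The 48-well plate is addressed as rows A-F by columns 1-8 and processed
#' row-major (A1, A2, ..., A8, B1, ..., F8), the common robotic convention.
#'
#' @return Character vector of the 48 well names in processing order.
#' @export
plate_wells <- function() {
  paste0(rep(LETTERS[1:6], each = 8), rep(1:8, times = 6))
}

#' Roles an injection or well can carry
#' @keywords internal
BATCH_ROLES <- c("dcm_blank", "acn_blank", "calibrant",
                 "qc_low", "qc_high", "unknown")
WELL_ROLES <- c("dcm_blank", "qc_low", "qc_high", "unknown")

#' Construct a plate batch
#'
#' A \code{vna_batch} holds the plate map of one 48-well batch (well,
#' sample id, role for each of the 48 positions, in processing order) and,
#' once acquired or simulated, the per-injection peak records.
#'
#' @param batch_id batch identifier.
#' @param wells data frame with columns \code{well}, \code{sample_id},
#'   \code{role}; one row per plate position.
#' @param records optional data frame of injection records (see
#'   \code{\link{generate_batch}} for the columns).
#' @return A list of class \code{vna_batch}.
#' @seealso \code{\link{validate_batch}}, \code{\link{default_layout}}
#' @export
vna_batch <- function(batch_id, wells, records = NULL) {
  structure(list(batch_id = as.character(batch_id),
                 wells = as.data.frame(wells),
                 records = records),
            class = "vna_batch")
}

#' Default plate layout
#'
#' A well-formed batch skeleton: DCM blanks in the first (A1) and last (F8)
#' wells, one low and one high QC pool (A2, A3), and 44 unknown samples.
#'
#' @param batch_id batch identifier.
#' @param sample_ids ids for the 44 unknowns; generated when \code{NULL}.
#' @return A \code{\link{vna_batch}} skeleton (no records).
#' @examples
#' b <- default_layout("B001")
#' validate_batch(b)  # character(0)
#' @export
default_layout <- function(batch_id = "BATCH1", sample_ids = NULL) {
  wells <- plate_wells()
  role <- rep("unknown", 48)
  role[c(1, 48)] <- "dcm_blank"
  role[2] <- "qc_low"
  role[3] <- "qc_high"
  if (is.null(sample_ids))
    sample_ids <- sprintf("%s-S%02d", batch_id, seq_len(44))
  if (length(sample_ids) != 44)
    stop("default layout needs exactly 44 unknown sample ids")
  sid <- character(48)
  sid[role == "dcm_blank"] <- paste0(batch_id, c("-DCMBLK1", "-DCMBLK2"))
  sid[role == "qc_low"] <- paste0(batch_id, "-QCL")
  sid[role == "qc_high"] <- paste0(batch_id, "-QCH")
  sid[role == "unknown"] <- sample_ids
  vna_batch(batch_id,
            data.frame(well = wells, sample_id = sid, role = role,
                       stringsAsFactors = FALSE))
}

#' Structural validation of a plate batch
#'
#' Checks the structural rules of a batch and returns the violations found
#' (an empty character vector for a well-formed batch); it never throws.
#' Rules: exactly 48 known wells, no duplicates, DCM blanks in the first
#' and last processing positions, known roles, and — when records are
#' present — records that reference known wells and carry no negative or
#' non-finite areas.
#'
#' @param batch a \code{\link{vna_batch}}.
#' @param panel analyte panel used to check record analyte names.
#' @return Character vector of human-readable violations.
#' @export
validate_batch <- function(batch, panel = default_panel()) {
  v <- character(0)
  w <- batch$wells
  expected <- plate_wells()
  if (!all(c("well", "sample_id", "role") %in% names(w)))
    return("wells table must have columns well, sample_id, role")
  if (nrow(w) != 48)
    v <- c(v, sprintf("expected 48 wells, found %d", nrow(w)))
  dup <- unique(w$well[duplicated(w$well)])
  if (length(dup))
    v <- c(v, paste0("duplicate well(s): ", paste(dup, collapse = ", ")))
  unknown_wells <- setdiff(w$well, expected)
  if (length(unknown_wells))
    v <- c(v, paste0("unknown well coordinate(s): ",
                     paste(unknown_wells, collapse = ", ")))
  bad_role <- setdiff(unique(w$role), WELL_ROLES)
  if (length(bad_role))
    v <- c(v, paste0("unknown role(s): ", paste(bad_role, collapse = ", "),
                     " (allowed: ", paste(WELL_ROLES, collapse = ", "), ")"))
  ord <- w[match(expected, w$well), ]
  first_last <- expected[c(1, 48)]
  for (fl in first_last) {
    r <- w$role[w$well == fl]
    if (length(r) == 1 && !is.na(r) && r != "dcm_blank")
      v <- c(v, sprintf("well %s must be a DCM blank (role is '%s')", fl, r))
    if (length(r) == 0)
      v <- c(v, sprintf("well %s (DCM blank position) is missing", fl))
  }
  if (!is.null(batch$records) && nrow(batch$records)) {
    rec <- batch$records
    known_pos <- c(w$well, unique(grep("^VIAL:", rec$well, value = TRUE)))
    bad_ref <- setdiff(unique(rec$well), known_pos)
    if (length(bad_ref))
      v <- c(v, paste0("records reference unknown position(s): ",
                       paste(bad_ref, collapse = ", ")))
    bad_an <- setdiff(unique(rec$analyte), panel$name)
    if (length(bad_an))
      v <- c(v, paste0("records reference unknown analyte(s): ",
                       paste(bad_an, collapse = ", ")))
    areas <- c(rec$quant_area, rec$confirm_area, rec$istd_area)
    if (any(!is.finite(areas) | areas < 0))
      v <- c(v, "records contain negative or non-finite peak areas")
    idx_by_an <- split(rec$injection_index, rec$analyte)
    if (any(vapply(idx_by_an, anyDuplicated, 0L) > 0))
      v <- c(v, "injection_index not unique within batch per analyte")
  }
  v
}

#' @export
print.vna_batch <- function(x, ...) {
  cat("VNA plate batch", x$batch_id, "\n")
  cat("  wells:", nrow(x$wells), "-",
      paste(names(table(x$wells$role)), table(x$wells$role),
            sep = "=", collapse = ", "), "\n")
  if (is.null(x$records)) {
    cat("  records: none (skeleton)\n")
  } else {
    cat("  records:", nrow(x$records), "injections x analytes\n")
  }
  viol <- validate_batch(x)
  if (length(viol)) cat("  VIOLATIONS:", paste(viol, collapse = "; "), "\n")
  invisible(x)
}
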