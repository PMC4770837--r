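#' Characterize QC pools
#'
#' Sample mean and SD of historical QC results per (analyte, pool), used as
#' the centre and scale of the control chart. Characterization is frozen:
#' it is not updated by in-flight batches, which prevents slow drift from
#' masking itself, and is only replaced by an explicit re-characterization.
#'
#' @param qc_values data frame with columns \code{analyte}, \code{pool}
#'   (\code{"qc_low"}/\code{"qc_high"}), \code{value} (pg/mL).
#' @return Data frame of class \code{vna_qc_char}: \code{analyte},
#'   \code{pool}, \code{mean}, \code{sd}, \code{n_runs}. Fewer than 2
#'   values or a zero SD in any group is an error; fewer than 20 values
#'   warns (the characterization is then statistically weak).
#' @examples
#' characterize_qc(data.frame(analyte = "NDMA", pool = "qc_low",
#'                            value = c(49, 51, 50, 48, 52) + rep(0, 5)))
#' @export
characterize_qc <- function(qc_values) {
  grp <- interaction(qc_values$analyte, qc_values$pool, drop = TRUE)
  out <- do.call(rbind, lapply(split(qc_values, grp), function(d) {
    if (nrow(d) < 2)
      stop("QC characterization needs at least 2 values for ",
           d$analyte[1], "/", d$pool[1])
    s <- stats::sd(d$value)
    if (s == 0)
      stop("QC values for ", d$analyte[1], "/", d$pool[1],
           " are constant; SD must be > 0 for control rules")
    data.frame(analyte = d$analyte[1], pool = d$pool[1],
               mean = mean(d$value), sd = s, n_runs = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (any(out$n_runs < 20))
    warning("QC characterization based on fewer than 20 runs for: ",
            paste(out$analyte[out$n_runs < 20], out$pool[out$n_runs < 20],
                  sep = "/", collapse = ", "))
  class(out) <- c("vna_qc_char", "data.frame")
  out
}

.zscore <- function(d, char, what = "QC") {
  key <- paste(d$analyte, d$pool)
  ck <- paste(char$analyte, char$pool)
  hit <- match(key, ck)
  if (anyNA(hit))
    stop("missing characterization for ",
         paste(unique(key[is.na(hit)]), collapse = ", "))
  (d$value - char$mean[hit]) / char$sd[hit]
}

#' Evaluate batch QC with Westgard multirules
#'
#' Computes z-scores of the batch's QC results against the frozen
#' characterization and evaluates the enabled rules:
#' \describe{
#'   \item{1_2s}{any |z| > 2 (warning by default).}
#'   \item{1_3s}{any |z| > 3.}
#'   \item{2_2s}{two consecutive z beyond the same-side 2 SD — evaluated
#'     across pools within the run and, when history is supplied, within a
#'     pool against the previous run.}
#'   \item{R_4s}{within the run, one z above +2 and another below -2.}
#'   \item{4_1s}{four consecutive z beyond the same-side 1 SD within a
#'     pool (needs 3 historical values).}
#'   \item{10_x}{ten consecutive values on the same side of the mean
#'     within a pool (needs 9 historical values).}
#' }
#' The verdict is \code{"reject"} if any enabled rejection rule fires,
#' otherwise \code{"warn"} if a warning rule fires, otherwise
#' \code{"accept"}. Enabling additional rules can only move the verdict
#' toward rejection, never away from it.
#'
#' @param current data frame of this batch's QC results: \code{analyte},
#'   \code{pool}, \code{value}.
#' @param char a \code{\link{characterize_qc}} result covering every
#'   (analyte, pool) in \code{current}.
#' @param rules a \code{\link{westgard_ruleset}}.
#' @param history optional data frame \code{(analyte, pool, value)} of
#'   recent historical QC values in chronological order, consumed by the
#'   sequential rules (2_2s within pool, 4_1s, 10_x).
#' @return List with \code{verdict} ("accept"/"warn"/"reject"),
#'   \code{z} (current data with z-scores), and \code{violations} (data
#'   frame: analyte, rule, pools, z-scores involved, action).
#' @export
evaluate_batch_qc <- function(current, char, rules = westgard_ruleset(),
                              history = NULL) {
  z <- .zscore(current, char)
  cur <- cbind(current, z = z)
  viol <- list()
  add_viol <- function(analyte, rule, pools, zs) {
    viol[[length(viol) + 1L]] <<- data.frame(
      analyte = analyte, rule = rule,
      pools = paste(pools, collapse = "+"),
      z = paste(sprintf("%+.2f", zs), collapse = ","),
      action = rules$action[[rule]], stringsAsFactors = FALSE)
  }
  en <- rules$enabled

  if (en[["1_2s"]]) {
    i <- which(abs(cur$z) > 2)
    for (k in i) add_viol(cur$analyte[k], "1_2s", cur$pool[k], cur$z[k])
  }
  if (en[["1_3s"]]) {
    i <- which(abs(cur$z) > 3)
    for (k in i) add_viol(cur$analyte[k], "1_3s", cur$pool[k], cur$z[k])
  }

  needs_groups <- en[["2_2s"]] || en[["R_4s"]]
  if (needs_groups) {
    for (d in split(cur, cur$analyte)) {
      an <- d$analyte[1]
      if (en[["2_2s"]] && nrow(d) >= 2) {
        if (sum(d$z > 2) >= 2)
          add_viol(an, "2_2s", d$pool[d$z > 2], d$z[d$z > 2])
        else if (sum(d$z < -2) >= 2)
          add_viol(an, "2_2s", d$pool[d$z < -2], d$z[d$z < -2])
      }
      if (en[["R_4s"]] && nrow(d) >= 2 &&
          any(d$z > 2) && any(d$z < -2))
        add_viol(an, "R_4s", d$pool, range(d$z))
    }
  }

  needs_seq <- (en[["2_2s"]] || en[["4_1s"]] || en[["10_x"]]) &&
    !is.null(history) && nrow(history) > 0
  if (needs_seq) {
    hz <- .zscore(history, char)
    hist2 <- cbind(history, z = hz)
    for (k in seq_len(nrow(cur))) {
      h <- hist2[hist2$analyte == cur$analyte[k] &
                   hist2$pool == cur$pool[k], ]
      series <- c(h$z, cur$z[k])
      n <- length(series)
      if (en[["2_2s"]] && n >= 2) {
        last2 <- series[(n - 1):n]
        if (all(last2 > 2) || all(last2 < -2))
          add_viol(cur$analyte[k], "2_2s", cur$pool[k], last2)
      }
      if (en[["4_1s"]] && n >= 4) {
        last4 <- series[(n - 3):n]
        if (all(last4 > 1) || all(last4 < -1))
          add_viol(cur$analyte[k], "4_1s", cur$pool[k], last4)
      }
      if (en[["10_x"]] && n >= 10) {
        last10 <- series[(n - 9):n]
        if (all(last10 > 0) || all(last10 < 0))
          add_viol(cur$analyte[k], "10_x", cur$pool[k], last10)
      }
    }
  }

  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(analyte = character(0), rule = character(0),
               pools = character(0), z = character(0),
               action = character(0), stringsAsFactors = FALSE)
  verdict <- if (any(violations$action == "reject")) "reject"
  else if (any(violations$action == "warn")) "warn"
  else "accept"
  list(verdict = verdict, z = cur, violations = violations)
}

#' Levey-Jennings export
#'
#' Flattens historical and current QC values into (run index, z-score) rows
#' per analyte and pool, ready for control-chart plotting.
#'
#' @inheritParams evaluate_batch_qc
#' @return Data frame: analyte, pool, run_index, value, z.
#' @export
levey_jennings_data <- function(current, char, history = NULL) {
  all_vals <- rbind(
    if (!is.null(history)) cbind(history, when = "history"),
    cbind(current, when = "current"))
  z <- .zscore(all_vals, char)
  out <- do.call(rbind, lapply(
    split(seq_len(nrow(all_vals)),
          interaction(all_vals$analyte, all_vals$pool, drop = TRUE)),
    function(i) data.frame(analyte = all_vals$analyte[i],
                           pool = all_vals$pool[i],
                           run_index = seq_along(i),
                           value = all_vals$value[i], z = z[i],
                           stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
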