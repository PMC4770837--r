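#' Default QC characterization
#'
#' The frozen control-chart centre and scale shipped with the package: for
#' every analyte, the low and high QC pools at their nominal values (50 and
#' 200 pg/mL), with the SD derived from the noise model of the matching
#' \code{\link{sim_config}} so that routine simulated batches are
#' in-control: total variance = nominal^2 * (run CV^2 + proportional CV^2)
#' + additive concentration variance (plus half of it again from the
#' two-blank subtraction). A production lab replaces this table with its
#' own \code{\link{characterize_qc}} output from real history.
#'
#' @param panel analyte panel.
#' @param sim the simulation settings the characterization must match.
#' @param constants method constants.
#' @param n_runs nominal characterization depth recorded (60).
#' @return A \code{vna_qc_char} data frame.
#' @export
default_qc_characterization <- function(panel = default_panel(),
                                        sim = sim_config(),
                                        constants = method_constants(),
                                        n_runs = 60) {
  out <- expand.grid(analyte = panel$name, pool = c("qc_low", "qc_high"),
                     stringsAsFactors = FALSE)
  attr(out, "out.attrs") <- NULL
  out$mean <- ifelse(out$pool == "qc_low", sim$qc_low_pg_ml,
                     sim$qc_high_pg_ml)
  g <- sim$response_factor[out$analyte]
  add_conc_sd <- ratio_to_conc(
    sim$additive_sd_area / (g * sim$istd_area_mean), constants)
  out$sd <- sqrt(out$mean^2 * (sim$run_cv^2 + sim$proportional_cv^2) +
                   1.5 * add_conc_sd^2)
  # A fully noise-free simulation would give sd 0 and undefined z-scores;
  # floor the scale far below any real spread so exact values score z = 0.
  out$sd <- pmax(out$sd, 1e-6)
  out$n_runs <- n_runs
  class(out) <- c("vna_qc_char", "data.frame")
  out
}

#' Assemble a full pipeline configuration
#'
#' @param panel analyte panel (\code{\link{default_panel}}).
#' @param constants method constants (\code{\link{method_constants}}).
#' @param qa QA tolerances (\code{\link{qa_rule_config}}).
#' @param westgard Westgard rule set (\code{\link{westgard_ruleset}}).
#' @param qc_char frozen QC characterization
#'   (\code{\link{default_qc_characterization}}).
#' @param sim simulation settings (\code{\link{sim_config}}).
#' @return A list of class \code{vna_config}.
#' @export
vna_config <- function(panel = default_panel(),
                       constants = method_constants(),
                       qa = qa_rule_config(),
                       westgard = westgard_ruleset(),
                       qc_char = default_qc_characterization(panel, sim,
                                                             constants),
                       sim = sim_config()) {
  structure(list(panel = panel, constants = constants, qa = qa,
                 westgard = westgard, qc_char = qc_char, sim = sim),
            class = "vna_config")
}

#' @rdname vna_config
#' @export
default_config <- function() vna_config()

#' Load a pipeline configuration from JSON
#'
#' The file has sections \code{panel}, \code{constants}, \code{qa_rules},
#' \code{westgard_rules}, \code{qc_characterization} and
#' \code{simulation}; any absent section or field falls back to the shipped
#' default. All invariants are re-validated on load (a missing ISTD pairing
#' names the analyte; non-positive thresholds are configuration errors).
#' \code{save_config} followed by \code{load_config} reproduces the
#' configuration exactly.
#'
#' @param path path to a JSON configuration file.
#' @return A \code{\link{vna_config}}.
#' @seealso \code{\link{save_config}}
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  panel <- if (is.null(raw$panel)) default_panel()
  else as_vna_panel(as.data.frame(raw$panel))
  constants <- do.call(method_constants, .known_args(raw$constants,
                                                     method_constants))
  qa <- do.call(qa_rule_config, .known_args(raw$qa_rules, qa_rule_config))
  westgard <- if (is.null(raw$westgard_rules)) westgard_ruleset()
  else westgard_ruleset(
    enabled = unlist(raw$westgard_rules$enabled),
    actions = unlist(raw$westgard_rules$actions))
  sim_args <- .known_args(raw$simulation, sim_config)
  for (nm in c("true_conc_pg_ml", "ion_ratio_true", "response_factor"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  sim <- do.call(sim_config, sim_args)
  qc_char <- if (is.null(raw$qc_characterization))
    default_qc_characterization(panel, sim, constants)
  else {
    qc <- as.data.frame(raw$qc_characterization)
    class(qc) <- c("vna_qc_char", "data.frame")
    qc
  }
  vna_config(panel, constants, qa, westgard, qc_char, sim)
}

.known_args <- function(section, fun) {
  if (is.null(section)) return(list())
  known <- names(formals(fun))
  unknown <- setdiff(names(section), known)
  if (length(unknown))
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "))
  section[intersect(names(section), known)]
}

#' Save a pipeline configuration to JSON
#'
#' @param config a \code{\link{vna_config}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  w <- config$westgard
  sim <- unclass(config$sim)
  for (nm in c("true_conc_pg_ml", "ion_ratio_true", "response_factor"))
    if (!is.null(sim[[nm]])) sim[[nm]] <- as.list(sim[[nm]])
  out <- list(
    panel = as.data.frame(unclass(config$panel)),
    constants = unclass(config$constants),
    qa_rules = unclass(config$qa),
    westgard_rules = list(enabled = names(w$enabled)[w$enabled],
                          actions = as.list(w$action)),
    qc_characterization = as.data.frame(unclass(config$qc_char)),
    simulation = sim)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.vna_config <- function(x, ...) {
  cat("VNA pipeline configuration\n")
  cat("  panel:", nrow(x$panel), "analytes;",
      "Westgard rules enabled:",
      paste(names(x$westgard$enabled)[x$westgard$enabled],
            collapse = ", "), "\n")
  cat("  sim seed:", x$sim$seed,
      " proportional CV:", x$sim$proportional_cv,
      " run CV:", x$sim$run_cv, "\n")
  invisible(x)
}
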