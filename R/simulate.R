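#' Simulation configuration
#'
#' Parameters of the synthetic injection-data generator. The generator
#' emulates the structure of a production batch: a 48-well plate with DCM
#' blanks in the first and last wells, QC pools at 50 and 200 pg/mL, a
#' calibration series up to the 400 ng/mL top standard injected ahead of
#' the plate, NDMA contamination in the DCM blanks at roughly 1-2x the
#' method LOD, and a small carryover after high injections for the
#' carryover-prone analytes.
#'
#' The noise model is multiplicative-plus-additive on the quant-ion area:
#' \code{quant_area = g * amount_ratio * istd_area * run_factor *
#' (1 + eps_prop) + eps_add}, truncated at zero, with
#' \code{eps_prop ~ N(0, proportional_cv)},
#' \code{eps_add ~ N(0, additive_sd_area)} and a per-run factor
#' \code{run_factor ~ N(1, run_cv)} shared by all injections of a batch.
#' The proportional term reproduces the concentration-independent CVs seen
#' in routine QC material; the additive term sets the noise floor that
#' determines the limit of detection; the run factor makes inter-run
#' variability exceed intra-run variability.
#'
#' @param seed integer seed; together with a batch id it fully determines a
#'   batch (see \code{\link{generate_batch}}).
#' @param true_conc_pg_ml named numeric, true concentration of each analyte
#'   in unknown wells, pg/mL. Defaults emulate non-smoker urine: a small
#'   endogenous level for NDMA, NPYR and NMOR, zero for the others.
#' @param qc_low_pg_ml,qc_high_pg_ml QC pool concentrations (50, 200).
#' @param proportional_cv fractional proportional noise on the response
#'   (0.05).
#' @param additive_sd_area additive area noise SD, counts (800; about 2
#'   pg/mL at the default response factor and ISTD level).
#' @param istd_area_mean,istd_area_cv ISTD area level and its fractional
#'   spread (1e5, 0.05).
#' @param run_cv SD of the per-run multiplicative factor (0.05).
#' @param ndma_blank_contamination_pg_ml NDMA level in DCM blanks (9.81,
#'   i.e. 1.5x the shipped NDMA LOD).
#' @param carryover_fraction fraction of the previous injection's quant
#'   area carried into the next injection for carryover-prone analytes
#'   (0.002).
#' @param rt_jitter_sd_min SD of retention-time jitter, minutes (0.01).
#' @param ion_ratio_true named numeric, true confirmation/quant ratio per
#'   analyte; defaults to the panel's expected ratios.
#' @param response_factor named numeric, detector response factor g per
#'   analyte (response ratio per unit amount ratio).
#' @return A list of class \code{vna_sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       true_conc_pg_ml = c(NDMA = 8, NMEA = 0, NDEA = 0,
                                           NPIP = 0, NPYR = 6, NMOR = 4),
                       qc_low_pg_ml = 50,
                       qc_high_pg_ml = 200,
                       proportional_cv = 0.05,
                       additive_sd_area = 800,
                       istd_area_mean = 1e5,
                       istd_area_cv = 0.05,
                       run_cv = 0.05,
                       ndma_blank_contamination_pg_ml = 9.81,
                       carryover_fraction = 0.002,
                       rt_jitter_sd_min = 0.01,
                       ion_ratio_true = NULL,
                       response_factor = c(NDMA = 0.95, NMEA = 1.05,
                                           NDEA = 1.10, NPIP = 0.90,
                                           NPYR = 1.00, NMOR = 0.85)) {
  if (proportional_cv < 0 || proportional_cv >= 1)
    stop("proportional_cv must be in [0, 1)")
  if (carryover_fraction < 0 || carryover_fraction >= 0.05)
    stop("carryover_fraction must be in [0, 0.05)")
  if (additive_sd_area < 0 || istd_area_cv < 0 || run_cv < 0 ||
      rt_jitter_sd_min < 0)
    stop("noise SDs must be non-negative")
  if (istd_area_mean <= 0) stop("istd_area_mean must be positive")
  structure(list(seed = as.integer(seed),
                 true_conc_pg_ml = unlist(true_conc_pg_ml),
                 qc_low_pg_ml = qc_low_pg_ml,
                 qc_high_pg_ml = qc_high_pg_ml,
                 proportional_cv = proportional_cv,
                 additive_sd_area = additive_sd_area,
                 istd_area_mean = istd_area_mean,
                 istd_area_cv = istd_area_cv,
                 run_cv = run_cv,
                 ndma_blank_contamination_pg_ml =
                   ndma_blank_contamination_pg_ml,
                 carryover_fraction = carryover_fraction,
                 rt_jitter_sd_min = rt_jitter_sd_min,
                 ion_ratio_true = if (is.null(ion_ratio_true)) NULL
                                  else unlist(ion_ratio_true),
                 response_factor = unlist(response_factor)),
            class = "vna_sim_config")
}

#' A noise-free simulation configuration
#'
#' All noise terms, contamination and carryover set to zero; useful for
#' identity checks (the full pipeline must then return true concentrations
#' exactly).
#'
#' @param ... overrides passed on to \code{\link{sim_config}}.
#' @export
noise_free_sim <- function(...) {
  args <- list(proportional_cv = 0, additive_sd_area = 0, istd_area_cv = 0,
               run_cv = 0, ndma_blank_contamination_pg_ml = 0,
               carryover_fraction = 0, rt_jitter_sd_min = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# Deterministic 31-bit stream seed from (seed, key), so each batch gets its
# own reproducible RNG stream.
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% m
  as.integer(((as.numeric(seed) %% m) * 48271 + h) %% m)
}

# Evaluate code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  pmax(stats::rnorm(n, mean, sd), 0)
}

# Sample content (what blank-subtracted quantitation should recover) of one
# sequence entry for one analyte, as an amount ratio.
.content_ratio <- function(role, analyte, cal_ratio, sim, constants) {
  switch(role,
         acn_blank = 0,
         dcm_blank = 0,
         calibrant = cal_ratio,
         qc_low = conc_to_ratio(sim$qc_low_pg_ml, constants),
         qc_high = conc_to_ratio(sim$qc_high_pg_ml, constants),
         unknown = conc_to_ratio(
           if (analyte %in% names(sim$true_conc_pg_ml))
             sim$true_conc_pg_ml[[analyte]] else 0, constants),
         stop("unknown role: ", role))
}

# Total analyte amount ratio including process contamination. NDMA is
# introduced wherever DCM touches plastic during sample preparation, so
# every plate-processed well (blanks, QCs, unknowns alike) carries the
# contamination level; solution vials (calibrants, ACN blanks) do not.
# This shared background is exactly what the in-batch DCM blank
# subtraction removes.
.true_ratio <- function(role, analyte, cal_ratio, sim, constants) {
  x <- .content_ratio(role, analyte, cal_ratio, sim, constants)
  if (analyte == "NDMA" &&
      role %in% c("dcm_blank", "qc_low", "qc_high", "unknown"))
    x <- x + conc_to_ratio(sim$ndma_blank_contamination_pg_ml, constants)
  x
}

#' Simulate injection records for a plate batch
#'
#' Builds the injection sequence for \code{layout} (leading ACN blank,
#' ascending calibrants, three ACN blanks after the top standard, then the
#' 48 wells in processing order), draws peak areas for every
#' (injection, analyte) under the model described in
#' \code{\link{sim_config}}, and applies injection carryover. The RNG
#' stream is keyed by \code{(sim$seed, batch_id)} so batches are
#' independently reproducible; the same configuration always yields
#' byte-identical records.
#'
#' @param sim a \code{\link{sim_config}}.
#' @param layout a \code{\link{vna_batch}} skeleton passing
#'   \code{\link{validate_batch}}.
#' @param panel analyte panel.
#' @param constants method constants.
#' @param cal_ratios ascending calibrant amount ratios.
#' @return The batch with \code{$records} filled (one row per injection and
#'   analyte; columns \code{sample_id}, \code{well},
#'   \code{injection_index}, \code{role}, \code{dilution}, \code{analyte},
#'   \code{quant_area}, \code{confirm_area}, \code{istd_area},
#'   \code{rt_quant_min}, \code{rt_istd_min},
#'   \code{calibrant_amount_ratio}) and \code{$truth} (true urine-phase
#'   concentration per sample and analyte, for recovery checks).
#' @examples
#' b <- generate_batch(noise_free_sim(), default_layout("B1"))
#' head(b$records)
#' @export
generate_batch <- function(sim, layout, panel = default_panel(),
                           constants = method_constants(),
                           cal_ratios = default_calibration_levels(constants)) {
  viol <- validate_batch(layout, panel)
  if (length(viol))
    stop("layout fails structural validation: ",
         paste(viol, collapse = "; "))
  seq_tab <- worklist_to_sequence(layout, cal_ratios)
  ion_true <- if (is.null(sim$ion_ratio_true))
    stats::setNames(panel$expected_ion_ratio, panel$name)
  else sim$ion_ratio_true

  n_inj <- nrow(seq_tab)
  n_an <- nrow(panel)
  with_seed(derive_seed(sim$seed, layout$batch_id), {
    run_factor <- stats::rnorm(1, 1, sim$run_cv)
    rows <- vector("list", n_an)
    for (j in seq_len(n_an)) {
      an <- panel$name[j]
      g <- sim$response_factor[[an]]
      x <- vapply(seq_len(n_inj), function(i)
        .true_ratio(seq_tab$role[i], an, seq_tab$calibrant_amount_ratio[i],
                    sim, constants), 0)
      istd <- rnorm_trunc0(n_inj, sim$istd_area_mean,
                           sim$istd_area_mean * sim$istd_area_cv)
      eps_prop <- stats::rnorm(n_inj, 0, sim$proportional_cv)
      eps_add <- stats::rnorm(n_inj, 0, sim$additive_sd_area)
      quant <- pmax(g * x * istd * run_factor * (1 + eps_prop) + eps_add, 0)
      eps_ion <- stats::rnorm(n_inj, 0, sim$proportional_cv)
      confirm <- pmax(quant * ion_true[[an]] * (1 + eps_ion), 0)
      rows[[j]] <- data.frame(
        sample_id = seq_tab$sample_id,
        well = seq_tab$position,
        injection_index = seq_tab$injection_index,
        role = seq_tab$role,
        dilution = seq_tab$dilution,
        analyte = an,
        quant_area = quant,
        confirm_area = confirm,
        istd_area = istd,
        rt_quant_min = panel$expected_rt_min[j] +
          stats::rnorm(n_inj, 0, sim$rt_jitter_sd_min),
        rt_istd_min = panel$expected_rt_istd_min[j] +
          stats::rnorm(n_inj, 0, sim$rt_jitter_sd_min),
        calibrant_amount_ratio = seq_tab$calibrant_amount_ratio,
        stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rows)
    rec <- rec[order(rec$injection_index, rec$analyte), ]
    rownames(rec) <- NULL
    rec <- apply_carryover(rec, sim, panel)

    # truth = sample content (excludes the process contamination that the
    # in-batch blank subtraction removes)
    truth <- do.call(rbind, lapply(panel$name, function(an) {
      conc <- vapply(seq_len(n_inj), function(i)
        ratio_to_conc(.content_ratio(seq_tab$role[i], an,
                                     seq_tab$calibrant_amount_ratio[i],
                                     sim, constants), constants), 0)
      data.frame(sample_id = seq_tab$sample_id, analyte = an,
                 role = seq_tab$role, true_conc_pg_ml = conc,
                 stringsAsFactors = FALSE)
    }))
    out <- layout
    out$records <- rec
    out$truth <- truth
    out
  })
}

#' Apply injection carryover to simulated records
#'
#' For each carryover-prone analyte, every injection after the first gains
#' \code{carryover_fraction} times the quant area its immediate predecessor
#' had before carryover was applied (non-cascading; at fractions below 5\%
#' the neglected second-order term is under 0.25\% of the added area).
#' Non-prone analytes and the first injection are unchanged, so total added
#' area equals \code{carryover_fraction} times the sum of predecessor
#' areas.
#'
#' @param records injection records sorted by \code{injection_index}.
#' @param sim a \code{\link{sim_config}}.
#' @param panel analyte panel (identifies carryover-prone analytes).
#' @return The records with carryover added.
#' @export
apply_carryover <- function(records, sim, panel = default_panel()) {
  if (is.unsorted(records$injection_index))
    stop("records must be sorted by injection_index")
  if (sim$carryover_fraction == 0) return(records)
  prone <- panel$name[panel$carryover_prone]
  for (an in prone) {
    i <- which(records$analyte == an)
    i <- i[order(records$injection_index[i])]
    if (length(i) < 2) next
    a <- records$quant_area[i]
    records$quant_area[i] <- a +
      sim$carryover_fraction * c(0, a[-length(a)])
  }
  records
}

#' Simulate a method-validation study
#'
#' Generates the measured concentrations of one of the three validation
#' designs, with the same noise model as \code{\link{generate_batch}} (the
#' simulated areas are inverted through the generating response factor, as
#' a perfect calibration would):
#' \describe{
#'   \item{\code{precision_6x5}}{6 replicates x 5 runs of the 50 and 200
#'     pg/mL QC pools; each run has its own run factor.}
#'   \item{\code{accuracy_matrix_3x3x3}}{triplicates on 3 days at spikes of
#'     100, 200 and 300 pg/mL over the endogenous baseline, plus unspiked
#'     triplicates per day (27 spiked + 9 baseline records per analyte).}
#'   \item{\code{lod_pools_60}}{60 runs (one per day) of the 4 low pools at
#'     0, 2.5, 5 and 7.5 pg/mL, plus one DCM blank per run. Pools and
#'     blanks are plate-processed, so for NDMA both carry the process
#'     contamination; per-run blank correction (pool minus the run's
#'     blank) recovers the nominal level and roughly doubles the variance.}
#' }
#'
#' @param design one of \code{"precision_6x5"},
#'   \code{"accuracy_matrix_3x3x3"}, \code{"lod_pools_60"}.
#' @param sim a \code{\link{sim_config}}.
#' @param panel analyte panel.
#' @param constants method constants.
#' @return A data frame with columns \code{analyte}, \code{run},
#'   \code{replicate}, \code{sample_type}, \code{nominal_pg_ml} (pool,
#'   spike or baseline-truth concentration) and \code{measured_pg_ml}.
#' @export
generate_validation_study <- function(design = c("precision_6x5",
                                                 "accuracy_matrix_3x3x3",
                                                 "lod_pools_60"),
                                      sim = sim_config(),
                                      panel = default_panel(),
                                      constants = method_constants()) {
  design <- match.arg(design)
  plan <- switch(design,
    precision_6x5 = {
      g <- expand.grid(replicate = 1:6, run = 1:5,
                       nominal = c(sim$qc_low_pg_ml, sim$qc_high_pg_ml))
      g$sample_type <- ifelse(g$nominal == sim$qc_low_pg_ml,
                              "qc_low", "qc_high")
      g$true <- g$nominal
      g
    },
    accuracy_matrix_3x3x3 = {
      sp <- expand.grid(replicate = 1:3, run = 1:3,
                        nominal = c(100, 200, 300))
      sp$sample_type <- "spiked"
      bl <- expand.grid(replicate = 1:3, run = 1:3, nominal = 0)
      bl$sample_type <- "baseline"
      rbind(sp, bl)
    },
    lod_pools_60 = {
      g <- expand.grid(replicate = 1L, run = 1:60,
                       nominal = c(0, 2.5, 5, 7.5))
      g$sample_type <- "pool"
      g$true <- g$nominal
      bl <- data.frame(replicate = 1L, run = 1:60, nominal = 0,
                       sample_type = "dcm_blank", true = 0)
      rbind(g, bl)
    })

  with_seed(derive_seed(sim$seed, paste0("study:", design)), {
    out <- lapply(panel$name, function(an) {
      g <- sim$response_factor[[an]]
      baseline <- if (an %in% names(sim$true_conc_pg_ml))
        sim$true_conc_pg_ml[[an]] else 0
      p <- plan
      if (design == "accuracy_matrix_3x3x3") p$true <- baseline + p$nominal
      if (design == "lod_pools_60" && an == "NDMA")
        p$true <- p$true + sim$ndma_blank_contamination_pg_ml
      n <- nrow(p)
      run_factor <- stats::rnorm(max(p$run), 1, sim$run_cv)[p$run]
      istd <- rnorm_trunc0(n, sim$istd_area_mean,
                           sim$istd_area_mean * sim$istd_area_cv)
      x <- conc_to_ratio(p$true, constants)
      quant <- pmax(g * x * istd * run_factor *
                      (1 + stats::rnorm(n, 0, sim$proportional_cv)) +
                      stats::rnorm(n, 0, sim$additive_sd_area), 0)
      measured <- ratio_to_conc((quant / istd) / g, constants)
      data.frame(analyte = an, run = p$run, replicate = p$replicate,
                 sample_type = p$sample_type, nominal_pg_ml = p$nominal,
                 true_pg_ml = p$true, measured_pg_ml = measured,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
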