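# Independent reference implementations ("oracles") used by the test suite.
# These are plain, loop-based transliterations of the rule definitions and
# deliberately share no code with the package internals, so agreement is a
# genuine cross-check rather than a tautology.

# Weighted least squares by direct normal equations.
wls_oracle <- function(x, y, w) {
  sw <- sum(w)
  sx <- sum(w * x)
  sy <- sum(w * y)
  sxx <- sum(w * x^2)
  sxy <- sum(w * x * y)
  slope <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
  intercept <- (sy - slope * sx) / sw
  c(intercept = intercept, slope = slope)
}

# Tiered duplicate-injection repeatability criterion (scalar).
repeatability_oracle <- function(a, b) {
  m <- (a + b) / 2
  if (m == 0) return(a == b)
  rel <- abs(a - b) / m * 100
  if (m < 50) rel <= 20 else rel <= 10
}

# Westgard multirules from their textbook definitions. `cur` is a named
# vector of the current run's z-scores (one value per pool); `hist` a named
# list of each pool's preceding z-scores in chronological order. Assumes
# the default actions (1_2s warns, all other rules reject).
westgard_oracle <- function(cur, hist = NULL,
                            enabled = c("1_2s", "1_3s", "2_2s", "R_4s")) {
  fired <- character(0)
  if (any(abs(cur) > 2)) fired <- c(fired, "1_2s")
  if (any(abs(cur) > 3)) fired <- c(fired, "1_3s")
  two2s <- length(cur) >= 2 && (sum(cur > 2) >= 2 || sum(cur < -2) >= 2)
  four1s <- FALSE
  tenx <- FALSE
  for (pool in names(cur)) {
    series <- c(if (!is.null(hist)) hist[[pool]], cur[[pool]])
    n <- length(series)
    if (n >= 2) {
      last2 <- series[(n - 1):n]
      if (all(last2 > 2) || all(last2 < -2)) two2s <- TRUE
    }
    if (n >= 4) {
      last4 <- series[(n - 3):n]
      if (all(last4 > 1) || all(last4 < -1)) four1s <- TRUE
    }
    if (n >= 10) {
      last10 <- series[(n - 9):n]
      if (all(last10 > 0) || all(last10 < 0)) tenx <- TRUE
    }
  }
  if (two2s) fired <- c(fired, "2_2s")
  if (length(cur) >= 2 && any(cur > 2) && any(cur < -2))
    fired <- c(fired, "R_4s")
  if (four1s) fired <- c(fired, "4_1s")
  if (tenx) fired <- c(fired, "10_x")
  fired <- sort(unique(intersect(fired, enabled)))
  verdict <- if (any(fired != "1_2s")) "reject"
  else if ("1_2s" %in% fired) "warn" else "accept"
  list(fired = fired, verdict = verdict)
}

# Drive the package engine on bare z-scores (unit characterization).
run_westgard_engine <- function(cur, hist = NULL,
                                enabled = c("1_2s", "1_3s", "2_2s", "R_4s"),
                                analyte = "NDMA") {
  char <- data.frame(analyte = analyte, pool = names(cur), mean = 0, sd = 1,
                     n_runs = 60, stringsAsFactors = FALSE)
  class(char) <- c("vna_qc_char", "data.frame")
  current <- data.frame(analyte = analyte, pool = names(cur),
                        value = unname(cur), stringsAsFactors = FALSE)
  history <- NULL
  if (!is.null(hist) && any(lengths(hist) > 0)) {
    history <- do.call(rbind, lapply(names(hist), function(p) {
      if (!length(hist[[p]])) return(NULL)
      data.frame(analyte = analyte, pool = p, value = hist[[p]],
                 stringsAsFactors = FALSE)
    }))
  }
  evaluate_batch_qc(current, char, westgard_ruleset(enabled = enabled),
                    history = history)
}

# Build a minimal synthetic (records, results) pair for the QA engine from
# a per-injection condition table. One analyte (NDMA); `spec` has columns
# role, rt_q_dev, rt_i_dev, ion_mult (NA = no quant peak), istd_area, conc.
make_qa_case <- function(spec, panel = default_panel(), batch = "Q") {
  n <- nrow(spec)
  an <- "NDMA"
  p <- panel[panel$name == an, ]
  quant <- ifelse(is.na(spec$ion_mult), 0, 1e4)
  confirm <- ifelse(is.na(spec$ion_mult), 0,
                    quant * p$expected_ion_ratio * spec$ion_mult)
  records <- data.frame(
    sample_id = sprintf("%s-%02d", batch, seq_len(n)),
    well = sprintf("W%02d", seq_len(n)),
    injection_index = seq_len(n),
    role = spec$role,
    dilution = 1,
    analyte = an,
    quant_area = quant,
    confirm_area = confirm,
    istd_area = spec$istd_area,
    rt_quant_min = p$expected_rt_min + spec$rt_q_dev,
    rt_istd_min = p$expected_rt_istd_min + spec$rt_i_dev,
    calibrant_amount_ratio = NA_real_,
    stringsAsFactors = FALSE)
  unq <- spec$istd_area <= 0
  results <- data.frame(
    sample_id = records$sample_id,
    well = records$well,
    injection_index = records$injection_index,
    role = spec$role,
    analyte = an,
    response_ratio = ifelse(unq, NA_real_, quant / spec$istd_area),
    raw_conc_pg_ml = ifelse(unq, NA_real_, spec$conc),
    unquantifiable = unq,
    blank_sub_conc_pg_ml = ifelse(unq, NA_real_, spec$conc),
    below_lod = FALSE,
    stringsAsFactors = FALSE)
  list(records = records, results = results)
}

# Brute-force evaluation of every QA rule for every row of `results`,
# straight from the rule statements. Returns (sample_id, analyte, rule_id,
# passed).
qa_oracle_flags <- function(results, records, panel = default_panel(),
                            cfg = qa_rule_config(),
                            constants = method_constants(),
                            reinjections = NULL) {
  idx <- sort(unique(results$injection_index))
  thr <- constants$carryover_flag_threshold_pg_ml
  rows <- list()
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    rec <- records[records$injection_index == r$injection_index &
                     records$analyte == r$analyte, ]
    p <- panel[panel$name == r$analyte, ]
    obs_ion <- if (rec$quant_area > 0) rec$confirm_area / rec$quant_area
               else NA_real_
    is_blank <- r$role == "dcm_blank" ||
      (cfg$check_leading_acn_blank && r$role == "acn_blank" &&
         r$injection_index == min(results$injection_index))
    pos <- which(idx == r$injection_index)
    if (pos == 1) {
      carry_pass <- TRUE
    } else {
      pred <- results$blank_sub_conc_pg_ml[
        results$injection_index == idx[pos - 1]]
      pred <- pred[!is.na(pred)]
      pred_max <- if (length(pred)) max(pred) else -Inf
      carry_pass <- !(r$role == "unknown" && pred_max > thr)
    }
    rp_pass <- TRUE
    if (!is.null(reinjections)) {
      hit <- which(reinjections$sample_id == r$sample_id &
                     reinjections$analyte == r$analyte)
      if (length(hit) == 1)
        rp_pass <- repeatability_oracle(r$blank_sub_conc_pg_ml,
                                        reinjections$conc_pg_ml[hit])
    }
    pass <- c(
      rt_quant = abs(rec$rt_quant_min - p$expected_rt_min) <=
        cfg$rt_tolerance_min,
      rt_istd = abs(rec$rt_istd_min - p$expected_rt_istd_min) <=
        cfg$rt_tolerance_min,
      ion_ratio = !is.na(obs_ion) &&
        abs(obs_ion - p$expected_ion_ratio) / p$expected_ion_ratio * 100 <=
          cfg$ion_ratio_tolerance_pct,
      istd_area = rec$istd_area >= cfg$istd_area_min,
      blank_limit = !is_blank ||
        (is.finite(r$raw_conc_pg_ml) &&
           r$raw_conc_pg_ml <= p$blank_limit_pg_ml),
      carryover_follow = carry_pass,
      unquantifiable = !r$unquantifiable,
      repeat_fail = rp_pass)
    rows[[i]] <- data.frame(sample_id = r$sample_id, analyte = r$analyte,
                            rule_id = names(pass), passed = unname(pass),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Brute-force per-sample disposition from a sample's rule passes.
disposition_oracle <- function(rule_pass, has_reinj) {
  core <- rule_pass[!(names(rule_pass) %in%
                        c("carryover_follow", "repeat_fail"))]
  if (rule_pass[["carryover_follow"]]) {
    if (all(core)) "report" else "fail_qa"
  } else if (!has_reinj) {
    "reinject"
  } else if (rule_pass[["repeat_fail"]]) {
    if (all(core)) "report" else "fail_qa"
  } else {
    "repeat"
  }
}
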