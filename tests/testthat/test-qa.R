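test_that("retention-time, ion-ratio and ISTD rules at their boundaries", {
  p <- default_panel()
  cfg <- qa_rule_config()           # rt tol 0.1 min, ion tol 20%, istd 2e4
  rec <- data.frame(
    sample_id = sprintf("s%d", 1:5), well = sprintf("A%d", 4:8),
    injection_index = 1:5, role = "unknown", analyte = "NDMA",
    quant_area = c(1e4, 1e4, 1e4, 0, 1e4),
    confirm_area = c(0.62, 0.62 * 1.2, 0.62 * 1.21, 0, 0.62 * 0.8) * 1e4,
    istd_area = c(1e5, 2e4, 2e4 - 1, 1e5, 1e5),
    rt_quant_min = 5.21 + c(0, 0.1, 0.11, 0, -0.1),
    rt_istd_min = 5.19 + c(0, 0, 0.2, 0, 0),
    stringsAsFactors = FALSE)

  rt <- check_retention_times(rec, p, cfg)
  q <- rt[rt$rule_id == "rt_quant", ]
  expect_equal(q$passed, c(TRUE, TRUE, FALSE, TRUE, TRUE))  # |0.1| passes
  i <- rt[rt$rule_id == "rt_istd", ]
  expect_equal(i$passed, c(TRUE, TRUE, FALSE, TRUE, TRUE))

  ion <- check_ion_ratio(rec, p, cfg)
  # +20% passes (closed interval), +21% fails, no quant peak fails,
  # -20% passes
  expect_equal(ion$passed, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_match(ion$detail[4], "no quant peak")

  istd <- check_istd_area(rec, cfg)
  expect_equal(istd$passed, c(TRUE, TRUE, FALSE, TRUE, TRUE))  # >= passes
})

test_that("run-blank rejection: strict limits, boundary, missing blank", {
  p <- default_panel()
  lim <- p$blank_limit_pg_ml[p$name == "NDMA"]      # 13.08
  mk <- function(conc1, conc2) data.frame(
    sample_id = c("B-ACNBLK0", "B-DCMBLK1", "B-DCMBLK2"),
    well = c("VIAL:ACN", "A1", "F8"),
    injection_index = c(1, 2, 3),
    role = c("acn_blank", "dcm_blank", "dcm_blank"),
    analyte = "NDMA", raw_conc_pg_ml = c(0, conc1, conc2),
    stringsAsFactors = FALSE)

  ok <- check_run_blanks(mk(lim - 0.1, lim), p)     # exactly at limit passes
  expect_true(ok$accept)
  expect_equal(ok$verdict, "accept")
  expect_equal(nrow(ok$offending), 0)

  bad <- check_run_blanks(mk(lim + 0.01, 1), p)
  expect_false(bad$accept)
  expect_match(bad$reasons, "NDMA")
  expect_match(bad$reasons, "exceeds limit")
  expect_equal(bad$offending$sample_id, "B-DCMBLK1")

  # one DCM blank missing rejects outright
  miss <- check_run_blanks(mk(1, 1)[-2, ], p)
  expect_false(miss$accept)
  expect_match(miss$reasons, "missing blank")

  # the leading ACN blank is held to the limits when configured
  d <- mk(1, 1); d$raw_conc_pg_ml[1] <- lim + 5
  expect_false(check_run_blanks(d, p)$accept)
  cfg_off <- qa_rule_config(check_leading_acn_blank = FALSE)
  expect_true(check_run_blanks(d, p, cfg_off)$accept)
})

test_that("carryover follow-up flags the right injections", {
  res <- data.frame(
    sample_id = sprintf("s%d", 1:4), well = sprintf("A%d", 1:4),
    injection_index = 1:4,
    role = c("unknown", "unknown", "unknown", "qc_low"),
    analyte = "NDMA",
    blank_sub_conc_pg_ml = c(250, 30, 150, 40), stringsAsFactors = FALSE)
  fl <- flag_carryover_follow(res)
  # injection 1 has no predecessor; injection 2 follows 250 > 200 ->
  # flagged; injection 3 follows 30 -> clean; injection 4 follows 150 but
  # is a QC, rule only applies to unknowns
  expect_equal(fl$passed, c(TRUE, FALSE, TRUE, TRUE))
  expect_match(fl$detail[2], "reinjection required")
  expect_error(flag_carryover_follow(res[4:1, ]), "sorted")
  # exactly at the threshold does not flag (strictly greater)
  res$blank_sub_conc_pg_ml[1] <- 200
  expect_true(all(flag_carryover_follow(res)$passed))
})

test_that("tiered repeatability reproduces the worked pairs", {
  expect_true(check_repeatability(40, 46))     # 13.95% against the 20% tier
  expect_false(check_repeatability(100, 115))  # 13.95% against the 10% tier
  expect_true(check_repeatability(100, 110))   # 9.52% passes the 10% tier
  expect_false(check_repeatability(30, 45))    # 40% fails the 20% tier
  expect_true(check_repeatability(0, 0))       # exact zeros pass
  expect_false(check_repeatability(0.5, -0.5)) # zero mean, unequal: fail
  # vectorized
  expect_equal(check_repeatability(c(40, 100), c(46, 115)), c(TRUE, FALSE))
})

test_that("repeatability agrees with the formula oracle on random pairs", {
  set.seed(502)
  a <- runif(400, 0, 300)
  b <- a * (1 + rnorm(400, 0, 0.12))
  got <- check_repeatability(a, b)
  want <- mapply(repeatability_oracle, a, b)
  expect_equal(got, unname(want))
})

test_that("sample dispositions follow the decision table", {
  lod_small <- 1   # keep concentrations clear of rule interactions
  spec <- data.frame(
    role = "unknown",
    rt_q_dev = c(0, 0, 0, 0, 0.3),
    rt_i_dev = 0,
    ion_mult = c(1, 1, 1, 1, 1),
    istd_area = 1e5,
    conc = c(250, 30, 30, 30, 30))
  case <- make_qa_case(spec, batch = "D")
  # injection 2 follows a 250 pg/mL injection -> carryover flag
  # no reinjection: disposition "reinject"
  qa0 <- evaluate_batch_qa(case$results, case$records)
  d0 <- qa0$dispositions
  expect_equal(d0$disposition, c("report", "reinject", "report", "report",
                                 "fail_qa"))
  expect_equal(d0$reportable, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(unique(d0$value_source[d0$disposition != "report"]),
               "original")

  # reinjection passing repeatability -> report, value from reinjection
  re_ok <- data.frame(sample_id = "D-02", analyte = "NDMA",
                      conc_pg_ml = 31)
  d1 <- evaluate_batch_qa(case$results, case$records,
                          reinjections = re_ok)$dispositions
  expect_equal(d1$disposition[2], "report")
  expect_equal(d1$value_source[2], "reinjection")
  expect_true(d1$reportable[2])

  # reinjection failing repeatability -> sample must be repeated
  re_bad <- data.frame(sample_id = "D-02", analyte = "NDMA",
                       conc_pg_ml = 80)
  d2 <- evaluate_batch_qa(case$results, case$records,
                          reinjections = re_bad)$dispositions
  expect_equal(d2$disposition[2], "repeat")
  expect_false(d2$reportable[2])
})

test_that("every injection gets exactly one flag per rule and analyte", {
  b <- generate_batch(sim_config(seed = 21), default_layout("F1"))
  q <- quantify_batch(b)
  qa <- evaluate_batch_qa(q$results, b$records)
  expect_equal(nrow(qa$flags), 60 * 6 * 8)
  counts <- table(qa$flags$rule_id)
  expect_true(all(counts == 360))
  expect_setequal(names(counts),
                  c("rt_quant", "rt_istd", "ion_ratio", "istd_area",
                    "blank_limit", "carryover_follow", "repeat_fail",
                    "unquantifiable"))
})
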