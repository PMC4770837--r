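test_that("3*S0: exactly linear SD profile returns LOD 6.0 exactly", {
  # per-pool SDs 2.0, 2.1, 2.2, 2.3 at 0/2.5/5/7.5 pg/mL lie exactly on a
  # line with intercept 2.0 -> LOD = 3 * 2.0 = 6.0
  sds <- c(2.0, 2.1, 2.2, 2.3)
  conc <- c(0, 2.5, 5, 7.5)
  vals <- lapply(sds, function(s) s / sqrt(2) * c(-1, 1) + 10)
  names(vals) <- conc
  expect_equal(sapply(vals, sd), setNames(sds, conc))
  est <- estimate_lod_3s0(vals, analyte = "NDMA")
  expect_equal(est$s0, 2.0, tolerance = 1e-12)
  expect_equal(est$lod, 6.0, tolerance = 1e-12)
  expect_equal(est$method, "three_s0")
})

test_that("3*S0: flat SD profile and degenerate inputs", {
  vals <- list(`0` = c(8, 12), `2.5` = c(8, 12) + 2.5, `5` = c(8, 12) + 5)
  est <- estimate_lod_3s0(vals)
  expect_equal(est$s0, sd(c(8, 12)), tolerance = 1e-10)
  expect_equal(est$lod, 3 * sd(c(8, 12)), tolerance = 1e-10)
  # a convex SD profile extrapolates to a negative intercept: an
  # estimation error advising the CLSI procedure
  pool <- function(s) 10 + c(-s, s) / sqrt(2)   # sample sd exactly s
  bad <- list(`0` = pool(0.1), `2.5` = pool(0.2), `5` = pool(10))
  expect_error(estimate_lod_3s0(bad), "CLSI")
  expect_error(estimate_lod_3s0(vals[1:2]), "at least 3 pools")
  expect_error(estimate_lod_3s0(list(`0` = 1, `2.5` = c(1, 2), `5` = c(1, 2),
                                     `7.5` = c(1, 2))),
               "at least 2 values")
})

test_that("CLSI LoB/LoD: hand-computed example", {
  # blanks mean 1.0, sd 0.5 -> LoB = 1.0 + 1.645 * 0.5 = 1.8225
  # low-pool sd 1.0        -> LoD = LoB + 1.645 * 1.0 = 3.4675
  blanks <- c(0.5, 1.0, 1.5)
  expect_equal(sd(blanks), 0.5)
  low <- c(1.5, 2.5, 3.5)                       # sd exactly 1.0
  expect_equal(sd(low), 1.0)
  est <- estimate_lod_clsi(blanks, low, analyte = "NPYR")
  expect_equal(est$lob, 1.8225, tolerance = 1e-12)
  expect_equal(est$lod, 3.4675, tolerance = 1e-12)
  # all-zero blanks: LoB 0, LoD driven by the low pool alone
  est0 <- estimate_lod_clsi(c(0, 0, 0), low)
  expect_equal(est0$lob, 0)
  expect_equal(est0$lod, 1.645)
  # beta quantile 0 collapses LoD to the blank mean
  estb <- estimate_lod_clsi(blanks, low, beta_quantile = 0)
  expect_equal(estb$lod, mean(blanks))
  # pooled SD across two low pools
  est2 <- estimate_lod_clsi(blanks, list(low, low))
  expect_equal(est2$lod, est$lod)
  expect_error(estimate_lod_clsi(1, low), "at least 2 blank")
  expect_error(estimate_lod_clsi(blanks, list(low, 3)), "2 values per")
})

test_that("precision summary: worked example and guards", {
  d <- data.frame(run = rep(1:2, each = 3),
                  measured_pg_ml = c(48, 50, 52, 47, 49, 51))
  pr <- precision_summary(d)
  expect_equal(pr$intra$cv_pct, c(100 * 2 / 50, 100 * 2 / 49))
  expect_equal(pr$inter$n_runs, 2)
  expect_equal(pr$inter$cv_pct, 100 * sd(c(50, 49)) / mean(c(50, 49)))
  # identical run means: inter-run CV is exactly zero
  d2 <- data.frame(run = rep(1:3, each = 2),
                   measured_pg_ml = c(48, 52, 49, 51, 47, 53))
  expect_equal(precision_summary(d2)$inter$cv_pct, 0)
  expect_error(precision_summary(d[d$run == 1, ]), "at least 2 runs")
  dz <- d; dz$measured_pg_ml[1:3] <- c(-50, 0, 50)
  expect_error(precision_summary(dz), "zero")
})

test_that("precision CVs are invariant under positive rescaling", {
  set.seed(701)
  d <- data.frame(run = rep(1:5, each = 6),
                  measured_pg_ml = rnorm(30, 50, 3))
  p1 <- precision_summary(d)
  for (k in c(1e-6, 0.37, 1000)) {
    ds <- d
    ds$measured_pg_ml <- ds$measured_pg_ml * k
    p2 <- precision_summary(ds)
    expect_equal(p2$intra$cv_pct, p1$intra$cv_pct)
    expect_equal(p2$inter$cv_pct, p1$inter$cv_pct)
  }
})

test_that("spike recovery: worked examples", {
  sp <- data.frame(nominal_pg_ml = rep(100, 3),
                   measured_pg_ml = c(90, 95, 100))
  # zero baseline: recovery is measured/nominal
  out0 <- accuracy_summary(sp, baseline = c(0, 0, 0))
  expect_equal(out0$mean_recovery_pct, 95)
  # baseline 10, measured 110 -> recovery (110 - 10)/100 = 100%
  sp2 <- data.frame(nominal_pg_ml = rep(100, 2),
                    measured_pg_ml = c(110, 110))
  out2 <- accuracy_summary(sp2, baseline = c(9, 10, 11))
  expect_equal(out2$mean_recovery_pct, 100)
  expect_error(accuracy_summary(
    data.frame(nominal_pg_ml = 0, measured_pg_ml = 1), baseline = 0),
    "non-zero")
})

test_that("noise-free accuracy study recovers 100% at every level", {
  d <- generate_validation_study("accuracy_matrix_3x3x3",
                                 noise_free_sim(seed = 8))
  for (an in unique(d$analyte)) {
    da <- d[d$analyte == an, ]
    out <- accuracy_summary(da[da$sample_type == "spiked", ],
                            baseline = da$measured_pg_ml[
                              da$sample_type == "baseline"])
    expect_equal(out$mean_recovery_pct, rep(100, 3), tolerance = 1e-9)
    expect_equal(out$nominal_pg_ml, c(100, 200, 300))
    expect_equal(out$n, rep(9L, 3), ignore_attr = TRUE)
  }
})

test_that("solution accuracy check against the working curve", {
  x <- default_calibration_levels()
  cal <- fit_calibration(x, 0.8 * x)
  lev <- 80 * c(0.005, 0.25, 0.5)
  meas <- data.frame(nominal_ratio = rep(lev, each = 3),
                     response_ratio = 0.8 * rep(lev, each = 3))
  out <- solution_accuracy_check(meas, cal, expected_levels = lev)
  expect_equal(out$mean_accuracy_pct, rep(100, 3), tolerance = 1e-9)
  expect_true(all(out$pass))
  # a +5% biased second source reads 105%
  meas5 <- meas
  meas5$response_ratio <- meas5$response_ratio * 1.05
  out5 <- solution_accuracy_check(meas5, cal)
  expect_equal(out5$mean_accuracy_pct, rep(105, 3), tolerance = 1e-9)
  # an 85% second source fails the 90% floor
  meas85 <- meas
  meas85$response_ratio <- meas85$response_ratio * 0.85
  expect_false(any(solution_accuracy_check(meas85, cal)$pass))
  # a missing design level is an error naming it
  expect_error(solution_accuracy_check(meas[meas$nominal_ratio > 1, ], cal,
                                       expected_levels = lev),
               "missing calibrator level")
})
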