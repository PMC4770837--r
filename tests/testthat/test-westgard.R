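test_that("QC characterization: worked values and guards", {
  d <- data.frame(analyte = "NDMA", pool = "qc_low",
                  value = c(49, 51, 50, 48, 52))
  ch <- suppressWarnings(characterize_qc(d))
  expect_equal(ch$mean, 50)
  expect_equal(ch$sd, sd(c(49, 51, 50, 48, 52)))
  expect_equal(ch$n_runs, 5)
  expect_warning(characterize_qc(d), "fewer than 20")

  expect_error(characterize_qc(data.frame(analyte = "NDMA",
                                          pool = "qc_low", value = 50)),
               "at least 2")
  expect_error(
    suppressWarnings(characterize_qc(
      data.frame(analyte = "NDMA", pool = "qc_low", value = rep(50, 5)))),
    "constant")
})

test_that("missing characterization is named in the error", {
  char <- suppressWarnings(characterize_qc(
    data.frame(analyte = "NDMA", pool = "qc_low", value = c(48, 50, 52))))
  cur <- data.frame(analyte = "NDMA", pool = c("qc_low", "qc_high"),
                    value = c(50, 200))
  expect_error(evaluate_batch_qc(cur, char), "NDMA qc_high")
})

test_that("canonical single-rule violations", {
  # 1_3s
  r <- run_westgard_engine(c(qc_low = 3.2, qc_high = 0))
  expect_equal(r$verdict, "reject")
  expect_true("1_3s" %in% r$violations$rule)
  # 1_2s alone only warns
  r <- run_westgard_engine(c(qc_low = 2.5, qc_high = 0))
  expect_equal(r$verdict, "warn")
  expect_setequal(r$violations$rule, "1_2s")
  # 2_2s across pools within the run
  r <- run_westgard_engine(c(qc_low = 2.4, qc_high = 2.6))
  expect_true("2_2s" %in% r$violations$rule)
  expect_equal(r$verdict, "reject")
  # R_4s: opposite sides beyond 2
  r <- run_westgard_engine(c(qc_low = 2.3, qc_high = -2.3))
  expect_true("R_4s" %in% r$violations$rule)
  expect_false("2_2s" %in% r$violations$rule)
  # 2_2s within a pool against history
  r <- run_westgard_engine(c(qc_low = 2.4, qc_high = 0),
                           hist = list(qc_low = c(0.5, 2.2), qc_high = 0.1))
  expect_true("2_2s" %in% r$violations$rule)
  # 4_1s needs enabling and four consecutive same-side > 1
  r <- run_westgard_engine(c(qc_low = 1.2, qc_high = 0),
                           hist = list(qc_low = c(1.1, 1.3, 1.5)),
                           enabled = c("1_3s", "4_1s"))
  expect_true("4_1s" %in% r$violations$rule)
  # 10_x: ten same-side values, all within 1 SD
  r <- run_westgard_engine(c(qc_low = 0.4),
                           hist = list(qc_low = rep(0.5, 9)),
                           enabled = c("1_3s", "10_x"))
  expect_true("10_x" %in% r$violations$rule)
  # everything near target accepts
  r <- run_westgard_engine(c(qc_low = 0.3, qc_high = -0.8))
  expect_equal(r$verdict, "accept")
  expect_equal(nrow(r$violations), 0)
})

test_that("all values within 1 SD accept for the level-based rules", {
  set.seed(601)
  for (i in 1:50) {
    cur <- c(qc_low = runif(1, -1, 1), qc_high = runif(1, -1, 1))
    hist <- list(qc_low = runif(8, -1, 1), qc_high = runif(8, -1, 1))
    r <- run_westgard_engine(cur, hist,
                             enabled = c("1_2s", "1_3s", "2_2s", "R_4s",
                                         "4_1s"))
    expect_equal(r$verdict, "accept")
  }
})

test_that("enabling more rules never rescues a rejected batch", {
  set.seed(602)
  base <- c("1_3s")
  extra <- c("1_2s", "2_2s", "R_4s", "4_1s", "10_x")
  for (i in 1:50) {
    cur <- c(qc_low = rnorm(1, 0, 1.8), qc_high = rnorm(1, 0, 1.8))
    hist <- list(qc_low = rnorm(10, 0, 1.8), qc_high = rnorm(10, 0, 1.8))
    v1 <- run_westgard_engine(cur, hist, enabled = base)$verdict
    v2 <- run_westgard_engine(cur, hist,
                              enabled = c(base, extra))$verdict
    if (v1 == "reject") expect_equal(v2, "reject")
  }
})

test_that("engine matches the textbook oracle exhaustively (short windows)", {
  grid <- seq(-3.5, 3.5, by = 0.5)
  all_rules <- c("1_2s", "1_3s", "2_2s", "R_4s", "4_1s", "10_x")
  # single pool, windows of length 1 and 2 (history = all but last value)
  for (z1 in grid) {
    for (z2 in c(NA, grid)) {
      w <- if (is.na(z2)) z1 else c(z1, z2)
      n <- length(w)
      cur <- c(qc_low = w[n])
      hist <- if (n > 1) list(qc_low = w[-n]) else NULL
      got <- run_westgard_engine(cur, hist, enabled = all_rules)
      want <- westgard_oracle(cur, hist, enabled = all_rules)
      expect_equal(sort(unique(got$violations$rule)), want$fired,
                   info = paste("window:", paste(w, collapse = ",")))
      expect_equal(got$verdict, want$verdict,
                   info = paste("window:", paste(w, collapse = ",")))
    }
  }
  # two pools, current run only: all 15 x 15 across-pool combinations
  for (zl in grid) {
    for (zh in grid) {
      cur <- c(qc_low = zl, qc_high = zh)
      got <- run_westgard_engine(cur, enabled = all_rules)
      want <- westgard_oracle(cur, enabled = all_rules)
      expect_equal(sort(unique(got$violations$rule)), want$fired,
                   info = sprintf("cur: %g/%g", zl, zh))
      expect_equal(got$verdict, want$verdict,
                   info = sprintf("cur: %g/%g", zl, zh))
    }
  }
})

test_that("engine matches the oracle on random long windows", {
  grid <- seq(-3.5, 3.5, by = 0.5)
  all_rules <- c("1_2s", "1_3s", "2_2s", "R_4s", "4_1s", "10_x")
  set.seed(603)
  for (i in 1:300) {
    n_hist <- sample(0:11, 1)
    hist <- list(qc_low = sample(grid, n_hist, replace = TRUE),
                 qc_high = sample(grid, sample(0:11, 1), replace = TRUE))
    cur <- c(qc_low = sample(grid, 1), qc_high = sample(grid, 1))
    got <- run_westgard_engine(cur, hist, enabled = all_rules)
    want <- westgard_oracle(cur, hist, enabled = all_rules)
    expect_equal(sort(unique(got$violations$rule)), want$fired)
    expect_equal(got$verdict, want$verdict)
  }
})

test_that("levey_jennings_data flattens history plus current", {
  char <- suppressWarnings(characterize_qc(
    data.frame(analyte = "NDMA", pool = "qc_low", value = c(45, 50, 55))))
  hist <- data.frame(analyte = "NDMA", pool = "qc_low", value = c(48, 52))
  cur <- data.frame(analyte = "NDMA", pool = "qc_low", value = 50)
  lj <- levey_jennings_data(cur, char, hist)
  expect_equal(nrow(lj), 3)
  expect_equal(lj$run_index, 1:3)
  expect_equal(lj$z[3], 0)
})
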