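test_that("trapezoidal AUC matches closed forms and is additive", {
  expect_equal(auc_trapezoid(c(0, 24), c(2, 2)), 48)
  # mono-exponential oracle at dense sampling
  k <- 0.18; c0 <- 3
  tt <- seq(0, 24, by = 0.01)
  auc <- auc_trapezoid(tt, c0 * exp(-k * tt))
  expect_lt(abs(auc - c0 * (1 - exp(-24 * k)) / k) / auc, 0.001)
  # additivity over contiguous sub-intervals
  cc <- c0 * exp(-k * tt)
  cut <- 1200
  expect_equal(auc_trapezoid(tt[1:cut], cc[1:cut]) +
                 auc_trapezoid(tt[cut:length(tt)], cc[cut:length(tt)]),
               auc)
  expect_error(auc_trapezoid(c(2, 1), c(1, 1)), "increasing")
  expect_error(auc_trapezoid(c(0, 1), c(1, -1)), "non-negative")
  expect_error(auc_trapezoid(3, 1), "2 matching")
})

test_that("Tmax picks the sampling time of the maximum, earliest on ties", {
  tt <- c(1, 2, 3, 4, 6, 10, 24)
  expect_equal(pk_tmax(tt, c(1, 2, 3, 4, 9, 5, 1)), 6)
  expect_equal(pk_tmax(tt, rev(seq_along(tt))), 1)
  expect_equal(pk_tmax(c(1, 2, 4, 6, 10), c(1, 2, 5, 5, 1)), 4)
  expect_error(pk_tmax(numeric(0), numeric(0)), "at least one")
})

test_that("terminal half-life is the log-linear slope after Tmax", {
  # exact two-fold decays
  expect_equal(pk_half_life(c(2, 6, 10), c(8, 4, 2)), 4)
  # synthetic decay with known rate: ln(2)/lambda oracle
  lam <- 0.1876
  tt <- c(1, 2, 3, 4, 6, 10, 24)
  cc <- c(0.5, 1.8 * exp(-lam * (c(2, 3, 4, 6, 10, 24) - 2)))
  expect_equal(pk_half_life(tt, cc), log(2) / lam, tolerance = 1e-10)
  expect_equal(round(log(2) / lam, 1), 3.7)
  # undefined on short terminal phases or rising tails
  expect_true(is.na(pk_half_life(c(1, 2, 4), c(1, 3, 2))))
  expect_true(is.na(pk_half_life(c(1, 2, 3, 4, 6), c(3, 0.1, 0.2, 1, 2.9))))
  # invariant to uniform scaling of the concentrations
  expect_equal(pk_half_life(tt, 37.5 * cc), pk_half_life(tt, cc))
})

test_that("named AUC ratios are plain quotients with strict bookkeeping", {
  auc <- c(fat_gd15 = 1247.08, fat_gd1 = 43.97, same = 5)
  r <- auc_ratios(auc, data.frame(name = c("fat_acc", "unit"),
                                  num = c("fat_gd15", "same"),
                                  den = c("fat_gd1", "same")))
  expect_equal(round(r[["fat_acc"]], 1), 28.4)
  expect_equal(r[["unit"]], 1)
  expect_error(auc_ratios(auc, data.frame(name = "x", num = "missing",
                                          den = "same")),
               "missing")
})

test_that("the LOQ/2 substitution rule is applied per censoring state", {
  expect_equal(loq_substitute(0.010, 0.026, TRUE), 0.013)
  expect_equal(loq_substitute(0.030, 0.026, TRUE), 0.030)
  expect_equal(loq_substitute(0.015, 0.020, TRUE), 0.010)
  expect_true(is.na(loq_substitute(0.001, 0.026, FALSE)))
  expect_error(loq_substitute(1, -1, TRUE))
})

test_that("nca_table collapses replicates into composite curves", {
  d <- expand.grid(gd = 1, time_h = c(1, 2, 4, 6, 10, 24),
                   animal_id = 1:4)
  d$matrix <- "blood"; d$isomer <- "cis"
  d$censor_state <- "quantified"; d$loq <- 0.026
  set.seed(2)
  d$concentration <- exp(-0.1 * d$time_h) * (1 + 0.01 * d$animal_id)
  tab <- nca_table(d, anchor_zero = TRUE)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$tmax, 1)
  # composite curve is the per-time mean, anchored at (0, 0)
  m <- tapply(d$concentration, d$time_h, mean)
  expect_equal(tab$auc_0_24,
               auc_trapezoid(c(0, as.numeric(names(m))), c(0, m)))
})
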