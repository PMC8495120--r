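test_that("simulation is linear in dose and zero without one", {
  s0 <- pbpk_simulate(cis_gd1, default_phys,
                      dose_schedule(0, times_gd = 1), t_end_gd = 1.5,
                      output_dt_h = 0.5)
  expect_true(all(s0$conc == 0, na.rm = TRUE))
  s1 <- pbpk_simulate(cis_gd1, default_phys,
                      dose_schedule(10, times_gd = 1), t_end_gd = 1.5,
                      output_dt_h = 0.5)
  s2 <- pbpk_simulate(cis_gd1, default_phys,
                      dose_schedule(20, times_gd = 1), t_end_gd = 1.5,
                      output_dt_h = 0.5)
  mats <- c("blood", "liver", "brain", "fat")
  expect_equal(2 * s1$conc[, mats], s2$conc[, mats], tolerance = 1e-6)
})

test_that("the output grid and series extraction behave as documented", {
  sim <- local_gd1_sim()
  expect_equal(length(sim$time_h),
               floor((2 - 1) * 24 / 0.05) + 1)
  ser <- concentration_series(sim, "blood")
  expect_true(all(ser$concentration >= 0))
  expect_gt(max(ser$concentration), 0)
  expect_error(concentration_series(sim, "placenta"), "inactive")
  expect_error(concentration_series(sim, "nonsense"), "valid matrices")
})

test_that("halving the solver tolerances leaves the blood AUC unchanged", {
  a1 <- pk_auc(pbpk_simulate(cis_gd1, default_phys,
                             dose_schedule(20, times_gd = 1),
                             t_end_gd = 2, output_dt_h = 0.1,
                             rtol = 1e-8, atol = 1e-10), "blood")
  a2 <- pk_auc(pbpk_simulate(cis_gd1, default_phys,
                             dose_schedule(20, times_gd = 1),
                             t_end_gd = 2, output_dt_h = 0.1,
                             rtol = 5e-9, atol = 5e-11), "blood")
  expect_lt(abs(a1 - a2) / a1, 0.001)
})

test_that("repeated dosing obeys superposition when physiology is frozen", {
  # frozen physiology makes the system linear and time-invariant, so n
  # identical doses must equal the sum of n time-shifted single-dose
  # responses
  phys <- default_phys
  single <- pbpk_simulate(cis_gd1, phys, dose_schedule(20, times_gd = 10),
                          t_end_gd = 14, output_dt_h = 0.5,
                          freeze_gd = 10)
  multi <- pbpk_simulate(cis_gd1, phys,
                         dose_schedule(20, times_gd = 10:12),
                         t_end_gd = 14, output_dt_h = 0.5,
                         freeze_gd = 10)
  t_rel <- single$time_h - 240
  blood1 <- single$conc[, "blood"]
  shift <- function(lag_h) {
    stats::approx(t_rel, blood1, xout = t_rel - lag_h, rule = 2,
                  yleft = 0)$y * ifelse(t_rel >= lag_h, 1, 0)
  }
  expected <- shift(0) + shift(24) + shift(48)
  got <- multi$conc[, "blood"]
  keep <- t_rel > 49  # after the last dose
  expect_lt(max(abs(got[keep] - expected[keep]) / max(got[keep])), 0.005)
})

test_that("doses scale with the current body weight when requested", {
  sim <- pbpk_simulate(cis_gd1, default_phys,
                       dose_schedule(20, times_gd = c(1, 15)),
                       t_end_gd = 16, output_dt_h = 1)
  expect_equal(sim$dose_log$dose_mg,
               20 * maternal_body_weight(c(1, 15), default_phys))
  sim0 <- pbpk_simulate(cis_gd1, default_phys,
                        dose_schedule(20, times_gd = c(1, 15),
                                      scale_to_current_bw = FALSE),
                        t_end_gd = 16, output_dt_h = 1)
  expect_equal(sim0$dose_log$dose_mg, rep(20 * 0.277, 2))
})
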