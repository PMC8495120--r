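tiny_loq <- function(eps = 1e-12) {
  lapply(default_loq_table(), function(x) x * 0 + eps)
}

test_that("a noise-free uncensored study reproduces the model exactly", {
  des <- study_design(gestational_days = 1, sample_times_h = c(2, 6, 24),
                      n_per_group = 2, loq_ng = tiny_loq())
  d <- generate_tk_study(list(cis = cis_gd1), default_phys, des,
                         sigma_log = 0, seed = 1, rtol = 1e-8)
  expect_true(all(d$censor_state == "quantified"))
  # replicates at one design point are identical without noise
  sp <- split(d$concentration, interaction(d$matrix, d$time_h))
  for (v in sp) if (length(v)) expect_equal(diff(range(v)), 0)
  # and equal to an independent forward computation of the same design
  out <- permpbpk:::pbpk_ode(
    cis_gd1, default_phys, 24 + c(0, 2, 6, 24),
    data.frame(time_h = 24,
               dose_mg = 20 * maternal_body_weight(1, default_phys)))
  blood6 <- pbpk_concentrations(out[out[, "time"] == 30, -1], 30 / 24,
                                default_phys, "blood")
  expect_equal(d$concentration[d$matrix == "blood" & d$time_h == 6][1],
               blood6[["blood"]])
  # feces records carry the cumulative amount excreted over 24 h
  fec <- out[out[, "time"] == 48, "A_fec"] -
    out[out[, "time"] == 24, "A_fec"]
  expect_equal(unique(d$concentration[d$matrix == "feces"]), unname(fec))
})

test_that("censoring follows the LOQ with LOQ/2 substitution", {
  # huge LOQs censor every record
  big <- lapply(default_loq_table(), function(x) x * 0 + 1e12)
  des <- study_design(gestational_days = 1, n_per_group = 2, loq_ng = big)
  d <- generate_tk_study(list(cis = cis_gd1), default_phys, des,
                         sigma_log = 0.15, seed = 1)
  expect_true(all(d$censor_state != "quantified"))
  expect_true(all(d$concentration[d$censor_state == "below_loq_detected"]
                  == d$loq[d$censor_state == "below_loq_detected"] / 2))
  expect_true(all(is.na(d$concentration[d$censor_state == "not_detected"])))
  # censoring frequency is monotone in the LOQ on a fixed seed
  censored_n <- sapply(c(1, 5, 25), function(f) {
    loq <- lapply(default_loq_table(), function(x) x * f)
    di <- generate_tk_study(list(cis = cis_gd1), default_phys,
                            study_design(gestational_days = 1,
                                         n_per_group = 2, loq_ng = loq),
                            sigma_log = 0.15, seed = 3)
    sum(di$censor_state != "quantified")
  })
  expect_true(all(diff(censored_n) >= 0))
  # quantified values are at or above their LOQ
  d2 <- generate_tk_study(list(cis = cis_gd1), default_phys,
                          study_design(gestational_days = 1,
                                       n_per_group = 2),
                          sigma_log = 0.15, seed = 5)
  q <- d2$censor_state == "quantified"
  expect_true(all(d2$concentration[q] >= d2$loq[q]))
})

test_that("the generator is a deterministic function of the seed", {
  des <- study_design(gestational_days = 1, n_per_group = 2)
  d1 <- generate_tk_study(list(cis = cis_gd1), default_phys, des,
                          seed = 11)
  d2 <- generate_tk_study(list(cis = cis_gd1), default_phys, des,
                          seed = 11)
  d3 <- generate_tk_study(list(cis = cis_gd1), default_phys, des,
                          seed = 12)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
})

test_that("the default design emits the protocol record counts", {
  d <- local_gd1_study()
  conc <- d[d$matrix != "feces", ]
  counts <- table(conc$matrix)
  expect_true(all(counts == 4 * 7))
  expect_equal(sum(d$matrix == "feces"), 4)
  expect_setdiff_empty <- function(a, b) expect_equal(setdiff(a, b),
                                                      character(0))
  expect_setdiff_empty(unique(d$matrix),
                       c("blood", "liver", "brain", "kidney", "fat",
                         "mammary", "feces"))
  # late-gestation designs add placental and fetal matrices
  des20 <- study_design(gestational_days = 20, n_per_group = 1,
                        sample_times_h = c(6, 24))
  d20 <- generate_tk_study(list(cis = cis_late), default_phys, des20,
                           sigma_log = 0, seed = 1,
                           rtol = 1e-6)
  expect_true(all(c("placenta", "fetal_blood", "fetal_liver",
                    "fetal_brain") %in% unique(d20$matrix)))
  expect_false("feces" %in% unique(d20$matrix))
})

test_that("the lognormal error layer has the configured spread", {
  des <- study_design(gestational_days = 1, sample_times_h = 6,
                      n_per_group = 10000, loq_ng = tiny_loq())
  d <- generate_tk_study(list(cis = cis_gd1), default_phys, des,
                         sigma_log = 0.15, seed = 21)
  s <- stats::sd(log(d$concentration[d$matrix == "blood"]))
  expect_lt(abs(s - 0.15), 0.005)
})

test_that("datasets round-trip losslessly through CSV", {
  d <- local_gd1_study()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tk_study(d, path)
  d2 <- read_tk_study(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
  # empty dataset round-trips
  write_tk_study(d[0, ], path)
  expect_equal(nrow(read_tk_study(path)), 0)
  # malformed censor token fails with its line number
  bad <- d
  bad$censor_state[3] <- "sometimes_detected"
  write_tk_study(bad, path)
  expect_error(read_tk_study(path), "line 4")
})
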