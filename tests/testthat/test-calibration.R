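test_that("prior log-density handles truncation, uniforms and bounds", {
  pri <- permethrin_priors("cis")
  # truncated normal: density ratio between two interior points equals
  # the untruncated normal ratio (the truncation constant cancels)
  r <- prior_logpdf(c(cl_liv = 6.20), pri) -
    prior_logpdf(c(cl_liv = 15), pri)
  expect_equal(r, stats::dnorm(6.20, 6.20, 3.10, log = TRUE) -
                 stats::dnorm(15, 6.20, 3.10, log = TRUE))
  # and the absolute level carries the numerically integrated constant
  konst <- stats::integrate(function(x) stats::dnorm(x, 6.20, 3.10),
                            1, 15)$value
  expect_equal(prior_logpdf(c(cl_liv = 6.20), pri),
               stats::dnorm(6.20, 6.20, 3.10, log = TRUE) - log(konst),
               tolerance = 1e-6)
  # uniform parameters contribute a constant inside their bounds
  expect_equal(prior_logpdf(c(sc_ktrans1 = 0.5), pri),
               prior_logpdf(c(sc_ktrans1 = 5.5), pri))
  expect_identical(prior_logpdf(c(sc_ktrans1 = 6.5), pri), -Inf)
  expect_identical(prior_logpdf(c(cl_liv = 0.5), pri), -Inf)
  # prior draws respect their bounds
  set.seed(1)
  pri_s <- pri[pri$family != "fixed", ]
  draws <- prior_sample(pri_s, 200)
  for (j in seq_len(nrow(pri_s)))
    expect_true(all(draws[, j] >= pri_s$lower[j] &
                      draws[, j] <= pri_s$upper[j]))
})

test_that("the lognormal likelihood matches its closed form", {
  # a record one log-SD above its prediction
  pred <- 0.4
  obs <- pred * exp(0.15)
  expect_equal(tk_log_likelihood(obs, pred, 0.15),
               stats::dlnorm(obs, log(pred), 0.15, log = TRUE))
  # prediction equal to every record maximises the likelihood
  obs <- c(0.2, 1.1, 3)
  at_mode <- tk_log_likelihood(obs, obs, 0.15)
  expect_gt(at_mode, tk_log_likelihood(obs, obs * 1.1, 0.15))
  expect_gt(at_mode, tk_log_likelihood(obs, obs * 0.9, 0.15))
  # doubling sigma lowers the density at the mode (normalisation)
  expect_gt(at_mode, tk_log_likelihood(obs, obs, 0.30))
})

test_that("the sampler recovers a conjugate lognormal posterior", {
  # lognormal likelihood (known sdlog) with lognormal prior: the
  # log-parameter has a conjugate normal posterior
  m0 <- 0; s0 <- 1
  y <- c(1.8, 2.4, 2.1, 1.5, 2.9); slik <- 0.3
  prec <- 1 / s0^2 + length(y) / slik^2
  m_post <- (m0 / s0^2 + sum(log(y)) / slik^2) / prec
  s_post <- sqrt(1 / prec)
  log_post <- function(theta)
    stats::dnorm(log(theta), m0, s0, log = TRUE) - log(theta) +
      sum(stats::dlnorm(y, log(theta), slik, log = TRUE))
  set.seed(42)
  run <- mcmc_mwg(log_post, c(theta = 1), n_iter = 20000)
  z <- log(run$draws[-(1:2000), 1])
  expect_equal(mean(z), m_post, tolerance = 3 * s_post / sqrt(500))
  expect_equal(stats::sd(z), s_post, tolerance = 0.05)
})

test_that("the potential scale reduction factor separates mixed from stuck chains", {
  set.seed(9)
  good <- array(stats::rnorm(10000 * 3 * 2), c(10000, 3, 2),
                dimnames = list(NULL, NULL, c("a", "b")))
  r <- gelman_rubin(good)
  expect_true(all(r > 0.99 & r < 1.01))
  bad <- good
  bad[, 2, 1] <- bad[, 2, 1] + 100
  expect_gt(gelman_rubin(bad)[["a"]], 10)
  expect_error(gelman_rubin(good[, 1, , drop = FALSE]), "2 chains")
  # zero within-chain variance is flagged, not fabricated
  flat <- array(1, c(100, 2, 1), dimnames = list(NULL, NULL, "c"))
  expect_true(is.na(gelman_rubin(flat)[["c"]]))
})

test_that("with no data the posterior reproduces the prior", {
  empty <- local_gd1_study()[0, ]
  fit <- pbpk_fit(empty, "cis", "gd1", default_phys, chains = 2,
                  iter = 1500, retain_window = 1000, thin = 2, seed = 5)
  pri <- fit$sampled
  tn <- pri$family == "truncnorm"
  # compare posterior means of truncated-normal parameters with their
  # simulated prior means (truncation shifts them off the location)
  set.seed(99)
  ref <- colMeans(prior_sample(pri[tn, ], 20000))
  est <- coef(fit)[pri$label[tn]]
  expect_true(all(abs(est - ref) / ref < 0.10))
})

test_that("a fixed seed reproduces a calibration draw for draw", {
  d <- local_gd1_study()
  f1 <- pbpk_fit(d, "cis", "gd1", default_phys, chains = 2, iter = 30,
                 retain_window = 20, thin = 2, seed = 4)
  f2 <- pbpk_fit(d, "cis", "gd1", default_phys, chains = 2, iter = 30,
                 retain_window = 20, thin = 2, seed = 4)
  expect_identical(f1$draws, f2$draws)
  # draws never leave the prior bounds
  for (k in seq_len(dim(f1$draws)[3])) {
    expect_true(all(f1$draws[, , k] >= f1$sampled$lower[k]))
    expect_true(all(f1$draws[, , k] <= f1$sampled$upper[k]))
  }
  # accessors work
  expect_named(coef(f1), f1$sampled$label, ignore.order = TRUE)
  res <- residuals(f1)
  expect_true(all(is.finite(res$log_residual)))
  pred <- predict(f1, gd = 1, times_h = c(2, 6),
                  matrices = c("blood", "brain"))
  expect_equal(nrow(pred), 4)
  expect_true(all(pred$concentration >= 0))
  pp <- simulate(f1, nsim = 1, seed = 2)
  expect_length(pp, 1)
  expect_s3_class(pp[[1]], "tk_dataset")
  expect_setequal(unique(pp[[1]]$gd), 1)
})

test_that("gd1 mode rejects placental and fetal records", {
  d <- local_gd1_study()
  d$matrix[1] <- "placenta"
  expect_error(pbpk_fit(d, "cis", "gd1", default_phys), "fetal")
})
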