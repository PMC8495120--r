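#' Log-density of the prior at a parameter point
#'
#' Sum of independent log-densities over the sampled parameters:
#' truncated-normal parameters contribute the normal log-density minus
#' the log truncation mass, uniform parameters a constant, and any bound
#' violation yields `-Inf`.
#'
#' @param theta named vector of parameter values on the natural scale;
#'   names must appear in `priors$parameter`.
#' @param priors a [permethrin_priors()] data frame (or subset).
#' @return scalar log-density.
#' @export
prior_logpdf <- function(theta, priors) {
  pri <- priors[match(names(theta), priors$parameter), ]
  if (anyNA(pri$parameter))
    stop("parameters without a prior: ",
         paste(names(theta)[is.na(pri$parameter)], collapse = ", "))
  if (any(theta < pri$lower | theta > pri$upper)) return(-Inf)
  lp <- 0
  tn <- pri$family == "truncnorm"
  if (any(tn)) {
    z <- stats::dnorm(theta[tn], pri$mean[tn], pri$sd[tn], log = TRUE)
    mass <- stats::pnorm(pri$upper[tn], pri$mean[tn], pri$sd[tn]) -
      stats::pnorm(pri$lower[tn], pri$mean[tn], pri$sd[tn])
    lp <- lp + sum(z - log(mass))
  }
  un <- pri$family == "uniform"
  if (any(un)) lp <- lp - sum(log(pri$upper[un] - pri$lower[un]))
  lp
}

#' Draw parameter vectors from the prior
#'
#' Truncated normals are drawn by inverse-CDF rejection-free sampling;
#' uniforms directly.  Used for overdispersed chain starts.
#'
#' @param priors a [permethrin_priors()] subset of sampled parameters.
#' @param n number of draws.
#' @return `n` x `nrow(priors)` matrix with parameter columns.
#' @export
prior_sample <- function(priors, n = 1) {
  draws <- sapply(seq_len(nrow(priors)), function(i) {
    p <- priors[i, ]
    switch(p$family,
      truncnorm = {
        plo <- stats::pnorm(p$lower, p$mean, p$sd)
        phi <- stats::pnorm(p$upper, p$mean, p$sd)
        stats::qnorm(plo + stats::runif(n) * (phi - plo), p$mean, p$sd)
      },
      uniform = stats::runif(n, p$lower, p$upper),
      fixed = rep(p$mean, n))
  })
  matrix(draws, nrow = n, dimnames = list(NULL, priors$parameter))
}

# prediction context: groups the dataset so that one ODE solve serves all
# records of an (isomer, gd) pair
tk_context <- function(data, phys, dose_per_kg = c(cis = 20, trans = 30),
                       rtol = 1e-6) {
  keep <- data$censor_state != "not_detected"
  data <- data[keep, , drop = FALSE]
  groups <- unique(data[, c("isomer", "gd")])
  grp <- lapply(seq_len(nrow(groups)), function(i) {
    iso <- groups$isomer[i]; gd <- groups$gd[i]
    rows <- which(data$isomer == iso & data$gd == gd)
    t_dose <- gd * 24
    conc_rows <- rows[data$matrix[rows] != "feces"]
    fec_rows <- rows[data$matrix[rows] == "feces"]
    tps <- sort(unique(data$time_h[conc_rows]))
    dose_times <- seq_len(gd)
    list(isomer = iso, gd = gd, t_dose = t_dose,
         conc_rows = conc_rows, fec_rows = fec_rows, times = tps,
         t_out = sort(unique(c(t_dose, t_dose + tps, t_dose + 24))),
         dose_events = data.frame(
           time_h = dose_times * 24,
           dose_mg = dose_per_kg[[iso]] *
             maternal_body_weight(dose_times, phys)))
  })
  list(data = data, groups = grp, phys = phys, rtol = rtol)
}

# model predictions aligned with ctx$data rows, given per-isomer
# chemical_params
tk_predict_ctx <- function(ctx, chem_by_isomer) {
  data <- ctx$data
  pred <- rep(NA_real_, nrow(data))
  for (g in ctx$groups) {
    chem <- chem_by_isomer[[g$isomer]]
    out <- pbpk_ode(chem, ctx$phys, g$t_out, g$dose_events,
                    rtol = ctx$rtol, atol = 1e-10)
    for (tp in g$times) {
      ridx <- g$conc_rows[data$time_h[g$conc_rows] == tp]
      st <- out[out[, "time"] == g$t_dose + tp, -1]
      gd_tp <- min(g$gd + tp / 24, 20)
      mats <- unique(data$matrix[ridx])
      cc <- pbpk_concentrations(st, gd_tp, ctx$phys, mats)
      pred[ridx] <- cc[data$matrix[ridx]]
    }
    if (length(g$fec_rows)) {
      fec24 <- out[out[, "time"] == g$t_dose + 24, "A_fec"] -
        out[out[, "time"] == g$t_dose, "A_fec"]
      pred[g$fec_rows] <- fec24
    }
  }
  pred
}

#' Lognormal measurement-error log-likelihood of a TK dataset
#'
#' Each detected record contributes a lognormal log-density of its
#' recorded value (LOQ/2-substituted for below-LOQ records, which is how
#' such values entered the calibration) around the model prediction,
#' with log-scale standard deviation `sigma_log`.  Non-detected records
#' are excluded.
#'
#' @param observed recorded values (mg/L; mg for feces).
#' @param predicted model predictions, same length.
#' @param sigma_log log-scale SD of the residual error (0.15 = 15%
#'   error).
#' @param floor lower floor applied to predictions before taking logs.
#' @return scalar log-likelihood.
#' @export
tk_log_likelihood <- function(observed, predicted, sigma_log = 0.15,
                              floor = 1e-12) {
  stopifnot(length(observed) == length(predicted), sigma_log > 0)
  predicted <- pmax(predicted, floor)
  if (any(!is.finite(predicted)))
    stop("non-finite model prediction at record ",
         which(!is.finite(predicted))[1])
  sum(stats::dlnorm(observed, meanlog = log(predicted),
                    sdlog = sigma_log, log = TRUE))
}

#' Adaptive Metropolis-within-Gibbs sampler on log-transformed parameters
#'
#' Generic component-wise random-walk Metropolis sampler for positive
#' parameters.  Proposals are Gaussian on the log scale with
#' per-component scales adapted in batches toward an acceptance rate of
#' 0.44; the target density is evaluated on the natural scale with the
#' log-transform Jacobian added.
#'
#' @param log_post function taking a named natural-scale parameter
#'   vector and returning its log posterior density (up to a constant).
#' @param start named positive starting vector.
#' @param n_iter number of full update sweeps.
#' @param init_scale initial proposal SD on the log scale.
#' @param adapt adapt proposal scales (Roberts-Rosenthal batch rule).
#' @param batch batch size for adaptation.
#' @return list with `draws` (`n_iter` x p matrix, natural scale),
#'   `acceptance` per parameter, and `scales`.
#' @export
mcmc_mwg <- function(log_post, start, n_iter, init_scale = 0.25,
                     adapt = TRUE, batch = 50) {
  p <- length(start)
  nm <- names(start)
  z <- log(start)
  lp <- log_post(stats::setNames(exp(z), nm)) + sum(z)
  if (!is.finite(lp)) stop("non-finite posterior at start")
  draws <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, nm))
  scales <- rep(init_scale, p)
  acc <- n_prop <- rep(0, p)
  acc_batch <- rep(0, p)
  for (it in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      zp <- z
      zp[j] <- z[j] + stats::rnorm(1, 0, scales[j])
      lpp <- log_post(stats::setNames(exp(zp), nm)) + sum(zp)
      n_prop[j] <- n_prop[j] + 1
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        z <- zp; lp <- lpp
        acc[j] <- acc[j] + 1; acc_batch[j] <- acc_batch[j] + 1
      }
    }
    if (adapt && it %% batch == 0) {
      delta <- min(0.1, 2 / sqrt(it / batch))
      rate <- acc_batch / batch
      scales <- scales * exp(ifelse(rate > 0.44, delta, -delta))
      acc_batch[] <- 0
    }
    draws[it, ] <- exp(z)
  }
  list(draws = draws, acceptance = acc / pmax(n_prop, 1), scales = scales)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-free PSRF from between- and within-chain variances:
#' `sqrt(((n-1)/n * W + B/n) / W)`.  Values at or below 1.2 are read as
#' acceptable convergence.
#'
#' @param draws iterations x chains x parameters array, or a list of
#'   per-chain draw matrices with identical dimensions.
#' @return named vector of R-hat values; `NA` where the within-chain
#'   variance is zero.
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws) && !is.array(draws)) {
    stopifnot(length(unique(vapply(draws, nrow, 1L))) == 1L)
    pn <- colnames(draws[[1]])
    arr <- array(unlist(draws),
                 dim = c(nrow(draws[[1]]), ncol(draws[[1]]),
                         length(draws)))
    draws <- aperm(arr, c(1, 3, 2))
    dimnames(draws) <- list(NULL, NULL, pn)
  }
  stopifnot(length(dim(draws)) == 3)
  n <- dim(draws)[1]; m <- dim(draws)[2]; p <- dim(draws)[3]
  if (m < 2) stop("need at least 2 chains")
  if (n < 10) stop("need at least 10 retained draws per chain")
  rhat <- numeric(p)
  for (k in seq_len(p)) {
    x <- draws[, , k]
    w <- mean(apply(x, 2, stats::var))
    b <- n * stats::var(colMeans(x))
    rhat[k] <- if (w <= 0) NA_real_ else
      sqrt(((n - 1) / n * w + b / n) / w)
  }
  stats::setNames(rhat, dimnames(draws)[[3]])
}

#' Bayesian calibration of the PBPK model against a TK dataset
#'
#' Fits the chemical-specific parameters of one permethrin isomer (or
#' both jointly) to censoring-aware concentration data by MCMC:
#' truncated-normal/uniform priors, a fixed-sigma lognormal likelihood
#' around the ODE model predictions, and multiple adaptive
#' Metropolis-within-Gibbs chains started from overdispersed prior
#' draws.
#'
#' In `"gd1"` mode only the maternal parameters are sampled from
#' single-administration data; `"gd15_20"` mode jointly fits the GD15
#' and GD20 repeated-dose data including the placental and fetal
#' parameters.  With `share_fetal = TRUE` (and both isomers present in
#' the data) the placental/fetal parameters are shared across isomers
#' and informed by both datasets, while maternal parameters remain
#' isomer-specific.
#'
#' @param data a TK dataset ([generate_tk_study()] / [read_tk_study()]).
#' @param isomer isomer(s) to calibrate.
#' @param mode `"gd1"` or `"gd15_20"`.
#' @param phys [gestational_physiology()].
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iter sweeps per chain.
#' @param retain_window retain draws from the last `retain_window`
#'   sweeps.
#' @param thin keep one in `thin` of the retained sweeps.
#' @param sigma_log fixed lognormal residual SD.
#' @param seed integer seed; chains use `seed + chain`.
#' @param rtol ODE solver relative tolerance during fitting.
#' @param share_fetal share placental/fetal parameters across isomers in
#'   `"gd15_20"` mode.
#' @param init_scale,adapt sampler tuning, see [mcmc_mwg()].
#' @param max_start_attempts redraw limit for non-finite starting
#'   points.
#' @return object of class `pbpk_fit`: posterior draws (`iterations x
#'   chains x parameters`, natural scale), `rhat`, posterior `summary`
#'   (mean and 95% interval), acceptance rates, and the inputs.
#' @seealso [coef.pbpk_fit()], [predict.pbpk_fit()],
#'   [residuals.pbpk_fit()], [simulate.pbpk_fit()]
#' @export
pbpk_fit <- function(data, isomer = "cis", mode = c("gd1", "gd15_20"),
                     phys = gestational_physiology(), chains = 3,
                     iter = 2000, retain_window = 800, thin = 2,
                     sigma_log = 0.15, seed = 1, rtol = 1e-6,
                     share_fetal = TRUE, init_scale = 0.25, adapt = TRUE,
                     max_start_attempts = 100) {
  mode <- match.arg(mode)
  stopifnot(all(isomer %in% c("cis", "trans")), chains >= 2,
            iter >= retain_window, retain_window >= thin)
  fetal_mats <- c("placenta", "fetal_blood", "fetal_liver", "fetal_brain")
  if (mode == "gd1") {
    sub <- data[data$gd == 1 & data$isomer %in% isomer, , drop = FALSE]
    if (any(sub$matrix %in% fetal_mats))
      stop("gd1 mode cannot use placental or fetal data")
  } else {
    sub <- data[data$gd %in% c(15, 20) & data$isomer %in% isomer, ,
                drop = FALSE]
  }
  # an empty dataset is legal: the posterior is then the prior
  if (nrow(sub)) isomer <- intersect(isomer, unique(sub$isomer))
  joint <- mode == "gd15_20" && share_fetal && length(isomer) > 1

  stage <- if (mode == "gd1") "gd1" else "gd15_20"
  base_chem <- lapply(stats::setNames(isomer, isomer), chemical_params,
                      stage = stage)
  priors <- lapply(stats::setNames(isomer, isomer), permethrin_priors)

  # sampled parameter table: (label, isomer, parameter)
  samp <- do.call(rbind, lapply(isomer, function(iso) {
    pri <- priors[[iso]]
    keep <- pri$family != "fixed" &
      (pri$maternal | (mode == "gd15_20" & pri$fetal))
    pri <- pri[keep, ]
    pri$isomer <- iso
    pri$label <- if (joint)
      ifelse(pri$fetal, pri$parameter, paste0(iso, ":", pri$parameter))
    else if (length(isomer) > 1) paste0(iso, ":", pri$parameter)
    else pri$parameter
    pri
  }))
  # in a joint fit the shared fetal rows appear once per isomer; collapse
  samp_u <- samp[!duplicated(samp$label), ]

  ctx <- tk_context(sub, phys, rtol = rtol)
  obs <- ctx$data$concentration

  build_chem <- function(theta) {
    chems <- base_chem
    for (i in seq_len(nrow(samp))) {
      chems[[samp$isomer[i]]] <- set_chemical_param(
        chems[[samp$isomer[i]]], samp$parameter[i],
        theta[[samp$label[i]]])
    }
    chems
  }
  log_post <- function(theta) {
    lp <- prior_logpdf(stats::setNames(theta, samp_u$parameter),
                       samp_u)
    if (!is.finite(lp)) return(-Inf)
    pred <- tryCatch(tk_predict_ctx(ctx, build_chem(theta)),
                     error = function(e) NULL)
    if (is.null(pred)) return(-Inf)
    lp + tk_log_likelihood(obs, pred, sigma_log)
  }

  n_keep <- floor(retain_window / thin)
  draws <- array(NA_real_, c(n_keep, chains, nrow(samp_u)),
                 dimnames = list(NULL, NULL, samp_u$label))
  acc <- matrix(NA_real_, chains, nrow(samp_u),
                dimnames = list(NULL, samp_u$label))
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch)
    start <- NULL
    for (att in seq_len(max_start_attempts)) {
      cand <- drop(prior_sample(samp_u, 1))
      names(cand) <- samp_u$label
      if (is.finite(log_post(cand))) { start <- cand; break }
    }
    if (is.null(start))
      stop("could not find a finite starting point in ",
           max_start_attempts, " attempts")
    run <- mcmc_mwg(log_post, start, n_iter = iter,
                    init_scale = init_scale, adapt = adapt)
    keep_idx <- seq(iter - retain_window + thin, iter, by = thin)
    draws[, ch, ] <- run$draws[keep_idx, , drop = FALSE]
    acc[ch, ] <- run$acceptance
  }
  rhat <- gelman_rubin(draws)
  flat <- apply(draws, 3, c)
  summ <- data.frame(
    parameter = samp_u$label,
    mean = colMeans(flat),
    sd = apply(flat, 2, stats::sd),
    q2.5 = apply(flat, 2, stats::quantile, 0.025),
    q97.5 = apply(flat, 2, stats::quantile, 0.975),
    rhat = rhat, row.names = NULL)
  structure(list(draws = draws, rhat = rhat, summary = summ,
                 acceptance = acc, sampled = samp_u, sampled_map = samp,
                 priors = priors, data = sub, mode = mode,
                 isomer = isomer, joint = joint, phys = phys,
                 sigma_log = sigma_log, seed = seed, rtol = rtol,
                 base_chem = base_chem, build_chem = build_chem,
                 ctx = ctx),
            class = "pbpk_fit")
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat(sprintf("PBPK calibration (%s mode): %s-permethrin, %d records\n",
              x$mode, paste(x$isomer, collapse = "+"), nrow(x$data)))
  cat(sprintf("  %d chains x %d retained draws, %d parameters; max R-hat %.3f\n",
              dim(x$draws)[2], dim(x$draws)[1], dim(x$draws)[3],
              max(x$rhat, na.rm = TRUE)))
  conv <- if (max(x$rhat, na.rm = TRUE) <= 1.2) "converged (R-hat <= 1.2)"
    else "NOT converged (R-hat > 1.2)"
  cat("  ", conv, "\n", sep = "")
  invisible(x)
}

#' @export
summary.pbpk_fit <- function(object, ...) {
  out <- object$summary
  class(out) <- c("summary.pbpk_fit", "data.frame")
  out
}

#' @export
print.summary.pbpk_fit <- function(x, digits = 3, ...) {
  cat("Posterior summary (mean, 95% interval, R-hat):\n")
  print.data.frame(cbind(x[1],
                         signif(x[, c("mean", "q2.5", "q97.5")], digits),
                         rhat = round(x$rhat, 3)), row.names = FALSE)
  invisible(x)
}

#' Posterior-mean parameter estimates
#' @param object a [pbpk_fit()] object.
#' @param ... unused.
#' @return named vector of posterior means.
#' @export
coef.pbpk_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' Chemical parameter object at the posterior mean
#' @param fit a [pbpk_fit()] object.
#' @param isomer which isomer to extract.
#' @return [chemical_params()] with sampled entries set to their
#'   posterior means.
#' @export
fitted_chemical_params <- function(fit, isomer = fit$isomer[1]) {
  stopifnot(inherits(fit, "pbpk_fit"), isomer %in% fit$isomer)
  fit$build_chem(coef(fit))[[isomer]]
}

#' Predict concentration time courses from a calibrated model
#'
#' Runs the forward model at the posterior-mean parameters through the
#' study dosing history for a gestational day.
#'
#' @param object a [pbpk_fit()] object.
#' @param gd sacrifice gestational day (dosing GD1..gd).
#' @param isomer isomer to predict.
#' @param times_h output times post-dose.
#' @param matrices matrices to report.
#' @param ... unused.
#' @return data frame `time_h` (post-dose), `matrix`, `concentration`.
#' @export
predict.pbpk_fit <- function(object, gd = 1, isomer = object$isomer[1],
                             times_h = seq(0, 24, by = 0.5),
                             matrices = c("blood", "brain", "liver"),
                             ...) {
  chem <- fitted_chemical_params(object, isomer)
  dose <- if (isomer == "cis") 20 else 30
  t_dose <- gd * 24
  out <- pbpk_ode(chem, object$phys,
                  sort(unique(c(t_dose, t_dose + times_h))),
                  data.frame(time_h = seq_len(gd) * 24,
                             dose_mg = dose *
                               maternal_body_weight(seq_len(gd),
                                                    object$phys)),
                  rtol = 1e-8)
  rows <- lapply(times_h, function(tp) {
    st <- out[out[, "time"] == t_dose + tp, -1]
    cc <- pbpk_concentrations(st, min(gd + tp / 24, 20), object$phys,
                              matrices)
    data.frame(time_h = tp, matrix = matrices,
               concentration = unname(cc))
  })
  do.call(rbind, rows)
}

#' Log-scale residuals at the posterior mean
#'
#' @param object a [pbpk_fit()] object.
#' @param ... unused.
#' @return data frame of the fitted records with `predicted` and
#'   `log_residual` = log(observed / predicted).
#' @export
residuals.pbpk_fit <- function(object, ...) {
  pred <- tk_predict_ctx(object$ctx, object$build_chem(coef(object)))
  out <- object$ctx$data
  out$predicted <- pred
  out$log_residual <- log(out$concentration / pmax(pred, 1e-12))
  out
}

#' Posterior-predictive synthetic studies
#'
#' Draws parameter vectors from the posterior and regenerates synthetic
#' datasets with the fitted design, giving posterior-predictive
#' replicates of the study.
#'
#' @param object a [pbpk_fit()] object.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `tk_dataset` data frames.
#' @export
simulate.pbpk_fit <- function(object, nsim = 1, seed = 1, ...) {
  n_draw <- dim(object$draws)[1] * dim(object$draws)[2]
  flat <- apply(object$draws, 3, c)
  set.seed(as.integer(seed))
  idx <- sample.int(n_draw, nsim, replace = nsim > n_draw)
  design <- study_design(gestational_days = sort(unique(object$data$gd)))
  lapply(seq_len(nsim), function(i) {
    theta <- stats::setNames(flat[idx[i], ], dimnames(object$draws)[[3]])
    chems <- object$build_chem(theta)
    generate_tk_study(chems, object$phys, design,
                      sigma_log = object$sigma_log, seed = seed + i,
                      rtol = object$rtol)
  })
}

#' @export
plot.pbpk_fit <- function(x, parameters = utils::head(x$summary$parameter, 4),
                          ...) {
  op <- graphics::par(mfrow = c(length(parameters), 1),
                      mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in parameters) {
    graphics::matplot(x$draws[, , p], type = "l", lty = 1,
                      ylab = p, xlab = "", ...)
  }
  invisible(x)
}
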