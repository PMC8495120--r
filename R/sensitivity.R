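#' Sobol variance-based sensitivity indices
#'
#' Saltelli-scheme Monte Carlo estimation of first-order and total-order
#' Sobol indices.  Two independent base matrices A and B of size
#' `n_base` are drawn from independent truncated-normal marginals by
#' inverse-CDF sampling; for each parameter i a hybrid matrix AB_i
#' (columns of A with column i from B) is evaluated.  First-order
#' indices use the Saltelli (2010) estimator
#' `S1_i = mean(fB * (fAB_i - fA)) / V` and total-order indices the
#' Jansen estimator `ST_i = mean((fA - fAB_i)^2) / (2 V)`.  Bootstrap
#' resampling of the base sample provides confidence bounds.  Small
#' negative estimates are Monte-Carlo noise.
#'
#' @param fn vectorised model: takes an `n x p` parameter matrix (columns
#'   named as `dists$parameter`), returns a numeric vector of length `n`
#'   or an `n x m` matrix for `m` outputs.  Rows that fail may be `NA`;
#'   the corresponding base-sample points are dropped (an error is
#'   raised if more than `max_reject` of them fail).
#' @param dists data frame with columns `parameter`, `mean`, `sd`,
#'   `lower`, `upper` describing independent truncated-normal marginals
#'   (use wide bounds for effectively normal marginals).
#' @param n_base base sample size N (total model evaluations
#'   `N * (p + 2)`).
#' @param seed integer seed.
#' @param n_boot bootstrap resamples for the confidence bounds.
#' @param conf confidence level.
#' @param max_reject tolerated fraction of failed sample points.
#' @return object of class `sobol_result`: data frame with one row per
#'   (output, parameter): `S1`, `S1_lo`, `S1_hi`, `ST`, `ST_lo`,
#'   `ST_hi`, plus attributes `n_base` and `seed`.
#' @examples
#' # additive test function: Y = X1 + X2, var 1 + 4 => S1 = 0.2, 0.8
#' d <- data.frame(parameter = c("x1", "x2"), mean = 0, sd = c(1, 2),
#'                 lower = -20, upper = 20)
#' sobol_indices(function(x) x[, 1] + x[, 2], d, n_base = 512, seed = 1)
#' @export
sobol_indices <- function(fn, dists, n_base = 256, seed = 1,
                          n_boot = 100, conf = 0.95, max_reject = 0.01) {
  stopifnot(all(c("parameter", "mean", "sd", "lower", "upper") %in%
                  names(dists)), n_base >= 8)
  p <- nrow(dists)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  qtn <- function(u, m, s, lo, hi) {
    plo <- stats::pnorm(lo, m, s); phi <- stats::pnorm(hi, m, s)
    stats::qnorm(plo + u * (phi - plo), m, s)
  }
  draw <- function() {
    u <- matrix(stats::runif(n_base * p), n_base, p)
    x <- sapply(seq_len(p), function(j)
      qtn(u[, j], dists$mean[j], dists$sd[j], dists$lower[j],
          dists$upper[j]))
    colnames(x) <- dists$parameter
    x
  }
  A <- draw(); B <- draw()
  evaluate <- function(x) {
    y <- fn(x)
    if (is.null(dim(y))) y <- matrix(y, ncol = 1)
    y
  }
  fA <- evaluate(A); fB <- evaluate(B)
  m_out <- ncol(fA)
  out_names <- colnames(fA)
  if (is.null(out_names)) out_names <- paste0("y", seq_len(m_out))
  fAB <- array(NA_real_, c(n_base, m_out, p))
  for (j in seq_len(p)) {
    ABj <- A; ABj[, j] <- B[, j]
    fAB[, , j] <- evaluate(ABj)
  }
  ok <- stats::complete.cases(fA) & stats::complete.cases(fB) &
    apply(fAB, 1, function(z) all(is.finite(z)))
  if (mean(!ok) > max_reject)
    stop(sprintf("%.1f%% of sample points failed (> %.1f%% allowed)",
                 100 * mean(!ok), 100 * max_reject))
  idx_all <- which(ok)
  est <- function(idx, k) {
    a <- fA[idx, k]; b <- fB[idx, k]
    v <- stats::var(c(a, b))
    s1 <- vapply(seq_len(p), function(j)
      mean(b * (fAB[idx, k, j] - a)) / v, numeric(1))
    st <- vapply(seq_len(p), function(j)
      mean((a - fAB[idx, k, j])^2) / (2 * v), numeric(1))
    c(s1, st)
  }
  alpha <- (1 - conf) / 2
  rows <- list()
  for (k in seq_len(m_out)) {
    point <- est(idx_all, k)
    boot <- replicate(n_boot, est(sample(idx_all, replace = TRUE), k))
    lo <- apply(boot, 1, stats::quantile, alpha)
    hi <- apply(boot, 1, stats::quantile, 1 - alpha)
    rows[[k]] <- data.frame(
      output = out_names[k], parameter = dists$parameter,
      S1 = point[seq_len(p)], S1_lo = lo[seq_len(p)],
      S1_hi = hi[seq_len(p)],
      ST = point[p + seq_len(p)], ST_lo = lo[p + seq_len(p)],
      ST_hi = hi[p + seq_len(p)], row.names = NULL)
  }
  res <- do.call(rbind, rows)
  attr(res, "n_base") <- n_base
  attr(res, "seed") <- seed
  attr(res, "n_used") <- length(idx_all)
  class(res) <- c("sobol_result", "data.frame")
  res
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("Sobol sensitivity indices (N = %d, seed %d)\n",
              attr(x, "n_base"), attr(x, "seed")))
  for (o in unique(x$output)) {
    sub <- x[x$output == o, ]
    sub <- sub[order(-sub$ST), ]
    cat(" output:", o, "\n")
    top <- utils::head(sub, 6)
    for (i in seq_len(nrow(top)))
      cat(sprintf("   %-22s S1 %6.3f  ST %6.3f\n", top$parameter[i],
                  top$S1[i], top$ST[i]))
  }
  invisible(x)
}

# GSA distribution table: truncated normals around the calibrated means
# (CV 30%), truncated at the calibration prior bounds
gsa_distributions <- function(chem, cv = 0.30) {
  pri <- permethrin_priors(chem$isomer)
  pri <- pri[pri$family != "fixed", ]
  means <- vapply(pri$parameter, function(p) get_chemical_param(chem, p),
                  numeric(1))
  data.frame(parameter = pri$parameter, mean = means, sd = cv * means,
             lower = pri$lower, upper = pri$upper)
}

#' Global sensitivity analysis of the PBPK model
#'
#' Sobol analysis of the calibrated model under the repeated-dose
#' exposure scenario: every calibrated chemical-specific parameter is
#' perturbed with an independent truncated normal centred on its
#' calibrated mean with a 30% coefficient of variation (truncated at
#' the calibration prior bounds), and the indices are estimated for the
#' selected output at several times after the oral administration on a
#' late-gestation day.
#'
#' @param chem [chemical_params()] at the calibrated means (cis isomer
#'   by default).
#' @param phys [gestational_physiology()].
#' @param output one of `"maternal_blood"` (arterial), `"fetal_blood"`
#'   or `"fetal_brain"`.
#' @param gd gestational day of the analysed dose (15 or 20).
#' @param times_h output times after that day's administration.
#' @param cv coefficient of variation of the parameter distributions.
#' @param n_base Sobol base sample size.
#' @param seed integer seed.
#' @param rtol ODE solver tolerance for the model runs.
#' @param n_boot bootstrap resamples.
#' @return `sobol_result` with one output per requested time, labelled
#'   `"<output>+<t>h"`.
#' @export
run_gsa <- function(chem = chemical_params("cis", "gd15_20"),
                    phys = gestational_physiology(),
                    output = c("maternal_blood", "fetal_blood",
                               "fetal_brain"),
                    gd = 15, times_h = c(4, 6, 12), cv = 0.30,
                    n_base = 256, seed = 1, rtol = 1e-6, n_boot = 100) {
  output <- match.arg(output)
  stopifnot(gd > phys$conceptus_onset_gd, gd <= 20)
  dists <- gsa_distributions(chem, cv)
  t_dose <- gd * 24
  t_out <- sort(unique(c(t_dose, t_dose + times_h)))
  dose_events <- data.frame(
    time_h = seq_len(gd) * 24,
    dose_mg = 20 * maternal_body_weight(seq_len(gd), phys))
  matrix_name <- switch(output, maternal_blood = "blood",
                        fetal_blood = "fetal_blood",
                        fetal_brain = "fetal_brain")
  fn <- function(x) {
    out <- matrix(NA_real_, nrow(x), length(times_h),
                  dimnames = list(NULL, sprintf("%s+%gh", output,
                                                times_h)))
    for (i in seq_len(nrow(x))) {
      ch <- chem
      for (j in seq_len(ncol(x)))
        ch <- set_chemical_param(ch, colnames(x)[j], x[i, j])
      sol <- tryCatch(
        pbpk_ode(ch, phys, t_out, dose_events, rtol = rtol,
                 atol = 1e-10),
        error = function(e) NULL)
      if (is.null(sol)) next
      out[i, ] <- vapply(times_h, function(tp) {
        st <- sol[sol[, "time"] == t_dose + tp, -1]
        pbpk_concentrations(st, min(gd + tp / 24, 20), phys,
                            matrix_name)
      }, numeric(1))
    }
    out
  }
  res <- sobol_indices(fn, dists, n_base = n_base, seed = seed,
                       n_boot = n_boot)
  attr(res, "output") <- output
  attr(res, "gd") <- gd
  res
}

#' Parameter ranking from a Sobol result
#'
#' @param result a [sobol_indices()] / [run_gsa()] result.
#' @param output output label to rank (default: the only/first one).
#' @return list with `by_total` and `by_first_order` (parameter names in
#'   decreasing index order) and the underlying table.
#' @export
rank_parameters <- function(result, output = unique(result$output)[1]) {
  stopifnot(inherits(result, "sobol_result"))
  sub <- result[result$output == output, ]
  if (!nrow(sub))
    stop("no such output '", output, "'; available: ",
         paste(unique(result$output), collapse = ", "))
  tab <- sub[order(-sub$ST), ]
  class(tab) <- "data.frame"
  rownames(tab) <- NULL
  list(by_total = sub$parameter[order(-sub$ST)],
       by_first_order = sub$parameter[order(-sub$S1)],
       table = tab)
}
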