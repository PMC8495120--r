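#' Linear trapezoidal AUC
#'
#' Area under the concentration-time curve by the linear trapezoidal
#' rule over the provided points only; no extrapolation beyond the last
#' sample.
#'
#' @param times sampling times (h), sorted increasing.
#' @param concs non-negative concentrations, same length.
#' @return AUC (concentration x h).
#' @examples
#' auc_trapezoid(c(0, 24), c(2, 2))  # 48
#' @export
auc_trapezoid <- function(times, concs) {
  if (length(times) < 2L || length(times) != length(concs))
    stop("need at least 2 matching time/concentration points")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(!is.finite(times)) || any(!is.finite(concs)) ||
      any(times < 0) || any(concs < 0))
    stop("times and concentrations must be finite and non-negative")
  sum(diff(times) * (utils::head(concs, -1) + utils::tail(concs, -1)) / 2)
}

#' Time of maximal concentration
#'
#' @inheritParams auc_trapezoid
#' @return the sampling time of the maximum; ties are broken by the
#'   earliest time.
#' @export
pk_tmax <- function(times, concs) {
  if (length(times) < 1L || length(times) != length(concs))
    stop("need at least one matching time/concentration point")
  times[which.max(concs)]
}

#' Terminal elimination half-life
#'
#' Log-linear regression of the terminal phase: all points from Tmax
#' onward enter an ordinary least-squares fit of log(concentration) on
#' time (sparse group-sacrifice designs often leave only two samples
#' beyond the peak, so the peak itself anchors the fit).  The half-life is `log(2)` over the negative slope.  When
#' fewer than three positive terminal points exist, or the fitted slope
#' is non-negative, the half-life is undefined and `NA` is returned (the
#' dashes of a sparse toxicokinetic table).
#'
#' @inheritParams auc_trapezoid
#' @return half-life in h, or `NA_real_` when undefined.
#' @examples
#' pk_half_life(c(2, 6, 10), c(8, 4, 2))  # exact 2-fold decay: 4 h
#' @export
pk_half_life <- function(times, concs) {
  tmax <- pk_tmax(times, concs)
  keep <- times >= tmax & concs > 0
  if (sum(keep) < 3L) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, times[keep]), log(concs[keep]))
  lambda <- -fit$coefficients[[2]]
  if (!is.finite(lambda) || lambda <= 0) return(NA_real_)
  log(2) / lambda
}

#' Non-compartmental summary of one concentration series
#'
#' @inheritParams auc_trapezoid
#' @param anchor_zero prepend a (0, 0) point before computing the AUC,
#'   the convention used for observed group-sacrifice curves whose first
#'   sample is at 1 h post-dose.
#' @return list with `auc_0_24`, `tmax`, `t_half` and `n_points_used`.
#' @export
pk_nca <- function(times, concs, anchor_zero = FALSE) {
  if (anchor_zero && times[1] > 0) {
    times <- c(0, times)
    concs <- c(0, concs)
  }
  list(auc_0_24 = auc_trapezoid(times, concs),
       tmax = pk_tmax(times, concs),
       t_half = pk_half_life(times, concs),
       n_points_used = length(times))
}

#' Ratios between named AUC entries
#'
#' Computes quotients between entries of a named AUC vector: tissue to
#' blood partitioning, late-to-early gestation accumulation,
#' feto-maternal transfer, or cis/trans comparisons -- any ratio is just
#' a named numerator/denominator pair.
#'
#' @param auc named numeric vector of AUC values.
#' @param ratios data frame with columns `name`, `num`, `den`; `num` and
#'   `den` must name entries of `auc`.
#' @return named numeric vector of ratios.
#' @examples
#' auc <- c(fat_gd15 = 1247.08, fat_gd1 = 43.97)
#' auc_ratios(auc, data.frame(name = "fat_accumulation",
#'                            num = "fat_gd15", den = "fat_gd1"))
#' @export
auc_ratios <- function(auc, ratios) {
  stopifnot(is.data.frame(ratios),
            all(c("name", "num", "den") %in% names(ratios)))
  missing <- setdiff(unique(c(ratios$num, ratios$den)), names(auc))
  if (length(missing))
    stop("missing AUC entries: ", paste(missing, collapse = ", "))
  stats::setNames(auc[ratios$num] / auc[ratios$den], ratios$name)
}

#' Limit-of-quantification substitution
#'
#' Handling rule of the analytical data: a sample in which the analyte
#' was detected but quantified below the LOQ is set to LOQ/2; values at
#' or above the LOQ are unchanged; samples with no detectable analyte
#' are excluded (`NA`).
#'
#' @param value measured concentration (same units as `loq`).
#' @param loq positive limit of quantification.
#' @param detected logical; was the analyte detected at all?
#' @return substituted concentration, vectorised.
#' @examples
#' loq_substitute(0.010, 0.026, TRUE)   # 0.013
#' loq_substitute(0.030, 0.026, TRUE)   # unchanged
#' @export
loq_substitute <- function(value, loq, detected = TRUE) {
  stopifnot(all(loq > 0))
  out <- ifelse(value >= loq, value, loq / 2)
  out[!detected] <- NA_real_
  out
}

#' Per-matrix NCA table from a toxicokinetic dataset
#'
#' Collapses a (possibly censored) dataset to one composite curve per
#' (gestational day, matrix, isomer) using the mean concentration per
#' time point -- the natural summary of a destructive group-sacrifice
#' design -- and computes the 24-h AUC, Tmax and terminal half-life.
#' Below-LOQ detected records enter at LOQ/2; non-detected records are
#' excluded.
#'
#' @param data a TK dataset data frame (see [generate_tk_study()]).
#' @param anchor_zero prepend a (0, 0) anchor to each composite curve.
#' @return data frame with one row per (gd, matrix, isomer).
#' @export
nca_table <- function(data, anchor_zero = TRUE) {
  stopifnot(all(c("gd", "time_h", "matrix", "isomer", "concentration",
                  "censor_state") %in% names(data)))
  data <- data[data$censor_state != "not_detected", , drop = FALSE]
  keys <- unique(data[, c("gd", "matrix", "isomer")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- merge(keys[i, ], data)
    agg <- stats::aggregate(concentration ~ time_h, sub, mean)
    agg <- agg[order(agg$time_h), ]
    if (nrow(agg) < 2L) return(NULL)
    m <- pk_nca(agg$time_h, agg$concentration, anchor_zero = anchor_zero)
    cbind(keys[i, ], auc_0_24 = m$auc_0_24, tmax = m$tmax,
          t_half = m$t_half, n_points_used = m$n_points_used)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
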