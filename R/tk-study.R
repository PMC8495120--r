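#' Design of the in-vivo toxicokinetic study
#'
#' Encodes the destructive-sampling gavage study: groups of
#' `n_per_group` dams sacrificed at fixed times after the last daily
#' dose, on one of several gestational days.  Feces were collected over
#' the 24 h following the dose (metabolic cages, GD1 and GD15 only);
#' placentas were sampled at GD15 and GD20, and fetal blood, liver and
#' brain at GD20.
#'
#' Limits of quantification are stored in ng/g (ng/ml for blood) as
#' reported by the analytical method and converted to mg/L internally
#' (1 ng/g = 1e-3 mg/L at unit tissue density).
#'
#' @param gestational_days sacrifice days (subset of 1, 15, 20 by
#'   default).
#' @param sample_times_h sampling times post-dose (h).
#' @param n_per_group animals per time point.
#' @param loq_ng named list per isomer of named LOQ vectors (ng/g).
#' @return object of class `study_design`.
#' @export
study_design <- function(gestational_days = c(1, 15, 20),
                         sample_times_h = c(1, 2, 3, 4, 6, 10, 24),
                         n_per_group = 4,
                         loq_ng = default_loq_table()) {
  stopifnot(all(gestational_days %in% 0:20), n_per_group >= 1,
            all(sample_times_h > 0), all(sample_times_h <= 24))
  stopifnot(all(unlist(loq_ng) > 0))
  structure(list(gestational_days = sort(gestational_days),
                 sample_times_h = sort(sample_times_h),
                 n_per_group = n_per_group, loq_ng = loq_ng),
            class = "study_design")
}

#' Default limits of quantification (ng/g or ng/ml)
#'
#' Matrix-specific LOQs of the LC-MS/MS assay for each isomer.  Fetal
#' matrices share the LOQ of the corresponding maternal matrix.
#' @return named list with elements `cis` and `trans`.
#' @export
default_loq_table <- function() {
  list(
    cis = c(blood = 26, liver = 20, brain = 20, kidney = 40, fat = 20,
            mammary = 20, placenta = 4, feces = 4,
            fetal_blood = 26, fetal_liver = 20, fetal_brain = 20),
    trans = c(blood = 52, liver = 80, brain = 20, kidney = 80, fat = 80,
              mammary = 80, placenta = 20, feces = 40,
              fetal_blood = 52, fetal_liver = 80, fetal_brain = 20))
}

# matrices sampled at each gestational day of the default protocol
design_matrices <- function(gd) {
  m <- c("blood", "liver", "brain", "kidney", "fat", "mammary")
  if (gd <= 15) m <- c(m, "feces")
  if (gd >= 15) m <- c(m, "placenta")
  if (gd >= 20) m <- c(m, "fetal_blood", "fetal_liver", "fetal_brain")
  m
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("TK study design: GD %s; %d/group at %s h post-dose\n",
              paste(x$gestational_days, collapse = ", "), x$n_per_group,
              paste(x$sample_times_h, collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic toxicokinetic study
#'
#' Simulates the full dosing history up to each sacrifice day with the
#' supplied "true" chemical parameters, reads the model concentration
#' at every design point, applies multiplicative lognormal measurement
#' error, and censors against the matrix-specific LOQ: values below the
#' LOQ but above the detection threshold (`loq / detect_frac`) are
#' recorded as LOQ/2 (`below_loq_detected`); smaller latent values are
#' `not_detected` and carry `NA`.  Feces records are the cumulative
#' amount (mg) excreted over the 24 h after the dose, one record per
#' animal.
#'
#' Measurement error is the only stochastic layer, matching the
#' lognormal residual-error model of the calibration; there is no
#' inter-animal kinetic variability.
#'
#' @param true_params list with elements `cis` and/or `trans`, each a
#'   [chemical_params()] object used as ground truth.
#' @param phys [gestational_physiology()].
#' @param design [study_design()].
#' @param sigma_log lognormal error SD on the log scale (0.15 = the
#'   assay/model residual error assumed by the calibration).
#' @param seed integer seed; the dataset is a deterministic function of
#'   it.
#' @param dose_per_kg named doses (mg/kg) per isomer.
#' @param detect_frac latent values below `loq/detect_frac` are reported
#'   as not detected.
#' @param rtol solver relative tolerance.
#' @return data frame of class `tk_dataset` with columns `gd`, `time_h`
#'   (post-dose), `matrix`, `isomer`, `animal_id`, `concentration`
#'   (mg/L; mg for feces; `NA` when not detected), `censor_state`
#'   (`quantified`, `below_loq_detected`, `not_detected`) and `loq`
#'   (mg/L).
#' @export
generate_tk_study <- function(true_params, phys = gestational_physiology(),
                              design = study_design(), sigma_log = 0.15,
                              seed = 1,
                              dose_per_kg = c(cis = 20, trans = 30),
                              detect_frac = 10, rtol = 1e-6) {
  stopifnot(is.list(true_params), length(true_params) >= 1,
            all(names(true_params) %in% c("cis", "trans")),
            sigma_log >= 0)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  rows <- list()
  for (iso in names(true_params)) {
    chem <- true_params[[iso]]
    loq_mgL <- design$loq_ng[[iso]] * 1e-3
    for (gd in design$gestational_days) {
      sched <- dose_schedule(dose_per_kg[[iso]], times_gd = seq_len(gd))
      t_dose <- gd * 24
      t_out <- sort(unique(c(t_dose, t_dose + design$sample_times_h,
                             t_dose + 24)))
      out <- pbpk_ode(chem, phys, t_out,
                      data.frame(time_h = sched$times_gd * 24,
                                 dose_mg = sched$dose_per_kg *
                                   maternal_body_weight(sched$times_gd, phys)),
                      rtol = rtol, atol = 1e-10)
      mats <- design_matrices(gd)
      for (m in mats) {
        if (m == "feces") {
          fec24 <- out[out[, "time"] == t_dose + 24, "A_fec"] -
            out[out[, "time"] == t_dose, "A_fec"]
          latent <- rep(fec24, design$n_per_group)
          tt <- rep(24, design$n_per_group)
          ids <- seq_len(design$n_per_group)
        } else {
          pred <- vapply(design$sample_times_h, function(tp) {
            st <- out[out[, "time"] == t_dose + tp, -1]
            pbpk_concentrations(st, min(gd + tp / 24, 20), phys, m)
          }, numeric(1))
          latent <- rep(pred, each = design$n_per_group)
          tt <- rep(design$sample_times_h, each = design$n_per_group)
          ids <- rep(seq_len(design$n_per_group),
                     times = length(design$sample_times_h))
        }
        eps <- stats::rnorm(length(latent), 0, sigma_log)
        obs <- latent * exp(eps)
        loq <- loq_mgL[[m]]
        state <- ifelse(obs >= loq, "quantified",
                        ifelse(obs >= loq / detect_frac,
                               "below_loq_detected", "not_detected"))
        value <- ifelse(state == "quantified", obs,
                        ifelse(state == "below_loq_detected", loq / 2,
                               NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          gd = gd, time_h = tt, matrix = m, isomer = iso,
          animal_id = ids, concentration = value, censor_state = state,
          loq = loq, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tk_dataset", "data.frame")
  out
}

.censor_tokens <- c("quantified", "below_loq_detected", "not_detected")

#' Write a TK dataset to CSV
#' @param data a `tk_dataset` data frame.
#' @param path output file.
#' @export
write_tk_study <- function(data, path) {
  cols <- c("gd", "time_h", "matrix", "isomer", "animal_id",
            "concentration", "censor_state", "loq")
  stopifnot(all(cols %in% names(data)))
  utils::write.csv(data[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TK dataset from CSV
#'
#' Validates the record schema; a malformed row fails with its line
#' number.
#' @param path CSV file written by [write_tk_study()].
#' @return `tk_dataset` data frame.
#' @export
read_tk_study <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("gd", "time_h", "matrix", "isomer", "animal_id",
            "concentration", "censor_state", "loq")
  if (!all(cols %in% names(data)))
    stop("missing columns: ", paste(setdiff(cols, names(data)),
                                    collapse = ", "))
  if (nrow(data)) {
    bad <- which(!data$censor_state %in% .censor_tokens)
    if (length(bad))
      stop("unknown censor_state token at line ", bad[1] + 1L, ": '",
           data$censor_state[bad[1]], "'")
    bad <- which(!is.finite(data$loq) | data$loq <= 0)
    if (length(bad))
      stop("invalid LOQ at line ", bad[1] + 1L)
    bad <- which(data$censor_state != "not_detected" &
                   !is.finite(data$concentration))
    if (length(bad))
      stop("missing concentration for detected record at line ",
           bad[1] + 1L)
  }
  data <- data[, cols]
  class(data) <- c("tk_dataset", "data.frame")
  data
}
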