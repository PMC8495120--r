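#' Chemical-specific parameters of one permethrin isomer
#'
#' Assembles the full chemical parameter vector of the pregnancy PBPK
#' model: maternal tissue:blood partition coefficients (PC, unitless),
#' permeability coefficients of the diffusion-limited tissues (PS,
#' unitless permeability:flow ratios -- the effective
#' permeability-surface area product of tissue T is `PS_T * Q_T(t)`),
#' oral absorption and fecal excretion rate constants (1/h), metabolic
#' clearances (L/h/kg), allometrically scaled placental transfer
#' constants (L/h/kg^0.75) and the fetal partition/permeability
#' parameters.  The GI partition coefficient is tied to the kidney value.
#'
#' Defaults are the calibrated posterior means for the requested isomer
#' and gestational stage; rate constants for intestinal absorption and
#' blood/intestinal metabolism are fixed to the adult-rat values, as in
#' the calibration.
#'
#' @param isomer `"cis"` or `"trans"`.
#' @param stage `"gd1"` (single administration, early gestation) or
#'   `"gd15_20"` (repeated administration, late gestation) posterior
#'   means.
#' @param ... named overrides for any parameter, e.g. `cl_liv = 5`,
#'   `pc = c(fat = 400)` (partial PC/PS vectors are merged).
#' @return object of class `chemical_params`.
#' @examples
#' chemical_params("cis", "gd1")$cl_liv    # 8.44 L/h/kg
#' chemical_params("cis", pc = c(fat = 400))$pc[["fat"]]
#' @export
chemical_params <- function(isomer = c("cis", "trans"),
                            stage = c("gd15_20", "gd1"), ...) {
  isomer <- match.arg(isomer)
  stage <- match.arg(stage)
  base <- .param_defaults[[isomer]][[stage]]
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% c("pc", "ps")) {
      upd <- dots[[nm]]
      if (is.null(names(upd)) || !all(names(upd) %in% names(base[[nm]])))
        stop("unknown ", nm, " tissue name in override")
      base[[nm]][names(upd)] <- upd
    } else if (nm %in% names(base)) {
      base[[nm]] <- dots[[nm]]
    } else {
      stop("unknown chemical parameter: ", nm)
    }
  }
  base$pc[["gi"]] <- base$pc[["kidney"]]
  base$isomer <- isomer
  base$stage <- stage
  # partition coefficients divide concentrations and must be positive;
  # rate-like parameters and permeability ratios may be zero (limiting
  # cases: no transfer, no clearance, no exchange)
  pcs <- c(base$pc, pc_liv_f = base$pc_liv_f, pc_brain_f = base$pc_brain_f,
           pc_rb_f = base$pc_rb_f)
  rest <- unlist(base[c("ps", "k_si", "k_ai", "k_fec", "cl_gi",
                        "cl_blood", "cl_liv", "sc_ktrans1", "sc_ktrans2",
                        "ps_brain_f")])
  if (any(!is.finite(pcs)) || any(pcs <= 0))
    stop("partition coefficients must be strictly positive and finite")
  if (any(!is.finite(rest)) || any(rest < 0))
    stop("rate and permeability parameters must be non-negative and finite")
  class(base) <- "chemical_params"
  base
}

#' @export
print.chemical_params <- function(x, ...) {
  cat(sprintf("Chemical parameters: %s-permethrin (%s posterior means)\n",
              x$isomer, x$stage))
  cat("  PC:", paste(sprintf("%s=%.3g", names(x$pc), x$pc), collapse = " "),
      "\n")
  cat("  PS (flow fraction):", paste(sprintf("%s=%.3g", names(x$ps), x$ps),
                           collapse = " "), "\n")
  cat(sprintf("  k_si=%.3g k_ai=%.3g k_fec=%.3g 1/h; CL gi/blood/liver = %.3g/%.3g/%.3g L/h/kg\n",
              x$k_si, x$k_ai, x$k_fec, x$cl_gi, x$cl_blood, x$cl_liv))
  cat(sprintf("  placental transfer: %.3g (dam->fetus), %.3g (fetus->dam) L/h/kg^0.75\n",
              x$sc_ktrans1, x$sc_ktrans2))
  invisible(x)
}

# calibrated posterior means by isomer and gestational stage; fixed
# parameters are the adult-rat values.  The cis GD1 column has no
# placental estimate (the conceptus is inactive at GD1), so the late
# gestation value is carried; likewise the trans GD1 liver PC.
.param_defaults <- list(
  cis = list(
    gd1 = list(
      pc = c(liver = 2.33, gi = 5.61, fat = 345, mammary = 212,
             muscle = 1.2, brain = 2.67, kidney = 5.61, placenta = 3.52,
             slowly_perfused = 14.7, rapidly_perfused = 1.1),
      ps = c(brain = 5.6e-3, kidney = 1.3e-2, fat = 0.10, mammary = 0.252,
             muscle = 0.32, slowly_perfused = 0.20),
      k_si = 0.15, k_ai = 0.52, k_fec = 0.07,
      cl_gi = 0.04, cl_blood = 0.07, cl_liv = 8.44,
      sc_ktrans1 = 1.91, sc_ktrans2 = 2.52,
      pc_liv_f = 5.41, pc_brain_f = 2.01, pc_rb_f = 57.20,
      ps_brain_f = 7.9e-3),
    gd15_20 = list(
      pc = c(liver = 1.48, gi = 3.00, fat = 545, mammary = 436,
             muscle = 1.2, brain = 1.15, kidney = 3.00, placenta = 3.52,
             slowly_perfused = 4.55, rapidly_perfused = 1.1),
      ps = c(brain = 3.5e-3, kidney = 0.24, fat = 4.5e-2, mammary = 0.125,
             muscle = 0.32, slowly_perfused = 0.79),
      k_si = 0.18, k_ai = 0.52, k_fec = 0.020,
      cl_gi = 0.04, cl_blood = 0.07, cl_liv = 2.40,
      sc_ktrans1 = 1.91, sc_ktrans2 = 2.52,
      pc_liv_f = 5.41, pc_brain_f = 2.01, pc_rb_f = 57.20,
      ps_brain_f = 7.9e-3)
  ),
  trans = list(
    gd1 = list(
      pc = c(liver = 1.36, gi = 0.21, fat = 60.5, mammary = 5.09,
             muscle = 0.82, brain = 0.72, kidney = 0.21, placenta = 3.00,
             slowly_perfused = 9.5, rapidly_perfused = 0.21),
      ps = c(brain = 1.6e-3, kidney = 1.3e-2, fat = 0.07, mammary = 0.522,
             muscle = 0.48, slowly_perfused = 0.07),
      k_si = 0.058, k_ai = 1.30, k_fec = 0.09,
      cl_gi = 0.3, cl_blood = 0.29, cl_liv = 19.4,
      sc_ktrans1 = 1.91, sc_ktrans2 = 2.52,
      pc_liv_f = 5.41, pc_brain_f = 2.01, pc_rb_f = 57.20,
      ps_brain_f = 7.9e-3),
    gd15_20 = list(
      pc = c(liver = 1.36, gi = 0.21, fat = 165, mammary = 46.7,
             muscle = 0.82, brain = 0.64, kidney = 0.21, placenta = 3.00,
             slowly_perfused = 1.55, rapidly_perfused = 0.21),
      ps = c(brain = 2.2e-3, kidney = 0.24, fat = 9.2e-3, mammary = 0.253,
             muscle = 0.48, slowly_perfused = 0.11),
      k_si = 0.084, k_ai = 1.30, k_fec = 0.033,
      cl_gi = 0.3, cl_blood = 0.29, cl_liv = 20.5,
      sc_ktrans1 = 1.91, sc_ktrans2 = 2.52,
      pc_liv_f = 5.41, pc_brain_f = 2.01, pc_rb_f = 57.20,
      ps_brain_f = 7.9e-3)
  )
)

#' Prior distributions of the calibrated chemical parameters
#'
#' Returns the prior specification used in the Bayesian calibration: a
#' truncated normal (coefficient of variation 50% except where a
#' tighter spread was carried from the adult model) for parameters with
#' adult-rat reference values, a bounded uniform for the others, and
#' fixed values for the parameters that are not sampled.
#'
#' @param isomer `"cis"` or `"trans"`.
#' @return data frame of class `prior_spec` with columns `parameter`
#'   (the flat override name understood by [set_chemical_param()]),
#'   `family` (`"truncnorm"`, `"uniform"` or `"fixed"`), `mean`, `sd`,
#'   `lower`, `upper`, and logical columns `maternal` and `fetal`
#'   flagging which calibration mode samples the parameter.
#' @export
permethrin_priors <- function(isomer = c("cis", "trans")) {
  isomer <- match.arg(isomer)
  tn <- function(p, m, s, lo, hi, fetal = FALSE)
    data.frame(parameter = p, family = "truncnorm", mean = m, sd = s,
               lower = lo, upper = hi, maternal = !fetal, fetal = fetal)
  un <- function(p, lo, hi, fetal = FALSE)
    data.frame(parameter = p, family = "uniform", mean = (lo + hi) / 2,
               sd = NA_real_, lower = lo, upper = hi,
               maternal = !fetal, fetal = fetal)
  fx <- function(p, v)
    data.frame(parameter = p, family = "fixed", mean = v, sd = NA_real_,
               lower = v, upper = v, maternal = FALSE, fetal = FALSE)
  shared <- rbind(
    un("sc_ktrans1", 0, 6, fetal = TRUE),
    un("sc_ktrans2", 0, 6, fetal = TRUE),
    un("pc_liv_f", 1e-3, 20, fetal = TRUE),
    un("pc_brain_f", 1e-3, 20, fetal = TRUE),
    un("pc_rb_f", 1e-3, 900, fetal = TRUE),
    un("ps_brain_f", 1e-5, 1, fetal = TRUE))
  pri <- if (isomer == "cis") rbind(
    tn("pc.liver", 0.89, 0.445, 1e-3, 20),
    tn("pc.fat", 225, 112.5, 5, 900),
    tn("pc.mammary", 225, 112.5, 5, 900),
    tn("pc.brain", 1.60, 0.80, 1e-3, 20),
    tn("pc.kidney", 1.10, 0.55, 1e-3, 20),
    un("pc.placenta", 1e-3, 20, fetal = TRUE),
    tn("pc.slowly_perfused", 19, 9.50, 1e-3, 20),
    tn("ps.brain", 1.0e-3, 0.5e-3, 1e-5, 1),
    un("ps.kidney", 1e-5, 1),
    tn("ps.fat", 4.8e-2, 2.4e-2, 1e-5, 1),
    un("ps.mammary", 1e-5, 1),
    tn("ps.slowly_perfused", 0.31, 0.055, 1e-5, 1),
    tn("k_si", 0.35, 0.175, 0, 2),
    tn("k_fec", 0.39, 0.195, 0, 2),
    tn("cl_liv", 6.20, 3.10, 1, 15),
    shared,
    fx("pc.muscle", 1.2), fx("pc.rapidly_perfused", 1.1),
    fx("ps.muscle", 0.32), fx("k_ai", 0.52),
    fx("cl_gi", 0.04), fx("cl_blood", 0.07)
  ) else rbind(
    un("pc.liver", 1e-3, 20),
    tn("pc.fat", 76, 38, 5, 900),
    tn("pc.mammary", 76, 38, 5, 900),
    tn("pc.brain", 0.57, 0.285, 1e-3, 20),
    un("pc.placenta", 1e-3, 20, fetal = TRUE),
    tn("pc.slowly_perfused", 8.4, 4.20, 1e-3, 20),
    tn("ps.brain", 1.2e-3, 0.6e-3, 1e-5, 1),
    un("ps.kidney", 1e-5, 1),
    tn("ps.fat", 0.11, 0.055, 1e-5, 1),
    un("ps.mammary", 1e-5, 1),
    tn("ps.slowly_perfused", 0.065, 0.032, 1e-5, 1),
    tn("k_si", 0.20, 0.10, 0, 2),
    tn("k_fec", 0.85, 0.42, 0, 2),
    tn("cl_liv", 24.30, 12.15, 1, 50),
    shared,
    fx("pc.muscle", 0.82), fx("pc.rapidly_perfused", 0.21),
    fx("pc.kidney", 0.21),
    fx("ps.muscle", 0.48), fx("k_ai", 1.30),
    fx("cl_gi", 0.3), fx("cl_blood", 0.29)
  )
  rownames(pri) <- NULL
  attr(pri, "isomer") <- isomer
  class(pri) <- c("prior_spec", "data.frame")
  pri
}

#' Set one chemical parameter by flat name
#'
#' Flat names address scalar parameters directly (`"cl_liv"`) and
#' entries of the PC/PS vectors with a dot (`"pc.fat"`, `"ps.brain"`).
#' Setting the kidney PC also updates the tied GI PC.
#'
#' @param chem a [chemical_params()] object.
#' @param name flat parameter name.
#' @param value new positive value.
#' @return updated `chemical_params` object.
#' @export
set_chemical_param <- function(chem, name, value) {
  stopifnot(inherits(chem, "chemical_params"))
  if (!is.finite(value) || value < 0 ||
      (value == 0 && grepl("^pc", name)))
    stop("invalid value for ", name,
         ": must be finite, non-negative (positive for partition ",
         "coefficients)")
  if (grepl("^p[cs]\\.", name)) {
    slot <- substr(name, 1, 2)
    tis <- sub("^p[cs]\\.", "", name)
    if (!tis %in% names(chem[[slot]]))
      stop("unknown tissue '", tis, "' for ", slot)
    chem[[slot]][[tis]] <- value
    if (slot == "pc" && tis == "kidney") chem$pc[["gi"]] <- value
  } else {
    if (!name %in% names(chem) || !is.numeric(chem[[name]]) ||
        length(chem[[name]]) != 1L)
      stop("unknown chemical parameter: ", name)
    chem[[name]] <- value
  }
  chem
}

#' Get one chemical parameter by flat name
#' @inheritParams set_chemical_param
#' @return numeric scalar.
#' @export
get_chemical_param <- function(chem, name) {
  if (grepl("^p[cs]\\.", name)) {
    slot <- substr(name, 1, 2)
    tis <- sub("^p[cs]\\.", "", name)
    if (!tis %in% names(chem[[slot]]))
      stop("unknown tissue '", tis, "' for ", slot)
    chem[[slot]][[tis]]
  } else {
    if (!name %in% names(chem)) stop("unknown chemical parameter: ", name)
    chem[[name]]
  }
}
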