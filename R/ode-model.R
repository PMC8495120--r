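#' State vector layout of the PBPK model
#'
#' Amounts are in mg.  The order is fixed and shared between the R and
#' compiled implementations of the derivatives; cumulative metabolism and
#' excretion sinks close the mass balance.
#'
#' @return character vector of the 28 state slot names.
#' @export
pbpk_state_names <- function() {
  c("A_St", "A_Int", "A_GI", "A_Liv", "A_Rp", "A_Pla",
    "A_BrB", "A_Br", "A_MuB", "A_Mu", "A_KiB", "A_Ki",
    "A_FaB", "A_Fa", "A_MaB", "A_Ma", "A_SpB", "A_Sp",
    "A_Blood", "A_Blood_F", "A_Liv_F", "A_BrB_F", "A_Br_F", "A_RB_F",
    "A_met_liv", "A_met_blood", "A_met_gi", "A_fec")
}

pbpk_zero_state <- function() {
  stats::setNames(numeric(28L), pbpk_state_names())
}

# diffusion-limited maternal tissues: (blood slot, tissue slot, flow name,
# ps name, pc name) in state order
.diff_tissues <- data.frame(
  tissue = c("brain", "muscle", "kidney", "fat", "mammary",
             "slowly_perfused"),
  blood_slot = c("A_BrB", "A_MuB", "A_KiB", "A_FaB", "A_MaB", "A_SpB"),
  cell_slot = c("A_Br", "A_Mu", "A_Ki", "A_Fa", "A_Ma", "A_Sp"),
  stringsAsFactors = FALSE)

#' Mass-balance derivatives of the PBPK model (reference implementation)
#'
#' Pure-R implementation of the maternal + fetal right-hand side,
#' mirroring the compiled version used by the solver.  It exists as a
#' readable reference and as an independent check of the compiled code;
#' production simulation always goes through the compiled model.
#'
#' @param t_h time in hours since GD0.
#' @param state named numeric state vector ([pbpk_state_names()] order).
#' @param chem [chemical_params()] object.
#' @param phys [gestational_physiology()] object.
#' @param freeze_gd if non-negative, evaluate the physiology at this
#'   fixed gestational day (static-physiology configuration).
#' @return named vector of rates (mg/h), same layout as `state`.
#' @export
pbpk_derivatives <- function(t_h, state, chem, phys = gestational_physiology(),
                             freeze_gd = -1) {
  if (anyNA(state)) stop("integration error: NA in state")
  gd <- if (freeze_gd >= 0) freeze_gd else max(min(t_h / 24, 20), 0)
  bw <- maternal_body_weight(gd, phys)
  vol <- volumes_at(gd, phys, split_blood = TRUE)
  flo <- flows_at(gd, phys)
  floor_v <- function(v) pmax(v, phys$volume_floor)
  d <- pbpk_zero_state()

  c_art <- state[["A_Blood"]] / floor_v(vol[["blood"]])

  d["A_St"] <- -chem$k_si * state[["A_St"]]
  d["A_Int"] <- chem$k_si * state[["A_St"]] -
    (chem$k_ai + chem$k_fec) * state[["A_Int"]]
  d["A_fec"] <- chem$k_fec * state[["A_Int"]]

  cv_gi <- state[["A_GI"]] / floor_v(vol[["gi"]]) / chem$pc[["gi"]]
  met_gi <- chem$cl_gi * bw * cv_gi
  d["A_GI"] <- flo[["gi"]] * (c_art - cv_gi) + chem$k_ai * state[["A_Int"]] -
    met_gi
  d["A_met_gi"] <- met_gi

  cv_liv <- state[["A_Liv"]] / floor_v(vol[["liver"]]) / chem$pc[["liver"]]
  met_liv <- chem$cl_liv * bw * cv_liv
  d["A_Liv"] <- flo[["liver_arterial"]] * c_art + flo[["gi"]] * cv_gi -
    flo[["liver_venous"]] * cv_liv - met_liv
  d["A_met_liv"] <- met_liv

  cv_rp <- state[["A_Rp"]] / floor_v(vol[["rapidly_perfused"]]) /
    chem$pc[["rapidly_perfused"]]
  d["A_Rp"] <- flo[["rapidly_perfused"]] * (c_art - cv_rp)

  venous <- flo[["liver_venous"]] * cv_liv +
    flo[["rapidly_perfused"]] * cv_rp

  for (i in seq_len(nrow(.diff_tissues))) {
    tis <- .diff_tissues$tissue[i]
    bs <- .diff_tissues$blood_slot[i]
    cs <- .diff_tissues$cell_slot[i]
    ctb <- state[[bs]] / floor_v(vol[[paste0(tis, "_blood")]])
    ct <- state[[cs]] / floor_v(vol[[paste0(tis, "_cell")]])
    ex <- chem$ps[[tis]] * flo[[tis]] * (ctb - ct / chem$pc[[tis]])
    d[bs] <- flo[[tis]] * (c_art - ctb) - ex
    d[cs] <- ex
    venous <- venous + flo[[tis]] * ctb
  }

  conceptus <- gd > phys$conceptus_onset_gd &&
    vol[["placenta"]] > phys$volume_floor
  cv_pla <- 0
  if (conceptus) {
    fet <- fetal_physiology_at(gd, phys)
    kbase <- switch(phys$ktrans_basis,
                    maternal = bw,
                    litter = fet$litter$bw,
                    fetus = fet$per_fetus[["bw"]])
    ktrans1 <- chem$sc_ktrans1 * kbase^0.75
    ktrans2 <- chem$sc_ktrans2 * kbase^0.75
    cv_pla <- state[["A_Pla"]] / floor_v(vol[["placenta"]]) /
      chem$pc[["placenta"]]
    vF <- floor_v(fet$litter$volumes)
    qF <- fet$litter$flows
    c_art_f <- state[["A_Blood_F"]] / vF[["blood"]]
    d["A_Pla"] <- flo[["placenta"]] * (c_art - cv_pla) -
      ktrans1 * cv_pla + ktrans2 * c_art_f

    cv_liv_f <- state[["A_Liv_F"]] / vF[["liver"]] / chem$pc_liv_f
    d["A_Liv_F"] <- qF[["liver"]] * (c_art_f - cv_liv_f)

    fe <- phys$fetal
    vtb <- floor_v(fe$bv_brain * vF[["brain"]])
    vt <- floor_v((1 - fe$bv_brain) * vF[["brain"]])
    ctb <- state[["A_BrB_F"]] / vtb
    ct <- state[["A_Br_F"]] / vt
    ex <- chem$ps_brain_f * qF[["brain"]] * (ctb - ct / chem$pc_brain_f)
    d["A_BrB_F"] <- qF[["brain"]] * (c_art_f - ctb) - ex
    d["A_Br_F"] <- ex

    cv_rb_f <- state[["A_RB_F"]] / vF[["rest_of_body"]] / chem$pc_rb_f
    d["A_RB_F"] <- qF[["rest_of_body"]] * (c_art_f - cv_rb_f)

    d["A_Blood_F"] <- ktrans1 * cv_pla - ktrans2 * c_art_f +
      qF[["liver"]] * cv_liv_f + qF[["rest_of_body"]] * cv_rb_f +
      qF[["brain"]] * ctb - qF[["cardiac_output"]] * c_art_f
  }
  venous <- venous + flo[["placenta"]] * cv_pla

  met_blood <- chem$cl_blood * bw * c_art
  draws <- flo[["gi"]] + flo[["liver_arterial"]] + flo[["muscle"]] +
    flo[["brain"]] + flo[["kidney"]] + flo[["slowly_perfused"]] +
    flo[["mammary"]] + flo[["fat"]] +
    (if (conceptus) flo[["placenta"]] else 0) + flo[["rapidly_perfused"]]
  d["A_Blood"] <- venous - draws * c_art - met_blood
  d["A_met_blood"] <- met_blood
  d
}

#' Matrix concentrations from a state vector
#'
#' Converts compartment amounts into the concentrations a tissue sample
#' would measure, in mg/L (equivalently ug/ml or ug/g at unit density).
#' For diffusion-limited tissues the homogenate includes the residual
#' capillary blood, so the measured concentration is
#' (tissue + capillary amount) / (tissue + capillary volume).  Fetal
#' matrices are litter totals.  `feces` returns the cumulative excreted
#' amount in mg rather than a concentration.
#'
#' @param state named state vector (mg).
#' @param t_gd gestational day at which the state applies.
#' @param phys [gestational_physiology()] object.
#' @param matrices character vector of matrices to report; default all
#'   active ones.  See [pbpk_matrices()].
#' @return named numeric vector of concentrations.
#' @export
pbpk_concentrations <- function(state, t_gd, phys = gestational_physiology(),
                                matrices = NULL) {
  vol <- volumes_at(t_gd, phys, split_blood = TRUE)
  conceptus <- t_gd > phys$conceptus_onset_gd &&
    vol[["placenta"]] > phys$volume_floor
  active <- pbpk_matrices(maternal_only = !conceptus)
  if (is.null(matrices)) matrices <- active
  bad <- setdiff(matrices, pbpk_matrices())
  if (length(bad))
    stop("unknown matrix: ", paste(bad, collapse = ", "),
         "; valid matrices: ", paste(pbpk_matrices(), collapse = ", "))
  inactive <- setdiff(matrices, active)
  if (length(inactive))
    stop("inactive compartment before conceptus onset: ",
         paste(inactive, collapse = ", "))
  fet <- if (conceptus) fetal_physiology_at(t_gd, phys) else NULL
  one <- function(m) {
    switch(m,
      blood = state[["A_Blood"]] / vol[["blood"]],
      liver = state[["A_Liv"]] / vol[["liver"]],
      gi = state[["A_GI"]] / vol[["gi"]],
      rapidly_perfused = state[["A_Rp"]] / vol[["rapidly_perfused"]],
      brain = (state[["A_Br"]] + state[["A_BrB"]]) / vol[["brain"]],
      muscle = (state[["A_Mu"]] + state[["A_MuB"]]) / vol[["muscle"]],
      kidney = (state[["A_Ki"]] + state[["A_KiB"]]) / vol[["kidney"]],
      fat = (state[["A_Fa"]] + state[["A_FaB"]]) / vol[["fat"]],
      mammary = (state[["A_Ma"]] + state[["A_MaB"]]) / vol[["mammary"]],
      slowly_perfused = (state[["A_Sp"]] + state[["A_SpB"]]) /
        vol[["slowly_perfused"]],
      placenta = state[["A_Pla"]] / vol[["placenta"]],
      fetal_blood = state[["A_Blood_F"]] / fet$litter$volumes[["blood"]],
      fetal_liver = state[["A_Liv_F"]] / fet$litter$volumes[["liver"]],
      fetal_brain = (state[["A_Br_F"]] + state[["A_BrB_F"]]) /
        fet$litter$volumes[["brain"]],
      feces = state[["A_fec"]])
  }
  stats::setNames(vapply(matrices, one, numeric(1)), matrices)
}

#' Matrices reportable by the model
#' @param maternal_only drop placenta and fetal matrices.
#' @return character vector of matrix names.
#' @export
pbpk_matrices <- function(maternal_only = FALSE) {
  m <- c("blood", "liver", "gi", "brain", "muscle", "kidney", "fat",
         "mammary", "slowly_perfused", "rapidly_perfused", "feces")
  if (!maternal_only)
    m <- c(m, "placenta", "fetal_blood", "fetal_liver", "fetal_brain")
  m
}

# low-level solver call on the compiled model; t_out_h must be sorted and
# include 0.  Dose events add mg to the stomach.
pbpk_ode <- function(chem, phys, t_out_h, dose_events = NULL,
                     freeze_gd = -1, rtol = 1e-8, atol = 1e-10) {
  y <- pbpk_zero_state()
  parms <- pack_parms(chem, phys, freeze_gd)
  events <- NULL
  times <- t_out_h
  if (!is.null(dose_events) && nrow(dose_events) > 0) {
    events <- list(data = data.frame(
      var = "A_St", time = dose_events$time_h, value = dose_events$dose_mg,
      method = "add"))
    times <- sort(unique(c(t_out_h, dose_events$time_h)))
  }
  out <- deSolve::lsoda(
    y = y, times = times, func = "pbpk_derivs", parms = parms,
    dllname = "permpbpk", initfunc = "pbpk_initmod",
    rtol = rtol, atol = atol, events = events, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure; last good time ", max(out[, "time"]), " h")
  out <- out[out[, "time"] %in% t_out_h, , drop = FALSE]
  colnames(out) <- c("time", pbpk_state_names())
  out
}

# exact evaluation of the compiled RHS at one point (test helper); a tiny
# solver call first pushes the parameter vector into the DLL
pbpk_derivatives_compiled <- function(t_h, state, chem,
                                      phys = gestational_physiology(),
                                      freeze_gd = -1) {
  pv <- pack_parms(chem, phys, freeze_gd)
  invisible(deSolve::lsoda(state, c(0, 1e-6), func = "pbpk_derivs",
                           parms = pv, dllname = "permpbpk",
                           initfunc = "pbpk_initmod"))
  out <- .C("pbpk_derivs", as.integer(length(state)), as.double(t_h),
            as.double(state), ydot = double(length(state)), double(1),
            integer(1), PACKAGE = "permpbpk")
  stats::setNames(out$ydot, names(state))
}
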