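#' Gestational physiology of the pregnant rat
#'
#' Builds the full physiological parameter set of the pregnancy PBPK model:
#' maternal body weight, cardiac output, tissue volumes and blood flows as
#' functions of gestational time (GD0--GD20), plus the fetal compartment
#' physiology.  Defaults describe a Sprague-Dawley dam of 0.277 kg at GD0
#' growing to 0.422 kg at GD20 with a mean litter of 13.5 fetuses.
#'
#' Constant-volume tissues are fixed fractions of the *initial* body
#' weight and constant flows are fixed fractions of the *initial* cardiac
#' output; only fat, mammary gland, placenta and the fetal compartments
#' change during gestation.  Fat and mammary gland interpolate linearly
#' between their GD0 and GD20 endpoints.  The placenta and all fetal
#' tissues follow a normalised logistic growth curve that is exactly zero
#' at conceptus onset (default GD6) and reaches its endpoint at GD20 with
#' midpoint GD15, reflecting the near-exponential growth of the conceptus
#' over the last week of gestation.
#'
#' @param bw0,bw15,bw20 maternal body weight (kg) at GD0, GD15 and GD20.
#' @param qci0,qci20 cardiac output index (L/h/kg) at GD0 and GD20.
#' @param n_fetuses litter size; non-integer means are allowed since the
#'   litter is modelled as one lumped fetal unit.
#' @param conceptus_onset_gd gestational day at which the placenta and
#'   fetal compartments activate; volumes and flows are zero before it.
#' @param logistic_rate shape rate (1/day) of the conceptus growth curve.
#' @param volume_floor guard volume (L) used in concentration divisions.
#' @param ktrans_basis body weight entering the allometric scaling of the
#'   placental transfer constants (`Ktrans_i = scKtrans_i * BW^0.75`):
#'   maternal weight (default), total litter weight, or per-fetus weight.
#' @return An object of class `gestational_physiology`: a list of scalar
#'   parameters understood by [volumes_at()], [flows_at()],
#'   [fetal_physiology_at()] and the ODE solver.
#' @examples
#' phys <- gestational_physiology()
#' maternal_body_weight(15, phys)      # 0.356 kg
#' volumes_at(20, phys)[["placenta"]]  # 0.167 L
#' @export
gestational_physiology <- function(bw0 = 0.277, bw15 = 0.356, bw20 = 0.422,
                                   qci0 = 24.56, qci20 = 21.6,
                                   n_fetuses = 13.5,
                                   conceptus_onset_gd = 6,
                                   logistic_rate = 0.5,
                                   volume_floor = 1e-9,
                                   ktrans_basis = c("maternal", "litter",
                                                    "fetus")) {
  ktrans_basis <- match.arg(ktrans_basis)
  stopifnot(bw0 > 0, bw20 > bw0, qci0 > 0, qci20 > 0, n_fetuses > 0,
            conceptus_onset_gd >= 0, conceptus_onset_gd < 20)
  phys <- list(
    bw0 = bw0, bw15 = bw15, bw20 = bw20,
    qci0 = qci0, qci20 = qci20,
    # tissue volumes, fraction of initial BW
    frac_volumes = c(blood = 0.06, gi = 0.027, liver = 0.0351,
                     muscle = 0.404, brain = 0.0073, kidney = 0.0076,
                     non_perfused = 0.05, rapidly_perfused = 0.046),
    # gestation-varying volumes (L), GD0 -> GD20 endpoints
    var_volumes = list(mammary = c(0.0024, 0.013),
                       fat = c(0.017, 0.024),
                       placenta = c(0, 0.167)),
    # blood flows, fraction of initial cardiac output
    frac_flows = c(liver_total = 0.174, portal = 0.151,
                   hepatic_arterial = 0.024, muscle = 0.278,
                   brain = 0.02, kidney = 0.141, slowly_perfused = 0.063),
    # gestation-varying flows (L/h), GD0 -> GD20 endpoints
    var_flows = list(mammary = c(0.012, 0.064),
                     fat = c(0.21, 0.29),
                     placenta = c(0, 1.42)),
    # capillary blood fraction of diffusion-limited tissues
    bv_fractions = c(brain = 0.03, muscle = 0.04, kidney = 0.16,
                     fat = 0.02, mammary = 0.02, slowly_perfused = 0.04),
    # v_brain20/v_liver20 are litter totals at the reference litter size
    # (a per-fetus reading would exceed the per-fetus body weight)
    fetal = list(bw20 = 0.0068, qci = 22.8, frac_blood = 0.0676,
                 v_brain20 = 0.0034, v_liver20 = 0.0044,
                 ref_litter = 13.5,
                 fq_brain = 0.1055, fq_liver = 0.061,
                 bv_brain = 0.03, bv_rest = 0.05),
    n_fetuses = n_fetuses,
    conceptus_onset_gd = conceptus_onset_gd,
    logistic_rate = logistic_rate,
    volume_floor = volume_floor,
    ktrans_basis = ktrans_basis
  )
  class(phys) <- "gestational_physiology"
  phys
}

#' @export
print.gestational_physiology <- function(x, ...) {
  cat("Gestational physiology (pregnant rat, GD0-GD20)\n")
  cat(sprintf("  body weight: %.3f -> %.3f kg; cardiac output index: %.2f -> %.2f L/h/kg\n",
              x$bw0, x$bw20, x$qci0, x$qci20))
  cat(sprintf("  litter size: %.1f fetuses; conceptus onset: GD%g\n",
              x$n_fetuses, x$conceptus_onset_gd))
  invisible(x)
}

check_gd <- function(t_gd) {
  if (!is.numeric(t_gd) || anyNA(t_gd) || any(t_gd < 0) || any(t_gd > 20))
    stop("gestational time must lie in [0, 20] days", call. = FALSE)
  unname(t_gd)
}

lin20 <- function(t_gd, v0, v20) v0 + (v20 - v0) * t_gd / 20

# normalised logistic growth: 0 at onset, endpoint at GD20, midpoint GD15
logi20 <- function(t_gd, vend, onset, rate) {
  s <- function(g) 1 / (1 + exp(-rate * (g - 15)))
  out <- vend * (s(t_gd) - s(onset)) / (s(20) - s(onset))
  out[t_gd <= onset] <- 0
  out
}

#' Maternal body weight during gestation
#'
#' Piecewise-linear growth through the measured study means at GD0, GD15
#' and GD20.
#'
#' @param t_gd gestational time in days, in `[0, 20]` (vectorised).
#' @param phys a [gestational_physiology()] object.
#' @return body weight in kg.
#' @export
maternal_body_weight <- function(t_gd, phys = gestational_physiology()) {
  t_gd <- check_gd(t_gd)
  ifelse(t_gd <= 15,
         phys$bw0 + (phys$bw15 - phys$bw0) * t_gd / 15,
         phys$bw15 + (phys$bw20 - phys$bw15) * (t_gd - 15) / 5)
}

#' Maternal tissue volumes at a gestational time
#'
#' Constant-fraction tissues are fractions of the initial body weight
#' (tissue density taken as 1 kg/L); the slowly perfused volume is the
#' balance left after all named organs and the non-perfused fraction.
#' Fat, mammary gland and placenta follow their gestational growth laws.
#'
#' @inheritParams maternal_body_weight
#' @param split_blood if `TRUE`, also return the capillary-blood and
#'   cellular sub-volumes of the diffusion-limited tissues (suffixes
#'   `_blood` and `_cell`).
#' @return named numeric vector of volumes (L).
#' @export
volumes_at <- function(t_gd, phys = gestational_physiology(),
                       split_blood = FALSE) {
  t_gd <- check_gd(t_gd)
  stopifnot(length(t_gd) == 1L)
  fv <- phys$frac_volumes
  fv_sp <- 1 - sum(fv[c("blood", "gi", "liver", "muscle", "brain",
                        "kidney", "rapidly_perfused")]) - fv[["non_perfused"]]
  v <- c(
    blood = fv[["blood"]] * phys$bw0,
    gi = fv[["gi"]] * phys$bw0,
    liver = fv[["liver"]] * phys$bw0,
    muscle = fv[["muscle"]] * phys$bw0,
    brain = fv[["brain"]] * phys$bw0,
    kidney = fv[["kidney"]] * phys$bw0,
    rapidly_perfused = fv[["rapidly_perfused"]] * phys$bw0,
    slowly_perfused = fv_sp * phys$bw0,
    mammary = lin20(t_gd, phys$var_volumes$mammary[1],
                    phys$var_volumes$mammary[2]),
    fat = lin20(t_gd, phys$var_volumes$fat[1], phys$var_volumes$fat[2]),
    placenta = logi20(t_gd, phys$var_volumes$placenta[2],
                      phys$conceptus_onset_gd, phys$logistic_rate)
  )
  if (any(v < 0)) stop("internal error: negative interpolated volume")
  if (split_blood) {
    bv <- phys$bv_fractions
    for (tis in names(bv)) {
      v[paste0(tis, "_blood")] <- bv[[tis]] * v[[tis]]
      v[paste0(tis, "_cell")] <- (1 - bv[[tis]]) * v[[tis]]
    }
  }
  v
}

#' Maternal blood flows at a gestational time
#'
#' Constant flows are fractions of the initial cardiac output; mammary,
#' fat and placental flows follow their gestational laws; the rapidly
#' perfused flow is the balance between total cardiac output and all
#' other tissue flows.
#'
#' @inheritParams maternal_body_weight
#' @return named numeric vector of flows (L/h) including
#'   `cardiac_output`; `liver_venous` is the total liver outflow.
#' @export
flows_at <- function(t_gd, phys = gestational_physiology()) {
  t_gd <- check_gd(t_gd)
  stopifnot(length(t_gd) == 1L)
  qc0 <- phys$qci0 * phys$bw0
  qc <- lin20(t_gd, phys$qci0, phys$qci20) * maternal_body_weight(t_gd, phys)
  ff <- phys$frac_flows
  q <- c(
    cardiac_output = qc,
    gi = ff[["portal"]] * qc0,
    liver_arterial = ff[["hepatic_arterial"]] * qc0,
    liver_venous = ff[["liver_total"]] * qc0,
    muscle = ff[["muscle"]] * qc0,
    brain = ff[["brain"]] * qc0,
    kidney = ff[["kidney"]] * qc0,
    slowly_perfused = ff[["slowly_perfused"]] * qc0,
    mammary = lin20(t_gd, phys$var_flows$mammary[1], phys$var_flows$mammary[2]),
    fat = lin20(t_gd, phys$var_flows$fat[1], phys$var_flows$fat[2]),
    placenta = logi20(t_gd, phys$var_flows$placenta[2],
                      phys$conceptus_onset_gd, phys$logistic_rate)
  )
  q["rapidly_perfused"] <- qc - sum(q[c("gi", "liver_arterial", "muscle",
                                        "brain", "kidney", "slowly_perfused",
                                        "mammary", "fat", "placenta")])
  if (q[["rapidly_perfused"]] < 0)
    stop("physiology configuration error: negative rapidly perfused flow")
  q
}

#' Fetal physiology at a gestational time
#'
#' Per-fetus body weight grows along the conceptus logistic law to its
#' GD20 endpoint; the brain and liver endpoints are litter totals at the
#' reference litter of 13.5 (divided down to per-fetus values so that
#' litter totals still scale linearly with litter size).  The fetal rest-of-body volume is the body
#' weight minus blood, brain and liver, and the rest-of-body flow is the
#' fetal cardiac output minus the brain and liver flows.
#'
#' @inheritParams maternal_body_weight
#' @param n_fetuses litter size; defaults to the value stored in `phys`.
#' @return list with `per_fetus` (bw and tissue volumes of one fetus) and
#'   `litter` (total volumes in L and flows in L/h for the lumped litter).
#' @export
fetal_physiology_at <- function(t_gd, phys = gestational_physiology(),
                                n_fetuses = phys$n_fetuses) {
  t_gd <- check_gd(t_gd)
  stopifnot(length(t_gd) == 1L, n_fetuses > 0)
  fe <- phys$fetal
  on <- phys$conceptus_onset_gd
  r <- phys$logistic_rate
  bw1 <- logi20(t_gd, fe$bw20, on, r)
  v_brain1 <- logi20(t_gd, fe$v_brain20 / fe$ref_litter, on, r)
  v_liver1 <- logi20(t_gd, fe$v_liver20 / fe$ref_litter, on, r)
  v_blood1 <- fe$frac_blood * bw1
  per <- c(bw = bw1, blood = v_blood1, brain = v_brain1, liver = v_liver1,
           rest_of_body = max(bw1 - v_blood1 - v_brain1 - v_liver1, 0))
  bwF <- n_fetuses * bw1
  qcF <- fe$qci * bwF
  litter <- list(
    bw = bwF,
    volumes = c(blood = n_fetuses * v_blood1,
                brain = n_fetuses * v_brain1,
                liver = n_fetuses * v_liver1,
                rest_of_body = n_fetuses * per[["rest_of_body"]]),
    flows = c(cardiac_output = qcF,
              brain = fe$fq_brain * qcF,
              liver = fe$fq_liver * qcF,
              rest_of_body = qcF * (1 - fe$fq_brain - fe$fq_liver))
  )
  list(per_fetus = per, litter = litter)
}

# flat parameter vector for the compiled ODE right-hand side; order must
# match src/pbpk_model.c
pack_parms <- function(chem, phys, freeze_gd = -1) {
  fv <- phys$frac_volumes
  ff <- phys$frac_flows
  bv <- phys$bv_fractions
  fe <- phys$fetal
  c(chem$pc[["liver"]], chem$pc[["gi"]], chem$pc[["fat"]],
    chem$pc[["mammary"]], chem$pc[["muscle"]], chem$pc[["brain"]],
    chem$pc[["kidney"]], chem$pc[["placenta"]], chem$pc[["slowly_perfused"]],
    chem$pc[["rapidly_perfused"]],
    chem$ps[["brain"]], chem$ps[["kidney"]], chem$ps[["fat"]],
    chem$ps[["mammary"]], chem$ps[["muscle"]], chem$ps[["slowly_perfused"]],
    chem$k_si, chem$k_ai, chem$k_fec,
    chem$cl_gi, chem$cl_blood, chem$cl_liv,
    chem$sc_ktrans1, chem$sc_ktrans2,
    chem$pc_liv_f, chem$pc_brain_f, chem$pc_rb_f, chem$ps_brain_f,
    phys$bw0, phys$bw15, phys$bw20, phys$qci0, phys$qci20,
    fv[["blood"]], fv[["gi"]], fv[["liver"]], fv[["muscle"]],
    fv[["brain"]], fv[["kidney"]], fv[["non_perfused"]],
    fv[["rapidly_perfused"]],
    phys$var_volumes$mammary[1], phys$var_volumes$mammary[2],
    phys$var_volumes$fat[1], phys$var_volumes$fat[2],
    phys$var_volumes$placenta[2],
    ff[["liver_total"]], ff[["portal"]], ff[["hepatic_arterial"]],
    ff[["muscle"]], ff[["brain"]], ff[["kidney"]], ff[["slowly_perfused"]],
    phys$var_flows$mammary[1], phys$var_flows$mammary[2],
    phys$var_flows$fat[1], phys$var_flows$fat[2],
    phys$var_flows$placenta[2],
    bv[["brain"]], bv[["muscle"]], bv[["kidney"]], bv[["fat"]],
    bv[["mammary"]], bv[["slowly_perfused"]],
    fe$bw20, fe$qci, fe$frac_blood,
    fe$v_brain20 / fe$ref_litter, fe$v_liver20 / fe$ref_litter,
    fe$fq_brain, fe$fq_liver, fe$bv_brain, fe$bv_rest,
    phys$n_fetuses, phys$conceptus_onset_gd, phys$logistic_rate,
    phys$volume_floor, freeze_gd,
    match(phys$ktrans_basis, c("maternal", "litter", "fetus")) - 1)
}
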