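#' Default run configuration
#'
#' One flat list gathering everything a simulation, generation or
#' calibration run needs: the gestational physiology, both isomers'
#' chemical parameters, the dosing schedule and study design, solver
#' tolerances and seeds.  Defaults reproduce the published parameter
#' tables verbatim (late-gestation posterior means for the chemistry).
#'
#' @param stage which posterior-mean set seeds the chemical sections.
#' @return list of class `pbpk_config` with elements `physiology`,
#'   `chemical` (per isomer), `schedule`, `design`, `solver`
#'   (`rtol`, `atol`), `sigma_log` and `seed`.
#' @export
pbpk_config <- function(stage = c("gd15_20", "gd1")) {
  stage <- match.arg(stage)
  structure(list(
    physiology = gestational_physiology(),
    chemical = list(cis = chemical_params("cis", stage),
                    trans = chemical_params("trans", stage)),
    schedule = list(dose_per_kg = c(cis = 20, trans = 30),
                    times_gd = 1:20, scale_to_current_bw = TRUE),
    design = study_design(),
    solver = list(rtol = 1e-8, atol = 1e-10),
    sigma_log = 0.15,
    seed = 1L), class = "pbpk_config")
}

#' Read a run configuration from a YAML file
#'
#' The file may override any subset of the default configuration;
#' unknown keys are rejected with the offending name.  Physiology
#' scalars are passed to [gestational_physiology()], chemical overrides
#' use the flat names of [set_chemical_param()] (e.g. `cl_liv`,
#' `pc.fat`).
#'
#' @param path YAML file.
#' @param stage base parameter set to override.
#' @return validated `pbpk_config` list.
#' @export
read_pbpk_config <- function(path, stage = c("gd15_20", "gd1")) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  cfg <- pbpk_config(match.arg(stage))
  known <- c("physiology", "chemical", "schedule", "design", "solver",
             "sigma_log", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config section: ", paste(bad, collapse = ", "),
         " (expected: ", paste(known, collapse = ", "), ")")
  if (!is.null(raw$physiology)) {
    ok <- names(formals(gestational_physiology))
    bad <- setdiff(names(raw$physiology), ok)
    if (length(bad))
      stop("unknown physiology key: ", paste(bad, collapse = ", "))
    cfg$physiology <- do.call(gestational_physiology, raw$physiology)
  }
  for (iso in names(raw$chemical)) {
    if (!iso %in% c("cis", "trans"))
      stop("unknown isomer section: ", iso)
    for (key in names(raw$chemical[[iso]]))
      cfg$chemical[[iso]] <- set_chemical_param(
        cfg$chemical[[iso]], key, raw$chemical[[iso]][[key]])
  }
  for (key in names(raw$schedule)) {
    if (!key %in% names(cfg$schedule))
      stop("unknown schedule key: ", key)
    cfg$schedule[[key]] <- raw$schedule[[key]]
  }
  if (!is.null(raw$design)) {
    ok <- names(formals(study_design))
    bad <- setdiff(names(raw$design), ok)
    if (length(bad))
      stop("unknown design key: ", paste(bad, collapse = ", "))
    cfg$design <- do.call(study_design, raw$design)
  }
  for (key in names(raw$solver)) {
    if (!key %in% c("rtol", "atol")) stop("unknown solver key: ", key)
    cfg$solver[[key]] <- raw$solver[[key]]
  }
  if (!is.null(raw$sigma_log)) {
    if (raw$sigma_log < 0) stop("sigma_log must be >= 0 (unitless)")
    cfg$sigma_log <- raw$sigma_log
  }
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  cfg
}

#' Reference 24-h AUC tables of the calibration study
#'
#' The published observed and model-estimated 24-h AUC values
#' (ug h/ml for blood, ug h/g for tissues) for cis-permethrin in
#' pregnant dams (GD1, GD15, GD20), trans-permethrin in dams, and
#' cis-permethrin in fetal matrices at GD20, as shipped in
#' `inst/extdata/`.  These are the worked-example inputs for the ratio
#' machinery; `NA` marks entries that could not be computed from the
#' measured data.
#'
#' @return list of data frames `cis_dam`, `trans_dam`, `cis_fetal`.
#' @export
reference_auc_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "permpbpk", mustWork = TRUE))
  list(cis_dam = rd("auc_cis_dam.csv"),
       trans_dam = rd("auc_trans_dam.csv"),
       cis_fetal = rd("auc_cis_fetal.csv"))
}
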