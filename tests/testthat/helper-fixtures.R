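# shared fixtures; heavier objects are memoised so each is built once
# per test run

default_phys <- gestational_physiology()

cis_gd1 <- chemical_params("cis", "gd1")
cis_late <- chemical_params("cis", "gd15_20")

# random non-negative state with mass in every slot
random_state <- function(seed = 1, scale = 0.2) {
  set.seed(seed)
  stats::setNames(abs(stats::rnorm(28, scale, scale)), pbpk_state_names())
}

# single 20 mg/kg cis dose at GD1, 24 h of kinetics
local_gd1_sim <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- pbpk_simulate(cis_gd1, default_phys,
                             dose_schedule(20, times_gd = 1),
                             t_end_gd = 2, output_dt_h = 0.05)
    memo
  }
})

# small synthetic GD1 study used by several calibration tests
local_gd1_study <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- generate_tk_study(list(cis = cis_gd1), default_phys,
                                 study_design(gestational_days = 1),
                                 sigma_log = 0.15, seed = 7)
    memo
  }
})

# cumulative administered dose at each output time (events applied at
# their instant)
cumsum_doses <- function(sim) {
  vapply(sim$time_h, function(t)
    sum(sim$dose_log$dose_mg[sim$dose_log$time_h <= t]), numeric(1))
}
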