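# Shared fixtures, lazily computed once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixtures)) assign(name, force(expr), .fixtures)
  get(name, .fixtures)
}

# a parameter row pinned at the central values of every sampling distribution
mean_params <- function() {
  data.frame(
    mu_B = 1 / 69.3, mu_OV = 0.0062, theta = 31.46 / (31.46 + 1239.87),
    xi = 0.0728, xi_oat = 0.0728, rho = log(5), m_inv = 1.83,
    RR_I = 5.03, RR_OAT = 0.56, RR_OATout = 2.43, RR_OATin = 2.10,
    RR_OATov = 0.21,
    target_prev_nonIDU = 0.090, target_prev_PWID = 0.0114,
    target_prop_unassisted = 0.17, target_oat_coverage = 0.21
  )
}

fixture_cal <- function() {
  memo("cal_mean", calibrate_parameter_set(mean_params()))
}

# small Monte Carlo batch shared across dynamics / calibration tests
fixture_small_cals <- function() {
  memo("small_cals", {
    p <- sample_parameter_sets(20, seed = 404)
    calibrate_sets(p)
  })
}

# the acceptance-scale uncertainty run (1,000 sets), shared by the
# acceptance criteria; seed fixed up front
fixture_acceptance_run <- function() {
  memo("acc_run",
       uncertainty_analysis(n_sets = 1000, seed = 1,
                            coverages = c(0.4, 0.5, 0.6), years = 10))
}
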