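# Shared simulation designs. Each is a stated world: parameter values are
# fixed here once and are not tuned per test.

# Landmark-faithful world with a linearly drifting dynamic effect:
# beta(s) = log(1.5) + slope * s for a continuous marker, and one binary
# fixed covariate with theta = log(2). Visits on integer months, markers
# constant within month, so a window-1 landmark fit has estimand beta(s).
design_faithful_linear <- function(n, seed, slope = 0.03, b0 = log(1.5)) {
  cohort_config(
    n_patients = n, seed = seed,
    baseline_covariates = list(z = list(dist = "bernoulli", prob = 0.5)),
    markers = list(biomarker = list(kind = "continuous", init_mean = 0,
                                    init_sd = 1, drift = 0, noise_sd = 0.5)),
    effects = list(biomarker = c(b0, slope)),
    theta = c(z = log(2)),
    baseline_hazard_rate = 0.08,
    censoring_rate = 0.02, admin_censoring = 36,
    landmark_faithful = TRUE
  )
}

# Constant world: per-patient constant marker (no drift, no visit noise)
# and a time-constant effect, so the landmark supermodel with full
# residual follow-up is exactly correctly specified at every landmark.
design_constant_effect <- function(n, seed, b = log(1.5)) {
  cohort_config(
    n_patients = n, seed = seed,
    baseline_covariates = list(),
    markers = list(biomarker = list(kind = "continuous", init_mean = 0,
                                    init_sd = 1, drift = 0, noise_sd = 0)),
    effects = list(biomarker = c(b)),
    theta = stats::setNames(numeric(0), character(0)),
    baseline_hazard_rate = 0.08,
    censoring_rate = 0.02, admin_censoring = 36,
    landmark_faithful = TRUE
  )
}

fit_linear_design <- function(cohort, window = 1, landmarks = 0:12) {
  lmd <- build_landmark_dataset(cohort, landmarks = landmarks)
  fit_dpm(lmd, window = window)
}
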