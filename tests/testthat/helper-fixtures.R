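# shared fixtures: small, generated in code at test time

fixture_pk_params <- function() pk_params(CL = 3.25, V1 = 4, Q = 2, V2 = 60)

fixture_single_dose <- function() {
  dose_regimen(start = 1, duration = 1, dose = 40, weight = 2)
}

# two-arm Gaussian outcome table for regression-model tests
fixture_mrs <- function(n = 12, effect = -0.5, sd = 0.4, seed = 1) {
  set.seed(seed)
  arm <- rep(c("vehicle", "treated"), each = n)
  data.frame(animal_id = sprintf("A%02d", seq_len(2 * n)),
             arm = arm,
             sex = rep(c("male", "female"), n),
             voxel = "BGT",
             log10_lacnaa = stats::rnorm(2 * n,
                                         ifelse(arm == "treated", effect, 0),
                                         sd))
}

# observations from a known PK truth for fitting tests; the sampling design
# covers the terminal phase (to ~3 half-lives) so clearance is identifiable
fixture_pk_obs <- function(n_subjects = 12, cv = 0.2, omega_cl = 0.3,
                           seed = 1,
                           times = c(2, 4, 8, 12, 25, 30, 36, 49, 54, 60,
                                     72, 96)) {
  set.seed(seed)
  reg <- regimen_azithromycin(2)
  do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    subj <- pk_params(3.25 * exp(stats::rnorm(1, 0, omega_cl)), 4, 2, 60)
    cbind(subject_id = sprintf("S%02d", i),
          generate_pk_samples(subj, reg, times, cv))
  }))
}
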