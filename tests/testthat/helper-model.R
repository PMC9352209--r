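# Shared model settings for the test suite.

# equal rates, moderate conjugation: the workhorse setting for stochastic
# parameter-recovery checks (gamma_D = gamma_T = 1e-6, D0 = R0 = 1e2)
baseline_params <- function() rate_params(1, 1, 1, 1e-6, 1e-6)
baseline_inoculum <- function() inoculum(1e2, 1e2)

# large-inoculum deterministic setting (D0 = R0 = 1e5, gamma_D = 1e-14);
# gamma_T equal for the identicality case, 1e-8 for the unequal-rates case
det_params <- function(gamma_T = 1e-14) rate_params(1, 1, 1, 1e-14, gamma_T)
det_inoculum <- function() inoculum(1e5, 1e5)

# minimal hand-built ensemble for the incubation-time selection rules
fake_ensemble <- function(tstars, times, T_paths) {
  runs <- lapply(seq_along(tstars), function(i) {
    structure(list(sample_times = times,
                   D = rep(0, length(times)), R = rep(0, length(times)),
                   T = T_paths[[i]],
                   t_star = tstars[i], end_time = max(times),
                   final = c(0, 0, 0), stop_reason = "t_max",
                   seed = i, engine = "gillespie", t_jumps = NULL,
                   params = baseline_params(), init = baseline_inoculum(),
                   volume = 1),
              class = "stochastic_run")
  })
  structure(list(runs = runs,
                 config = list(sample_times = times, volume = 1),
                 master_seed = 0, seeds = seq_along(tstars)),
            class = "mating_ensemble")
}

# wrap raw numbers as valid estimate objects for summary/comparison tests
new_est_list <- function(values) {
  lapply(values, function(v) {
    structure(list(method = "LDM", value = v, valid = TRUE,
                   reason = NA_character_, inputs = NULL),
              class = "conj_estimate")
  })
}

# random valid estimator inputs for identity/property sweeps
random_inputs <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(params = rate_params(runif(1, 0.1, 1.5), runif(1, 0.1, 1.5),
                              runif(1, 0.1, 1.5),
                              10^runif(1, -9, -6), 10^runif(1, -9, -6)),
         init = inoculum(10^runif(1, 1, 3), 10^runif(1, 1, 3)),
         t = runif(1, 0.2, 2),
         p0 = runif(1, 0.05, 0.95),
         f = 10^runif(1, -1, 1))
  })
}
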