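# Shared fixtures, built in code.

# Stationary reference scenario: asymmetric perceptual biases, sizable
# decision bias, 15-deg sensory noise, zero lapses.
ref_truth <- function() bias_set(P_L = 20, P_R = -10, D = 10)

# Priors centered on the reference truth with SD 5 (perceptual) / 10
# (decision); noise and lapse priors at package defaults.
ref_priors <- function() {
  prior_spec(P_L_mean = 20, P_L_sd = 5, P_R_mean = -10, P_R_sd = 5,
             D_mean = 10, D_sd = 10)
}

ref_session <- function(seed = 1, n_blocks = 30, truth = ref_truth(), ...) {
  simulate_session(make_design(n_blocks = n_blocks, seed = seed),
                   truth, S = 15, seed = seed + 1000L, ...)
}

quick_config <- function(seed = 1, n_draws = 2000, burn_in = 1000, ...) {
  sampler_config(n_draws = n_draws, burn_in = burn_in, seed = seed, ...)
}

# Root-mean-square error of a vector of estimates against a scalar truth.
rmse <- function(est, truth) sqrt(mean((est - truth)^2))
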