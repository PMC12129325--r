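test_that("a near-degenerate prior dominates the posterior", {
  tr <- ref_session(seed = 2, n_blocks = 4)
  pri <- prior_spec(P_L_mean = 7, P_L_sd = 0.01,
                    P_R_mean = -10, D_mean = 10)
  fit <- fit_posterior(tr, pri, quick_config(seed = 3))
  expect_lt(abs(fit$means[["P_L"]] - 7), 0.1)
})

test_that("neutral-condition empirical bias equals the decision bias draw-wise", {
  tr <- ref_session(seed = 4, n_blocks = 2)
  fit <- fit_posterior(tr, ref_priors(), quick_config(seed = 5, n_draws = 1000,
                                                      burn_in = 500))
  expect_identical(fit$draws[, "B_N"], fit$draws[, "D"])
  expect_equal(fit$draws[, "B_L"], fit$draws[, "P_L"] + fit$draws[, "D"])
  expect_equal(fit$draws[, "B_R"], fit$draws[, "P_R"] + fit$draws[, "D"])
})

test_that("posterior summaries are internally consistent", {
  tr <- ref_session(seed = 6, n_blocks = 3)
  cfg <- quick_config(seed = 7, n_draws = 1500, burn_in = 500, n_chains = 2)
  fit <- fit_posterior(tr, ref_priors(), cfg)
  expect_equal(fit$n_kept, 2 * 1000)
  core <- c("P_L", "P_R", "D", "S_L", "S_N", "S_R")
  expect_true(all(fit$means[core] >= fit$ci95[1, core] &
                  fit$means[core] <= fit$ci95[2, core]))
  expect_true(all(fit$draws[, c("S_L", "S_N", "S_R")] > 0))
  lam <- fit$draws[, grep("lambda", colnames(fit$draws))]
  expect_true(all(lam >= 0 & lam < 1))
  # reproducible under a fixed seed
  fit2 <- fit_posterior(tr, ref_priors(), cfg)
  expect_identical(fit$draws, fit2$draws)
  # warns when the decision bias cannot be anchored
  expect_warning(fit_posterior(tr[tr$condition != "N", ], ref_priors(),
                               quick_config(n_draws = 200, burn_in = 100)),
                 "neutral")
})

test_that("MCMC marginals match the brute-force grid posterior", {
  # small instance, flat bias priors, noise and lapses fixed to truth:
  # the sampler must reproduce the exact lattice posterior
  tr <- ref_session(seed = 8, n_blocks = 2)[1:60, ]
  lattice <- seq(-80, 80, by = 1)
  oracle <- grid_posterior_biases(tr, lattice, S = 15, lapse = 0)
  fit <- fit_flat(tr, config = sampler_config(n_draws = 220000, burn_in = 20000,
                                              seed = 9),
                  fix = list(S = 15, lapse = 0))
  for (p in c("P_L", "P_R", "D")) {
    expect_lt(tv_to_oracle(fit$draws[, p], oracle[[p]], lattice), 0.05)
    om <- sum(lattice * oracle[[p]])
    expect_lt(abs(mean(fit$draws[, p]) - om), 1.5)
  }
})

test_that("grid oracle also validates informative-prior posteriors", {
  tr <- ref_session(seed = 10, n_blocks = 2)[1:60, ]
  lattice <- seq(-60, 70, by = 1)
  pri <- ref_priors()
  oracle <- grid_posterior_biases(tr, lattice, S = 15, lapse = 0, priors = pri)
  fit <- fit_posterior(tr, pri, sampler_config(n_draws = 120000,
                                               burn_in = 20000, seed = 11),
                       fix = list(S = 15, lapse = 0))
  for (p in c("P_L", "P_R", "D"))
    expect_lt(tv_to_oracle(fit$draws[, p], oracle[[p]], lattice), 0.05)
})

test_that("shrinkage interpolates between the prior and the flat posterior", {
  tr <- ref_session(seed = 12, n_blocks = 6)
  cfg <- quick_config(seed = 13)
  narrow <- fit_posterior(tr, prior_spec(P_L_mean = 5, P_L_sd = 0.05,
                                         P_R_mean = -10, D_mean = 10), cfg)
  expect_lt(abs(narrow$means[["P_L"]] - 5), 0.15)
  wide <- fit_posterior(tr, prior_spec(P_L_mean = 5, P_L_sd = 500,
                                       P_R_mean = -10, P_R_sd = 500,
                                       D_mean = 10, D_sd = 500), cfg)
  flat <- fit_flat(tr, config = cfg)
  for (p in c("P_L", "P_R", "D"))
    expect_lt(abs(wide$means[[p]] - flat$means[[p]]), 1.5)
})

test_that("flat-prior posterior means approach the ML estimate at large n", {
  tr <- ref_session(seed = 14, n_blocks = 30)
  fit <- fit_flat(tr, config = quick_config(seed = 15, n_draws = 4000,
                                            burn_in = 2000),
                  fix = list(lapse = 0))
  ml <- ml_biases_oracle(tr)
  for (p in c("P_L", "P_R", "D"))
    expect_lt(abs(fit$means[[p]] - ml[[p]]), 1)
})

test_that("empirical-bias priors convolve by summing means and variances", {
  expect_equal(convolve_bias_priors(0, 10, 0, 10)$sd, 14.1421, tolerance = 1e-4)
  expect_equal(convolve_bias_priors(0, 0, 0, 7)$sd, 7)
  expect_equal(convolve_bias_priors(20, 5, 10, 10)$mean, 30)
  # the garbled-width scenarios share one empirical prior width
  w1 <- convolve_bias_priors(0, 2 * sqrt(46), 0, 4)$sd
  w2 <- convolve_bias_priors(0, 10, 0, 10)$sd
  w3 <- convolve_bias_priors(0, 4, 0, 2 * sqrt(46))$sd
  expect_equal(w1, sqrt(200))
  expect_equal(w2, sqrt(200))
  expect_equal(w3, sqrt(200))
})

test_that("the baseline estimator recovers biases by neutral subtraction", {
  tr <- ref_session(seed = 16, n_blocks = 30)
  ep <- list(B_L = convolve_bias_priors(20, 5, 10, 10),
             B_N = list(mean = 10, sd = 10),
             B_R = convolve_bias_priors(-10, 5, 10, 10))
  fit <- fit_baseline_empirical(tr, ep, config = quick_config(seed = 17))
  expect_equal(fit$draws[, "P_L"], fit$draws[, "B_L"] - fit$draws[, "B_N"])
  # large n: baseline and full model agree on the perceptual biases
  full <- fit_posterior(tr, ref_priors(), quick_config(seed = 18))
  expect_lt(abs(fit$means[["P_L"]] - full$means[["P_L"]]), 2.5)
  expect_lt(abs(fit$means[["P_R"]] - full$means[["P_R"]]), 2.5)
})

test_that("posterior summaries serialize to JSON", {
  tr <- ref_session(seed = 19, n_blocks = 2)
  fit <- fit_posterior(tr, ref_priors(), quick_config(seed = 20, n_draws = 600,
                                                      burn_in = 300))
  path <- withr::local_tempfile(fileext = ".json")
  write_posterior_json(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$means$P_L, unname(fit$means[["P_L"]]), tolerance = 1e-9)
  expect_equal(back$n_trials_used, nrow(tr))
})

test_that("prior specifications round-trip through YAML", {
  pri <- prior_spec(P_L_mean = -11, P_L_sd = 7, P_R_mean = 10, P_R_sd = 7,
                    D_mean = 0, D_sd = 10)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_prior_spec(pri, path)
  expect_equal(read_prior_spec(path), pri)
  expect_error(prior_spec(P_L_sd = -1), "positive")
  expect_error(sampler_config(n_draws = 100, burn_in = 100), "burn_in")
})
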