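test_that("temporal-difference update evaluates exactly", {
  expect_equal(update_criterion(3, C = 1, r = 1, q = 1, alpha = 0.04), 3)
  expect_equal(update_criterion(0, C = 1, r = 0, q = 0.8, alpha = 0.04), 0.032)
  expect_equal(update_criterion(5, C = -1, r = 1, q = 0.6, alpha = 0.04), 5.016)
  expect_error(update_criterion(0, C = 2, r = 1, q = 0.6, alpha = 0.04), "-1 or \\+1")
  expect_error(update_criterion(0, C = 1, r = 1, q = 0.2, alpha = 0.04), "0.5")
})

test_that("confidence is the larger cumulative-Gaussian tail", {
  expect_equal(predicted_q(0, 0, 16), 0.5)
  expect_equal(predicted_q(16, 0, 16), phi_oracle(1), tolerance = 1e-6)
  expect_equal(round(predicted_q(16, 0, 16), 5), 0.84134)
  expect_equal(predicted_q(-1e6, 0, 16), 1)
  expect_equal(predicted_q(-16, 0, 16), predicted_q(16, 0, 16))
})

test_that("MAP choice compares the percept to the criterion", {
  expect_equal(choose_map(5, 0), 1)
  expect_equal(choose_map(-5, 0), -1)
  expect_equal(choose_map(5, 10), -1)
  expect_equal(choose_map(5, 5), 1)   # tie resolves rightward
})

test_that("percepts are Gaussian around the bias-shifted stimulus", {
  set.seed(20)
  x <- perceive(rep(20, 10000), P = 20, Sigma = 16)
  expect_lt(abs(mean(x)), 3 * 16 / 100)
  expect_lt(abs(sd(x) - 16), 0.5)
  expect_error(perceive(0, 0, -1), "positive")
})

test_that("single-trial criterion moves are bounded by the learning rate", {
  res <- run_rl_experiment("veridical", n_sessions = 2, n_reps = 1,
                           seed = 5, keep_psi = TRUE)
  psi <- attr(res, "psi_trace")[[1]]
  steps <- abs(diff(rbind(c(0, 0, 0), psi)))
  expect_lte(max(steps), 0.04 + 1e-12)
})

test_that("a zero learning rate leaves criteria at zero and biases at truth", {
  res <- run_rl_experiment("veridical", rl_agent_config(alpha = 0),
                           truth = bias_set(20, -10, 0), n_sessions = 2,
                           n_reps = 2, seed = 6)
  expect_true(all(res$psi_end == 0))
  m <- aggregate(B_hat ~ condition, res, mean)
  expect_equal(m$B_hat[m$condition == "L"], 20, tolerance = 2)
  expect_equal(m$B_hat[m$condition == "N"], 0, tolerance = 2)
  expect_equal(m$B_hat[m$condition == "R"], -10, tolerance = 2)
})

test_that("veridical rewards erode measured biases across sessions", {
  res <- run_rl_experiment("veridical", truth = bias_set(20, -10, 0),
                           n_sessions = 12, n_reps = 3, seed = 7)
  m <- aggregate(B_hat ~ session, res[res$condition == "L", ], mean)
  # monotone erosion trend: strong negative rank correlation with session
  expect_lt(cor(m$session, m$B_hat, method = "spearman"), -0.8)
  expect_lt(m$B_hat[12], m$B_hat[1] / 2)
})

test_that("ambiguous-trial strategies plateau at reduced biases", {
  for (kind in c("random_ambiguous", "always_ambiguous", "never_ambiguous")) {
    res <- run_rl_experiment(kind, truth = bias_set(20, -10, 0),
                             n_sessions = 20, n_reps = 2, seed = 8)
    mL <- aggregate(B_hat ~ session, res[res$condition == "L", ], mean)
    late <- mean(mL$B_hat[16:20])
    expect_lt(late, 16)     # reduced relative to the true 20
    expect_gt(late, 0)      # but not fully erased
  }
})

test_that("oracle rewards keep biases at truth; symmetric grids pin criteria", {
  res <- run_rl_experiment("oracle", truth = bias_set(20, -10, 0),
                           n_sessions = 15, n_reps = 3, seed = 9,
                           symmetric_grid = TRUE)
  late <- res[res$session > 10, ]
  mB <- aggregate(B_hat ~ condition, late, mean)
  expect_equal(mB$B_hat[mB$condition == "L"], 20, tolerance = 2)
  expect_equal(mB$B_hat[mB$condition == "R"], -10, tolerance = 2)
  expect_lt(max(abs(late$psi_end)), 1)
})

test_that("a shared criterion cannot corrupt perceptual-bias estimates", {
  # fast-learning shared-criterion agent under estimated-bias rewards:
  # criterion shifts are common to all contexts and cancel in P = B - B_N
  res <- run_rl_experiment(
    "estimated", rl_agent_config(alpha = 4, criterion_mode = "shared"),
    truth = bias_set(20, -10, 0), n_sessions = 3, n_reps = 1,
    estimator_opts = list(
      priors = prior_spec(P_L_mean = 20, P_R_mean = -10),
      config = sampler_config(n_draws = 800, burn_in = 400,
                              refit_cadence = 25, seed = 11)),
    seed = 10)
  P_L_meas <- res$B_hat[res$condition == "L"] - res$B_hat[res$condition == "N"]
  P_R_meas <- res$B_hat[res$condition == "R"] - res$B_hat[res$condition == "N"]
  expect_equal(mean(P_L_meas), 20, tolerance = 3.5)
  expect_equal(mean(P_R_meas), -10, tolerance = 3.5)
})
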