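test_that("reward rule compares choice side to the boundary", {
  expect_true(decide_reward("left", -5, 0))
  expect_true(decide_reward("right", -5, -10))
  expect_false(decide_reward("right", -5, 0))
  # stimulus exactly on the boundary: rewarded regardless of choice
  expect_true(decide_reward("left", 0, 0))
  expect_true(decide_reward("right", 0, 0))
  expect_error(decide_reward("left", Inf, 0), "finite")
})

test_that("flipping the choice flips the reward off the boundary", {
  set.seed(12)
  om <- runif(200, -40, 40)
  bnd <- runif(200, -20, 20)
  r_left <- decide_reward(rep("left", 200), om, bnd)
  r_right <- decide_reward(rep("right", 200), om, bnd)
  off <- om != bnd
  expect_true(all(xor(r_left[off], r_right[off])))
})

test_that("ambiguity is the closed band between zero and the context bias", {
  truth <- bias_set(20, -10, 0)
  expect_true(is_ambiguous(10, "L", truth))
  expect_true(is_ambiguous(0, "L", truth))
  expect_true(is_ambiguous(20, "L", truth))
  expect_false(is_ambiguous(30, "L", truth))
  expect_false(is_ambiguous(-1, "L", truth))
  expect_true(is_ambiguous(-5, "R", truth))
  expect_false(is_ambiguous(5, "R", truth))
  expect_false(any(is_ambiguous(seq(-40, 40, 8), "N", truth)))
})

test_that("strategies choose the documented boundaries", {
  truth <- bias_set(20, -10, 0)
  expect_true(strategy_reward(reward_strategy("veridical"),
                              "right", 8, "L", truth)$reward)
  # inside the ambiguous band: never / always, independent of choice
  nv <- reward_strategy("never_ambiguous")
  expect_false(strategy_reward(nv, "left", 10, "L", truth)$reward)
  expect_false(strategy_reward(nv, "right", 10, "L", truth)$reward)
  aw <- reward_strategy("always_ambiguous")
  expect_true(strategy_reward(aw, "left", 10, "L", truth)$reward)
  # outside the band the ambiguous variants act veridically
  expect_true(strategy_reward(nv, "right", 30, "L", truth)$reward)
  # oracle boundary is the ground-truth perceptual bias
  expect_true(strategy_reward(reward_strategy("oracle"),
                              "left", 10, "L", truth)$reward)
  expect_equal(strategy_reward(reward_strategy("oracle"),
                               "left", 10, "L", truth)$boundary, 20)
  # estimated uses the reward-state boundary; neutral is pinned at zero
  st <- reward_state(boundary_L = 15, boundary_R = -5)
  es <- reward_strategy("estimated")
  expect_equal(strategy_reward(es, "left", 10, "L", state = st)$boundary, 15)
  expect_equal(strategy_reward(es, "left", 10, "N", state = st)$boundary, 0)
  expect_error(strategy_reward(reward_strategy("oracle"), "left", 0, "L"),
               "ground-truth")
  expect_error(strategy_reward(es, "left", 0, "L"), "reward_state")
})

test_that("random-ambiguous strategy rewards at the configured rate", {
  truth <- bias_set(20, -10, 0)
  strat <- reward_strategy("random_ambiguous", random_prob = 0.8)
  set.seed(31)
  r <- replicate(2000, strategy_reward(strat, "left", 10, "L", truth)$reward)
  expect_lt(abs(mean(r) - 0.8), 3 * sqrt(0.8 * 0.2 / 2000))
})

test_that("boundary updates move toward the posterior mean under the clamp", {
  st <- reward_state(boundary_L = 0, boundary_R = 0, max_step = 1)
  st <- update_boundary(st, c(P_L = 5, P_R = 0), "L", trial = 1)
  expect_equal(st$boundary[["L"]], 1)
  st2 <- update_boundary(reward_state(), c(P_L = 0.3, P_R = 0), "L")
  expect_equal(st2$boundary[["L"]], 0.3)
  st3 <- update_boundary(reward_state(), c(P_L = 0, P_R = -7), "R")
  expect_equal(st3$boundary[["R"]], -1)
  # before the first posterior the boundary sits at the prior mean
  st4 <- reward_state(boundary_L = -10, boundary_R = 10)
  expect_equal(unname(st4$boundary), c(-10, 0, 10))
})

test_that("boundary trajectories are 1-Lipschitz under repeated updates", {
  set.seed(14)
  st <- reward_state(max_step = 1)
  traj <- numeric(200)
  for (i in 1:200) {
    st <- update_boundary(st, c(P_L = rnorm(1, 10, 15), P_R = 0), "L", i)
    traj[i] <- st$boundary[["L"]]
  }
  expect_lte(max(abs(diff(traj))), 1 + 1e-12)
})

test_that("the ground-truth boundary maximizes reward for an unbiased criterion", {
  # agent with percept omega - P and criterion 0; sweep fixed boundaries
  set.seed(15)
  P <- 20
  om <- rep(seq(-40, 40, by = 8), times = 600)
  percept <- rnorm(length(om), om - P, 16)
  choice <- ifelse(percept >= 0, "right", "left")
  sweep <- seq(-12, 44, by = 8)
  rate <- vapply(sweep, function(b) mean(decide_reward(choice, om, b)), 0)
  expect_equal(sweep[which.max(rate)], P, tolerance = 8)
})
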