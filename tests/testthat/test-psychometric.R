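test_that("choice probability follows the lapse-scaled cumulative Gaussian", {
  expect_equal(choice_prob(7, bias = 7, sigma = 15), 0.5)
  expect_equal(choice_prob(1e6, bias = 0, sigma = 15, lapse_high = 0.1), 0.9)
  expect_equal(choice_prob(-1e6, bias = 0, sigma = 15, lapse_low = 0.05), 0.05)
  # one noise-SD above the bias: standard normal CDF at 1, checked against
  # a numerical-integration oracle
  expect_equal(choice_prob(12 + 15, bias = 12, sigma = 15),
               phi_oracle(1), tolerance = 1e-6)
  expect_equal(round(choice_prob(15, 0, 15), 5), 0.84134)
})

test_that("choice probability rejects invalid parameters", {
  expect_error(choice_prob(Inf, 0, 15), "finite")
  expect_error(choice_prob(0, 0, -1), "positive")
  expect_error(choice_prob(0, 0, 15, lapse_low = 0.6, lapse_high = 0.5), "lapse")
})

test_that("choice probability is monotone in the stimulus for varied parameters", {
  set.seed(11)
  for (i in 1:25) {
    B <- runif(1, -30, 30)
    S <- runif(1, 2, 40)
    l1 <- runif(1, 0, 0.3)
    l2 <- runif(1, 0, 0.3)
    th <- choice_prob(seq(-60, 60, by = 2), B, S, l1, l2)
    expect_true(all(diff(th) >= 0))
    expect_equal(choice_prob(B, B, S, l1, l2), l1 + (1 - l1 - l2) / 2)
  }
})

test_that("choice sampling is Bernoulli with the requested rate", {
  expect_identical(sample_choice(rep(1, 5)), rep("right", 5))
  expect_identical(sample_choice(rep(0, 5)), rep("left", 5))
  expect_error(sample_choice(1.2), "0, 1")
  set.seed(42)
  draws <- sample_choice(rep(0.5, 10000))
  # within 3 binomial SDs of one half
  expect_lt(abs(mean(draws == "right") - 0.5), 3 * sqrt(0.25 / 10000))
  set.seed(7)
  a <- sample_choice(rep(0.3, 100))
  set.seed(7)
  expect_identical(a, sample_choice(rep(0.3, 100)))
})

test_that("choice codings convert both ways", {
  ch <- c("left", "right", "right", "left")
  expect_identical(choice_code(ch, "binary"), c(0, 1, 1, 0))
  expect_identical(choice_code(ch, "signed"), c(-1, 1, 1, -1))
  expect_identical(choice_decode(choice_code(ch, "signed")), ch)
  expect_identical(choice_decode(choice_code(ch, "binary")), ch)
})

test_that("empirical biases are the sums of perceptual and decision biases", {
  expect_equal(empirical_biases(bias_set(20, -10, 10)),
               c(B_L = 30, B_N = 10, B_R = 0))
  expect_equal(empirical_biases(bias_set(0, 0, 0)), c(B_L = 0, B_N = 0, B_R = 0))
  expect_equal(empirical_biases(bias_set(20, -20, 10)),
               c(B_L = 30, B_N = 10, B_R = -10))
  # linearity: scaling all inputs scales all outputs
  set.seed(3)
  for (i in 1:10) {
    v <- rnorm(3, 0, 15)
    c1 <- empirical_biases(bias_set(v[1], v[2], v[3]))
    c3 <- empirical_biases(bias_set(3 * v[1], 3 * v[2], 3 * v[3]))
    expect_equal(c3, 3 * c1)
  }
})

test_that("ML psychometric fit recovers generating parameters", {
  set.seed(21)
  om <- rep(seq(-40, 40, by = 8), times = 900)      # ~9900 trials
  th <- choice_prob(om, bias = 12, sigma = 15)
  ch <- sample_choice(th)
  f <- fit_empirical_bias(om, ch)
  expect_true(f$identifiable)
  expect_lt(abs(f$B - 12), 1)
  expect_lt(abs(f$S - 15), 1.5)
  # agrees with probit regression as an independent ML oracle
  g <- stats::glm(choice_code(ch, "binary") ~ om, family = binomial("probit"))
  expect_equal(f$B, unname(-coef(g)[1] / coef(g)[2]), tolerance = 1e-3)
  expect_equal(f$S, unname(1 / coef(g)[2]), tolerance = 1e-3)
})

test_that("ML psychometric fit handles symmetric and degenerate data", {
  # perfect left/right split around the grid midpoint
  om <- rep(c(-8, 8), each = 50)
  ch <- rep(c("left", "right"), each = 50)
  f <- fit_empirical_bias(om, ch)
  expect_lt(abs(f$B), 8)          # step location within one grid spacing
  # near-noiseless observer: step between all-left and all-right points
  om2 <- rep(seq(-40, 40, by = 8), times = 10)
  ch2 <- ifelse(om2 > 12, "right", "left")
  set.seed(5)
  flip <- runif(length(ch2)) < 0.01                # break perfect separation
  ch2[flip] <- ifelse(ch2[flip] == "left", "right", "left")
  f2 <- fit_empirical_bias(om2, ch2)
  expect_lt(abs(f2$B - 12), 8)
  # all choices identical: flagged non-identifiable with a boundary value
  f3 <- fit_empirical_bias(om2, rep("right", length(om2)))
  expect_false(f3$identifiable)
  expect_equal(f3$B, -40)
})
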