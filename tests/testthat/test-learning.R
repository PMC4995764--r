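# Closed-form checks of every learning-rule primitive against values
# computed by independent arithmetic.

test_that("food-choice probability follows the selectivity rule", {
  # (0.05/0.1)^5 + 0.01 = 0.03125 + 0.01
  expect_equal(choose_food_probability(0.05, 0.1, 5, P_E = 0.01), 0.04125)
  # valued at or above the environmental expectation: certain choice
  expect_equal(choose_food_probability(0.2, 0.1, 7), 1)
  expect_equal(choose_food_probability(0.1, 0.1, 3), 1)
  # unknown types are unreachable without exploration or social stimulus
  expect_equal(choose_food_probability(0, 0.1, 5), 0)
  expect_equal(choose_food_probability(0, 0.1, 5, P_E = 0.07, P_S = 0.2),
               0.27)
  expect_error(choose_food_probability(0.1, 0, 5), "a_ie")
  expect_error(choose_food_probability(0.1, 0.1, 5, P_E = 2), "P_E")
})

test_that("large selectivity exponents approach the zero-one rule", {
  expect_lt(choose_food_probability(0.099, 0.1, 500), 1e-2)
  expect_equal(choose_food_probability(0.101, 0.1, 500), 1)
})

test_that("exploration probability is damped by certainty", {
  expect_equal(exploration_probability(0.1, 0.4), 0.06)
  expect_equal(exploration_probability(0.7, 1), 0)
  expect_equal(exploration_probability(0.3, 0), 0.3)
  expect_error(exploration_probability(1.2, 0))
})

test_that("certainty updates track the relative reward discrepancy", {
  expect_equal(update_certainty(0, 0.5, 0.1, 0.1), 0.5)   # no surprise
  expect_equal(update_certainty(0, 1, 0.1, 0), 0)         # maximal surprise
  expect_equal(update_certainty(0.37, 0, 0.5, 0.1), 0.37) # zero rate
  # zero reward: discrepancy treated as maximal, certainty decays
  expect_equal(update_certainty(0.8, 0.5, 0, 0.1), 0.4)
  # stays in [0, 1] for arbitrary finite inputs
  set.seed(1)
  for (i in 1:200) {
    c2 <- update_certainty(runif(1), runif(1), rnorm(1, 0, 10),
                           rnorm(1, 0, 10))
    expect_gte(c2, 0)
    expect_lte(c2, 1)
  }
})

test_that("skill is half-maximal at t = H for every sigmoid shape", {
  for (H in c(0.1, 1, 10)) {
    for (S in 1:4) expect_equal(skill(H, H, S), 0.5)
  }
  expect_equal(skill(0, 3, 2), 0)
  expect_equal(skill(0.2, 0.1, 2), 0.8) # 0.04 / 0.05
})

test_that("skill is monotone in practice, H and S the right way round", {
  t <- seq(0.05, 20, length.out = 60)
  for (S in 1:4) {
    s <- skill(t, 2, S)
    expect_true(all(diff(s) > 0))          # strictly increasing in t
    expect_true(all(skill(t, 5, S) < s))   # harder tasks: lower skill
  }
  # larger S: shallower initial rise below H
  expect_true(all(skill(0.3, 1, 2:4) < skill(0.3, 1, 1:3)))
})

test_that("rewards are skill-scaled quality plus calibrated noise", {
  expect_equal(reward_draw(0.2, 0.5, Z = 0), 0.1)
  expect_equal(reward_draw(0.9, 0, Z = 0), 0)
  set.seed(42)
  e <- reward_draw(rep(0.1, 1e5), rep(0.5, 1e5), Z = 0.005)
  # sampling s.d. of an s.d. estimate is about sd / sqrt(2 n)
  expect_lt(abs(sd(e) - 0.005), 3 * 0.005 / sqrt(2 * 1e5))
  expect_lt(abs(mean(e) - 0.05), 3 * 0.005 / sqrt(1e5))
})

test_that("reinforcement converges geometrically to the reward", {
  expect_equal(reinforce(0, 0.8, 0.1), 0.08)
  expect_equal(reinforce(0.3, 1, 0.9), 0.9)
  expect_equal(reinforce(0.25, 0.6, 0.25), 0.25)
  for (lambda in c(0.1, 0.5, 0.9, 1)) {
    a <- 0.7
    e <- 0.1
    for (n in 1:10) {
      a <- reinforce(a, lambda, e)
      expect_equal(abs(a - e), (1 - lambda)^n * abs(0.7 - e),
                   tolerance = 1e-8)
    }
  }
})

test_that("stimulus enhancement needs a fresh matching observation", {
  expect_equal(
    stimulus_enhancement_probability(0.4, 7, 7, stimulus_time = 0, now = 10),
    0.4)
  expect_equal(
    stimulus_enhancement_probability(0.4, 7, 7, stimulus_time = 0, now = 31),
    0)
  expect_equal(
    stimulus_enhancement_probability(0.4, 7, 3, stimulus_time = 0, now = 1),
    0)
  expect_equal(
    stimulus_enhancement_probability(0, 7, 7, stimulus_time = 0, now = 1),
    0)
  expect_equal(stimulus_enhancement_probability(0.4, NA, 7), 0)
})

test_that("observational learning transfers only an experience lead", {
  expect_equal(observational_learning_gain(0.1, 0.5, 1, 10, 2), 0.4)
  expect_equal(observational_learning_gain(0.1, 1, 1, 2, 2), 0)
  expect_equal(observational_learning_gain(0.1, 1, 1, 1, 5), 0)
  expect_equal(effective_observation_time(1, 0.3), 0.3)
  expect_equal(effective_observation_time(0.2, 0.9), 0.2)
  expect_error(observational_learning_gain(0.1, 2, 1, 1, 0), "o_ik")
})

test_that("environmental expectation shrinks when intake falls short", {
  expect_equal(update_environment_expectation(0.1, 0.05, FALSE), 0.095)
  expect_equal(update_environment_expectation(0.1, 0.05, TRUE), 0.105)
  expect_equal(update_environment_expectation(0.2, 0, TRUE), 0.2)
  expect_equal(update_environment_expectation(0.2, 0, FALSE), 0.2)
  expect_error(update_environment_expectation(0, 0.1, TRUE), "a_ie")
})
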