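# Event-queue semantics: ordering against a brute-force chronological
# replay, the fixed-cadence clocks, and the energy ledger.

test_that("event-driven processing equals brute-force chronological replay", {
  for (seed in 1:25) {
    s <- random_micro_scenario(seed)
    sim <- simulate_foragers(s$world, s$population, s$params, "SOL",
                             minutes = 20, seed = seed, mutate = FALSE,
                             log_events = TRUE)
    ev <- sim$events
    expect_gt(nrow(ev), 10)
    # processing order is non-decreasing in time
    expect_true(all(diff(ev$t) >= -1e-12))
    # per-forager chains: each decision happens when the previous action
    # completes
    for (id in unique(ev$id)) {
      e <- ev[ev$id == id, ]
      expect_equal(e$t[-1], head(e$t + e$duration, -1), tolerance = 1e-9)
    }
    # global interleaving matches the linear-scan replay
    oracle <- replay_event_order(ev)
    expect_equal(ev$t, oracle$t, tolerance = 1e-9)
    expect_equal(ev$slot, oracle$slot)
  }
})

test_that("a short observation finishes before a long meal", {
  scn <- make_two_forager_eating_scenario(t_demo = 10, omega = 1, tau = 0.5,
                                          eat_remaining = 1)
  sim <- run_scenario(scn, minutes = 2)
  ev <- sim$events
  obs_end <- ev$t[ev$id == 2 & ev$action == "OBSERVE"][1] +
    ev$duration[ev$id == 2 & ev$action == "OBSERVE"][1]
  # the observer's next decision (at 0.5) precedes the eater's (at 1.0)
  second_decisions <- ev[ev$t > 0, ]
  expect_equal(second_decisions$id[1], 2)
  expect_equal(obs_end, 0.5)
})

test_that("digestion credits rewards, resets the stomach and tunes a_ie", {
  scn <- make_learning_curve_scenario(H = 1, S = 1, n_meals = 8, Q = 0.3)
  scn$params <- forage_params(N = 1, Z = 0, metabolism_rate = 1e-9,
                              stomach_capacity = 8,
                              satiation_threshold = 99, H = 1)
  scn$population$phi <- 0.1
  sim <- run_scenario(scn, minutes = 101)
  pop <- sim$population
  expect_equal(pop$stomach_n, 0) # cleared at the 100-minute boundary
  # stomach of 8 < capacity... capacity is 8, so it was full: a_ie rises
  expect_equal(pop$a_ie, 0.01 * 1.1, tolerance = 1e-9)
  # energy: initial + sum of rewards - metabolism
  expect_equal(pop$energy,
               pop$energy0 + sum(sim$meals$reward[sim$meals$t <= 100]) -
                 101 * 1e-9,
               tolerance = 1e-6)
})

test_that("an unfilled stomach lowers the environmental expectation", {
  scn <- make_learning_curve_scenario(H = 1, S = 1, n_meals = 5, Q = 0.3)
  scn$params <- forage_params(N = 1, Z = 0, metabolism_rate = 1e-9,
                              stomach_capacity = 20,
                              satiation_threshold = 3, H = 1)
  scn$population$phi <- 0.1
  sim <- run_scenario(scn, minutes = 101)
  # satiation stopped intake at 3 items < capacity: expectation shrinks
  expect_equal(sim$population$a_ie, 0.01 * 0.9, tolerance = 1e-9)
})

test_that("a zero horizon yields only the initial snapshot", {
  s <- random_micro_scenario(99)
  sim <- simulate_foragers(s$world, s$population, s$params, "SOL",
                           minutes = 0, seed = 1, log_events = TRUE)
  expect_equal(nrow(sim$trace), 1)
  expect_equal(sim$trace$t, 0)
  expect_equal(nrow(sim$events), 0)
  expect_equal(nrow(sim$deaths), 0)
})

test_that("with no intake, starvation strikes at energy0 / metabolism", {
  p <- forage_params(N = 1, metabolism_rate = 2, founder_energy = 100,
                     birth_energy = 100)
  w <- fixture_world(types = tibble::tibble(Q = 0.1, H = 1, S = 1),
                     items = tibble::tibble(x = numeric(), y = numeric(),
                                            type = integer()),
                     side = 100)
  pop <- fixture_population(p, x = 50, y = 50, energy = 100)
  sim <- simulate_foragers(w, pop, p, "SOL", minutes = 200, seed = 1)
  expect_true(sim$extinct) # the sole forager starved; none left to breed
  expect_equal(sim$deaths$t[1], 50) # 100 energy / 2 per minute
  expect_equal(sim$deaths$cause[1], 2)
})

test_that("death at the maximum age triggers an immediate replacement", {
  p <- forage_params(N = 3, Z = 0, metabolism_rate = 1e-9)
  w <- fixture_world(types = tibble::tibble(Q = 0.1, H = 1, S = 1),
                     items = tibble::tibble(x = numeric(), y = numeric(),
                                            type = integer()),
                     side = 100)
  age_max <- p$max_age * year_minutes(p)
  pop <- fixture_population(p, x = c(40, 50, 60), y = 50,
                            age = c(age_max - 5, 0, 0),
                            energy = c(1e6, 2e6, 1e6))
  sim <- simulate_foragers(w, pop, p, "SOL", minutes = 20, seed = 1)
  expect_equal(nrow(sim$deaths), 1)
  expect_equal(sim$deaths$t, 5)
  expect_equal(sim$deaths$cause, 1)
  expect_equal(sim$deaths$id, 1)
  expect_equal(nrow(sim$population), 3) # replaced at once
  expect_equal(sim$checks$n_bad, 0)
  # the newborn is recorded with its parent in the ancestor trace
  nb <- sim$ancestors[sim$ancestors$id == 4, ]
  expect_equal(nrow(nb), 1)
  expect_true(nb$parent %in% 2:3)
  expect_equal(nb$birth, 5)
})

test_that("the energy ledger closes exactly", {
  s <- random_micro_scenario(7)
  p <- s$params
  p$metabolism_rate <- 0.01
  sim <- simulate_foragers(s$world, s$population, p, "SOL",
                           minutes = 500, seed = 7)
  pop <- sim$population
  expect_equal(pop$energy, pop$energy0 + pop$credit - pop$debit,
               tolerance = 1e-8)
})

test_that("identical seeds reproduce identical runs", {
  s <- random_micro_scenario(3)
  run <- function() {
    simulate_foragers(s$world, s$population, s$params, "SOL",
                      minutes = 100, seed = 123, log_events = TRUE)
  }
  a <- run()
  b <- run()
  expect_equal(a$trace, b$trace)
  expect_equal(a$events, b$events)
  expect_equal(a$population, b$population)
})
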