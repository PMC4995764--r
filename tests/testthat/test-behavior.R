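# Decision-cascade behavior, exercised through miniature scripted
# scenarios run on the event engine, plus the R-level safety check.

test_that("safety needs enough group mates within the safe radius", {
  p <- forage_params()
  # focal at origin, 9 mates at exactly 17 m (inclusive boundary), group 1
  mk <- function(n_at, d, n_far = 0) {
    tibble::tibble(
      x = c(0, rep(d, n_at), rep(80, n_far)),
      y = 0, group = 1L)
  }
  expect_true(check_safe(mk(9, 17), 1, p, side = 500)$safe)
  expect_false(check_safe(mk(8, 17, n_far = 1), 1, p, side = 500)$safe)
  expect_false(check_safe(mk(9, 17.01), 1, p, side = 500)$safe)
  # small groups: safe only when everyone is close
  expect_true(check_safe(mk(3, 10), 1, p, side = 500)$safe)
  expect_false(check_safe(mk(3, 10, n_far = 1), 1, p, side = 500)$safe)
  expect_false(check_safe(mk(3, 10),
                          1, forage_params(small_group_safe = FALSE),
                          side = 500)$safe)
  # solitary foragers are always safe
  solo <- tibble::tibble(x = 0, y = 0, group = NA_integer_)
  expect_true(check_safe(solo, 1, p, side = 500)$safe)
  # the safety radius is minimum-image: a mate across the seam counts
  wrapped <- tibble::tibble(x = c(1, 499), y = 0, group = 1L)
  expect_equal(check_safe(wrapped, 1, p, side = 500)$n_neighbors, 1L)
})

test_that("a full stomach produces one-minute NOTHING rests", {
  scn <- make_learning_curve_scenario(H = 1, S = 1, n_meals = 30)
  scn$params <- forage_params(N = 1, Z = 0, metabolism_rate = 1e-9,
                              stomach_capacity = 3,
                              satiation_threshold = 99, H = 1)
  sim <- run_scenario(scn, minutes = 30)
  ev <- sim$events
  expect_equal(sum(ev$action == "EAT"), 3) # capacity reached
  rests <- ev[ev$action == "NOTHING", ]
  expect_gt(nrow(rests), 10)
  expect_true(all(rests$duration == 1))
  # rests start only after the third meal
  expect_gt(min(rests$t), max(ev$t[ev$action == "EAT"]))
})

test_that("satiation aversion suppresses a type for one digestion cycle", {
  scn <- make_learning_curve_scenario(H = 0.5, S = 1, n_meals = 30)
  scn$params <- forage_params(N = 1, Z = 0, metabolism_rate = 1e-9,
                              stomach_capacity = 10,
                              satiation_threshold = 2, H = 0.5)
  sim <- run_scenario(scn, minutes = 160)
  m <- sim$meals
  # two meals allowed, then a 100-minute aversion, then eating resumes
  expect_equal(sum(m$t < 100), 2)
  t_aversion <- max(m$t[1:2])
  resumed <- m$t[m$t > t_aversion + 1]
  expect_gt(length(resumed), 0)
  expect_gt(min(resumed), t_aversion + 100)
})

test_that("realised rewards track the skill curve meal by meal", {
  for (S in c(1, 4)) {
    scn <- make_learning_curve_scenario(H = 2, S = S, n_meals = 12, Q = 0.3)
    sim <- run_scenario(scn)
    e <- sim$meals$reward
    expect_gte(length(e), 12)
    k <- seq_along(e)
    expect_equal(e, 0.3 * skill((k - 1) * 1, H = 2, S = S),
                 tolerance = 1e-12)
  }
  # rewards increase monotonically towards Q, and high S starts lower
  scn1 <- run_scenario(make_learning_curve_scenario(2, 1, 10))
  scn4 <- run_scenario(make_learning_curve_scenario(2, 4, 10))
  expect_true(all(diff(scn1$meals$reward) > 0))
  expect_lt(scn4$meals$reward[2], scn1$meals$reward[2])
})

test_that("after an empty search the forager relocates by delta", {
  p <- forage_params(N = 1, Z = 0, metabolism_rate = 1e-9, turn_sd = 0)
  w <- fixture_world(types = tibble::tibble(Q = 0.1, H = 1, S = 1),
                     items = tibble::tibble(x = numeric(), y = numeric(),
                                            type = integer()),
                     side = 200)
  pop <- fixture_population(p, x = 100, y = 100, heading = 0,
                            traits = list(delta = 6, epsilon = 1))
  sim <- simulate_foragers(w, pop, p, "SOL", minutes = 5, seed = 1,
                           mutate = FALSE, log_events = TRUE)
  ev <- sim$events
  expect_equal(as.character(ev$action[1]), "SEARCH")
  # a solitary relocation covers delta in one action at 0.5 m/s
  mv <- ev[ev$action == "MOVE", ]
  expect_equal(mv$duration[1], 6 / 30)
  # cycle: SEARCH, MOVE, SEARCH again
  expect_equal(as.character(ev$action[1:3]), c("SEARCH", "MOVE", "SEARCH"))
  # with no turning, every completed relocation advanced x by 6 m
  done_moves <- sum(mv$t + mv$duration <= 5 + 1e-9)
  expect_equal(sim$population$x, (100 + 6 * done_moves) %% 200,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("contested items are consumed exactly once", {
  p <- forage_params(N = 2, Z = 0, metabolism_rate = 1e-9)
  w <- fixture_world(types = tibble::tibble(Q = 0.2, H = 1, S = 1),
                     items = tibble::tibble(x = 100, y = 100, type = 1L),
                     side = 200)
  pop <- fixture_population(p, x = c(99.5, 100.5), y = c(100, 100),
                            traits = list(epsilon = 1, lambda = 1))
  sim <- simulate_foragers(w, pop, p, "SOL", minutes = 5, seed = 1,
                           mutate = FALSE, log_events = TRUE)
  expect_equal(nrow(sim$meals), 1)
  expect_false(any(sim$world$items$available))
  # both scheduled an EAT, only the first to finish got the item
  expect_equal(sum(sim$events$action == "EAT"), 2)
})

test_that("an unsafe group member steps towards its group", {
  p <- forage_params(N = 11, Z = 0, metabolism_rate = 1e-9)
  w <- fixture_world(types = tibble::tibble(Q = 0.1, H = 1, S = 1),
                     items = tibble::tibble(x = numeric(), y = numeric(),
                                            type = integer()),
                     side = 400)
  th <- seq(0, 2 * pi, length.out = 11)[-11]
  pop <- fixture_population(
    p, x = c(200, 230 + 3 * cos(th)), y = c(200, 200 + 3 * sin(th)),
    group = 1L, traits = list(epsilon = 0.5))
  sim <- simulate_foragers(w, pop, p, "G_LE", minutes = 2, seed = 1,
                           mutate = FALSE, log_events = TRUE)
  ev1 <- sim$events[sim$events$id == 1, ]
  expect_equal(as.character(ev1$action[1]), "MOVETOGROUP")
  expect_equal(ev1$duration[1], 1 / 30) # one metre at 0.5 m/s
  # it closes in on the clump over the run
  x1 <- sim$population$x[sim$population$id == 1]
  expect_gt(x1, 210)
})

test_that("demonstrators are sampled uniformly from eligible neighbours", {
  # two demonstrators mid-meal on different types; a gamma = 1 observer
  # reveals which one set its stimulus by what it then eats
  p <- forage_params(N = 3, Z = 0, metabolism_rate = 1e-9)
  w <- fixture_world(
    types = tibble::tibble(Q = c(0.2, 0.2), H = c(1, 1), S = c(1, 1)),
    items = tibble::tibble(x = c(95, 105, 99.6, 100.4),
                           y = c(100, 100, 100, 100),
                           type = c(1L, 2L, 1L, 2L)),
    side = 200)
  picks <- integer(200)
  for (i in seq_len(200)) {
    pop <- fixture_population(p, x = c(95, 105, 100), y = 100, group = 1L,
                              traits = list(gamma = 1, omega = 0,
                                            epsilon = 0, lambda = 1))
    mem <- list(a = matrix(0, 3, 2), c = matrix(0, 3, 2),
                t = matrix(0, 3, 2))
    sim <- simulate_foragers(
      w, pop, p, "G_SE", minutes = 3, seed = i, mutate = FALSE,
      log_events = TRUE, init_memory = mem,
      init_action = list(code = c(4L, 4L, 0L), end = c(0.9, 0.9, 0),
                         item = c(1L, 2L, 0L)))
    m3 <- sim$meals[sim$meals$id == 3, ]
    picks[i] <- if (nrow(m3)) m3$type[1] else 0L
  }
  expect_true(all(picks %in% 1:2))
  ct <- table(factor(picks, levels = 1:2))
  expect_gt(stats::chisq.test(ct, p = c(0.5, 0.5))$p.value, 1e-3)
})
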