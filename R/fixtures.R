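#' Build a miniature hand-specified world
#'
#' Constructs a `forage_world` directly from explicit resource types and
#' item coordinates, bypassing the random landscape generator. Intended
#' for deterministic scripted scenarios and tests.
#'
#' @param types tibble/data frame with columns `Q`, `H`, `S` (one row per
#'   resource type).
#' @param items tibble/data frame with columns `x`, `y`, `type`.
#' @param side world side length in meters.
#' @param EC environmental-change rate (types per year).
#' @param change_mode `"replace_type"` or `"quality_change"`.
#' @return A `forage_world`.
#' @export
fixture_world <- function(types, items, side = 200, EC = 0,
                          change_mode = "replace_type") {
  types <- tibble::as_tibble(types)
  types$id <- seq_len(nrow(types))
  types$alive <- TRUE
  items <- tibble::as_tibble(items)
  items$item <- seq_len(nrow(items))
  items$patch <- NA_integer_
  items$available <- TRUE
  structure(
    list(types = types[, c("id", "Q", "H", "S", "alive")],
         patch_types = tibble::tibble(patch_type = integer(),
                                      type = integer()),
         patches = tibble::tibble(patch = integer(), x = numeric(),
                                  y = numeric(), patch_type = integer()),
         items = items[, c("item", "x", "y", "type", "patch", "available")],
         side = side, env_type = "mixed", change_mode = change_mode,
         EC = EC, n_replacements = 0L),
    class = "forage_world"
  )
}

# Hand-build a population tibble for scripted scenarios.
fixture_population <- function(params, x, y, group = NA_integer_,
                               heading = 0, energy = 1e6, age = 0,
                               traits = list()) {
  n <- length(x)
  tr <- matrix(0, n, 8, dimnames = list(NULL, .trait_names))
  tr[, "delta"] <- 2
  tr[, "sigma"] <- 1
  tr[, "tau"] <- 0.5
  for (nm in names(traits)) tr[, nm] <- rep_len(traits[[nm]], n)
  dplyr::bind_cols(
    tibble::tibble(id = seq_len(n),
                   group = rep_len(group, n),
                   x = x, y = y,
                   heading = rep_len(heading, n),
                   energy = rep_len(energy, n),
                   age = rep_len(age, n)),
    tibble::as_tibble(tr)
  )
}

#' Scripted scenario: a demonstrator mid-meal and a naive observer
#'
#' Two grouped foragers: forager 1 is pinned mid-EAT on a known resource
#' type (with processing experience `t_demo`), forager 2 starts its
#' decision cascade at time 0 within observation range. The scenario
#' isolates demonstrator sampling during the safety check, the setting of
#' the stimulus-enhancement short-term memory, and the
#' observational-learning experience gain.
#'
#' @param t_demo demonstrator's processing experience for the type, min.
#' @param Q,H,S the resource type.
#' @param gamma,omega,tau social traits of the observer.
#' @param eat_remaining minutes left of the demonstrator's EAT at t = 0.
#' @param distance observer-demonstrator distance, meters.
#' @return A list of class `forage_scenario` with the pinned world,
#'   population, memory and initial actions; run it with
#'   [run_scenario()].
#' @export
make_two_forager_eating_scenario <- function(t_demo = 10, Q = 0.2, H = 1,
                                             S = 1, gamma = 0, omega = 0,
                                             tau = 1, eat_remaining = 0.5,
                                             distance = 5) {
  params <- forage_params(N = 2, Z = 0, metabolism_rate = 1e-9,
                          stochastic_death_rate = 0)
  world <- fixture_world(
    types = tibble::tibble(Q = Q, H = H, S = S),
    items = tibble::tibble(x = c(100, 100.2, 100.4, 100 + distance + 0.5),
                           y = c(100, 100, 100, 100), type = 1L),
    side = 200
  )
  pop <- fixture_population(
    params,
    x = c(100, 100 + distance), y = c(100, 100),
    group = 1L,
    traits = list(gamma = gamma, omega = omega, tau = tau,
                  epsilon = 0, lambda = 1)
  )
  n_types <- nrow(world$types)
  mem <- list(a = matrix(0, 2, n_types), c = matrix(0, 2, n_types),
              t = matrix(0, 2, n_types))
  mem$t[1, 1] <- t_demo
  mem$a[1, 1] <- Q
  init_action <- list(code = c(4L, 0L), end = c(eat_remaining, 0),
                      item = c(1L, 0L))
  structure(list(world = world, population = pop, params = params,
                 condition = forage_condition("G_OL"),
                 init_memory = mem, init_action = init_action,
                 minutes = 2),
            class = "forage_scenario")
}

#' Scripted scenario: one forager practising one resource type
#'
#' A solitary forager surrounded by items of a single noiseless resource
#' type, with full exploration and a one-shot learning rate, so that the
#' realised reward of the k-th meal must track `Q * skill((k-1) * M)`
#' exactly. Satiation aversion and stomach limits are lifted out of the
#' way so the meals happen back to back.
#'
#' @param H practice time to half-maximal skill, minutes.
#' @param S sigmoid shape.
#' @param n_meals number of meals the scenario must allow.
#' @param Q resource quality.
#' @return A `forage_scenario`; run with [run_scenario()], then read the
#'   realised reward sequence from the `meals` log.
#' @export
make_learning_curve_scenario <- function(H, S, n_meals = 20, Q = 0.2) {
  stopifnot(n_meals >= 1)
  params <- forage_params(N = 1, Z = 0, metabolism_rate = 1e-9,
                          stomach_capacity = n_meals + 5,
                          satiation_threshold = n_meals + 5,
                          H = H)
  th <- seq(0, 2 * pi, length.out = n_meals + 11)[-1]
  world <- fixture_world(
    types = tibble::tibble(Q = Q, H = H, S = S),
    items = tibble::tibble(x = 100 + 0.5 * cos(th), y = 100 + 0.5 * sin(th),
                           type = 1L),
    side = 200
  )
  pop <- fixture_population(params, x = 100, y = 100,
                            traits = list(epsilon = 1, lambda = 1,
                                          sigma = 1))
  structure(list(world = world, population = pop, params = params,
                 condition = forage_condition("SOL"),
                 init_memory = NULL, init_action = NULL,
                 minutes = ceiling(n_meals * 1.5) + 5),
            class = "forage_scenario")
}

#' Run a scripted scenario
#'
#' @param scenario a `forage_scenario`.
#' @param minutes run length (defaults to the scenario's own).
#' @param seed integer seed.
#' @param ... passed to [simulate_foragers()].
#' @return A `forage_sim` with event and meal logs.
#' @export
run_scenario <- function(scenario, minutes = scenario$minutes, seed = 1,
                         ...) {
  simulate_foragers(scenario$world, scenario$population, scenario$params,
                    scenario$condition, minutes = minutes, seed = seed,
                    mutate = FALSE, log_events = TRUE,
                    return_memory = TRUE,
                    init_memory = scenario$init_memory,
                    init_action = scenario$init_action, ...)
}
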