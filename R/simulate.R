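.action_labels <- c("MOVE", "SEARCH", "MOVETOFOOD", "EAT", "MOVETOGROUP",
                    "OBSERVE", "NOTHING")

#' Run the event-driven foraging simulation
#'
#' Advances the world and population through `years` (or `minutes`) of
#' simulated time. Foragers sit in an event queue ordered by the
#' completion time of their current action; the forager with the least
#' time remaining decides next, so actions overlap asynchronously.
#' Per-minute metabolism and mortality, 100-minute digestion, per-minute
#' environmental change and yearly regrowth interleave with the action
#' events; each death triggers an immediate energy-weighted replacement
#' birth, keeping the population at `params$N`.
#'
#' @param world a [generate_world()] landscape.
#' @param population an [init_population()] tibble.
#' @param params a [forage_params()] list.
#' @param condition a [forage_condition()] or its label; controls grouping
#'   and which traits are frozen under mutation.
#' @param years,minutes run length (supply one; `minutes` wins).
#' @param specs an [evolvable_specs()] tibble (bounds and mutation sd).
#' @param record_every trace sampling interval in minutes (default one
#'   day, 720).
#' @param seed optional integer seed.
#' @param mutate enable mutation at birth (disable for parameter-sweep and
#'   switch protocols).
#' @param log_events record per-forager action and meal logs (capped at
#'   `max_log` rows; intended for small scripted scenarios).
#' @param max_log cap on logged rows.
#' @param diet_from minute from which per-forager diet statistics
#'   accumulate (default 0).
#' @param switch_time optional minute at which `switch_traits` are imposed
#'   on every living forager.
#' @param switch_traits named numeric vector of trait values applied at
#'   `switch_time`.
#' @param return_memory return the full association/certainty/experience
#'   matrices of the final population.
#' @param return_diet_matrix return per-forager-by-type diet counts.
#' @param init_memory optional list of `N x n_types` matrices `a`, `c`,
#'   `t` pinning initial long-term memory (scripted scenarios).
#' @param init_aie optional vector of initial environmental expectations.
#' @param init_action optional list (`code`, `end`, `item`) pinning the
#'   initial action of each forager (scripted scenarios); `code` uses the
#'   engine's action codes, 0 for an immediate decision.
#' @return An object of class `forage_sim`: a list with tibbles `trace`,
#'   `ancestors`, `deaths`, `population`, `diet` (and `events` / `meals`
#'   when logged), the final `world` state, `checks` on the constant
#'   population size, and run metadata.
#' @export
#' @examples
#' p <- desk_params(scale = 1000, N = 10)
#' w <- generate_world(p, seed = 1)
#' pop <- init_population(p, evolvable_specs("SOL"), "SOL",
#'                        side = w$side, seed = 1)
#' sim <- simulate_foragers(w, pop, p, "SOL", minutes = 200, seed = 1)
#' glance(sim)
simulate_foragers <- function(world, population, params,
                              condition = "SOL",
                              years = NULL, minutes = NULL,
                              specs = evolvable_specs(condition),
                              record_every = params$day_length,
                              seed = NULL, mutate = TRUE,
                              log_events = FALSE, max_log = 1e6,
                              diet_from = 0,
                              switch_time = NULL, switch_traits = NULL,
                              return_memory = FALSE,
                              return_diet_matrix = FALSE,
                              init_memory = NULL, init_aie = NULL,
                              init_action = NULL) {
  stopifnot(inherits(world, "forage_world"))
  validate_params(params)
  cond <- if (inherits(condition, "forage_condition")) condition
          else forage_condition(condition)
  if (is.null(minutes)) {
    if (is.null(years)) stop("supply either years or minutes", call. = FALSE)
    minutes <- round(years * year_minutes(params))
  }
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(switch_time) && switch_time <= 0) {
    # a switch at (or before) the start is just a different initial state
    if (!is.null(switch_traits)) {
      for (nm in names(switch_traits)) {
        population[[nm]] <- switch_traits[[nm]]
      }
    }
    switch_time <- NULL
    switch_traits <- NULL
  }

  wl <- list(
    type_q = world$types$Q, type_h = world$types$H,
    type_s = as.integer(world$types$S), type_alive = world$types$alive,
    item_x = world$items$x, item_y = world$items$y,
    item_type = as.integer(world$items$type),
    item_avail = world$items$available, side = world$side
  )
  tr <- as.matrix(population[, .trait_names])
  pl <- list(
    x = population$x, y = population$y, heading = population$heading,
    energy = population$energy, age = population$age,
    group = {
      g <- population$group
      g[is.na(g)] <- 0L
      as.integer(g)
    },
    traits = tr
  )
  par <- params[c("N", "G", "copy_space", "safe_space", "safe_neighbors",
                  "align_space", "view_radius", "reach",
                  "max_assessed_items", "stomach_capacity", "digestion_time",
                  "K", "Z", "W", "reproduction_cost", "mutation_prob",
                  "se_memory_window", "M", "EC", "Q_mean", "Q_sd", "H",
                  "S_min", "S_max", "search_item_time", "movetogroup_step",
                  "turn_sd", "satiation_threshold", "a_ie_init",
                  "birth_energy", "stochastic_death_rate")]
  par <- c(par, list(
    metabolism_rate = params$metabolism_rate,
    max_age_min = params$max_age * year_minutes(params),
    year_min = year_minutes(params),
    speed_mpm = params$speed * 60,
    neg_q_redraw = params$negative_q == "redraw",
    repro_gate = isTRUE(params$reproduction_gate),
    small_group_safe = isTRUE(params$small_group_safe),
    grouping = cond$grouping,
    quality_mode = world$change_mode == "quality_change"
  ))
  par$EC <- world$EC

  sw_vals <- rep(NA_real_, 8)
  if (!is.null(switch_traits)) {
    bad <- setdiff(names(switch_traits), .trait_names)
    if (length(bad)) stop("unknown switch trait(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    sw_vals[match(names(switch_traits), .trait_names)] <-
      as.numeric(switch_traits)
  }
  ctrl <- list(
    until = as.double(minutes), record_every = as.double(record_every),
    mutate = isTRUE(mutate), frozen = specs$frozen,
    tmin = specs$min, tmax = specs$max, tsd = specs$mutation_sd,
    switch_time = if (is.null(switch_time)) -1 else as.double(switch_time),
    switch_vals = sw_vals,
    log_events = isTRUE(log_events), max_log = as.double(max_log),
    diet_from = as.double(diet_from),
    return_memory = isTRUE(return_memory),
    return_diet_matrix = isTRUE(return_diet_matrix),
    init_memory = init_memory, init_aie = init_aie,
    init_action = init_action
  )

  raw <- sim_run_cpp(wl, pl, par, ctrl)

  pop_out <- tibble::as_tibble(raw$population[setdiff(names(raw$population),
                                                      "traits")])
  traits_out <- tibble::as_tibble(raw$population$traits,
                                  .name_repair = ~.trait_names)
  pop_out <- dplyr::bind_cols(pop_out, traits_out)
  pop_out$group[pop_out$group == 0L] <- NA_integer_

  new_world <- world
  new_world$items$available <- raw$world$item_avail
  new_world$items$type <- raw$world$item_type
  nt_new <- length(raw$world$type_q)
  if (nt_new > nrow(world$types)) {
    new_world$types <- tibble::tibble(
      id = seq_len(nt_new), Q = raw$world$type_q, H = raw$world$type_h,
      S = raw$world$type_s, alive = raw$world$type_alive)
  } else {
    new_world$types$Q <- raw$world$type_q
    new_world$types$alive <- raw$world$type_alive
  }
  new_world$n_replacements <- world$n_replacements + raw$n_replacements

  out <- list(
    trace = tibble::as_tibble(raw$trace),
    ancestors = tibble::as_tibble(raw$ancestors),
    deaths = tibble::as_tibble(raw$deaths),
    population = pop_out,
    diet = tibble::as_tibble(raw$diet),
    world = new_world,
    checks = raw$checks,
    extinct = raw$extinct,
    extinct_t = raw$extinct_t,
    n_replacements = raw$n_replacements,
    replacement_times = raw$replacement_times,
    condition = cond,
    params = params,
    minutes = minutes,
    years = minutes / year_minutes(params)
  )
  if (!is.null(raw$events)) {
    ev <- tibble::as_tibble(raw$events)
    ev$action <- factor(.action_labels[ev$action], levels = .action_labels)
    out$events <- ev
    out$meals <- tibble::as_tibble(raw$meals)
  }
  if (!is.null(raw$memory)) out$memory <- raw$memory
  if (!is.null(raw$diet_matrix)) out$diet_matrix <- raw$diet_matrix
  class(out) <- "forage_sim"
  out
}

#' @export
print.forage_sim <- function(x, ...) {
  cat("<forage_sim> ", x$condition$label, ", ",
      signif(x$years, 3), " years, ", nrow(x$population),
      " foragers alive, ", nrow(x$deaths), " deaths, ",
      x$n_replacements, " resource replacements",
      if (x$extinct) " [EXTINCT]" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy the population trace of a simulation
#'
#' @param x a `forage_sim`.
#' @param ... unused.
#' @return The trace tibble in long format: `t`, `year`, `variable`,
#'   `value`.
#' @export
tidy.forage_sim <- function(x, ...) {
  ym <- year_minutes(x$params)
  x$trace |>
    dplyr::mutate(year = .data$t / ym) |>
    tidyr::pivot_longer(cols = -c("t", "year"), names_to = "variable",
                        values_to = "value")
}

#' One-row summary of a simulation
#'
#' @param x a `forage_sim`.
#' @param ... unused.
#' @return A one-row tibble: condition, run length, final population size,
#'   mean energy, mean trait values, deaths, replacements, extinction.
#' @export
glance.forage_sim <- function(x, ...) {
  pop <- x$population
  tr_means <- colMeans(pop[, .trait_names, drop = FALSE])
  dplyr::bind_cols(
    tibble::tibble(
      condition = x$condition$label,
      years = x$years,
      n_alive = nrow(pop),
      mean_energy = mean(pop$energy),
      n_deaths = nrow(x$deaths),
      n_replacements = x$n_replacements,
      extinct = x$extinct
    ),
    tibble::as_tibble(as.list(tr_means))
  )
}

#' Plot a simulation trace
#'
#' @param object a `forage_sim`.
#' @param vars trace columns to plot against time.
#' @param ... unused.
#' @return A ggplot faceted by variable.
#' @export
autoplot.forage_sim <- function(object,
                                vars = c("mean_energy", "epsilon",
                                         "diet_quality", "diet_skill"),
                                ...) {
  d <- tidy(object) |> dplyr::filter(.data$variable %in% vars)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "simulated years", y = NULL)
}
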