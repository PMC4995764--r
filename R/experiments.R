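#' Define an experiment plan
#'
#' Bundles everything one experiment needs: the protocol (`evolutionary`,
#' `parsweep` or `switch`), condition, environment settings, run length,
#' replicate count and base seed. Replicate r runs on seed
#' `seed + r - 1`, each with its own independently generated world and
#' founding population, so replicates are statistically independent and a
#' plan is fully reproducible from its seed.
#'
#' @param protocol one of `"evolutionary"`, `"parsweep"`, `"switch"`.
#' @param condition condition label or [forage_condition()].
#' @param params a [forage_params()] list (use [desk_params()] for
#'   reduced-scale runs).
#' @param years run length in simulated years.
#' @param replicates number of replicate runs.
#' @param seed base integer seed.
#' @param init_traits named trait values used to initialise the population
#'   (required for non-solitary evolutionary runs, which start from
#'   solitary-evolved values, and for the non-evolutionary protocols);
#'   `"random"` for solitary evolutionary runs.
#' @param sweep_trait,sweep_grid,sweep_scope for `parsweep`: the swept
#'   trait, its value grid, and whether values vary `"across_groups"`
#'   (one value per group) or `"within_groups"` (grid distributed over the
#'   members of every group).
#' @param switch_year,switch_traits for `switch`: the year at which the
#'   named traits jump to the second mechanism's values for every living
#'   forager.
#' @param measure_window years over which diet statistics accumulate
#'   (defaults to the second half of the run).
#' @param record_every trace sampling interval, minutes.
#' @return A list of class `forage_plan`.
#' @export
forage_plan <- function(protocol = c("evolutionary", "parsweep", "switch"),
                        condition = "SOL",
                        params = forage_params(),
                        years = 1, replicates = 10, seed = 1,
                        init_traits = "random",
                        sweep_trait = NULL, sweep_grid = NULL,
                        sweep_scope = c("across_groups", "within_groups"),
                        switch_year = NULL, switch_traits = NULL,
                        measure_window = c(years / 2, years),
                        record_every = params$day_length) {
  protocol <- match.arg(protocol)
  cond <- if (inherits(condition, "forage_condition")) condition
          else forage_condition(condition)
  validate_params(params)
  if (protocol == "parsweep") {
    sweep_scope <- match.arg(sweep_scope)
    if (is.null(sweep_trait) || is.null(sweep_grid)) {
      stop("parsweep plans need sweep_trait and sweep_grid", call. = FALSE)
    }
    if (!sweep_trait %in% .trait_names) {
      stop("unknown sweep trait: ", sweep_trait, call. = FALSE)
    }
    frozen <- evolvable_specs(cond)$frozen[match(sweep_trait, .trait_names)]
    if (frozen) stop("cannot sweep a trait frozen by the condition",
                     call. = FALSE)
  } else {
    sweep_scope <- NULL
  }
  if (protocol == "switch") {
    if (is.null(switch_year) || is.null(switch_traits)) {
      stop("switch plans need switch_year and switch_traits", call. = FALSE)
    }
    if (switch_year > years) stop("switch year beyond run length",
                                  call. = FALSE)
  }
  if (protocol != "evolutionary" && identical(init_traits, "random")) {
    stop("non-evolutionary protocols need explicit init_traits",
         call. = FALSE)
  }
  if (protocol == "evolutionary" && cond$grouping &&
      identical(init_traits, "random")) {
    stop("grouping evolutionary runs start from solitary-evolved traits; ",
         "pass init_traits (e.g. from evolved_parameters() of a SOL run)",
         call. = FALSE)
  }
  structure(
    list(protocol = protocol, condition = cond, params = params,
         years = years, replicates = replicates, seed = seed,
         init_traits = init_traits, sweep_trait = sweep_trait,
         sweep_grid = sweep_grid, sweep_scope = sweep_scope,
         switch_year = switch_year, switch_traits = switch_traits,
         measure_window = measure_window, record_every = record_every),
    class = "forage_plan"
  )
}

# One replicate: seed -> world -> population -> simulation. All randomness
# flows from the single set.seed() call, so a (plan, replicate) pair is
# fully deterministic.
run_replicate <- function(plan, r, population_fn = NULL, ...) {
  set.seed(plan$seed + r - 1)
  p <- plan$params
  specs <- evolvable_specs(plan$condition)
  world <- generate_world(p)
  pop <- if (is.null(population_fn)) {
    init_population(p, specs, plan$condition, traits = plan$init_traits,
                    side = world$side)
  } else {
    population_fn(p, specs, world)
  }
  simulate_foragers(world, pop, p, plan$condition, years = plan$years,
                    specs = specs, record_every = plan$record_every,
                    ...)
}

#' Run evolutionary simulations
#'
#' Runs `replicates` independent evolutionary simulations (mutation on).
#' Solitary populations start on random trait values within bounds;
#' grouping populations start from supplied solitary-evolved values (with
#' the condition's frozen traits pinned at 0) and continue evolving.
#'
#' @param plan a [forage_plan()] with `protocol = "evolutionary"`.
#' @param evolved_window years over which [evolved_parameters()] averages
#'   ancestors (defaults to 85--95% of the run).
#' @return A list of class `forage_experiment` with `results` (one row per
#'   replicate: [glance()] plus ancestor-trace trait means prefixed
#'   `evolved_`), `traces` (all replicate traces), and the plan.
#' @export
run_evolutionary <- function(plan,
                             evolved_window = plan$years * c(0.85, 0.95)) {
  stopifnot(inherits(plan, "forage_plan"), plan$protocol == "evolutionary")
  rows <- list()
  traces <- list()
  for (r in seq_len(plan$replicates)) {
    sim <- run_replicate(plan, r, mutate = TRUE)
    ev <- tryCatch(evolved_parameters(sim, evolved_window),
                   error = function(e) NULL)
    row <- glance(sim)
    row$replicate <- r
    if (!is.null(ev)) {
      names(ev) <- paste0("evolved_", names(ev))
      row <- dplyr::bind_cols(row, ev)
    }
    rows[[r]] <- row
    tr <- sim$trace
    tr$replicate <- r
    traces[[r]] <- tr
  }
  structure(list(results = dplyr::bind_rows(rows),
                 traces = dplyr::bind_rows(traces),
                 plan = plan),
            class = "forage_experiment")
}

#' Run parameter-sweep simulations
#'
#' Non-evolutionary runs (mutation off) in which a single trait is varied
#' systematically while all other traits are held at supplied evolved
#' values. With `sweep_scope = "across_groups"` every member of a group
#' shares one grid value (groups are cycled over the grid); with
#' `"within_groups"` the grid is distributed over the members of each
#' group, so variation exists inside every group. Solitary sweeps assign
#' grid values over individuals.
#'
#' Per-forager total energy intake accumulates over
#' `plan$measure_window`; the summary reports mean and sd of intake per
#' grid value over replicates.
#'
#' @param plan a [forage_plan()] with `protocol = "parsweep"`.
#' @return A `forage_experiment` list with `results` (per replicate x grid
#'   value: mean intake, quality, skill), `summary` (aggregated over
#'   replicates) and the plan.
#' @export
run_parsweep <- function(plan) {
  stopifnot(inherits(plan, "forage_plan"), plan$protocol == "parsweep")
  ti <- match(plan$sweep_trait, .trait_names)
  grid <- plan$sweep_grid
  rows <- list()
  ym <- year_minutes(plan$params)
  for (r in seq_len(plan$replicates)) {
    assign_fn <- function(p, specs, world) {
      pop <- init_population(p, specs, plan$condition,
                             traits = plan$init_traits, side = world$side)
      if (plan$condition$grouping && plan$sweep_scope == "across_groups") {
        gids <- sort(unique(pop$group))
        vals <- rep_len(grid, length(gids))
        pop[[plan$sweep_trait]] <- vals[match(pop$group, gids)]
      } else if (plan$condition$grouping &&
                 plan$sweep_scope == "within_groups") {
        for (g in unique(pop$group)) {
          idx <- which(pop$group == g)
          pop[[plan$sweep_trait]][idx] <- rep_len(grid, length(idx))
        }
      } else {
        pop[[plan$sweep_trait]] <- rep_len(grid, nrow(pop))
      }
      pop
    }
    sim <- run_replicate(plan, r, population_fn = assign_fn,
                         mutate = FALSE,
                         diet_from = plan$measure_window[1] * ym)
    d <- dplyr::bind_cols(sim$diet,
                          value = sim$population[[plan$sweep_trait]])
    d$value <- vapply(d$value, function(v) grid[which.min(abs(grid - v))],
                      numeric(1))
    agg <- d |>
      dplyr::group_by(.data$value) |>
      dplyr::summarise(mean_intake = mean(.data$total_intake),
                       sd_intake = stats::sd(.data$total_intake),
                       mean_quality = mean(.data$repertoire_quality,
                                           na.rm = TRUE),
                       mean_skill = mean(.data$average_skill, na.rm = TRUE),
                       n = dplyr::n(), .groups = "drop")
    agg$replicate <- r
    rows[[r]] <- agg
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$value) |>
    dplyr::summarise(mean_intake = mean(.data$mean_intake),
                     sd_intake = stats::sd(.data$mean_intake),
                     mean_quality = mean(.data$mean_quality),
                     mean_skill = mean(.data$mean_skill),
                     .groups = "drop")
  structure(list(results = results, summary = summary, plan = plan),
            class = "forage_experiment")
}

#' Run switch simulations
#'
#' Non-evolutionary runs in which the population is initialised with the
#' evolved values of one learning mechanism (the second mechanism's traits
#' at 0) and, at `switch_year`, the second mechanism's evolved values are
#' imposed on every living forager. The dense trace around the switch
#' exposes the immediate transient: newly adopted social cues let foragers
#' sample higher-quality but unfamiliar resources, so diet repertoire
#' quality rises at once while average skill over the consumed diet dips
#' until practice catches up.
#'
#' @param plan a [forage_plan()] with `protocol = "switch"`.
#' @return A `forage_experiment` list with `traces` (per replicate, with a
#'   `post_switch` flag), `results` (per replicate pre/post means of diet
#'   quality and skill over `window_years` around the switch) and the
#'   plan.
#' @param window_years years before/after the switch over which pre and
#'   post means are taken (default 1).
#' @export
run_switch <- function(plan, window_years = 1) {
  stopifnot(inherits(plan, "forage_plan"), plan$protocol == "switch")
  ym <- year_minutes(plan$params)
  st <- plan$switch_year * ym
  rows <- list()
  traces <- list()
  for (r in seq_len(plan$replicates)) {
    sim <- run_replicate(plan, r, mutate = FALSE,
                         switch_time = st,
                         switch_traits = plan$switch_traits)
    tr <- sim$trace
    tr$replicate <- r
    tr$post_switch <- tr$t > st
    traces[[r]] <- tr
    pre <- tr$t > st - window_years * ym & tr$t <= st
    post <- tr$t > st & tr$t <= st + window_years * ym
    rows[[r]] <- tibble::tibble(
      replicate = r,
      pre_quality = mean(tr$diet_quality[pre], na.rm = TRUE),
      post_quality = mean(tr$diet_quality[post], na.rm = TRUE),
      pre_skill = mean(tr$diet_skill[pre], na.rm = TRUE),
      post_skill = mean(tr$diet_skill[post], na.rm = TRUE),
      extinct = sim$extinct
    )
  }
  structure(list(results = dplyr::bind_rows(rows),
                 traces = dplyr::bind_rows(traces),
                 plan = plan),
            class = "forage_experiment")
}

#' @export
print.forage_experiment <- function(x, ...) {
  cat("<forage_experiment> ", x$plan$protocol, " / ",
      x$plan$condition$label, ", ", x$plan$replicates, " replicate(s), ",
      x$plan$years, " year(s)\n", sep = "")
  if (!is.null(x$summary)) print(x$summary) else print(head(x$results))
  invisible(x)
}

#' Plot sweep or switch experiment summaries
#'
#' @param object a `forage_experiment`.
#' @param ... unused.
#' @return A ggplot: intake against swept value for sweeps; diet quality
#'   and skill against time for switch runs; evolved trait distributions
#'   for evolutionary runs.
#' @export
autoplot.forage_experiment <- function(object, ...) {
  plan <- object$plan
  if (plan$protocol == "parsweep") {
    return(
      ggplot2::ggplot(object$results,
                      ggplot2::aes(x = .data$value, y = .data$mean_intake)) +
        ggplot2::geom_point(alpha = 0.5) +
        ggplot2::stat_summary(fun = mean, geom = "line") +
        ggplot2::labs(x = plan$sweep_trait, y = "mean energy intake")
    )
  }
  if (plan$protocol == "switch") {
    ym <- year_minutes(plan$params)
    d <- object$traces |>
      tidyr::pivot_longer(cols = c("diet_quality", "diet_skill"),
                          names_to = "metric", values_to = "value")
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$t / ym, y = .data$value,
                                      group = .data$replicate)) +
        ggplot2::geom_line(alpha = 0.4) +
        ggplot2::geom_vline(xintercept = plan$switch_year,
                            linetype = "dashed") +
        ggplot2::facet_wrap(~metric, scales = "free_y") +
        ggplot2::labs(x = "simulated years", y = NULL)
    )
  }
  ev <- object$results |>
    dplyr::select(dplyr::starts_with("evolved_"), "replicate") |>
    tidyr::pivot_longer(cols = -"replicate", names_to = "trait",
                        values_to = "value")
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$trait, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "evolved value (ancestor-trace mean)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
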