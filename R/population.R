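#' Initialise a forager population
#'
#' Builds the founding population tibble consumed by
#' [simulate_foragers()]. Every forager starts life without knowledge of
#' any resource (all reward expectations, certainties and processing
#' experience are zero) and with the initial environmental expectation
#' `params$a_ie_init`. Founders receive `params$founder_energy` reserves
#' and ages drawn uniformly on `[0, max_age)` so that mortality and
#' replacement operate from the start of a run.
#'
#' In grouping conditions foragers are packed into groups of at most `G`
#' members; each group gets a uniformly random centre and its members are
#' scattered within a patch radius of it. Solitary foragers are scattered
#' uniformly over the world.
#'
#' @param params a [forage_params()] list.
#' @param specs an [evolvable_specs()] tibble.
#' @param condition a [forage_condition()] or its label.
#' @param traits `"random"` (each trait uniform within its bounds), or a
#'   named list / single-row data frame of trait values applied to every
#'   forager. Frozen traits are always pinned to their frozen value.
#' @param side world side length in meters (use `world$side`).
#' @param seed optional integer seed.
#' @return A tibble with columns `id`, `group` (`NA` when solitary), `x`,
#'   `y`, `heading`, `energy`, `age` (minutes) and the eight trait columns
#'   `delta`, `phi`, `sigma`, `epsilon`, `lambda`, `gamma`, `omega`, `tau`.
#' @export
#' @examples
#' w <- generate_world(desk_params(scale = 1000), seed = 1)
#' pop <- init_population(desk_params(scale = 1000), evolvable_specs("SOL"),
#'                        "SOL", side = w$side, seed = 1)
init_population <- function(params, specs = evolvable_specs(condition),
                            condition = "SOL", traits = "random",
                            side = sqrt(params$world_area), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond <- if (inherits(condition, "forage_condition")) condition
          else forage_condition(condition)
  n <- params$N
  tr <- matrix(NA_real_, n, 8, dimnames = list(NULL, .trait_names))
  if (identical(traits, "random")) {
    for (i in seq_len(8)) {
      tr[, i] <- runif(n, specs$min[i], specs$max[i])
    }
  } else {
    traits <- as.list(traits)
    bad <- setdiff(names(traits), .trait_names)
    if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    for (nm in .trait_names) {
      i <- match(nm, .trait_names)
      v <- if (!is.null(traits[[nm]])) traits[[nm]] else
        stats::median(c(specs$min[i], specs$max[i]))
      tr[, i] <- rep_len(v, n)
    }
  }
  for (i in which(specs$frozen)) tr[, i] <- specs$value[i]
  out_of_bounds <- vapply(seq_len(8), function(i) {
    !specs$frozen[i] && any(tr[, i] < specs$min[i] | tr[, i] > specs$max[i])
  }, logical(1))
  if (any(out_of_bounds)) {
    stop("trait value(s) outside bounds: ",
         paste(.trait_names[out_of_bounds], collapse = ", "), call. = FALSE)
  }

  if (cond$grouping) {
    n_groups <- ceiling(n / params$G)
    group <- rep(seq_len(n_groups), each = params$G)[seq_len(n)]
    cx <- runif(n_groups, 0, side)
    cy <- runif(n_groups, 0, side)
    r <- params$patch_diameter / 2 * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    x <- (cx[group] + r * cos(th)) %% side
    y <- (cy[group] + r * sin(th)) %% side
  } else {
    group <- rep(NA_integer_, n)
    x <- runif(n, 0, side)
    y <- runif(n, 0, side)
  }
  dplyr::bind_cols(
    tibble::tibble(
      id = seq_len(n),
      group = group,
      x = x, y = y,
      heading = runif(n, 0, 2 * pi),
      energy = rep(params$founder_energy, n),
      age = runif(n, 0, params$max_age * year_minutes(params))
    ),
    tibble::as_tibble(tr)
  )
}

#' Selection weights for reproduction
#'
#' The probability that forager i is selected to reproduce is
#' \deqn{P_R = h_i^W / \sum_j h_j^W}
#' with energy `h_i` and selection exponent `W = 3`, so a doubling of
#' energy gives an 8-fold higher weight. Negative energies are clamped to
#' zero before weighting; if every weight is zero the fallback is uniform.
#'
#' @param energy numeric vector of energy reserves.
#' @param W selection exponent (default 3).
#' @return Normalised probability vector.
#' @export
#' @examples
#' selection_weights(c(1, 2))  # 1/9, 8/9
selection_weights <- function(energy, W = 3) {
  if (!length(energy)) stop("empty population", call. = FALSE)
  h <- pmax(energy, 0)^W
  s <- sum(h)
  if (s <= 0) return(rep(1 / length(energy), length(energy)))
  h / s
}

#' Select a parent for a replacement birth
#'
#' Samples one index with probability proportional to clamped
#' `energy^W`. With `gate = TRUE` (the default), selection is restricted to
#' foragers whose reserves cover the reproduction cost; when none qualify
#' the richest forager is selected.
#'
#' @param energy numeric vector of energy reserves.
#' @param W selection exponent.
#' @param gate require `energy >= reproduction_cost`?
#' @param reproduction_cost energy cost of one birth.
#' @return The selected index.
#' @export
select_parent <- function(energy, W = 3, gate = TRUE,
                          reproduction_cost = 5000) {
  if (!length(energy)) stop("empty population", call. = FALSE)
  if (gate) {
    ok <- which(energy >= reproduction_cost)
    if (!length(ok)) return(which.max(energy))
    return(ok[sample.int(length(ok), 1,
                         prob = selection_weights(energy[ok], W))])
  }
  sample.int(length(energy), 1, prob = selection_weights(energy, W))
}

#' Inherit a genotype with mutation
#'
#' Each unfrozen trait independently mutates with probability
#' `mutation_prob`; a mutated value is drawn from a normal distribution
#' centred on the parent's value with standard deviation `max / 5` and
#' clamped to the trait's bounds. Frozen traits are copied unchanged.
#'
#' @param parent named numeric vector (or single-row data frame) of the
#'   eight trait values.
#' @param specs an [evolvable_specs()] tibble.
#' @param mutation_prob per-trait mutation probability.
#' @return Named numeric vector of offspring trait values.
#' @export
reproduce_genotype <- function(parent, specs, mutation_prob = 0.05) {
  parent <- unlist(parent[.trait_names])
  child <- parent
  for (i in seq_len(nrow(specs))) {
    if (specs$frozen[i]) next
    if (runif(1) < mutation_prob) {
      v <- rnorm(1, parent[i], specs$mutation_sd[i])
      child[i] <- min(max(v, specs$min[i]), specs$max[i])
    }
  }
  child
}

#' Randomly split an oversized group
#'
#' A group that exceeds the maximum size `G` splits into two equally sized
#' daughter groups (sizes differing by at most one when odd), with members
#' assigned at random.
#'
#' @param members vector of member identifiers.
#' @param G maximum group size.
#' @return A list of one (no split) or two membership vectors.
#' @export
#' @examples
#' lengths(split_group(1:21, 20))  # 11 and 10, or 10 and 11
split_group <- function(members, G = 20) {
  n <- length(members)
  if (n <= G) return(list(members))
  shuffled <- members[sample.int(n)]
  k <- ceiling(n / 2)
  list(shuffled[seq_len(k)], shuffled[(k + 1):n])
}

#' Safety check against group mates
#'
#' A grouping forager is safe when at least `safe_neighbors` of its group
#' mates are within `safe_space` meters (boundary inclusive, minimum-image
#' distances). Groups too small to ever muster that many neighbours count
#' as safe when all their members are within `safe_space`
#' (`params$small_group_safe`). Solitary foragers are always safe.
#'
#' @param population tibble with columns `x`, `y`, `group`.
#' @param i row index of the focal forager.
#' @param params a [forage_params()] list.
#' @param side world side length in meters.
#' @return A list with `safe` (logical) and `n_neighbors` (count of group
#'   mates within `safe_space`).
#' @export
check_safe <- function(population, i, params, side) {
  g <- population$group[i]
  if (is.na(g)) return(list(safe = TRUE, n_neighbors = 0L))
  mates <- which(population$group == g)
  mates <- mates[mates != i]
  d <- torus_distance(population$x[i], population$y[i],
                      population$x[mates], population$y[mates], side)
  n_in <- sum(d <= params$safe_space)
  safe <- if (length(mates) >= params$safe_neighbors) {
    n_in >= params$safe_neighbors
  } else if (isTRUE(params$small_group_safe)) {
    n_in == length(mates)
  } else FALSE
  list(safe = safe, n_neighbors = as.integer(n_in))
}
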