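#' Fixed model parameters
#'
#' Builds the full set of fixed (non-evolving) parameters of the foraging
#' model, with defaults corresponding to a primate-like group forager in a
#' patchy environment of 250 resource species spread over roughly 40 km2.
#' Any default can be overridden by name.
#'
#' Spatial units are meters, temporal units minutes, and energy is in the
#' same arbitrary units as resource quality `Q`. A year is
#' `year_length * day_length` minutes of active (daylight) foraging time.
#'
#' @param ... named overrides of any default listed below.
#'
#' @details Key fields (defaults in parentheses):
#' \describe{
#'   \item{R}{number of resource species (250)}
#'   \item{N}{population size, held constant by birth-on-death (100)}
#'   \item{G}{maximum group size before a group splits (20)}
#'   \item{copy_space, safe_space, align_space}{social radii in meters
#'     (20, 17, 20); a forager is safe with at least `safe_neighbors` (9)
#'     group mates within `safe_space`}
#'   \item{view_radius, reach}{search radius (2) and eating reach (0.9)}
#'   \item{max_assessed_items}{items assessed per SEARCH (20)}
#'   \item{stomach_capacity, digestion_time}{20 items; 100 minutes}
#'   \item{K, Z, W}{observational-learning effectiveness (0.1), reward
#'     noise s.d. (0.005), selection exponent (3)}
#'   \item{reproduction_cost, metabolism_rate}{5000; 0.008 energy/min,
#'     a calibrated default giving a modest surplus at full intake}
#'   \item{mutation_prob}{per-trait mutation probability (0.05)}
#'   \item{max_age, year_length, day_length}{20 years; 360 days; 720 min}
#'   \item{world_area, patch_diameter}{4e7 m2; 20 m}
#'   \item{n_patches, items_per_patch}{24500; 1200}
#'   \item{n_patch_types, types_per_patch_type, types_per_patch}{50; 5; 3}
#'   \item{se_memory_window}{stimulus-enhancement memory, minutes (30)}
#'   \item{M}{maximum processing time of one item, minutes (1)}
#'   \item{H}{global task difficulty: practice minutes to half-maximal
#'     skill (1; the interesting range is 0.1--10)}
#'   \item{EC}{environmental change: resource types replaced per year (0)}
#'   \item{Q_mean, Q_sd}{resource-quality distribution (0.1, 0.1)}
#'   \item{S_min, S_max}{range of the integer sigmoid shape (1, 4)}
#'   \item{speed}{movement speed, m/s (0.5)}
#'   \item{search_item_time}{minutes spent assessing one item (1/60)}
#'   \item{movetogroup_step}{step length towards the group centroid (1)}
#'   \item{turn_sd}{s.d. of the random heading change before MOVE, rad (0.5)}
#'   \item{negative_q}{"redraw" (default) or "clamp" negative quality draws}
#'   \item{satiation_threshold}{items of one type per digestion cycle that
#'     trigger a satiation aversion (20)}
#'   \item{a_ie_init}{initial environmental expectation (0.01)}
#'   \item{birth_energy, founder_energy}{newborn reserves
#'     (`reproduction_cost / 2`); founder reserves
#'     (`2 * reproduction_cost`, enough to fund one replacement birth)}
#'   \item{reproduction_gate}{require parental energy >= reproduction cost,
#'     falling back to the richest survivor when no one qualifies (TRUE)}
#'   \item{stochastic_death_rate}{per-minute death hazard (0)}
#'   \item{small_group_safe}{groups smaller than `safe_neighbors + 1` count
#'     as safe when fully within `safe_space` (TRUE)}
#'   \item{env_type}{"mixed", "pure" or "random" resource layout}
#'   \item{change_mode}{"replace_type" or "quality_change"}
#' }
#'
#' @return A named list of class `forage_params`.
#' @seealso [desk_params()] for reduced-scale presets, [evolvable_specs()],
#'   [forage_condition()], [read_config()].
#' @export
#' @examples
#' p <- forage_params(H = 2, EC = 10)
#' p$R
forage_params <- function(...) {
  p <- list(
    R = 250, N = 100, G = 20,
    copy_space = 20, safe_space = 17, safe_neighbors = 9, align_space = 20,
    view_radius = 2, reach = 0.9, max_assessed_items = 20,
    stomach_capacity = 20, digestion_time = 100,
    K = 0.1, Z = 0.005, W = 3,
    reproduction_cost = 5000, metabolism_rate = 0.008,
    mutation_prob = 0.05,
    max_age = 20, year_length = 360, day_length = 720,
    world_area = 4e7, patch_diameter = 20,
    items_per_patch = 1200, n_patches = 24500,
    n_patch_types = 50, types_per_patch_type = 5, types_per_patch = 3,
    se_memory_window = 30, M = 1,
    H = 1, EC = 0,
    Q_mean = 0.1, Q_sd = 0.1, S_min = 1, S_max = 4,
    speed = 0.5, search_item_time = 1 / 60, movetogroup_step = 1,
    turn_sd = 0.5,
    negative_q = "redraw",
    satiation_threshold = 20,
    a_ie_init = 0.01,
    birth_energy = 2500, founder_energy = 10000,
    reproduction_gate = TRUE,
    stochastic_death_rate = 0,
    small_group_safe = TRUE,
    env_type = "mixed",
    change_mode = "replace_type"
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(over)] <- over
  }
  p <- structure(p, class = "forage_params")
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of radii, durations and counts, that probabilities lie
#' in `[0, 1]`, and the structural constraints linking patch types to
#' resource species (`n_patch_types * types_per_patch_type == R`,
#' `types_per_patch <= types_per_patch_type`).
#'
#' @param p a `forage_params` list.
#' @return `p`, invisibly; errors on the first violated constraint.
#' @export
validate_params <- function(p) {
  pos <- c("R", "N", "G", "copy_space", "safe_space", "safe_neighbors",
           "align_space", "view_radius", "reach", "max_assessed_items",
           "stomach_capacity", "digestion_time", "reproduction_cost",
           "metabolism_rate", "max_age", "year_length", "day_length",
           "world_area", "patch_diameter", "items_per_patch", "n_patches",
           "n_patch_types", "types_per_patch_type", "types_per_patch",
           "se_memory_window", "M", "H", "speed", "search_item_time",
           "movetogroup_step", "satiation_threshold", "a_ie_init",
           "Q_sd", "S_min", "S_max")
  for (k in pos) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("parameter '", k, "' must be a single positive number",
           call. = FALSE)
    }
  }
  prob <- c("mutation_prob", "stochastic_death_rate")
  for (k in prob) {
    v <- p[[k]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("parameter '", k, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  nonneg <- c("EC", "K", "Z", "W", "turn_sd", "birth_energy",
              "founder_energy")
  for (k in nonneg) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop("parameter '", k, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (p$types_per_patch > p$types_per_patch_type) {
    stop("types_per_patch must not exceed types_per_patch_type",
         call. = FALSE)
  }
  if (p$n_patch_types * p$types_per_patch_type != p$R) {
    stop("n_patch_types * types_per_patch_type must equal R", call. = FALSE)
  }
  if (p$EC > p$R) stop("EC must not exceed R", call. = FALSE)
  if (p$S_min > p$S_max) stop("S_min must not exceed S_max", call. = FALSE)
  if (!p$env_type %in% c("mixed", "pure", "random")) {
    stop("env_type must be 'mixed', 'pure' or 'random'", call. = FALSE)
  }
  if (!p$change_mode %in% c("replace_type", "quality_change")) {
    stop("change_mode must be 'replace_type' or 'quality_change'",
         call. = FALSE)
  }
  if (!p$negative_q %in% c("redraw", "clamp")) {
    stop("negative_q must be 'redraw' or 'clamp'", call. = FALSE)
  }
  invisible(p)
}

#' Minutes in one simulated year
#'
#' @param p a `forage_params` list.
#' @return `year_length * day_length`, in minutes (259200 by default).
#' @export
year_minutes <- function(p) p$year_length * p$day_length

#' Reduced-scale parameter presets
#'
#' Shrinks the world by a linear factor applied to its area and patch
#' count, keeping resource-type structure, patch size and item density per
#' patch unchanged. Intended for desk-scale experiments and tests; results
#' at these scales illustrate the model's dynamics but are not the
#' full-scale conditions.
#'
#' @param scale divisor applied to `world_area` and `n_patches` (default 50).
#' @param ... further overrides passed to [forage_params()].
#' @return A `forage_params` list.
#' @export
#' @examples
#' desk_params(scale = 250, N = 30)$n_patches
desk_params <- function(scale = 50, ...) {
  base <- forage_params()
  forage_params(world_area = base$world_area / scale,
                n_patches = max(1L, as.integer(round(base$n_patches / scale))),
                ...)
}

#' Specifications of the evolvable traits
#'
#' The eight heritable traits and their bounds: movement distance `delta`
#' (m), environmental-expectation update rate `phi`, selectivity exponent
#' `sigma`, exploration rate `epsilon`, reinforcement learning rate
#' `lambda`, stimulus-enhancement strength `gamma`, observation probability
#' `omega`, and maximum observation time `tau` (min). The mutation kernel's
#' standard deviation is one fifth of each trait's maximum value.
#'
#' @param condition optional [forage_condition()] (or its label); traits the
#'   condition holds constant are marked `frozen` with `value` 0.
#' @param delta_range,phi_range,sigma_range numeric length-2 bounds for the
#'   traits whose ranges are configurable.
#' @return A tibble with columns `name`, `min`, `max`, `frozen`, `value`
#'   (the pinned value for frozen traits, `NA` otherwise) and
#'   `mutation_sd`.
#' @export
#' @examples
#' evolvable_specs(condition = "G_SE")
evolvable_specs <- function(condition = NULL,
                            delta_range = c(1, 20),
                            phi_range = c(0, 1),
                            sigma_range = c(0, 10)) {
  stopifnot(length(delta_range) == 2, length(phi_range) == 2,
            length(sigma_range) == 2)
  specs <- tibble::tibble(
    name = .trait_names,
    min = c(delta_range[1], phi_range[1], sigma_range[1], 0, 0, 0, 0, 0.01),
    max = c(delta_range[2], phi_range[2], sigma_range[2], 1, 1, 1, 1, 1)
  )
  if (any(specs$min >= specs$max)) {
    stop("each trait must satisfy min < max", call. = FALSE)
  }
  specs$frozen <- FALSE
  specs$value <- NA_real_
  if (!is.null(condition)) {
    cond <- if (inherits(condition, "forage_condition")) condition
            else forage_condition(condition)
    frozen <- cond$frozen_traits
    specs$frozen[specs$name %in% frozen] <- TRUE
    specs$value[specs$name %in% frozen] <- 0
  }
  specs$mutation_sd <- mutation_sd(specs)
  specs
}

#' Mutation standard deviation of a trait
#'
#' Mutated offspring values are drawn from a normal distribution centred on
#' the parent's value with a standard deviation equal to one fifth of the
#' trait's maximum value, truncated to the trait bounds.
#'
#' @param spec a row (or several rows) of [evolvable_specs()], or a list
#'   with a `max` element.
#' @return Numeric vector of standard deviations (`max / 5`).
#' @export
#' @examples
#' mutation_sd(list(max = 1))  # 0.2
mutation_sd <- function(spec) {
  if (is.null(spec$max)) stop("spec must have a 'max' field", call. = FALSE)
  spec$max / 5
}

#' Simulation conditions
#'
#' The four study conditions: `SOL` (solitary foragers, no grouping),
#' `G_LE` (grouping with local enhancement only: both `gamma` and `omega`
#' held at 0), `G_SE` (stimulus enhancement free to evolve, `omega` held at
#' 0) and `G_OL` (observational learning free to evolve, `gamma` held at
#' 0). The exploration rate `epsilon` evolves freely in every condition.
#'
#' @param label one of `"SOL"`, `"G_LE"`, `"G_SE"`, `"G_OL"`.
#' @return A list of class `forage_condition` with elements `label`,
#'   `grouping`, `se_evolves`, `ol_evolves` and `frozen_traits`.
#' @export
#' @examples
#' forage_condition("G_OL")$frozen_traits
forage_condition <- function(label = c("SOL", "G_LE", "G_SE", "G_OL")) {
  label <- match.arg(label)
  frozen <- switch(label,
    SOL  = c("gamma", "omega"),
    G_LE = c("gamma", "omega"),
    G_SE = "omega",
    G_OL = "gamma"
  )
  structure(
    list(label = label,
         grouping = label != "SOL",
         se_evolves = label == "G_SE",
         ol_evolves = label == "G_OL",
         frozen_traits = frozen),
    class = "forage_condition"
  )
}

# Flat-config field names for the per-trait range overrides.
.config_trait_keys <- function() {
  c(t(outer(.trait_names, c("_min", "_max"), paste0)))
}

#' Write a flat configuration file
#'
#' Serialises a parameter set, trait ranges and condition label to a flat
#' key-value YAML document that [read_config()] restores exactly.
#'
#' @param path file path to write.
#' @param params a [forage_params()] list.
#' @param specs an [evolvable_specs()] tibble (ranges are stored; frozen
#'   flags are re-derived from the condition on read).
#' @param condition a [forage_condition()] or its label.
#' @return `path`, invisibly.
#' @export
write_config <- function(path, params = forage_params(),
                         specs = evolvable_specs(),
                         condition = "SOL") {
  cond <- if (inherits(condition, "forage_condition")) condition
          else forage_condition(condition)
  doc <- unclass(params)
  for (i in seq_len(nrow(specs))) {
    doc[[paste0(specs$name[i], "_min")]] <- specs$min[i]
    doc[[paste0(specs$name[i], "_max")]] <- specs$max[i]
  }
  doc$condition <- cond$label
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read and validate a flat configuration file
#'
#' Reads a flat YAML key-value document. Missing keys are filled with the
#' package defaults; unknown keys are an error; every value is validated.
#'
#' @param path file path; the file must parse as a flat YAML mapping.
#' @return A list with elements `params` ([forage_params()]), `specs`
#'   ([evolvable_specs()], with the condition's frozen traits applied) and
#'   `condition` ([forage_condition()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed config file: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("config must be a flat key-value mapping",
                          call. = FALSE)
  known_par <- names(forage_params())
  known <- c(known_par, .config_trait_keys(), "condition")
  bad <- setdiff(names(doc), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cond_label <- if (!is.null(doc$condition)) doc$condition else "SOL"
  cond <- forage_condition(cond_label)
  params <- do.call(forage_params, doc[intersect(names(doc), known_par)])
  rng <- function(trait, default) {
    lo <- doc[[paste0(trait, "_min")]]
    hi <- doc[[paste0(trait, "_max")]]
    c(if (is.null(lo)) default[1] else lo, if (is.null(hi)) default[2] else hi)
  }
  specs <- evolvable_specs(condition = cond,
                           delta_range = rng("delta", c(1, 20)),
                           phi_range = rng("phi", c(0, 1)),
                           sigma_range = rng("sigma", c(0, 10)))
  ranged <- c("epsilon", "lambda", "gamma", "omega", "tau")
  for (tr in ranged) {
    r <- rng(tr, c(specs$min[specs$name == tr], specs$max[specs$name == tr]))
    if (r[1] >= r[2]) stop("trait '", tr, "' must satisfy min < max",
                           call. = FALSE)
    specs$min[specs$name == tr] <- r[1]
    specs$max[specs$name == tr] <- r[2]
  }
  specs$mutation_sd <- mutation_sd(specs)
  list(params = params, specs = specs, condition = cond)
}

#' Default configuration as YAML text
#'
#' @param condition condition label stored in the emitted document.
#' @return A character scalar of YAML (also printed when interactive); the
#'   same document `--print-defaults` of the command-line wrapper emits.
#' @export
default_config <- function(condition = "SOL") {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_config(tmp, condition = condition)
  paste(readLines(tmp), collapse = "\n")
}

#' @export
print.forage_params <- function(x, ...) {
  cat("<forage_params> ", x$R, " resource types, N = ", x$N,
      ", world ", signif(x$world_area / 1e6, 3), " km2, ",
      x$n_patches, " patches, H = ", x$H, ", EC = ", x$EC, "\n", sep = "")
  invisible(x)
}

#' @export
print.forage_condition <- function(x, ...) {
  cat("<forage_condition> ", x$label,
      if (x$grouping) " (grouping)" else " (solitary)",
      "; frozen: ", paste(x$frozen_traits, collapse = ", "), "\n", sep = "")
  invisible(x)
}
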