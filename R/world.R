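#' Generate a resource landscape
#'
#' Creates the synthetic foraging environment: `R` resource species
#' partitioned exclusively over `n_patch_types` patch types
#' (`types_per_patch_type` species each), and `n_patches` circular patches
#' of `patch_diameter` meters whose items are placed uniformly inside the
#' patch disc. In the default `"mixed"` layout every patch carries
#' `types_per_patch` species drawn from its patch type's set; `"pure"`
#' patches carry a single species; `"random"` scatters all items uniformly
#' over the world with no patch structure.
#'
#' The world is a square of side `sqrt(world_area)` meters with toroidal
#' (wrap-around) boundaries; all distances in the package are
#' minimum-image. Resource qualities are drawn from
#' `Normal(Q_mean, Q_sd)`; negative draws are redrawn (or clamped to 0,
#' per `params$negative_q`). All species share the run's global task
#' difficulty `H`; the sigmoid shape `S` is a uniform integer in
#' `[S_min, S_max]`.
#'
#' @param params a [forage_params()] list.
#' @param seed optional integer seed (applied via [set.seed()]).
#' @param env_type overrides `params$env_type`.
#' @return A list of class `forage_world`: tibbles `types` (id, Q, H, S,
#'   alive), `patch_types` (patch_type, type id), `patches` (patch, x, y,
#'   patch_type), `items` (item, x, y, type, patch, available), plus
#'   `side`, `env_type`, `change_mode`, `EC` and the replacement counter
#'   `n_replacements`.
#' @export
#' @examples
#' w <- generate_world(desk_params(scale = 1000), seed = 1)
#' nrow(w$types)
generate_world <- function(params, seed = NULL, env_type = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  env_type <- if (is.null(env_type)) params$env_type else
    match.arg(env_type, c("mixed", "pure", "random"))
  side <- sqrt(params$world_area)

  types <- tibble::tibble(
    id = seq_len(params$R),
    Q = draw_quality(params$R, params),
    H = rep(params$H, params$R),
    S = sample(seq(params$S_min, params$S_max), params$R, replace = TRUE),
    alive = TRUE
  )
  # exclusive partition of species over patch types
  patch_types <- tibble::tibble(
    patch_type = rep(seq_len(params$n_patch_types),
                     each = params$types_per_patch_type),
    type = sample.int(params$R)
  )

  np <- params$n_patches
  ipp <- params$items_per_patch
  if (env_type == "random") {
    n_items <- np * ipp
    items <- tibble::tibble(
      item = seq_len(n_items),
      x = runif(n_items, 0, side),
      y = runif(n_items, 0, side),
      type = sample.int(params$R, n_items, replace = TRUE),
      patch = NA_integer_,
      available = TRUE
    )
    patches <- tibble::tibble(patch = integer(), x = numeric(),
                              y = numeric(), patch_type = integer())
  } else {
    patches <- tibble::tibble(
      patch = seq_len(np),
      x = runif(np, 0, side),
      y = runif(np, 0, side),
      patch_type = sample.int(params$n_patch_types, np, replace = TRUE)
    )
    k_local <- if (env_type == "pure") 1L else params$types_per_patch
    pool <- split(patch_types$type, patch_types$patch_type)
    # each patch draws its local species from its patch type's exclusive set
    lt <- matrix(unlist(lapply(patches$patch_type,
                               function(pt) {
                                 s <- pool[[pt]]
                                 s[sample.int(length(s), k_local)]
                               })),
                 nrow = np, ncol = k_local, byrow = TRUE)
    # one uniform draw from the patch's local set per item
    type_mat <- matrix(NA_integer_, nrow = np, ncol = ipp)
    idx <- matrix(sample.int(k_local, np * ipp, replace = TRUE), np, ipp)
    for (j in seq_len(ipp)) type_mat[, j] <- lt[cbind(seq_len(np), idx[, j])]
    r <- params$patch_diameter / 2 * sqrt(runif(np * ipp))
    th <- runif(np * ipp, 0, 2 * pi)
    items <- tibble::tibble(
      item = seq_len(np * ipp),
      x = (rep(patches$x, ipp) + r * cos(th)) %% side,
      y = (rep(patches$y, ipp) + r * sin(th)) %% side,
      type = as.vector(type_mat),
      patch = rep(patches$patch, ipp),
      available = TRUE
    )
  }
  structure(
    list(types = types, patch_types = patch_types, patches = patches,
         items = items, side = side, env_type = env_type,
         change_mode = params$change_mode, EC = params$EC,
         n_replacements = 0L),
    class = "forage_world"
  )
}

# Quality draws with the configured treatment of negative values.
draw_quality <- function(n, params) {
  q <- rnorm(n, params$Q_mean, params$Q_sd)
  if (params$negative_q == "clamp") return(pmax(q, 0))
  bad <- which(q < 0)
  while (length(bad)) {
    q[bad] <- rnorm(length(bad), params$Q_mean, params$Q_sd)
    bad <- bad[q[bad] < 0]
  }
  q
}

#' @export
print.forage_world <- function(x, ...) {
  cat("<forage_world> ", nrow(x$types), " types (",
      sum(x$types$alive), " alive), ", nrow(x$patches), " patches, ",
      nrow(x$items), " items (", sum(x$items$available), " available), ",
      "side ", round(x$side), " m, ", x$env_type, "/", x$change_mode,
      ", EC = ", x$EC, "\n", sep = "")
  invisible(x)
}

#' Yearly regrowth
#'
#' At each year boundary every consumed item reappears at its exact
#' original position with its current type (items whose species was
#' replaced by environmental change regrow as the new species, because
#' replacement rewrites the item's type at the moment of change).
#'
#' @param world a `forage_world`.
#' @param t current time in minutes; must fall on a year boundary.
#' @param params a [forage_params()] list (for the year length).
#' @return The world with all items available.
#' @export
regrow <- function(world, t = 0, params = forage_params()) {
  if (t %% year_minutes(params) != 0) {
    stop("regrowth is scheduled only at year boundaries", call. = FALSE)
  }
  world$items$available <- TRUE
  world
}

#' One minute of environmental change
#'
#' With per-minute probability `EC / year_minutes`, one uniformly chosen
#' living resource species is changed. In `"replace_type"` mode the species
#' is retired and a freshly drawn species (new Q, new S, same global H,
#' unknown to every forager) takes over all of its items under a new id.
#' In `"quality_change"` mode only Q is redrawn: the id persists, and so do
#' forager memories keyed to it.
#'
#' @param world a `forage_world`.
#' @param params a [forage_params()] list.
#' @param dt time step in minutes (default 1).
#' @return The (possibly) updated world; `world$n_replacements` counts
#'   change events.
#' @export
environmental_change_step <- function(world, params, dt = 1) {
  p <- world$EC * dt / year_minutes(params)
  if (p > 0 && runif(1) < p) world <- apply_environmental_change(world, params)
  world
}

# One change event (unconditional).
apply_environmental_change <- function(world, params) {
  live <- which(world$types$alive)
  if (!length(live)) return(world)
  old <- live[sample.int(length(live), 1)]
  if (world$change_mode == "quality_change") {
    world$types$Q[old] <- draw_quality(1, params)
  } else {
    new_id <- nrow(world$types) + 1L
    world$types <- dplyr::bind_rows(
      world$types,
      tibble::tibble(id = new_id, Q = draw_quality(1, params),
                     H = params$H,
                     S = sample(seq(params$S_min, params$S_max), 1),
                     alive = TRUE))
    world$types$alive[old] <- FALSE
    world$items$type[world$items$type == world$types$id[old]] <- new_id
    # the new species inherits the retired one's place in the patch-type map
    world$patch_types$type[world$patch_types$type == world$types$id[old]] <-
      new_id
  }
  world$n_replacements <- world$n_replacements + 1L
  world
}

#' Simulate environmental change over whole years
#'
#' Draws the per-minute Bernoulli change process for `years` simulated
#' years (hazard `EC / year_minutes` per minute, at most one change event
#' per minute) and applies each event in sequence. Used to study the
#' realised replacement rate; the expected number of events is
#' `EC * years`.
#'
#' @param world a `forage_world`.
#' @param params a [forage_params()] list.
#' @param years number of simulated years.
#' @return The updated world; compare `n_replacements` to `EC * years`.
#' @export
simulate_environmental_change <- function(world, params, years = 1) {
  n_min <- round(years * year_minutes(params))
  p <- world$EC / year_minutes(params)
  if (p <= 0 || n_min <= 0) return(world)
  hits <- sum(runif(n_min) < p)
  for (i in seq_len(hits)) {
    world <- apply_environmental_change(world, params)
  }
  world
}

#' Minimum-image distance on the toroidal world
#'
#' @param x1,y1,x2,y2 coordinates in meters.
#' @param side world side length in meters.
#' @return Euclidean distance under wrap-around boundaries, vectorised.
#' @export
torus_distance <- function(x1, y1, x2, y2, side) {
  dx <- abs(x1 - x2); dx <- pmin(dx, side - dx)
  dy <- abs(y1 - y2); dy <- pmin(dy, side - dy)
  sqrt(dx^2 + dy^2)
}

#' Write a world snapshot to CSV tables
#'
#' Writes `types.csv`, `patches.csv` and `items.csv` into `dir` for
#' debugging and fixture construction.
#'
#' @param world a `forage_world`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world_snapshot <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(world$types, file.path(dir, "types.csv"),
                   row.names = FALSE)
  utils::write.csv(world$patches, file.path(dir, "patches.csv"),
                   row.names = FALSE)
  utils::write.csv(world$items, file.path(dir, "items.csv"),
                   row.names = FALSE)
  invisible(dir)
}
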