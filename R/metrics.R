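#' Total energy intake of a diet
#'
#' \deqn{\sum_r d_{ir} \bar e_{ir}} where `d_ir` counts items of type r
#' consumed and `e_ir` is the mean per-item reward obtained from that
#' type. Rewards are the realised, logged values at consumption, not
#' re-evaluated with current skill.
#'
#' @param d named (or positional) vector of item counts by type.
#' @param e per-item rewards by type, aligned with `d`.
#' @return Total energy intake.
#' @export
#' @examples
#' total_energy_intake(c(2, 1), c(0.05, 0.1)) # 0.2
total_energy_intake <- function(d, e) {
  if (length(d) != length(e)) stop("d and e must align", call. = FALSE)
  if (any(d < 0)) stop("counts must be non-negative", call. = FALSE)
  sum(d * e)
}

#' Repertoire quality of a diet
#'
#' Diet-proportion-weighted mean of the maximal qualities of the consumed
#' resource types: \deqn{\sum_r p_{ir} Q_r}.
#'
#' @param p diet proportions (must sum to 1).
#' @param Q resource qualities aligned with `p`.
#' @return Weighted mean quality.
#' @export
repertoire_quality <- function(p, Q) {
  if (length(p) != length(Q)) stop("p and Q must align", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) stop("diet proportions must sum to 1",
                                   call. = FALSE)
  sum(p * Q)
}

#' Average skill over a diet
#'
#' Diet-proportion-weighted mean processing skill:
#' \deqn{\sum_r p_{ir} s_{ir}}.
#'
#' @param p diet proportions (must sum to 1).
#' @param s skills in `[0, 1]` aligned with `p`.
#' @return Weighted mean skill.
#' @export
average_skill <- function(p, s) {
  if (length(p) != length(s)) stop("p and s must align", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) stop("diet proportions must sum to 1",
                                   call. = FALSE)
  if (any(s < 0 | s > 1)) stop("skills must lie in [0, 1]", call. = FALSE)
  sum(p * s)
}

#' Evolved trait values from ancestor traces
#'
#' Follows the lineage of every member of the final population back
#' through the ancestor table and averages trait values over the distinct
#' ancestors whose lifetimes intersect a late-run window (year 850--950 at
#' full scale). This reads off the population's evolutionary attractor
#' without the noise of the final generation.
#'
#' @param sim a `forage_sim` (or a list with `ancestors`, `deaths`,
#'   `population` tibbles and `params`).
#' @param window numeric length-2 window in years.
#' @return A one-row tibble of mean trait values plus `n_ancestors`.
#' @export
evolved_parameters <- function(sim, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  ym <- year_minutes(sim$params)
  if (window[1] * ym > sim$minutes) {
    stop("window lies outside the simulated horizon", call. = FALSE)
  }
  anc <- sim$ancestors
  # integer-indexed lookups (ids are dense, assigned in birth order)
  max_id <- max(anc$id)
  parent_of <- integer(max_id); parent_of[anc$id] <- anc$parent
  birth_of <- rep(NA_real_, max_id); birth_of[anc$id] <- anc$birth
  death_at <- rep(NA_real_, max_id)
  if (nrow(sim$deaths)) death_at[sim$deaths$id] <- sim$deaths$t
  lo <- window[1] * ym
  hi <- window[2] * ym
  mark <- logical(max_id)
  visited <- logical(max_id)
  for (id in sim$population$id) {
    cur <- id
    while (cur > 0 && cur <= max_id && !is.na(birth_of[cur]) &&
           !visited[cur]) {
      visited[cur] <- TRUE
      b <- birth_of[cur]
      d <- if (is.na(death_at[cur])) sim$minutes else death_at[cur]
      if (b <= hi && d >= lo) mark[cur] <- TRUE
      cur <- parent_of[cur]
    }
  }
  keep <- which(mark)
  rows <- anc[anc$id %in% keep, .trait_names, drop = FALSE]
  if (!nrow(rows)) {
    stop("no ancestors intersect the requested window", call. = FALSE)
  }
  dplyr::bind_cols(tibble::as_tibble(as.list(colMeans(rows))),
                   tibble::tibble(n_ancestors = nrow(rows)))
}

#' Time-averaged population energy over a window
#'
#' Averages the trace's mean forager energy over all samples falling in
#' the window (year 950--1000 at full scale). Extinct runs have no defined
#' value and raise an error.
#'
#' @param sim a `forage_sim`.
#' @param window numeric length-2 window in years.
#' @return Mean population energy over the window.
#' @export
population_energy <- function(sim, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (isTRUE(sim$extinct)) {
    stop("population went extinct; energy level undefined", call. = FALSE)
  }
  ym <- year_minutes(sim$params)
  rows <- sim$trace$t >= window[1] * ym & sim$trace$t <= window[2] * ym
  if (!any(rows)) stop("window contains no trace samples", call. = FALSE)
  mean(sim$trace$mean_energy[rows])
}

#' Per-forager diet statistics
#'
#' Returns the per-forager diet summary accumulated during the run (from
#' `diet_from` onwards): item counts, total energy intake (realised
#' rewards), repertoire quality and average (current) skill over the diet.
#'
#' @param sim a `forage_sim`.
#' @return The `diet` tibble.
#' @export
diet_statistics <- function(sim) sim$diet
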