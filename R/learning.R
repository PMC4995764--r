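#' Food-choice probability
#'
#' Probability that a forager chooses to eat an assessed item of resource
#' type r,
#' \deqn{P_F = \min\left[1,\; (a_{ir}/a_{ie})^{\sigma_i} + P_E + P_S\right]}
#' where `a_ir` is the expected reward of the type, `a_ie` the forager's
#' environmental expectation, and `sigma` its selectivity exponent. The
#' power term is taken as 0 for non-positive `a_ir` (unknown types are only
#' reachable through exploration `P_E` or stimulus enhancement `P_S`); a
#' type already valued above the environmental expectation is chosen with
#' certainty.
#'
#' @param a_ir expected reward(s) of the assessed type.
#' @param a_ie environmental expectation, strictly positive.
#' @param sigma selectivity exponent, >= 0.
#' @param P_E exploration probability, see [exploration_probability()].
#' @param P_S stimulus-enhancement probability, see
#'   [stimulus_enhancement_probability()].
#' @return Probability in `[0, 1]`, vectorised over the inputs.
#' @export
#' @examples
#' choose_food_probability(0.05, 0.1, sigma = 5, P_E = 0.01) # 0.04125
choose_food_probability <- function(a_ir, a_ie, sigma, P_E = 0, P_S = 0) {
  if (any(a_ie <= 0)) stop("a_ie must be strictly positive", call. = FALSE)
  if (any(P_E < 0 | P_E > 1) || any(P_S < 0 | P_S > 1)) {
    stop("P_E and P_S must lie in [0, 1]", call. = FALSE)
  }
  base <- ifelse(a_ir > 0, (a_ir / a_ie)^sigma, 0)
  pmin(1, base + P_E + P_S)
}

#' Exploration probability
#'
#' Probability of sampling a (partially) unfamiliar resource type,
#' \deqn{P_E = \varepsilon_i (1 - c_{ir})}
#' damped by the certainty `c_ir` so that familiar types stop being
#' explored.
#'
#' @param epsilon exploration rate in `[0, 1]`.
#' @param c_ir certainty in `[0, 1]`.
#' @return `epsilon * (1 - c_ir)`, vectorised.
#' @export
exploration_probability <- function(epsilon, c_ir) {
  if (any(epsilon < 0 | epsilon > 1)) stop("epsilon must be in [0, 1]",
                                           call. = FALSE)
  if (any(c_ir < 0 | c_ir > 1)) stop("c_ir must be in [0, 1]", call. = FALSE)
  epsilon * (1 - c_ir)
}

#' Certainty update
#'
#' After consuming an item with realised reward `e_ir`, certainty about
#' that type is updated with the same learning rate as the reward
#' expectation:
#' \deqn{c_{ir}' = (1-\lambda) c_{ir} +
#'   \lambda \left(1 - \min(1, |(e_{ir}-a_{ir})/e_{ir}|)\right)}
#' A zero realised reward leaves the relative discrepancy undefined; it is
#' then taken as 1, so certainty decays towards 0.
#'
#' @param c_ir current certainty in `[0, 1]`.
#' @param lambda learning rate in `[0, 1]`.
#' @param e_ir realised reward.
#' @param a_ir expected reward before the update.
#' @return Updated certainty in `[0, 1]`, vectorised.
#' @export
update_certainty <- function(c_ir, lambda, e_ir, a_ir) {
  if (any(c_ir < 0 | c_ir > 1)) stop("c_ir must be in [0, 1]", call. = FALSE)
  if (any(lambda < 0 | lambda > 1)) stop("lambda must be in [0, 1]",
                                         call. = FALSE)
  disc <- ifelse(e_ir == 0, 1, pmin(1, abs((e_ir - a_ir) / e_ir)))
  (1 - lambda) * c_ir + lambda * (1 - disc)
}

#' Processing skill
#'
#' A forager's skill for a resource type as a sigmoidal function of its
#' accumulated processing experience,
#' \deqn{s_{ir} = t_{ir}^{S_r} / (H_r^{S_r} + t_{ir}^{S_r})}
#' Skill is 0 without experience, 0.5 at `t = H` for every shape `S`, and
#' tends to 1 with practice. Larger `H` postpones, and larger `S` flattens,
#' the initial rise.
#'
#' @param t_ir processing experience, minutes, >= 0.
#' @param H practice time to half-maximal skill, > 0.
#' @param S integer sigmoid shape, typically 1--4.
#' @return Skill in `[0, 1)`, vectorised.
#' @export
#' @examples
#' skill(1, H = 1, S = 3) # 0.5 at t = H for any S
skill <- function(t_ir, H, S) {
  if (any(t_ir < 0)) stop("t_ir must be non-negative", call. = FALSE)
  if (any(H <= 0)) stop("H must be strictly positive", call. = FALSE)
  ts <- t_ir^S
  ts / (H^S + ts)
}

#' Realised reward of a consumed item
#'
#' \deqn{e_{ir} = Q_r s_{ir} + N(0, Z)}
#' the type's maximal quality scaled by current skill, plus Gaussian
#' environmental noise.
#'
#' @param Q resource quality (maximal per-item reward).
#' @param s skill in `[0, 1]`.
#' @param Z noise standard deviation (0 for deterministic rewards).
#' @param n number of draws (defaults to the common length of `Q` and `s`).
#' @return Numeric vector of realised rewards.
#' @export
reward_draw <- function(Q, s, Z = 0.005, n = max(length(Q), length(s))) {
  if (any(s < 0 | s > 1)) stop("skill must be in [0, 1]", call. = FALSE)
  if (Z < 0) stop("Z must be non-negative", call. = FALSE)
  Q * s + if (Z > 0) rnorm(n, 0, Z) else 0
}

#' Rescorla-Wagner reinforcement of expected reward
#'
#' \deqn{a_{ir}' = a_{ir} + \lambda_i (e_{ir} - a_{ir})}
#'
#' @param a_ir expected reward before the update.
#' @param lambda learning rate in `[0, 1]`.
#' @param e_ir realised reward.
#' @return Updated expectation, vectorised.
#' @export
reinforce <- function(a_ir, lambda, e_ir) {
  if (any(lambda < 0 | lambda > 1)) stop("lambda must be in [0, 1]",
                                         call. = FALSE)
  a_ir + lambda * (e_ir - a_ir)
}

#' Stimulus-enhancement probability
#'
#' \deqn{P_S = d\, \gamma_i}
#' where `d = 1` if the forager observed a neighbour consuming the assessed
#' resource type within the stimulus-enhancement memory window (30 min by
#' default) and 0 otherwise. Only one type is under stimulus enhancement at
#' a time.
#'
#' @param gamma stimulus-enhancement strength in `[0, 1]`.
#' @param stimulus_type type id currently under stimulus enhancement
#'   (`NA` for none).
#' @param type_id type id of the assessed item.
#' @param stimulus_time minute at which the stimulus was observed.
#' @param now current minute.
#' @param window memory window in minutes (default 30).
#' @return `gamma` or 0, vectorised over `type_id`.
#' @export
stimulus_enhancement_probability <- function(gamma, stimulus_type, type_id,
                                             stimulus_time = 0, now = 0,
                                             window = 30) {
  if (any(gamma < 0 | gamma > 1)) stop("gamma must be in [0, 1]",
                                       call. = FALSE)
  d <- !is.na(stimulus_type) & type_id == stimulus_type &
    (now - stimulus_time) <= window & (now - stimulus_time) >= 0
  ifelse(d, gamma, 0)
}

#' Effective observation time
#'
#' The time an observer actually spends watching a demonstrator,
#' `o_ik = min(tau_i, p_k)`: its own maximum observation time capped by the
#' time the demonstrator needs to finish its current action.
#'
#' @param tau observer's maximum observation duration, minutes.
#' @param p_k demonstrator's remaining action time, minutes.
#' @return `pmin(tau, p_k)`.
#' @export
effective_observation_time <- function(tau, p_k) pmin(tau, p_k)

#' Observational-learning gain in processing experience
#'
#' \deqn{\Delta t_{ir} = \max\left[K \frac{o_{ik}}{M} (t_{kr} - t_{ir}),
#'   0\right]}
#' Watching a more experienced demonstrator adds processing experience in
#' proportion to the effective observation time; watching an equally or
#' less experienced one yields nothing. Observation never provides
#' information about rewards (expectations and certainty are untouched) and
#' never alters the demonstrator.
#'
#' @param K effectiveness of observational learning.
#' @param o_ik effective observation time, in `[0, M]`.
#' @param M maximum processing time of one item, minutes.
#' @param t_kr demonstrator's processing experience for the observed type.
#' @param t_ir observer's processing experience for the observed type.
#' @return Non-negative experience increment, vectorised.
#' @export
#' @examples
#' observational_learning_gain(0.1, 0.5, 1, t_kr = 10, t_ir = 2) # 0.4
observational_learning_gain <- function(K, o_ik, M, t_kr, t_ir) {
  if (any(o_ik < 0 | o_ik > M)) stop("o_ik must lie in [0, M]",
                                     call. = FALSE)
  if (any(t_kr < 0) || any(t_ir < 0)) {
    stop("experience must be non-negative", call. = FALSE)
  }
  pmax(K * (o_ik / M) * (t_kr - t_ir), 0)
}

#' Environmental-expectation update at digestion
#'
#' At each digestion event the forager tunes the reference quality that
#' scales its selectivity: a stomach below capacity means it was too
#' selective and the expectation shrinks by a factor `(1 - phi)`; a full
#' stomach lets it grow by `(1 + phi)`.
#'
#' @param a_ie current environmental expectation, > 0.
#' @param phi update rate in `[0, 1]`.
#' @param stomach_full logical: was the stomach at capacity?
#' @return Updated expectation, vectorised.
#' @export
update_environment_expectation <- function(a_ie, phi, stomach_full) {
  if (any(a_ie <= 0)) stop("a_ie must be strictly positive", call. = FALSE)
  if (any(phi < 0 | phi > 1)) stop("phi must be in [0, 1]", call. = FALSE)
  ifelse(stomach_full, (1 + phi) * a_ie, (1 - phi) * a_ie)
}
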