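#' Parameters of the hybrid reinforcement-learning agent
#'
#' The agent has seven free parameters: stage-specific learning rates
#' (`alpha1`, `alpha2`) and softmax inverse temperatures (`beta1`, `beta2`),
#' the eligibility-trace weight `lambda` passing the second-stage reward
#' prediction error back to the first-stage value within a trial, the
#' perseveration bonus `pi` added to the value of repeating the previous
#' first-stage action, and the model-based weight `omega` mixing model-based
#' and model-free first-stage values (0 = purely model-free, 1 = purely
#' model-based).
#'
#' @param alpha1,alpha2 Learning rates in \[0, 1\].
#' @param beta1,beta2 Inverse temperatures, non-negative.
#' @param lambda Eligibility-trace weight in \[0, 1\].
#' @param pi Perseveration bonus (positive: stay bias; negative: switch bias).
#' @param omega Model-based weight in \[0, 1\].
#' @return An object of class `agent_parameters` (a named list).
#' @examples
#' agent_parameters(0.63, 0.49, 3.91, 4.71, 0.23, 0.21, 0.57)
#' @export
agent_parameters <- function(alpha1, alpha2, beta1, beta2, lambda, pi, omega) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
            lambda = lambda, pi = pi, omega = omega)
  bad <- !vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                 logical(1))
  if (any(bad)) abort(paste("Non-finite or non-scalar parameter(s):",
                            paste(names(p)[bad], collapse = ", ")))
  for (nm in c("alpha1", "alpha2", "lambda", "omega")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) abort(paste0("`", nm, "` must be in [0, 1]."))
  }
  if (p$beta1 < 0 || p$beta2 < 0) abort("Inverse temperatures must be >= 0.")
  structure(p, class = "agent_parameters")
}

#' Coerce a named vector, list or one-row data frame to agent parameters
#'
#' @param x Named numeric vector, list, or one-row data frame containing
#'   `alpha1`, `alpha2`, `beta1`, `beta2`, `lambda`, `pi`, `omega`.
#' @return An [agent_parameters()] object.
#' @export
as_agent_parameters <- function(x) {
  if (inherits(x, "agent_parameters")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort("Data-frame input must have exactly one row.")
    x <- as.list(x)
  }
  x <- as.list(x)
  missing <- setdiff(PARAM_NAMES, names(x))
  if (length(missing)) abort(paste("Missing parameter(s):",
                                   paste(missing, collapse = ", ")))
  do.call(agent_parameters, lapply(x[PARAM_NAMES], as.numeric))
}

#' @export
print.agent_parameters <- function(x, ...) {
  cat("<agent_parameters>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
as.double.agent_parameters <- function(x, ...) unlist(x)[PARAM_NAMES]

#' Initialize the agent's value state
#'
#' Holds the model-free Q-tables for the first stage (2 actions) and second
#' stage (2 states x 2 actions) plus the previous first-stage action needed by
#' the perseveration term. All Q values start at `q_init`; 0.5 (the midpoint
#' of the unit reward) is the default, and properties that should not depend
#' on the starting point can be checked at 0 as well.
#'
#' @param q_init Initial Q value for every state-action pair.
#' @return An object of class `value_state`.
#' @export
value_state <- function(q_init = 0.5) {
  structure(
    list(q1 = c(q_init, q_init),
         q2 = matrix(q_init, 2, 2, dimnames = list(c("B", "C"), c("a0", "a1"))),
         prev_first_action = NA_integer_),
    class = "value_state"
  )
}

#' Model-based first-stage values via the Bellman equation
#'
#' Each first-stage action is valued prospectively: the best attainable
#' second-stage value in its common destination, weighted by the common
#' transition probability, plus the best value in the other state weighted by
#' the rare probability.
#'
#' @param q2_mf 2 x 2 matrix of second-stage model-free values (rows `B`, `C`;
#'   columns actions 0, 1).
#' @param structure A [transition_structure()].
#' @return Numeric vector of length 2: model-based values of actions 0 and 1.
#' @examples
#' q2 <- rbind(B = c(0.8, 0.2), C = c(0.6, 0.4))
#' model_based_values(q2, transition_structure()) # 0.74, 0.66
#' @export
model_based_values <- function(q2_mf, structure = transition_structure()) {
  state_max <- c(B = max(q2_mf[1, ]), C = max(q2_mf[2, ]))
  vapply(1:2, function(a) {
    dest <- structure$common_destination[a]
    other <- setdiff(c("B", "C"), dest)
    structure$common_prob * state_max[[dest]] + structure$rare_prob * state_max[[other]]
  }, numeric(1))
}

#' Net first-stage values: weighted model-based/model-free mixture
#'
#' @param q1_mb Model-based values (length 2).
#' @param q1_mf Model-free values (length 2).
#' @param omega Model-based weight in \[0, 1\].
#' @return Numeric vector of length 2: `omega * q1_mb + (1 - omega) * q1_mf`.
#' @export
net_first_stage_values <- function(q1_mb, q1_mf, omega) {
  if (omega < 0 || omega > 1) abort("`omega` must be in [0, 1].")
  omega * q1_mb + (1 - omega) * q1_mf
}

softmax2 <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' First-stage softmax choice probabilities with perseveration
#'
#' `P(a)` is proportional to `exp(beta1 * (q_net[a] + pi * rep(a)))`, where
#' `rep(a)` is 1 if `a` repeats the previous first-stage action and 0
#' otherwise (0 for both actions on the first trial).
#'
#' @param q_net Net first-stage values (length 2).
#' @param beta1 Inverse temperature, >= 0.
#' @param pi Perseveration bonus.
#' @param prev_action Previous first-stage action (0/1) or `NA` before the
#'   first completed trial.
#' @return Probabilities of actions 0 and 1; they sum to 1.
#' @export
first_stage_choice_probs <- function(q_net, beta1, pi = 0, prev_action = NA) {
  if (beta1 < 0) abort("`beta1` must be >= 0.")
  rep_a <- if (is.na(prev_action)) c(0, 0) else as.numeric(0:1 == prev_action)
  softmax2(beta1 * (q_net + pi * rep_a))
}

#' Second-stage softmax choice probabilities
#'
#' At the second stage the net value equals the model-free value, so the
#' choice rule is a plain softmax over the visited state's two Q values.
#'
#' @param q2_state The visited state's two Q values.
#' @param beta2 Inverse temperature, >= 0.
#' @return Probabilities of actions 0 and 1; they sum to 1.
#' @export
second_stage_choice_probs <- function(q2_state, beta2) {
  if (beta2 < 0) abort("`beta2` must be >= 0.")
  softmax2(beta2 * q2_state)
}

#' Apply one trial's SARSA(lambda) value updates
#'
#' The chosen second-stage value moves toward the reward by `alpha2` times the
#' reward prediction error. The chosen first-stage value moves toward the
#' *pre-update* second-stage value by `alpha1`, plus an eligibility-trace term
#' `alpha1 * lambda` times the second-stage reward prediction error.
#' Eligibility traces do not carry over across trials. Unchosen entries are
#' untouched. An aborted trial leaves the state unchanged (including the
#' previous first-stage action, which is retained from the last completed
#' trial).
#'
#' @param state A [value_state()].
#' @param outcome A list or one-row data frame with `first_action`,
#'   `second_state`, `second_action`, `reward` (and optionally `aborted`).
#' @param params An [agent_parameters()] object.
#' @return The updated `value_state`.
#' @export
update_values <- function(state, outcome, params) {
  if (isTRUE(outcome$aborted)) return(state)
  a1 <- outcome$first_action
  s2 <- outcome$second_state
  a2 <- outcome$second_action
  r <- outcome$reward
  if (any(is.na(c(a1, s2, a2, r)))) abort("Completed outcome has missing fields.")
  q2_old <- state$q2[s2, a2 + 1L]
  rpe2 <- r - q2_old
  state$q2[s2, a2 + 1L] <- q2_old + params$alpha2 * rpe2
  state$q1[a1 + 1L] <- state$q1[a1 + 1L] +
    params$alpha1 * (q2_old - state$q1[a1 + 1L]) +
    params$alpha1 * params$lambda * rpe2
  state$prev_first_action <- as.integer(a1)
  state
}

#' Generate one trial: choose, transition, choose, collect reward, learn
#'
#' Combines the agent's choice rules with the task environment for a single
#' trial: the first action is sampled from the softmax over net values, the
#' transition and reward are sampled from the environment, the second action
#' from the second-stage softmax, and the value state is updated.
#'
#' @param state A [value_state()].
#' @param params An [agent_parameters()] object.
#' @param trajectory Reward-probability matrix from [generate_walks()].
#' @param structure A [transition_structure()].
#' @param t 0-based trial index.
#' @return A list with `trial` (a one-row tibble matching the session-log
#'   columns) and `state` (the updated `value_state`).
#' @export
act_and_learn <- function(state, params, trajectory,
                          structure = transition_structure(), t) {
  q1_mb <- model_based_values(state$q2, structure)
  q_net <- net_first_stage_values(q1_mb, state$q1, params$omega)
  p1 <- first_stage_choice_probs(q_net, params$beta1, params$pi,
                                 state$prev_first_action)
  a1 <- as.integer(runif(1) >= p1[1])
  tr <- sample_transition(a1, structure)
  p2 <- second_stage_choice_probs(state$q2[tr$second_state, ], params$beta2)
  a2 <- as.integer(runif(1) >= p2[1])
  r <- sample_reward(tr$second_state, a2, trajectory, t)
  outcome <- list(first_action = a1, second_state = tr$second_state,
                  second_action = a2, reward = r)
  list(
    trial = tibble::tibble(
      trial_index = as.integer(t), first_action = a1,
      transition_type = tr$transition_type, second_state = tr$second_state,
      second_action = a2, reward = r, aborted = FALSE
    ),
    state = update_values(state, outcome, params)
  )
}

# vectorized trial loop shared by simulate_session (same event stream as
# repeated act_and_learn calls, without per-trial tibble construction)
run_agent <- function(params, trajectory, structure, q_init) {
  n <- nrow(trajectory)
  a1 <- integer(n); a2 <- integer(n); rew <- integer(n)
  s2 <- character(n); ttype <- character(n)
  state <- value_state(q_init)
  dest_of <- structure$common_destination
  for (t in seq_len(n)) {
    q1_mb <- model_based_values(state$q2, structure)
    q_net <- net_first_stage_values(q1_mb, state$q1, params$omega)
    p1 <- first_stage_choice_probs(q_net, params$beta1, params$pi,
                                   state$prev_first_action)
    a <- as.integer(runif(1) >= p1[1])
    common <- runif(1) < structure$common_prob
    dest <- dest_of[a + 1L]
    s <- if (common) dest else setdiff(c("B", "C"), dest)
    p2 <- second_stage_choice_probs(state$q2[s, ], params$beta2)
    b <- as.integer(runif(1) >= p2[1])
    r <- as.integer(runif(1) < trajectory[t, trajectory_column(s, b)])
    a1[t] <- a; s2[t] <- s; a2[t] <- b; rew[t] <- r
    ttype[t] <- if (common) "common" else "rare"
    state <- update_values(state, list(first_action = a, second_state = s,
                                       second_action = b, reward = r), params)
  }
  tibble::tibble(trial_index = seq_len(n) - 1L, first_action = a1,
                 transition_type = ttype, second_state = s2,
                 second_action = a2, reward = rew, aborted = FALSE)
}

#' Simulate a full session of the two-stage task
#'
#' Runs a hybrid agent through `n_trials` trials of one random-walk condition,
#' generating fresh reward-probability trajectories. Simulated agents always
#' respond, so no trials are aborted; the `aborted` column exists so that
#' real-format logs share the same schema.
#'
#' @param params An [agent_parameters()] object (or coercible input).
#' @param condition `"narrow"` or `"wide"` reward-probability range.
#' @param n_trials Number of trials (201 per condition in the study design).
#' @param structure A [transition_structure()].
#' @param walk_config Optional [random_walk_config()]; defaults to the
#'   condition's preset.
#' @param q_init Initial Q value.
#' @param seed Optional integer seed; the same seed reproduces the session
#'   exactly.
#' @param subject_id,group_label Labels stored in the session log.
#' @return A tibble with one row per trial and columns `subject_id`,
#'   `group_label`, `condition`, `trial_index` (0-based), `first_action`,
#'   `transition_type`, `second_state`, `second_action`, `reward`, `aborted`.
#'   The reward-probability trajectory is attached as attribute
#'   `"trajectory"`.
#' @examples
#' p <- agent_parameters(0.63, 0.49, 3.91, 4.71, 0.23, 0.21, 0.57)
#' s <- simulate_session(p, "narrow", n_trials = 50, seed = 1)
#' head(s)
#' @export
simulate_session <- function(params, condition = c("narrow", "wide"),
                             n_trials = 201, structure = transition_structure(),
                             walk_config = NULL, q_init = 0.5, seed = NULL,
                             subject_id = "s1", group_label = NA_character_) {
  params <- as_agent_parameters(params)
  condition <- match.arg(condition)
  walk_config <- walk_config %||% random_walk_config(condition)
  with_seed_if(seed, {
    trajectory <- generate_walks(walk_config, n_trials)
    out <- run_agent(params, trajectory, structure, q_init)
    out <- dplyr::mutate(out, subject_id = subject_id,
                         group_label = group_label, condition = condition,
                         .before = 1)
    attr(out, "trajectory") <- trajectory
    out
  })
}
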