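#' Transition structure of the two-stage task
#'
#' The first-stage choice leads to one of two second-stage states, `"B"` or
#' `"C"`. Each first-stage action has a *common* destination reached with
#' probability `common_prob` (0.7 by default) and a *rare* destination reached
#' otherwise. Participants (and the model-based system of the agent) are
#' assumed to know these probabilities; they are fixed, not learned.
#'
#' @param common_prob Probability of the common transition; must exceed the
#'   rare probability, so `common_prob > 0.5`.
#' @param common_destination Character vector of length 2 mapping first-stage
#'   action 0 and action 1 to their common second-stage state; must be a
#'   permutation of `c("B", "C")`.
#' @return An object of class `transition_structure`.
#' @examples
#' transition_structure()
#' @export
transition_structure <- function(common_prob = 0.7,
                                 common_destination = c("B", "C")) {
  if (!is.numeric(common_prob) || length(common_prob) != 1 ||
      common_prob <= 0.5 || common_prob > 1) {
    abort("`common_prob` must be a single probability in (0.5, 1].")
  }
  if (!identical(sort(common_destination), c("B", "C"))) {
    abort("`common_destination` must be a permutation of c(\"B\", \"C\").")
  }
  structure(
    list(common_prob = common_prob,
         rare_prob = 1 - common_prob,
         common_destination = common_destination),
    class = "transition_structure"
  )
}

#' @export
print.transition_structure <- function(x, ...) {
  cat(sprintf(
    "<transition_structure> common %.0f%% / rare %.0f%%; action 0 -> %s, action 1 -> %s\n",
    100 * x$common_prob, 100 * x$rare_prob,
    x$common_destination[1], x$common_destination[2]))
  invisible(x)
}

#' Configuration of the reward-probability random walks
#'
#' Each of the four second-stage options (2 states x 2 actions) pays off with
#' a probability that drifts across trials as a Gaussian random walk with
#' reflecting boundaries. Two study conditions are used: a *narrow* range with
#' boundaries 0.25--0.75 and a *wide* range with boundaries 0.00--1.00; in
#' both, per-trial Gaussian steps have mean 0 and standard deviation 0.025.
#'
#' @param range `"narrow"` (bounds 0.25--0.75) or `"wide"` (bounds 0--1).
#' @param lower_bound,upper_bound Override the preset reflecting boundaries.
#' @param step_sd Standard deviation of the per-trial Gaussian step.
#' @param init Either `"uniform_random"` (each walk starts uniformly within
#'   the bounds) or a numeric vector of starting probabilities (recycled to 4).
#' @return An object of class `random_walk_config`.
#' @examples
#' random_walk_config("narrow")
#' random_walk_config("wide", init = 0.5)
#' @export
random_walk_config <- function(range = c("narrow", "wide"),
                               lower_bound = NULL, upper_bound = NULL,
                               step_sd = 0.025, init = "uniform_random") {
  range <- match.arg(range)
  preset <- if (range == "narrow") c(0.25, 0.75) else c(0, 1)
  lower_bound <- lower_bound %||% preset[1]
  upper_bound <- upper_bound %||% preset[2]
  if (!(lower_bound >= 0 && lower_bound < upper_bound && upper_bound <= 1)) {
    abort("Bounds must satisfy 0 <= lower_bound < upper_bound <= 1.")
  }
  if (!is.numeric(step_sd) || step_sd <= 0) abort("`step_sd` must be > 0.")
  if (is.numeric(init)) {
    init <- rep_len(init, 4)
    if (any(init < lower_bound | init > upper_bound)) {
      abort("Numeric `init` values must lie within the bounds.")
    }
  } else if (!identical(init, "uniform_random")) {
    abort("`init` must be \"uniform_random\" or a numeric vector.")
  }
  structure(
    list(range = range, lower_bound = lower_bound, upper_bound = upper_bound,
         step_sd = step_sd, init = init),
    class = "random_walk_config"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# mirror-reflect values into [lower, upper], re-applying until in range
reflect_into_bounds <- function(p, lower, upper) {
  repeat {
    over <- p > upper
    p[over] <- 2 * upper - p[over]
    under <- p < lower
    p[under] <- 2 * lower - p[under]
    if (!any(over) && !any(under)) return(p)
  }
}

#' Advance a reward probability by one random-walk step
#'
#' Adds a Gaussian step (mean 0, sd `config$step_sd`) and mirror-reflects the
#' proposal back into the configured bounds, re-applying the reflection until
#' the value is in range. Vectorized over `p`.
#'
#' @param p Current probability (or vector of probabilities) within bounds.
#' @param config A [random_walk_config()].
#' @param noise Optional pre-drawn Gaussian steps (same length as `p`); by
#'   default fresh `rnorm(length(p), 0, step_sd)` draws are used.
#' @return Updated probabilities, within bounds.
#' @examples
#' cfg <- random_walk_config("narrow")
#' step_random_walk(0.74, cfg, noise = 0.02) # reflects off 0.75 -> 0.74
#' @export
step_random_walk <- function(p, config, noise = NULL) {
  if (any(p < config$lower_bound | p > config$upper_bound)) {
    abort("`p` must lie within the configured bounds.")
  }
  noise <- noise %||% rnorm(length(p), 0, config$step_sd)
  reflect_into_bounds(p + noise, config$lower_bound, config$upper_bound)
}

#' Generate reward-probability trajectories for the four second-stage options
#'
#' Runs four mutually independent reflected Gaussian random walks, one per
#' (second-stage state, action) pair, for `n_trials` trials.
#'
#' @param config A [random_walk_config()].
#' @param n_trials Number of trials (rows); at least 1.
#' @param seed Optional integer seed for reproducible trajectories.
#' @return An `n_trials` x 4 numeric matrix with columns `B_0`, `B_1`, `C_0`,
#'   `C_1`. The attribute `"reflected"` is a logical matrix of the same shape
#'   marking steps whose pre-reflection proposal fell outside the bounds
#'   (first row is `FALSE`); the attribute `"config"` carries `config`.
#' @examples
#' traj <- generate_walks(random_walk_config("narrow"), 201, seed = 1)
#' range(traj) # within [0.25, 0.75]
#' @export
generate_walks <- function(config, n_trials, seed = NULL) {
  if (!is.numeric(n_trials) || n_trials < 1) abort("`n_trials` must be >= 1.")
  n_trials <- as.integer(n_trials)
  with_seed_if(seed, {
    probs <- matrix(NA_real_, n_trials, 4,
                    dimnames = list(NULL, c("B_0", "B_1", "C_0", "C_1")))
    reflected <- matrix(FALSE, n_trials, 4,
                        dimnames = list(NULL, colnames(probs)))
    p <- if (is.numeric(config$init)) config$init else
      runif(4, config$lower_bound, config$upper_bound)
    probs[1, ] <- p
    if (n_trials > 1) {
      for (t in 2:n_trials) {
        proposal <- p + rnorm(4, 0, config$step_sd)
        reflected[t, ] <- proposal < config$lower_bound | proposal > config$upper_bound
        p <- reflect_into_bounds(proposal, config$lower_bound, config$upper_bound)
        probs[t, ] <- p
      }
    }
    attr(probs, "reflected") <- reflected
    attr(probs, "config") <- config
    probs
  })
}

#' Sample second-stage states for first-stage choices
#'
#' Each chosen first-stage action leads to its common destination with
#' probability `structure$common_prob` and to the other state otherwise.
#' Vectorized over `first_action`.
#'
#' @param first_action Integer vector of first-stage actions (0 or 1).
#' @param structure A [transition_structure()].
#' @return A tibble with columns `second_state` (`"B"`/`"C"`) and
#'   `transition_type` (`"common"`/`"rare"`), one row per input action.
#' @examples
#' set.seed(1)
#' table(sample_transition(rep(0L, 1000), transition_structure())$transition_type)
#' @export
sample_transition <- function(first_action, structure = transition_structure()) {
  if (!all(first_action %in% c(0L, 1L))) {
    abort("`first_action` must contain only 0 and 1.")
  }
  common <- runif(length(first_action)) < structure$common_prob
  dest <- structure$common_destination[first_action + 1L]
  other <- ifelse(dest == "B", "C", "B")
  tibble::tibble(
    second_state = ifelse(common, dest, other),
    transition_type = ifelse(common, "common", "rare")
  )
}

# column of the trajectory matrix for a (state, action) pair
trajectory_column <- function(second_state, second_action) {
  (second_state == "C") * 2L + second_action + 1L
}

#' Sample rewards for second-stage choices
#'
#' Draws a Bernoulli reward with the probability that the chosen option's
#' random walk holds at trial `t`. Vectorized over all arguments.
#'
#' @param second_state `"B"` or `"C"` (vector allowed).
#' @param second_action Second-stage action, 0 or 1 (vector allowed).
#' @param trajectory Matrix from [generate_walks()].
#' @param t 0-based trial index (vector allowed); must be `< nrow(trajectory)`.
#' @return Integer vector of rewards in `{0, 1}`.
#' @export
sample_reward <- function(second_state, second_action, trajectory, t) {
  if (any(t < 0 | t >= nrow(trajectory))) {
    abort("`t` must be a 0-based trial index within the trajectory.")
  }
  if (!all(second_action %in% c(0L, 1L)) || !all(second_state %in% c("B", "C"))) {
    abort("Invalid second-stage state or action.")
  }
  idx <- cbind(t + 1L, trajectory_column(second_state, second_action))
  as.integer(runif(length(second_state)) < trajectory[idx])
}
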