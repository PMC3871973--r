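test_that("Bellman model-based values weight state maxima by transition probability", {
  q2 <- rbind(B = c(0.8, 0.2), C = c(0.6, 0.4))
  expect_equal(model_based_values(q2, transition_structure()), c(0.74, 0.66))
  # equal state maxima make both actions equally valuable
  q2_eq <- rbind(B = c(0.7, 0.1), C = c(0.3, 0.7))
  mb <- model_based_values(q2_eq, transition_structure())
  expect_equal(mb[1], mb[2])
  # swapped common destinations swap the action values
  swapped <- transition_structure(common_destination = c("C", "B"))
  expect_equal(model_based_values(q2, swapped), c(0.66, 0.74))
})

test_that("net first-stage values interpolate between model-based and model-free", {
  mb <- c(0.74, 0.66); mf <- c(0.5, 0.5)
  expect_equal(net_first_stage_values(mb, mf, 1), mb)
  expect_equal(net_first_stage_values(mb, mf, 0), mf)
  expect_equal(net_first_stage_values(mb, mf, 0.57), c(0.6368, 0.5912))
})

test_that("first-stage softmax with perseveration matches closed forms", {
  expect_equal(first_stage_choice_probs(c(0.9, 0.1), beta1 = 0), c(0.5, 0.5))
  # equal values, perseveration on action 0: P(0) = 1/(1+exp(-beta1*pi))
  p <- first_stage_choice_probs(c(0.4, 0.4), beta1 = 5, pi = 0.2,
                                prev_action = 0)
  expect_equal(p[1], 1 / (1 + exp(-1)), tolerance = 1e-10)
  # value difference 0.08 at beta1 = 3.91
  p <- first_stage_choice_probs(c(0.74, 0.66), beta1 = 3.91, pi = 0)
  expect_equal(p[1], 1 / (1 + exp(-3.91 * 0.08)), tolerance = 1e-10)
  expect_equal(sum(p), 1)
})

test_that("second-stage softmax matches the two-option closed form", {
  expect_equal(second_stage_choice_probs(c(1, 0), beta2 = 0), c(0.5, 0.5))
  expect_equal(second_stage_choice_probs(c(0.3, 0.3), beta2 = 7), c(0.5, 0.5))
  p <- second_stage_choice_probs(c(1, 0), beta2 = 4.71)
  expect_equal(p[1], 1 / (1 + exp(-4.71)), tolerance = 1e-10)
})

test_that("SARSA(lambda) updates follow the hand-unrolled equations", {
  outcome <- list(first_action = 0L, second_state = "B", second_action = 0L,
                  reward = 1L)
  # zero learning rates leave the Q-tables unchanged
  s <- update_values(value_state(0.5), outcome,
                     default_params(alpha1 = 0, alpha2 = 0))
  expect_equal(s$q1, c(0.5, 0.5))
  expect_equal(as.numeric(s$q2), rep(0.5, 4))
  expect_equal(s$prev_first_action, 0L)
  # hand-unrolled one-step update, both corrections use pre-update values
  s <- update_values(value_state(0.5), outcome,
                     default_params(alpha1 = 0.5, alpha2 = 0.5, lambda = 1))
  expect_equal(unname(s$q2["B", 1]), 0.75)
  expect_equal(s$q1[1], 0.5 + 0.5 * (0.5 - 0.5) + 0.5 * 1 * (1 - 0.5))
  # zero prediction errors change nothing, for any rates
  s0 <- value_state(1)
  s <- update_values(s0, outcome, default_params(alpha1 = 0.9, alpha2 = 0.7,
                                                 lambda = 0.4))
  expect_equal(s$q1, s0$q1)
  expect_equal(s$q2, s0$q2)
  # unchosen entries are untouched
  s <- update_values(value_state(0.5), outcome, default_params())
  expect_equal(s$q1[2], 0.5)
  expect_equal(as.numeric(s$q2[, 2]), c(0.5, 0.5))
  expect_equal(as.numeric(s$q2["C", ]), c(0.5, 0.5))
  # aborted outcomes skip the update and retain the previous action
  s$prev_first_action <- 1L
  s2 <- update_values(s, list(aborted = TRUE), default_params())
  expect_identical(s2, s)
})

test_that("Q values stay in [0, 1] with unit rewards (convex updates)", {
  p <- default_params(alpha1 = 0.9, alpha2 = 0.95, lambda = 1)
  for (seed in 1:3) {
    sess <- simulate_session(p, "wide", n_trials = 300, seed = seed)
    state <- value_state(0.5)
    in_range <- TRUE
    for (i in seq_len(nrow(sess))) {
      state <- update_values(state, as.list(sess[i, ]), p)
      in_range <- in_range && all(state$q1 >= 0, state$q1 <= 1,
                                  state$q2 >= 0, state$q2 <= 1)
    }
    expect_true(in_range)
  }
})

test_that("simulated sessions are reproducible and schema-complete", {
  p <- default_params()
  a <- simulate_session(p, "narrow", n_trials = 100, seed = 9)
  b <- simulate_session(p, "narrow", n_trials = 100, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "trajectory"), attr(b, "trajectory"))
  expect_equal(nrow(a), 100)
  expect_equal(a$trial_index, 0:99)
  expect_false(any(a$aborted))
  # transition labels are consistent with destinations
  dest <- c("B", "C")[a$first_action + 1]
  expect_identical(a$transition_type == "common", a$second_state == dest)
})

test_that("simulate_session reproduces a manual act_and_learn loop", {
  p <- default_params()
  sess <- simulate_session(p, "narrow", n_trials = 40, seed = 77)
  manual <- withr::with_seed(77, {
    traj <- generate_walks(random_walk_config("narrow"), 40)
    state <- value_state(0.5)
    rows <- vector("list", 40)
    for (t in 0:39) {
      step <- act_and_learn(state, p, traj, transition_structure(), t)
      rows[[t + 1]] <- step$trial
      state <- step$state
    }
    dplyr::bind_rows(rows)
  })
  attr(sess, "trajectory") <- NULL
  expect_equal(as.data.frame(sess[names(manual)]), as.data.frame(manual))
})

test_that("uniform choice at zero inverse temperatures", {
  p <- default_params(beta1 = 0, beta2 = 0, pi = 0)
  sess <- simulate_session(p, "narrow", n_trials = 2000, seed = 4)
  expect_equal(mean(sess$first_action), 0.5, tolerance = 0.05)
  expect_equal(mean(sess$second_action), 0.5, tolerance = 0.05)
})

test_that("positive perseveration increases overall stay probability", {
  stay_rate <- function(pi_val, seed) {
    sess <- simulate_session(default_params(pi = pi_val, omega = 0.5),
                             "narrow", n_trials = 201, seed = seed)
    mean(diff(sess$first_action) == 0)
  }
  with_pi <- mean(vapply(1:6, function(s) stay_rate(1.5, s), numeric(1)))
  without <- mean(vapply(1:6, function(s) stay_rate(0, s), numeric(1)))
  expect_gt(with_pi, without)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(agent_parameters(1.2, 0.5, 3, 3, 0.5, 0, 0.5), "alpha1")
  expect_error(agent_parameters(0.5, 0.5, -1, 3, 0.5, 0, 0.5), ">= 0")
  expect_error(as_agent_parameters(c(alpha1 = 0.5)), "Missing parameter")
  p <- as_agent_parameters(data.frame(alpha1 = 0.1, alpha2 = 0.2, beta1 = 1,
                                      beta2 = 2, lambda = 0.3, pi = -0.1,
                                      omega = 0.9))
  expect_s3_class(p, "agent_parameters")
  expect_equal(as.double(p), c(alpha1 = 0.1, alpha2 = 0.2, beta1 = 1,
                               beta2 = 2, lambda = 0.3, pi = -0.1, omega = 0.9))
})
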