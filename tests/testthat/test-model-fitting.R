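test_that("likelihood replay matches the independent step-by-step oracle", {
  # hand-built 3-trial sequence at non-degenerate parameters
  sess3 <- make_session(
    first_action = c(0, 1, 0),
    transition_type = c("common", "rare", "common"),
    second_state = c("B", "B", "B"),
    second_action = c(0, 1, 0),
    reward = c(1, 0, 1))
  p <- default_params()
  expect_equal(negative_log_likelihood(p, sess3),
               oracle_nll(unclass(p), sess3), tolerance = 1e-12)
  # longer random event sequences, several parameter vectors
  for (seed in 1:5) {
    sess <- random_session(60, seed)
    pars <- withr::with_seed(seed, default_params(
      alpha1 = runif(1), alpha2 = runif(1), beta1 = runif(1, 0, 10),
      beta2 = runif(1, 0, 10), lambda = runif(1), pi = runif(1, -1, 1),
      omega = runif(1)))
    expect_equal(negative_log_likelihood(pars, sess),
                 oracle_nll(unclass(pars), sess), tolerance = 1e-12)
  }
  # replay through the R-level update/probability functions agrees too
  r_replay <- function(params, session, q_init = 0.5) {
    state <- value_state(q_init)
    nll <- 0
    for (i in seq_len(nrow(session))) {
      row <- as.list(session[i, ])
      mb <- model_based_values(state$q2)
      qn <- net_first_stage_values(mb, state$q1, params$omega)
      p1 <- first_stage_choice_probs(qn, params$beta1, params$pi,
                                     state$prev_first_action)
      p2 <- second_stage_choice_probs(state$q2[row$second_state, ],
                                      params$beta2)
      nll <- nll - log(p1[row$first_action + 1]) -
        log(unname(p2[row$second_action + 1]))
      state <- update_values(state, row, params)
    }
    nll
  }
  sess <- random_session(40, 99)
  expect_equal(negative_log_likelihood(p, sess), r_replay(p, sess),
               tolerance = 1e-12)
})

test_that("zero inverse temperatures give the chance-level closed form", {
  p0 <- default_params(beta1 = 0, beta2 = 0)
  for (n in c(1, 3, 57)) {
    sess <- random_session(n, n)
    expect_equal(negative_log_likelihood(p0, sess), 2 * n * log(2),
                 tolerance = 1e-12)
  }
})

test_that("symmetric initial values make the first trial chance level", {
  sess1 <- make_session(0, "common", "B", 0, 1)
  p <- default_params(beta1 = 2, beta2 = 2, pi = 0, omega = 0.5)
  expect_equal(negative_log_likelihood(p, sess1), -2 * log(0.5),
               tolerance = 1e-12)
})

test_that("aborted trials contribute no likelihood and no updates", {
  completed <- make_session(
    first_action = c(0, 1, 1),
    transition_type = c("common", "rare", "common"),
    second_state = c("B", "B", "C"),
    second_action = c(1, 0, 0),
    reward = c(1, 0, 1))
  with_abort <- make_session(
    first_action = c(0, NA, 1, 1),
    transition_type = c("common", NA, "rare", "common"),
    second_state = c("B", NA, "B", "C"),
    second_action = c(1, NA, 0, 0),
    reward = c(1, NA, 0, 1))
  p <- default_params(pi = 0) # perseveration-free: retention is irrelevant
  expect_equal(negative_log_likelihood(p, with_abort),
               negative_log_likelihood(p, completed), tolerance = 1e-12)
  # with perseveration, the previous action is retained across the gap
  p_pi <- default_params(pi = 0.8)
  expect_equal(negative_log_likelihood(p_pi, with_abort),
               oracle_nll(unclass(p_pi), with_abort), tolerance = 1e-12)
  all_aborted <- make_session(c(NA, NA), c(NA, NA), c(NA, NA), c(NA, NA),
                              c(NA, NA))
  expect_error(negative_log_likelihood(p, all_aborted), "completed")
})

test_that("likelihood ignores trial-order metadata that preserves the event sequence", {
  sess <- random_session(30, 7)
  p <- default_params()
  relabeled <- sess
  relabeled$trial_index <- relabeled$trial_index * 10L  # same order, new labels
  shuffled <- relabeled[withr::with_seed(1, sample(nrow(relabeled))), ]
  expect_equal(negative_log_likelihood(p, shuffled),
               negative_log_likelihood(p, sess), tolerance = 1e-12)
})

test_that("grid search returns candidates sorted by ascending NLL", {
  sess <- simulate_session(default_params(), "narrow", 100, seed = 2)
  single <- grid_spec(alpha1 = 0.5, alpha2 = 0.5, beta1 = 3, beta2 = 3,
                      lambda = 0.3, pi = 0, omega = 0.5)
  g1 <- grid_search(sess, single)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$nll, negative_log_likelihood(as_agent_parameters(
    g1[1, 1:7]), sess), tolerance = 1e-12)
  g <- grid_search(sess, grid_spec(alpha1 = c(0.2, 0.6), alpha2 = c(0.2, 0.6),
                                   beta1 = c(2, 6), beta2 = c(2, 6),
                                   lambda = c(0.2, 0.8), pi = c(0, 0.3),
                                   omega = c(0.2, 0.8)))
  expect_true(!is.unsorted(g$nll))
  expect_equal(nrow(g), 2^7)
})

test_that("the factorial grid is capped by deterministic thinning", {
  g <- grid_spec()
  thinned <- twostepr:::thin_grid_values(g$values, g$max_points)
  expect_lte(prod(vapply(thinned, length, integer(1))), g$max_points)
  expect_equal(thinned$alpha1, c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(thinned$beta1, c(1, 3, 5, 8, 12)) # short lists untouched
  # thinned values are a subset of the originals
  expect_true(all(thinned$omega %in% g$values$omega))
})

test_that("the generating parameters rank highly in the grid", {
  truth <- default_params(alpha1 = 0.5, alpha2 = 0.5, beta1 = 5, beta2 = 5,
                          lambda = 0.5, pi = 0, omega = 0.5)
  sess <- simulate_session(truth, "narrow", 201, seed = 31)
  grid <- grid_spec(alpha1 = c(0.1, 0.5, 0.9), alpha2 = c(0.1, 0.5, 0.9),
                    beta1 = c(1, 5, 12), beta2 = c(1, 5, 12),
                    lambda = c(0.1, 0.5, 0.9), pi = c(-0.5, 0, 0.5),
                    omega = c(0.1, 0.5, 0.9))
  g <- grid_search(sess, grid)
  truth_row <- which(g$alpha1 == 0.5 & g$alpha2 == 0.5 & g$beta1 == 5 &
                       g$beta2 == 5 & g$lambda == 0.5 & g$pi == 0 &
                       g$omega == 0.5)
  expect_lte(truth_row, ceiling(nrow(g) / 10))
})

test_that("coordinate-descent mode finds a competitive candidate", {
  sess <- simulate_session(default_params(), "narrow", 150, seed = 13)
  gf <- grid_search(sess)
  gc <- grid_search(sess, method = "coordinate")
  expect_true(!is.unsorted(gc$nll))
  expect_lt(gc$nll[1], gf$nll[1] + 5)
})

test_that("refinement descends from its starts and respects bounds", {
  truth <- default_params()
  sess <- simulate_session(truth, "narrow", 201, seed = 17)
  fit <- refine_fit(sess, tibble::as_tibble(as.list(unclass(truth))))
  expect_s3_class(fit, "hybrid_fit")
  expect_lte(fit$neg_log_likelihood,
             negative_log_likelihood(truth, sess) + 1e-9)
  b <- fit_bounds()
  est <- as.double(fit$params)
  expect_true(all(est >= b$lower - 1e-9 & est <= b$upper + 1e-9))
  # degenerate one-trial session still yields an in-bounds result
  fit1 <- refine_fit(make_session(0, "common", "B", 0, 1),
                     tibble::as_tibble(as.list(unclass(truth))))
  expect_true(all(as.double(fit1$params) >= b$lower - 1e-9))
  expect_equal(fit1$n_trials_used, 1)
})

test_that("tidy and glance summarize fits in broom style", {
  sess <- simulate_session(default_params(), "narrow", 60, seed = 23)
  fit <- refine_fit(sess, tibble::as_tibble(as.list(unclass(default_params()))))
  td <- tidy(fit)
  expect_equal(td$term, c("alpha1", "alpha2", "beta1", "beta2", "lambda",
                          "pi", "omega"))
  expect_type(td$estimate, "double")
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_trials_used, 60)
  expect_equal(gl$condition, "narrow")
})

test_that("subject fits use 12 starts per condition and do not cross-talk", {
  p <- default_params()
  narrow <- simulate_session(p, "narrow", 120, seed = 41)
  wide <- simulate_session(p, "wide", 120, seed = 42)
  small_grid <- grid_spec(alpha1 = c(0.3, 0.7), alpha2 = c(0.3, 0.7),
                          beta1 = c(3, 6), beta2 = c(3, 6),
                          lambda = c(0.2, 0.6), pi = c(0, 0.2),
                          omega = c(0.3, 0.7))
  fits <- fit_subject(narrow, wide, grid = small_grid)
  expect_equal(fits$narrow$n_starts, 12)
  expect_equal(fits$wide$n_starts, 12)
  # swapping the condition inputs swaps the results exactly
  swapped <- fit_subject(wide, narrow, grid = small_grid)
  expect_equal(as.double(swapped$narrow$params), as.double(fits$wide$params))
  expect_equal(swapped$narrow$neg_log_likelihood, fits$wide$neg_log_likelihood)
})
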