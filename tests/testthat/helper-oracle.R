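# Independent step-by-step likelihood replay, coded directly from the model
# equations with naive arithmetic (explicit softmax fractions, data-frame
# indexing). Deliberately shares no code with the package's likelihood path;
# used as the oracle for replay tests.
oracle_nll <- function(par, session, common_prob = 0.7,
                       common_dest = c("B", "C"), q_init = 0.5) {
  q1 <- c(q_init, q_init)                       # first-stage MF values
  q2 <- list(B = c(q_init, q_init), C = c(q_init, q_init))
  prev_a1 <- NULL
  total <- 0
  session <- session[order(session$trial_index), ]
  for (i in seq_len(nrow(session))) {
    row <- session[i, ]
    if (isTRUE(row$aborted) || is.na(row$first_action) ||
        is.na(row$second_action)) next
    # Bellman model-based values from current second-stage MF values
    mb <- numeric(2)
    for (a in 0:1) {
      dest <- common_dest[a + 1]
      other <- if (dest == "B") "C" else "B"
      mb[a + 1] <- common_prob * max(q2[[dest]]) +
        (1 - common_prob) * max(q2[[other]])
    }
    qnet <- par$omega * mb + (1 - par$omega) * q1
    rep_bonus <- c(0, 0)
    if (!is.null(prev_a1)) rep_bonus[prev_a1 + 1] <- par$pi
    z <- exp(par$beta1 * (qnet + rep_bonus))
    p1 <- z[row$first_action + 1] / (z[1] + z[2])
    z2 <- exp(par$beta2 * q2[[row$second_state]])
    p2 <- z2[row$second_action + 1] / (z2[1] + z2[2])
    total <- total - log(p1) - log(p2)
    # SARSA(lambda) updates, all right-hand values pre-update
    q2_chosen <- q2[[row$second_state]][row$second_action + 1]
    delta2 <- row$reward - q2_chosen
    q2[[row$second_state]][row$second_action + 1] <- q2_chosen + par$alpha2 * delta2
    q1[row$first_action + 1] <- q1[row$first_action + 1] +
      par$alpha1 * (q2_chosen - q1[row$first_action + 1]) +
      par$alpha1 * par$lambda * delta2
    prev_a1 <- row$first_action
  }
  total
}

# build a session tibble from parallel event vectors (NA fields => aborted)
make_session <- function(first_action, transition_type, second_state,
                         second_action, reward, condition = "narrow",
                         subject_id = "s1") {
  tibble::tibble(
    subject_id = subject_id, group_label = NA_character_,
    condition = condition,
    trial_index = seq_along(first_action) - 1L,
    first_action = as.integer(first_action),
    transition_type = transition_type,
    second_state = second_state,
    second_action = as.integer(second_action),
    reward = as.integer(reward),
    aborted = is.na(first_action) | is.na(second_action)
  )
}

default_params <- function(...) {
  p <- list(alpha1 = 0.63, alpha2 = 0.49, beta1 = 3.91, beta2 = 4.71,
            lambda = 0.23, pi = 0.21, omega = 0.57)
  p[names(list(...))] <- list(...)
  as_agent_parameters(p)
}

# random completed session for property tests (events need not be agent-like)
random_session <- function(n, seed) {
  withr::with_seed(seed, {
    a1 <- sample(0:1, n, replace = TRUE)
    tr <- sample(c("common", "rare"), n, replace = TRUE, prob = c(0.7, 0.3))
    dest <- c("B", "C")[a1 + 1]
    s2 <- ifelse(tr == "common", dest, ifelse(dest == "B", "C", "B"))
    make_session(a1, tr, s2, sample(0:1, n, replace = TRUE),
                 sample(0:1, n, replace = TRUE))
  })
}
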