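#' Specify a synthetic agent group
#'
#' Each parameter is drawn independently from a normal distribution truncated
#' to its fitting bounds (sd = 0 gives a fixed value). Defaults for the means
#' come from the published group medians ([agent_presets()], narrow range);
#' default standard deviations are set so that typical draws roughly span the
#' published 25th--75th percentile ranges.
#'
#' @param label Group label carried through sessions and summaries.
#' @param n_subjects Number of agents in the group.
#' @param means Named numeric vector of the seven parameter means, or a
#'   preset name understood by [preset_parameters()].
#' @param sds Named numeric vector of standard deviations; 0 fixes a
#'   parameter at its mean and `Inf` draws it uniformly over its bounds.
#' @param bounds A [fit_bounds()]; draws are truncated to these boxes.
#' @return An object of class `group_spec`.
#' @examples
#' group_spec("younger", 10, means = "younger_low")
#' @export
group_spec <- function(label, n_subjects,
                       means = "younger_low",
                       sds = c(alpha1 = 0.2, alpha2 = 0.2, beta1 = 2.5,
                               beta2 = 1.5, lambda = 0.25, pi = 0.12,
                               omega = 0.2),
                       bounds = fit_bounds()) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  if (is.character(means)) means <- unlist(preset_parameters(means))
  means <- means[PARAM_NAMES]; sds <- sds[PARAM_NAMES]
  if (anyNA(means) || anyNA(sds)) abort("`means` and `sds` must cover all 7 parameters.")
  if (any(sds < 0)) abort("`sds` must be >= 0.")
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 means = means, sds = sds, bounds = bounds),
            class = "group_spec")
}

# inverse-CDF draw from a normal truncated to [lower, upper];
# sd = 0 -> the mean exactly; sd = Inf -> uniform over the bounds
rtruncnorm_vec <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  if (is.infinite(sd)) return(runif(n, lower, upper))
  lo <- pnorm((lower - mean) / sd)
  hi <- pnorm((upper - mean) / sd)
  qnorm(runif(n, lo, hi)) * sd + mean
}

#' Draw agent parameters for a synthetic group
#'
#' @param spec A [group_spec()].
#' @param n Number of parameter vectors to draw (default: the group size).
#' @param seed Optional integer seed.
#' @return A tibble with `n` rows and the seven parameter columns.
#' @export
sample_agent_parameters <- function(spec, n = spec$n_subjects, seed = NULL) {
  with_seed_if(seed, {
    draws <- lapply(PARAM_NAMES, function(nm) {
      rtruncnorm_vec(n, spec$means[[nm]], spec$sds[[nm]],
                     spec$bounds$lower[[nm]], spec$bounds$upper[[nm]])
    })
    tibble::as_tibble(stats::setNames(draws, PARAM_NAMES))
  })
}

#' Specify a synthetic cohort
#'
#' A cohort is one or more groups of agents, each of whom performs one
#' session per random-walk condition (201 trials each in the study design).
#' Walks are independently seeded per subject and condition by default; with
#' `yoked_walks = TRUE` every subject experiences the same trajectories
#' within a condition (useful for variance-reduction experiments).
#'
#' @param groups A list of [group_spec()] objects (a single one is accepted).
#' @param n_trials Trials per condition, at least 2.
#' @param conditions Conditions each subject performs.
#' @param master_seed Integer seed from which all randomness derives.
#' @param yoked_walks Share reward-probability trajectories across subjects.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, n_trials = 201,
                        conditions = c("narrow", "wide"),
                        master_seed = 1, yoked_walks = FALSE) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  if (!length(groups) || !all(vapply(groups, inherits, logical(1), "group_spec"))) {
    abort("`groups` must be a list of group_spec objects.")
  }
  if (n_trials < 2) abort("`n_trials` must be >= 2.")
  conditions <- match.arg(conditions, c("narrow", "wide"), several.ok = TRUE)
  structure(list(groups = groups, n_trials = as.integer(n_trials),
                 conditions = conditions, master_seed = as.integer(master_seed),
                 yoked_walks = yoked_walks),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of simulated sessions
#'
#' For every subject: draw one parameter vector from the group distribution,
#' then simulate one session per condition with independently seeded reward
#' walks. Fully reproducible from the spec's `master_seed`.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort`: a list with `sessions` (all trial
#'   rows bound together) and `truth` (one row per subject: `subject_id`,
#'   `group_label` and the seven true parameters).
#' @examples
#' g <- group_spec("demo", 2, means = "younger_low")
#' ch <- generate_cohort(cohort_spec(g, n_trials = 50, master_seed = 7))
#' nrow(ch$sessions) # 2 subjects x 2 conditions x 50 trials
#' @export
generate_cohort <- function(spec) {
  n_total <- sum(vapply(spec$groups, `[[`, integer(1), "n_subjects"))
  n_cond <- length(spec$conditions)
  # one seed per group draw + one per subject-condition session (+ yoked walks)
  seeds <- derive_seeds(spec$master_seed,
                        length(spec$groups) + n_total * n_cond + n_cond)
  yoked_traj <- NULL
  if (spec$yoked_walks) {
    yoked_traj <- lapply(seq_len(n_cond), function(k) {
      generate_walks(random_walk_config(spec$conditions[k]), spec$n_trials,
                     seed = seeds[length(seeds) - n_cond + k])
    })
    names(yoked_traj) <- spec$conditions
  }
  truth <- list(); sessions <- list()
  subj <- 0L; s_i <- length(spec$groups)
  for (g in seq_along(spec$groups)) {
    gs <- spec$groups[[g]]
    pars <- sample_agent_parameters(gs, seed = seeds[g])
    for (i in seq_len(gs$n_subjects)) {
      subj <- subj + 1L
      id <- sprintf("s%03d", subj)
      truth[[subj]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = id, group_label = gs$label), pars[i, ])
      for (cond in spec$conditions) {
        s_i <- s_i + 1L
        sess <- if (spec$yoked_walks) {
          with_seed_if(seeds[s_i], simulate_yoked(
            as_agent_parameters(pars[i, ]), cond, yoked_traj[[cond]], id, gs$label))
        } else {
          simulate_session(as_agent_parameters(pars[i, ]), cond,
                           n_trials = spec$n_trials, seed = seeds[s_i],
                           subject_id = id, group_label = gs$label)
        }
        sessions[[s_i - length(spec$groups)]] <- sess
      }
    }
  }
  structure(list(sessions = dplyr::bind_rows(sessions),
                 truth = dplyr::bind_rows(truth), spec = spec),
            class = "cohort")
}

# simulate against a fixed, shared trajectory (yoked-walk mode)
simulate_yoked <- function(params, condition, trajectory, subject_id, group_label) {
  state <- value_state()
  n <- nrow(trajectory)
  trials <- vector("list", n)
  for (t in seq_len(n) - 1L) {
    step <- act_and_learn(state, params, trajectory, transition_structure(), t)
    trials[[t + 1L]] <- step$trial
    state <- step$state
  }
  out <- dplyr::bind_rows(trials)
  dplyr::mutate(out, subject_id = subject_id, group_label = group_label,
                condition = condition, .before = 1)
}

#' Parameter-recovery experiment on a synthetic cohort
#'
#' Fits every subject-by-condition session with the grid + multistart
#' procedure, pairs each subject's true parameters with the mean of their two
#' per-condition estimates, and summarizes recovery per parameter
#' (Pearson correlation, bias, RMSE) plus recovered medians per group.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param grid A [grid_spec()].
#' @param bounds A [fit_bounds()].
#' @param n_starts Refinement starts per session.
#' @return An object of class `recovery_report`: `by_parameter` (correlation,
#'   bias, RMSE per parameter), `merged` (true and recovered values per
#'   subject), `fits` (per-session fits), `group_medians`, `n_converged`.
#' @export
parameter_recovery <- function(cohort, grid = grid_spec(),
                               bounds = fit_bounds(), n_starts = 12) {
  if (nrow(cohort$truth) < 2) abort("Recovery needs at least 2 subjects.")
  fits <- fit_sessions(cohort$sessions, grid, bounds, n_starts)
  recovered <- dplyr::summarise(
    dplyr::group_by(fits, .data$subject_id),
    dplyr::across(dplyr::all_of(PARAM_NAMES), mean),
    converged_all = all(.data$converged), .groups = "drop")
  merged <- dplyr::inner_join(cohort$truth, recovered, by = "subject_id",
                              suffix = c("_true", "_rec"))
  unfitted <- setdiff(cohort$truth$subject_id, recovered$subject_id)
  by_parameter <- purrr::map_dfr(PARAM_NAMES, function(nm) {
    tr <- merged[[paste0(nm, "_true")]]
    rc <- merged[[paste0(nm, "_rec")]]
    tibble::tibble(
      parameter = nm,
      correlation = if (sd(tr) > 0 && sd(rc) > 0) cor(tr, rc) else NA_real_,
      bias = mean(rc - tr),
      rmse = sqrt(mean((rc - tr)^2)),
      median_abs_error = median(abs(rc - tr)))
  })
  group_medians <- dplyr::summarise(
    dplyr::group_by(dplyr::inner_join(fits,
                                      cohort$truth[c("subject_id", "group_label")],
                                      by = c("subject_id", "group_label")),
                    .data$group_label),
    dplyr::across(dplyr::all_of(PARAM_NAMES), median), .groups = "drop")
  structure(list(by_parameter = by_parameter, merged = merged, fits = fits,
                 group_medians = group_medians,
                 n_converged = sum(fits$converged),
                 unfitted_subjects = unfitted),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d subjects, %d/%d session fits converged\n",
              nrow(x$merged), x$n_converged, nrow(x$fits)))
  print(x$by_parameter)
  invisible(x)
}

#' @rdname recovery_report_tidiers
#' @export
tidy.recovery_report <- function(x, ...) x$by_parameter

#' Tidiers for recovery reports
#'
#' `tidy()` returns the per-parameter recovery summary; `glance()` a one-row
#' overview.
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @name recovery_report_tidiers
#' @export
glance.recovery_report <- function(x, ...) {
  omega_row <- x$by_parameter[x$by_parameter$parameter == "omega", ]
  tibble::tibble(n_subjects = nrow(x$merged), n_fits = nrow(x$fits),
                 n_converged = x$n_converged,
                 omega_correlation = omega_row$correlation,
                 omega_median_abs_error = omega_row$median_abs_error)
}
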