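#' Grid of starting values for maximum-likelihood fitting
#'
#' A coarse full-factorial grid over the seven parameters is evaluated first
#' to locate promising regions; its best points seed the local refinement. If
#' the factorial product exceeds `max_points`, the longest per-parameter value
#' lists are thinned evenly (largest first, deterministic) until the grid fits
#' the cap, so the default grid stays desk-scale without any randomness.
#'
#' @param alpha1,alpha2,lambda,omega Value lists for the unit-interval
#'   parameters.
#' @param beta1,beta2 Value lists for the inverse temperatures.
#' @param pi Value list for the perseveration bonus.
#' @param max_points Cap on the number of factorial grid points.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(alpha1 = seq(0.1, 0.9, by = 0.1),
                      alpha2 = seq(0.1, 0.9, by = 0.1),
                      beta1 = c(1, 3, 5, 8, 12),
                      beta2 = c(1, 3, 5, 8, 12),
                      lambda = seq(0.1, 0.9, by = 0.1),
                      pi = c(-0.5, 0, 0.25, 0.5),
                      omega = seq(0.1, 0.9, by = 0.1),
                      max_points = 1e5) {
  values <- list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1,
                 beta2 = beta2, lambda = lambda, pi = pi, omega = omega)
  if (any(vapply(values, length, integer(1)) == 0)) {
    abort("Every parameter needs at least one grid value.")
  }
  structure(list(values = values, max_points = max_points), class = "grid_spec")
}

# thin value lists (longest first) until the factorial product fits the cap
thin_grid_values <- function(values, max_points) {
  repeat {
    sizes <- vapply(values, length, integer(1))
    if (prod(sizes) <= max_points) return(values)
    if (all(sizes == 1)) return(values)
    i <- which.max(sizes)
    v <- values[[i]]
    keep <- unique(round(seq(1, length(v), length.out = ceiling(length(v) / 2))))
    values[[i]] <- v[keep]
  }
}

#' Box constraints for parameter refinement
#'
#' Unit-interval parameters are bounded in \[0, 1\]; the inverse temperatures
#' default to \[0, 20\] and the perseveration bonus to \[-5, 5\], wide enough
#' to contain published percentile ranges with room to spare.
#'
#' @param lower,upper Named numeric vectors over the seven parameters.
#' @return An object of class `fit_bounds`.
#' @export
fit_bounds <- function(lower = c(alpha1 = 0, alpha2 = 0, beta1 = 0, beta2 = 0,
                                 lambda = 0, pi = -5, omega = 0),
                       upper = c(alpha1 = 1, alpha2 = 1, beta1 = 20, beta2 = 20,
                                 lambda = 1, pi = 5, omega = 1)) {
  lower <- lower[PARAM_NAMES]; upper <- upper[PARAM_NAMES]
  if (anyNA(lower) || anyNA(upper)) abort("Bounds must cover all 7 parameters.")
  if (any(lower >= upper)) abort("Each lower bound must be below its upper bound.")
  structure(list(lower = lower, upper = upper), class = "fit_bounds")
}

# extract the completed-trial event vectors a C-level likelihood needs
session_arrays <- function(session) {
  session <- dplyr::arrange(session, .data$trial_index)
  ok <- !is.na(session$first_action) & !is.na(session$second_state) &
    !is.na(session$second_action) & !is.na(session$reward) &
    !(session$aborted %||% FALSE)
  list(
    a1 = as.integer(ifelse(ok, session$first_action, 0L)),
    s2 = as.integer(ifelse(ok, session$second_state == "C", 0L)),
    a2 = as.integer(ifelse(ok, session$second_action, 0L)),
    r = as.integer(ifelse(ok, session$reward, 0L)),
    ok = as.integer(ok),
    n_completed = sum(ok)
  )
}

#' Negative log-likelihood of a session under the hybrid agent
#'
#' Deterministically replays the session: for every completed trial the
#' observed first- and second-stage choices contribute their negative log
#' softmax probabilities, and the observed outcome then drives the
#' SARSA(lambda) value updates. Aborted trials contribute no likelihood terms
#' and no updates.
#'
#' @param params An [agent_parameters()] object (or coercible input).
#' @param session A session tibble (one subject, one condition), as produced
#'   by [simulate_session()] or [read_sessions()].
#' @param structure A [transition_structure()].
#' @param q_init Initial Q value used for the replay.
#' @return The negative log-likelihood in nats (a single non-negative number).
#' @examples
#' p <- agent_parameters(0.63, 0.49, 3.91, 4.71, 0.23, 0.21, 0.57)
#' s <- simulate_session(p, "narrow", n_trials = 50, seed = 1)
#' negative_log_likelihood(p, s)
#' @export
negative_log_likelihood <- function(params, session,
                                    structure = transition_structure(),
                                    q_init = 0.5) {
  params <- as_agent_parameters(params)
  arr <- session_arrays(session)
  if (arr$n_completed < 1) abort("Session has no completed trials.")
  nll_hybrid_cpp(as.double(params), arr$a1, arr$s2, arr$a2, arr$r, arr$ok,
                 structure$common_prob,
                 as.integer(structure$common_destination[1] == "C"), q_init)
}

#' Evaluate the likelihood over a parameter grid
#'
#' @param session A session tibble (one subject, one condition).
#' @param grid A [grid_spec()].
#' @param structure A [transition_structure()].
#' @param q_init Initial Q value.
#' @param method `"factorial"` evaluates the (capped) full-factorial grid;
#'   `"coordinate"` sweeps one parameter at a time from the grid midpoint,
#'   repeating until no sweep improves the best point.
#' @return A tibble of candidates with the seven parameter columns and `nll`,
#'   sorted by ascending negative log-likelihood.
#' @export
grid_search <- function(session, grid = grid_spec(),
                        structure = transition_structure(), q_init = 0.5,
                        method = c("factorial", "coordinate")) {
  method <- match.arg(method)
  arr <- session_arrays(session)
  if (arr$n_completed < 1) abort("Session has no completed trials.")
  dest0 <- as.integer(structure$common_destination[1] == "C")
  eval_mat <- function(m) {
    nll_hybrid_grid_cpp(m, arr$a1, arr$s2, arr$a2, arr$r, arr$ok,
                        structure$common_prob, dest0, q_init)
  }
  if (method == "factorial") {
    values <- thin_grid_values(grid$values, grid$max_points)
    pts <- as.matrix(expand.grid(values, KEEP.OUT.ATTRS = FALSE))
    nll <- eval_mat(pts)
  } else {
    values <- grid$values
    current <- vapply(values, function(v) v[ceiling(length(v) / 2)], numeric(1))
    visited <- list()
    best <- Inf
    for (sweep in 1:10) {
      improved <- FALSE
      for (j in seq_along(values)) {
        m <- matrix(rep(current, each = length(values[[j]])),
                    ncol = 7, dimnames = list(NULL, PARAM_NAMES))
        m[, j] <- values[[j]]
        nll_j <- eval_mat(m)
        visited[[length(visited) + 1L]] <- cbind(m, nll = nll_j)
        k <- which.min(nll_j)
        if (nll_j[k] < best - 1e-12) {
          best <- nll_j[k]
          current <- m[k, 1:7]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    all <- do.call(rbind, visited)
    all <- all[!duplicated(all[, 1:7, drop = FALSE]), , drop = FALSE]
    pts <- all[, 1:7, drop = FALSE]
    nll <- all[, "nll"]
  }
  out <- tibble::as_tibble(as.data.frame(pts))
  names(out) <- PARAM_NAMES
  out$nll <- nll
  dplyr::arrange(out, .data$nll)
}

#' Refine a fit by bounded local optimization from multiple starts
#'
#' Runs L-BFGS-B from each starting point (at most 500 iterations per start)
#' and keeps the solution with the lowest negative log-likelihood. The result
#' is deterministic given the session and the starts.
#'
#' @param session A session tibble (one subject, one condition).
#' @param starts A tibble/data frame of starting parameter vectors (columns
#'   `alpha1` ... `omega`), or a list of [agent_parameters()].
#' @param bounds A [fit_bounds()].
#' @param structure A [transition_structure()].
#' @param q_init Initial Q value.
#' @return An object of class `hybrid_fit`: fitted [agent_parameters()], the
#'   negative log-likelihood, the number of completed trials and starts, a
#'   convergence flag and per-start optimizer diagnostics.
#' @export
refine_fit <- function(session, starts, bounds = fit_bounds(),
                       structure = transition_structure(), q_init = 0.5) {
  if (is.list(starts) && !is.data.frame(starts) &&
      all(vapply(starts, inherits, logical(1), "agent_parameters"))) {
    starts <- dplyr::bind_rows(lapply(starts, function(p) as.list(unclass(p))))
  }
  starts <- as.data.frame(starts)[, PARAM_NAMES, drop = FALSE]
  if (nrow(starts) < 1) abort("At least one starting point is required.")
  arr <- session_arrays(session)
  if (arr$n_completed < 1) abort("Session has no completed trials.")
  dest0 <- as.integer(structure$common_destination[1] == "C")
  fn <- function(par) {
    nll_hybrid_cpp(par, arr$a1, arr$s2, arr$a2, arr$r, arr$ok,
                   structure$common_prob, dest0, q_init)
  }
  lo <- bounds$lower; hi <- bounds$upper
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    par0 <- pmin(pmax(as.numeric(starts[i, ]), lo), hi)
    res <- tryCatch(
      optim(par0, fn, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      list(par = par0, value = fn(par0), convergence = -1L, failed = TRUE)
    } else {
      list(par = res$par, value = res$value, convergence = res$convergence,
           failed = FALSE)
    }
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(values)]]
  fitted <- as_agent_parameters(stats::setNames(best$par, PARAM_NAMES))
  structure(
    list(params = fitted,
         neg_log_likelihood = best$value,
         n_trials_used = arr$n_completed,
         n_starts = nrow(starts),
         converged = !best$failed && best$convergence == 0L,
         condition = session$condition[1] %||% NA_character_,
         diagnostics = tibble::tibble(
           start = seq_along(runs),
           nll = values,
           convergence = vapply(runs, `[[`, integer(1), "convergence"))),
    class = "hybrid_fit"
  )
}

#' @export
print.hybrid_fit <- function(x, ...) {
  cat(sprintf("<hybrid_fit> condition %s: -LL = %.2f over %d trials (%d starts%s)\n",
              x$condition, x$neg_log_likelihood, x$n_trials_used, x$n_starts,
              if (x$converged) ", converged" else ", NOT converged"))
  print(unlist(x$params))
  invisible(x)
}

#' @rdname hybrid_fit_tidiers
#' @export
tidy.hybrid_fit <- function(x, ...) {
  tibble::tibble(term = PARAM_NAMES, estimate = as.double(x$params))
}

#' Tidiers for fitted hybrid models
#'
#' `tidy()` returns the parameter estimates, one row per term; `glance()`
#' returns a one-row model summary.
#'
#' @param x A `hybrid_fit` object.
#' @param ... Unused.
#' @name hybrid_fit_tidiers
#' @export
glance.hybrid_fit <- function(x, ...) {
  tibble::tibble(neg_log_likelihood = x$neg_log_likelihood,
                 n_trials_used = x$n_trials_used, n_starts = x$n_starts,
                 converged = x$converged, condition = x$condition)
}

#' Fit one subject's two sessions by grid search plus multistart refinement
#'
#' For each condition independently, the likelihood is evaluated over the
#' grid, the `n_starts` best candidates (12 in the study procedure) seed the
#' bounded local refinement, and the best refined solution is returned. With
#' `pool_starts = TRUE` the candidate pool is instead the best `n_starts`
#' points of the two conditions' grids combined, used for both fits.
#'
#' @param narrow,wide Session tibbles for the two conditions.
#' @param grid A [grid_spec()].
#' @param bounds A [fit_bounds()].
#' @param n_starts Number of grid candidates used as refinement starts.
#' @param pool_starts Pool grid candidates across the two conditions.
#' @param structure A [transition_structure()].
#' @param q_init Initial Q value.
#' @return A named list with `hybrid_fit` elements `narrow` and `wide`.
#' @export
fit_subject <- function(narrow, wide, grid = grid_spec(), bounds = fit_bounds(),
                        n_starts = 12, pool_starts = FALSE,
                        structure = transition_structure(), q_init = 0.5) {
  cand <- list(narrow = grid_search(narrow, grid, structure, q_init),
               wide = grid_search(wide, grid, structure, q_init))
  pick <- function(tbl) utils::head(tbl, n_starts)[PARAM_NAMES]
  starts <- if (pool_starts) {
    pooled <- dplyr::arrange(dplyr::bind_rows(cand), .data$nll)
    list(narrow = pick(pooled), wide = pick(pooled))
  } else {
    list(narrow = pick(cand$narrow), wide = pick(cand$wide))
  }
  list(narrow = refine_fit(narrow, starts$narrow, bounds, structure, q_init),
       wide = refine_fit(wide, starts$wide, bounds, structure, q_init))
}

#' Fit every subject-by-condition session in a table of trial logs
#'
#' Splits the data by `subject_id` and `condition` and applies the grid +
#' multistart procedure to each session.
#'
#' @param data Session tibble covering one or more subjects and conditions.
#' @inheritParams fit_subject
#' @return A tibble with one row per subject x condition: `subject_id`,
#'   `group_label`, `condition`, the seven parameter estimates, `negLL`,
#'   `n_trials_used` and `converged`.
#' @export
fit_sessions <- function(data, grid = grid_spec(), bounds = fit_bounds(),
                         n_starts = 12, structure = transition_structure(),
                         q_init = 0.5) {
  groups <- dplyr::group_split(dplyr::group_by(data, .data$subject_id,
                                               .data$condition))
  purrr::map_dfr(groups, function(sess) {
    cand <- grid_search(sess, grid, structure, q_init)
    fit <- refine_fit(sess, utils::head(cand, n_starts)[PARAM_NAMES],
                      bounds, structure, q_init)
    tibble::tibble(
      subject_id = sess$subject_id[1],
      group_label = if ("group_label" %in% names(sess)) sess$group_label[1] else NA_character_,
      condition = sess$condition[1],
      !!!stats::setNames(as.list(as.double(fit$params)), PARAM_NAMES),
      negLL = fit$neg_log_likelihood,
      n_trials_used = fit$n_trials_used,
      converged = fit$converged
    )
  })
}
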