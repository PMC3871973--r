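#' Plot stay probabilities in the previous-transition x previous-reward design
#'
#' The classic two-stage task figure: bars of the probability of repeating
#' the previous first-stage choice, split by whether the previous transition
#' was common or rare and whether it was rewarded. A purely model-free agent
#' shows a main effect of reward (both rewarded bars high); a model-based
#' agent shows the crossover interaction (common-rewarded and rare-unrewarded
#' high).
#'
#' @param scores Output of [analyze_sessions()] (one row per subject x
#'   condition) or a single stay table from [compute_stay_table()].
#' @return A ggplot object.
#' @export
plot_stay_probabilities <- function(scores) {
  if (all(c("prev_transition", "stay_prob") %in% names(scores))) {
    long <- dplyr::mutate(
      scores,
      outcome = ifelse(.data$prev_reward == 1, "rewarded", "unrewarded"),
      mean_stay = .data$stay_prob, se = NA_real_)
  } else {
    long <- tidyr::pivot_longer(
      scores, dplyr::all_of(c("stay_cr", "stay_cn", "stay_rr", "stay_rn")),
      names_to = "cell", values_to = "stay")
    long <- dplyr::mutate(
      long,
      prev_transition = ifelse(.data$cell %in% c("stay_cr", "stay_cn"),
                               "common", "rare"),
      outcome = ifelse(.data$cell %in% c("stay_cr", "stay_rr"),
                       "rewarded", "unrewarded"))
    long <- dplyr::summarise(
      dplyr::group_by(long, .data$prev_transition, .data$outcome),
      mean_stay = mean(.data$stay, na.rm = TRUE),
      se = sd(.data$stay, na.rm = TRUE) / sqrt(sum(!is.na(.data$stay))),
      .groups = "drop")
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$outcome, y = .data$mean_stay,
                                     fill = .data$prev_transition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_stay - .data$se,
                   ymax = .data$mean_stay + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.2, na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "previous outcome", y = "stay probability",
                  fill = "previous transition") +
    ggplot2::theme_minimal()
}

#' Plot reward-probability random walks
#'
#' @param trajectory Matrix from [generate_walks()] (or the attribute
#'   attached to a simulated session).
#' @return A ggplot object showing the four walks over trials.
#' @export
plot_trajectory <- function(trajectory) {
  df <- tibble::as_tibble(as.data.frame(trajectory))
  df$trial <- seq_len(nrow(df)) - 1L
  long <- tidyr::pivot_longer(df, -"trial", names_to = "option",
                              values_to = "p_reward")
  ggplot2::ggplot(long, ggplot2::aes(.data$trial, .data$p_reward,
                                     color = .data$option)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "trial", y = "reward probability", color = "option") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter true versus recovered parameters
#'
#' @param object A `recovery_report` from [parameter_recovery()].
#' @param ... Unused.
#' @return A ggplot object, one facet per parameter, identity line overlaid.
#' @export
autoplot.recovery_report <- function(object, ...) {
  long <- purrr::map_dfr(PARAM_NAMES, function(nm) {
    tibble::tibble(parameter = nm,
                   true = object$merged[[paste0(nm, "_true")]],
                   recovered = object$merged[[paste0(nm, "_rec")]])
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$true, .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "true parameter", y = "recovered parameter") +
    ggplot2::theme_minimal()
}
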