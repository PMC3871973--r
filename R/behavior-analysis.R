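#' Stay probabilities by previous transition and previous reward
#'
#' Stay-switch behavior is scored over consecutive completed trial pairs: for
#' each pair the later trial counts as a "stay" when its first-stage action
#' repeats the earlier trial's, and the pair is classified by the earlier
#' trial's transition type (common/rare) and reward. Pairs separated by an
#' aborted trial are dropped entirely, and the first trial is never a stay
#' target. Cells with no scored pairs carry `NA` stay probabilities rather
#' than 0, so downstream difference scores are not biased.
#'
#' @param session A session tibble for a single subject and condition.
#' @return A tibble with one row per cell (`prev_transition` x `prev_reward`),
#'   columns `n_pairs`, `n_stay`, `stay_prob`.
#' @examples
#' p <- agent_parameters(0.63, 0.49, 3.91, 4.71, 0.23, 0.21, 0.57)
#' compute_stay_table(simulate_session(p, "narrow", 100, seed = 1))
#' @export
compute_stay_table <- function(session) {
  session <- dplyr::arrange(session, .data$trial_index)
  completed <- !is.na(session$first_action) & !is.na(session$second_action) &
    !(session$aborted %||% FALSE)
  if (sum(completed) < 2) abort("Need at least 2 completed trials.")
  n <- nrow(session)
  prev <- seq_len(n - 1)
  ok_pair <- completed[prev] & completed[prev + 1]
  pairs <- tibble::tibble(
    prev_transition = session$transition_type[prev][ok_pair],
    prev_reward = session$reward[prev][ok_pair],
    stay = session$first_action[prev + 1][ok_pair] ==
      session$first_action[prev][ok_pair]
  )
  cells <- tidyr::expand_grid(prev_transition = c("common", "rare"),
                              prev_reward = c(1L, 0L))
  counts <- dplyr::summarise(
    dplyr::group_by(pairs, .data$prev_transition, .data$prev_reward),
    n_pairs = dplyr::n(), n_stay = sum(.data$stay), .groups = "drop")
  out <- dplyr::left_join(cells, counts, by = c("prev_transition", "prev_reward"))
  out <- dplyr::mutate(out,
    n_pairs = dplyr::coalesce(.data$n_pairs, 0L),
    n_stay = dplyr::coalesce(.data$n_stay, 0L),
    stay_prob = dplyr::if_else(.data$n_pairs > 0,
                               .data$n_stay / .data$n_pairs, NA_real_))
  out
}

stay_cell <- function(table, transition, reward) {
  table$stay_prob[table$prev_transition == transition &
                    table$prev_reward == reward]
}

#' Model-based and model-free strategy scores from a stay table
#'
#' The model-based difference score is the interaction contrast
#' `(common rewarded + rare unrewarded) - (rare rewarded + common unrewarded)`
#' and the model-free score is the previous-reward main effect
#' `(common rewarded + rare rewarded) - (common unrewarded + rare unrewarded)`,
#' both on the stay probabilities. An undefined (zero-count) cell propagates
#' to `NA` scores.
#'
#' @param table A stay table from [compute_stay_table()].
#' @return A tibble with columns `mb_diff` and `mf_diff`, both in \[-2, 2\].
#' @export
strategy_scores <- function(table) {
  cr <- stay_cell(table, "common", 1L); cn <- stay_cell(table, "common", 0L)
  rr <- stay_cell(table, "rare", 1L); rn <- stay_cell(table, "rare", 0L)
  tibble::tibble(mb_diff = (cr + rn) - (rr + cn),
                 mf_diff = (cr + rr) - (cn + rn))
}

#' Session payoff in euros
#'
#' Every rewarded trial pays 10 cents.
#'
#' @param session A session tibble.
#' @param reward_value Euros per rewarded trial.
#' @return Total payoff in euros.
#' @export
mean_payoff <- function(session, reward_value = 0.10) {
  reward_value * sum(session$reward, na.rm = TRUE)
}

#' Per-session behavioral read-outs for a table of trial logs
#'
#' Computes, for every subject x condition, the four stay probabilities, the
#' model-based/model-free difference scores and the payoff.
#'
#' @param data Session tibble covering one or more subjects and conditions.
#' @return A tibble with columns `subject_id`, `group_label`, `condition`,
#'   `stay_cr`, `stay_cn`, `stay_rr`, `stay_rn`, `mb_diff`, `mf_diff`,
#'   `payoff_eur`.
#' @export
analyze_sessions <- function(data) {
  groups <- dplyr::group_split(dplyr::group_by(data, .data$subject_id,
                                               .data$condition))
  purrr::map_dfr(groups, function(sess) {
    tbl <- compute_stay_table(sess)
    scores <- strategy_scores(tbl)
    tibble::tibble(
      subject_id = sess$subject_id[1],
      group_label = if ("group_label" %in% names(sess)) sess$group_label[1] else NA_character_,
      condition = sess$condition[1],
      stay_cr = stay_cell(tbl, "common", 1L),
      stay_cn = stay_cell(tbl, "common", 0L),
      stay_rr = stay_cell(tbl, "rare", 1L),
      stay_rn = stay_cell(tbl, "rare", 0L),
      mb_diff = scores$mb_diff,
      mf_diff = scores$mf_diff,
      payoff_eur = mean_payoff(sess)
    )
  })
}

#' Group-level summary of strategy scores and payoffs
#'
#' @param scores Output of [analyze_sessions()] (or any tibble with
#'   `group_label`, `condition`, `mb_diff`, `mf_diff`, `payoff_eur`).
#' @return A tibble with per group x condition means and standard errors of
#'   the mean (`NA` standard error for singleton groups).
#' @export
cohort_summary <- function(scores) {
  if (nrow(scores) == 0) abort("`scores` is empty.")
  se <- function(x) sd(x) / sqrt(length(x))
  dplyr::summarise(
    dplyr::group_by(scores, .data$group_label, .data$condition),
    n = dplyr::n(),
    mb_diff_mean = mean(.data$mb_diff), mb_diff_se = se(.data$mb_diff),
    mf_diff_mean = mean(.data$mf_diff), mf_diff_se = se(.data$mf_diff),
    payoff_mean = mean(.data$payoff_eur), payoff_se = se(.data$payoff_eur),
    .groups = "drop")
}
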