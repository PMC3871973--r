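#' Read and write session logs as CSV
#'
#' Session logs are delimited text with one row per trial and columns
#' `subject_id`, `group_label`, `condition`, `trial_index`, `first_action`,
#' `transition_type`, `second_state`, `second_action`, `reward`, `aborted`.
#' Missing values (aborted trials' absent responses) are written as empty
#' fields.
#'
#' @param data Session tibble to write.
#' @param path File path.
#' @return `read_sessions()` returns the session tibble; `write_sessions()`
#'   returns `data` invisibly.
#' @export
write_sessions <- function(data, path) {
  cols <- c("subject_id", "group_label", "condition", "trial_index",
            "first_action", "transition_type", "second_state",
            "second_action", "reward", "aborted")
  missing <- setdiff(cols, names(data))
  if (length(missing)) abort(paste("Missing column(s):",
                                   paste(missing, collapse = ", ")))
  readr::write_csv(data[cols], path, na = "")
  invisible(data)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group_label = readr::col_character(),
      condition = readr::col_character(),
      trial_index = readr::col_integer(),
      first_action = readr::col_integer(),
      transition_type = readr::col_character(),
      second_state = readr::col_character(),
      second_action = readr::col_integer(),
      reward = readr::col_integer(),
      aborted = readr::col_logical()
    ))
}

#' Write a reward-probability trajectory sidecar CSV
#'
#' @param trajectory Matrix from [generate_walks()].
#' @param path File path.
#' @export
write_trajectory <- function(trajectory, path) {
  out <- tibble::as_tibble(as.data.frame(trajectory))
  out <- dplyr::mutate(out, trial_index = dplyr::row_number() - 1L, .before = 1)
  readr::write_csv(out, path)
  invisible(trajectory)
}
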