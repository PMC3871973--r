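#' Published median parameter estimates by group and probability range
#'
#' Median maximum-likelihood estimates of the seven hybrid-model parameters
#' reported for younger and older adults split by working-memory capacity
#' (low/high performance), separately for the narrow and wide random-walk
#' conditions. These anchor the synthetic-cohort generator: "younger-like"
#' agents carry a high model-based weight (omega 0.57--0.64) and "older-like"
#' agents a low one (0.11--0.35).
#'
#' @return A tibble with columns `preset` (e.g. `"younger_low"`), `range`,
#'   the seven parameters and the reported median negative log-likelihood.
#' @examples
#' agent_presets()
#' @export
agent_presets <- function() {
  tibble::tribble(
    ~preset, ~range, ~beta1, ~beta2, ~alpha1, ~alpha2, ~lambda, ~pi, ~omega, ~neg_ll,
    "younger_low", "narrow", 3.91, 4.71, 0.63, 0.49, 0.23, 0.21, 0.57, 208.55,
    "younger_low", "wide", 5.12, 4.02, 0.52, 0.56, 0.17, 0.16, 0.57, 200.94,
    "younger_high", "narrow", 7.63, 4.82, 0.39, 0.64, 0.09, 0.11, 0.61, 191.52,
    "younger_high", "wide", 9.99, 4.59, 0.40, 0.65, 0.15, 0.12, 0.64, 183.55,
    "older_low", "narrow", 5.83, 2.92, 0.65, 0.33, 0.33, 0.18, 0.24, 218.33,
    "older_low", "wide", 6.12, 3.36, 0.33, 0.44, 0.33, 0.14, 0.35, 208.76,
    "older_high", "narrow", 3.62, 2.69, 0.40, 0.56, 0.38, 0.18, 0.15, 202.09,
    "older_high", "wide", 6.32, 3.75, 0.62, 0.32, 0.49, 0.18, 0.11, 187.34
  )
}

#' Look up one preset as an `agent_parameters` object
#'
#' @param preset One of `"younger_low"`, `"younger_high"`, `"older_low"`,
#'   `"older_high"`.
#' @param range `"narrow"` or `"wide"`.
#' @return An [agent_parameters()] object.
#' @examples
#' preset_parameters("younger_low")
#' @export
preset_parameters <- function(preset = c("younger_low", "younger_high",
                                         "older_low", "older_high"),
                              range = c("narrow", "wide")) {
  preset <- match.arg(preset)
  range <- match.arg(range)
  row <- dplyr::filter(agent_presets(), .data$preset == !!preset,
                       .data$range == !!range)
  as_agent_parameters(row[PARAM_NAMES])
}
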