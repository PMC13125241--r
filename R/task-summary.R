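# Behavioral summaries of simulated sessions.

#' Summarize behavior across a session
#'
#' Computes session-level behavioral statistics. Turnaround statistics are
#' computed only over conflict trials with at least one turnaround (the
#' final turnaround is the decision to avoid); conflict-free trials and
#' trials without a turn are excluded, matching the exclusion rules of the
#' behavioral analysis.
#'
#' @param trials Tibble from [run_session()] (or any tibble with columns
#'   `conflict`, `dots_collected`, `turnaround_distance`, `last_dot_size`,
#'   `attack_onset`, `attack_type`, `n_turnarounds`).
#' @return One-row tibble: `n_trials`, `mean_dots_per_trial`,
#'   `mean_turnaround_distance`, `turnaround_distance_small`,
#'   `turnaround_distance_large` (means by last-dot size),
#'   `attack_count`, and `chase_fraction` (fraction of triggered attacks
#'   that were Chases).
#' @export
summarize_behavior <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0) stop_bad("no trials to summarize")
  turn <- dplyr::filter(trials, .data$conflict, .data$n_turnarounds > 0,
                        !is.na(.data$turnaround_distance))
  if (nrow(turn) == 0) stop_bad("no conflict trials with a turnaround")
  attacks <- dplyr::filter(trials, !is.na(.data$attack_onset))
  by_size <- turn |>
    group_by(.data$last_dot_size) |>
    summarise(m = mean(.data$turnaround_distance), .groups = "drop")
  get_size <- function(s) {
    v <- by_size$m[by_size$last_dot_size == s]
    if (length(v)) v else NA_real_
  }
  tibble(
    n_trials = nrow(trials),
    mean_dots_per_trial = mean(trials$dots_collected),
    mean_turnaround_distance = mean(turn$turnaround_distance),
    turnaround_distance_small = get_size("small"),
    turnaround_distance_large = get_size("large"),
    attack_count = nrow(attacks),
    chase_fraction = if (nrow(attacks)) mean(attacks$attack_type == "chase")
                     else NA_real_
  )
}

#' Extract per-trial event times for LFP generation
#'
#' Converts a session tibble into the event table consumed by
#' [generate_lfp()]: one row per trial with `movement_onset`,
#' `turnaround`, `attack_onset` and `trial_end` in milliseconds relative
#' to trial onset.
#'
#' @param trials Tibble from [run_session()].
#' @return Tibble with columns `trial`, `movement_onset`, `turnaround`,
#'   `attack_onset`, `trial_end` (ms).
#' @export
lfp_events <- function(trials) {
  tibble(
    trial = seq_len(nrow(trials)),
    movement_onset = trials$movement_onset,
    turnaround = trials$turnaround_time,
    attack_onset = trials$attack_onset,
    trial_end = trials$trial_end
  )
}
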