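#' Task configuration
#'
#' Parameters of the continuous-choice approach-avoidance task: a linear
#' corridor along which the player (at one end) approaches a patrolling
#' ghost (at the other end) to collect five dots of small or large reward
#' value, under a distance-dependent attack hazard. Defaults reproduce the
#' published design: 240 trials in blocks of 20, 20% conflict-free, five
#' dots worth 10 or 20 points, three lives per minigame.
#'
#' The per-tick attack hazard at player-ghost distance `d` is
#' `hazard_max * pbeta(1 - d / corridor_length, hazard_alpha, hazard_beta)`,
#' a scaled beta CDF of proximity: zero at maximal distance, monotonically
#' increasing as the player closes in, capped at `hazard_max`.
#'
#' @param n_trials Trials per session (default 240).
#' @param block_length Trials per block/minigame (default 20).
#' @param conflict_free_fraction Fraction of trials without a ghost
#'   (default 0.20). `conflict_free_fraction * block_length` must be an
#'   integer so conflict-free trials stratify evenly across blocks.
#' @param n_dots Dots per trial (default 5).
#' @param reward_small,reward_large Points per small/large dot (10, 20).
#' @param n_lives Lives per minigame (default 3).
#' @param corridor_length Corridor length in distance units (default 200).
#' @param pacman_speed Player speed in units per tick (default 2).
#' @param strike_speed_multiplier Ghost speed multiplier in the Strike
#'   state; must exceed 1 and is raised further at run time whenever the
#'   geometry would otherwise allow escape, so a Strike always captures.
#' @param hazard_alpha,hazard_beta Beta shape parameters of the hazard.
#' @param hazard_max Maximum per-tick attack probability.
#' @param tick_ms Milliseconds per game tick (default 50).
#' @param pacman_start_offset Player start position, units from their exit.
#' @param dot_jitter Uniform jitter (units) applied to evenly spaced dots.
#' @param patrol_buffer Gap between the last dot and the ghost patrol zone.
#' @param tick_cap Maximum ticks per trial before a timeout is logged.
#' @return A `task_config` list, validated.
#' @examples
#' cfg <- task_config()
#' attack_probability(c(200, 50, 10), cfg)
#' @export
task_config <- function(n_trials = 240,
                        block_length = 20,
                        conflict_free_fraction = 0.20,
                        n_dots = 5,
                        reward_small = 10,
                        reward_large = 20,
                        n_lives = 3,
                        corridor_length = 200,
                        pacman_speed = 2,
                        strike_speed_multiplier = 2.5,
                        hazard_alpha = 5,
                        hazard_beta = 2,
                        hazard_max = 0.02,
                        tick_ms = 50,
                        pacman_start_offset = 10,
                        dot_jitter = 3,
                        patrol_buffer = 20,
                        tick_cap = 600) {
  check_count(n_trials, "n_trials")
  check_count(block_length, "block_length")
  check_number(conflict_free_fraction, "conflict_free_fraction", 0, 1)
  check_count(n_dots, "n_dots")
  check_count(n_lives, "n_lives")
  check_number(hazard_max, "hazard_max", min = 1e-12, max = 1)
  check_number(strike_speed_multiplier, "strike_speed_multiplier")
  check_number(corridor_length, "corridor_length", min = 1)

  if (n_trials %% block_length != 0) {
    stop_bad("n_trials (%d) must be divisible by block_length (%d)",
             n_trials, block_length)
  }
  n_cf_block <- conflict_free_fraction * block_length
  if (abs(n_cf_block - round(n_cf_block)) > 1e-9) {
    stop_bad("conflict_free_fraction * block_length must be an integer, got %.3f",
             n_cf_block)
  }
  if (strike_speed_multiplier <= 1) {
    stop_bad("strike_speed_multiplier must be > 1")
  }
  if (reward_small >= reward_large) {
    stop_bad("reward_small must be less than reward_large")
  }

  structure(
    list(
      n_trials = as.integer(n_trials),
      block_length = as.integer(block_length),
      conflict_free_fraction = conflict_free_fraction,
      n_dots = as.integer(n_dots),
      reward_values = c(small = reward_small, large = reward_large),
      n_lives = as.integer(n_lives),
      corridor_length = corridor_length,
      pacman_speed = pacman_speed,
      ghost_pace_speed = pacman_speed,
      strike_speed_multiplier = strike_speed_multiplier,
      hazard_alpha = hazard_alpha,
      hazard_beta = hazard_beta,
      hazard_max = hazard_max,
      tick_ms = tick_ms,
      pacman_start_offset = pacman_start_offset,
      dot_jitter = dot_jitter,
      patrol_buffer = patrol_buffer,
      tick_cap = as.integer(tick_cap)
    ),
    class = "task_config"
  )
}

#' Per-tick ghost attack probability
#'
#' Scaled beta CDF of proximity: attacks are rare when the player is far
#' from the ghost and common when close. Monotone non-increasing in
#' distance for any valid shape parameters.
#'
#' @param distance Player-ghost distance(s), in corridor units; must be
#'   non-negative.
#' @param config A [task_config()].
#' @return Vector of per-tick probabilities in `[0, hazard_max]`.
#' @export
attack_probability <- function(distance, config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  if (any(distance < 0)) stop_bad("distance must be non-negative")
  d <- pmin(distance, config$corridor_length)
  config$hazard_max *
    pbeta(1 - d / config$corridor_length, config$hazard_alpha, config$hazard_beta)
}
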