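# Tick-level trial simulation.
#
# Trials run in normalized coordinates: the player's exit is at 0, the
# ghost patrol zone at the far end of the corridor, regardless of the
# counterbalanced presentation side. Positions are units, one step per
# tick of `tick_ms` milliseconds.

new_trial_state <- function(spec, config) {
  dots <- tibble(
    pos = spec$dot_positions[[1]],
    size = spec$dot_sizes[[1]],
    value = unname(config$reward_values[spec$dot_sizes[[1]]]),
    collected = FALSE
  )
  list(
    tick = 0L,
    pacman_pos = spec$pacman_start_position,
    pacman_dir = 0L,     # +1 toward ghost, -1 away
    moving = FALSE,
    ghost_pos = if (spec$conflict) spec$ghost_start_position else NA_real_,
    ghost_dir = if (identical(spec$ghost_start_direction, "toward")) -1L else 1L,
    ghost_state = "PACE",
    ghost_speed = config$ghost_pace_speed,
    patrol_min = spec$patrol_min,
    conflict = isTRUE(spec$conflict),
    attack_outcome = spec$attack_outcome,
    dots = dots,
    movement_onset = NA_integer_,
    turnaround_ticks = integer(0),
    turnaround_distance = NA_real_,
    attack_tick = NA_integer_,
    caught = FALSE,
    ended = FALSE,
    end_reason = NA_character_
  )
}

#' Advance a trial by one tick
#'
#' Applies the commanded action, moves the player at constant speed in the
#' last commanded direction, collects dots the player reaches, moves the
#' ghost (patrol in Pace at player speed; pursuit in Chase at unchanged
#' speed; pursuit in Strike at boosted speed guaranteeing capture), and
#' evaluates the distance-dependent attack hazard. State transitions are
#' only Pace to Chase or Pace to Strike; an attack state is absorbing for
#' the rest of the trial.
#'
#' @param state Trial state from [new_trial_state()] (internal) or a prior
#'   [step_trial()] call.
#' @param action One of `"toward"`, `"away"`, `"none"`.
#' @param config A [task_config()].
#' @return Updated state list; `state$ended` flags trial end.
#' @export
step_trial <- function(state, action = c("none", "toward", "away"),
                       config = task_config()) {
  action <- match.arg(action)
  if (state$ended) stop_bad("trial already ended")
  state$tick <- state$tick + 1L

  if (action == "toward") {
    if (!state$moving) state$movement_onset <- state$tick
    state$moving <- TRUE
    state$pacman_dir <- 1L
  } else if (action == "away") {
    if (state$moving && state$pacman_dir == 1L) {
      state$turnaround_ticks <- c(state$turnaround_ticks, state$tick)
      state$turnaround_distance <-
        if (state$conflict) state$ghost_pos - state$pacman_pos else NA_real_
    }
    if (!state$moving) state$movement_onset <- state$tick
    state$moving <- TRUE
    state$pacman_dir <- -1L
  }

  if (state$moving) {
    state$pacman_pos <- state$pacman_pos + state$pacman_dir * config$pacman_speed
  }

  # collect any dot the player has reached
  hit <- !state$dots$collected & state$dots$pos <= state$pacman_pos
  if (any(hit)) state$dots$collected[hit] <- TRUE

  if (state$conflict) {
    if (state$ghost_state == "PACE") {
      state$ghost_pos <- state$ghost_pos + state$ghost_dir * config$ghost_pace_speed
      if (state$ghost_pos >= config$corridor_length) {
        state$ghost_pos <- config$corridor_length
        state$ghost_dir <- -1L
      } else if (state$ghost_pos <= state$patrol_min) {
        state$ghost_pos <- state$patrol_min
        state$ghost_dir <- 1L
      }
    } else {
      state$ghost_pos <- state$ghost_pos - state$ghost_speed
    }

    if (state$ghost_pos <= state$pacman_pos) {
      state$caught <- TRUE
      state$ended <- TRUE
      state$end_reason <- "caught"
      return(state)
    }

    if (state$ghost_state == "PACE") {
      d <- state$ghost_pos - state$pacman_pos
      if (runif(1) < attack_probability(d, config)) {
        state$ghost_state <- toupper(state$attack_outcome)
        state$attack_tick <- state$tick
        if (state$ghost_state == "STRIKE") {
          # boost speed so capture is guaranteed even under immediate flight:
          # gap d closes at (s - 1) * v while the player needs pos / v ticks
          # to reach the exit, so require s > 1 + d / pos (plus margin)
          needed <- 1 + d / max(state$pacman_pos, 1e-6) + 0.25
          state$ghost_speed <- config$pacman_speed *
            max(config$strike_speed_multiplier, needed)
        } else {
          state$ghost_speed <- config$ghost_pace_speed
        }
      }
    }
  }

  if (state$moving && state$pacman_dir == -1L && state$pacman_pos <= 0) {
    state$ended <- TRUE
    state$end_reason <- "exit"
  } else if (state$tick >= config$tick_cap) {
    state$ended <- TRUE
    state$end_reason <- "timeout"
  }
  state
}

trial_observation <- function(state) {
  remaining <- state$dots$pos[!state$dots$collected]
  list(
    tick = state$tick,
    pacman_pos = state$pacman_pos,
    ghost_pos = state$ghost_pos,
    distance = if (state$conflict) state$ghost_pos - state$pacman_pos else Inf,
    ghost_state = state$ghost_state,
    moving = state$moving,
    dir = state$pacman_dir,
    conflict = state$conflict,
    dots_collected = sum(state$dots$collected),
    all_dots_collected = all(state$dots$collected),
    next_dot_pos = if (length(remaining)) min(remaining) else NA_real_,
    last_dot_size = tail(state$dots$size, 1)
  )
}

#' Run one trial under an agent policy
#'
#' Composes [step_trial()] with a policy (a function mapping the
#' observable state to an action). Capture zeroes the trial's points; a
#' policy that never ends the trial is cut off at `config$tick_cap` ticks
#' and logged as a timeout.
#'
#' @param spec One-row trial spec from [generate_session()] (or a list
#'   with the same fields).
#' @param policy A function `observation -> "toward" | "away" | "none"`;
#'   see [policy_approach_all()] and friends.
#' @param config A [task_config()].
#' @param seed Integer seed (drives the attack hazard draws).
#' @return A `trial_log`: list with per-tick `ticks` tibble, event times
#'   in ms (`movement_onset`, `turnaround_times`, `attack_onset`,
#'   `trial_end`), and outcome fields (`dots_collected`, `points`,
#'   `caught`, `last_dot_size`, `turnaround_distance`, `outcome`).
#' @export
run_trial <- function(spec, policy, config = task_config(), seed = 1) {
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1)
    spec <- as.list(spec)
  }
  with_seed(seed, {
    state <- new_trial_state(spec, config)
    n_cap <- config$tick_cap
    ticks <- vector("list", n_cap)
    while (!state$ended) {
      action <- policy(trial_observation(state))
      state <- step_trial(state, action, config)
      ticks[[state$tick]] <- c(state$pacman_pos,
                               if (state$conflict) state$ghost_pos else NA_real_)
    }
    tick_mat <- do.call(rbind, ticks[seq_len(state$tick)])
    ms <- function(tk) if (length(tk) && !all(is.na(tk))) tk * config$tick_ms else tk * config$tick_ms
    points <- if (state$caught) 0 else sum(state$dots$value[state$dots$collected])
    turn_ms <- state$turnaround_ticks * config$tick_ms
    structure(
      list(
        trial_id = spec$trial_id %||% NA_integer_,
        conflict = state$conflict,
        ticks = tibble(
          tick = seq_len(state$tick),
          time_ms = seq_len(state$tick) * config$tick_ms,
          pacman_pos = tick_mat[, 1],
          ghost_pos = tick_mat[, 2]
        ),
        movement_onset = if (is.na(state$movement_onset)) NA_real_ else
          state$movement_onset * config$tick_ms,
        turnaround_times = turn_ms,
        turnaround_final = if (length(turn_ms)) tail(turn_ms, 1) else NA_real_,
        attack_onset = if (is.na(state$attack_tick)) NA_real_ else
          state$attack_tick * config$tick_ms,
        attack_type = if (is.na(state$attack_tick)) NA_character_ else
          tolower(state$ghost_state),
        trial_end = state$tick * config$tick_ms,
        dots_collected = sum(state$dots$collected),
        points = points,
        caught = state$caught,
        last_dot_size = if (nrow(state$dots)) tail(state$dots$size, 1) else "none",
        turnaround_distance = state$turnaround_distance,
        outcome = state$end_reason
      ),
      class = "trial_log"
    )
  })
}

#' Run a full session of trials
#'
#' Runs the specs in order while tracking minigame structure: each
#' minigame starts with `n_lives` lives and zero score, and ends when the
#' player is caught `n_lives` times or when `block_length` trials have
#' been completed in the current minigame.
#'
#' Chase/Strike labels are consumed in trial order from the session's
#' pre-drawn balanced sequence whenever an attack actually triggers, so
#' the realized split stays near 50/50 regardless of when attacks occur.
#'
#' @param specs Tibble from [generate_session()].
#' @param policy Agent policy; see [run_trial()].
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return Tibble with one row per trial (identifiers, minigame id,
#'   lives at trial start, event times, outcome fields) and a `log`
#'   list-column of full `trial_log` objects.
#' @export
run_session <- function(specs, policy, config = task_config(), seed = 1) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1)
  queue <- sample_chase_strike_queue(specs, seed)
  queue_pos <- 0L
  minigame <- 1L
  lives <- config$n_lives
  trials_in_game <- 0L
  score <- 0L
  rows <- vector("list", nrow(specs))

  for (i in seq_len(nrow(specs))) {
    spec <- as.list(specs[i, ])
    # consume the session-level balanced Chase/Strike queue
    spec$attack_outcome <- queue[queue_pos + 1L]
    log <- run_trial(spec, policy, config, seed = child_seed(seed, i))
    if (!is.na(log$attack_onset)) queue_pos <- queue_pos + 1L
    lives_at_start <- lives
    if (log$caught) lives <- lives - 1L
    score <- score + log$points
    trials_in_game <- trials_in_game + 1L

    rows[[i]] <- tibble(
      trial_id = specs$trial_id[i],
      block = specs$block[i],
      minigame = minigame,
      lives_at_start = lives_at_start,
      conflict = specs$conflict[i],
      last_dot_size = specs$last_dot_size[i],
      movement_onset = log$movement_onset,
      turnaround_time = log$turnaround_final,
      n_turnarounds = length(log$turnaround_times),
      attack_onset = log$attack_onset,
      attack_type = log$attack_type,
      trial_end = log$trial_end,
      dots_collected = log$dots_collected,
      points = log$points,
      caught = log$caught,
      turnaround_distance = log$turnaround_distance,
      outcome = log$outcome,
      score_after = score,
      log = list(log)
    )

    if (lives == 0L || trials_in_game == config$block_length) {
      minigame <- minigame + 1L
      lives <- config$n_lives
      trials_in_game <- 0L
      score <- 0L
    }
  }
  bind_rows(rows)
}

sample_chase_strike_queue <- function(specs, seed) {
  n <- nrow(specs)
  with_seed(child_seed(seed, 97L), sample(rep(c("chase", "strike"), length.out = n)))
}

# ---- policies -------------------------------------------------------------

#' Agent policies for the task simulator
#'
#' Deterministic closures mapping observations to actions.
#'
#' * `policy_approach_all()` approaches until every dot is collected (or an
#'   attack begins), then flees.
#' * `policy_threshold(base, large_shrink)` is reward-sensitive: it turns
#'   around once the ghost is within `base` units, or `base - large_shrink`
#'   units when the trial's last dot is large, mirroring the finding that
#'   players approach closer for larger final rewards. Flees on attack.
#' * `policy_avoid()` immediately heads for the exit.
#' * `policy_none()` never presses a key.
#'
#' @param base Turnaround distance threshold, units.
#' @param large_shrink Reduction of the threshold when the last dot is
#'   large, units.
#' @return A function `observation -> action`.
#' @export
policy_approach_all <- function() {
  function(obs) {
    if (obs$conflict && obs$ghost_state != "PACE") return("away")
    if (obs$all_dots_collected) "away" else "toward"
  }
}

#' @rdname policy_approach_all
#' @export
policy_threshold <- function(base = 40, large_shrink = 12) {
  function(obs) {
    if (obs$conflict && obs$ghost_state != "PACE") return("away")
    if (obs$all_dots_collected) return("away")
    thr <- if (identical(obs$last_dot_size, "large")) base - large_shrink else base
    if (obs$conflict && obs$distance <= thr) "away" else "toward"
  }
}

#' @rdname policy_approach_all
#' @export
policy_avoid <- function() {
  function(obs) "away"
}

#' @rdname policy_approach_all
#' @export
policy_none <- function() {
  function(obs) "none"
}
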