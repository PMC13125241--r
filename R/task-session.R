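# Session generation: counterbalanced trial specifications.

# Canonical dot-size patterns; two end on a small dot, two on a large dot,
# so the last-reward factor is balanced within every block.
dot_patterns <- function(n_dots, seed) {
  if (n_dots == 5) {
    return(list(
      c("large", "small", "large", "small", "small"),
      c("small", "large", "small", "large", "small"),
      c("small", "large", "small", "small", "large"),
      c("large", "small", "small", "large", "large")
    ))
  }
  # other dot counts: four seeded pseudorandom patterns, last size balanced
  with_seed(child_seed(seed, 17L), {
    lapply(1:4, function(i) {
      sizes <- sample(c("small", "large"), n_dots, replace = TRUE)
      sizes[n_dots] <- if (i <= 2) "small" else "large"
      sizes
    })
  })
}

#' Generate a counterbalanced session of trial specifications
#'
#' Produces `n_trials` trial specs stratified into blocks: within each
#' block, conflict trials form a full crossing of player start side x
#' ghost start direction x dot-size pattern, and the configured fraction
#' of conflict-free trials (ghost absent) covers each side x direction
#' combination. Dot positions are evenly spaced between the player start
#' and the ghost patrol zone with seeded jitter; the patrol boundary sits
#' a jittered buffer beyond the last dot. Deterministic given
#' `(config, seed)`.
#'
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per trial: `trial_id`, `block`,
#'   `conflict`, `pacman_start_side`, `ghost_start_direction`,
#'   `pacman_start_position`, `ghost_start_position`, `patrol_min`,
#'   `dot_positions` and `dot_sizes` (list-columns), `last_dot_size`,
#'   and `attack_outcome` (pre-drawn Chase/Strike label, balanced across
#'   the session and used only if an attack triggers).
#' @export
generate_session <- function(config = task_config(), seed = 1) {
  stopifnot(inherits(config, "task_config"))
  n_blocks <- config$n_trials %/% config$block_length
  n_cf_block <- as.integer(round(config$conflict_free_fraction * config$block_length))
  n_conflict_block <- config$block_length - n_cf_block
  if (n_conflict_block %% 4 != 0 || (n_cf_block > 0 && n_cf_block %% 4 != 0)) {
    stop_bad(paste0(
      "counterbalancing impossible: per-block conflict (%d) and ",
      "conflict-free (%d) counts must both be multiples of the 4 ",
      "side x direction combinations"), n_conflict_block, n_cf_block)
  }
  patterns <- dot_patterns(config$n_dots, seed)

  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      crossing_conflict <- expand.grid(
        pacman_start_side = c("left", "right"),
        ghost_start_direction = c("toward", "away"),
        pattern = seq_along(patterns),
        stringsAsFactors = FALSE
      )
      conflict <- crossing_conflict[
        rep(seq_len(nrow(crossing_conflict)),
            length.out = n_conflict_block), , drop = FALSE]
      conflict$conflict <- TRUE
      cf <- expand.grid(
        pacman_start_side = c("left", "right"),
        ghost_start_direction = c("toward", "away"),
        stringsAsFactors = FALSE
      )
      cf <- cf[rep(seq_len(nrow(cf)), length.out = n_cf_block), , drop = FALSE]
      if (n_cf_block > 0) {
        cf$pattern <- sample(seq_along(patterns), n_cf_block, replace = TRUE)
        cf$conflict <- FALSE
      }
      block <- rbind(conflict, if (n_cf_block > 0) cf)
      block <- block[sample(nrow(block)), , drop = FALSE]
      block$block <- b
      block
    })
    specs <- do.call(rbind, blocks)
    specs$trial_id <- seq_len(nrow(specs))

    L <- config$corridor_length
    dot_lo <- config$pacman_start_offset + 15
    dot_hi <- 0.75 * L
    base_pos <- seq(dot_lo, dot_hi, length.out = config$n_dots)

    geom <- lapply(seq_len(nrow(specs)), function(i) {
      jit <- runif(config$n_dots, -config$dot_jitter, config$dot_jitter)
      pos <- sort(base_pos + jit)
      patrol_min <- max(pos) + config$patrol_buffer +
        runif(1, 0, 2 * config$dot_jitter)
      ghost_start <- patrol_min + 0.5 * (L - patrol_min)
      list(pos = pos, patrol_min = patrol_min, ghost_start = ghost_start)
    })

    attack_outcome <- sample(rep(c("chase", "strike"),
                                 length.out = config$n_trials))

    tibble(
      trial_id = specs$trial_id,
      block = specs$block,
      conflict = specs$conflict,
      pacman_start_side = specs$pacman_start_side,
      ghost_start_direction = specs$ghost_start_direction,
      pacman_start_position = config$pacman_start_offset,
      patrol_min = map_dbl(geom, "patrol_min"),
      ghost_start_position = map_dbl(geom, "ghost_start"),
      dot_positions = map(geom, "pos"),
      dot_sizes = map(specs$pattern, ~ patterns[[.x]]),
      last_dot_size = map_chr(specs$pattern, ~ tail(patterns[[.x]], 1)),
      attack_outcome = attack_outcome
    )
  })
}

#' @importFrom purrr map_chr
NULL
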