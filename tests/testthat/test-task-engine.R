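test_that("session generation is counterbalanced, stratified and deterministic", {
  cfg <- task_config()
  s <- generate_session(cfg, seed = 42)
  expect_equal(nrow(s), 240)
  expect_equal(sum(!s$conflict), 48)
  expect_equal(length(unique(s$block)), 12)
  # conflict-free trials stratify evenly across blocks
  per_block <- s |> dplyr::group_by(block) |>
    dplyr::summarise(cf = sum(!conflict))
  expect_true(all(per_block$cf == 4))
  # side x ghost-direction crossing balanced within each block
  combos <- s |> dplyr::count(block, pacman_start_side, ghost_start_direction)
  expect_true(all(combos$n == 5))
  # last-reward size balanced among conflict trials
  expect_equal(sum(s$last_dot_size[s$conflict] == "large"), 96)
  expect_identical(s, generate_session(cfg, seed = 42))
  expect_false(identical(s, generate_session(cfg, seed = 43)))
})

test_that("trial geometry respects dot and patrol invariants", {
  s <- generate_session(task_config(), seed = 5)
  for (i in c(1, 57, 240)) {
    pos <- s$dot_positions[[i]]
    expect_true(all(diff(pos) > 0))
    expect_true(all(pos > s$pacman_start_position[i]))
    expect_true(all(pos < s$patrol_min[i]))
    expect_lt(s$patrol_min[i], s$ghost_start_position[i])
  }
})

test_that("counterbalancing errors for impossible configurations", {
  expect_error(generate_session(task_config(block_length = 10,
                                            conflict_free_fraction = 0.3),
                                seed = 1),
               "counterbalancing")
  expect_error(task_config(n_trials = 230), "divisible")
  expect_error(task_config(conflict_free_fraction = 0.17), "integer")
})

test_that("attack hazard follows the scaled beta CDF of proximity", {
  cfg <- task_config()
  d_grid <- seq(0, cfg$corridor_length, length.out = 41)
  p <- attack_probability(d_grid, cfg)
  # independent evaluation of the scaled beta form
  oracle <- cfg$hazard_max *
    pbeta(1 - d_grid / cfg$corridor_length, cfg$hazard_alpha, cfg$hazard_beta)
  expect_equal(p, oracle)
  expect_true(all(diff(p) <= 1e-12))            # monotone non-increasing
  expect_true(all(p >= 0 & p <= cfg$hazard_max))
  expect_lt(attack_probability(cfg$corridor_length, cfg), 1e-6)
  expect_error(attack_probability(-1, cfg), "non-negative")
})

test_that("stepping obeys movement, dot-collection and end rules", {
  cfg <- task_config()
  s <- generate_session(cfg, seed = 2)
  spec <- as.list(s[which(!s$conflict)[1], ])
  state <- aacircuit:::new_trial_state(spec, cfg)
  p0 <- state$pacman_pos
  state <- step_trial(state, "none", cfg)
  expect_equal(state$pacman_pos, p0)           # no movement before a press
  state <- step_trial(state, "toward", cfg)
  expect_equal(state$pacman_pos, p0 + cfg$pacman_speed)
  state <- step_trial(state, "none", cfg)      # keeps last commanded direction
  expect_equal(state$pacman_pos, p0 + 2 * cfg$pacman_speed)
  state <- step_trial(state, "away", cfg)
  expect_length(state$turnaround_ticks, 1)
})

test_that("run_trial outcomes match the scoring rules", {
  cfg <- task_config()
  s <- generate_session(cfg, seed = 3)
  cf <- s[which(!s$conflict)[1], ]
  log <- run_trial(cf, policy_approach_all(), cfg, seed = 1)
  expect_equal(log$dots_collected, 5)
  expect_equal(log$points,
               sum(ifelse(unlist(cf$dot_sizes) == "small", 10, 20)))
  expect_false(log$caught)
  expect_equal(log$outcome, "exit")

  log0 <- run_trial(s[1, ], policy_avoid(), cfg, seed = 1)
  expect_equal(log0$dots_collected, 0)
  expect_equal(log0$points, 0)

  logn <- run_trial(s[1, ], policy_none(), cfg, seed = 1)
  expect_equal(logn$outcome, "timeout")
  expect_equal(logn$trial_end, cfg$tick_cap * cfg$tick_ms)
})

test_that("strike always captures and zeroes points; chase is escapable", {
  cfg <- task_config(hazard_max = 0.2)  # frequent attacks for coverage
  s <- generate_session(cfg, seed = 9)
  trials <- run_session(s[s$conflict, ][1:60, ], policy_approach_all(), cfg,
                        seed = 9)
  strikes <- dplyr::filter(trials, attack_type == "strike")
  chases <- dplyr::filter(trials, attack_type == "chase")
  expect_gt(nrow(strikes), 5)
  expect_gt(nrow(chases), 5)
  expect_true(all(strikes$caught))
  expect_true(all(strikes$points == 0))
  # fleeing at attack onset with matched speeds preserves the gap
  expect_true(all(!chases$caught))
  expect_true(all(trials$caught[!is.na(trials$attack_type)] ==
                    (trials$attack_type[!is.na(trials$attack_type)] == "strike")))
})

test_that("minigame bookkeeping resets lives and score", {
  cfg <- task_config()
  s <- generate_session(cfg, seed = 4)
  trials <- run_session(s, policy_avoid(), cfg, seed = 4)
  expect_equal(max(trials$minigame), 12)        # never caught: 12 x 20 trials
  firsts <- trials |> dplyr::group_by(minigame) |> dplyr::slice(1)
  expect_true(all(firsts$lives_at_start == 3))

  # forced captures end a minigame after 3 losses
  cfg2 <- task_config(hazard_max = 0.9)
  aggressive <- function(obs) "toward"
  tr2 <- run_session(s[1:30, ], aggressive, cfg2, seed = 5)
  caught_cum <- cumsum(tr2$caught[tr2$minigame == 1])
  expect_lte(max(caught_cum), 3)
})

test_that("behavior summary applies exclusions and reward grouping", {
  cfg <- task_config()
  s <- generate_session(cfg, seed = 6)
  trials <- run_session(s, policy_threshold(base = 40, large_shrink = 12),
                        cfg, seed = 6)
  bs <- summarize_behavior(trials)
  expect_equal(bs$n_trials, 240)
  expect_true(bs$mean_dots_per_trial > 2 && bs$mean_dots_per_trial <= 5)
  # reward-sensitive agent approaches closer when the last dot is large
  expect_lt(bs$turnaround_distance_large, bs$turnaround_distance_small)
  # oracle: direct group means over the same exclusion set
  turn <- dplyr::filter(trials, conflict, n_turnarounds > 0,
                        !is.na(turnaround_distance))
  expect_equal(bs$mean_turnaround_distance, mean(turn$turnaround_distance))
  expect_equal(bs$turnaround_distance_large,
               mean(turn$turnaround_distance[turn$last_dot_size == "large"]))

  one <- trials[which(trials$conflict & trials$n_turnarounds > 0)[1], ]
  expect_equal(summarize_behavior(one)$mean_turnaround_distance,
               one$turnaround_distance)
  expect_error(summarize_behavior(trials[0, ]), "no trials")
})

test_that("session-level chase/strike assignment stays balanced", {
  cfg <- task_config(hazard_max = 0.15)
  s <- generate_session(cfg, seed = 8)
  trials <- run_session(s, policy_approach_all(), cfg, seed = 8)
  attacks <- dplyr::filter(trials, !is.na(attack_type))
  expect_gt(nrow(attacks), 50)
  frac <- mean(attacks$attack_type == "chase")
  se <- sqrt(0.25 / nrow(attacks))
  expect_lt(abs(frac - 0.5), 3 * se + 1e-9)
})
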