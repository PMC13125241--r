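test_that("spectral GC recovers unidirectional AR coupling", {
  cfg <- gc_config(fs = 100)
  withr::with_seed(3, {
    ntr <- 30; ns <- 80
    x <- matrix(rnorm(ntr * ns), ntr)
    y <- matrix(rnorm(ntr * ns), ntr)
    y[, 3:ns] <- y[, 3:ns] + 0.8 * x[, 1:(ns - 2)]   # x leads by 2 samples
  })
  g <- spectral_gc(x, y, cfg)
  expect_gt(g$gc_xy, g$gc_yx)
  expect_gt(g$gc_xy, 0.1)

  # independent brute-force oracle: time-domain variance-ratio GC from
  # restricted vs full lag regressions, pooled across trials
  p <- 6
  embed_tr <- function(m) {
    do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
      stats::embed(m[i, ], p + 1)
    }))
  }
  ey <- embed_tr(y); ex <- embed_tr(x)
  restricted <- stats::lm.fit(cbind(1, ey[, -1]), ey[, 1])
  full <- stats::lm.fit(cbind(1, ey[, -1], ex[, -1]), ey[, 1])
  oracle_xy <- log(mean(restricted$residuals^2) / mean(full$residuals^2))
  ry <- stats::lm.fit(cbind(1, ex[, -1]), ex[, 1])
  fy <- stats::lm.fit(cbind(1, ex[, -1], ey[, -1]), ex[, 1])
  oracle_yx <- log(mean(ry$residuals^2) / mean(fy$residuals^2))
  expect_gt(oracle_xy, oracle_yx)              # oracle agrees on direction
  # band-averaged spectral score tracks the time-domain score
  expect_lt(abs(g$gc_yx - oracle_yx), 0.1)

  # independent channels: both directions near zero
  withr::with_seed(4, {
    x0 <- matrix(rnorm(30 * 80), 30); y0 <- matrix(rnorm(30 * 80), 30)
  })
  g0 <- spectral_gc(x0, y0, cfg)
  expect_lt(max(g0$gc_xy, g0$gc_yx), 0.05)

  expect_error(spectral_gc(x, x, cfg), "itself")
})

test_that("net Granger is antisymmetric and detects the planted direction", {
  ep <- coupled_epochs()
  ng <- cached("ng_ab", net_granger(ep, "AMY_1", "OFC_1"))
  ng_rev <- net_granger(ep, "OFC_1", "AMY_1")
  expect_lt(max(abs(ng$series$net + ng_rev$series$net)), 1e-10)
  expect_gt(mean(ng$series$net), 0)            # AMY leads OFC by design
  # analysis restricted to the final 1500 ms of approach
  expect_true(all(ng$series$time >= -1500 & ng$series$time <= 0))
  # literal (ungrouped) reading is offered but not antisymmetric in general
  lit <- net_granger(ep, "AMY_1", "OFC_1", literal = TRUE)
  expect_false(isTRUE(all.equal(lit$series$net, ng$series$net)))
})

test_that("shared zero-lag signal produces no net directionality", {
  withr::with_seed(9, {
    ntr <- 40; ns <- 450
    shared <- matrix(rnorm(ntr * ns), ntr)
    a <- shared + 0.7 * matrix(rnorm(ntr * ns), ntr)
    b <- shared + 0.7 * matrix(rnorm(ntr * ns), ntr)
  })
  ep <- epochs_from_matrices(list(a, b), fs = 100, t0 = -2500)
  gt <- gc_permutation_test(ep, "ch1", "ch2", gc_config(n_perm = 100),
                            seed = 4)
  expect_false(gt$qualifies)
  expect_lt(abs(gt$mean_net), 0.05)
})

test_that("permutation test qualifies the coupled pair with the right sign", {
  ep <- coupled_epochs()
  gt <- cached("gc_test_coupled",
               gc_permutation_test(ep, "AMY_1", "OFC_1",
                                   gc_config(n_perm = 150), seed = 5))
  expect_true(gt$qualifies)
  expect_gte(gt$n_sig, 50)                     # at least 500 ms at 100 Hz
  expect_equal(gt$direction, 1)
  null_pair <- gc_permutation_test(ep, "HC_1", "MFG_1",
                                   gc_config(n_perm = 100), seed = 5)
  expect_false(null_pair$qualifies)
  # duration rule above the analyzable window: nothing qualifies
  strict <- gc_permutation_test(ep, "AMY_1", "OFC_1",
                                gc_config(n_perm = 100, min_ms = Inf),
                                seed = 5)
  expect_false(strict$qualifies)
})

test_that("concatenation bookkeeping is exact", {
  ds <- coupled_fixture()
  ept <- epoch_lfp(ds, "trial_onset", c(-500, 3500))
  th <- bandpass_theta(resample_epochs(ept, 100))
  cn <- concat_approach(th, ds$events)
  lens <- round((ds$events$turnaround - ds$events$movement_onset) / 10)
  expect_equal(ncol(cn$x), sum(cn$boundaries$length))
  expect_equal(nrow(cn$boundaries) + length(cn$dropped), nrow(ds$events))
  expect_equal(cn$boundaries$length, lens[cn$boundaries$trial],
               tolerance = 0.05)
  # 10 trials of exactly 1 s at 100 Hz concatenate to 1000 samples
  ev10 <- tibble::tibble(trial = 1:10, movement_onset = 500,
                         turnaround = 1500,
                         attack_onset = NA, trial_end = 3000)
  ds10 <- ds; ds10$events <- ev10[seq_len(nrow(ds$events)), ]
  ds10$events$trial <- seq_len(nrow(ds$events))
  cn10 <- concat_approach(th, ds10$events)
  expect_true(all(cn10$boundaries$length == 100))
})

test_that("cross-correlation identifies identity and planted lags", {
  ds <- coupled_fixture()
  cn <- cached("concat", {
    ept <- epoch_lfp(ds, "trial_onset", c(-500, 3500))
    concat_approach(bandpass_theta(resample_epochs(ept, 100)), ds$events)
  })
  same <- cross_correlation_test(cn, "AMY_1", "AMY_1", n_perm = 100, seed = 1)
  expect_equal(same$best_lag, 0)
  expect_equal(same$max_corr, 1)

  cc <- cross_correlation_test(cn, "AMY_1", "OFC_1", n_perm = 150, seed = 2)
  expect_true(cc$retained)
  expect_lte(abs(cc$best_lag_ms - 25), 10)     # within one 100 Hz sample
  expect_gt(cc$best_lag, 0)                    # source leads target

  cc0 <- cross_correlation_test(cn, "HC_1", "MFG_1", n_perm = 150, seed = 2)
  expect_false(cc0$retained)

  few <- cn
  few$boundaries <- few$boundaries[1:2, ]
  expect_error(cross_correlation_test(few, "AMY_1", "OFC_1"), "3 trials")
})

test_that("granger and cross-correlation agree on the coupled direction", {
  gt <- cached("gc_test_coupled",
               gc_permutation_test(coupled_epochs(), "AMY_1", "OFC_1",
                                   gc_config(n_perm = 150), seed = 5))
  cn <- cached("concat", {
    ds <- coupled_fixture()
    ept <- epoch_lfp(ds, "trial_onset", c(-500, 3500))
    concat_approach(bandpass_theta(resample_epochs(ept, 100)), ds$events)
  })
  cc <- cross_correlation_test(cn, "AMY_1", "OFC_1", n_perm = 100, seed = 3)
  expect_equal(sign(gt$mean_net), sign(cc$best_lag))
})

test_that("consensus rule requires strong agreement in the same direction", {
  expect_true(direction_consensus(0.97, 0.96)$consensus)
  expect_equal(direction_consensus(0.97, 0.96)$direction, 1)
  expect_false(direction_consensus(0.99, 0.60)$consensus)
  expect_true(direction_consensus(0.01, 0.03)$consensus)
  expect_equal(direction_consensus(0.01, 0.03)$direction, -1)
  # opposite strong evidence is not consensus
  expect_false(direction_consensus(0.99, 0.01)$consensus)
  # a missing method leaves consensus undefined, not false
  expect_true(is.na(direction_consensus(NA, 0.99)$consensus))
})
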