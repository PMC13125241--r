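test_that("preprocessing removes line noise and keeps the signal band", {
  fs <- 1000
  t <- (0:(8 * fs - 1)) / fs
  x <- 1 + sin(2 * pi * 5 * t) + 0.8 * sin(2 * pi * 60 * t) +
    0.5 * sin(2 * pi * 120 * t)
  y <- preprocess_lfp(x, fs)
  expect_length(y, length(x))
  band_amp <- function(sig, f0) {
    n <- length(sig)
    sp <- Mod(fft(sig)) / n
    idx <- round(f0 * n / fs) + 1
    2 * max(sp[(idx - 2):(idx + 2)])
  }
  mid <- (2 * fs):(6 * fs)
  expect_lt(20 * log10(band_amp(y[mid], 60) / band_amp(x[mid], 60)), -20)
  expect_lt(20 * log10(band_amp(y[mid], 120) / band_amp(x[mid], 120)), -20)
  expect_lt(abs(band_amp(y[mid], 5) / band_amp(x[mid], 5) - 1), 0.01)
  expect_lt(abs(mean(y[mid]) - 1), 0.01)       # DC preserved
  expect_error(preprocess_lfp(x, fs = 250), "exceed 300")
})

test_that("bipolar referencing cancels common signal", {
  fs <- 500
  t <- (0:999) / fs
  common <- sin(2 * pi * 60 * t)
  diff5 <- sin(2 * pi * 5 * t)
  data <- rbind(c1 = common + diff5, c2 = common, c3 = common - diff5)
  out <- bipolar_reference(data, shaft_pairs(c("c1", "c2", "c3")))
  expect_equal(nrow(out), 2)                   # n contacts -> n - 1 channels
  expect_equal(out["c1-c2", ], diff5, ignore_attr = TRUE)
  # identical contacts cancel exactly
  same <- rbind(a = common, b = common)
  expect_equal(max(abs(bipolar_reference(same, shaft_pairs(c("a", "b"))))), 0)
  # shared 60 Hz is gone, differential 5 Hz retained
  sp <- function(sig, f0) {
    n <- length(sig); idx <- round(f0 * n / fs) + 1
    Mod(fft(sig))[idx]
  }
  expect_lt(sp(out[1, ], 60) / sp(data[1, ], 60), 1e-6)
  expect_gt(sp(out[1, ], 5), 0.9 * sp(diff5, 5))
  expect_error(bipolar_reference(data, tibble::tibble(anode = "c1",
                                                      cathode = "zz")),
               "unmatched")
})

test_that("epoching aligns events and masks missing ones", {
  ds <- make_fixture("attack_hfa", seed = 3, n_trials = 8)
  ep <- epoch_lfp(ds, "turnaround", c(-2500, 2500))
  expect_equal(range(ep$times), c(-2500, 2500))
  # sample at time 0 equals the raw sample at the event
  tr <- 1
  i_ev <- which.min(abs(ds$times - ds$events$turnaround[tr]))
  expect_equal(ep$data[, tr, which(ep$times == 0)], ds$signal[, tr, i_ev])
  # attack lock masks attack-free trials
  expect_warning(epa <- epoch_lfp(ds, "attack_onset", c(-500, 500)),
                 "masked")
  expect_equal(sum(epa$valid), sum(!is.na(ds$events$attack_onset)))
  # a window only some trials can support masks the others, with a warning
  hi <- max(ds$times) - stats::median(ds$events$trial_end)
  expect_warning(epw <- epoch_lfp(ds, "trial_end", c(-500, hi)), "masked")
  expect_lt(sum(epw$valid), length(epw$valid))
  expect_gt(sum(epw$valid), 0)
  # a window no trial supports is an error
  expect_error(suppressWarnings(epoch_lfp(ds, "trial_end", c(-500, 60000))),
               "no valid trials")
  expect_error(epoch_lfp(ds, "turnaround", c(2500, -2500)))
})

test_that("morlet TFR localizes tones and vanishes on zero signal", {
  gt <- ground_truth(channels = tibble::tibble(
    channel_id = "HC_1", region = "HC", hemisphere = "L"),
    theta_schedule = c(approach = 1, avoid = 1))
  ev <- synth_events(3, 1)
  ds <- generate_lfp(gt, ev, fs = 500, seed = 2)
  for (tr in 1:3) ds$signal[1, tr, ] <- sin(2 * pi * 5 * ds$times / 1000)
  ep <- epoch_lfp(ds, "trial_onset", c(0, 3000))
  tf <- morlet_tfr(ep, decim = 5)
  mid <- tf$edge_valid[which.min(abs(tf$freqs - 5)), ]
  pw <- rowMeans(tf$power[1, 1, , mid])
  peak <- which.max(pw)
  bin5 <- which.min(abs(tf$freqs - 5))
  expect_lte(abs(peak - bin5), 1)              # within one frequency bin

  ds$signal[1, , ] <- 0
  tfz <- morlet_tfr(epoch_lfp(ds, "trial_onset", c(0, 3000)), decim = 5)
  expect_equal(max(tfz$power), 0)
  expect_error(morlet_tfr(epoch_lfp(ds, "trial_onset", c(0, 500))),
               "shorter than the widest wavelet")
})

test_that("white-noise power is flat across frequencies", {
  gt <- ground_truth(channels = tibble::tibble(
    channel_id = "HC_1", region = "HC", hemisphere = "L"))
  ev <- synth_events(6, 2)
  ds <- generate_lfp(gt, ev, fs = 500, seed = 3)
  withr::with_seed(8, {
    for (tr in 1:6) ds$signal[1, tr, ] <- rnorm(dim(ds$signal)[3])
  })
  tf <- morlet_tfr(epoch_lfp(ds, "trial_onset", c(0, 3000)), decim = 5)
  sel <- tf$freqs > 5 & tf$freqs < 100
  pw <- sapply(which(sel), function(fi)
    mean(tf$power[1, , fi, tf$edge_valid[fi, ]]))
  slope <- unname(coef(stats::lm(log(pw) ~ log(tf$freqs[sel])))[2])
  expect_lt(abs(slope), 0.3)
})

test_that("ITI z-scoring is an identity on its own baseline", {
  ds <- make_fixture("task_modulated", seed = 5, n_trials = 10)
  ep <- epoch_lfp(ds, "trial_onset", c(-1000, 2000))
  tf <- morlet_tfr(ep, decim = 10)
  z <- baseline_zscore(tf, c(-1000, 0))
  bl <- which(z$times >= -1000 & z$times <= 0)
  for (fi in c(10, 40, 70)) {
    vals <- z$power[1, , fi, bl]
    expect_lt(abs(mean(vals)), 1e-8)
    expect_lt(abs(sd(vals) - 1), 0.01)
  }
  expect_error(band_power(tf, "theta", baseline = c(5e4, 6e4)), "baseline")
})

test_that("injected high-frequency burst elevates sub-band HFA", {
  ds <- make_fixture("attack_hfa", seed = 6, n_trials = 12)
  suppressWarnings(ep <- epoch_lfp(ds, "attack_onset", c(-800, 800)))
  grid_hi <- dplyr::filter(wavelet_grid(), freq >= 20)
  tf <- morlet_tfr(ep, grid = grid_hi, decim = 10)
  hfa <- band_power(tf, "hfa", baseline = c(-800, -500))
  burst <- window_power(hfa, c(50, 250))
  pre <- window_power(hfa, c(-450, -250))
  d <- burst$value - pre$value
  burst_ch <- burst$channel %in% ds$ground_truth$hfa_events$channel
  expect_gt(min(tapply(d[burst_ch], burst$channel[burst_ch], mean)), 2)
  expect_lt(max(abs(tapply(d[!burst_ch], burst$channel[!burst_ch], mean))), 1)
})

test_that("band power pipeline commutes with channel reordering", {
  ds <- make_fixture("task_modulated", seed = 7, n_trials = 6)
  ep <- epoch_lfp(ds, "turnaround", c(-1000, 1000))
  grid <- dplyr::filter(wavelet_grid(), freq >= 2)
  bp1 <- band_power(morlet_tfr(ep, grid = grid, decim = 10), "theta",
                    baseline = c(-1000, -800))
  ep_r <- ep
  ord <- rev(seq_len(nrow(ep$channels)))
  ep_r$data <- ep$data[ord, , , drop = FALSE]
  ep_r$channels <- ep$channels[ord, ]
  bp2 <- band_power(morlet_tfr(ep_r, grid = grid, decim = 10), "theta",
                    baseline = c(-1000, -800))
  expect_equal(bp2$values[1, , ], bp1$values[ord[1], , ])
  expect_equal(bp2$values, bp1$values[ord, , ], tolerance = 1e-12)
})

test_that("theta band-pass is zero-phase with the designed band edges", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  mid <- (3 * fs):(7 * fs)
  y5 <- bandpass_theta(sin(2 * pi * 5 * t), fs)
  y20 <- bandpass_theta(sin(2 * pi * 20 * t), fs)
  expect_gt(sd(y5[mid]) / sd(sin(2 * pi * 5 * t)[mid]), 0.95)
  expect_lt(20 * log10(sd(y20[mid]) / sd(sin(2 * pi * 20 * t)[mid])), -20)
  # zero phase: cross-correlation of input and output peaks at lag 0
  cc <- stats::ccf(y5[mid], sin(2 * pi * 5 * t)[mid], lag.max = 20,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("512 and 2000 Hz dialects of one process agree after the pipeline", {
  ds <- make_fixture("task_modulated", seed = 9, n_trials = 12)
  two <- list()
  for (fs_new in c(2000, 512)) {
    d2 <- ds
    n_new <- length(aacircuit:::resample_to(ds$signal[1, 1, ], ds$fs, fs_new))
    sig <- array(NA_real_, dim = c(2, dim(ds$signal)[2], n_new))
    for (ch in 1:2) for (tr in seq_len(dim(ds$signal)[2])) {
      sig[ch, tr, ] <- aacircuit:::resample_to(ds$signal[ch, tr, ],
                                               ds$fs, fs_new)
    }
    d2$signal <- sig
    d2$channels <- ds$channels[1:2, ]
    d2$fs <- fs_new
    d2$times <- ds$times[1] + (seq_len(n_new) - 1) * 1000 / fs_new
    ep <- epoch_lfp(d2, "turnaround", c(-1500, 1500))
    bp <- band_power(morlet_tfr(ep, decim = round(fs_new / 100)), "theta",
                     baseline = c(-1500, -1300))
    two[[as.character(fs_new)]] <- window_power(bp, c(-1200, 1200))$value
  }
  expect_lt(max(abs(two[["2000"]] - two[["512"]])), 0.2)
})
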