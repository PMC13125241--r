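# Synthetic trial-structured LFP surrogates with known ground truth.

REGIONS <- c("HC", "AMY", "OFC", "ACC", "MFG")

#' Ground-truth structure for synthetic LFP generation
#'
#' Encodes the statistical structure the analysis stages are designed to
#' recover: channel/region layout, directed theta couplings with lags,
#' task-locked theta amplitude schedules, high-frequency bursts, and an
#' optional zero-lag (volume-conduction-like) mixing matrix.
#'
#' @param channels Tibble with columns `channel_id`, `region` (one of
#'   HC, AMY, OFC, ACC, MFG), `hemisphere` (`"L"`/`"R"`), and optionally
#'   `modulated` (logical; whether the channel's theta follows the
#'   approach/avoid schedule, default `TRUE`).
#' @param couplings Tibble with `source`, `target` (channel ids),
#'   `lag_ms` (>= 0) and `gain` (>= 0): the target receives a lagged,
#'   gain-weighted copy of the source's theta oscillator.
#' @param theta_schedule Named numeric, amplitude multipliers
#'   `c(approach = , avoid = )` applied to the theta oscillator between
#'   movement onset and turnaround (approach) and between turnaround and
#'   trial end (avoid); baseline multiplier is 1 elsewhere.
#' @param hfa_events Tibble with `channel`, `anchor` (an event column
#'   name, typically `"attack_onset"`), `amplitude`: a 300-ms
#'   raised-cosine burst of 80-120 Hz noise added at the anchor.
#' @param zero_lag_mixing Optional square, invertible mixing matrix
#'   (channels x channels) applied instantaneously after generation.
#' @param theta_amp Baseline oscillator SD in signal units.
#' @param noise_exponent Spectral exponent of the 1/f background.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(channels,
                         couplings = NULL,
                         theta_schedule = c(approach = 2, avoid = 1),
                         hfa_events = NULL,
                         zero_lag_mixing = NULL,
                         theta_amp = 1,
                         noise_exponent = 1) {
  channels <- as_tibble(channels)
  stopifnot(all(c("channel_id", "region") %in% names(channels)))
  if (!all(channels$region %in% REGIONS)) {
    stop_bad("regions must be among %s", paste(REGIONS, collapse = ", "))
  }
  if (anyDuplicated(channels$channel_id)) stop_bad("duplicate channel ids")
  if (!"hemisphere" %in% names(channels)) channels$hemisphere <- "L"
  if (!"modulated" %in% names(channels)) channels$modulated <- TRUE
  if (!is.null(couplings)) {
    couplings <- as_tibble(couplings)
    stopifnot(all(c("source", "target", "lag_ms", "gain") %in% names(couplings)))
    if (any(couplings$lag_ms < 0)) stop_bad("coupling lag_ms must be >= 0")
    if (any(couplings$gain < 0)) stop_bad("coupling gain must be >= 0")
    bad <- setdiff(c(couplings$source, couplings$target), channels$channel_id)
    if (length(bad)) stop_bad("unknown coupling channel: %s", bad[1])
  }
  if (!is.null(hfa_events)) {
    hfa_events <- as_tibble(hfa_events)
    stopifnot(all(c("channel", "anchor", "amplitude") %in% names(hfa_events)))
  }
  if (!is.null(zero_lag_mixing)) {
    zero_lag_mixing <- as.matrix(zero_lag_mixing)
    if (nrow(zero_lag_mixing) != nrow(channels) ||
        ncol(zero_lag_mixing) != nrow(channels)) {
      stop_bad("mixing matrix must be channels x channels")
    }
    if (rcond(zero_lag_mixing) < 1e-12) stop_bad("mixing matrix is singular")
  }
  stopifnot(all(c("approach", "avoid") %in% names(theta_schedule)))
  structure(
    list(channels = channels, couplings = couplings,
         theta_schedule = theta_schedule, hfa_events = hfa_events,
         zero_lag_mixing = zero_lag_mixing, theta_amp = theta_amp,
         noise_exponent = noise_exponent),
    class = "ground_truth"
  )
}

#' Synthetic per-trial task event times
#'
#' Draws realistic event schedules: movement onset about one second after
#' trial onset, an approach lasting about 1.4 s, and a two-second
#' avoidance period, matching the behavioral timing the task simulator
#' produces.
#'
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param attack_fraction Fraction of trials with an attack onset (placed
#'   shortly before the turnaround).
#' @return Tibble with `trial`, `movement_onset`, `turnaround`,
#'   `attack_onset`, `trial_end` in ms relative to trial onset.
#' @export
synth_events <- function(n_trials, seed = 1, attack_fraction = 0) {
  with_seed(child_seed(seed, 3L), {
    mo <- pmin(pmax(rnorm(n_trials, 1000, 100), 700), 1300)
    app <- pmin(pmax(rnorm(n_trials, 1400, 150), 1000), 1800)
    turn <- mo + app
    attack <- rep(NA_real_, n_trials)
    n_att <- round(attack_fraction * n_trials)
    if (n_att > 0) {
      idx <- sample(n_trials, n_att)
      attack[idx] <- turn[idx] - runif(n_att, 100, 400)
    }
    tibble(trial = seq_len(n_trials), movement_onset = mo, turnaround = turn,
           attack_onset = attack, trial_end = turn + 2000)
  })
}

# AR(2) stochastic oscillator: spectral peak at `f0`, pole radius `r`,
# generated at an internal 100 Hz rate and band-limited-upsampled to fs.
theta_oscillator <- function(n_samples, fs, f0 = 5, r = 0.95) {
  fs_int <- 100
  n100 <- ceiling(n_samples * fs_int / fs) + 1
  burn <- 200
  a1 <- 2 * r * cos(2 * pi * f0 / fs_int)
  a2 <- -r^2
  innov <- rnorm(n100 + burn)
  x <- as.numeric(signal::filter(1, c(1, -a1, -a2), innov))
  x <- x[(burn + 1):(burn + n100)]
  x <- x / sd(x)
  if (fs != fs_int) {
    x <- resample_to(x, fs_int, fs)
  }
  x[seq_len(n_samples)]
}

# Spectrally shaped Gaussian background, power ~ 1/f^exponent.
pink_noise <- function(n, fs, exponent = 1) {
  nf <- n %/% 2
  f <- seq_len(nf) * fs / n
  amp <- f^(-exponent / 2)
  phases <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  full[seq(n, n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(fft(full, inverse = TRUE))
  x / sd(x)
}

raised_cosine <- function(n) 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))

#' Generate a synthetic LFP dataset
#'
#' Each channel is a sum of 1/f background noise, a stochastic theta
#' oscillator (AR(2), 5 Hz peak) whose amplitude follows the ground
#' truth's approach/avoid schedule around the per-trial events, lagged
#' gain-weighted copies of source oscillators for every coupling, and
#' high-frequency (80-120 Hz) bursts at anchored events. Deterministic
#' given `seed`.
#'
#' @param gt A [ground_truth()].
#' @param events Event table ([synth_events()] or [lfp_events()]).
#' @param fs Sampling rate in Hz (512, 1000 and 2000 supported).
#' @param snr Ratio of theta oscillator SD to background SD.
#' @param seed Integer seed.
#' @param trial_dur_ms Trial duration; default covers the latest trial end.
#' @param iti_ms Inter-trial-interval samples prepended before trial onset
#'   (time axis starts at `-iti_ms`); used as the z-scoring baseline.
#' @param store_components If `TRUE`, the noiseless scheduled oscillator
#'   components are kept in `$components` (used by ground-truth recovery
#'   checks).
#' @return An `lfp_dataset`: list with `signal` (channels x trials x
#'   samples), `fs`, `times` (ms), `channels`, `events`, `ground_truth`,
#'   and optionally `components`.
#' @export
generate_lfp <- function(gt, events, fs = 1000, snr = 1, seed = 1,
                         trial_dur_ms = NULL, iti_ms = 1000,
                         store_components = FALSE) {
  stopifnot(inherits(gt, "ground_truth"))
  events <- as_tibble(events)
  n_trials <- nrow(events)
  if (is.null(trial_dur_ms)) {
    # leave room for a turnaround-locked +2500 ms epoch window
    need <- max(c(events$trial_end, events$turnaround + 2600), na.rm = TRUE)
    trial_dur_ms <- 500 * ceiling(need / 500)
  }
  n <- round((iti_ms + trial_dur_ms) * fs / 1000)
  times <- (seq_len(n) - 1) * 1000 / fs - iti_ms
  chans <- gt$channels
  n_ch <- nrow(chans)
  max_lag <- if (!is.null(gt$couplings)) max(gt$couplings$lag_ms) else 0
  if (max_lag >= trial_dur_ms + iti_ms) stop_bad("coupling lag exceeds trial length")
  pad <- ceiling(max_lag * fs / 1000) + 1L

  sched_one <- function(ev) {
    s <- rep(1, n)
    ramp_n <- max(round(0.1 * fs), 2)
    set_span <- function(s, from, to, value) {
      i0 <- findInterval(from, times); i1 <- findInterval(to, times)
      if (i1 <= i0) return(s)
      s[i0:i1] <- value
      s
    }
    s <- set_span(s, ev$movement_onset, ev$turnaround, gt$theta_schedule[["approach"]])
    s <- set_span(s, ev$turnaround, min(ev$trial_end, max(times)), gt$theta_schedule[["avoid"]])
    # short smoothing to avoid step edges
    k <- rep(1 / ramp_n, ramp_n)
    as.numeric(stats::filter(s, k, sides = 2, circular = TRUE))
  }

  with_seed(seed, {
    signal_arr <- array(0, dim = c(n_ch, n_trials, n))
    comp_arr <- if (store_components) array(0, dim = c(n_ch, n_trials, n)) else NULL
    noise_sd <- gt$theta_amp / snr

    for (tr in seq_len(n_trials)) {
      ev <- as.list(events[tr, ])
      sched <- sched_one(ev)
      raw_osc <- matrix(0, n_ch, n + pad)
      for (ch in seq_len(n_ch)) {
        raw_osc[ch, ] <- theta_oscillator(n + pad, fs)
      }
      eff_osc <- raw_osc
      if (!is.null(gt$couplings)) {
        for (k in seq_len(nrow(gt$couplings))) {
          cp <- gt$couplings[k, ]
          si <- match(cp$source, chans$channel_id)
          ti <- match(cp$target, chans$channel_id)
          lag_s <- round(cp$lag_ms * fs / 1000)
          shifted <- c(rep(0, lag_s), raw_osc[si, seq_len(n + pad - lag_s)])
          eff_osc[ti, ] <- eff_osc[ti, ] + cp$gain * shifted
        }
      }
      eff_osc <- eff_osc[, pad + seq_len(n), drop = FALSE]
      for (ch in seq_len(n_ch)) {
        s_ch <- if (isTRUE(chans$modulated[ch])) sched else rep(1, n)
        comp <- gt$theta_amp * s_ch * eff_osc[ch, ]
        x <- comp + noise_sd * pink_noise(n, fs, gt$noise_exponent)
        if (!is.null(gt$hfa_events)) {
          hits <- gt$hfa_events[gt$hfa_events$channel == chans$channel_id[ch], ]
          for (h in seq_len(nrow(hits))) {
            anchor_t <- ev[[hits$anchor[h]]]
            if (!is.null(anchor_t) && !is.na(anchor_t)) {
              burst_n <- round(0.3 * fs)
              i0 <- findInterval(anchor_t, times)
              idx <- i0:min(i0 + burst_n - 1, n)
              bp <- signal::butter(4, c(80, 120) / (fs / 2), "pass")
              bnoise <- as.numeric(signal::filtfilt(bp, rnorm(length(idx) + 200)))
              bnoise <- bnoise[100 + seq_along(idx)]
              bnoise <- bnoise / sd(bnoise)
              x[idx] <- x[idx] + hits$amplitude[h] *
                raised_cosine(length(idx)) * bnoise
            }
          }
        }
        signal_arr[ch, tr, ] <- x
        if (store_components) comp_arr[ch, tr, ] <- comp
      }
    }

    ds <- structure(
      list(signal = signal_arr, fs = fs, times = times, channels = chans,
           events = events, ground_truth = gt, components = comp_arr),
      class = "lfp_dataset"
    )
    if (!is.null(gt$zero_lag_mixing)) {
      ds <- inject_zero_lag_mixing(ds, gt$zero_lag_mixing)
    }
    ds
  })
}

#' Apply instantaneous linear mixing across channels
#'
#' Replaces each time sample's channel vector `x` by `M %*% x`,
#' emulating zero-lag volume conduction. Event metadata, trial count and
#' sampling rate are unchanged. Imaginary coherence and the weighted
#' phase-lag index are insensitive to such mixing; real-part coherence is
#' not — the contrast the analysis chain relies on.
#'
#' @param dataset An `lfp_dataset`.
#' @param mixing_matrix Square invertible matrix, dimension = channels.
#' @return The mixed `lfp_dataset`.
#' @export
inject_zero_lag_mixing <- function(dataset, mixing_matrix) {
  stopifnot(inherits(dataset, "lfp_dataset"))
  M <- as.matrix(mixing_matrix)
  d <- dim(dataset$signal)
  if (nrow(M) != d[1] || ncol(M) != d[1]) {
    stop_bad("mixing matrix must be %d x %d", d[1], d[1])
  }
  if (rcond(M) < 1e-12) stop_bad("mixing matrix is singular")
  flat <- matrix(dataset$signal, nrow = d[1])
  dataset$signal <- array(M %*% flat, dim = d)
  dataset$ground_truth$zero_lag_mixing <- M
  dataset
}

#' Canned synthetic datasets with documented ground truth
#'
#' Small datasets used throughout the test suite and the calibration
#' analyses:
#'
#' * `"null"`: 21 mutually independent channels (210 pairs), flat theta
#'   schedule — the type-I-error calibration input.
#' * `"coupled_lagged"`: four channels; `AMY_1` drives `OFC_1` at a 25 ms
#'   lag with gain 0.8; `HC_1` and `MFG_1` independent. Noiseless
#'   oscillator components stored for lag-recovery oracles.
#' * `"task_modulated"`: two channels per region; theta amplitude 2:1
#'   approach:avoid in all regions except the MFG (unmodulated).
#' * `"attack_hfa"`: right-MFG channels carry a high-frequency burst at
#'   attack onset (attacks on half the trials); left-MFG and hippocampal
#'   channels do not.
#'
#' @param name Fixture name.
#' @param seed Integer seed.
#' @param fs Sampling rate, Hz.
#' @param n_trials Number of trials (default 40).
#' @param snr Oscillator-to-background SD ratio.
#' @return An `lfp_dataset`.
#' @export
make_fixture <- function(name = c("null", "coupled_lagged", "task_modulated",
                                  "attack_hfa"),
                         seed = 1, fs = 1000, n_trials = 40, snr = 1) {
  name <- match.arg(name)
  ev <- synth_events(n_trials, seed,
                     attack_fraction = if (name == "attack_hfa") 0.5 else 0)
  gt <- switch(
    name,
    null = ground_truth(
      channels = tibble(
        channel_id = sprintf("%s_%d", rep(REGIONS, length.out = 21),
                             rep(1:5, each = 5)[1:21]),
        region = rep(REGIONS, length.out = 21),
        hemisphere = rep(c("L", "R"), length.out = 21)
      ),
      couplings = NULL,
      theta_schedule = c(approach = 1, avoid = 1)
    ),
    coupled_lagged = ground_truth(
      channels = tibble(
        channel_id = c("AMY_1", "OFC_1", "HC_1", "MFG_1"),
        region = c("AMY", "OFC", "HC", "MFG"),
        hemisphere = "L"
      ),
      couplings = tibble(source = "AMY_1", target = "OFC_1",
                         lag_ms = 25, gain = 0.8),
      theta_schedule = c(approach = 1, avoid = 1)
    ),
    task_modulated = ground_truth(
      channels = tibble(
        channel_id = sprintf("%s_%d", rep(REGIONS, each = 2), rep(1:2, 5)),
        region = rep(REGIONS, each = 2),
        hemisphere = rep(c("L", "R"), 5),
        modulated = rep(REGIONS, each = 2) != "MFG"
      ),
      theta_schedule = c(approach = 2, avoid = 1)
    ),
    attack_hfa = ground_truth(
      channels = tibble(
        channel_id = c("MFG_R1", "MFG_R2", "MFG_L1", "MFG_L2", "HC_1", "HC_2"),
        region = c("MFG", "MFG", "MFG", "MFG", "HC", "HC"),
        hemisphere = c("R", "R", "L", "L", "L", "R")
      ),
      hfa_events = tibble(channel = c("MFG_R1", "MFG_R2"),
                          anchor = "attack_onset", amplitude = 3),
      theta_schedule = c(approach = 1, avoid = 1)
    )
  )
  generate_lfp(gt, ev, fs = fs, snr = snr, seed = child_seed(seed, 11L),
               store_components = name == "coupled_lagged")
}

#' @export
print.lfp_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<lfp_dataset> %d channels x %d trials x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %g..%g ms; regions: %s\n", min(x$times), max(x$times),
              paste(unique(x$channels$region), collapse = ", ")))
  invisible(x)
}
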