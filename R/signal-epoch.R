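# Epoching around task events.

LOCK_EVENTS <- c("trial_onset", "movement_onset", "turnaround", "trial_end",
                 "attack_onset")

#' Re-lock trials to a task event
#'
#' Extracts a fixed window around a per-trial event from an
#' `lfp_dataset`, producing an aligned channels x trials x samples array
#' with time 0 at the lock event. Trials lacking the event, or whose
#' window would exceed the recorded samples, are masked invalid (with a
#' warning) rather than dropped, so trial indices stay aligned across
#' objects.
#'
#' @param dataset An `lfp_dataset`.
#' @param lock_event One of `"trial_onset"`, `"movement_onset"`,
#'   `"turnaround"`, `"trial_end"`, `"attack_onset"`.
#' @param window Numeric length-2, window in ms around the event
#'   (e.g. `c(-2500, 2500)`).
#' @return An `epochs` object: `data`, `fs`, `times` (ms, 0 at event),
#'   `lock_event`, `window`, `valid` mask, `events`, `channels`.
#' @export
epoch_lfp <- function(dataset, lock_event = "turnaround",
                      window = c(-2500, 2500)) {
  stopifnot(inherits(dataset, "lfp_dataset"))
  lock_event <- match.arg(lock_event, LOCK_EVENTS)
  stopifnot(length(window) == 2, window[1] < window[2])
  fs <- dataset$fs
  d <- dim(dataset$signal)
  n_keep <- round((window[2] - window[1]) * fs / 1000) + 1
  out_times <- window[1] + (seq_len(n_keep) - 1) * 1000 / fs

  ev_times <- if (lock_event == "trial_onset")

    rep(0, d[2]) else dataset$events[[lock_event]]
  if (is.null(ev_times)) stop_bad("events table lacks column `%s`", lock_event)

  data <- array(NA_real_, dim = c(d[1], d[2], n_keep))
  valid <- rep(TRUE, d[2])
  for (tr in seq_len(d[2])) {
    t_ev <- ev_times[tr]
    if (is.na(t_ev)) { valid[tr] <- FALSE; next }
    i_ev <- which.min(abs(dataset$times - t_ev))
    i0 <- i_ev + round(window[1] * fs / 1000)
    i1 <- i0 + n_keep - 1
    if (i0 < 1 || i1 > d[3]) { valid[tr] <- FALSE; next }
    data[, tr, ] <- dataset$signal[, tr, i0:i1]
  }
  if (!all(valid)) {
    warn(sprintf("%d of %d trials lack `%s` within bounds; masked invalid",
                 sum(!valid), d[2], lock_event))
  }
  if (!any(valid)) stop_bad("no valid trials after epoching")
  structure(
    list(data = data, fs = fs, times = out_times, lock_event = lock_event,
         window = window, valid = valid, events = dataset$events,
         channels = dataset$channels),
    class = "epochs"
  )
}

#' Resample epochs to a new rate
#'
#' Polyphase FIR resampling of every channel/trial; event metadata and
#' the time axis are rescaled accordingly. Connectivity and Granger
#' stages operate at 100 Hz.
#'
#' @param epochs An `epochs` object.
#' @param fs_new Target sampling rate, Hz.
#' @return An `epochs` object at `fs_new`.
#' @export
resample_epochs <- function(epochs, fs_new) {
  stopifnot(inherits(epochs, "epochs"))
  if (fs_new == epochs$fs) return(epochs)
  d <- dim(epochs$data)
  n_new <- length(resample_to(numeric(d[3]), epochs$fs, fs_new))
  out <- array(NA_real_, dim = c(d[1], d[2], n_new))
  for (ch in seq_len(d[1])) {
    for (tr in seq_len(d[2])) {
      if (epochs$valid[tr]) {
        out[ch, tr, ] <- resample_to(epochs$data[ch, tr, ], epochs$fs, fs_new)
      }
    }
  }
  epochs$data <- out
  epochs$times <- epochs$times[1] + (seq_len(n_new) - 1) * 1000 / fs_new
  epochs$fs <- fs_new
  epochs
}

#' Restrict epochs to a subset of channels
#'
#' @param epochs An `epochs` object.
#' @param channels Channel ids or indices to keep.
#' @return An `epochs` object.
#' @export
select_channels <- function(epochs, channels) {
  stopifnot(inherits(epochs, "epochs"))
  idx <- if (is.character(channels)) {
    match(channels, epochs$channels$channel_id)
  } else as.integer(channels)
  if (anyNA(idx)) stop_bad("unknown channel id")
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$channels <- epochs$channels[idx, ]
  epochs
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epochs> %d ch x %d trials (%d valid) x %d samples @ %g Hz, locked to %s [%g, %g] ms\n",
    d[1], d[2], sum(x$valid), d[3], x$fs, x$lock_event,
    x$window[1], x$window[2]))
  invisible(x)
}
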