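# Filtering and referencing.

#' Preprocess continuous data: low-pass and line-noise filters
#'
#' Zero-phase (forward-backward) low-pass at 150 Hz plus notch filters at
#' 60 Hz and its harmonic at 120 Hz. Output length equals input length.
#'
#' @param x Numeric vector, or an `lfp_dataset` (filtered per
#'   channel/trial).
#' @param fs Sampling rate, Hz; must exceed 300 so the 150 Hz band is
#'   representable with margin. Taken from the dataset when `x` is one.
#' @return Same shape as the input.
#' @export
preprocess_lfp <- function(x, fs = NULL) {
  if (inherits(x, "lfp_dataset")) {
    fs <- x$fs
    d <- dim(x$signal)
    for (ch in seq_len(d[1])) {
      for (tr in seq_len(d[2])) {
        x$signal[ch, tr, ] <- preprocess_lfp(x$signal[ch, tr, ], fs)
      }
    }
    return(x)
  }
  if (is.null(fs)) stop_bad("fs is required for vector input")
  if (fs <= 300) stop_bad("fs must exceed 300 Hz for the 150 Hz low-pass")
  nyq <- fs / 2
  lp <- signal::butter(4, 150 / nyq, "low")
  y <- signal::filtfilt(lp, as.numeric(x))
  for (f0 in c(60, 120)) {
    bs <- signal::butter(2, c(f0 - 2, f0 + 2) / nyq, "stop")
    y <- signal::filtfilt(bs, y)
  }
  y
}

#' Bipolar re-referencing of adjacent contacts
#'
#' Each output channel is the difference of two physically adjacent
#' contacts on a shaft; signal common to both contacts (reference noise,
#' volume-conducted activity) cancels.
#'
#' @param data Numeric matrix, contacts x samples, with rownames naming
#'   the contacts.
#' @param pairs Tibble with columns `anode` and `cathode` (contact
#'   names); output is `anode - cathode`. An optional `name` column
#'   labels the derived channels (default `"anode-cathode"`).
#' @return Matrix, pairs x samples.
#' @export
bipolar_reference <- function(data, pairs) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  pairs <- as_tibble(pairs)
  stopifnot(all(c("anode", "cathode") %in% names(pairs)))
  missing <- setdiff(c(pairs$anode, pairs$cathode), rownames(data))
  if (length(missing)) stop_bad("unmatched contact: %s", missing[1])
  out <- data[pairs$anode, , drop = FALSE] - data[pairs$cathode, , drop = FALSE]
  rownames(out) <- if ("name" %in% names(pairs)) pairs$name else
    paste0(pairs$anode, "-", pairs$cathode)
  out
}

#' Sequential bipolar pairs along a shaft
#'
#' @param contacts Character vector of contact names in physical order.
#' @return Tibble of `n - 1` adjacent `anode`/`cathode` pairs.
#' @export
shaft_pairs <- function(contacts) {
  stopifnot(length(contacts) >= 2)
  tibble(anode = contacts[-length(contacts)], cathode = contacts[-1])
}

# FIR taps for the theta band-pass: Hamming-window design, ~2 Hz
# transition band, capped so filtfilt remains stable on short epochs.
theta_fir <- function(fs, low, high, n_samples) {
  n_taps <- round(1.65 * fs)
  n_taps <- min(n_taps, floor(n_samples / 3) - 1)
  if (n_taps %% 2 == 1) n_taps <- n_taps - 1  # even order -> odd-length type I
  if (n_taps < 30) stop_bad("epoch too short for the theta FIR filter")
  signal::fir1(n_taps, c(low, high) / (fs / 2), type = "pass")
}

#' Zero-phase theta band-pass filter
#'
#' FIR band-pass between 3 and 8 Hz (Hamming window design) applied
#' forward and backward, so the net filter delay is zero samples and the
#' amplitude envelope can be read off the analytic signal.
#'
#' @param x Numeric vector, or an `epochs` object (filtered per
#'   channel/trial).
#' @param fs Sampling rate (ignored for `epochs` input).
#' @param low,high Band edges, Hz.
#' @return Same shape as the input.
#' @export
bandpass_theta <- function(x, fs = NULL, low = 3, high = 8) {
  if (inherits(x, "epochs")) {
    d <- dim(x$data)
    b <- theta_fir(x$fs, low, high, d[3])
    for (ch in seq_len(d[1])) {
      for (tr in seq_len(d[2])) {
        x$data[ch, tr, ] <- signal::filtfilt(signal::Ma(b), x$data[ch, tr, ])
      }
    }
    return(x)
  }
  if (is.null(fs)) stop_bad("fs is required for vector input")
  if (fs < 100) stop_bad("fs must be at least 100 Hz")
  b <- theta_fir(fs, low, high, length(x))
  signal::filtfilt(signal::Ma(b), as.numeric(x))
}
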