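# Morlet time-frequency decomposition and band power.

#' Canonical wavelet frequency grid
#'
#' 80 log-spaced frequencies from 1 to 150 Hz with 80 log-spaced cycle
#' counts from 2 to 30 matched to them, so temporal smoothing grows with
#' frequency.
#'
#' @return Tibble with `freq` (Hz) and `cycles`.
#' @export
wavelet_grid <- function() {
  tibble(
    freq = exp(seq(log(1), log(150), length.out = 80)),
    cycles = exp(seq(log(2), log(30), length.out = 80))
  )
}

# Complex Morlet wavelet sampled at fs; sigma_t = cycles / (2 pi f).
morlet_wavelet <- function(freq, cycles, fs) {
  sigma_t <- cycles / (2 * pi * freq)
  half <- ceiling(3.5 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))   # unit energy
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every channel/trial with complex Morlet wavelets on the
#' canonical 80-frequency grid (or a subset) via FFT. Power output is
#' block-averaged down by `decim`; complex output (needed for
#' cross-spectra) requires `decim = 1`. Samples within half a wavelet
#' support of the epoch edges are flagged per frequency in `edge_valid`
#' and should be excluded from statistics windows.
#'
#' @param epochs An `epochs` object.
#' @param grid Tibble with `freq` and `cycles`; defaults to
#'   [wavelet_grid()].
#' @param decim Integer temporal decimation factor applied to power.
#' @param output `"power"` or `"complex"`.
#' @return A `tfr` object: `power` (channels x trials x freqs x time; or
#'   complex coefficients), `freqs`, `cycles`, `times`, `fs_out`,
#'   `edge_valid` (freqs x time), plus channel/trial metadata.
#' @export
morlet_tfr <- function(epochs, grid = wavelet_grid(), decim = 10,
                       output = c("power", "complex")) {
  stopifnot(inherits(epochs, "epochs"))
  output <- match.arg(output)
  if (output == "complex" && decim != 1) {
    stop_bad("complex output requires decim = 1")
  }
  fs <- epochs$fs
  d <- dim(epochs$data)
  n <- d[3]
  freqs <- grid$freq
  cycles <- grid$cycles

  wl <- lapply(seq_along(freqs),
               function(i) morlet_wavelet(freqs[i], cycles[i], fs))
  max_half <- max(map_int(wl, ~ (length(.x) - 1L) %/% 2L))
  if (2 * max_half + 1 > n) {
    stop_bad("epoch (%d samples) shorter than the widest wavelet (%d samples)",
             n, 2 * max_half + 1)
  }
  nfft <- stats::nextn(n + 2 * max_half, 2)
  wfft <- lapply(wl, function(w) {
    half <- (length(w) - 1L) %/% 2L
    # centre the wavelet so convolution output is aligned with the input
    padded <- complex(real = numeric(nfft))
    idx <- c(seq_len(half + 1), nfft - seq_len(half) + 1)
    padded[idx] <- c(w[(half + 1):length(w)], rev(w[seq_len(half)]))
    fft(padded)
  })

  n_out <- if (output == "power") floor(n / decim) else n
  arr <- array(if (output == "power") NA_real_ else NA_complex_,
               dim = c(d[1], d[2], length(freqs), n_out))
  for (ch in seq_len(d[1])) {
    for (tr in seq_len(d[2])) {
      if (!epochs$valid[tr]) next
      xf <- fft(c(epochs$data[ch, tr, ], numeric(nfft - n)))
      for (fi in seq_along(freqs)) {
        conv <- fft(xf * wfft[[fi]], inverse = TRUE)[seq_len(n)] / nfft
        if (output == "power") {
          arr[ch, tr, fi, ] <- block_average(Mod(conv)^2, decim)
        } else {
          arr[ch, tr, fi, ] <- conv
        }
      }
    }
  }
  times <- if (output == "power") {
    block_average(epochs$times, decim)
  } else epochs$times
  edge_valid <- matrix(TRUE, length(freqs), n_out)
  for (fi in seq_along(freqs)) {
    half <- (length(wl[[fi]]) - 1L) %/% 2L
    bad <- epochs$times < epochs$times[1] + half * 1000 / fs |
      epochs$times > epochs$times[n] - half * 1000 / fs
    edge_valid[fi, ] <- if (output == "power") {
      block_average(as.numeric(!bad), decim) > 0.999
    } else !bad
  }
  structure(
    list(power = arr, freqs = freqs, cycles = cycles, times = times,
         fs_out = fs / (if (output == "power") decim else 1),
         edge_valid = edge_valid, output = output,
         channels = epochs$channels, valid = epochs$valid,
         lock_event = epochs$lock_event),
    class = "tfr"
  )
}

hfa_subbands <- function() {
  lo <- seq(70, 130, by = 10)
  tibble(lo = lo, hi = lo + 20)
}

#' Log-transform and z-score wavelet power against an ITI baseline
#'
#' Natural-log-transforms power and z-scores every (channel, frequency)
#' series against the mean and SD of the baseline window, pooled across
#' valid trials. Applying the baseline window to itself therefore returns
#' mean 0 and SD 1 at every frequency.
#'
#' @param tfr A power `tfr`.
#' @param baseline Length-2 ms window on the `tfr` time axis.
#' @return The `tfr` with z-scored power and a `baseline` field.
#' @export
baseline_zscore <- function(tfr, baseline) {
  stopifnot(inherits(tfr, "tfr"), tfr$output == "power")
  stopifnot(length(baseline) == 2, baseline[1] < baseline[2])
  bl_idx <- which(tfr$times >= baseline[1] & tfr$times <= baseline[2])
  if (length(bl_idx) < 2) stop_bad("baseline window contains too few samples")
  d <- dim(tfr$power)
  logp <- log(pmax(tfr$power, .Machine$double.xmin))
  z <- array(NA_real_, dim = d)
  for (ch in seq_len(d[1])) {
    for (fi in seq_len(d[3])) {
      bl <- logp[ch, tfr$valid, fi, bl_idx]
      m <- mean(bl); s <- sd(bl)
      if (!is.finite(s) || s < 1e-12) stop_bad("zero-variance baseline")
      z[ch, , fi, ] <- (logp[ch, , fi, ] - m) / s
    }
  }
  tfr$power <- z
  tfr$output <- "zscore"
  tfr$baseline <- baseline
  tfr
}

#' Band-limited, baseline-normalized power
#'
#' Log-transforms wavelet power, z-scores each frequency against an
#' inter-trial-interval baseline (per channel, pooled across trials),
#' averages frequencies within the requested band, and block-averages
#' the result down to a common 20 Hz rate for statistics. The theta band
#' averages the frequencies in 3-8 Hz directly; high-frequency activity
#' first averages frequencies within seven overlapping 20 Hz sub-bands
#' (70-90 ... 130-150 Hz) and then averages the sub-bands, limiting the
#' 1/f bias toward the low end of a wide band.
#'
#' @param tfr A power `tfr`.
#' @param band `"theta"` (3-8 Hz) or `"hfa"` (70-150 Hz sub-bands).
#' @param baseline Length-2 ms window (on the `tfr` time axis) of
#'   baseline samples, e.g. the final second of the inter-trial interval.
#' @param fs_out Output rate, Hz (default 20).
#' @return A `band_power` object: `values` (channels x trials x time,
#'   z-units), `times`, `band`, `fs_out`, `baseline`.
#' @export
band_power <- function(tfr, band = c("theta", "hfa"), baseline = NULL,
                       fs_out = 20) {
  stopifnot(inherits(tfr, "tfr"))
  band <- match.arg(band)
  if (tfr$output == "power") {
    if (is.null(baseline)) stop_bad("baseline window required for raw power")
    tfr <- baseline_zscore(tfr, baseline)
  }
  stopifnot(tfr$output == "zscore")
  d <- dim(tfr$power)
  z <- tfr$power

  fsel <- if (band == "theta") {
    list(which(tfr$freqs >= 3 & tfr$freqs <= 8))
  } else {
    sb <- hfa_subbands()
    lapply(seq_len(nrow(sb)), function(i)
      which(tfr$freqs >= sb$lo[i] & tfr$freqs <= sb$hi[i]))
  }
  if (any(lengths(fsel) == 0)) {
    stop_bad("frequency grid does not cover the %s band", band)
  }

  band_z <- array(NA_real_, dim = c(d[1], d[2], d[4]))
  for (ch in seq_len(d[1])) {
    for (tr in seq_len(d[2])) {
      sub_means <- vapply(fsel, function(idx)
        colMeans(matrix(z[ch, tr, idx, ], nrow = length(idx))), numeric(d[4]))
      band_z[ch, tr, ] <- rowMeans(as.matrix(sub_means))
    }
  }

  factor <- max(1L, round(tfr$fs_out / fs_out))
  n_out <- floor(d[4] / factor)
  values <- array(NA_real_, dim = c(d[1], d[2], n_out))
  for (ch in seq_len(d[1])) {
    for (tr in seq_len(d[2])) {
      values[ch, tr, ] <- block_average(band_z[ch, tr, ], factor)
    }
  }
  structure(
    list(values = values, times = block_average(tfr$times, factor),
         band = band, fs_out = tfr$fs_out / factor, baseline = tfr$baseline,
         channels = tfr$channels, valid = tfr$valid,
         lock_event = tfr$lock_event),
    class = "band_power"
  )
}

#' @export
#' @rdname band_power
#' @param x A `band_power` object.
#' @param ... Unused.
tidy.band_power <- function(x, ...) {
  d <- dim(x$values)
  tibble(
    channel = rep(x$channels$channel_id, times = d[2] * d[3]),
    region = rep(x$channels$region, times = d[2] * d[3]),
    trial = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    value = as.vector(x$values)
  ) |>
    dplyr::filter(x$valid[.data$trial])
}

#' Average band power within a time window
#'
#' @param bp A `band_power` object.
#' @param window Length-2 ms window.
#' @return Tibble with one row per channel x trial: `channel`, `region`,
#'   `trial`, `value` (mean z-scored power in the window).
#' @export
window_power <- function(bp, window) {
  stopifnot(inherits(bp, "band_power"))
  idx <- which(bp$times >= window[1] & bp$times <= window[2])
  if (!length(idx)) stop_bad("window outside the band-power time axis")
  d <- dim(bp$values)
  vals <- apply(bp$values[, , idx, drop = FALSE], c(1, 2), mean)
  tibble(
    channel = rep(bp$channels$channel_id, times = d[2]),
    region = rep(bp$channels$region, times = d[2]),
    trial = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(vals)
  ) |>
    dplyr::filter(bp$valid[.data$trial])
}
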