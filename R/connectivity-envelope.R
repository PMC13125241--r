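# Trial-level amplitude-envelope synchrony.

#' Trial-by-trial amplitude-envelope synchrony between two channels
#'
#' Across-trial coherence is unstable at the single-trial level, so
#' trial-level coupling is measured as the Pearson correlation between
#' the two channels' amplitude envelopes over each trial's approach
#' window (movement onset to turnaround; the stationary pre-movement
#' period is excluded). Correlations are Fisher-z transformed and then
#' standardized within the pair across trials.
#'
#' @param env_a,env_b Numeric matrices, trials x time: amplitude
#'   envelopes of the two channels (theta envelope via
#'   [bandpass_theta()] + [amplitude_envelope()], or the high-frequency
#'   band power from [band_power()]).
#' @param times Time axis (ms) matching the matrix columns.
#' @param windows Tibble with per-trial `start` and `end` (ms); trials
#'   whose window is shorter than `min_ms` or whose envelope is constant
#'   are dropped with a warning.
#' @param min_ms Minimum approach-window duration (default 500 ms).
#' @return Tibble: `trial`, `r`, `z` (Fisher z), `z_std` (standardized
#'   within pair).
#' @export
envelope_synchrony <- function(env_a, env_b, times, windows, min_ms = 500) {
  stopifnot(is.matrix(env_a), is.matrix(env_b),
            all(dim(env_a) == dim(env_b)), ncol(env_a) == length(times))
  windows <- as_tibble(windows)
  stopifnot(all(c("start", "end") %in% names(windows)),
            nrow(windows) == nrow(env_a))
  n_tr <- nrow(env_a)
  rs <- rep(NA_real_, n_tr)
  dropped <- 0L
  for (tr in seq_len(n_tr)) {
    w <- windows[tr, ]
    if (is.na(w$start) || is.na(w$end) || (w$end - w$start) < min_ms) {
      dropped <- dropped + 1L
      next
    }
    idx <- which(times >= w$start & times <= w$end)
    if (length(idx) < 3) { dropped <- dropped + 1L; next }
    xa <- env_a[tr, idx]; xb <- env_b[tr, idx]
    if (sd(xa) < 1e-12 || sd(xb) < 1e-12) { dropped <- dropped + 1L; next }
    rs[tr] <- cor(xa, xb)
  }
  if (dropped > 0) {
    warn(sprintf("%d trial(s) dropped from envelope synchrony", dropped))
  }
  keep <- which(!is.na(rs))
  if (!length(keep)) stop_bad("no usable trials for envelope synchrony")
  z <- atanh(pmin(pmax(rs[keep], -1 + 1e-12), 1 - 1e-12))
  z_std <- if (length(z) > 1 && sd(z) > 1e-12) (z - mean(z)) / sd(z) else z * 0
  tibble(trial = keep, r = rs[keep], z = z, z_std = z_std)
}
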