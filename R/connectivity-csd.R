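# Theta-band complex spectra for across-trial connectivity.

#' Theta-band Morlet coefficients at the connectivity rate
#'
#' Resamples epochs to 100 Hz and computes complex Morlet coefficients at
#' the theta frequencies of the canonical 80-frequency grid (the
#' log-spaced frequencies falling in 3-8 Hz, with their matched cycle
#' counts). This is the shared input of the coherence metrics and their
#' permutation nulls: all metrics are computed across trials, per
#' timepoint and frequency, from these coefficients.
#'
#' @param epochs An `epochs` object (any sampling rate).
#' @param fs_out Connectivity rate, Hz (default 100).
#' @param band Band limits, Hz.
#' @return A `theta_csd` object: `coef` (channels x trials x freqs x
#'   time, complex), `freqs`, `times`, `fs`, `valid`, `channels`,
#'   `edge_valid` (freqs x time).
#' @export
theta_csd <- function(epochs, fs_out = 100, band = c(3, 8)) {
  stopifnot(inherits(epochs, "epochs"))
  ep <- resample_epochs(epochs, fs_out)
  grid <- wavelet_grid()
  grid <- grid[grid$freq >= band[1] & grid$freq <= band[2], ]
  tf <- morlet_tfr(ep, grid = grid, decim = 1, output = "complex")
  structure(
    list(coef = tf$power, freqs = tf$freqs, times = tf$times, fs = fs_out,
         valid = ep$valid, channels = ep$channels,
         edge_valid = tf$edge_valid),
    class = "theta_csd"
  )
}

# Across-trial connectivity metrics. The permutation machinery only
# reorders trial rows of channel b, so the complex coefficients are
# split once into real/imaginary part matrices and every metric is
# evaluated with real arithmetic; per-channel power terms are
# permutation-invariant and precomputed.
prep_pair_parts <- function(Sa, Sb) {
  Paa <- colMeans(Mod(Sa)^2)
  Pbb <- colMeans(Mod(Sb)^2)
  list(Ra = Re(Sa), Ia = Im(Sa), Rb = Re(Sb), Ib = Im(Sb),
       denom = sqrt(Paa * Pbb), n = nrow(Sa))
}

# Returns the metric averaged over frequencies: one value per timepoint.
metric_from_parts <- function(parts, metric, nf, nt, perm = NULL) {
  Rb <- parts$Rb; Ib <- parts$Ib
  if (!is.null(perm)) { Rb <- Rb[perm, , drop = FALSE]; Ib <- Ib[perm, , drop = FALSE] }
  n <- parts$n
  cross_im <- parts$Ia * Rb - parts$Ra * Ib   # Im(Sa * Conj(Sb))
  val <- switch(
    metric,
    imag_coh = abs(colMeans(cross_im)) / parts$denom,
    real_coh = {
      # naive real-part coherence; volume-conduction sensitive, used only
      # as a negative control in validation
      cross_re <- parts$Ra * Rb + parts$Ia * Ib
      abs(colMeans(cross_re)) / parts$denom
    },
    ppc = {
      cross_re <- parts$Ra * Rb + parts$Ia * Ib
      m <- sqrt(cross_re^2 + cross_im^2)
      m[m < 1e-300] <- 1
      sr <- colSums(cross_re / m)
      si <- colSums(cross_im / m)
      (sr^2 + si^2 - n) / (n * (n - 1))
    },
    wpli_debiased = {
      s_im <- colSums(cross_im)
      s_abs <- colSums(abs(cross_im))
      s_sq <- colSums(cross_im^2)
      num <- s_im^2 - s_sq
      den <- s_abs^2 - s_sq
      out <- num / den
      out[den <= 0] <- 0
      out
    },
    stop_bad("unknown metric `%s`", metric)
  )
  colMeans(matrix(val, nf, nt))
}

COH_METRICS <- c("imag_coh", "ppc", "wpli_debiased")

csd_pair_mats <- function(csd, a, b) {
  idx <- function(ch) {
    if (is.character(ch)) match(ch, csd$channels$channel_id) else as.integer(ch)
  }
  ia <- idx(a); ib <- idx(b)
  if (is.na(ia) || is.na(ib)) stop_bad("unknown channel")
  keep <- which(csd$valid)
  nf <- length(csd$freqs); nt <- length(csd$times)
  Sa <- matrix(csd$coef[ia, keep, , ], nrow = length(keep))
  Sb <- matrix(csd$coef[ib, keep, , ], nrow = length(keep))
  list(Sa = Sa, Sb = Sb, nf = nf, nt = nt, n_trials = length(keep))
}
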