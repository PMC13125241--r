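# Internal helpers shared across modules.

# Run code with a local, seeded RNG stream without disturbing the caller's
# RNG state. All user-facing randomness goes through this, so every
# simulation is a pure function of its `seed` argument.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result in 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483647)
}

stop_bad <- function(msg, ...) abort(sprintf(msg, ...), class = "aacircuit_error")

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    stop_bad("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    stop_bad("`%s` must be an integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    stop_bad("`%s` must be a number in [%s, %s]", name, format(min), format(max))
  }
  invisible(as.numeric(x))
}

# Analytic signal via frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Amplitude envelope of a signal
#'
#' Magnitude of the analytic signal (Hilbert transform). Used to extract
#' theta and high-frequency amplitude envelopes for synchrony analyses.
#'
#' @param x Numeric vector (one channel, one trial).
#' @return Numeric vector of the same length.
#' @export
amplitude_envelope <- function(x) {
  Mod(analytic_signal(as.numeric(x)))
}

# Resample a vector from fs to fs_new using a polyphase FIR resampler.
resample_to <- function(x, fs, fs_new) {
  if (fs == fs_new) return(as.numeric(x))
  frac <- rational_approx(fs_new / fs)
  as.numeric(signal::resample(as.numeric(x), frac[1], frac[2]))
}

rational_approx <- function(r, max_den = 1024) {
  # continued-fraction expansion
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < 1e-12) break
    x <- 1 / (x - a)
  }
  c(p1, q1)
}

# Longest run of TRUE values, and total count.
longest_run <- function(mask) {
  if (!any(mask)) return(0L)
  r <- rle(mask)
  max(r$lengths[r$values])
}

# Permutation p-value: one-sided, observed never in its own null,
# conservative +1 correction.
perm_pval <- function(obs, null_mat) {
  # null_mat: n_perm x n_stat; obs: n_stat
  n_perm <- nrow(null_mat)
  ge <- colSums(null_mat >= rep(obs, each = n_perm))
  (1 + ge) / (n_perm + 1)
}

# Block-average downsampling of a time series (anti-alias by construction).
block_average <- function(x, factor) {
  n <- floor(length(x) / factor) * factor
  colMeans(matrix(x[seq_len(n)], nrow = factor))
}
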