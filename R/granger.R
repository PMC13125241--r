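# Time-reversed net spectral Granger causality.
#
# Pairwise VAR models are fit per timepoint on short sliding windows
# pooled across trials; spectral (Geweke) Granger scores are averaged
# over the theta band; and the directional contrast is debiased by
# subtracting the same contrast computed on time-reversed signals, which
# cancels directionality driven purely by signal-to-noise differences.

#' Granger analysis configuration
#'
#' @param n_lags VAR model order (default 12; acts as a spectral
#'   smoothing parameter).
#' @param band Frequency band averaged for the score, Hz.
#' @param fs Analysis rate, Hz (data are resampled to this).
#' @param window_samples Sliding-window length per timepoint (odd;
#'   default 31 samples = 310 ms at 100 Hz, giving
#'   `(window - n_lags) * n_trials` regression rows per fit).
#' @param n_perm Trial shuffles for the permutation null.
#' @param alpha Significance level on FDR-corrected p-values.
#' @param min_ms Duration rule: the pair qualifies when at least this
#'   much time is significant (500 ms = 50 timepoints at 100 Hz).
#' @param analysis_window Timepoints analyzed, ms relative to the lock
#'   event (default the final 1500 ms of approach).
#' @return A `gc_config` list.
#' @export
gc_config <- function(n_lags = 12, band = c(3, 8), fs = 100,
                      window_samples = 31, n_perm = 1000, alpha = 0.05,
                      min_ms = 500, analysis_window = c(-1500, 0)) {
  check_count(n_lags, "n_lags")
  check_count(window_samples, "window_samples", min = n_lags + 3)
  if (window_samples %% 2 == 0) stop_bad("window_samples must be odd")
  if (min_ms > diff(analysis_window) + 1e-9 && is.finite(min_ms)) {
    stop_bad("duration rule exceeds the analysis window")
  }
  grid <- wavelet_grid()
  structure(
    list(n_lags = n_lags, band = band, fs = fs,
         window_samples = window_samples, n_perm = n_perm, alpha = alpha,
         min_ms = min_ms, analysis_window = analysis_window,
         freqs = grid$freq[grid$freq >= band[1] & grid$freq <= band[2]]),
    class = "gc_config"
  )
}

# Lag-embed a trials x window matrix into stacked [lags, response]
# blocks: rows are (window - p) observations per trial, columns are the
# p lags followed by the response.
lag_embed <- function(W, p) {
  w <- ncol(W); ntr <- nrow(W); nobs <- w - p
  out <- matrix(0, ntr * nobs, p + 1)
  for (k in seq_len(p)) {
    out[, k] <- as.vector(t(W[, (p + 1 - k):(w - k), drop = FALSE]))
  }
  out[, p + 1] <- as.vector(t(W[, (p + 1):w, drop = FALSE]))
  out
}

# Geweke spectral GC for both directions from stacked blocks.
# A_blk/B_blk: N x (p+1) [lags, response]; SAA/SBB their crossprods.
# rows: optional row permutation applied to the B blocks.
gc_from_blocks <- function(A_blk, B_blk, SAA, SBB, p, zmat, rows = NULL) {
  Bb <- if (is.null(rows)) B_blk else B_blk[rows, , drop = FALSE]
  SAB <- crossprod(A_blk, Bb)
  ip <- seq_len(p)
  XtX <- rbind(cbind(SAA[ip, ip], SAB[ip, ip]),
               cbind(t(SAB[ip, ip]), SBB[ip, ip]))
  XtY <- cbind(c(SAA[ip, p + 1], SAB[p + 1, ip]),
               c(SAB[ip, p + 1], SBB[ip, p + 1]))
  YtY <- matrix(c(SAA[p + 1, p + 1], SAB[p + 1, p + 1],
                  SAB[p + 1, p + 1], SBB[p + 1, p + 1]), 2, 2)
  N <- nrow(A_blk)
  coefs <- tryCatch(
    solve(XtX + diag(1e-10 * mean(diag(XtX)), 2 * p), XtY),
    error = function(e) stop_bad("ill-conditioned VAR fit: %s", conditionMessage(e))
  )
  Sig <- (YtY - crossprod(XtY, coefs)) / N
  Sig <- (Sig + t(Sig)) / 2
  if (any(diag(Sig) <= 0)) stop_bad("degenerate innovation covariance")

  # transfer function H(f) = A(f)^-1 with A(f) = I - sum_k A_k z^k
  Pa <- zmat %*% coefs[ip, , drop = FALSE]        # lags of a -> responses
  Pb <- zmat %*% coefs[p + ip, , drop = FALSE]    # lags of b -> responses
  Aaa <- 1 - Pa[, 1]; Aab <- -Pb[, 1]
  Aba <- -Pa[, 2];    Abb <- 1 - Pb[, 2]
  det <- Aaa * Abb - Aab * Aba
  Haa <- Abb / det; Hab <- -Aab / det
  Hba <- -Aba / det; Hbb <- Aaa / det

  Saa <- Re(Mod(Haa)^2 * Sig[1, 1] + 2 * Re(Haa * Conj(Hab)) * Sig[1, 2] +
              Mod(Hab)^2 * Sig[2, 2])
  Sbb <- Re(Mod(Hba)^2 * Sig[1, 1] + 2 * Re(Hba * Conj(Hbb)) * Sig[1, 2] +
              Mod(Hbb)^2 * Sig[2, 2])
  s2_a <- Sig[1, 1] - Sig[1, 2]^2 / Sig[2, 2]
  s2_b <- Sig[2, 2] - Sig[1, 2]^2 / Sig[1, 1]
  gc_ab <- mean(log(Sbb / pmax(Sbb - s2_a * Mod(Hba)^2, 1e-300)))
  gc_ba <- mean(log(Saa / pmax(Saa - s2_b * Mod(Hab)^2, 1e-300)))
  c(ab = gc_ab, ba = gc_ba)
}

gc_zmat <- function(config) {
  exp(-2i * pi * outer(config$freqs / config$fs, seq_len(config$n_lags)))
}

#' Band-averaged spectral Granger causality between two signals
#'
#' Fits a bivariate VAR by ordinary least squares on trials pooled into
#' one regression, factorizes its spectrum, and returns the Geweke
#' Granger score in both directions averaged over the configured band.
#'
#' @param x,y Numeric matrices (trials x samples) or vectors (treated as
#'   one trial) at `config$fs`.
#' @param config A [gc_config()].
#' @return Tibble with `gc_xy`, `gc_yx` (band-averaged, non-negative up
#'   to numerical tolerance).
#' @export
spectral_gc <- function(x, y, config = gc_config()) {
  stopifnot(inherits(config, "gc_config"))
  if (is.vector(x)) x <- matrix(x, 1)
  if (is.vector(y)) y <- matrix(y, 1)
  stopifnot(all(dim(x) == dim(y)))
  if (identical(x, y)) stop_bad("Granger causality of a channel on itself is undefined")
  p <- config$n_lags
  if (ncol(x) < p + 3) stop_bad("need at least n_lags + 3 samples per trial")
  A_blk <- lag_embed(x, p); B_blk <- lag_embed(y, p)
  g <- gc_from_blocks(A_blk, B_blk, crossprod(A_blk), crossprod(B_blk),
                      p, gc_zmat(config))
  tibble(gc_xy = g[["ab"]], gc_yx = g[["ba"]])
}

# Extract per-trial analysis matrices for a channel pair at config$fs.
gc_prepare <- function(epochs, a, b, config) {
  ep <- resample_epochs(epochs, config$fs)
  idx <- function(ch) {
    if (is.character(ch)) match(ch, ep$channels$channel_id) else as.integer(ch)
  }
  ia <- idx(a); ib <- idx(b)
  if (is.na(ia) || is.na(ib)) stop_bad("unknown channel")
  keep <- which(ep$valid)
  half <- (config$window_samples - 1) / 2
  half_ms <- half * 1000 / config$fs
  centers <- which(ep$times >= config$analysis_window[1] &
                     ep$times <= config$analysis_window[2] &
                     ep$times >= ep$times[1] + half_ms &
                     ep$times <= ep$times[length(ep$times)] - half_ms)
  if (!length(centers)) stop_bad("no timepoints with full window support")
  list(Xa = ep$data[ia, keep, , drop = TRUE], Xb = ep$data[ib, keep, , drop = TRUE],
       centers = centers, times = ep$times, half = half)
}

net_from_gc <- function(fwd, rev, literal) {
  if (literal) {
    fwd[["ab"]] - fwd[["ba"]] - rev[["ab"]] - rev[["ba"]]
  } else {
    (fwd[["ab"]] - fwd[["ba"]]) - (rev[["ab"]] - rev[["ba"]])
  }
}

#' Per-timepoint net Granger score between two channels
#'
#' For each timepoint in the analysis window, fits the pairwise VAR on a
#' short centered window pooled across trials, computes band-averaged
#' spectral GC in both directions on the raw and on the within-trial
#' time-reversed segments, and forms the net score
#' `[GC(a->b) - GC(b->a)] - [GC_rev(a->b) - GC_rev(b->a)]`. Positive
#' values mean channel `a` leads channel `b`; the score is antisymmetric
#' under swapping the pair.
#'
#' @param epochs An `epochs` object (locked to the turnaround for the
#'   published analysis).
#' @param a,b Channel ids or indices.
#' @param config A [gc_config()].
#' @param literal If `TRUE`, uses the literal left-to-right reading of
#'   the net-score formula (no grouping of the reversed terms), which is
#'   not antisymmetric; provided for comparability only.
#' @return A `net_granger_series`: tibble `series` (`time`, `net`,
#'   `gc_ab`, `gc_ba`, `gc_rev_ab`, `gc_rev_ba`), plus `pair`, `config`.
#' @export
net_granger <- function(epochs, a, b, config = gc_config(), literal = FALSE) {
  prep <- gc_prepare(epochs, a, b, config)
  p <- config$n_lags
  zmat <- gc_zmat(config)
  rows <- NULL
  out <- map(prep$centers, function(ci) {
    span <- (ci - prep$half):(ci + prep$half)
    Wa <- prep$Xa[, span, drop = FALSE]
    Wb <- prep$Xb[, span, drop = FALSE]
    A_blk <- lag_embed(Wa, p); B_blk <- lag_embed(Wb, p)
    Ar <- lag_embed(Wa[, rev(seq_along(span)), drop = FALSE], p)
    Br <- lag_embed(Wb[, rev(seq_along(span)), drop = FALSE], p)
    fwd <- gc_from_blocks(A_blk, B_blk, crossprod(A_blk), crossprod(B_blk), p, zmat)
    rv <- gc_from_blocks(Ar, Br, crossprod(Ar), crossprod(Br), p, zmat)
    c(net = net_from_gc(fwd, rv, literal),
      ab = fwd[["ab"]], ba = fwd[["ba"]],
      rab = rv[["ab"]], rba = rv[["ba"]])
  })
  m <- do.call(rbind, out)
  structure(
    list(
      series = tibble(time = prep$times[prep$centers], net = m[, "net"],
                      gc_ab = m[, "ab"], gc_ba = m[, "ba"],
                      gc_rev_ab = m[, "rab"], gc_rev_ba = m[, "rba"]),
      pair = c(a, b), config = config, literal = literal
    ),
    class = "net_granger_series"
  )
}

#' Permutation test of net Granger directionality
#'
#' Null distributions come from shuffling the trial labels of channel
#' `b` and recomputing the net score at every timepoint; p-values
#' compare `|net|` to the null `|net|` (two-sided on the signed score),
#' are FDR-corrected across timepoints, and the pair qualifies when at
#' least `config$min_ms` of the analysis window is significant.
#'
#' @param epochs An `epochs` object.
#' @param a,b Channel ids or indices.
#' @param config A [gc_config()].
#' @param seed Integer seed.
#' @param literal See [net_granger()].
#' @return A `gc_test` list: `series` tibble (`time`, `net`, `p`,
#'   `p_fdr`, `sig`), `qualifies`, `n_sig`, `direction` (sign of the
#'   mean net score over the window), `mean_net`.
#' @export
gc_permutation_test <- function(epochs, a, b, config = gc_config(), seed = 1,
                                literal = FALSE) {
  prep <- gc_prepare(epochs, a, b, config)
  p <- config$n_lags
  zmat <- gc_zmat(config)
  n_tr <- nrow(prep$Xa)
  nobs <- config$window_samples - p

  # precompute embedded blocks per timepoint
  blocks <- map(prep$centers, function(ci) {
    span <- (ci - prep$half):(ci + prep$half)
    Wa <- prep$Xa[, span, drop = FALSE]
    Wb <- prep$Xb[, span, drop = FALSE]
    A_blk <- lag_embed(Wa, p); B_blk <- lag_embed(Wb, p)
    Ar <- lag_embed(Wa[, rev(seq_along(span)), drop = FALSE], p)
    Br <- lag_embed(Wb[, rev(seq_along(span)), drop = FALSE], p)
    list(A = A_blk, B = B_blk, Ar = Ar, Br = Br,
         SAA = crossprod(A_blk), SBB = crossprod(B_blk),
         SAAr = crossprod(Ar), SBBr = crossprod(Br))
  })
  net_one <- function(bl, rows = NULL) {
    fwd <- gc_from_blocks(bl$A, bl$B, bl$SAA, bl$SBB, p, zmat, rows)
    rv <- gc_from_blocks(bl$Ar, bl$Br, bl$SAAr, bl$SBBr, p, zmat, rows)
    net_from_gc(fwd, rv, literal)
  }
  obs <- map_dbl(blocks, net_one)

  null_mat <- with_seed(seed, {
    t(vapply(seq_len(config$n_perm), function(i) {
      perm <- sample(n_tr)
      rows <- as.vector(outer(seq_len(nobs), (perm - 1L) * nobs, `+`))
      vapply(blocks, net_one, numeric(1), rows = rows)
    }, numeric(length(blocks))))
  })

  pvals <- perm_pval(abs(obs), abs(null_mat))
  p_fdr <- p.adjust(pvals, method = "BH")
  sig <- p_fdr < config$alpha
  min_samples <- ceiling(config$min_ms * config$fs / 1000)
  structure(
    list(
      series = tibble(time = prep$times[prep$centers], net = obs,
                      p = pvals, p_fdr = p_fdr, sig = sig),
      qualifies = is.finite(config$min_ms) && sum(sig) >= min_samples,
      n_sig = sum(sig),
      direction = sign(mean(obs)),
      mean_net = mean(obs),
      pair = c(a, b),
      config = config
    ),
    class = "gc_test"
  )
}

#' @export
print.gc_test <- function(x, ...) {
  cat(sprintf(
    "<gc_test> %s->%s: mean net %.4g, %d sig timepoints, %squalifying\n",
    x$pair[1], x$pair[2], x$mean_net, x$n_sig,
    if (x$qualifies) "" else "not "))
  invisible(x)
}

#' Screen channel pairs for qualifying net Granger directionality
#'
#' @param epochs An `epochs` object.
#' @param pairs Tibble with columns `a`, `b`.
#' @param config A [gc_config()].
#' @param seed Integer seed.
#' @param literal See [net_granger()].
#' @return Tibble: `a`, `b`, `qualifies`, `n_sig`, `mean_net`,
#'   `direction`.
#' @export
gc_screen <- function(epochs, pairs, config = gc_config(), seed = 1,
                      literal = FALSE) {
  pairs <- as_tibble(pairs)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    gt <- gc_permutation_test(epochs, pairs$a[i], pairs$b[i], config,
                              seed = child_seed(seed, i), literal = literal)
    tibble(a = pairs$a[i], b = pairs$b[i], qualifies = gt$qualifies,
           n_sig = gt$n_sig, mean_net = gt$mean_net,
           direction = gt$direction)
  })
  bind_rows(res)
}
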