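# Cross-correlation lag analysis on concatenated approach windows.

#' Concatenate per-trial approach windows into one sequence per channel
#'
#' Extracts each trial's approach window (movement onset to turnaround),
#' z-scores it within trial, and concatenates across trials, recording
#' trial boundaries so permutations can preserve segment lengths. Trials
#' without both events, or with an empty approach window, are dropped
#' (and reported).
#'
#' @param epochs An `epochs` object locked to `trial_onset` and covering
#'   the trials (typically theta-band-passed and at 100 Hz).
#' @param events Event table with `movement_onset` and `turnaround` (ms).
#' @return A `concat_approach` list: `x` (channels x total samples),
#'   `boundaries` tibble (`trial`, `start`, `length`), `fs`, `channels`,
#'   `dropped` (trial indices).
#' @export
concat_approach <- function(epochs, events) {
  stopifnot(inherits(epochs, "epochs"))
  events <- as_tibble(events)
  stopifnot(all(c("movement_onset", "turnaround") %in% names(events)))
  d <- dim(epochs$data)
  stopifnot(nrow(events) == d[2])
  segs <- vector("list", d[2])
  dropped <- integer(0)
  for (tr in seq_len(d[2])) {
    mo <- events$movement_onset[tr]; tu <- events$turnaround[tr]
    if (!epochs$valid[tr] || is.na(mo) || is.na(tu) || tu <= mo) {
      dropped <- c(dropped, tr); next
    }
    idx <- which(epochs$times >= mo & epochs$times < tu)
    if (length(idx) < 3) { dropped <- c(dropped, tr); next }
    seg <- epochs$data[, tr, idx, drop = FALSE]
    seg <- matrix(seg, d[1], length(idx))
    seg <- t(scale(t(seg)))   # z-score within trial, per channel
    segs[[tr]] <- seg
  }
  keep <- setdiff(seq_len(d[2]), dropped)
  if (!length(keep)) stop_bad("no trials with a usable approach window")
  lens <- map_int(segs[keep], ncol)
  x <- do.call(cbind, segs[keep])
  structure(
    list(
      x = x,
      boundaries = tibble(trial = keep,
                          start = cumsum(c(1L, head(lens, -1))),
                          length = lens),
      fs = epochs$fs, channels = epochs$channels, dropped = dropped
    ),
    class = "concat_approach"
  )
}

ccf_lags <- function(xa, xb, max_lag) {
  n <- length(xa)
  vapply(-max_lag:max_lag, function(l) {
    if (l >= 0) cor(xa[seq_len(n - l)], xb[seq_len(n - l) + l])
    else cor(xa[seq_len(n + l) - l], xb[seq_len(n + l)])
  }, numeric(1))
}

#' Cross-correlation lag test between two channels
#'
#' Computes the cross-correlation function over +/- `max_lag` samples on
#' the concatenated approach signal (positive best lag means channel `a`
#' leads channel `b`), and a permutation null obtained by shuffling the
#' order of channel `b`'s trial segments while keeping every segment's
#' length — so the discontinuity structure of the concatenated series is
#' identical under the null. The best lag is retained only when the
#' maximum correlation is in the top 5% of the null maxima.
#'
#' @param concat A [concat_approach()] result.
#' @param a,b Channel ids or indices.
#' @param max_lag Maximum lag in samples (default 25 = 250 ms at 100 Hz).
#' @param n_perm Number of segment shuffles (default 200).
#' @param seed Integer seed.
#' @param top_quantile Retention quantile of the null maxima.
#' @return A `ccf_test` list: `lags` tibble (`lag`, `lag_ms`, `corr`),
#'   `best_lag` (samples), `best_lag_ms`, `max_corr`, `p`, `retained`.
#' @export
cross_correlation_test <- function(concat, a, b, max_lag = 25, n_perm = 200,
                                   seed = 1, top_quantile = 0.95) {
  stopifnot(inherits(concat, "concat_approach"))
  if (nrow(concat$boundaries) < 3) stop_bad("need at least 3 trials")
  idx <- function(ch) {
    if (is.character(ch)) match(ch, concat$channels$channel_id) else as.integer(ch)
  }
  ia <- idx(a); ib <- idx(b)
  if (is.na(ia) || is.na(ib)) stop_bad("unknown channel")
  xa <- concat$x[ia, ]; xb <- concat$x[ib, ]
  lags <- -max_lag:max_lag
  obs <- ccf_lags(xa, xb, max_lag)
  best_i <- which.max(obs)

  nb <- nrow(concat$boundaries)
  seg_idx <- lapply(seq_len(nb), function(i) {
    s <- concat$boundaries$start[i]
    s:(s + concat$boundaries$length[i] - 1L)
  })
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      xb_perm <- unlist(seg_idx[sample(nb)], use.names = FALSE)
      max(ccf_lags(xa, xb[xb_perm], max_lag))
    }, numeric(1))
  })
  p <- (1 + sum(null_max >= obs[best_i])) / (n_perm + 1)
  structure(
    list(
      lags = tibble(lag = lags, lag_ms = lags * 1000 / concat$fs, corr = obs),
      best_lag = lags[best_i],
      best_lag_ms = lags[best_i] * 1000 / concat$fs,
      max_corr = obs[best_i],
      p = p,
      retained = obs[best_i] > quantile(null_max, top_quantile),
      pair = c(a, b)
    ),
    class = "ccf_test"
  )
}

#' @export
print.ccf_test <- function(x, ...) {
  cat(sprintf(
    "<ccf_test> %s->%s: best lag %d samples (%.0f ms), r = %.3f, %sretained (p = %.3f)\n",
    x$pair[1], x$pair[2], x$best_lag, x$best_lag_ms, x$max_corr,
    if (x$retained) "" else "not ", x$p))
  invisible(x)
}

#' Dual-method directionality consensus
#'
#' A region pair's directionality is interpreted only when both the
#' Granger model and the cross-correlation model give strong posterior
#' evidence in the same direction: consensus requires both P+ above
#' `threshold` (a consistently positive effect, channel `a` leading) or
#' both below `1 - threshold` (channel `b` leading).
#'
#' @param p_plus_granger,p_plus_ccf Posterior probabilities of direction
#'   from the two hierarchical models (see [prob_positive()]).
#' @param threshold Evidence threshold (default 0.95).
#' @return One-row tibble: `p_plus_granger`, `p_plus_ccf`, `consensus`
#'   (NA when either method is missing), `direction` (+1, -1, or NA).
#' @export
direction_consensus <- function(p_plus_granger, p_plus_ccf, threshold = 0.95) {
  if (is.null(p_plus_granger) || is.null(p_plus_ccf) ||
      is.na(p_plus_granger) || is.na(p_plus_ccf)) {
    return(tibble(p_plus_granger = p_plus_granger %||% NA_real_,
                  p_plus_ccf = p_plus_ccf %||% NA_real_,
                  consensus = NA, direction = NA_real_))
  }
  pos <- p_plus_granger > threshold && p_plus_ccf > threshold
  neg <- p_plus_granger < 1 - threshold && p_plus_ccf < 1 - threshold
  tibble(
    p_plus_granger = p_plus_granger,
    p_plus_ccf = p_plus_ccf,
    consensus = pos || neg,
    direction = if (pos) 1 else if (neg) -1 else NA_real_
  )
}
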