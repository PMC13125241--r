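# Across-trial theta coherence with trial-shuffle permutation testing.

#' Per-timepoint theta coherence between two channels, across trials
#'
#' Computes the chosen metric across trials at every timepoint and
#' frequency of the theta grid, then averages over frequencies. The
#' supported metrics are the absolute imaginary part of coherency
#' (`imag_coh`), pairwise phase consistency (`ppc`), and the debiased
#' squared weighted phase-lag index (`wpli_debiased`); all three are
#' symmetric in the pair.
#'
#' @param csd A [theta_csd()].
#' @param a,b Channel ids or indices.
#' @param metric One of `"imag_coh"`, `"ppc"`, `"wpli_debiased"`.
#' @return Tibble with `time` (ms) and `value`.
#' @export
coherence_series <- function(csd, a, b, metric = "imag_coh") {
  stopifnot(inherits(csd, "theta_csd"))
  metric <- match.arg(metric, COH_METRICS)
  p <- csd_pair_mats(csd, a, b)
  if (p$n_trials < 20) stop_bad("need at least 20 trials for stable estimates")
  parts <- prep_pair_parts(p$Sa, p$Sb)
  tibble(time = csd$times,
         value = metric_from_parts(parts, metric, p$nf, p$nt))
}

#' Trial-shuffle permutation test of elevated theta coherence
#'
#' Builds the null by shuffling the trial labels of one member of the
#' pair `n_perm` times and recomputing the metric per timepoint; the
#' observed series is never part of its own null. One-sided p-values
#' (elevated coherence) are Benjamini-Hochberg corrected across
#' timepoints, and the pair is flagged significant when a run of
#' corrected-significant timepoints spans at least `min_ms` (contiguous
#' by default; set `contiguous = FALSE` to count total significant time).
#'
#' @param csd A [theta_csd()].
#' @param a,b Channel ids or indices.
#' @param metric Connectivity metric (see [coherence_series()]).
#' @param n_perm Number of trial shuffles (>= 100).
#' @param seed Integer seed for the shuffles.
#' @param alpha Significance level on corrected p-values.
#' @param min_ms Duration rule in ms.
#' @param contiguous Whether the duration rule requires a contiguous run.
#' @return A `coh_test` list: `series` tibble (`time`, `value`, `p`,
#'   `p_fdr`, `sig`), `significant` flag, `max_run_ms`, `metric`, `pair`.
#' @export
coherence_test <- function(csd, a, b, metric = "imag_coh", n_perm = 1000,
                           seed = 1, alpha = 0.05, min_ms = 100,
                           contiguous = TRUE) {
  stopifnot(inherits(csd, "theta_csd"))
  metric <- match.arg(metric, c(COH_METRICS, "real_coh"))
  if (n_perm < 100) stop_bad("n_perm must be >= 100")
  p <- csd_pair_mats(csd, a, b)
  if (p$n_trials < 20) stop_bad("need at least 20 trials for stable estimates")

  parts <- prep_pair_parts(p$Sa, p$Sb)
  obs <- metric_from_parts(parts, metric, p$nf, p$nt)
  null_mat <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      metric_from_parts(parts, metric, p$nf, p$nt, perm = sample(p$n_trials))
    }, numeric(p$nt)))
  })
  finalize_perm_series(obs, null_mat, csd$times, csd$fs, alpha, min_ms,
                       contiguous, metric, c(a, b))
}

finalize_perm_series <- function(obs, null_mat, times, fs, alpha, min_ms,
                                 contiguous, metric, pair) {
  pvals <- perm_pval(obs, null_mat)
  p_fdr <- p.adjust(pvals, method = "BH")
  sig <- p_fdr < alpha
  min_samples <- ceiling(min_ms * fs / 1000)
  run <- longest_run(sig)
  significant <- if (is.infinite(min_ms)) FALSE else if (contiguous) {
    run >= min_samples
  } else sum(sig) >= min_samples
  structure(
    list(
      series = tibble(time = times, value = obs, p = pvals,
                      p_fdr = p_fdr, sig = sig),
      significant = significant,
      max_run_ms = run * 1000 / fs,
      n_sig = sum(sig),
      metric = metric,
      pair = pair,
      null_mean = colMeans(null_mat)
    ),
    class = "coh_test"
  )
}

#' @export
print.coh_test <- function(x, ...) {
  cat(sprintf("<coh_test> %s %s-%s: %ssignificant (max run %g ms, %d sig pts)\n",
              x$metric, x$pair[1], x$pair[2],
              if (x$significant) "" else "not ", x$max_run_ms, x$n_sig))
  invisible(x)
}

#' Screen many channel pairs for elevated theta coherence
#'
#' Applies [coherence_test()] to each pair and returns a per-pair
#' summary, the building block of the percentage-of-significant-pairs
#' analyses and of the type-I-error calibration.
#'
#' @param csd A [theta_csd()].
#' @param pairs Tibble with columns `a` and `b` (channel ids), or `NULL`
#'   for all unordered channel pairs.
#' @inheritParams coherence_test
#' @return Tibble: `a`, `b`, `region_a`, `region_b`, `significant`,
#'   `max_run_ms`, `n_sig`, `mean_value`.
#' @export
coherence_screen <- function(csd, pairs = NULL, metric = "imag_coh",
                             n_perm = 1000, seed = 1, alpha = 0.05,
                             min_ms = 100, contiguous = TRUE) {
  stopifnot(inherits(csd, "theta_csd"))
  if (is.null(pairs)) {
    ids <- csd$channels$channel_id
    cmb <- utils::combn(ids, 2)
    pairs <- tibble(a = cmb[1, ], b = cmb[2, ])
  }
  pairs <- as_tibble(pairs)
  reg <- setNames(csd$channels$region, csd$channels$channel_id)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ct <- coherence_test(csd, pairs$a[i], pairs$b[i], metric = metric,
                         n_perm = n_perm, seed = child_seed(seed, i),
                         alpha = alpha, min_ms = min_ms,
                         contiguous = contiguous)
    tibble(a = pairs$a[i], b = pairs$b[i],
           region_a = unname(reg[pairs$a[i]]),
           region_b = unname(reg[pairs$b[i]]),
           significant = ct$significant, max_run_ms = ct$max_run_ms,
           n_sig = ct$n_sig, mean_value = mean(ct$series$value))
  })
  bind_rows(res)
}
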