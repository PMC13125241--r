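# ggplot2 methods for result objects.

#' @importFrom ggplot2 ggplot aes geom_line geom_ribbon geom_point geom_col
#'   geom_hline geom_vline geom_density labs facet_wrap theme_minimal
NULL

#' Plot band power time courses
#'
#' Mean z-scored power across trials per channel, with a standard-error
#' ribbon, time-locked to the epoch's lock event.
#'
#' @param object A `band_power` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.band_power <- function(object, ...) {
  df <- tidy(object) |>
    group_by(.data$channel, .data$region, .data$time) |>
    summarise(m = mean(.data$value), se = sd(.data$value) / sqrt(n()),
              .groups = "drop")
  ggplot(df, aes(x = .data$time, y = .data$m, colour = .data$region,
                 group = .data$channel)) +
    geom_ribbon(aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se,
                    fill = .data$region), alpha = 0.2, colour = NA) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = sprintf("time from %s (ms)", object$lock_event),
         y = sprintf("%s power (z)", object$band)) +
    theme_minimal()
}

#' Plot a coherence permutation test
#'
#' Observed per-timepoint coherence against the mean of the shuffled
#' null, with significant timepoints marked.
#'
#' @param object A `coh_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coh_test <- function(object, ...) {
  df <- object$series
  df$null_mean <- object$null_mean
  ggplot(df, aes(x = .data$time)) +
    geom_line(aes(y = .data$null_mean), colour = "grey60") +
    geom_line(aes(y = .data$value), colour = "#d8a100") +
    geom_point(data = dplyr::filter(df, .data$sig),
               aes(y = .data$value), size = 0.6, colour = "firebrick") +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "time (ms)", y = object$metric,
         title = sprintf("%s - %s (%s)", object$pair[1], object$pair[2],
                         if (object$significant) "significant" else "n.s.")) +
    theme_minimal()
}

#' Plot a net Granger series or test
#'
#' @param object A `net_granger_series` or `gc_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.net_granger_series <- function(object, ...) {
  ggplot(object$series, aes(x = .data$time, y = .data$net)) +
    geom_hline(yintercept = 0, linetype = 2) +
    geom_line(colour = "#2a6099") +
    labs(x = "time (ms)", y = "net Granger score",
         title = sprintf("%s -> %s", object$pair[1], object$pair[2])) +
    theme_minimal()
}

#' @rdname autoplot.net_granger_series
#' @export
autoplot.gc_test <- function(object, ...) {
  df <- object$series
  ggplot(df, aes(x = .data$time, y = .data$net)) +
    geom_hline(yintercept = 0, linetype = 2) +
    geom_line(colour = "#2a6099") +
    geom_point(data = dplyr::filter(df, .data$sig), size = 0.6,
               colour = "firebrick") +
    labs(x = "time (ms)", y = "net Granger score",
         title = sprintf("%s -> %s (%s)", object$pair[1], object$pair[2],
                         if (object$qualifies) "qualifying" else "n.s.")) +
    theme_minimal()
}

#' Plot a cross-correlation lag test
#'
#' @param object A `ccf_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ccf_test <- function(object, ...) {
  ggplot(object$lags, aes(x = .data$lag_ms, y = .data$corr)) +
    geom_col(width = 8, fill = "grey70") +
    geom_vline(xintercept = object$best_lag_ms, colour = "firebrick") +
    labs(x = "lag (ms; positive = first channel leads)", y = "correlation",
         title = sprintf("%s -> %s: best lag %.0f ms (r = %.2f)",
                         object$pair[1], object$pair[2], object$best_lag_ms,
                         object$max_corr)) +
    theme_minimal()
}

#' Plot posterior densities of the fixed effects
#'
#' @param object An `hbm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hbm_fit <- function(object, ...) {
  terms <- colnames(object$spec$X)
  df <- tibble(
    term = rep(terms, each = nrow(object$draws)),
    draw = as.vector(object$draws[, terms])
  )
  ggplot(df, aes(x = .data$draw)) +
    geom_density(fill = "#2a6099", alpha = 0.4) +
    geom_vline(xintercept = 0, linetype = 2) +
    facet_wrap(~term, scales = "free") +
    labs(x = "posterior draw", y = "density") +
    theme_minimal()
}

#' Behavioral overview of a simulated session
#'
#' Turnaround distances by last-reward size for conflict trials with a
#' turnaround: the risk/reward trade-off signature.
#'
#' @param trials Tibble from [run_session()].
#' @return A ggplot.
#' @export
plot_turnaround_by_reward <- function(trials) {
  df <- dplyr::filter(trials, .data$conflict, .data$n_turnarounds > 0,
                      !is.na(.data$turnaround_distance))
  ggplot(df, aes(x = .data$last_dot_size, y = .data$turnaround_distance)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    labs(x = "last reward size", y = "player-ghost distance at turnaround") +
    theme_minimal()
}
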