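# Hierarchical Bayesian fitting via Gibbs sampling (JAGS backend).

hbm_model_string <- function(has_electrode) {
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    y[i] ~ dnorm(mu[i], tau_e)\n",
    "    mu[i] <- inprod(X[i, ], beta[])",
    " + u[subj[i]]",
    if (has_electrode) " + v[elec[i]]" else "",
    "\n  }\n",
    "  beta[1] ~ dnorm(0, prec_int)\n",
    "  for (k in 2:K) { beta[k] ~ dnorm(0, prec_coef) }\n",
    "  for (s in 1:NS) { u[s] ~ dnorm(0, tau_u) }\n",
    if (has_electrode) "  for (e in 1:NE) { v[e] ~ dnorm(0, tau_v) }\n" else "",
    "  sd_u ~ dexp(ranef_rate)\n",
    if (has_electrode) "  sd_v ~ dexp(ranef_rate)\n" else "",
    "  sd_e ~ dexp(sigma_rate)\n",
    "  tau_u <- pow(sd_u, -2)\n",
    if (has_electrode) "  tau_v <- pow(sd_v, -2)\n" else "",
    "  tau_e <- pow(sd_e, -2)\n",
    "}\n"
  )
}

#' Fit a hierarchical Bayesian mixed model
#'
#' Gaussian response with fixed effects and nested random intercepts
#' (subject, and electrode-within-subject when the analysis is
#' electrode-level), sampled by MCMC. Priors: Normal(0, 5) on the
#' intercept, Normal(0, 2) on coefficients, Exponential(1) on all
#' standard deviations. Four chains of 5000 iterations (1000 warmup) by
#' default; if any coefficient's Rhat exceeds 1.01 the sampler escalates
#' once to 10000 iterations with 5000 warmup.
#'
#' @param spec A [build_model()] specification (for degenerate designs
#'   with a single grouping level the hierarchy collapses gracefully).
#' @param seed Integer seed (one RNG stream per chain is derived).
#' @param chains Number of chains.
#' @param iter,warmup Total and warmup iterations per chain.
#' @param escalate Whether to refit at 10000/5000 on non-convergence.
#' @param monitor_ranef Whether to keep random-effect draws (needed for
#'   posterior predictive checks; default on when there are at most 1000
#'   levels).
#' @return An `hbm_fit`: `draws` (matrix, iterations x monitored
#'   parameters), `summary` tibble (per coefficient: `estimate`,
#'   `conf.low`, `conf.high`, `p_plus`, `rhat`, `ess`), `converged`,
#'   `escalated`, and the spec.
#' @export
fit_hbm <- function(spec, seed = 1, chains = 4, iter = 5000, warmup = 1000,
                    escalate = TRUE, monitor_ranef = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  has_elec <- "electrode" %in% names(spec$groups)
  subj <- factor(spec$groups$subject)
  elec <- if (has_elec) factor(spec$groups$electrode)
  n_ranef <- nlevels(subj) + if (has_elec) nlevels(elec) else 0L
  if (is.null(monitor_ranef)) monitor_ranef <- n_ranef <= 1000

  jdata <- list(
    y = spec$data$.y, X = spec$X, N = nrow(spec$X), K = ncol(spec$X),
    subj = as.integer(subj), NS = nlevels(subj),
    prec_int = 1 / spec$priors$intercept_sd^2,
    prec_coef = 1 / spec$priors$coef_sd^2,
    ranef_rate = spec$priors$ranef_rate, sigma_rate = spec$priors$sigma_rate
  )
  if (has_elec) {
    jdata$elec <- as.integer(elec)
    jdata$NE <- nlevels(elec)
  }
  if (ncol(spec$X) == 1) {
    # JAGS cannot loop 2:1; drop the coefficient loop by duplicating the
    # intercept column bound (K >= 2 kept with a zero column)
    jdata$X <- cbind(spec$X, 0)
    jdata$K <- 2L
  }

  run <- function(n_iter, n_warm) {
    inits <- lapply(seq_len(chains), function(i) {
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = child_seed(seed, i))
    })
    jm <- rjags::jags.model(
      textConnection(hbm_model_string(has_elec)), data = jdata,
      inits = inits, n.chains = chains,
      n.adapt = min(500L, n_warm), quiet = TRUE
    )
    stats::update(jm, n_warm)
    monitors <- c("beta", "sd_u", if (has_elec) "sd_v", "sd_e",
                  if (monitor_ranef) "u", if (monitor_ranef && has_elec) "v")
    rjags::coda.samples(jm, monitors, n.iter = n_iter - n_warm)
  }

  summarize <- function(samples) {
    coef_names <- colnames(spec$X)
    keep <- paste0("beta[", seq_along(coef_names), "]")
    rhat <- tryCatch(
      coda::gelman.diag(samples[, keep, drop = FALSE],
                        autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
      error = function(e) rep(NA_real_, length(keep))
    )
    ess <- coda::effectiveSize(samples[, keep, drop = FALSE])
    draws <- as.matrix(samples)
    sm <- lapply(seq_along(coef_names), function(k) {
      dk <- draws[, keep[k]]
      tibble(term = coef_names[k], estimate = mean(dk),
             conf.low = unname(quantile(dk, 0.025)),
             conf.high = unname(quantile(dk, 0.975)),
             p_plus = mean(dk > 0), rhat = unname(rhat[k]),
             ess = unname(ess[k]))
    })
    list(summary = bind_rows(sm), draws = draws)
  }

  samples <- run(iter, warmup)
  res <- summarize(samples)
  escalated <- FALSE
  if (escalate && any(!is.na(res$summary$rhat) & res$summary$rhat > 1.01)) {
    escalated <- TRUE
    samples <- run(10000, 5000)
    res <- summarize(samples)
  }
  converged <- all(res$summary$rhat <= 1.01, na.rm = TRUE) &&
    all(res$summary$ess >= 1000)
  beta_cols <- paste0("beta[", seq_len(ncol(spec$X)), "]")
  colnames(res$draws)[match(beta_cols, colnames(res$draws))] <-
    colnames(spec$X)

  structure(
    list(draws = res$draws, summary = res$summary, converged = converged,
         escalated = escalated, spec = spec, chains = chains,
         iter = if (escalated) 10000 else iter,
         warmup = if (escalated) 5000 else warmup, seed = seed,
         monitor_ranef = monitor_ranef),
    class = "hbm_fit"
  )
}

#' @export
print.hbm_fit <- function(x, ...) {
  cat(sprintf("<hbm_fit> %s (%d draws%s%s)\n", x$spec$analysis_id,
              nrow(x$draws),
              if (x$converged) ", converged" else ", NOT converged",
              if (x$escalated) ", escalated" else ""))
  print(x$summary)
  invisible(x)
}

#' Posterior probability of direction (P+)
#'
#' The proportion of posterior draws of an effect that exceed zero:
#' values near 1 indicate a consistently positive effect, near 0 a
#' consistently negative one. Invariant under any monotone increasing
#' transform of the draws that fixes zero.
#'
#' @param draws Numeric vector of posterior draws, or an `hbm_fit` with
#'   `term` naming the coefficient.
#' @param term Coefficient name for `hbm_fit` input (default the last
#'   fixed effect).
#' @return P+ in `[0, 1]`.
#' @export
prob_positive <- function(draws, term = NULL) {
  if (inherits(draws, "hbm_fit")) {
    term <- term %||% tail(colnames(draws$spec$X), 1)
    draws <- draws$draws[, term]
  }
  draws <- as.numeric(draws)
  if (length(draws) < 1000) {
    warn("fewer than 1000 draws; P+ may be imprecise")
  }
  mean(draws > 0)
}

#' Connectivity-strength ratio from a logged-response contrast
#'
#' Exponentiates a contrast estimated on log-scale coherence draw by
#' draw, giving a multiplicative connectivity-strength ratio with its
#' credible interval (a contrast of 0 maps to a ratio of exactly 1).
#'
#' @param x An `hbm_fit` whose response was log-transformed, or a
#'   numeric vector of contrast draws already on the log scale.
#' @param term Coefficient name for `hbm_fit` input.
#' @return One-row tibble: `ratio` (posterior mean of the exponentiated
#'   contrast), `conf.low`, `conf.high`.
#' @export
connectivity_ratio <- function(x, term = NULL) {
  if (inherits(x, "hbm_fit")) {
    if (!x$spec$transform %in% c("log", "log_scale")) {
      stop_bad("connectivity_ratio requires a log-transformed response")
    }
    term <- term %||% tail(colnames(x$spec$X), 1)
    x <- x$draws[, term]
  }
  r <- exp(as.numeric(x))
  tibble(ratio = mean(r),
         conf.low = unname(quantile(r, 0.025)),
         conf.high = unname(quantile(r, 0.975)))
}

#' Posterior predictive check on mean and standard deviation
#'
#' Simulates replicated datasets from the fitted model (conditional on
#' the sampled random effects) and compares their means and SDs with the
#' observed data; tail probabilities near 0 or 1 indicate misfit of the
#' corresponding statistic.
#'
#' @param fit An `hbm_fit` fitted with `monitor_ranef = TRUE`.
#' @param n_rep Number of replicated datasets (default 200).
#' @param seed Integer seed.
#' @return Tibble with one row per statistic: `stat`, `observed`,
#'   `rep_mean`, `rep_sd`, `p_tail` (fraction of replicates at or above
#'   the observed value).
#' @export
posterior_predictive_check <- function(fit, n_rep = 200, seed = 1) {
  stopifnot(inherits(fit, "hbm_fit"))
  if (!fit$monitor_ranef) {
    stop_bad("fit was run without random-effect draws; refit with monitor_ranef = TRUE")
  }
  spec <- fit$spec
  has_elec <- "electrode" %in% names(spec$groups)
  subj <- as.integer(factor(spec$groups$subject))
  elec <- if (has_elec) as.integer(factor(spec$groups$electrode))
  draws <- fit$draws
  u_cols <- grep("^u\\[", colnames(draws))
  v_cols <- grep("^v\\[", colnames(draws))
  beta_cols <- match(colnames(spec$X), colnames(draws))
  idx <- with_seed(child_seed(seed, 29L),
                   sample(nrow(draws), min(n_rep, nrow(draws))))
  obs <- spec$data$.y
  stats_rep <- with_seed(child_seed(seed, 31L), {
    t(vapply(idx, function(i) {
      mu <- as.vector(spec$X %*% draws[i, beta_cols]) +
        draws[i, u_cols][subj] +
        (if (has_elec) draws[i, v_cols][elec] else 0)
      yr <- rnorm(length(mu), mu, draws[i, "sd_e"])
      c(mean = mean(yr), sd = sd(yr))
    }, numeric(2)))
  })
  tibble(
    stat = c("mean", "sd"),
    observed = c(mean(obs), sd(obs)),
    rep_mean = colMeans(stats_rep),
    rep_sd = apply(stats_rep, 2, sd),
    p_tail = c(mean(stats_rep[, "mean"] >= mean(obs)),
               mean(stats_rep[, "sd"] >= sd(obs)))
  )
}

#' @export
#' @rdname fit_hbm
#' @param x An `hbm_fit`.
#' @param ... Unused.
tidy.hbm_fit <- function(x, ...) x$summary

#' @export
#' @rdname fit_hbm
glance.hbm_fit <- function(x, ...) {
  tibble(nobs = nrow(x$spec$X), n_draws = nrow(x$draws),
         chains = x$chains, iter = x$iter, warmup = x$warmup,
         max_rhat = max(x$summary$rhat, na.rm = TRUE),
         min_ess = min(x$summary$ess), converged = x$converged,
         escalated = x$escalated)
}
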