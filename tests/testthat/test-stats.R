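test_that("the analysis registry builds specs and enforces columns", {
  d <- sim_hbm_data(1, n_subj = 4, n_elec = 2, n_trials = 6)
  spec <- build_model("theta_approach_avoid", d)
  expect_s3_class(spec, "model_spec")
  expect_equal(colnames(spec$X), c("(Intercept)", "approach"))
  expect_equal(names(spec$groups), c("subject", "electrode"))
  # electrode labels are nested within subject
  expect_true(all(grepl("^P\\d+:", spec$groups$electrode)))

  # exclusions: conflict-free and attack trials are removed
  d2 <- d
  d2$conflict[1:20] <- FALSE
  d2$attack <- FALSE
  d2$attack[21:30] <- TRUE
  spec2 <- build_model("theta_approach_avoid", d2)
  expect_equal(nrow(spec2$data), nrow(d) - 30)

  expect_error(build_model("nope", d), "unknown analysis_id")
  expect_error(build_model("theta_approach_avoid",
                           dplyr::select(d, -electrode)),
               "electrode")
  expect_gte(nrow(list_analyses()), 8)
})

test_that("behavioral model applies the no-turn and conflict-free exclusions", {
  cfg <- task_config()
  trials <- run_session(generate_session(cfg, seed = 3),
                        policy_threshold(), cfg, seed = 3)
  trials$subject <- "P01"
  spec <- build_model("behavior_reward", trials)
  kept <- dplyr::filter(trials, conflict, n_turnarounds > 0,
                        !is.na(turnaround_distance))
  expect_equal(nrow(spec$data), nrow(kept))
  expect_true("last_dot_size_small" %in% colnames(spec$X))
})

test_that("fitting recovers a planted coefficient with calibrated intervals", {
  d <- sim_hbm_data(2)
  spec <- build_model("theta_approach_avoid", d)
  fit <- cached("hbm_fit_1",
                fit_hbm(spec, seed = 1, chains = 2, iter = 1200, warmup = 400,
                        escalate = FALSE))
  est <- dplyr::filter(fit$summary, term == "approach")
  expect_lt(est$conf.low, 0.24)
  expect_gt(est$conf.high, 0.24)
  expect_lt(abs(est$estimate - 0.24), 0.1)
  expect_gt(est$p_plus, 0.99)
  expect_true(all(c("rhat", "ess") %in% names(fit$summary)))
  g <- glance(fit)
  expect_equal(g$nobs, nrow(spec$X))
  expect_identical(tidy(fit), fit$summary)
})

test_that("fits are reproducible given a seed", {
  d <- sim_hbm_data(3, n_subj = 4, n_elec = 2, n_trials = 8)
  spec <- build_model("theta_approach_avoid", d)
  f1 <- fit_hbm(spec, seed = 9, chains = 2, iter = 500, warmup = 200,
                escalate = FALSE, monitor_ranef = FALSE)
  f2 <- fit_hbm(spec, seed = 9, chains = 2, iter = 500, warmup = 200,
                escalate = FALSE, monitor_ranef = FALSE)
  expect_equal(f1$summary, f2$summary)
})

test_that("a single-subject hierarchy collapses gracefully", {
  d <- sim_hbm_data(4, n_subj = 1, n_elec = 3, n_trials = 20)
  spec <- build_model("theta_approach_avoid", d)
  fit <- fit_hbm(spec, seed = 2, chains = 2, iter = 500, warmup = 200,
                 escalate = FALSE, monitor_ranef = FALSE)
  expect_s3_class(fit, "hbm_fit")
  expect_true(is.finite(fit$summary$estimate[2]))
})

test_that("P+ matches analytic values and transform invariance", {
  withr::with_seed(5, {
    sym <- rnorm(2e4)
    expect_lt(abs(prob_positive(sym) - 0.5), 0.02)
    expect_equal(prob_positive(abs(sym) + 1), 1)
    tail95 <- rnorm(1e5, qnorm(0.95), 1)
    expect_lt(abs(prob_positive(tail95) - 0.95), 0.005)
    # invariant under monotone transforms fixing zero
    expect_equal(prob_positive(sym), prob_positive(sym^3))
    expect_equal(prob_positive(sym), prob_positive(expm1(sym)))
  })
  expect_warning(prob_positive(rnorm(10)), "1000")
})

test_that("connectivity ratio transforms log contrasts exactly", {
  expect_equal(connectivity_ratio(rep(log(1.5), 1500))$ratio, 1.5)
  r0 <- connectivity_ratio(rep(0, 1500))
  expect_equal(r0$ratio, 1)
  expect_equal(r0$conf.low, 1)
  # refuses a fit whose response is not on the log scale
  d <- sim_hbm_data(6, n_subj = 3, n_elec = 2, n_trials = 5)
  spec <- build_model("theta_approach_avoid", d)
  fit <- fit_hbm(spec, seed = 3, chains = 1, iter = 300, warmup = 100,
                 escalate = FALSE, monitor_ranef = FALSE)
  expect_error(connectivity_ratio(fit), "log")
})

test_that("connectivity ratio recovers a planted region contrast", {
  # two partner regions with true coherence ratio 1.5 on the log scale
  withr::with_seed(7, {
    d <- tidyr::expand_grid(subject = sprintf("P%02d", 1:10),
                            electrode = sprintf("e%d", 1:4),
                            partner_region = c("MFG", "HC"),
                            rep = 1:10)
    u <- stats::setNames(rnorm(10, 0, 0.2), sprintf("P%02d", 1:10))
    d$coherence <- exp(log(0.05) + log(1.5) * (d$partner_region == "HC") +
                         u[d$subject] + rnorm(nrow(d), 0, 0.4))
  })
  spec <- build_model("coherence_partner_region", d)
  fit <- fit_hbm(spec, seed = 4, chains = 2, iter = 1500, warmup = 500,
                 escalate = FALSE, monitor_ranef = FALSE)
  cr <- connectivity_ratio(fit, term = "partner_regionMFG")
  # contrast is MFG vs HC: ratio 1/1.5; invert for the HC/MFG ratio
  ratio <- 1 / cr$ratio
  expect_lt(abs(ratio - 1.5), 0.15)
  expect_true(1.5 >= 1 / cr$conf.high && 1.5 <= 1 / cr$conf.low)
})

test_that("priors used by the sampler have the published scales", {
  d <- sim_hbm_data(8, n_subj = 2, n_elec = 2, n_trials = 4)
  spec <- build_model("theta_approach_avoid", d)
  # sample the prior distributions with the hyperparameters the spec carries
  pr <- spec$priors
  code <- sprintf(
    "model { b0 ~ dnorm(0, %g); b1 ~ dnorm(0, %g); s ~ dexp(%g) }",
    1 / pr$intercept_sd^2, 1 / pr$coef_sd^2, pr$ranef_rate)
  jm <- rjags::jags.model(textConnection(code), n.chains = 1, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 1))
  s <- rjags::coda.samples(jm, c("b0", "b1", "s"), n.iter = 20000)
  draws <- as.matrix(s)
  expect_lt(abs(sd(draws[, "b0"]) - 5) / 5, 0.1)
  expect_lt(abs(sd(draws[, "b1"]) - 2) / 2, 0.1)
  expect_lt(abs(mean(draws[, "s"]) - 1), 0.1)
})

test_that("posterior predictive checks are calibrated for a correct model", {
  fit <- cached("hbm_fit_1", {
    spec <- build_model("theta_approach_avoid", sim_hbm_data(2))
    fit_hbm(spec, seed = 1, chains = 2, iter = 1200, warmup = 400,
            escalate = FALSE)
  })
  ppc <- posterior_predictive_check(fit, n_rep = 200, seed = 2)
  expect_equal(ppc$stat, c("mean", "sd"))
  expect_true(all(ppc$p_tail >= 0.05 & ppc$p_tail <= 0.95))
  expect_lt(abs(ppc$observed[1] - ppc$rep_mean[1]), 3 * ppc$rep_sd[1])
  # without random-effect draws the check refuses
  spec_s <- build_model("theta_approach_avoid",
                        sim_hbm_data(9, n_subj = 3, n_elec = 2, n_trials = 5))
  fit_s <- fit_hbm(spec_s, seed = 5, chains = 1, iter = 300, warmup = 100,
                   escalate = FALSE, monitor_ranef = FALSE)
  expect_error(posterior_predictive_check(fit_s), "monitor_ranef")
})

test_that("region-level models recover where theta modulation lives", {
  ds <- modulated_fixture()
  ep <- epoch_lfp(ds, "turnaround", c(-1500, 1500))
  bp <- band_power(morlet_tfr(ep, decim = 10), "theta",
                   baseline = c(-1500, -1400))
  app <- window_power(bp, c(-1400, -100)) |> dplyr::mutate(period = "approach")
  avd <- window_power(bp, c(100, 1400)) |> dplyr::mutate(period = "avoid")
  d <- dplyr::bind_rows(app, avd) |>
    dplyr::mutate(subject = "P01", electrode = channel, theta = value,
                  conflict = TRUE)
  p_plus <- sapply(unique(d$region), function(rg) {
    spec <- build_model("theta_approach_avoid",
                        dplyr::filter(d, region == rg))
    fit <- fit_hbm(spec, seed = 6, chains = 2, iter = 800, warmup = 300,
                   escalate = FALSE, monitor_ranef = FALSE)
    prob_positive(fit, "approach")
  })
  mod_regions <- setdiff(unique(d$region), "MFG")
  expect_true(all(p_plus[mod_regions] > 0.95))
  expect_true(p_plus["MFG"] >= 0.025 && p_plus["MFG"] <= 0.975)
})
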