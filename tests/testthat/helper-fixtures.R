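# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

coupled_fixture <- function() {
  cached("coupled", make_fixture("coupled_lagged", seed = 7, n_trials = 40))
}

coupled_epochs <- function() {
  cached("coupled_ep",
         epoch_lfp(coupled_fixture(), "turnaround", c(-2500, 2500)))
}

coupled_csd <- function() {
  cached("coupled_csd", theta_csd(coupled_epochs()))
}

null_fixture <- function() {
  cached("null", make_fixture("null", seed = 11, n_trials = 40))
}

null_csd <- function() {
  cached("null_csd", {
    ep <- epoch_lfp(null_fixture(), "turnaround", c(-2500, 2500))
    theta_csd(ep)
  })
}

modulated_fixture <- function() {
  cached("modulated", make_fixture("task_modulated", seed = 13, n_trials = 40))
}

# Synthetic hierarchical data with a known approach-vs-avoid coefficient.
sim_hbm_data <- function(seed, n_subj = 15, n_elec = 6, n_trials = 40,
                         beta = 0.24, sd_subj = 0.5, sd_elec = 0.3,
                         sd_noise = 1) {
  withr::with_seed(seed, {
    d <- tidyr::expand_grid(
      subject = sprintf("P%02d", seq_len(n_subj)),
      electrode = sprintf("e%d", seq_len(n_elec)),
      trial = seq_len(n_trials),
      period = c("approach", "avoid")
    )
    u <- stats::setNames(rnorm(n_subj, 0, sd_subj),
                         sprintf("P%02d", seq_len(n_subj)))
    ve <- tidyr::expand_grid(subject = sprintf("P%02d", seq_len(n_subj)),
                             electrode = sprintf("e%d", seq_len(n_elec)))
    v <- stats::setNames(rnorm(nrow(ve), 0, sd_elec),
                         paste(ve$subject, ve$electrode, sep = ":"))
    d$theta <- beta * (d$period == "approach") +
      u[d$subject] + v[paste(d$subject, d$electrode, sep = ":")] +
      rnorm(nrow(d), 0, sd_noise)
    d$conflict <- TRUE
    d
  })
}

# Hand-built epochs object around white-noise matrices (trials x samples),
# for directionality nulls that need exact control of the signals.
epochs_from_matrices <- function(mats, fs = 100, t0 = -1500) {
  n_ch <- length(mats)
  ntr <- nrow(mats[[1]]); ns <- ncol(mats[[1]])
  data <- array(NA_real_, dim = c(n_ch, ntr, ns))
  for (i in seq_len(n_ch)) data[i, , ] <- mats[[i]]
  structure(
    list(
      data = data, fs = fs,
      times = t0 + (seq_len(ns) - 1) * 1000 / fs,
      lock_event = "turnaround", window = c(t0, t0 + (ns - 1) * 1000 / fs),
      valid = rep(TRUE, ntr),
      events = tibble::tibble(trial = seq_len(ntr)),
      channels = tibble::tibble(
        channel_id = paste0("ch", seq_len(n_ch)),
        region = rep(c("HC", "AMY", "OFC", "ACC", "MFG"),
                     length.out = n_ch),
        hemisphere = "L", modulated = TRUE
      )
    ),
    class = "epochs"
  )
}
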