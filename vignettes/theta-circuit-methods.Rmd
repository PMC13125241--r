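---
title: "Models and methods: approach-avoidance theta-circuit analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: approach-avoidance theta-circuit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aacircuit` is a self-contained, fully testable re-implementation of an
intracranial-EEG analysis chain for approach-avoidance conflict: a
behavioral task simulator, a synthetic LFP generator with known
ground-truth coupling, and the spectral power → coherence →
directionality → hierarchical-Bayesian-inference pipeline. Every stage
can be validated against a planted answer key, without patient data.
This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the design was
genuinely open.

## 1. The behavioral task model

The task is a continuous-choice corridor game. The player starts near
one exit of a 200-unit corridor, a ghost patrols the far end, and five
dots worth 10 (small) or 20 (large) points lie between them. Approaching
collects reward but raises threat: the per-tick probability of a ghost
attack is a function of the player-ghost distance. A session is 240
trials in 12 blocks of 20, 20% of trials conflict-free (no ghost), and
the task is played as minigames that end after three captures or twenty
trials, with lives and score resetting.

Simulation is in discrete time, `tick_ms = 50` ms per tick, speeds in
units/tick (2 by default). Only *relative* speed matters for the
Chase/Strike logic, so the absolute scale is a free parameter chosen to
give trials of a few seconds, matching the recorded epoch lengths.

**Attack hazard.** The hazard is a scaled beta CDF of proximity:

$$h(d) = h_{\max} \cdot F_\beta\!\left(1 - d/L;\ \alpha, \beta\right),$$

with corridor length $L$, cap $h_{\max} = 0.02$ per tick, and shape
defaults $\alpha = 5$, $\beta = 2$. The CDF form guarantees
monotonicity (attacks never become *less* likely as the player closes
in) and the $[0, h_{\max}]$ range for any valid shapes. The shape
defaults were chosen so the hazard is negligible over the far half of
the corridor and rises steeply near the patrol zone — attacks far from
the ghost are rare, attacks close to it common. All hazard parameters
are configurable; the hazard is evaluated once per tick (evaluation per
position change would give near-identical dynamics at these speeds).

**Chase and Strike.** Triggered attacks consume labels in order from a
pre-drawn, balanced per-session sequence, so the realized Chase/Strike
split is ~50/50 no matter when attacks occur. A Chase keeps the ghost at
patrol speed: a player who turns immediately keeps the gap and escapes.
A Strike multiplies ghost speed by `strike_speed_multiplier` (2.5), and
the simulator additionally verifies capture geometrically at trigger
time — if the configured multiplier would allow escape from the current
positions, the speed is raised for that trial. The design intent is an
outcome guarantee, not a particular speed.

**Counterbalancing.** Within each block, conflict trials are a full
crossing of start side (2) × ghost start direction (2) × dot-size
pattern (4; two patterns end on a small dot, two on a large one), and
conflict-free trials cover the side × direction crossing. Dots are
evenly spaced between the player start and the patrol zone with ±3
units of seeded jitter; the patrol boundary sits a jittered buffer
beyond the last dot. Session generation is a pure function of
`(config, seed)`.

**Turnarounds.** When the player turns multiple times, the *final*
toward→away switch is the decision to avoid; its player-ghost distance
is the turnaround distance. Behavioral summaries exclude conflict-free
trials and trials without a turn.

## 2. The synthetic LFP generator

`generate_lfp()` builds channels × trials × samples arrays from a
`ground_truth()` object. Each channel is a sum of:

* **1/f background** — spectrally shaped Gaussian noise with exponent
  1.0 (power ∝ 1/f), the dominant feature of field-potential spectra;
* **a theta oscillator** — an AR(2) process with spectral peak at 5 Hz
  and pole radius 0.95 *at an internal 100 Hz rate*, band-limited
  upsampled to the target rate. At 100 Hz the 0.95 pole gives a ~1.6 Hz
  bandwidth — a stochastic oscillator rather than a sinusoid, so
  coherence stays below 1 and permutation tests are meaningful. (A 0.95
  pole defined directly at 1000 or 2000 Hz would be ~16-33 Hz wide and
  not a theta oscillator at all, which is why the pole is anchored at
  the internal rate.)
* **directed couplings** — each target channel receives a lagged,
  gain-weighted copy of the source channel's oscillator (lag in ms,
  realized in samples at the output rate);
* **task-locked amplitude schedule** — the oscillator is scaled by an
  approach multiplier between movement onset and turnaround and an
  avoid multiplier afterwards (default 2:1), with a 100 ms smoothing of
  the steps; channels can opt out (`modulated = FALSE`), which is how
  the MFG-like control channels are built;
* **high-frequency bursts** — 80-120 Hz filtered noise under a 300 ms
  raised-cosine envelope at an anchored event (attack onset), in
  designated channels only.

`snr` sets the oscillator-SD-to-background-SD ratio (default 1). The
sampling-rate dialects of the recording sites (2000 and 512 Hz) are
supported and tested; fixtures default to 1000 Hz for speed.

What the generator does **not** emulate: epileptiform artifacts,
non-stationary 1/f slopes, cross-frequency coupling, volume-conduction
geometry beyond an explicit mixing matrix, and electrode-distance
effects. Passing tests therefore demonstrate the *correctness of the
analysis chain against its own assumptions*, not robustness to every
pathology of clinical recordings.

The paper-scale effect sizes in patients are not knowable at desk
scale; fixture gains (coupling gain 0.8 at 25 ms lag; schedule 2:1)
were chosen once so that recovery is reliable at 30-40 trials, and are
documented in `make_fixture()`.

## 3. Spectral estimation

Preprocessing low-passes at 150 Hz and notches 60/120 Hz
(forward-backward Butterworth; zero phase, length-preserving). Bipolar
referencing subtracts adjacent contacts.

The TFR uses 80 log-spaced frequencies from 1 to 150 Hz with 80
log-spaced cycle counts from 2 to 30 matched to them (`wavelet_grid()`),
complex Morlet wavelets, FFT convolution. Samples within half a wavelet
support of the epoch edge are flagged per frequency and excluded from
statistics windows.

Band power is natural-log-transformed and z-scored per (channel,
frequency) against an inter-trial-interval baseline pooled across
trials; the log base is immaterial after z-scoring. Theta is the mean
of the 3-8 Hz frequencies; high-frequency activity averages seven
overlapping 20 Hz sub-bands (70-90, 80-100, …, 130-150 Hz) before
averaging the sub-bands, which keeps the estimate from being dominated
by the 1/f-favored low end of a single wide band. The sub-band step of
10 Hz (7 bands) follows the printed example pattern. Band power is
block-averaged down to a common 20 Hz for statistics, which also
anti-aliases by construction. The default ITI baseline is the final
1000 ms before trial onset; the exact window is configuration, not
model.

## 4. Across-trial theta coherence

Connectivity runs at 100 Hz on the theta frequencies of the canonical
grid (the 15 log-spaced frequencies in 3-8 Hz with matched cycles).
Metrics are computed **across trials** at every timepoint and frequency,
then averaged over frequencies:

* absolute imaginary coherency $|\mathrm{Im}(C_{ab})|$ — discards the
  zero-phase-lag component that volume conduction produces;
* pairwise phase consistency — the unbiased estimator of squared phase
  locking;
* debiased squared weighted phase-lag index — weights phase differences
  by their imaginary magnitude and removes the small-sample bias.

Significance comes from shuffling the trial labels of *one* member of
the pair (1000 shuffles at full scale; fixtures use 120-200), one-sided
p-values (elevated coherence), Benjamini-Hochberg FDR across
timepoints, and a duration rule: the pair counts as connected only if a
**contiguous** run of corrected-significant timepoints spans at least
100 ms (10 samples at 100 Hz). Contiguity is a design decision exposed
as `contiguous = FALSE` for total-duration counting; FDR is applied per
pair, matching a correction "for the number of time points". A naive
real-part coherence is implemented as a deliberately fragile negative
control (`metric = "real_coh"`) and is used only in validation: under
zero-lag mixing of independent channels it is grossly inflated while
the phase-lag metrics stay at their calibrated false-positive rate.

Trial-level coupling uses amplitude-envelope synchrony instead (per
trial Pearson correlation of two channels' envelopes over the approach
window, Fisher-z, standardized within pair), because across-trial
coherence has no stable single-trial analogue.

## 5. Directionality

**Net spectral Granger causality.** At each timepoint of the final
1500 ms of approach (edge-artifact-free region of the 2500 ms pre-turn
epoch), a bivariate VAR with 12 lags is fit by OLS on a centered 310 ms
(31-sample) window pooled across trials — 19 regression rows per trial,
so ≥ 8 × 12 samples enter every fit. The spectral (Geweke)
decomposition of the fitted VAR gives GC in both directions, averaged
over 3-8 Hz. The VAR route is used because the spectral factorization
of a fitted VAR coincides with that of its state-space embedding; 12
lags act as the spectral smoothing parameter. The directional contrast
is then debiased with time reversal:

$$\mathrm{net}(a,b) = \left[\mathrm{GC}(a \to b) - \mathrm{GC}(b \to a)\right] -
\left[\mathrm{GC}_{\mathrm{rev}}(a \to b) - \mathrm{GC}_{\mathrm{rev}}(b \to a)\right]$$

with the reversed scores computed on within-trial time-flipped
segments. A genuine lagged interaction flips sign under reversal while
SNR-driven pseudo-directionality does not, so the subtraction cancels
the latter. This grouping makes the score antisymmetric,
net(a,b) = −net(b,a), which the consensus logic relies on; the printed
formula without grouping is available behind `literal = TRUE` but is
not antisymmetric and is provided for comparability only. Permutation
nulls shuffle trial labels of one channel; p-values compare |net| to
the null (two-sided on the signed score), are FDR-corrected across
timepoints, and a pair qualifies with ≥ 500 ms (50 timepoints)
significant.

**Cross-correlation.** As an independent check computed from a
different theta estimate (FIR band-pass rather than wavelets), each
trial's approach window is z-scored and concatenated, the CCF over ±25
lags (±250 ms at 100 Hz) is computed on the concatenated sequence, and
the null shuffles the *order* of one channel's trial segments while
keeping every segment's length — so the discontinuity structure is
identical under the null. The best (signed-maximum) lag is retained if
the maximum correlation is in the top 5% of null maxima; positive lag
means the first channel leads.

**Consensus.** Direction is interpreted only when the hierarchical
models of both methods give P+ > 0.95 (or both < 0.05) in the same
direction.

## 6. Hierarchical Bayesian inference

All contrasts are fit as Gaussian mixed models with nested random
intercepts — subject, and electrode (or first electrode of a pair)
within subject — sampled by MCMC (Gibbs, JAGS backend). The grouping
"electrode hierarchically within patient" is realized as nested random
intercepts; no random slopes are used, so the prior on random-effect
*correlations* (an LKJ(2) prior in the reference configuration) never
enters the likelihood here. Priors: Normal(0, 5) on intercepts,
Normal(0, 2) on coefficients, Exponential(1) on random-effect SDs, and
Exponential(1) on the residual SD (the reference configuration states
priors only for the first three; Exponential(1) keeps the residual
scale weakly informative on z-scored responses). Four chains, 5000
iterations with 1000 warmup, escalating once to 10000/5000 if any
coefficient Rhat exceeds 1.01; convergence requires Rhat ≤ 1.01 and
bulk ESS ≥ 1000. The test suite and acceptance script run at reduced
sampler settings (2 chains, 1200/400) with convergence of the effect
of interest verified empirically.

Inference is summarized by the posterior mean, 95% credible interval,
and **P+**, the fraction of posterior draws above zero — invariant under
any monotone increasing transform fixing zero. Responses are
transformed per analysis (scaled; logged for coherence strength, so
that exponentiating a contrast draw-wise yields a connectivity-strength
*ratio*; scaled-but-not-centered for the intercept-only directionality
models, preserving sign). Bayes factors are out of scope: they require
marginal-likelihood machinery (bridge sampling) that adds nothing to
the directional questions P+ answers, and are deliberately not
reported. Posterior predictive checks simulate replicates conditional
on the sampled random effects and compare the mean and SD.

Per-electrode "ratio of significant electrodes" summaries, where used,
take the conditional (random-effect) draws rather than per-electrode
refits.

## 7. Numerical choices and degenerate inputs

* Permutation p-values use the conservative $(1 + \#\{null \ge
  obs\})/(n_{perm} + 1)$ estimator; the observed statistic is never in
  its own null.
* The VAR normal equations get a $10^{-10}$ relative ridge; an
  ill-conditioned fit raises an error with diagnostics rather than
  returning noise.
* wPLI's debiased denominator can be non-positive in degenerate cells;
  those cells are set to 0.
* Constant envelopes, empty approach windows, and trials missing the
  lock event are dropped/masked with warnings, never silently.
* A single-subject hierarchy collapses gracefully (the subject SD is
  weakly identified by its prior); a Granger model of a channel on
  itself is an error.
* Resampling uses polyphase FIR with a rational approximation of the
  rate ratio (e.g. 25/128 for 512→100 Hz).

## 8. Problem sizes used in validation

The test suite and the acceptance script validate at desk scale, chosen
once: null-calibration at 210 pairs × 200 permutations for coherence
(the full 1000-permutation null is used in production settings) and
16-24 pairs × 100 permutations for Granger qualification; coupling
recovery on 30-40 trial fixtures; hierarchical recovery at 15 patients
× 6 electrodes × 40 trials × 2 conditions with a planted coefficient of
0.24. With FDR plus the duration rules, the null qualifying rates sit
far below the nominal 5%, so these sizes separate cleanly.

## 9. Known limitations

* The generator's stationary 1/f background and single oscillator class
  understate the diversity of real iEEG; effect sizes recovered from
  fixtures say nothing about patient-level effect sizes.
* Pairwise GC cannot distinguish direct from relayed influence;
  conditional/multivariate GC is intentionally out of scope.
* The permutation nulls assume exchangeable trials within a channel;
  slow drifts across a session would violate this.
* The dataset text container stores signals at CSV precision
  (~7 significant digits), adequate for the analyses but not
  bit-identical round trips.
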