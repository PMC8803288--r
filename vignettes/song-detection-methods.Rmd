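---
title: "Detecting song behavior from single-axis accelerometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting song behavior from single-axis accelerometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Male European Nightjars (*Caprimulgus europaeus*) produce a sustained trilled
"churring" song from stationary song posts at night. The body vibration that
accompanies churring is detectable by a tail-mounted accelerometer sampling a
single (Z) axis at 25 Hz, which makes it possible to quantify an individual's
song output continuously — something stationary audio recorders cannot do,
because they only capture song produced within a short audible radius
(about 20 m).

`nightsong` implements the full analysis chain for this problem:

1. decompose raw acceleration into a static (gravity/tag-angle) and a dynamic
   (movement-induced) component by running-mean subtraction;
2. segment the dynamic signal with an unsupervised univariate Gaussian hidden
   Markov model (HMM), fitted by Baum–Welch expectation maximization from
   seeded random initializations and decoded with the Viterbi algorithm;
3. map the decoded states onto a four-behavior ethogram (rest, sing, fly,
   leap), subsample to a 1-s grid, and extract song bouts with a 10-s
   minimum-duration rule;
4. validate the classified song bouts against audio-recorder annotations,
   gating each bout by GPS distance to the recorders and comparing matched
   bout durations with rank and location statistics.

Because the original field data are not required, the package ships a seeded
synthetic-night generator that reproduces the statistical structure the
analysis assumes, so the whole chain is testable end to end.

## The model

The dynamic acceleration \(y_t\) (g) is modeled as a K-state HMM with
univariate Gaussian emissions,

\[ y_t \mid s_t = k \sim \mathcal{N}(\mu_k, \sigma_k^2), \qquad
   P(s_{t+1} = j \mid s_t = k) = A_{kj}, \]

with initial distribution \(\pi\). Dynamic acceleration is near zero-mean in
every behavior, so states separate chiefly by their emission scale
\(\sigma_k\): quiet rest, medium-amplitude body vibration during song, strong
wingbeat signal in flight, and still stronger brief bursts while leaping
after prey. Emissions are single Gaussians, not mixtures, and transitions
carry no covariates.

Fitting uses the scaled forward–backward recursions (implemented in C++ for
speed; the scaling constants give the log-likelihood directly) with
closed-form M-steps. The log-likelihood trace is non-decreasing by
construction and is asserted to be so in the test suite on every fit.

### Fitting parameters

| parameter | default | meaning |
|---|---|---|
| `K_range` | 4–7 | candidate state counts |
| `K_pinned` | 5 | state count used for classification |
| `max_iter` | 10,000 | EM iteration cap |
| `tol` | 1e-6 | relative log-likelihood early stop (0 = run the full cap) |
| `n_restarts` | 10 | seeded random initializations, best kept |
| `train_fraction` | 0.5 | contiguous share of the night used for fitting |
| `sigma_floor` | 1e-4 g | emission-sd clamp preventing degenerate collapse |
| `smooth_window_s` | 2 s | running-mean window |
| `min_sing_s` | 10 s | minimum retained song bout |
| `threshold_m` | 20 m | near/far audibility gate |
| `match_tol_s` | 1 s | bout-matching timing tolerance |
| `min_recorded_s` | 20 s | recorded-duration cut for the paired t branch |
| `shapiro_cutoff` | 0.9 | Shapiro–Wilk W normality gate |

Design choices where the procedure was genuinely open:

* **Number of restarts.** Random initialization is part of the procedure but
  no count is canonical; the default is 10, and each restart's seed and final
  log-likelihood are recorded so a run is exactly reproducible.
* **Early stopping.** The 10,000-iteration cap is retained, with an early
  stop when the relative log-likelihood improvement falls below `tol`; on
  well-separated data the optimum is reached within tens of iterations, and
  `tol = 0` restores strict fixed-iteration behavior.
* **Initialization.** Emission-scale seeds are log-spaced between the median
  and the 0.9995 quantile of |obs| (rescaled by the half-normal median),
  with multiplicative jitter. This matters: quiet samples dominate a night
  (the bird rests most of the time), and quantile-spaced seeds drawn
  uniformly in probability never land near the rare high-amplitude flight
  and leap regimes, leaving EM in local optima that merge them. Means are
  seeded near zero; transition rows are diagonal-dominant random draws,
  reflecting behavioral persistence at 25 Hz.
* **Model selection.** The choice among 4–7 states was originally made by
  visual inspection, which is not reproducible; `select_model()` substitutes
  BIC with `n_params = (K-1) + K(K-1) + 2K`, while `K_pinned = 5` honors the
  five-state choice by default. The full BIC table is always reported.
* **Training subset.** "Half of one night" does not specify how the half is
  taken; the default is the first contiguous 50% (preserving dwell-time
  structure), with an alternating-block option for sensitivity checks.
* **Fit signal.** The pipeline fits the dynamic component by default — it is
  the physically meaningful activity signal — with a `fit_signal = "smoothed"`
  switch, since descriptions of the procedure are ambiguous on this point.

### Preprocessing

A 2-s running mean at 25 Hz spans 50 samples; the filter uses a centered
51-tap window (±1 s inclusive) so it is symmetric and phase-free. At segment
edges the window shrinks to the available samples rather than padding with
fabricated data. The decomposition `raw = smoothed + dynamic` is exact at
every sample. No local edge scheme can also make the dynamic component
exactly mean-free over a finite segment (the filter does not preserve column
sums at the edges); mean-freeness holds on the full-window interior, and
tests assert it there. Smoothing is applied per contiguous segment
(`split_gaps()`), never across the daytime off period.

### State-to-behavior mapping

With five states ordered by emission sd, the two quietest are inactive
(rest: the five-state solution dedicates two states to inactive behavior),
the middle one is song, and the two most active are flight and leaping.
Emission scale alone cannot separate sustained flight from brief foraging
leaps, so the state with the longer mean decoded run length becomes `fly`.
This run-length heuristic is an interpretation — the original assignment
drew on species-specific literature — and a user-supplied map bypasses it.
Ties anywhere break toward the lower state index.

The processing order is: Viterbi at 25 Hz → per-second majority labels (ties
broken by activity precedence fly > leap > sing > rest) → maximal-run bout
extraction → 10-s song filter. A bout of exactly 10 s is retained ("at least
10 s"). Sub-threshold song bouts are relabeled to rest rather than deleted —
the bird was stationary either way — so the 1-s grid stays gap-free and
total labeled time is conserved; a `filter_order = "before_subsample"`
switch applies the 10-s rule to the 25 Hz label runs instead.

### Validation

Each classified song bout is located at the GPS fix nearest in time to its
midpoint (fixes are 3 min apart; a bout with no fix within 15 min is flagged
unlocatable, mirroring the observation that brief stationarity can leave a
song post unregistered). The minimum haversine distance (sphere radius
6,371,000 m) to any recorder classes the bout as near (< 20 m) or far.
Model and audio bout tables are matched one-to-one greedily by descending
interval overlap after expanding both sides by the ±1-s annotation
tolerance; on the near-diagonal tables this produces, greedy matching
attains the optimal match count (asserted against an exhaustive assignment
oracle in tests). Matched pairs are counted in the model bout's distance
class, which keeps `n = match + only` conservation exact within every class.

Duration statistics follow the published branching: Shapiro–Wilk on each
duration sample; with W < 0.9 the durations are treated as non-normal and a
Spearman rank correlation (reporting rho, S, n, p; S may be tie-corrected
and non-integer) plus a Wilcoxon signed-rank test are run on all pairs; a
paired t test (df = n−1) runs on the subset with recorded duration ≥ 20 s.
P-values are two-sided; the Wilcoxon uses the exact distribution up to
n = 25 and the continuity-corrected normal approximation above. The
accuracy denominator corrects the model's near-recorder bout count upward
by audio-only bouts (false negatives evident on the recordings):
`accuracy = 100 · n_model_near / (n_model_near + n_audio_only_near)`.
Because the published far-class detection figure was rounded from a raw
fraction, the summary reports raw percentages and leaves rounding to the
caller.

## The synthetic-night generator

`simulate_behavior_script()` builds a gap-free tiling of a 21:00–06:00 GMT
night under a semi-Markov site-session model: the bird dwells at a site for
10–25 min — alternating rest with song bouts at song posts, or rest with
1–5-s leap bursts at foraging patches — then commutes by flight (site
distance over a 10 m/s flight speed) to another site. Explicit dwell-time
distributions, rather than a plain Markov chain, are essential: real bout
durations are strongly non-geometric, and the 10-s song filter and duration
statistics are only meaningful against such durations. Song-bout durations
are lognormal with median 25 s (sdlog 0.9) truncated to 11–204 s, the July
duration regime of nocturnal churring.

`render_acceleration()` adds behavior-specific dynamic components to a
bounded random-walk static component (correlation time far above the 2-s
window, so running-mean subtraction removes it):

* **rest** — white noise with two per-interval sub-regimes, deep
  (0.004 g) and alert (0.012 g), mirroring the two inactive states of the
  five-state classification;
* **sing** — zero-mean noise at 0.05 g. The trill repetition rate of
  churring exceeds the 12.5 Hz Nyquist limit of 25 Hz sampling, so the tag
  records only the aliased/envelope energy of the vibration; rendering song
  as an explicit tone would let the HMM model the tone's phase structure
  with extra states, which no real tag signal supports;
* **fly** — a 6 Hz wingbeat sinusoid carrying 30% of the variance plus
  noise, effective sd 0.15 g;
* **leap** — white-noise bursts at 0.35 g.

These amplitudes are free parameters of the generator, not claims about real
nightjars (no per-behavior amplitudes in g are published); they were chosen
once to give the five-state model distinct, realistically ordered regimes
(σ_rest < σ_sing < σ_fly < σ_leap) and are exposed in the configuration.

`render_gps()` emits one fix per 180 s at the true position (interpolated
along the route during flight) displaced by an isotropic error with uniform
bearing and half-normal radial magnitude of scale 20/1.96 m — the stated
±20 m spatial error read as a 95% coverage radius, which tests verify by
Monte Carlo (≥ 93% of fixes within 20 m). `render_audio_truth()` emits one
annotation row per song bout of at least 10 s sung within 20 m of a
recorder, with ±1-s boundary jitter; a row whose jittered duration falls
below 10 s is dropped, matching the annotation convention. An optional miss
probability (default 0) emulates detection failure.

The default site geometry places one song post ~5 m from a recorder and all
other sites well beyond 20 m, so both distance classes of the validation are
exercised; GPS error makes occasional class flips near the threshold part of
the emulation (the published counts show the same phenomenon in the
> 20 m row).

### What the generator does *not* emulate

Wing-clapping and "bubbling" aerial display, multiple interfering
individuals, tag-angle shifts correlated with behavior (posture changes),
heteroscedastic or autocorrelated within-behavior noise, GPS fix dropouts,
and recorder failure (unless `audio_miss_prob` is raised). Passing tests
therefore show the pipeline is correct *given* the assumed amplitude-regime
structure; they do not show the regimes of real nightjar data are this
clean. The transition shoulders that the 2-s window produces around
high-amplitude bursts are, however, genuinely present and are handled by the
10-s song filter.

## Numerical choices

* Scaled (not log-space) forward–backward, with the per-step scaling
  constants accumulated into the log-likelihood; underflow raises an error
  rather than returning garbage.
* `sigma_floor = 1e-4` g clamps emission sds; a state whose posterior mass
  starves (< 1e-12) is re-seeded from a residual quantile with a warning.
* Viterbi ties break toward the lower state index; the per-second majority
  vote breaks ties by activity precedence (the more active behavior wins).
* Degenerate inputs error early with the offending file line or parameter
  named.

## Problem sizes used in the tests

The full default night is 9 h × 25 Hz = 810,000 samples; the pipeline fits
its training half in well under a minute and the acceptance script runs the
complete simulate→validate chain at that scale. Unit tests use a 45-min
night (67,500 samples) for end-to-end smoke checks and a 20-min excerpt
(30,000 samples) — chosen as the first window containing a healthy mix of
all four behaviors — for the parameter-recovery check, sizes at which the
fit is exact enough for the stated thresholds while keeping the suite fast.
Enumeration oracles (forward, Viterbi, assignment) run at K ≤ 3, T ≤ 12,
where exhaustive summation is feasible.

## Known limitations

* A single fitted night: the model is refit per deployment; no
  across-individual pooling or hierarchical structure.
* The fly/leap run-length heuristic can swap labels if a real dataset's
  flights are brief and its leaps sustained; supply an explicit map then.
* The 20-m gate uses one fix per bout (nearest the midpoint); birds that
  move during long bouts are classed by a single position.
* Aerial display components of song (terminal wing claps) register as
  flight, shortening classified bouts by a few seconds at the end — the
  synthetic generator does not model this, but the matched-duration
  statistics in the pipeline would expose it on real data.
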