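---
title: "Models and methods behind metawager"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metawager}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The task and what the package computes

`metawager` analyzes two-alternative visual discrimination data in which the
animal, after reporting the orientation of a noisy Gabor stimulus, wagers time
on its decision: a correct choice is rewarded with 70% probability after an
exponentially distributed delay (mean 8 s), and on unrewarded trials the
animal may abandon the wait and reinitiate. The time waited before
reinitiation is a graded, post-decision report of confidence. The package
provides the trial-table data model and filters, type-1 and type-2
signal-detection estimation (d′, criterion, meta-d′ and the efficiency ratio
meta-d′/d′), Win–Stay/Lose–Switch strategy scoring with a rule-based
repetition index for reversal learning, exponential learning-curve fitting,
and permutation inference — plus a simulator that generates trial tables with
the statistical structure all of these analyses assume, so that every stage
is testable without animal data.

# The simulated observer and wagering policy

Perception follows the equal-variance Gaussian signal-detection model. On a
trial with stimulus strength given by the (SNR, contrast) cell of the 3×3
design, evidence is drawn as

x ~ Normal(±d′/2, 1),

positive mean for a vertical stimulus, and the choice is the V-mapped
response iff x exceeds the criterion c (0 by default). Confidence is the
balance of evidence |x − c|, corrupted by Gaussian readout noise
(`confidence_noise_sd`, default 0.2 evidence units); the intended wait is

w = clamp(a + b·confidence + ε, 2 s, 40 s),

with Gaussian policy noise ε (`wait_noise_sd`, default 2.5 s). The 2 s floor
is the task's imposed minimum before reinitiation is possible; 40 s is the
trial cap. Reaction time decreases with evidence strength,
rt = max(0.05, r0 − r1·|x| + noise), and carries a rare slow lapse component
(probability 0.01, exponential with mean 8 s) representing disengaged trials;
this is what the session-level 3 SD reaction-time filter is designed to
remove (about 1% of trials under the defaults).

## Calibration of the sensitivity grid and the wagering line

The per-cell generating d′ values encode pooled accuracies of 0.69, 0.74 and
0.80 at SNR 2–4 via accuracy = Φ(d′/2), with a ±0.04 accuracy spread across
the 40/60/80% contrast levels (so accuracy rises with both stimulus
attributes and pooling over contrast reproduces the SNR targets exactly).

The intercept a and slope b of the wagering line are not free: they are
solved at construction time (`build_default_observer()`) so that, *after* the
wager-trial filter, (i) the mean waiting time on correct trials exceeds that
on incorrect trials by 4.74 s and (ii) the overall mean wager wait is 19 s.
The filter matters because reward delivery censors waits: a correct trial
goes unrewarded with probability 0.3 + 0.7·exp(−w/8), which decreases with
the intended wait, so retained correct trials are biased toward short waits.
The package computes the censored means by numerical quadrature over the
generative model (folded-Gaussian confidence densities on bin midpoints ×
a Gaussian noise grid, with the clamp and the censoring weight applied
exactly) and inverts the two conditions with `uniroot`. A 15 s mean — a
plausible first anchor for this task — cannot support a 4.74 s gap: under the
exponential censoring race and the [2, 40] s clamp the attainable gap peaks
near 2.8 s at that mean, which is why the default mean anchor is 19 s.

## Regional-inhibition manipulations

Chemogenetic inhibition is modeled purely as a shift of the wagering policy
(`manipulation_spec()`), never of perception or reaction time:

* ACC: the confidence slope is multiplied by 0 — waiting becomes insensitive
  to stimulus strength and accuracy — and the mean wager wait shifts by
  +3.45 s; confidence-readout noise also increases.
* BLA: the slope is preserved and the mean wager wait shifts by −4.59 s
  (delay aversion).
* Either inhibition scales the reversal learner's confidence deltas by 0,
  removing the confidence benefit on learning.

`wait_intercept_shift_s` is defined as the *realized* difference in mean
wager-trial waiting time relative to the unmanipulated observer;
`apply_manipulation()` solves the raw policy intercept with the same
quadrature, because naively shifting the intercept would confound the target
with the removed slope term (≈ b·E[confidence] ≈ 15 s under ACC) and with
arm-specific censoring bias (~0.5–1 s).

# The wagering race and the censoring structure

Per trial the simulator draws the reward schedule first (scheduled with
probability 0.7 on correct; exponential delay, untruncated), then an
independent decision to reinitiate at all (`reinit_prob`, default 0.3 —
yielding the realistic situation that most unrewarded trials simply time
out). A trial is rewarded iff a scheduled delay beats the horizon (the
intended wait for reinitiators, the 40 s cap otherwise); rewarded trials
carry no waiting time (censored), reinitiated trials carry w, and timeout
trials end at the cap with no recorded wait. This generates exactly the
selection structure the wager-trial filter (`select_wager_trials()`)
assumes: waiting times exist only on unrewarded, reinitiated trials.

# Type-2 estimation (meta-d′)

`compute_sdt()` estimates d′ and c with the log-linear correction applied
always (0.5 per cell, 1 per denominator): unconditional correction avoids the
discontinuity of correcting only empty cells. The signal convention is
V = signal; d′ is symmetric under the convention, c flips sign.

Waiting times of wager trials are quantile-binned into K = 4 ratings
(`bin_confidence()`; ties to the lower bin; K reduced with a warning when
there are too few distinct values). Four bins balance resolution against
cell occupancy for session-scale data, and the fit is invariant to any
order-preserving relabeling.

`fit_meta_d()` implements the equal-variance type-2 model: holding the
relative criterion c′ = c/d′ fixed, meta-d′ and the 2(K−1) ordered
response-conditional type-2 criteria maximize the multinomial likelihood of
ratings conditional on (stimulus, response). Criteria are parameterized as
log-gaps fanning out from the meta criterion, which enforces ordering
without constraints; every type-2 cell is padded by 1/(2K) before fitting;
the optimizer is Nelder–Mead at relative tolerance 1e-6 with a maximum of
1e4 evaluations and a restart polish, and the convergence flag is reported
honestly. The type-1 stage uses *all* trials while ratings exist only on
wager trials — `metacognitive_efficiency()` wires both in. Efficiency
meta-d′/d′ is reported only when d′ > 0.2 (`unstable` flag otherwise), and
no clamping to [0, 1] is applied: sampling noise can push the MLE above 1.

An ideal wagerer (no readout noise, no policy noise, no reward so nothing is
censored) attains efficiency 1 up to sampling noise, because quantile bins
of |x − c| are intervals of the evidence axis — exactly the model's ratings.
Under the default (noisy, censored) observer efficiency is below 1, and
under the ACC manipulation it collapses toward 0 since waits no longer carry
confidence.

# The reversal learner and strategy scoring

The reversal learner is deliberately *not* a reinforcement-learning value
model: it is a two-state Markov agent over the intended stimulus–response
rule (new/correct vs. old/incorrect), because the strategy statistics the
analyses estimate are then exactly its transition probabilities, giving
closed-form oracles. After a rewarded correct-rule trial it stays with
probability WS; after an unrewarded correct-rule trial it switches with
probability LSC; after an incorrect-rule trial (never rewarded) it switches
with probability LSI. The stationary probability of the correct rule is

p* = s / (s + u),  with u = 0.7(1 − WS) + 0.3·LSC and s = LSI,

and the relaxation factor is λ = 1 − u − s. In the high-confidence (HC)
condition additive deltas (ΔWS > 0, ΔLSC < 0, ΔLSI > 0) are applied.

## Why the defaults sit where they do

The HC condition must simultaneously show, in the first half of a session:
more Win–Stay, less Lose–Switch after correct, more Lose–Switch after
incorrect, a *larger* repetition index, and faster learning. At
stationarity this combination is impossible for the two-state chain: RRI =
2su(1 − s − u)/(s + u)², and the required delta signs reduce both the
balance term su/(s+u)² (when s > u) and 1 − s − u, so stationary ΔRRI is
negative whenever the other three signs hold. The combination is attainable
only in the transient window after the reversal, when the slow LC chain is
still escaping the old rule (first-half p(C) ≈ 0.36, so its chance
repetition rate is computed around an intermediate p(C)) while the HC chain
has reached ≈ 0.65. The defaults — LC (WS 0.994, LSC 0.006, LSI 0.012), HC
deltas (+0.004, −0.004, +0.020), start on the old rule with probability 0.9,
sessions of 160 trials — place the first-half window in that regime, with
the HC chain relaxing about twice as fast (time constants ≈ 29 vs 55
trials). Two knowing simplifications follow from the chain algebra: the HC
asymptote is necessarily higher than the LC asymptote (rats show matched
steady states), and the ΔRRI > 0 direction inverts for sessions much longer
than ~300 trials, where both chains approach stationarity.

`compute_strategy_profile()` scores consecutive within-session pairs only;
pairs containing a trial removed by the reaction-time filter are dropped
(adjacency by `trial_index`); conditioning sets with zero denominator yield
`NA`, never 0, with denominators reported. p(C) in the repetition index is
the block-level fraction of correct-rule trials. Note that short windows
make the conditional probabilities ratio estimators with O(1/n) bias — the
profile is a description of the window, and group comparisons use the same
window on both sides.

# Learning curves and the exponential fit

`sliding_window_accuracy()` pools sessions aligned on post-reversal index
and averages correctness over a 100-trial sliding window (the curve is
purely descriptive). The early/late comparison splits at floor(N/2) and
floor(3N/4) — first half vs. last quarter — and ratios are compared with the
Pearson chi-square on the 2×2 table, 1 df, no continuity correction.

The learning-rate fit uses the saturating exponential

P(C)_t = p_asym − (p_asym − p_start)·exp(−t/α),

with α (trials) the learning parameter, fitted by maximizing the Bernoulli
likelihood on raw trials rather than least squares on the smoothed curve
(window smoothing induces autocorrelation that least squares ignores). A
printed reciprocal form of this curve that exceeds 1 for all positive trial
counts cannot be a probability; `fit_form` records the implemented form.
Confidence intervals for α are percentile bootstrap over sessions. Flatness
is diagnosed by a 2-df likelihood-ratio criterion against the constant
model (plus coincident start/asymptote); a flat curve reports α = NA rather
than a number.

Parameter recovery has an information limit worth stating: at 20 sessions ×
800 trials the Cramér–Rao bound for α is 9–18% of its value across α ∈
{100, 200, 400} (widest at 400, where the asymptote is barely reached), so
no estimator recovers a single draw within 15% reliably. The package's
tests therefore assess recovery of the mean estimate over 12 replicate
cohorts at that problem size, the standard parameter-recovery design.

# Permutation inference

Condition labels (drug, confidence group) attach to whole sessions, so the
exchange unit is the session: per-session strategy measures are permuted
across groups, two-sided, with the +1 smoothing convention
p = (1 + #{|T*| ≥ |T|})/(n + 1) and ties counted as exceedances. With at
most 12 units and no more distinct reassignments than requested, the null is
enumerated exactly (with a notice), giving p = #{|T*| ≥ |T|}/M. Bonferroni
correction defaults to m = 4, the family of the four strategy measures
tested together, and is overridable.

# Filters and normalization

* Reaction-time outliers: trials deviating from the session mean by more
  than 3 session SDs are removed, with mean and SD computed once on the
  unfiltered session — a single pass, not re-iterated, which is the simplest
  reading of a session-level criterion. Applied per session (not per drug
  condition), since the disengagement it targets is session-local.
* Wager-trial selection: rewarded trials are excluded from all waiting-time
  analyses (their waits are censored); timeout trials carry no wait.
* `zscore_within_session()` standardizes within sessions using the
  population (1/n) SD, so {1, 2, 3} maps to ±1.2247; constant sessions
  yield zeros with a warning. Z-scoring is idempotent.

# Numerical choices

* Quadrature: confidence densities are evaluated on bin midpoints (0.02
  evidence units, up to 9) — midpoint placement matters, since including the
  folded boundary point at 0 makes the rectangle sum first-order biased —
  and the policy noise on a ±8 SD grid of 601 points; the censoring weight
  and the [2, 40] clamp enter the integrand exactly. Calibration roots are
  solved to 1e-5.
* Calibrated observers are cached per parameter set within a session.
* Per-session simulator streams are derived deterministically from the
  global seed and the session counter; identical seeds give identical
  tables.
* Optimizers: Nelder–Mead with restart polish everywhere a likelihood is
  maximized; the learning fit multi-starts over five initial time constants
  because the α-profile can be shallow.

# What the simulator does and does not emulate

It emulates: accuracy rising with SNR and contrast; waits rising with SNR
and with accuracy; reaction times falling with SNR; the 70%/8 s/40 s/2 s
reward and timing constants; the censoring structure of the wagering race;
reinitiation as a separate propensity; reversal learning driven by
stay/switch tendencies with a confidence benefit; and inhibition as
slope-flattening (ACC) vs. intercept-shifting (BLA) of the wagering policy.

It does not emulate: waits *increasing* with stimulus strength on incorrect
trials (in the balance-of-evidence model the incorrect-trial mean confidence
decreases with d′ — real animals in this task show the opposite, a known
point of divergence for confidence models; only the pooled increase is
reproduced); matched HC/LC steady states (see the learner section);
per-animal reinforcement histories that make equal-d′ stimulus cells differ
in wait (the HC/LC cell selection on simulated rats works off estimation
noise); drift-diffusion reaction-time structure; and any biophysics of the
inhibition itself. Passing tests on simulated data therefore validate the
estimators and the pipeline plumbing, not claims about animals.

# Problem sizes used by the test suite

Calibration checks run at 1e5 simulated trials per arm; ideal-observer
efficiency at 5e4 trials; noise-degradation curves average 20 seeds of 2e4
trials; strategy sign checks use 500–800 sessions of 160 trials per group;
type-I-error calibration uses 1000 null replicates at 999 permutations;
learning recovery uses 12 replicate cohorts of 20 × 800 trials. These sizes
keep every Monte-Carlo comparison at 3+ standard errors of resolution.
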