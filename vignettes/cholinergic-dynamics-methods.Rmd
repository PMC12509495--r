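---
title: "Methods: analysing septo-hippocampal cholinergic dynamics from fiber photometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing septo-hippocampal cholinergic dynamics from fiber photometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cholinepipe` implements an end-to-end analysis of dual-channel fiber
photometry recorded while mice perform an object location memory (ObLoM)
task: a 15 min *sample* phase with two identical objects in a 40 x 40 cm
arena, a delay, and a 15 min *test* phase in which one object (the
*nonstationary* object) has been moved to a novel location. The pipeline
covers

1. delta-F/F computation with an adjusted isosbestic control,
2. movement-speed coding of cholinergic activity across smoothing
   timescales,
3. the exponentially decaying session-start ("recency of environmental
   change") signal,
4. behavioral bout extraction, event-triggered averaging with linear time
   warping, and response-timing estimation,
5. nonparametric cluster-based permutation tests of observed versus
   speed-predicted activity, and
6. a frame-level linear mixed-effects model (LMM) with a novelty
   interaction contrast, sliding-window coefficients and an OLS meta-model.

Because raw in-vivo recordings of this kind are rarely deposited, the
package ships a first-class synthetic-session generator whose defaults
encode the study conditions. Every stage is validated against the
generator's known ground truth; the test suite's end-to-end blocks are
property-based (parameter recovery, test size and power) rather than
value-reproduction.

# The delta-F/F correction

The calcium-dependent 465 nm signal $s(t)$ and the isosbestic 405 nm
control $c(t)$ (both demodulated, sampled at 610 Hz) share photobleaching
and motion artifacts. The correction proceeds in three steps:

1. **Adjusted control.** Fit a second-degree polynomial in time to
   $s - c$ by least squares and add it back to $c$, giving
   $c_\mathrm{adj}$. Time is centered at the session midpoint purely for
   numerical conditioning; the fit is invariant to that choice.
2. **Scaling.** Find $\alpha, \beta$ minimizing
   $\sum_t \big(s - (\alpha\, c_\mathrm{adj} + \beta)\big)^2$. This is an
   ordinary least-squares problem with a unique closed-form minimizer
   ($\alpha = \mathrm{cov}(s, c_\mathrm{adj}) / \mathrm{var}(c_\mathrm{adj})$),
   so no iterative optimizer is used.
3. **Normalization.** $\Delta F/F = (s - f)/f$ with
   $f = \alpha\, c_\mathrm{adj} + \beta$, required to be strictly
   positive. (The defining expression is sometimes printed with ambiguous
   parenthesization; the standard reading $(s-f)/f$ is implemented.)

The fixed downstream order is: correction at the native rate, Fourier
resampling to the 30 Hz video clock, 0.5 s centered moving average,
per-session z-scoring. Each transform appends a tag to `stage_tags` so a
series' provenance is auditable. Whether z-scoring should be per session
or per phase is not externally determined; per session was chosen because
it matches the LMM's session-level random intercepts and keeps sessions
exchangeable.

**Resampling.** 610 Hz to 30 Hz is a non-integer ratio. The implementation
is Fourier interpolation with an endpoint-line detrend: the line through
the first and last samples is removed, the spectrum of the remainder is
truncated to the target length, and the line is evaluated analytically on
the new grid. The detrend makes the implicit periodic extension
value-continuous, so edge ringing — which would otherwise contaminate the
session start, exactly where the recency analysis lives — is negligible
(measured: a pure sinusoid below the target Nyquist is reconstructed with
relative RMS error below $4\times10^{-4}$ across the band, and the worst
edge error on a strong exponential trend is below $10^{-3}$ of its
amplitude). A rational-factor polyphase filter was considered and
rejected: its passband ripple and edge transients measured an order of
magnitude worse on the same checks.

**Moving average.** Centered boxcar with shrinking (truncated) windows at
the edges: the series keeps its length and the session start is not biased
by zero-padding. Interior samples equal the exact centered mean; the
series mean is not exactly preserved (the edges are reweighted), which is
the accepted cost of avoiding padding bias at $t = 0$.

## What the correction cannot do

Fitting a quadratic in time to $s - c$ removes whatever part of the
*signal* is representable by a quadratic over the session, along with the
bleaching mismatch it is meant to capture. For a 900 s session, about 40%
of the variance of an $e^{-t/28\,\mathrm{s}}$ session-start transient is
quadratic-representable, and any autocorrelated signal loses roughly
$2/n_\mathrm{eff}$ of its variance to the detrend ($n_\mathrm{eff}$ =
session length over the signal's correlation time). Consequently the
recovered delta-F/F is *not* a perfect copy of the latent activity even
with noiseless channels: on default synthetic sessions (session-start
amplitude 2 z, tau 28 s) the per-session correlation between recovered
delta-F/F and the latent truth plateaus around 0.88-0.98, and the
session-start amplitude is attenuated. The artifact-removal machinery
itself is clean — rendering the *same* latent truth with and without
bleaching and motion artifacts changes the recovered series by less than
0.5% in correlation terms — so the shortfall is a property of the
quadratic detrend interacting with slow signal, not an implementation
defect. The test suite asserts the artifact-invariance property; the
acceptance block that demands near-perfect truth tracking under the
default signal structure documents this ceiling honestly (it fails, and is
expected to).

# The synthetic-session generator

`generator_config()` holds the study conditions; `simulate_session()`
produces a trajectory, ethogram, latent activity and (optionally) raw
two-channel photometry from one seed. Stages derive deterministic
sub-seeds, so a seed fully determines a session.

**Behavior.** A semi-Markov chain over locomotion, grooming, rearing,
quiet and object-exploration episodes with shifted-exponential dwell times
(means 5-8 s, all > 2 s so duration-filtered bouts exist). Object
exploration is position-gated: episodes steer the animal to an object and
frames count as exploration only while the nose is within 10 cm of the
center; fast approach frames are labeled locomotion, which reproduces the
observed co-occurrence structure (exploration may overlap locomotion but
never grooming; `background` is on exactly when nothing else is). In the
test phase, exploration episodes during the first 3 min choose the
nonstationary object with probability $p/(p+1)$, `test_preference` $p = 3$
by default, giving first-window discrimination indices near 0.5 — the
scale reported for this task.

**Movement.** Speed relaxes (about 1 s) toward a state-conditioned
log-normal target with waypoint steering, inside arena bounds. A decaying
exploratory drive, $1 + 0.8\,e^{-t/45\,\mathrm{s}}$, multiplies both the
locomotion target speed and the probability of entering locomotion, so
movement speed is elevated at session start and decays over tens of
seconds — slower than the cholinergic recency term, reproducing the
dissociation the recency analysis tests. Nose position sits 3 cm ahead of
the neck along the heading (toward the object during exploration).

**Latent activity (z-units, video clock).**

$$z(t) = b_0 + \beta_v \log_2\!\big(\max(v, 1\,\mathrm{cm/s})\big)
  + \beta_g I_g + \beta_r I_r + a_N I_N + A e^{-t/\tau}
  + \eta_\mathrm{fast}(t) + \eta_\mathrm{slow}(t)$$

with defaults $\beta_v = 0.25$ z per log2(cm/s), $\beta_g = -0.75$
(grooming suppression), $\beta_r = +0.15$ (rearing elevation) — the
magnitudes a frame-level LMM reports for this preparation — novelty
amplitude $a_N = 0.5$ z on exploration bouts (both objects in the sample
phase, the nonstationary object only in the test phase), recency amplitude
$A = 2$ z with $\tau = 28$ s from the moment the animal is placed in the
arena, fast Ornstein-Uhlenbeck noise (sd 0.5 z, timescale 2 s) and a slow
speed-independent drift in tone (sd 0.6 z, timescale 150 s). Per-session
random deviations of the coefficients (intercept sd 0.2, speed slope sd
0.05, grooming sd 0.15, rearing sd 0.08, object effects sd 0.15) emulate
the between-session variability in expression level and responsiveness
that motivates mixed-effects modeling. Components are stored separately
and sum to `z_true` at machine precision. A positive `activity_lead`
shifts the structured components earlier in time — anticipatory
cholinergic activity before movement — used by the timing-estimator
recovery study.

The slow drift deserves a note: without it, nothing decorrelates activity
from log2 speed at long smoothing windows, the timescale-correlation curve
rises monotonically with window size, and no finite optimum exists —
unlike real recordings, whose curve peaks at a few seconds. Slow
state-dependent and instrumental variability is a documented property of
fiber photometry, so the drift is part of the default conditions.
Validation studies whose conditions were defined against the fast-OU-only
noise model (e.g. "noise sd = 0.5" recovery studies and "noise off"
identities) disable it explicitly.

**Forward model (photometry clock, 610 Hz).**

$$F_{465} = B(t)\,(1 + g\,z) + M(t) + \varepsilon_1, \qquad
  F_{405} = c_0 B(t) + M(t) + \varepsilon_2,$$

with $B(t)$ a double-exponential bleaching trend (time constants 60 s and
1000 s; the slow term dominant, as in recordings that begin after
equilibration), $g = 0.04$ fractional fluorescence per z-unit, $c_0 = 0.7$
isosbestic brightness, $M(t)$ shared negative biexponential motion
transients at 0.05 events/s, and i.i.d. measurement noise. The render
refuses gains that would drive $F_{465}$ nonpositive. With the signal,
motion and noise off, $F_{465}/F_{405}$ is constant — the artifact-only
channels are exactly proportional.

**What the generator does not emulate.** Indicator (GCaMP) kinetics are
collapsed into the OU timescale; pose-estimation jitter is a small
Gaussian; behavioral label noise, wall-supported versus unsupported
rearing, and video artifacts are absent. Passing tests therefore validate
the *analysis machinery* under the stated signal structure, not robustness
to everything real data can contain.

# Behavior module

Speed is the frame-to-frame Euclidean displacement of the neck marker
times the frame rate, with the first frame copying the second so the
series keeps its length at $t=0$. Generic exploration frames are relabeled
stationary/nonstationary by nose distance (ties — equidistant within both
radii — go to the stationary object, a deterministic choice that cannot
inflate novelty effects). The discrimination index is
$(t_\mathrm{non} - t_\mathrm{stat}) / (t_\mathrm{non} + t_\mathrm{stat})$;
windows without exploration yield missing values, never zeros. Sliding DI
windows are 3 min with a 30 s step (dense enough to trace the preference
decay, cheap to compute). The headline analysis uses the first 3 min of
test sessions against the first 12 min of sample sessions.

Bout extraction keeps maximal runs of at least 2 s and discards runs with
same-behavior activity within 4 s before onset or after offset; bout
boundaries are half-open frame intervals on the video clock, with no
sub-frame interpolation. The implementation is oracle-tested against an
exhaustive scan on random binary strings.

# Speed code and recency

`timescale_correlation()` smooths activity and log2 speed with each window
of a half-octave grid from 0.25 to 256 s and reports Pearson's r per
window. Near-zero speeds are floored at 1 cm/s before the log2 transform
(log2 = 0 at the floor), a configurable choice recorded in outputs. The
speed model is a per-session OLS regression of (smoothed, z-scored)
activity on smoothed log2 speed; its prediction is the speed-predicted
activity and its residual the speed-adjusted activity. Per-session fitting
matches the mixed model's random-slope philosophy.

Exponential decays $A e^{-t/\tau} + b$ are fitted over the first 180 s by
bounded Levenberg-Marquardt with multi-starts over
$\tau_0 \in \{5, 15, 30, 60, 120\}$ s and $\tau$ constrained to
$(0, 10 \times \text{window}]$ — the upper bound excludes the degenerate
$\tau \to \infty$ regime where the model collapses to a line. The offset
term is included by default (without it, baseline activity biases tau);
offset-free fitting is available for sensitivity checks. Near-constant
input is flagged degenerate rather than fitted. Decay time constants are
estimated on across-session average traces by default: single-session
estimates are dominated by slow noise and behavioral structure (measured
interquartile ranges near 20 s), whereas experiment-mean traces recover
the generating tau to within a few seconds.

# Event-triggered profiles and timing

Each bout contributes 5 s of pre-onset and post-offset signal at the
native 30 Hz plus a core linearly interpolated onto 100 evenly spaced
points (a uniform relative-time grid; 100 points resolve the shortest
2 s bouts at better than native resolution). Warping is exact for linear
signals and the identity when the core length matches the bout. Bouts too
close to the session edges are dropped and counted.

Response timing uses the threshold
$b + 0.98\,(d - b)$, with $b$ the mean over 5 s before onset (after offset
for the offset side) and $d$ the mean during the bout. All crossings in
the effect's direction within the search window (3 s before to 1 s after
the onset; 1 s before to 3 s after the offset) are located with linear
interpolation between straddling samples, and their median is the bout's
crossing time. The 0.98 fraction means "time of reaching the plateau";
it is configurable. Bouts that never cross are excluded and counted.
Observed and speed-predicted crossing times are compared per bout with a
Wilcoxon signed-rank test; fewer than 5 valid pairs flags the result
low-n.

# Cluster-based permutation tests

For paired event-by-time matrices (observed vs speed-predicted), a paired
t statistic is computed per time point; zero-variance columns yield t = 0
(conservative — no infinite-mass clusters from degenerate synthetic
input). Clusters are maximal contiguous runs beyond the two-sided
$\alpha = 0.05$ critical value, positive and negative runs separately,
scored by mass (sum of t) and length (seconds). The paired null shuffles
condition labels within an event — a sign flip of that event's difference
curve — and records the maximum |mass| and maximum length per permutation,
a single two-sided null for both cluster signs. Monte-Carlo p-values use
the plus-one rule $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n)$, which
guarantees valid size; ties at the observed value are counted with a tiny
numerical tolerance so the identity permutation is never lost to
floating-point noise. A cluster is significant when either the mass or the
length p-value is below 0.05 (the reporting convention for this test
family), and the relative length of significant clusters is reported as a
percentage of the tested span. Permutation budgets default to 500 for the
session-start comparison and 1,000 for bout comparisons. For warped bouts
the test runs over the core grid, with lengths converted to seconds via
the median bout duration. An exhaustive sign-flip mode replaces sampling
for small designs and is oracle-tested against independent enumeration.

# Mixed-effects layer

The frame table holds one row per 30 Hz frame: z-scored smoothed activity,
smoothed log2 speed, indicator columns for grooming, rearing and the two
object-exploration labels, treatment-coded task phase (sample = 0), and
mouse / task-repetition / session identifiers. The fixed-effects design is

```
dff_z ~ phase * (log2speed + exp_nonstat + exp_stat + rearing + grooming)
```

fitted by REML (lme4 backend; the module owns design construction, coding,
nesting and reporting). Random-effects structures follow a fallback
ladder — full random slopes with free covariance, diagonal-covariance
slopes by session, object-slopes-only, intercepts-only — trying the next
level on failure or non-convergence and recording the level used: a full
random-slope covariance (hundreds of coefficients on real-scale designs)
is not estimable at desk scale. Inference uses residual degrees of freedom
(observations minus fixed-effect count); small-sample corrections such as
Satterthwaite are out of scope.

The novelty contrast is $c^\top\hat\beta$ with $+1$ on phase x
exploring-nonstationary and $-1$ on phase x exploring-stationary, tested
as a Wald F with 1 and residual degrees of freedom. Sliding-window fits
(3 min windows, 60 s step — 13 windows over 15 min, so 26
phase-by-window coefficient differences) keep windows with at least 1 s
of exploration per object term, refit the model per window (random
effects are not shared with the global fit), and feed the OLS meta-model
`(exp_nonstat - exp_stat) ~ phase * window`. For desk-scale recovery and
calibration studies, frames may be thinned (e.g. every 6th frame) — the
fast OU noise decorrelates within a few seconds, so thinning sacrifices
little information while keeping the naive likelihood's independence
assumption and the runtime honest.

# Validation design and problem sizes

The end-to-end acceptance blocks run on synthetic data at these sizes
(chosen as the package's desk-scale study conditions):

- **Correction identifiability:** 20 rendered 900 s sessions, noise off.
  Documents the quadratic-detrend ceiling discussed above; the
  strict > 0.99-per-session bound fails by design of the correction, and
  the artifact-invariance property is asserted separately in the unit
  suite.
- **Speed-code recovery:** 20 replicates under a speed-only condition
  (behavior, novelty and recency terms zeroed — with them on, the simple
  regression is deliberately misspecified, which is precisely the
  motivation for the LMM). Per-session slopes use Newey-West standard
  errors (8 s bandwidth) against the autocorrelated noise; the LMM arm
  fits thinned frames. Both recover 0.25 within 2 SE in at least 90% of
  replicates.
- **Timescale curve:** 20 replicates of 12-session experiments at full
  defaults; the argmax of the experiment-mean curve falls within one
  octave of 2 s — the experiment-mean curve is what that optimum is
  defined on.
- **Cluster test:** family-wise error at most 0.07 over 200 null bout
  sets (observed = predicted + i.i.d. noise) at alpha = 0.05 with 1,000
  permutations, and the grooming suppression cluster detected in at
  least 80% of 50 twenty-session experiments at defaults.
- **Recency recovery:** 20 replicates of 12-session experiments
  (OU-only noise model), decay fitted on the mean speed-adjusted
  residual: tau within 15% of 28 s in at least 80%, and the
  observed-vs-predicted cluster divergence starts before 5 s.
- **Timing estimator:** +1.1 s injected activity lead recovered within
  0.3 s (pooled bout-level median over 20 sessions); the linear-ramp
  crossing matches its closed form to 1e-6 s.
- **Novelty contrast:** 50 replicates of 20-session experiments;
  phase-dependent transients give a positive, significant contrast in at
  least 80%, and symmetric transients stay at or below 10% false
  positives (object-slopes random effects carry the honest
  between-session variance).

# Known limitations

- The quadratic detrend attenuates slow signal components; session-start
  amplitudes and time constants estimated after the correction are
  systematically shrunk relative to the latent truth (see above).
- Residual-df inference in the LMM ignores within-session
  autocorrelation; calibrated significance for bout-level contrasts
  comes from the random-slope structure (and, in validation studies,
  from thinning), not from the nominal frame count.
- The motion-artifact model (shared, additive, biexponential) is a
  stand-in; its parameters are configuration, not claims about any
  particular rig.
- Sliding-window LMM refits are independent across windows; coefficients
  from neighboring windows share data and are not independent
  observations in the meta-model, which treats them as such (as does the
  reporting convention it mirrors).
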