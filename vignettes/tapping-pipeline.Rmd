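---
title: "From force traces to group inference: the tapsync methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From force traces to group inference: the tapsync methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapsync)
```

`tapsync` analyses paced finger tapping to isochronous metronomes in a
two-group (cochlear-implant users, CI, vs hearing controls, HC), four-condition
design: auditory-only (A), visual-only (V), synchronous audiovisual (AVsync)
and asynchronous audiovisual (AVasync). This vignette is the package's own
account of the models and the decisions behind them.

## The task geometry

Metronomes run at 2.4 Hz (inter-stimulus interval, ISI = 416.7 ms) for 39.5 s,
giving 95 onsets per trial; the asynchronous visual stream runs at 2.6 Hz.
Participants tap once every *two* beats starting on the third, so the
instructed tap period is one "beat" of P = 2 × ISI = 833.3 ms and a trial
yields about 47 taps. All scoring lives on the circle of that period: a tap at
time t maps to the angle θ = 2π·(t − nearest anchor)/P, wrapped to (−π, π],
where the anchors are the odd- or even-indexed stimuli (whichever the
participant actually locked to). Negative angles mean anticipation, the usual
finding in paced tapping, and the generator's default mean phase is −0.3 rad
(≈ −40 ms) for that reason.

Per-trial consistency is the mean resultant length R of those angles;
direction (accuracy) is computed and reported but not analysed further.
Because R is bounded, trial values are logit-transformed before linear
modelling, with R clamped to [ε, 1 − ε], ε = 10⁻⁶: a perfectly consistent
trial (R = 1, which noise-free simulations do produce) maps to logit
13.82 rather than infinity. Chance-level tapping is flagged by the Rayleigh
test, p ≈ exp(√(1 + 4n + 4(n² − Zn)) − (1 + 2n)) with Z = nR²; at the
median scored tap count of the default study (~35) the p = .05 boundary sits
near logit −0.9, which is why consistency values below about −0.9 can be read
as chance performance.

## Cleaning rules and their parameters

The cleaning pipeline runs in a fixed order; each step conserves events by
moving discards (with a reason code) rather than deleting them.

* **Dropout guard.** The recording hardware produced a single 1.46 s signal
  dropout at a variable position in most trials. The first crossing after the
  trace resumes is unreliable, so any tap in the half-open window
  [dropout_end, dropout_end + w) is discarded, w = 0.75 × instructed tap
  period = 625 ms at the study parameters. The half-open boundary is a
  determinism choice; a tap exactly at dropout_end + w is kept.
* **Double-tap suppression** replaces manual inspection with a reproducible
  150 ms refractory rule (well under half the shortest plausible instructed
  interval, 2/2.6 Hz ≈ 769 ms): scanning left to right, a tap closer than the
  refractory period to the last *kept* tap is discarded, so bursts collapse
  to their first contact.
* **Interval-multiple detection.** The trial's median inter-tap interval is
  classified to the nearest of {1, 2, 3} × ISI; ties break to the smaller
  multiple. Trials at 1× or 3× are excluded (`wrong_rate`) — participants
  occasionally tapped every or every third stimulus. The median is what makes
  this robust: even at near-chance concentration the *count* of taps per
  period is preserved, so the median interval still sits near the true
  multiple unless phase noise spans whole beats (at which point "rate" is no
  longer meaningful; the guarantee is stated for jitter ≤ 40 ms).
* **Phase (parity) detection.** Tappers instructed to start on beat 3 (odd
  stimuli) often settle on the even ones. Both candidate anchor trains and
  the tap train are smoothed with a Gaussian (sd 50 ms on a 1 ms grid —
  narrow enough that adjacent stimuli 417 ms apart do not blur together, wide
  enough to tolerate tens of ms of jitter) and the parity with the larger
  Pearson correlation wins; exact ties fall back to odd with a warning. The
  series are used raw (not mean-centred): Pearson correlation is
  location-invariant, so centring would not change the decision.
* **Initial trim.** The first 5 taps are discarded as pre-stabilization.
* **Pause pruning.** Inter-tap intervals above Q3 + 3·IQR (type-7 quantiles,
  the interpolation convention that R's `quantile()` defaults to — fixed
  because it moves the threshold) mark pauses; the tap *terminating* each
  outlier interval is discarded. A single pass is made; the threshold is not
  recomputed after removal. A 1 ns guard on the comparison keeps equal
  intervals (IQR = 0) from being flagged through floating-point rounding.
* **Usability.** Trials with fewer than 8 scored taps are flagged rather
  than scored; 8 is a pragmatic floor below which R and the Rayleigh test
  are too unstable to interpret.

## The generative model

The synthetic tapper is the package's testing substrate and defines the
study conditions it emulates. Tap times are anchor times plus von Mises
phase noise of concentration κ — the circular analogue of Gaussian noise,
chosen because it is standard for tapping phase data and gives the
closed-form population consistency R = A(κ) = I₁(κ)/I₀(κ), so every scored
quantity has an oracle. κ = 0 is uniform (chance) tapping; κ = ∞ is the
noise-free limit, implemented exactly.

Defaults are anchored on the observed performance levels of this paradigm:
the per-cell mean logit consistencies (`default_cell_logits()`: e.g. HC
auditory 2.64, HC visual −1.22, CI auditory 1.38, CI asynchronous −1.72) are
inverted through the logit and A(κ) to per-cell concentrations. Participant
heterogeneity enters as lognormal multipliers on κ: one shared across
conditions (sd 0.8 on log κ, giving a between-participant logit spread of
roughly 1–1.5, comparable to the observed cell SDs) and one per
participant × condition cell (sd 0.4), which is what gives the random
condition slopes in the mixed model something real to absorb. Two caveats
follow: the *means* of scored cells sit somewhat above the planted logits
(finite-sample upward bias of R, plus Jensen effects of the lognormal
heterogeneity — visible mainly in the low-consistency cells), and the
near-floor AVasync cell shows more spread than real data, where the floor
compresses variance. Artifact rates: wrong-rate lapses per trial at the
observed exclusion rates (CI 88/800 = 11%, HC 45/680 ≈ 6.6%, split evenly
between 1× and 3×), 30% of trials locking to the even parity, 2% per-tap
pause onset (pause length 3.5 s, over four tap periods, so a pause always
trips the quartile rule), 2% double taps (50 ms bounce), 2% misses, and a
1.46 s dropout in 90% of trials, uniformly placed after the first three
beats. In the audiovisual conditions the simulated tapper follows the
*visual* stream — the congruence/interference questions are framed against
the visual-only baseline — and this is a configurable interpretation, since
the task instructions do not pin down the target stream in the asynchronous
case.

Force traces render each tap as an impact-like pulse (instant attack,
quarter-cosine decay over 40 ms): a fingertip strike loads the sensor within
one sample, which is what lets threshold detection recover onsets to within
one sample period. Dropouts hold the last pre-dropout sample. The default
detection threshold (midway between the baseline median and the trace
maximum) is a documented stand-in: the original recordings' trigger level
was not archived. For efficiency, the full study generator applies the
dropout at the event level (taps inside the window are lost, the dropout end
is kept for the guard) rather than rendering 58 million force samples; the
trace path is exercised by its own round-trip tests.

## Inference

Trial-level logit consistencies enter
`logit_R ~ group × condition + (1 + condition | participant)` with both
factors sum-to-zero coded — trial-level because the random condition slope
is only identified with replicates within participant × condition. Omnibus
type-III Wald F tests use Kenward-Roger denominator df by default;
Satterthwaite is offered (and used in the package's own simulation studies)
because Kenward-Roger costs seconds per fit against milliseconds, with
negligible difference at these sample sizes. If the full 4 × 4 slope
covariance fails to converge the model downgrades to uncorrelated slopes,
then to a random intercept, each step recorded in the fit object; a
*singular* fit, by contrast, is retained with a flag — boundary estimates
are routine for this structure and refitting a simpler model would quietly
change the testing target.

Eleven planned contrasts on the estimated marginal means compare the groups
within the unisensory conditions, the auditory advantage (A − V) within and
between groups, and the congruence (AVsync − V) and interference
(AVasync − V) effects within and between groups. The Bonferroni family size
is fixed at 11 and asserted against the contrast list, and
p_adj = min(1, 11·p). Clinical regressions are ordinary least squares on
per-participant condition means within the CI group (means, because one
clinical value per participant leaves n = 20 and df = n − 2 = 18), with
pre-linguistic deafness onset coded as 2 years.

## Numerical and design notes

* Angles wrap to (−π, π] with the boundary mapping to +π; a tap equidistant
  between anchors gets +π deterministically.
* `wrap_angle`, the tie conventions (interval multiple to the smaller m,
  parity ties to odd) and the half-open guard window are all chosen so that
  reruns are bit-identical; every generator and pipeline entry point takes a
  seed, and the same seed reproduces event tables byte-for-byte.
* The von Mises sampler is the Best-Fisher rejection method; `bessel_ratio()`
  uses exponentially scaled Bessel functions so large κ cannot overflow, and
  `kappa_from_R()` inverts it by bisection to 10⁻¹⁰.
* The mean resultant length of n angles is upward-biased for finite n
  (E[R²] = ρ² + (1 − ρ²)/n): at κ = 0.5 and n = 40 the bias is ≈ +0.03.
  Calibration checks against the asymptotic A(κ) are therefore expected to
  resolve that bias at low κ once the Monte-Carlo error falls below it; the
  test suite carries a companion check against a finite-n Monte-Carlo oracle
  that isolates exactly this effect.
* Simulation studies in the tests use the trial-level score generator
  (`simulate_score_table()`), which draws phases directly and skips event
  cleaning: the quantity under calibration there is the inference stage, and
  this keeps 500-replicate studies at the full design size (20 + 17
  participants, 10 trials/condition) tractable on one core.

## Limitations

The generator makes no attempt to model tempo drift, error correction
dynamics (taps are conditionally independent given κ), force amplitudes, or
any perceptual model of implant hearing; pauses have fixed length; and the
clinical covariates attach to synthetic outcomes, so clinical regressions in
synthetic runs demonstrate machinery (coding rules, df, slope recovery), not
clinical findings. Passing tests show the pipeline recovers what the
generative model plants at the study's scale — they cannot show that real
tapping data satisfy the model's assumptions.
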