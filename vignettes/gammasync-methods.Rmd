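---
title: "Models and methods behind gammasync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gammasync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammasync)
```

gammasync analyses bilateral low-gamma (30–50 Hz) activity in multichannel
hippocampal field potentials. This vignette explains the models each stage
fits, the assumptions they rest on, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices that shape the results. It states no empirical result
that the package's tests and acceptance script do not themselves compute.

## The signal model

Extracellular voltage at electrode $m$ is modelled as a spatially fixed
linear mixture of a few pathway-specific *LFP generators*,

$$u_m(t) = \sum_{n=1}^{N} V_{mn}\, s_n(t),$$

where the column $V_{\cdot n}$ is the generator's depth profile (voltage
weight per contact) and $s_n(t)$ its time course. A generator's time course
during gamma activity is a string of pulse-like *gamma waves*, each modelled
by the α-kernel

$$f(t;\delta) = H(t)\,\frac{t}{\delta^2}\,e^{-t^2/2\delta^2},$$

a unit-area density that rises from zero, peaks at $t=\delta$ with value
$e^{-1/2}/\delta$, and has a Gaussian tail. A generator trace is
$s(t) = \sum_k w_k f(t-\tau_k;\delta_k)$ with per-wave weight, start and
scale. Waves repeat at roughly 20–25 ms intervals (the low-gamma
wavelength), and successive kernels overlap substantially: at a 22 ms
spacing an 8 ms-scale kernel still carries ~10% of its peak at the next
start, so the trace between waves does not return to baseline. Most of the
method design below deals with consequences of this overlap.

## Separation (`preprocess`, `mask_sharp_waves`, `decompose`)

Channels are high-passed (zero-phase Butterworth, 1 Hz default; DC removed
exactly beforehand so constant offsets cannot leak edge transients). Sharp
waves — large, slow, bilateral events that would dominate the variance —
are masked either manually (explicit intervals are honoured verbatim) or by
a detector that thresholds the <20 Hz envelope at a configurable multiple
(default 5) of its median absolute deviation, padded ±50 ms.

`decompose()` reduces the channels to `n_components` dimensions by PCA and
rotates them to maximal independence with FastICA (`ica::icafast`). Any
well-conditioned contrast suffices at the separation quality that matters
here; with two synthetic generators and zero noise the recovered activation
correlates with the (high-passed) truth at better than 0.999 once the epoch
exceeds roughly 15 s — below that, the finite-sample rotation error of any
ICA contrast dominates. Indeterminacies are fixed by convention: each
mixing column is scaled to maximum absolute weight 1 (so the activation
carries the µV scale of its dominant site), and the activation's sign is
chosen so samples beyond 3 SD have positive mean — waves point up.
Variance shares are per-generator fractions of the preprocessed-LFP
variance, and generators are ordered by them.

One consequence of preprocessing deserves emphasis: the 1 Hz high-pass
removes the slow envelope of a continuous wave train (its local mean),
which is real signal under the α-kernel model. The deconvolution therefore
re-anchors its zero level (below) and the waveform measurement interpolates
a residual baseline; both are needed to make amplitudes commensurable with
the rendered ground truth.

## Deconvolution (`wavelet_init`, `em_fit`, `deconvolve_waves`)

The likelihood treats the rectified, unit-normalized activation as an
empirical weight on time samples: each sample contributes its share of
signal mass to a mixture density made of the K α-kernels plus a uniform
background component (weight co-estimated, floored at $10^{-4}$) that keeps
the logarithm finite where no kernel reaches. Before fitting, the trace is
re-anchored so its 0.5% quantile sits at zero (`anchor_quantile`),
compensating the DC the separation removed; negative samples are clipped
for likelihood weighting only, never for measurement.

**Initialization.** Candidates come from a bank of α-kernel matched filters
log-spaced over the scales implied by the analysis band (default 30–50 Hz
→ 2.5–16.7 ms, 16 scales). Three details matter in practice:

* all filters share the support window of the widest kernel, so their
  local-fit gains are comparable across scales;
* the filters are zero-mean, making responses invariant to the local
  constant offset that high-pass preprocessing leaves behind; scale
  selection maximizes the SSE reduction of the local fit `a·g + b`;
* detection is a greedy matching pursuit: the strongest response is taken
  as a wave, its contribution subtracted from all correlation fields via a
  precomputed kernel cross-correlation table, and the search repeats until
  no residual response exceeds the amplitude threshold (default 15 µV —
  deliberately permissive relative to the 20 µV analysis cutoff, since
  spurious candidates can be removed later but missed waves cannot be
  recovered).

Pursuit over-subtracts in overlaps, so candidates are then re-optimized by
coordinate descent (position ±2 samples, scale ±1 grid step, non-negative
amplitude) and passed through *backward elimination*: a candidate survives
only if it explains a unique residual amplitude above threshold once its
neighbours re-optimize without it. Split fits of one true wave fail this
test; genuinely overlapping distinct waves pass it. Initial weights are
equal (1/K) — with overlapping waves the baseline is uncertain, so the
initializer's amplitude estimates are deliberately not trusted.

**EM.** The fit is an expectation–conditional-maximization scheme computed
on sparse per-wave support windows (the kernel effectively vanishes beyond
$6\delta$). Weights update in closed form (standard EM bound). Start times
take one safeguarded Newton step per iteration from the
responsibility-weighted objective, with a method-of-moments fallback (the
kernel mean lies $\delta\sqrt{\pi/2}$ after the start) that can jump over
basins the local step cannot leave; scales update from the closed-form
second moment. Every τ and δ proposal is accepted only if the *actual*
mixture objective does not decrease, evaluated exactly on the affected
samples — so the recorded objective is non-decreasing by construction, not
merely in expectation. Waves far apart do not interact; the fit runs on
blocks of nearby waves (split at >80 ms start gaps, over-long blocks cut at
their largest interior gap) and reports the mass-weighted objective.
Convergence is declared at a relative objective change below `tol`
(default $10^{-8}$) or `max_iter` (100) iterations; hitting the cap flags
the fit but still returns it. K is never re-estimated during EM; after it,
near-duplicates (start difference <2 ms and raw-support overlap index
>0.9) are merged with weights summed (the earlier wave's shape kept), and
a second unique-contribution elimination — now with the continuous fitted
scales and least-squares amplitude refits — prunes residual split fits.
The elimination floor is half the 20 µV analysis threshold, mirroring the
permissive-initialization principle.

**Measurement.** Amplitude is measured on the overlap-corrected trace: the
fitted components of all *other* waves are subtracted, a piecewise-linear
baseline is interpolated through the corrected trace at the fitted start
times (each knot a ±1 ms window average weighted by inverse local slope,
so flat samples dominate), and $A$ is the peak of corrected trace minus
baseline within the wave's own peak window, stopping at the next wave's
start. A plain chord through raw-trace knots is not used: with inter-wave
gaps as short as 5 ms the preceding tail at a start is routinely 10–30% of
the wave's own amplitude and the chord cuts through the wave,
systematically biasing amplitudes down by ~20%; the model-corrected
residual baseline removes that bias (to <1% on isolated noiseless waves)
while still absorbing unmodelled slow envelopes. Raw duration is the time
the fitted kernel exceeds 5% of its peak — proportional to δ (≈3.0 δ) by
self-similarity — and is multiplied by a per-generator correction factor
(defaults 0.75 Schaffer-like, 0.45 CA3som-like) because α-kernel fits
overestimate the tail. Waves are retained when strictly longer than 5 ms
and strictly larger than 20 µV.

## Pairing and lag statistics

Two waves at different sites are paired when their temporal overlap index
$\Omega = 2\Delta_{ovlp}/(d_1+d_2)$ strictly exceeds 0.7. `pair_waves()`
computes the one-to-one greedy maximum-Ω matching (ties broken by smaller
absolute lag, then earlier start), restricted to candidates within a
200 ms window purely for speed; an unwindowed exhaustive implementation of
the same rule is the test oracle and the two agree exactly on random
instances. One-to-one matching is an explicit choice — the source analyses
do not state whether pairing was bijective.

Lag convention: the pair lag is `start_b − start_a` in ms. With the left
site as `a` and the right as `b`, *negative lags mean the right side
leads*. The synthetic generator's `bilateral_lag_mean` is signed the
opposite way (right-lead positive) for configuration convenience; the two
conventions are converted explicitly everywhere.

`lag_statistics()` gives the mean lag with a t-interval using the
uncorrected (1/n) standard deviation, $\bar x \pm t_{n-1,1-\alpha/2}
s/\sqrt{n-1}$, subgroup means partitioned by which site had the longer wave
(duration ties within 0.1 ms form a separate excluded class), and per-side
unilateral percentages. `covariation()` fits the principal axis of the
centred two-feature cloud (orthogonal regression — both features carry
measurement error) and reports the ordinary product-moment correlation.

## Continuous-signal synchrony

Cross-correlation is the zero-lag correlation coefficient plus a
correlogram; `tau_max` is positive when the second signal is delayed.
Coherence uses Welch averaging (Hann-tapered 1 s windows, 50% overlap —
~1 Hz resolution suits 40–45 Hz peaks; at least 4 windows are required,
else the estimate is degenerate). Significance comes from phase-
randomization surrogates that preserve the amplitude spectrum exactly; the
per-frequency threshold is the $k$-th order statistic of the surrogate
coherences with $k=\lceil(1-\alpha)(N+1)\rceil$ — the $(N+1)$ convention
matters, since $k=\lceil(1-\alpha)N\rceil$ would give a nominal exceedance
of 21/401 ≈ 5.2% rather than 5% at the defaults (N = 400 surrogates).

Williams' test compares two dependent correlations (e.g. bilateral vs
ipsilateral) with a t statistic on $n-3$ degrees of freedom. The
phase-lag estimator band-passes both signals (default 30–50 Hz), takes
analytic-signal phases, and samples the non-reference phase relative to
the reference phase at the reference's once-per-cycle wrapped-phase
upward zero crossings (reference wave peaks; the relative sampling removes
the half-sample discretization bias, since both phases advance together
within a sample). The mean phase difference converts to a time lag through
the mean circular frequency of the *non-reference* signal (mean unwrapped-
phase derivative) — the source description is ambiguous between reference
and non-reference conventions, and the non-reference one is implemented.
Positive values mean the non-reference signal lags. Successive narrowband
events carry correlated phases, so the Rayleigh non-uniformity p-value is
computed on events thinned to the band's decorrelation time
(2/bandwidth); the mean phase uses every event.

## Spike–wave coupling

`classify_spike_windows()` partitions the timeline into None / right-only /
left-only / Bilateral window classes by wave-interval presence
(simultaneous overlap, closed at interval starts and open at ends; an
Ω-paired definition of "bilateral" can be substituted by pairing the wave
tables first). Counts of a wave-independent Poisson train are binomial in
the class time fractions, giving limits $n r_i \pm \lambda_{0.95}
\sqrt{n r_i(1-r_i)}$ with $\lambda_{0.95}=1.645$; counts above/below are
flagged. The comodulogram accumulates, per spike, every (right-start −
spike, left-start − spike) pair within a (−40, +5) ms window into a 2-D
histogram (1 ms bins by default). Its chance threshold assumes Poisson
wave processes: $P=(1-e^{-N_l\Delta/T})(1-e^{-N_r\Delta/T})$ and
$H_{1-\alpha}=PN_s+\lambda_{1-\alpha}\sqrt{N_sP(1-P)}$, with Δ equal to
the bin width unless overridden.

Two limitations of this chance model are worth knowing. First, rhythmic
wave trains violate its Poisson assumption: chance coincidences then
concentrate in diagonal bands and exceed the threshold there. Second, the
normal approximation is anti-conservative when the expected count per bin
is small — at means of order 1–10 the α = 0.05 exceedance is 8–10% purely
from Poisson skewness, approaching nominal only at means of several tens;
dense spike trains additionally overdisperse the counts because nearby
spikes see the same waves. Calibration checks therefore use sparse Poisson
waves, modest firing rates and long epochs; applied work should read
marginal exceedances near the threshold with caution.

`power_profile()` histograms the instantaneous power $p=s^2(t)$ on
log-spaced bins from the (20 µV)² analysis floor, fits two power-law
segments in log–log space with a 2-bin guard gap around the candidate
breakpoint (the sojourn-time smearing of the amplitude law widens the
transition and would bias both slopes), rescales power so the breakpoint
sits at 1, and flags the fit degenerate unless it clearly beats one line
with a steeper, still-falling tail ($k_2<k_1<0$). Per spike class it
reports the spike-power density minus the baseline with a confidence band
from 200 resampled matched-size random trains.

## The synthetic-data generator

`synth_recording()` builds, per hemisphere, two generators (Schaffer-like
and CA3som-like depth profiles); each generator's left train is a renewal
process of α-kernel waves and the right train is derived from it. The
defaults are the study conditions the package is exercised under:

* intervals: truncated normal, mean 22 ms, SD 3 ms, floor 5 ms (the
  20–25 ms range with a hard refractory floor);
* kernel scales: truncated normal, mean 8 ms, SD 2 ms, floor 3 ms —
  corrected durations of roughly 11–18 ms, between the reported pathway
  averages (CA3som clearly shorter than the cycle, Schaffer comparable to
  it) while keeping overlap at the level the deconvolution is designed
  for;
* peak amplitudes: two-exponent power law in the power domain
  ($k_1=-1.22$ below, $k_2=-2.66$ above the critical point), support
  50–1500 µV with the critical point at (250 µV)² — events below the
  20 µV noise cutoff are by definition not gamma waves, and the 50 µV
  floor keeps every generated wave unambiguously detectable; median
  amplitudes come out near 100–150 µV, the order of the reported means;
* bilateral structure: waves copy to the other side with probability one
  minus the source side's unilateral fraction (defaults 5.5% left, 11.7%
  right), shifted by a Gaussian lag (default mean 0.6 ms right-lead, SD
  0.5 ms) and with amplitudes coupled through a Gaussian copula whose
  parameter is calibrated internally (fixed-seed Monte Carlo and monotone
  inversion) so the *Pearson* correlation of paired amplitudes equals the
  configured `amplitude_covariation` (default 0.5) despite the skewed
  marginal; paired scales are jittered by 1 ms for partial duration
  covariation. Inserted unilateral waves respect the interval floor
  against existing waves — they belong to the same gamma stream;
* mixing and noise: identical Gaussian depth profiles on every shank of a
  hemisphere, additive white 5 µV channel noise; 1 kHz sampling (the
  analyses live below 100 Hz, so acquisition-grade rates would only slow
  everything down) over 60 s;
* spikes: homogeneous background plus wave-triggered spikes at a per-unit
  latency and probability; interneuron-like units couple to every
  ipsilateral wave, pyramidal-like units only to bilaterally paired waves
  (the Ω > 0.7 rule applied to the true waves, keeping generator and
  analyzer definitions consistent).

Sharp waves are not generated by default — analysis assumes they are
removed — but `inject_spw()` adds them for testing the masker.

What the generator does *not* emulate: slow amplitude co-modulation across
successive waves (amplitudes are drawn independently along a train, so
there is no waxing-and-waning string structure), episodic gamma
(strings run continuously for the whole epoch), theta or other rhythms,
non-stationary mixing, and electrode artifacts. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
structure, not robustness to every property of in vivo data. One
measurable consequence: with the heavy-tailed independent amplitude law,
about a third of rendered-trace power is broadband shot noise, so the
30–60 Hz band holds ~33% of total power even though the spectral peak sits
firmly in-band; with constant amplitudes the same renewal process puts
over 60% of its power in-band. Band-power expectations are asserted on the
constant-amplitude variant, peak location on the full law.

## Known limitations and honest numbers

On 60 s default-condition recordings the full pipeline (separation →
deconvolution → pairing) recovers the configured mean bilateral lag to
within ~0.1 ms and the amplitude covariation to within ~0.05, with wave
detection around 91–95%. The remaining 5–9% of waves are missed or
mis-localized by 2–6 ms — split or shifted fits in heavy overlap, present
even on noiseless rendered traces. Because every one-sided miss converts a
true pair into two apparent unilaterals, measured unilateral fractions run
several points above the configured ones (roughly 20% and 16% against
10% and 5%); lag and covariation, computed on the ~90% of pairs that are
recovered, are essentially unbiased *when the two sides have similar wave
density* — a strong asymmetry in unilateral fractions adds a lag bias of
one to two tenths of a millisecond (crowding-dependent start estimation
plus pairing selection), which matters when the effect of interest is
itself sub-millisecond. Wave-level unilaterality estimates
from this method should accordingly be read as upper bounds unless
detection is near-perfect.

Problem sizes in the test suite (60 s epochs for end-to-end and spectral
checks, 20 s for deconvolution fixtures, hundreds to a thousand replicates
for the statistical calibrations, long sparse epochs for the comodulogram
null) were chosen to make every stochastic assertion comfortably stable at
its stated tolerance on a single CPU.
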