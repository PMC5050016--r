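# gammasync

Bilateral gamma-wave analysis for multichannel hippocampal local field
potentials (LFPs).

During irregular activity, the CA3 region of each hippocampus emits its
Schaffer-collateral output to CA1 as strings of pulse-like **gamma waves**
repeating every 20–25 ms (low gamma, 30–50 Hz). Comparing these waves
between hemispheres — which side leads, by how much, how strongly paired
waves covary, how often a wave appears on one side only, and how spikes of
CA1 neurons relate to unilateral versus bilateral waves — requires a chain
of non-trivial steps that this package implements as a tested, reusable
pipeline for electrophysiologists:

1. **Separation** — multichannel LFPs are decomposed into pathway-specific
   *LFP generators* under the linear mixing model
   `u_m(t) = Σ_n V_mn s_n(t)` (PCA reduction + FastICA rotation, with
   1 Hz zero-phase high-pass and sharp-wave masking).
2. **Deconvolution** — each generator time course is split into individual
   gamma waves modelled as α-kernels
   `f(t; δ) = H(t) (t/δ²) exp(−t²/2δ²)`, by matched-filter matching
   pursuit followed by expectation–maximization on the mixture likelihood
   `L = Σ_n ln[Σ_k w_k f(t_n − τ_k; δ_k)]`, then amplitude/duration
   measurement with baseline interpolation and duration correction
   (`deconvolve_waves()`, the package's central fitted model, with the
   usual `print/summary/coef/logLik/fitted/residuals/predict/plot/simulate`
   methods).
3. **Pairing** — waves at two sites are paired when their temporal overlap
   index `Ω = 2Δovlp/(d₁+d₂)` exceeds 0.7; lag statistics use a t-interval
   on the start-time differences and covariation uses orthogonal
   (principal-axis) regression.
4. **Synchrony** — cross-correlation, Welch spectral coherence with
   phase-randomization surrogate significance, Williams' test for
   dependent correlations, and Hilbert phase-lag estimation with circular
   statistics.
5. **Spike–wave coupling** — four-window (none/right/left/bilateral) spike
   classification with binomial confidence limits, bilateral
   wave-start comodulograms with a Poisson chance threshold
   `H₁₋α = P·N_s + λ₁₋α √(N_s P(1−P))`, and differential spike probability
   over generator power with piecewise power-law fits.
6. **Synthesis** — `synth_recording()` generates multichannel recordings
   and coupled spike trains with full ground truth (configurable bilateral
   lag, amplitude covariation via a calibrated Gaussian copula, unilateral
   fractions, two-exponent amplitude power law), so every stage is testable
   without any experimental data.

See the methods vignette (`vignettes/gammasync-methods.Rmd`) for the
models, assumptions, parameter defaults and known limitations.

## Worked example

Generate a 20 s bilateral recording with a configured 1.0 ms right-lead
lag, 0.5 amplitude covariation and 10%/5% unilateral fractions, then run
the full pipeline on the Schaffer-like generator of each hemisphere:

```r
library(gammasync)

cfg <- synth_config(epoch_length = 20, bilateral_lag_mean = 1.0,
                    unilateral_fraction_left = 0.10,
                    unilateral_fraction_right = 0.05, rng_seed = 42)
sr  <- synth_recording(cfg, unit_params = NA)
sr
#> Synthetic bilateral gamma recording
#>   channels: 64  samples: 20000  rate: 1000 Hz
#>   true waves: L 1820 / R 1705  pairs: 1620

rec  <- preprocess(sr$recording)
side <- rec$channel_meta$side
templates <- lapply(gammasync:::default_profiles(16),
                    function(p) rep(p, 2))

decL <- label_generators(
  decompose(lfp_recording(rec$voltages[side == "L", ], rec$rate),
            2, seed = 1), templates)
decL
#> Generator decomposition: 2 generators, 20000 samples @ 1000 Hz
#>   1 (schaffer): variance share 0.624
#>   2 (ca3som): variance share 0.368

fitL <- deconvolve_waves(decL$activations[decL$labels == "schaffer", ],
                         rec$rate, side = "L")
summary(fitL)
#> Deconvolved gamma waves: 894 fitted, 893 above thresholds
#>   amplitude (uV): median 100.9 [67.7, 167.5]
#>   duration (ms): median 16.6
#>   inter-start interval (ms): median 22.0

# ... same for the right hemisphere (decR, fitR), then:
pairs <- pair_waves(fitL$waves, fitR$waves)
lag_statistics(pairs)
#> Lag (b - a): -1.054 ms, 99% CI [-1.213, -0.895], n = 698
#>   subgroups: longer-L -0.386 ms, longer-R -1.563 ms
#>   unilateral: L 21.8%, R 18.2%

covariation(pairs, "amplitude")$r
#> [1] 0.49
```

Reading the numbers: the pair lag is `start_R − start_L`, so the mean of
−1.05 ms (99% CI −1.21 to −0.90) recovers the configured 1.0 ms
right-side lead; the amplitude covariation r = 0.49 recovers the
configured 0.5. The measured unilateral percentages exceed the configured
fractions because every wave missed on one side turns a true pair into two
apparent unilaterals — see the vignette's limitations section.

The same activations feed the continuous-signal estimators:

```r
actL <- decL$activations[decL$labels == "schaffer", ]
actR <- decR$activations[decR$labels == "schaffer", ]
phase_lag(actR, actL, rec$rate)      # reference: right generator
#> Phase lag: 0.2840 rad (1.070 ms) over 821 events
#>   mean frequency 42.25 Hz, Rayleigh p = 8.32e-40
```

A positive phase lag of 0.28 rad (1.07 ms at the 42 Hz mean frequency)
again says the left generator lags the right — the wave-level and
phase-level estimates agree.

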