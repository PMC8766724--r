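---
title: "Methods: theta-band power and directed connectivity during working-memory encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: theta-band power and directed connectivity during working-memory encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`thetadtf` implements an EEG analysis chain for the encoding phase of a
delayed match-to-sample working-memory task: band power with resting-baseline
normalization, directed transfer function (DTF) connectivity from
multivariate autoregressive (MVAR) models, behavioral phenotyping against a
control group, and the accompanying statistical battery. Because clinical
EEG of this kind is rarely shareable, the package ships a synthetic cohort
generator with known ground truth, so every stage of the chain is testable
end to end. This vignette records the model, the parameter choices, and the
design decisions a maintainer would want to know about.

## The analysis model

### Spectral analysis

The power spectral density (PSD) is a Welch-style average of squared
short-time Fourier transform magnitudes: 0.4 s Hamming windows, 50% overlap,
each windowed segment zero-padded to a 0.5 Hz frequency grid. The native
resolution of a 0.4 s window is 2.5 Hz, so the 0.5 Hz grid is an
interpolation obtained by zero-padding — the reading that reconciles a
"0.4 s window" with "0.5 Hz resolution" in the recording protocol this
pipeline follows. The estimate is one-sided and normalized so that
`sum(psd) * df` equals the windowed signal's mean power (Parseval, up to
taper correction); for epoched input the per-epoch PSDs are averaged over
the 60 encoding epochs before anything else is computed.

Band powers are per-bin means over half-open bands `[low, high)`
(delta 0.05–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–100 Hz), so a
shared edge such as 8 Hz is counted once, in the upper band. Using the
per-bin mean rather than the band integral is a scale choice only: the two
differ by a constant factor per band, which cancels in every group contrast
and correlation the pipeline reports. Working-memory efficiency power is
the element-wise baseline contrast `p_wm = p_raw − p_rs`, where `p_rs`
comes from the eyes-closed resting baseline; it may legitimately be
negative. The *prominent band* is the band with maximum channel-averaged
power, ties broken toward the lower band (and reported), and region-level
summaries are unweighted means over the four scalp clusters (frontal,
central-parietal, occipital, temporal). F7 and F8 belong to no printed
cluster and stay out of region aggregates while remaining in whole-scalp
computations. The montage records T7/T8/P7/P8; the older nomenclature
T3/T4/T5/T6 is accepted on input and normalized.

### Connectivity

Each subject's encoding epochs are fitted by one MVAR model with
multi-epoch ordinary least squares — regression rows are pooled across
epochs and never span an epoch boundary. The normal equations are
accumulated in compiled code without materializing the design matrix. The
default order is 2, matching the oscillatory-pair process class the
generator emulates; `"auto"` selects the order in 1..20 by BIC (AIC
available) and is the sensible choice for real data. The pipeline warns
when the regression has fewer than 10 rows per parameter.

From the fitted coefficients, the transfer matrix is
`H(f) = [I − Σ_r A_r e^(−i2πfr/fs)]⁻¹` and the DTF is the row-normalized
squared magnitude

γ_ij(f) = |H_ij(f)|² / Σ_m |H_im(f)|²,

with row i the sink and column j the source; every row sums to one at every
frequency. The numerator is `|H_ij|²` — the subscript-free form sometimes
printed for this quantity would make γ independent of the source and cannot
be meant. Band-averaged γ over theta is aggregated three ways: the global
mean over off-diagonal entries `DTF_g`; the per-channel node strength
`DTF_i = (1/(2(n−1))) Σ_{j≠i} (γ_ji + γ_ij)`; and region-pair means
`DTF_kl` over sink channels in region k and source channels in region l,
excluding diagonal entries when k = l (γ_ii is a normalization remainder,
not a connection). Frontal outflow `DTF_out` (inflow `DTF_in`) is the mean
of region-pair values with the frontal cluster as source (sink) against
each other region.

Two connectivity-specific choices deserve emphasis:

* **Reference for the MVAR fit.** The common average reference (CAR) makes
  the channels sum to zero at every sample, so a full-channel MVAR
  regression on exactly re-referenced data is singular — not numerically
  awkward but rank-deficient by construction. The pipeline therefore
  applies CAR on the spectral path only and estimates directed connectivity
  in the original recording reference; `car_connectivity = TRUE` restores
  CAR before the fit for users who work with channel subsets.
* **One fit per subject.** Encoding epochs are pooled into a single fit
  rather than fitting per trial and averaging: a 4 s epoch is short
  relative to the parameter count at 34 channels, while the pooled
  regression has tens of thousands of rows. `fit_mvar` accepts any epoch
  set, so a per-trial sensitivity analysis is a loop away.

Because γ is row-normalized per frequency, the pipeline evaluates it only
on the grid frequencies inside the analysis band when band-averaging; the
full-spectrum γ is available through `dtf()` directly.

### Behavior and statistics

Task performance per subject is mean reaction time (RT) over correct trials
and response accuracy (ACC). Both are z-scored against the control group's
mean and sample SD (n−1); a subject is performance-impaired when
`z_rt > 1.5` or `z_acc < −1.5`. The rule is directional — faster-than-normal
responses are not a deficit — with a two-sided variant behind a flag.
Controls are scored like everyone else but keep their control label, and
simulated patients are split into performance-normal and
performance-impaired groups by this rule (never by the generator's hidden
flags, which are reserved for recovery scoring).

The statistical battery mirrors a conventional SPSS-style workflow: Student
t-tests (Welch behind a flag), one-way ANOVA with Fisher's LSD post-hoc
comparisons on the pooled within-group mean square, Pearson chi-square
without continuity correction, Pearson correlation, and Shapiro-Wilk /
Levene (mean-centered) assumption checks reported alongside every contrast.
No multiple-testing correction is applied anywhere — LSD applies none by
definition, and the workflow this package reproduces applies none — which
the documentation states rather than hides. Assumption checks are advisory:
the pipeline warns but never switches tests silently.

## The synthetic cohort generator

No generative model is given by the protocols this package follows, so the
generator uses the minimal structure that produces the qualitative findings
the pipeline is designed to detect:

* **Per-channel oscillatory dynamics.** Every channel is an AR(2) process
  with a complex pole pair. During task encoding the resonance sits in
  theta (per-subject peak ~U(5.5, 6.5) Hz, per-channel jitter ±0.25 Hz,
  pole radius 0.96), which makes theta the prominent band. The resting
  baseline is alpha-resonant (~10 Hz, radius 0.95), the classic eyes-closed
  pattern, so theta `p_wm` is positive during encoding.
* **A frontal hub.** Fz sends lag-1 outflow to the frontal and occipital
  target channels with gain 0.02 (jittered ±20% per target). The gain was
  chosen, by desk calculation on the closed-form DTF of the two-channel
  system, to keep the band-averaged hub DTF in its *monotone response
  regime* (per-edge γ ≈ 0.3): at much larger gains the row-normalized DTF
  saturates near 1 around the resonance and group differences in coupling
  become invisible.
* **Weak dense background coupling.** Every ordered channel pair receives
  a lag-1 coefficient drawn N(0, 0.001²), identically in every group. This
  gives all regions a small, real inflow — in scalp EEG no region is ever
  fully isolated — and matters for the frontal-inflow null: with purely
  feed-forward coupling, `DTF_in` would be an estimation-noise artifact
  whose magnitude depends on the group's row denominator, producing a
  spurious group effect. Because the oscillatory poles sit close to the
  unit circle, the background draw occasionally destabilizes the process;
  it is then halved until the companion-matrix spectral radius clears a
  0.995 margin (a rare, group-independent event; every emitted tensor is
  verified stable).
* **The group effect.** Impaired (`tle_wm`) subjects have their hub-outflow
  gains multiplied by `impairment_factor` (default 0.5). `tle_n` subjects
  are EEG-identical to controls in distribution.
* **The behavior link.** A per-subject latent scalar ~N(0, 1) scales the
  innovation SD of frontal channels during the task (by `exp(0.2·latent)`)
  and shifts behavior: per-trial RT mean decreases by
  `behavior_link · rt_sd · latent` (default link 0.8, RT 700 ± 150 ms) and
  the probability of a correct response increases on the logit scale from a
  0.9 baseline. Impaired subjects additionally receive a +3 control-SD RT
  shift and a 0.15 accuracy deficit, so the 1.5 SD rule recovers them with
  high probability. RT is generated for correct trials only, and the latent
  scalar is the only bridge between EEG and behavior — sufficient to
  reproduce the sign structure of power-behavior correlations and far
  simpler than trial-locked neural coupling.

Each subject's recording is the resting baseline followed by the 60
encoding epochs (six blocks of ten trials, 4.039 s per epoch: four 1 s
pictures separated by 0.013 s gaps — the protocol's stated gap, taken at
face value). Cue, maintenance and retrieval segments are not synthesized:
the process is stationary within a condition, so simulating and discarding
them would change nothing statistically. The events table carries one
`rest` row plus the 60 `encoding` rows; requesting an absent phase returns
an empty epoch set with a warning.

What the generator deliberately does **not** emulate: volume conduction,
eye blinks, muscle and electrode artifacts, seizures or interictal
discharges, nonstationarity within epochs, and realistic cross-spectral
scalp topographies. Passing tests therefore demonstrate that the estimators
recover the truth for the process class they assume — not that the pipeline
is robust to artifactual real-world EEG, which is what the artifact-removal
hook (`remove_artifacts`) is for on real data.

## Numerical choices

* Filters are 4th-order Butterworth designs applied forward-backward
  (zero-phase), with odd-reflection padding sized from the slowest filter
  pole so that edge transients decay below 1e-10 even for the narrow 49–51
  Hz notch.
* Drift removal defaults to exact per-channel linear detrending; a
  zero-phase high-pass (default 0.05 Hz, the lower delta edge) is the
  alternative.
* Sample indexing is 0-based half-open `[onset, onset + duration)` in all
  event tables, eliminating off-by-one ambiguity; the R containers index
  1-based internally.
* Welch segments use a compiled radix-2 FFT when the FFT length is a power
  of two (two real signals packed per complex transform) and `stats::mvfft`
  otherwise; both paths agree to 1e-10 and are tested against each other.
* MVAR innovations in the simulator come from a Box–Muller transform over
  R's uniform RNG, so `set.seed` fully determines every cohort; all stage
  seeds derive from one root seed via named substreams.
* Exact ties in `prominent_band` break toward the lower-frequency band and
  are reported via a message.
* Delimited EEG files are written with 17 significant digits, so a written
  cohort re-reads bit-exactly; EDF output quantizes to the 16-bit grid over
  the per-channel physical range (writer and reader use the identical
  8-character header representation of that range).

## Default problem sizes

The full montage is 34 channels at 1,024 Hz with a 5-minute baseline; the
package defaults to 256 Hz and a 60 s baseline, which preserve every
qualitative property of the analysis at desk scale, and the Monte-Carlo
checks in the test suite use a 16-channel reduction of the montage that
covers all four regions. The full protocol-scale settings remain one
`simulation_config(fs = 1024, rest_duration = 300, n_channels = 34)` away.
Repeated-cohort checks (effect recovery, null calibration, correlation
signs) use 20–35 subjects per group over tens of seeds; single-cohort
examples in the README use smaller sizes.

## Known limitations

* The DTF is not immune to common-input confounds; a partial directed
  coherence variant is out of scope.
* `DTF_in`/`DTF_out` aggregate over region pairs with equal weight per
  pair, not per channel, so unequal region sizes weight channels unevenly
  across pairs (this matches the region-pair definition used throughout).
* The OLS fit assumes within-epoch stationarity; no adaptive/short-time
  DTF is provided.
* Statistical results are reported without multiplicity correction by
  design; users running many contrasts should apply their own control.
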