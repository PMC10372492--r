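---
title: "Models and methods of the ripple fitting battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the ripple fitting battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripplemetrics)
```

This vignette is the package's own account of the science behind each
analysis family: the models, their assumptions, the parameters that
matter, the numerical choices made where conventions were genuinely open,
and what the built-in simulators do — and do not — tell you about real
patient data.

## Moving spectrotemporal ripples

A moving spectrotemporal ripple modulates a carrier's log-frequency
envelope with a drifting sinusoid,

$$R(x, t) = 1 + \Delta M \cos\!\big(2\pi(\Omega x + \omega t)\big),$$

where $x$ is the spectral position in octaves above the band's lowest
frequency (`octave_position()`), $t$ is time since ripple onset,
$\Omega$ is the spectral density in cycles/octave, $\omega$ the temporal
velocity in Hz, and $\Delta M \in [0, 1]$ the modulation depth. Natural
speech lives almost entirely at $|\omega| \lesssim 10$ Hz and
$|\Omega| \lesssim 1$ c/o (`classify_speech_ripples()`), which is what
makes ripple sensitivity a speech-relevant, yet cognition-free, probe.

**Direction convention.** Both sign conventions for "upward" appear in
the literature, and they genuinely conflict across sources. This package
fixes one — a ripple drifts *upward* in frequency iff
$\omega/\Omega < 0$ — and exposes the opposite labeling as
`convention = "flipped"` in `ripple_direction()` and
`direction_asymmetry()`, rather than pretending the ambiguity does not
exist. The envelope formula itself always uses the $+$ sign.

**Synthesis.** All carriers are realized as superpositions of log-spaced
tones with independent uniform random phases: the tone-complex carrier at
the user's spacing (default 1/20 octave), and the "white" and "pink"
noise carriers as dense 1/64-octave complexes whose component amplitudes
follow the white (power flat per Hz, amplitude $\propto \sqrt{f}$) or
pink (power flat per octave, equal amplitudes) spectrum. Component
synthesis was chosen over filtering time-domain noise because the moving
envelope is defined in log-frequency: scaling each component by
$R(x_k, t)$ applies it *exactly*, whereas a filterbank on a noise
realization would only approximate it. With 1/64-octave spacing the
component density (several per auditory filter) makes the result
statistically noise-like.

Key trial-structure choices:

- The flat lead uses the *identical* carrier realization with the
  envelope held at 1, so the modulation itself is the only event at
  ripple onset — the quantity the reaction time is measured from.
- The lead duration is drawn uniformly from `noise_lead_range_s`
  (default 1–3 s) per trial, to make onset time unpredictable.
- The rippled segment is rescaled to the lead's RMS ("same carrier and
  mean sound level"). Modulation adds $\Delta M^2/2$ relative power, so
  equal RMS and envelope excursions of exactly $1 \pm \Delta M$ relative
  to the *lead* cannot both hold; the package equalizes RMS and the
  envelope bounds hold relative to each band's own mean level, which is
  what the depth of modulation means perceptually.
- A 5 ms raised-cosine ramp is applied at stimulus start only — never at
  ripple onset, which must stay untouched as the detection event.

**Verification oracle.** `band_envelopes()` and
`envelope_modulation_spectrum()` analyze a synthesized waveform by a
route independent of the synthesis (Hann STFT, RMS magnitude per
log-frequency band, 2-D FFT over octave × time): a correct ripple shows a
single modulation peak at $(\Omega, \omega)$. The band envelope uses RMS
rather than mean magnitude across bins so empty leakage bins do not
dilute the modulation.

## LATER reaction-time analysis

Under the LATER model a decision signal rises linearly from a starting
level to a threshold at a rate drawn once per trial from a Gaussian; the
reaction time is then an inverse Gaussian variate in the sense that the
*promptness* $p = 1/\mathrm{RT}$ is Gaussian, $p \sim N(\mu_p,
\sigma_p)$. The four underlying quantities (rate mean and SD, starting
level, threshold) are not separately identifiable from reaction times —
only the two ratios are — so `(mu_p, sigma_p)` is the parametrization
throughout.

- **Misses** (no response before the timeout $T$) are promptness values
  left-censored at $1/T$ and contribute
  $\Phi\!\big((1/T - \mu_p)/\sigma_p\big)$ to the likelihood. They are
  part of the distribution's slow tail, not missing data.
- **Anticipatory responses** faster than `min_rt_s` (default 0.08 s,
  below the ~35–50 ms auditory sensorimotor floor plus margin) are
  excluded from the likelihood and counted as outliers; presses before
  ripple onset are false alarms, reported per condition, never reaction
  times.
- **Optimization.** Without misses the closed-form Gaussian MLE is
  returned exactly (so censored and uncensored estimates coincide when
  censoring is inactive, by construction). With misses, BFGS on
  $(\mu_p, \log\sigma_p)$ with the analytic gradient, multi-started from
  moment estimates, relative tolerance $10^{-12}$. The covariance is the
  inverse observed information mapped to the $(\mu_p, \sigma_p)$ scale.
- **Reciprobit plots** use plotting positions $(i - 0.5)/n$ with misses
  counted in $n$; the x-coordinate is $-1/\mathrm{RT}$ so fast responses
  sit left and the missed tail at the far right. Recinormal data fall on
  a straight line with slope $1/\sigma_p$ and intercept
  $\mu_p/\sigma_p$; the median RT is read from the line at probability
  one half.
- **Condition comparison.** Nested censored-ML fits — both parameters
  shared; shared $\sigma_p$ ("shift", parallel reciprobit lines); shared
  $\mu_p$ ("slope" change); both free — compared by likelihood-ratio
  tests. The preferred model is chosen hierarchically at level $\alpha$:
  keep the shared model unless the full model beats it, then prefer the
  single-parameter relaxation the full model does not improve on.

## Spectrotemporal modulation transfer functions

The MTF collects each ripple's fitted promptness mode (for a Gaussian,
the mode *is* $\mu_p$) over the velocity × density grid; rows are
velocities and columns densities, stated explicitly because published
figures disagree on orientation. The (0, 0) catch cell has nothing to
detect: it is always masked for MTF purposes and its response rate is
reported separately as the false-alarm rate.

- **Separability.** A separable MTF factorizes as
  $v(\omega)\,s(\Omega)$; the index is
  $\sigma_1^2 / \sum_i \sigma_i^2$ from an SVD of the value matrix, so a
  rank-1 (fully separable) grid gives exactly 1. The SVD is taken on the
  *uncentered* matrix by default: centering by the grand mean turns a
  rank-1 matrix into a rank-2 one and destroys that identity.
  `center = "grand"` is available for the complementary question — how
  separable the modulation *about* the mean sensitivity is — which is
  the right null for i.i.d.-noise reference distributions.
- **Imputation.** Masked cells are completed by iterating
  $\widehat{v}_{ij} = \bar r_i \bar c_j / \bar g$ (row mean × column
  mean / grand mean) to a fixed point, which reproduces a separable grid
  exactly; additive completion is the fallback near a zero grand mean.
- **Direction asymmetry.**
  $(\bar\mu_\text{down} - \bar\mu_\text{up}) / (\bar\mu_\text{down} +
  \bar\mu_\text{up}) \in [-1, 1]$ over cells with a defined drift
  direction; flipping the direction convention flips its sign. Axis
  cells ($\omega = 0$ or $\Omega = 0$) have no direction and are
  excluded.
- **Averaging across subjects** can be done on promptness (default) or
  on reaction time (`average_mtf(on = "rt")`); the two differ because
  the mean of reciprocals is not the reciprocal of the mean, and both
  are exposed rather than silently choosing one.

## Distortion products and steady-state targets

A static nonlinearity acting on carriers $f_1, \dots, f_M$ produces
components at $f_{NL} = |n_1 f_1 + \dots + n_M f_M|$ with integer
$n_i$; the order is $\sum_i |n_i|$. Because of the absolute value,
$\{v, -v\}$ coefficient vectors alias to one physical frequency, so
enumeration keeps one canonical representative per sign class (first
nonzero coefficient positive). Products are labeled binaural iff their
nonzero coefficients touch carriers of both ears — binaural products can
only arise central to the two monaural pathways, which is what makes
them evidence of binaural integration. Frequencies coinciding within
`tol_hz` (default 0.1 Hz) are grouped with the lowest order first; 0 Hz
products are kept but flagged non-measurable.

Counting conventions for distortion products differ across the
literature (whether sign classes, distinct frequencies, or in-band
components are counted); `count_products()` therefore reports both the
number of coefficient classes and the number of distinct frequencies at
the tolerance, and the package deliberately hard-codes no published
count. Correctness is instead anchored to an exhaustive brute-force
enumeration oracle in the test suite.

`predict_eassr_targets()` restricts the enumeration to the usable EEG
analysis band (default 0–120 Hz) and flags second-order difference
products as the primary targets — e.g. pulse rates of 143 and 184 Hz
predict the difference response at 41 Hz.

## ASSR detection

`coherent_spectrum()` averages the stimulus-locked epochs in the time
domain *before* the Fourier transform: stimulus-locked components are
phase-consistent and survive, background EEG attenuates as
$1/\sqrt{n_\text{epochs}}$. Steady-state analysis needs sub-Hz
resolution, so epochs shorter than 2 s (bins wider than 0.5 Hz) are
rejected unless explicitly overridden. Amplitudes are one-sided
($2|X|/N$ except DC and Nyquist) in the record's units.

No standard reference prescribes a specific detection statistic for
these spectra, so the package adopts the field's standard spectral
F-test: power at the target bin against the mean power of
`n_neighbors` (default 10) bins per side, excluding the two bins
adjacent to the target as a leakage guard. Under Gaussian background
noise the ratio is $F(2, 4\,n_\text{neighbors})$ — each complex bin
carries two degrees of freedom — making the test exact for white noise,
scale-invariant, and only locally sensitive to colored (1/f) background.
Targets must fall on a bin center (within 1% of a bin by default);
off-bin targets are an analysis design error, not something to paper
over, so they raise an error.

`synthesize_eeg()` generates fixed-phase sinusoids repeated identically
per epoch plus white and/or 1/f noise drawn independently per epoch. It
emulates exactly what the detector assumes — stationary stimulus-locked
components in stationary noise — and deliberately nothing else: no
stimulus artifacts, no eye blinks, no drift, no alpha bursts. Passing
tests therefore validate the detection machinery, not robustness to
artifact-laden clinical EEG, which is out of scope here.

## Sound localization

The bilinear regression
$R_\text{azi} = b_0 + \alpha T_\text{azi} + \lambda L_\text{snd}$
is fitted by OLS separately per sound type (LP 0.25–1.5 kHz for ITD
cues, HP 3–10 kHz for ILD cues, BB 0.25–10 kHz), with seeded
nonparametric bootstrap percentile CIs (default 2000 resamples).
$\lambda$ is only identifiable if the level is roved — a constant level
raises an identifiability error rather than returning a meaningless
coefficient. Shifting all levels by $c$ dB changes $\widehat{b}_0$ by
$-\widehat\lambda c$ and leaves $\widehat\alpha, \widehat\lambda$
unchanged (exact OLS equivariance, tested).

The simulator defaults — targets uniform on $[-75, +75]^\circ$, a 25 dB
rove, 30–50 trials per sound type — mirror practical free-field
sessions; the 8° response noise SD is a plausible round figure for the
package's own simulations, since pilot regressions' residual noise is
not published.

## Reproducibility and the pipeline

Every stochastic operation takes an explicit seed and restores the
caller's RNG state. `derive_seed()` splits a global seed into
independent per-(operation, repetition) streams via a 31-bit polynomial
hash, so `run_pipeline()` is byte-identical under a fixed configuration
(`load_config()` rejects unknown keys and validates ranges).
`run_pipeline()` simulates the full battery: the grid design, per-ripple
reaction times from a smooth band-pass generating promptness surface
(peak near 8 Hz and $\Omega = 0$, as in normal-hearing sensitivity, with
$\sigma_p = 0.2\,\mu_p$), Bernoulli false alarms at the catch cell,
per-ripple censored fits, the assembled MTF, and a JSON report — plus a
manifest with md5 hashes, version and seeds for every artifact.

## Problem sizes and what the tests show

The test suite checks the statistical guarantees at the sizes a careful
simulation study would use: LATER parameter recovery over 200 replicates
of 1000 trials; reciprobit linearity at $10^4$ trials; likelihood-ratio
type-I error over 500 null replicates; detector false-positive rate over
1000 noise-only records and power at a 20 dB spectral SNR; bootstrap
coverage over 500 replicates of 50-trial sessions; and modulation-spectrum
peaks for 10 randomized ripple specifications. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bands while
keeping the default run around half a minute.

Passing them shows the implementations are correct and calibrated *under
their own models*. Real patients add what the simulators omit: lapses
and fatigue (non-recinormal RT contamination), session-to-session
drift, EEG artifacts, and perceptual idiosyncrasies — the analyses are
designed to flag some of these (outlier and false-alarm reporting,
masked MTF cells) but the simulators do not generate them.

## Known limitations

- No loudness calibration to dB SPL/HL and no CI-processor (vocoder)
  simulation: stimulus levels are arbitrary units.
- Distortion-product *amplitudes* are not predicted — that would require
  a nonlinearity model; only frequencies, orders and laterality are.
- Single-channel ASSR analysis; no EEG preprocessing or artifact
  rejection.
- Reciprobit slope maps across the ripple grid are exported with the
  per-cell fits but no summary statistics are defined for them.
- Elevation (spectral-cue) localization is out of scope; the regression
  covers azimuth only.
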