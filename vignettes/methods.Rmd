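---
title: "Dual-frequency SSmVEP coding and bifold CCA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-frequency SSmVEP coding and bifold CCA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
stimulus-coding scheme, the decoding model and its assumptions, the
evaluation quantities, the synthetic-data generator, and the numerical and
design choices that were genuinely open.

## Stimulus coding

A motion target reverses direction at its stimulation frequency $f$. On a
monitor at refresh rate $R_r$ frames/s, frame $i$ of the binary sequence
holds the square wave $\mathrm{square}(2\pi f\, i/R_r)$: $+1$ on the first
half of each period ("expansion"), $-1$ on the second. When $f \nmid R_r$
the half-cycles contain unequal frame counts; this asymmetric sampling is
the intended behaviour, not an artefact, and no rounding scheme is added.
A comfortable motion needs at least $k$ frames per half-cycle, bounding the
usable band by $f \le R_r/k$; $k$ is a configuration parameter with default
3 (at $R_r = 60$ this admits the 5–20 Hz band actually used by visual
BCIs).

*Boundary convention.* The sign is decided from the fractional phase of
$f\,i/R_r$, not from $\mathrm{sign}(\sin\theta)$: in floating point
$\sin(k\pi)$ evaluates to $\pm 10^{-16}$ and would place every second
half-cycle boundary frame on the wrong side, breaking the exact
$R_r/(2f)$ frames-per-half-cycle structure. Phase comparison (with a
$10^{-9}$ guard) realises the textbook square wave exactly.

**Dual-frequency plan.** For sorted base frequencies
$f_1 < \dots < f_N$, the midpoints are $g_i = (f_i+f_{i+1})/2$ for
$i<N$ and $g_N = f_N + M$ with margin $M = \min_i (f_{i+1}-f_i)/2$. Each
target then carries a (primary, secondary) pair: target 1 gets
$(f_1, g_{N-1})$, targets $2..N-1$ get $(f_{i+1}, g_{i-1})$, and target
$N$ gets $(f_2, g_N)$. The construction interleaves secondaries far from
their primaries so that any two targets share at most one *adjacent*
frequency, where adjacency is the relation "each $g_i$ neighbours $f_i$
and $f_{i+1}$" (plus $f_N \sim g_N$). `adjacency_audit()` verifies this by
exhaustive counting over all target pairs.

Two points were open:

* *Adjacency reading.* "Adjacent" could alternatively mean neighbours in
  the sorted union of all $2N$ frequencies. Both readings validate the
  canonical 5-target plan; the audit implements the explicit
  $g_i \sim f_i, f_{i+1}$ relation because it is the one stated
  constructively, and the alternative is noted here rather than
  implemented as a second code path.
* *Frame-index origin.* Only half-cycle frame counts are observable, so
  the 0-based origin is a free choice; it is fixed for reproducibility.

The coder refuses $N < 5$: the rotation pattern of the assignment is
defined from five targets up, and extrapolating it to fewer would be an
invention. Frequency distinctness is checked at an absolute tolerance of
$10^{-9}$ Hz.

## Pre-processing

Channels are band-pass filtered to 2–40 Hz with a Chebyshev type I design
(analog prototype order 4, 0.5 dB passband ripple — engineering defaults,
both configurable) applied with **zero phase**. Rather than time-domain
forward–backward filtering with finite padding, the squared magnitude
response of the designed filter is applied in the frequency domain on an
even-reflected extension of each channel. This is the limit of
forward–backward filtering with unbounded padding: with a 2 Hz edge at
500 Hz sampling the filter's poles sit so close to the unit circle that
any practical padding leaves start-up transients, while the
frequency-domain form has identically zero phase, exact linearity, and no
edge transients on 3.5 s trials. The passband consequently sees the
*squared* one-pass response (ripple doubled to 1 dB, stopband attenuation
doubled), exactly as forward–backward filtering would.

Epochs are half-open windows $[s, s+\ell)$ seconds, converted to 0-based
sample indices by flooring; successive epoching composes by offset
addition.

## Decoding model

**References.** For stimulation frequency $f$, the reference set stacks
$\cos(2\pi h f t), \sin(2\pi h f t)$ for harmonics $h = 1..N_h$ at the
1-based sample times $t = 1/f_s, \dots, m/f_s$. The time origin is
irrelevant (the sin/cos pair spans the same subspace under any shift — a
property the tests check at $10^{-9}$), but is fixed for reproducibility.

**CCA.** The first canonical correlation between the channel matrix $X$
and a reference set $Y$ is computed by row-centering both, reducing each
to an orthonormal basis of its row space with a rank-revealing QR, and
taking the largest singular value of the product of the bases. This route
was chosen over the also-considered ridge-regularised covariance solve: a
ridge term proportional to the trace is *not* invariant under invertible
channel mixing (CCA itself is), whereas the QR–SVD formulation is exactly
invariant and absorbs rank deficiency by truncation at a relative
tolerance, never crashing on collinear channels or duplicated reference
rows. Only the first canonical pair is used. Correlations are clamped to
$[0,1]$ against rounding.

**Standard CCA classification** scores each candidate frequency's
reference set and predicts the argmax; ties resolve to the lowest target
index and are logged.

**BCCA.** Each dual-frequency target contributes three reference sets:
$y_1$ and $y_2$ (each pair frequency with its harmonics) and the combined
set $y_c$ stacking $y_1$, $y_2$, and the sum-frequency pair
$\cos/\sin(2\pi(f_1+f_2)t)$ — $4N_h+2$ rows, de-duplicated when
frequencies collide within $10^{-9}$ Hz (degenerate pairs). Only the sum
frequency is included in $y_c$, not difference or other intermodulation
terms: the combined set is implemented exactly as specified, and the
simulator correspondingly asserts no intermodulation by default. The
target's score is the averaged correlation
$\rho_a = (\rho_1+\rho_2+\rho_c)/3$; averaging keeps a target competitive
when only one of its two frequencies evoked a response, which is the
empirical motivation for the bifold design. BCCA runs on the filtered
multi-channel trial directly; no spatial-filtering front-end is applied
or modelled.

**Harmonic count.** $N_h = 2$ by default: for the 5–9.5 Hz plans the
second harmonics (≤ 19 Hz) and the sum frequencies (≤ 15.5 Hz) all fall
inside the 2–40 Hz passband, while higher harmonics of motion responses
are weak. `select_harmonics()` offers the empirical route: the largest
$h$ whose multiples all exceed the local Welch-PSD noise floor (median
power within ±3 Hz, excluding the peak's immediate bins) by a factor of 3.

## Welch PSD

$P(w) = \frac{1}{M}\sum_{i=1}^{M}\frac{1}{L P_0}\left|\sum_{n=1}^{L}
w(n)x_i(n)e^{-jwn}\right|^2$ with $P_0 = \frac{1}{L}\sum_n |w(n)|^2$,
Hamming window, $L = f_s$ (1 s) and 50% overlap by default. The estimator
is implemented exactly as printed — normalised by window power, not
additionally by $f_s$ — so values are power per bin of width $f_s/L$;
peak locations and ratios, which are what the package uses it for, are
unaffected.

## Evaluation

The information transfer rate for $K$ choices at accuracy $\sigma$ and
$T$ seconds per selection is
$\mathrm{ITR} = \frac{60}{T}\left[\log_2 K + \sigma\log_2\sigma +
(1-\sigma)\log_2\frac{1-\sigma}{K-1}\right]$ bits/min, with
$0\log_2 0 = 0$. Two conventions were settled here:

* $T$ is the decoding window length by default. A rest-time-inclusive
  convention exists, but the reference working points
  ($\sigma = 0.925, K = 5$ giving ≈ 30.6 bits/min; $\sigma = 0.8438$
  giving ≈ 23.7) back-compute cleanly only with $T = 3.5$ s, the window
  alone; callers charging rest time simply pass a larger $T$.
* Below chance ($\sigma < 1/K$) the formula is *positive* again — it is
  $\log_2 K$ minus a bounded entropy term, non-negative everywhere and
  zero only at chance, since systematic miscoding also carries
  information. The value is returned as computed and flagged with a
  message; clamping or negating it would misstate the formula.

Per-class indices follow the standard confusion-matrix definitions;
the fourth index is per-class accuracy $(TP+TN)/\mathrm{total}$. A class
with no positive trials has undefined sensitivity and is reported as
`NA`, never silently as 0.

## Synthetic data generator

The generator is a declared test fixture, not a biophysical model. A trial
is

$$x_{c}(t) = g_c\,s(t)\,\alpha + n_c(t), \qquad
s(t) = \sum_{h=1}^{N_h^{sig}} d^{\,h-1}\sin(2\pi h f_1 t + \phi_h)
     + \beta \sum_{h} d^{\,h-1}\sin(2\pi h f_2 t + \psi_h)$$

with per-channel gains $g_c$ (lognormal, log-SD 0.2, drawn once per
subject), harmonic decay $d = 0.5$, imbalance $\beta$ (default 1; small
$\beta$ emulates trials where only one embedded frequency responds), and
$\alpha$ scaling the evoked component so that evoked/noise power across
channels equals the configured SNR in dB. Noise is independent per
channel: a pink ($1/f$) component, a white fraction (0.1), and a
narrowband alpha rhythm at 10 Hz (fraction 0.3, ~2 Hz bandwidth) —
fractions chosen once as a realistic occipital mixture, with alpha the
dominant background rhythm near the stimulation band. An optional
sum-frequency evoked term exists but defaults to amplitude 0: no
intermodulation strength is asserted. Defaults mirror the emulated
protocol: 500 Hz, 6 channels (Po3 Po4 Po7 Po8 Pz Oz), 3.5 s trials,
10 subjects × 2 sessions × 5 targets × 4 trials = 400 trials, per-subject
SNR jitter SD 1 dB, default SNR 5 dB. A single base seed expands to
per-trial substreams through a fixed affine counter map, so every trial is
individually bit-reproducible and the caller's RNG stream is left
untouched.

What the generator does **not** emulate: non-stationarity and artefacts
(blinks, EMG), channel-specific phase/topography structure (the evoked
component is rank-1 across channels up to gains), nonlinear
harmonic/intermodulation generation, and inter-trial amplitude drift.
Passing recovery tests on this fixture therefore demonstrates decoder
correctness and relative behaviour (BCCA vs CCA, SNR trends), not
real-data accuracy levels.

## Problem sizes and detectability

The validation suite uses the full 400-trial default dataset for
parameter-recovery checks, 200-trial datasets for the imbalance-ordering
and SNR-monotonicity sweeps, 50 trials for spectral-peak statistics, and
small (≤ 100-trial) datasets elsewhere; these sizes give binomial error
bars of a few percent while keeping each check to seconds.

One detectability property deserves note. Canonical correlation against a
$2N_h$-dimensional reference integrates ~1750 samples over 6 channels,
a processing gain of well over 20 dB relative to broadband SNR; on this
generator the decoder is still clearly above chance at −20 dB
(accuracy ≈ 0.3) and reaches chance only around −25 to −30 dB. Any
expectation that −20 dB broadband SNR is undecodable underestimates this
gain. The imbalance comparison (β = 0.25) is run at the 5 dB default,
where BCCA ≥ CCA holds; in a narrow mid-SNR band the averaged score can
dilute BCCA slightly below primary-frequency CCA, because the weak
frequency's correlation contributes mostly noise there — a known property
of unweighted score averaging.

## Known limitations

* The adjacency audit implements one reading of "adjacent" (see above).
* EDF support is the 16-bit single-record subset sufficient for trial
  exchange, not the full EDF+ specification.
* The below-chance ITR flag and the tie-logging are messages, not
  conditions a caller can programmatically distinguish.
* The generator's rank-1 evoked topography makes channel mixing
  information-free for CCA; decoders that exploit topography would not be
  differentiated by this fixture.
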