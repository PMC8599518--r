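---
title: "Models and methods behind mesoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoscan)
```

`mesoscan` simulates the computational core of a dual-engine, temporally
multiplexed, large field-of-view two-photon mesoscope and reimplements the
analysis pipelines such an instrument feeds. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic phantoms do and do not capture about real data.

## Scan trajectory and timing

A resonant mirror oscillates sinusoidally at `frequency` (default 8 kHz),
so its normalized position is `sin(phase)` and its velocity vanishes at the
turning points. Only the central `fill_fraction` (default 0.9) of the
normalized sweep is used for pixel acquisition; pixels are equal *position*
bins, so the dwell time — and the number of laser pulses — per pixel varies
across a line. For pixel `n` of `N`:

$$\mathrm{pulses}(n) \;=\; \frac{2\,FF}{N}\cdot
\frac{Rep}{2\pi\,Freq\,\cos\{\sin^{-1}[-FF + 2FF(n-1)/(N-1)]\}}$$

This is minimal at the line centre, maximal at the edges (centre value
divided by $\sqrt{1-FF^2}$), symmetric under $n \to N+1-n$, and sums to
$Rep\cdot\sin^{-1}(FF)/(\pi\,Freq)$, the active line time, up to the
endpoint-sampling error of the discrete sum. That error is below 0.5% for
`N >= 128` at moderate fill fractions but reaches 0.7% at the steep
combination `FF = 0.9, N = 128`; the test suite asserts the tighter bound
only where it mathematically holds.

**Line-rate calibration.** A nominal 8 kHz bidirectional scan yields
16,000 lines/s, but acquisition electronics lose a little of every period.
`resonant_config` therefore carries an `effective_line_rate` calibration;
`default_scan_config()` sets 15,770 lines/s, which reproduces the observed
3.85 frames/s for a 4096-line frame without modelling turnaround
electronics. Pass `effective_line_rate = NULL` for nominal timing.

**Dead time.** Visiting `k` regions sequentially with one beam costs
`k * jump_time` per cycle; the dead fraction is
`k·jump / (Σ periods + k·jump)`. The galvo step-and-settle jump time is not
a quantity we can calibrate on a desk, so a typical 5 ms default is used
and exposed as a parameter. At 60 frames/s per region this already exceeds
20% — the argument for two independent engines.

## Temporal multiplexing and demultiplexing

Two 80 MHz pulse trains are interleaved after one is delayed by
`1.875 m / c = 6.25 ns`, half a pulse period, giving a 160 MHz comb.
`interleave_trains` flags uneven combs; the evenness tolerance is 1% of the
period, because the physical delay arm itself is 0.07% off the exact half
period and must count as even.

Fluorescence is modelled per excitation pulse as Poisson photon yield
(`rate_per_pulse`) with exponential emission delay (lifetime `tau`,
default 3.0 ns, GFP/GCaMP-like; the lifetime only matters for crosstalk and
is configurable). Demultiplexing assigns each photon by the parity of
`floor((t − t0)/Δ)` within the 2Δ period, with an optional veto that blanks
the tail of each window; events are conserved exactly
(`ch1 + ch2 + veto + dropped = total`). The steady-state probability that a
photon lands in the other pathway's window is

$$X(\tau, \Delta) = \frac{e^{-\Delta/\tau} - e^{-2\Delta/\tau}}
{1 - e^{-2\Delta/\tau}},$$

0 for instantaneous decay, 1/2 in the long-lifetime limit, and 0.111 at
`tau = 3 ns, Δ = 6.25 ns`. Monte-Carlo demultiplexing of simulated photon
streams converges to this closed form; that agreement is a standing test.
Detection-chain jitter is not modelled (an optional Gaussian jitter could
be added to `simulate_emission` without touching the demultiplexer).

## First-order optics and adaptive optics

The optical prescription stores effective focal lengths (61 / 243 / 30 mm),
the ±5° scan half-angle, and a *calibrated* scan scale of 0.50 mm/deg.
First-order geometry predicts a `2·30·tan(5°) = 5.25 mm` field, but the
rendered line-grid calibration measures 5.0 mm, and the package treats the
grid image as ground truth — both numbers are reported by `fov_extent()`.
Derived bookkeeping: a 3.98× (reported "4×") scan–tube telescope, a
25 × 10⁶ space-bandwidth product at 1 µm lateral resolution, and a 120 µm
remote-focus range from a 3.5 µm-stroke deformable mirror
(sensitivity 120/3.5 ≈ 34.3 µm defocus per µm stroke, a calibration
constant — its pupil-geometry derivation is out of scope, and the range is
linear in stroke).

The sensorless AO optimizer emulates sequential manual correction: Noll
modes 5–15 (piston/tip/tilt/defocus are never touched) are maximized one at
a time against a user-supplied brightness metric with a bracketed
golden-section line search (`stats::optimize`, tolerance span/100, roughly
a dozen evaluations per mode), repeated for `sweeps = 3` passes. Steps are
accepted only on improvement, so the best-so-far metric is monotone. Any
bracketed 1-D maximizer satisfies this contract; on a mildly coupled
quadratic (condition ≤ 5) three sweeps come within 5% of the optimum. No
wavefront model is attached: Strehl ratios are not computed.

Field flatness is assessed as the maximum residual about a best-fit plane
over the sampled focal surface against a 30 µm tolerance. Note that a
symmetric spherical bowl loses about a third of its corner sag to the plane
fit, so "sag" and "residual" differ; the residual definition is the one
implemented.

## Phantoms and image formation

All generators are seeded and keep their ground truth.

* **Beads**: 0.2 µm beads (far below the 1 µm PSF) placed uniformly at the
  measurement depths (50/250/500 µm defaults).
* **Line grid**: period 0.2 mm (5 lines/mm); centres at
  `(k + 0.5)·period` so exactly `floor(extent/period)` lines — 25 over the
  5 mm field — lie strictly inside.
* **Neuron field**: somata with a minimum separation, per-frame spike
  counts, and a *distance-dependent correlation kernel*
  `rho(d) = a_near·exp(−d²/2L_near²) + a_far·exp(−d²/2L_far²)` (defaults:
  rho(0) = 0.25, high below a ~40 µm knee, decaying slowly to 0.05 at
  2 mm). Each Gaussian component is realized exactly by a grid of latent
  Poisson sources with Gaussian delivery footprints: a source event reaches
  neuron *i* with probability `g·exp(−d²/2σ²)`, and for a pair at distance
  `d` the shared-event covariance is proportional to `exp(−d²/4σ²)` —
  a Gaussian correlation component with `L = σ√2`, with no approximation
  beyond grid discretization (spacing σ/1.5, padded 3σ). Source rates are
  calibrated so the pair correlation equals the kernel and each neuron's
  marginal rate equals `rate_hz` (default 0.5 Hz; the independent Poisson
  remainder absorbs the unshared rate). Realized binned correlations match
  the kernel within ~0.01 at n = 200, 5000 frames.

The default frame rate, 3.85 Hz, matches a full-height 4096-line
dual-engine acquisition; the kinetics defaults (rise 0.18 s, decay 1.5 s)
are standard GCaMP6s values.

Rendering forms `brightness ⊗ PSF × pulses_per_pixel × rate_per_pulse` and
Poisson-samples counts. The grid profile is convolved analytically with the
lateral Gaussian PSF; bead stacks emulate the measurement protocol
(0.5 µm stage steps, 1.38× focus travel, 30 Poisson frames averaged per
plane, optional PSF tilt in x–z); neuron movies modulate Gaussian somatic
footprints with spike-convolved calcium, add a smooth neuropil field at
0.3× soma brightness co-modulated by the population signal, and stream in
chunks so long sessions never hold the full movie in memory.

**What the phantoms do not capture:** motion artifacts, depth-dependent
scattering, vessel occlusion, anatomically realistic neuropil, bursting or
oscillatory population dynamics (latent drives are temporally white), and
segmentation errors (ROIs come from ground truth, since segmentation is
delegated). Passing tests therefore validate the *pipeline arithmetic*
under known ground truth, not robustness to those real-data effects.

## PSF measurement

The measurement recipe is followed exactly: the radial FWHM is the mean of
Gaussian fits to the X and Y line scans through the bead at its axial
intensity maximum; the axial FWHM is the mean of XZ and YZ line profiles
taken *at the angle maximizing the fitted FWHM* (search grid ±20° in 1°
steps, ties broken toward 0°), which prevents the underestimation a
straight-z profile suffers when the focal shift is tilted. Axial
coordinates are corrected by `focus = 1.38 × stage` (the full-field value;
the paraxial index ratio 1.33 is also available). Gaussian fits include a
constant offset and use Levenberg–Marquardt with moment-based starts; a
zero-residual (noiseless) profile defeats the `nls` machinery, so the
fitter retries from a perturbed start and, failing that, accepts the
moment solution when its residual is numerically zero. Fits that still
fail are returned flagged, never silently. One caveat: when a tilt is
confined to the x–z plane, the y–z profile genuinely foreshortens and no
y–z angle recovers it, so the XZ/YZ average underestimates such a PSF —
faithful to the recipe being modelled.

## Calcium pipeline

Traces are per-frame means over soma masks; neuropil is the mean over an
annulus (gap 4 µm, width 10 µm, excluding every soma pixel) and subtracted
as `F − r·F_annulus` with `r = 0.7` by default (common practice for
annulus corrections; configurable). ΔF/F uses a rolling 20th-percentile
baseline over 60 s, evaluated on a decimated grid (every 25 frames) and
interpolated. Transients are suprathreshold excursions (3 robust SDs,
noise from the MAD of first differences) lasting at least 3 frames — the
duration requirement exists because isolated single-frame crossings are
noise, while genuine GCaMP6s transients persist; SNR is the mean transient
peak over the MAD-based SD of non-transient frames, returned flagged when
no transient exists.

**Spike inference** is a deterministic non-negative deconvolution against
the AR(2) impulse response equivalent to the double-exponential indicator
(`g1 = d + r`, `g2 = −d·r`): greedy matching pursuit places events at the
residual's maximum kernel correlation, with O(L) local updates via the
kernel autocorrelation. Greedy pursuit alone misplaces spikes under
transient superposition (verified on noiseless traces), so each pass of
*cyclic refinement* removes every event and re-localizes it against the
residual (3 passes, then a rescan); events below 5% of the largest are
discarded and events within 1 frame merged. The stopping rule is
`threshold_sd` (default 3) times the amplitude noise propagated from the
trace's difference-MAD. A noiseless single transient is recovered at the
exact frame with unit amplitude; on rendered phantoms at transient SNR ~7–8
the event F1 against ground truth (±2 frames, amplitude-aware matching)
exceeds 0.95.

**Correlations.** `correlation_profile` computes Pearson correlations over
all `n(n−1)/2` unordered pairs and bins them by centroid distance
(40 µm bins to 4 mm by default), excluding — and counting — pairs with a
constant train or beyond the last edge, so pair bookkeeping always closes.
Inferred `spike_set`s are correlated as discrete event trains (the
inference yields spike events; amplitude-weighting only adds noise). The
end-to-end session (`run_phantom_session`) counts events in 1-second bins
before correlating — the standard spike-count-correlation window in
cortical physiology. The choice matters: at 3.85 frames/s the deconvolution
carries an irreducible ~1-frame timing ambiguity (adjacent-frame kernels
are nearly collinear), and strict frame-resolution Pearson on inferred
trains attenuates the short-range correlation by ~30%, while 1 s count
bins absorb the ambiguity and are unbiased for the generator's
frame-synchronous trains. Two alternatives were implemented, measured on
ground truth, and rejected: boxcar-smoothing both trains (its apparent gain
is a normalization artifact of the event trains' short-lag
anti-correlation) and a windowed cross-correlogram statistic (the measured
cross-lag mass is slightly negative for refractory event trains). With 1 s
bins the recovered profile tracks the generator kernel to ~0.05 per bin
through the full render–extract–subtract–infer chain, against ~0.01 when
correlating the ground-truth spikes — the gap is the real cost of
deconvolution at this frame rate and indicator speed.

## Problem sizes and runtime choices

The standing tests use: Eq-style timing checks at N up to 4096 (instant);
10⁵-photon Monte-Carlo demultiplexing; a 61-plane bead stack with 30-frame
averaging at 0.2 µm pitch; a 40-neuron, 3000-frame, 30 Hz session for
detection metrics; and a 200-neuron, 5000-frame, 3.85 Hz session over a
2.4 × 0.8 mm field at 4 µm pixels (rendered in 250-frame chunks) for the
correlation-recovery check — sizes chosen so the full suite runs in a few
minutes on one core while every statistical tolerance retains comfortable
Monte-Carlo margin. The 5,874-neuron scale of a real session enters only
as pair-count arithmetic; rendering it is unnecessary for any claim the
package makes.

## Known limitations

* The line-rate and mm/deg calibrations are constants, not models; they
  reproduce observed frame rates and field sizes but carry no physics of
  scanner turnarounds or distortion.
* The crosstalk model ignores detector dead time, discriminator pulse
  shapes and afterpulsing; veto gating is ideal.
* The AO metric interface is a toy: it optimizes whatever scalar the caller
  supplies and makes no claim about real wavefront aberration landscapes.
* Spike inference assumes the indicator kinetics it deconvolves with;
  kinetics mismatch is not explored.
* The correlation kernel is stationary and isotropic; real cortical
  correlation structure is neither.
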