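---
title: "Models and methods behind hemofus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hemofus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemofus)
```

# Scope

`hemofus` implements the computation chain of dual-modality functional
ultrasound (fUS) and multispectral photoacoustic (PA) brain imaging:
power-Doppler cerebral blood volume (CBV), directional autocorrelation
velocimetry for cerebral blood flow (CBF), non-negative spectral unmixing
to oxygen saturation (SO~2~) and indocyanine green (ICG), microbubble
ultrasound localization microscopy (ULM), acquisition-sequence timing, and
the relative-change / cross-correlation analysis layer. Because no public
raw acquisitions accompany this class of experiment, the package ships
physics-informed simulators with exact ground truth; every processing
stage is validated end-to-end against what the simulators encode.

This vignette explains the models, the conventions, the tunable parameters
and their defaults, and — importantly — what the synthetic validation does
and does not demonstrate about real data.

# Conventions

Arrays are ordered (depth *z*, lateral *x*, slow time *t*), with depth
increasing away from the transducer and pixel indices 1-based at the
transducer-proximal corner. The default acquisition mirrors the target
system: center frequency $f_0 = 15$ MHz, sound speed $c = 1540$ m/s,
0.1 mm pixel pitch, and a compounded frame rate
$\mathrm{PRF}_c = 1/525\,\mu s = 1904.76$ Hz from seven plane-wave angles
fired 75 µs apart.

**Flow sign convention.** Descending flow (away from the transducer,
deeper) produces a *negative* Doppler shift: the two-way echo phase is
$\varphi = -4\pi f_0 z / c$, so increasing depth decreases phase. The
`VelocityMap` class therefore populates its descending map from the
negative-frequency directional component and displays it conventionally in
red, ascending in blue; `vSigned` is positive for descending flow.

# Acquisition timing model

Sequence timing is exact integer microsecond arithmetic: a compounded
frame period is `length(angleList) * interAngleInterval`, an acquisition
window is `nCompoundFrames` periods, and block durations append transfer
time plus a configurable trigger-synchronization slack (nominally
~0.2 s — hardware-bound, hence a parameter rather than a constant). With
the defaults this reproduces the 525 µs compound period, the 78.75 ms
window per CBV map, the 16-frame / 1.6 s PA block at the 10 Hz laser
repetition rate, the 560 ms ULM sequence of 400 frames at 200 µs per
angle, and 168 s of accumulation over 300 sequences. Microsecond integers
avoid any float drift when windows are multiplied out.

# The IQ simulator

`simulateIQMovie()` works at the *beamformed, compounded IQ* level — the
point where vendor processing hands data to the science — and composes
three processes:

**Blood.** Each vessel is populated with point scatterers drawn uniformly
over its lumen (`scattererDensity` per mm², default 300). Scatterers
advect along depth at the flow speed of their own radial position —
plug flow by default, since a `vesselSpec` prescribes one axial velocity;
a parabolic (Poiseuille) profile is available and used where intravascular
shear matters. Each scatterer carries the two-way travel phase
$e^{-i 4\pi f_0 z(t)/c}$ of its instantaneous, unwrapped depth, so Doppler
arises from motion itself: the ground-truth modulation frequency is
$f_d = -2 f_0 v_z / c$ (10.27 mm/s ⇒ 200 Hz at 15 MHz). Scatterers are
rendered with a Gaussian axial point-spread function (`axialPsfSigma`,
default 0.2 mm, the axial extent of a beamformed 15 MHz pulse) and
recycled through the lumen under a raised-cosine end taper, which keeps
the rendered speckle free of wideband amplitude steps. Scatterer
amplitudes fluctuate with a *Gaussian-shaped* spectrum of standard
deviation $1/(2\pi\,\texttt{speckleTau})$ (default `speckleTau` 0.2 s),
emulating out-of-plane and transverse decorrelation. The Gaussian shape
matters: heavy (Lorentzian) modulation tails would leak past the 70 Hz
clutter wall and bury the attenuated Doppler carrier of slow flows under
the signal's own sidebands.

**Tissue clutter.** Clutter is an exactly rank-limited process:
`nModes` smooth complex spatial fields, each modulated by a band-limited
temporal envelope (random phasors with frequencies uniform on
±`modeBandwidth`), with geometrically decaying mode energies
(`modeDecay`, default 0.6) mimicking the decaying singular spectrum of
real tissue motion. Total clutter amplitude is set relative to the blood
speckle RMS (default 30 dB). Two constraints shape the defaults and are
worth stating because they are *physics, not convenience*:

* A band-limited process of bandwidth $B$ over a window of $T$ seconds
  supports only about $2BT + 1$ temporal degrees of freedom. A clutter
  process that genuinely occupies ten singular values — which is what a
  processing chain that rejects ten ranks presumes of its tissue — needs
  $B \gtrsim 10/(2T)$. The default `modeBandwidth` of 30 Hz sustains
  rank 10 over the 400-frame ensembles used for velocimetry validation.
* The clutter band must stay clear of both the 70 Hz high-pass wall and
  the Doppler band of the slowest flow the chain is asked to resolve
  (2 mm/s ⇒ 39 Hz). 30 Hz tissue bandwidth corresponds to tissue moving
  below ~1.5 mm/s axially, a plausible anesthetized-brain regime, and its
  hard band edge means any clutter energy that survives rank rejection is
  subsequently removed by the high-pass rather than aliasing into the
  blood band.

**Noise.** Additive circular complex Gaussian noise, default $3\times
10^{-4}$ of the blood speckle RMS (−70 dB). The default is set once by a
signal-chain argument: the 70 Hz wall attenuates a 39 Hz carrier by
~40 dB in power, and the chain is expected to still resolve that flow, so
the noise floor must sit well below −40 dB of blood; −70 dB represents a
well-compounded plane-wave acquisition through a cranial window.

The simulator returns per-pixel ground truth (signed velocity, Doppler
frequency, blood mask, the clutter-free blood movie and the blood-free
clutter movie) and flags scenes whose Doppler frequencies exceed
$\pm\mathrm{PRF}_c/2$ as aliased.

# Clutter rejection

`svdClutterFilter()` forms the Casorati matrix (space × time), removes the
leading `nReject` singular components (9 on the CBV path, 10 on the CBF
path), and reshapes back. The SVD is economical on the thin time
dimension. The energy identity — filtered Frobenius energy equals
$\sum_{i > n} \sigma_i^2$ — is asserted in the tests against an
independent eigendecomposition of the temporal covariance.

`slowTimeHighpass()` applies a 4th-order Butterworth high-pass (default
70 Hz) forward and backward per pixel, for zero phase distortion of the
Doppler signal that the velocimeter consumes downstream; power at the
cutoff is attenuated to ~0.25 (two −3 dB passes). The implementation pads
by odd reflection with steady-state initial conditions and then discards
the filter's settling region at both record ends (default two cutoff
periods per side, capped at a quarter of the record). The trim is not
cosmetic: when a strong sub-cutoff carrier is being rejected, the edge
transients are broadband at the percent level of the carrier — orders of
magnitude above what the stopband leaves of the carrier itself — and
would otherwise dominate slow-flow velocity estimates.

The high-pass is applied immediately after the SVD stage and before the
directional split; the stage order of the flow path is fixed as
SVD(10) → 70 Hz high-pass → directional split → autocorrelation.

A genuine limitation, documented rather than hidden: rank rejection
removes the top singular directions of the *mixture*, so some blood
energy inevitably rides along. The absorbed share shrinks with ensemble
length and with the diversity of the blood signal (many vessels, velocity
shear, speckle decorrelation). On a rich six-vessel scene with 400-frame
ensembles the tests show >90% of blood power surviving nine-rank
rejection; on a single slow plug-flow tube with short ensembles the
assumption of blood–tissue separability degrades, exactly as it does in
vivo.

# Power-Doppler CBV

`powerDopplerMap()` is deliberately minimal: per-pixel mean squared IQ
magnitude over slow time, the standard proxy for fractional moving blood
volume (red cells dominate the filtered echoes). No spatial smoothing is
applied by default; a Gaussian option exists behind a flag. The dB view
is referenced to the map maximum, matching conventional display
normalization. Intensity scales as $|a|^2$ and, on simulated scenes, is
monotone in scatterer density — both asserted in tests.

# Directional autocorrelation velocimetry

`directionalSplit()` splits each pixel's slow-time spectrum at 0 Hz and
reconstructs positive- and negative-frequency movies by inverse FFT. The
DC bin is excluded from both components (clutter-filtered input is
DC-free); for even-length records the Nyquist bin joins the negative
component. Power fractions are relative to total spectral power, so they
sum to at most one, with equality when the DC bin is empty.

`axialVelocity()` is the lag-1 (Kasai-type) phase estimator:
$R(1) = \sum_t \overline{IQ}(t)\, IQ(t{+}1)$,
$f_d = \mathrm{PRF}_c \arg R(1) / 2\pi$,
$v_z = c f_d / (2 f_0)$, bounded by the Nyquist velocity
$c\,\mathrm{PRF}_c/(4 f_0)$ (≈48.9 mm/s here) by construction of
$\arg(\cdot)$. The published description cites a nonlinear
autocorrelation regression without printing its model; the lag-1 phase
estimator is adopted as the fully specified default — the two coincide on
noiseless phasors, which the tests verify against a brute-force linear
phase fit. The normalized magnitude $|R(1)|/R(0)$ feeds the validity
masking; note it equals $(N-1)/N$ for a pure tone of length $N$.

Validity follows the published thresholds: a positive component is kept
where it holds >0.2 of total spectral power, negative where it holds
>0.25, and either additionally requires normalized lag-1 autocorrelation
>0.2. Whether the 0.2 autocorrelation floor refers to lag-1 or to a
fitted value is not stated in the source description; lag-1 normalized by
$R(0)$ is used. `assembleCbfMap()` populates descending velocities from
the negative component and ascending from the positive; pixels valid in
both directions keep both per-direction maps, and the signed map takes
the larger-magnitude component.

**Validation conditions.** Velocity recovery is validated on single-tube
scenes at 15 MHz / 1904.76 Hz / 0.1 mm with clutter 30 dB above blood,
rejecting ten ranks and high-passing at 70 Hz, for true speeds
{2, 5, 10, 20, 40} mm/s; the in-vessel median absolute error stays below
5% of the true speed and the descending/ascending assignment always
matches ground truth. These runs use 400-frame ensembles (32 × 32 px):
over a 150-frame window, a realizable rank-10 tissue process must occupy
a bandwidth whose removal-residue overlaps the slow-flow Doppler band, so
the shorter ensemble conflates clutter defects with estimator defects;
400 frames is also a standard resting-state/ULM sequence length. The
2 mm/s case is the edge of the chain's regime — its 39 Hz carrier sits
*below* the 70 Hz wall and survives only because the simulated line width
(speckle + transit + shear) is a few Hz; real capillary flow with broader
lines would not be recovered this accurately, and the validity masks are
what keeps such pixels out of the maps in practice.

# Spectral unmixing

The PA forward model is linear: at wavelength $\lambda$,
$p_\lambda = E_\lambda \, \Phi(z) \sum_k \varepsilon_k(\lambda)\, c_k$
with pulse energy $E_\lambda$, fluence $\Phi$, molar extinctions
$\varepsilon$ and concentrations $c_k$ for
$k \in \{\mathrm{HbO}, \mathrm{HbD}, \mathrm{ICG}\}$. The 750/800/850 nm
extinction values are frozen package constants from the standard compiled
optical-absorption tables, shared by the simulator and the unmixer so
that recovery tests are exact. Fluence is $e^{-\mu_{\rm eff} z}$ with a
single configurable coefficient and no wavelength dependence, and *no
fluence correction is applied* in the unmixing — concentrations carry the
depth bias, SO~2~ does not (it is a ratio).

`buildSystemMatrix()` scales row $\lambda$ by its absolute pulse energy.
Scaling by energy *ratios* relative to a reference wavelength would break
a desirable invariance — multiplying all energies and all images by the
same constant must leave concentrations unchanged — so absolute scaling
is used; all other stated behaviors (equal energies give the raw matrix
up to scale, doubling one energy doubles that row) are preserved.
Energies are per-session scalars; per-frame normalization is not modeled.

Per pixel, `unmixStack()` solves $\min_{c \ge 0} \|E c - p\|_2$ by
Lawson–Hanson NNLS, taking the unconstrained solution directly where it
is already non-negative (the same optimum). Tests verify optimality
against a $50^3$ brute-force grid. SO~2~ = HbO/(HbO+HbD) is computed on a
support mask (total hemoglobin above 1% of the map maximum by default —
the source normalizes and displays SO~2~ only where hemoglobin signal
exists but states no threshold). ICG maps display with 20·log10
compression referenced to the map maximum. At 30 dB image SNR with
five-set averaging, recovery tests show SO~2~ mean absolute error <0.02
and ICG amounts within 5%.

The `nSets`-fold wavelength-set averaging reduces noise as
$1/\sqrt{n}$; `paStackFromFrames()` assembles the canonical 16-frame
block into 5 complete sets, discarding the spare trigger-guard frame.

# Ultrasound localization microscopy

`localizeMbs()` detects strict regional maxima above a threshold
(absolute, or a noise-floor multiple — the source states no value, so the
multiple is exposed in config) and refines each to sub-pixel precision by
the three-point log-quadratic fit applied to the 3×3 patch *marginals*:
for a separable Gaussian PSF the marginal along one axis is itself
Gaussian, so the fit stays exact while averaging noise over three pixels.
Ties (a peak exactly between two pixels) are broken by scan order, one
detection per plateau. Localization is exact on noiseless PSFs and
~0.15 px at 20 dB SNR in the tests.

`linkTracks()` associates detections frame-to-frame by minimum total
Euclidean displacement using an exact Hungarian assignment
(potentials + shortest augmenting paths, $O(n^3)$; verified against
brute-force permutation enumeration). Pairs farther than
`maxLinkDistance` are forbidden via a skip-cost construction, unmatched
detections open tracks, unmatched tracks close (no gap bridging — not
described in the source), and tracks shorter than `minTrackLength` are
discarded. The source's "minimum duration of 100 s" cannot be literal
within 560 ms sequences; the package default is 20 frames, prominent in
the configuration, and tracking never spans the inter-sequence transfer
gaps. The default linking radius derives from a configured maximum
expected speed, $d = v_{\max} / (\text{frame rate} \times \text{pitch})$,
since no radius is published.

`accumulateMaps()` bins every localization onto the super-resolution grid
(default 10 µm), accumulates counts (density), signs them by each track's
net depth displacement (direction), and averages per-step speeds
(displacement × frame rate) into the bins each step touches. Total
density always equals the number of accumulated localizations. On
synthetic data, two parallel vessels 20 µm apart — far below the 1.3 px
PSF — resolve into two distinct density ridges, and per-bin mean speeds
recover constant-speed tracks within 5%. That demonstrates the
*algorithmic* super-resolution chain; it does not by itself establish
in vivo resolution, which depends on bubble statistics, motion and
registration not modeled here.

# Hemodynamic analysis

`relativeChange()` computes $r(t) = 100\,(x(t) - \bar{x}_{1..n_0}) /
\bar{x}_{1..n_0}$ with the baseline window $n_0 = 10$ frames — the same
formula serving relative CBV, CBF and SO~2~. The window length is
configurable because 10 frames spans ~33 s at the interleaved dual-mode
rate but ~7 s at the continuous resting-state rate, and the same formula
is used in both regimes. `roiRelativeTimecourse()` matches the published
order of operations: per-pixel relative change first, then the ROI mean,
with the across-pixel standard deviation per frame as the uncertainty
band (the across-pixels reading of the shaded bands; across-time is the
other possible reading of the source figures).

Cross-correlation is Pearson (mean-removed, normalized) at integer frame
lags over the truncated overlap window — no zero padding, so $R$ does not
decay artificially with lag; reported $R$ values in $[-1, 1]$ imply a
normalized coefficient even though the source does not specify one. Lags
are reported in seconds (`lag × framePeriod`, ~0.71 s per frame for
continuous imaging). Zero-variance voxels are masked. No detrending or
filtering is applied to resting-state series by default. The classic
construction — a vein series built as the anti-phase cortical reference
delayed two frames — produces its trough at +1.42 s, as asserted in the
tests.

`paradigmSummary()` reports window means and peak timing for the
stimulation paradigm (default: 2-min baseline, 3-min stimulus, 3-min
post, the hypercapnia protocol).

# Container, export, pipeline

All stages share one lossless dataset container (groups /iq, /pa, /maps,
/truth, /meta) so acquisition metadata travels with the arrays; reading
validates the schema and names any missing required field. On disk the
container uses R-native serialization — the environment provides no HDF5
bindings — with bit-identical round-trips; the group schema is preserved
so the layout is portable. Float TIFF export stores values normalized by
`max(|value|)` (the TIFF container stores float32 in [0, 1]) with the
scale in a plain-text sidecar that `importMap()` reapplies; CSV export is
the exact-value path; dB PNG export documents its maximum-referenced
scale. `runPipeline()` validates the configuration before execution
(stage dependencies, rejection counts against frame counts, cutoff
against the frame rate), runs simulate → filter → {CBV, CBF} / unmix,
and stamps every container with the exact config, seed and package
version; identical config and seed reproduce /maps bit for bit. The
command-line interface (`inst/cli/hemofus.R`) is a thin wrapper over
these exported functions, one subcommand per stage plus `run`.

# Problem sizes used in validation

The shipped tests and the acceptance script run, by design, at desk
scale: 32–48 px square fields of view, 60–400-frame ensembles, 16–24 px
photoacoustic phantoms, tens of microbubble frames, and 3–10 random seeds
per stochastic claim. These sizes were chosen as the smallest at which
each property is stably measurable; all processing code is size-agnostic.

# What passing tests do and do not show

The simulators encode exactly the physics the estimators invert — linear
PA mixing with known extinctions, Gaussian PSFs, tone-like Doppler with
controlled line shapes, exactly rank-limited clutter. Passing therefore
shows the chain is *correct* (it inverts its own forward models at the
stated accuracy under realistic noise), not that it is *sufficient* for
arbitrary in vivo data: real clutter is not exactly low-rank, real PSFs
are anisotropic and depth-dependent, real spectra include chromophores
beyond the three modeled, wavelength-dependent fluence biases deep
SO~2~, and animal motion, skull aberration and registration are outside
scope. Published in vivo effect sizes (e.g. ~100–120% CBV responses to
hypercapnia, cortex–vein anticorrelation structure) are not quantitative
targets here — no raw data is deposited — and are covered qualitatively
by the end-to-end synthetic demonstrations: a hypercapnia-like run in
which vessel dilation during the stimulus window produces the expected
relative-CBV time course, and a resting-state-like run in which an
anti-phase vein voxel is recovered by the lag-correlation map.
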