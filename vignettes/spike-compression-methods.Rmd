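---
title: "Methods: simulating, compressing and evaluating extracellular spike waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, compressing and evaluating extracellular spike waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikecodec)
```

## The problem

A wireless brain-machine interface (BMI) records extracellular potentials on
many channels but can only afford a modest radio link and a strict power
budget on the implanted side. Streaming raw samples (25 kHz at 10 bits) costs
250 kbps per channel; transmitting only detected spike waveforms costs 640
bits per spike; transform coding the waveform down to a handful of basis
coefficients cuts that by another order of magnitude. The open design
question is how to split detection, alignment, compression and reconstruction
between the implant and the external unit, and which compression basis to
hold fixed on the implant. `spikecodec` implements a simulation testbed for
that question: synthetic ground-truth recordings, two time-domain spike
detectors, fractional-delay alignment, five transform-coding bases, PCA +
K-means spike sorting, and a set of evaluation measures including an
implant-side operation count and the wireless data-rate budget.

## The synthetic recordings

`make_test_recording()` synthesizes the standard test condition: a linear
array of 19 electrode sites spaced 50 um along the z axis, four target
neurons placed near the array at the reference coordinates
(10, 20, -2), (-2, 18, 20), (-20, -5, -10) and (16, -13, 15) um, and a
population of background ("noise") neurons placed uniformly in a hollow
cylinder around the array (inner radius 120 um, outer radius 250 um,
half-height 250 um). The SNR condition is set by scaling the target
coordinates by 1.0, 1.5 or 2.0 (high, medium, low): the targets move away
from the array — to mean x-y distances of roughly 20, 31 and 41 um — while
the noise shell stays put, so their amplitudes fall as 1/r against a fixed
noise floor.

Every neuron fires with gamma-distributed inter-spike intervals
(shape 2 by default, 1 ms refractory floor); target rates are drawn uniformly
from 1-10 spikes/s, background rates from 1-50 spikes/s. Each channel is the
superposition of site-specific templates at the spike times plus white
thermal noise (SD 3 amplitude units by default), bandpass filtered 300 Hz to
5 kHz with a zero-phase 4th-order Butterworth filter, sampled at 25 kHz.

**The surrogate waveform model.** Templates are built from a parametric
difference-of-gammas family: a sharp main phase (gamma kernel with per-unit
shape `k1` and time constant `tau1`), a slower opposite-sign after-phase
(`tau2`, relative size `ratio`), and an optional small leading phase. Shape
is distance-invariant; only amplitude decays (monopolar 1/r point source with
reference distance 20 um). The four target units differ in sharpness,
after-potential size and leading phase, and one unit is positive-dominant —
diversity chosen so the units are separable by PCA + K-means at the
high-SNR condition, and chosen along *gross* morphological axes (polarity,
after-potential, leading phase) of the kind a generic spike basis captures
in its leading components. That choice is part of the surrogate design:
with units differentiated instead by fine temporal structure, no
library-derived fixed basis could preserve their differences at four
coefficients, which would contradict the behaviour the testbed is meant to
reproduce.

**What the simulator does not model.** No biophysics (the templates are
parametric, not compartmental), no electrode impedance or drift, no bursting
(rate-stationary trains), no overlapping-spike resolution (near-coincident
spikes appear as outliers and are discarded during extraction), and no LFP
beyond the summed background-neuron activity. Passing tests therefore say
nothing about those regimes.

**Calibration.** The noise-neuron density (5e6 neurons/cm^3, about 470
neurons in the default shell) and thermal noise SD were fixed once so that
the mean target SNR — peak-to-peak amplitude of the mean waveform over the
robust noise SD `median(|x|)/0.6745` — lands near 8 at the high-SNR
condition. The 1/r model ties the conditions together: low-SNR is
structurally about half of high-SNR (~4.3), medium ~6.

## Detection and jitter emulation

Two detectors are implemented. ABS thresholds the absolute signal at
`k * sigma_n` (default `k = 4`) with `sigma_n` the robust noise SD. NEO
thresholds the nonlinear energy operator
`psi[n] = x[n]^2 - x[n-1] x[n+1]` at `C * mean(psi)` (default `C = 8`).
Both multipliers are conventional values from the detection literature and
are configuration-exposed. NEO responds to simultaneous amplitude and
frequency increases, which makes its detections roughly self-aligning at
high SNR; ABS is an order of magnitude cheaper but jitters: different spikes
cross the threshold at different points in the waveform.

To keep sorting-accuracy estimates free of false-positive contamination,
extraction is anchored on the ground truth (`extract_with_jitter()`): one
64-sample window (2.5 ms) per true spike; windows that never cross the
detector threshold are discarded; each retained spike's crossing time is
measured on an 8x-upsampled (200 kHz) grid via Fourier interpolation; each
waveform is shifted with a band-limited delay filter so its crossing lands
on the modal crossing time; crossings more than 1.5 SD from the mode are
discarded as outliers (these are mostly spike overlaps); the result is
decimated back to 25 kHz. The crossing-time SD is computed over all spikes
that crossed, before outlier removal. The net effect is a spike matrix with
exactly the detector's characteristic jitter but with known identities.

## Alignment

`align_spikes()` aligns each spike on its maximum absolute amplitude within
13 samples (~0.5 ms) after the detection index, placing the peak at sample
17 — the sample where the first basis waveform of the compression bases
peaks, so that aligned spikes and basis are registered. External-unit
alignment works on the 200 kHz grid (sub-sample resolution); implant
alignment uses integer shifts at 25 kHz only, since fractional-delay
filtering is too expensive on-implant. Ties in the peak search break toward
the earlier sample.

## Transform coding

With spikes in the columns of the 64 x N matrix X, the full transform is
A = W'X; an L x 64 row-selection matrix E keeps L coefficients, C = E A, and
the external unit reconstructs X-hat = W E' C. The five bases:

- **optimal** — left singular vectors of X itself; the Eckart-Young
  reference case (recomputing it per recording is exactly what an implant
  cannot afford).
- **fixed 1** — SVD basis of a 40 000-waveform library computed at 10 000
  random measurement points around each of the four target-neuron models.
  Because the surrogate waveform shape is distance-invariant, this library
  is exactly rank 4 (four shapes times amplitude scalars); basis columns
  beyond rank 4 are an orthonormal completion, which is harmless since
  reconstruction only uses the spanned subspace.
- **fixed 2** — SVD basis of the packaged surrogate *generic* library (see
  below); the case of main interest, since it is derived independently of
  the data being compressed.
- **downsample** — W = I and E keeps every D-th sample, `D = round(64/L)`,
  no antialiasing (deliberately: the question is what plain sample-dropping
  costs); reconstruction zero-stuffs and applies an ideal frequency-domain
  lowpass at `fs/(2D)` with gain D. When D does not divide 64 the kept count
  differs slightly from L; the kept count is what enters the rate budget.
- **Haar** — the orthonormal scale-major Haar matrix; E keeps the first L
  rows without any per-spike coefficient search, the cheap choice on an
  implant.

SVD column signs are fixed (largest-magnitude element positive) so bases are
bit-stable. For the SVD and Haar bases E selects the leading rows; for SVD
bases these are ordered by significance, which is the property that makes a
fixed SVD-derived basis attractive: no coefficient-selection logic on the
implant.

**The surrogate generic library.** The empirically recorded waveform library
that a deployed system would use is not available here, so
`make_surrogate_library()` generates a stand-in: 500 unit-peak waveforms
from a Gaussian-derivative family (first-derivative-of-Gaussian main phase,
width 0.08-0.45 ms; Gaussian after-potential and leading bumps of random
size and lag; 20% positive-dominant), frozen at a fixed seed. The family is
deliberately different from the difference-of-gammas family that generates
the test data, preserving the key property that the generic basis is
unrelated to the signals it compresses. Its SVD concentrates >80% of library
energy in the first four components, as a library of aligned mean spike
waveforms does.

Coefficients can be uniformly quantized (`quantize_coefficients()`,
mid-rise over the observed range, 10 bits by default) for rate realism; at
10 bits the effect on reconstruction accuracy is below 0.005, so the
processing chains leave it off.

## Architectures

- **0** extract -> transmit raw -> external align -> sort (reference)
- **1** extract -> compress -> transmit -> reconstruct -> sort
- **2** as 1, plus external alignment before sorting
- **3** extract -> implant align -> compress -> transmit -> reconstruct -> sort

Architecture 1 relies on the detector for alignment (which only NEO
provides, and only at high SNR); architecture 3 buys alignment on the
implant for 13 comparisons per spike.

## Evaluation

**Reconstruction accuracy** is the lag-maximised normalised cross-correlation
between each reconstructed spike and the noiseless (filtered) template of
its true neuron, averaged over spikes. Normalisation uses the overlapping
segments' norms at each lag and the lag search is limited to +/-10 samples:
this scores a purely shifted noiseless template as exactly 1 while
preventing spurious matches at near-zero overlap. Note the measure can
*exceed* the no-compression reference: truncating to the leading SVD
coefficients removes noise from the waveform, so moderate compression
denoises.

**Sorting accuracy** is the fraction of spikes assigned to the right unit
under the best cluster-to-unit matching, found by exhaustive permutation
(24 mappings for four units). Features are the first three principal
components of the reconstructed spikes, recomputed per configuration;
clustering is best-of-10-restart K-means with the true cluster count (4)
supplied.

**Score and minimum coefficient count.** The combined score is the
arithmetic mean of reconstruction and sorting accuracy — a deliberate
design choice: both accuracies lie in [0, 1], so the score does too, it
weighs the two objectives equally, and it is monotone in each (the product
is available as an alternative). Scores measured at L in {2, 4, 8, 16, 32}
are cubic-spline interpolated onto the integer grid, and the effective
minimum coefficient count is the smallest integer L whose interpolated
score is within 0.01 of the maximum. With a handful of 60-second recordings
the score curves carry some clustering noise; within one sweep the
clustering seed is held fixed across L so a curve reflects the coefficient
count alone.

**Median comparisons** between configurations use percentile-bootstrap 95%
confidence intervals for each group median (2000 resamples); a difference
is called significant when the intervals are disjoint.

**Operation counting.** One operation is a one-bit addition; adding two
10-bit words costs 10 operations, comparison costs the same as addition,
multiplication ten times as much. The detection statistic runs on every
sample and is counted per second of signal: ABS costs one comparison per
sample (0.25 Mops/s at 25 kHz), NEO two multiplications, a subtraction and
a comparison (5.5 Mops/s). Implant alignment costs 13 comparisons per spike
and compression one 64-point multiply-accumulate per transmitted
coefficient per spike, both attributed at 40 spikes/s (four units at 10
spikes/s). The total is quoted per coefficient ("per dimension") for the
compression stage; under this convention NEO-with-architecture-1 costs
about 5.8 Mops and ABS-with-architecture-3 about 0.54 Mops — an
order-of-magnitude gap driven entirely by the detector.

**Data-rate budget.** Closed-form accounting: L coefficients at 10 bits per
spike versus 640 bits raw per spike and 250 kbps raw streaming per channel.
At L = 4: 40 bits/spike, compression factor 16, a mean channel rate of
1.6 kbps (4 neurons x 10 spikes/s), a 99.36% reduction against raw
streaming, and 625 channels on a 1 Mbps link against 4 channels raw — a
156.25-fold gain. (A frequently quoted reduction of 99.8% does not follow
from this arithmetic; the package reports the computed 99.36%.)

## Problem sizes and numerical choices

The packaged study conditions are scaled down from five-minute recordings to
60-second single-site recordings over 5-6 seeds: about 1 300 target spikes
per recording, which keeps a full sweep (five bases, five coefficient
counts, the reference and the NEO chain) near half a minute per seed while
leaving the qualitative orderings stable. Upsampling is Fourier (spectrum
zero-padding, Nyquist bin split), exact at original sample instants;
fractional delays use a frequency-domain linear-phase ramp on a zero-padded
window, so content shifted past the window edge is lost (windows are wide
enough that edge energy is negligible for aligned spikes). SVD sign
ambiguity is fixed as described; K-means degeneracies (coincident points)
fall back to exact centres when the number of distinct points equals K.
Degenerate inputs error early: zero rates give empty trains, empty spike
sets give empty matrices with a warning, zero-energy spikes score zero with
a warning.

## Known limitations

Units are separable here by design; real recordings contain unsortable
units, overlaps and drift, so absolute accuracies do not transfer — the
testbed supports *relative* statements between architectures, detectors and
bases under matched conditions. The implant-mode alignment is exactly
idempotent, but external (sub-sample) alignment is not guaranteed idempotent
on multi-peak noisy waveforms, where a later local peak can enter the second
search window. The minimum-coefficient rule with its 0.01 tolerance is
sensitive to score noise at small problem sizes; medians over seeds are the
stable summary. The operation count covers the dominating arithmetic of
detection, alignment and compression only — no memory traffic, control flow
or transmitter energy.
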