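---
title: "Methods: multi-objective neural-network compression of ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective neural-network compression of ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgcomp)
```

## The model

`ecgcomp` compresses single-channel ECG beat by beat. Each detected beat is
cut to a fixed 270-sample window (105 samples before the R peak, 165 from it
on), reduced to 70 samples, min–max normalized, and passed through a
three-layer 70–Nd–70 autoencoder. The Nd sigmoid hidden activations are the
stored code; the linear output layer reconstructs the 70-sample beat, which is
then denormalized and re-interpolated to 270 samples. With Nd = 14 the stored
payload per beat is 14 values against 270 raw samples, a ratio of about 1:19
before container overhead.

Training minimizes the scalarized multi-objective energy

$$E = W_1 N_d + W_2\,\mathrm{PRD} + W_3\,(1 - \mathrm{CC}),$$

with default weights $(W_1, W_2, W_3) = (0.25, 0.45, 0.3)$, which sum to 1.
PRD is the baseline-corrected percentage root-mean-squared difference and CC
the Pearson correlation between the original and reconstructed waveforms,
both entered as fractions (PRD = 0.12 for 12%). $N_d$ is discrete, so its
gradient in the weights is zero: the continuous part
$W_2\,\mathrm{PRD} + W_3\,(1-\mathrm{CC})$ is minimized by full-batch gradient
descent (learning rate $\alpha$, default 0.4, 10,000 cycles by default), and
the $W_1 N_d$ term is handled by an outer discrete search over candidate
hidden sizes (default 12, 14, 16) that trains one network per candidate under
identical seed and budget and keeps the energy argmin, ties going to the
smaller (more compressive) size. We deliberately use *descent*: the energy is
a cost, and CC enters through $1-\mathrm{CC}$ so that all three terms are
minimized together. Training-set energy is what the search compares;
held-out distortion can be reported alongside via `train_split()` (default
67% of beats studied).

PRD and CC are implemented in their canonical baseline-corrected forms,

$$\mathrm{PRD} = \sqrt{\frac{\sum_i\big((r_i-\bar r)-(o_i-\bar o)\big)^2}
{\sum_i (o_i-\bar o)^2}},\qquad
\mathrm{CC} = \frac{\sum_i (o_i-\bar o)(r_i-\bar r)}
{\sqrt{\sum_i (o_i-\bar o)^2}\sqrt{\sum_i (r_i-\bar r)^2}},$$

and the tests hold them to independent textbook implementations at 1e-12.
Note one scaling consequence of the energy definition: with the default
weights, $W_1 N_d$ alone is 4.0 at $N_d = 16$, so energies near or below 4
for 16 hidden units are only reachable in the degenerate limit of zero
distortion; the discrete search therefore tends to prefer smaller hidden
sizes whenever the extra capacity buys little PRD — which is exactly the
intended trade-off.

## Wavelet preprocessing

All wavelet stages use the undecimated (à-trous) dyadic transform with the
quadratic-spline pair `h = (1,3,3,1)/8`, `g = (2,−2)`: every level has the
length of the input, the smoothing recursion dilates the filter taps by
$2^{j-1}$, and boundaries are mirrored (symmetric extension avoids edge
spikes that would fake modulus maxima). Two detail variants share the same
smoothing recursion:

* **analytic** (`g`-filtered): antisymmetric, derivative-like responses used
  for R detection;
* **additive** ($W_j = S_{j-1} - S_j$): telescopes, so
  $S_J + \sum_j W_j$ reproduces the input to machine precision — the variant
  used for denoising and baseline handling.

**Filter alignment and detector delay.** The `h` taps sit at
$k \in \{-1,0,1,2\}$ and the `g` taps at $k \in \{0,1\}$. Each smoothing
stage then delays by half a (dilated) sample and the final high-pass stage by
another half, so at level $j$ the zero-crossing of the analytic detail trails
the R peak by $(2^j - 1)/2$ samples — 3.5 at the detection level $j = 3$.
The detector corrects with the integer $2^{j-1}$ (4 samples at $j=3$),
landing within one sample of the true peak; on noise-free synthetic records
detection is exact to ±2 samples.

**Baseline removal depth.** Respiratory baseline wander occupies roughly
0.15–0.3 Hz. Subtracting the approximation $S_J$ only cancels the wander if
the approximation still *tracks* it, and the short spline cascade rolls off
far below its nominal $f_s/2^{J+1}$ band edge. The depth is therefore chosen
from the filter's own response: `baseline_level()` returns the largest $J$
whose analytic cascade gain leaves residual power
$|1 - \prod_{l\le J} H(2^{l-1} f)|^2 \le 0.15$ at the band edge
$f_{\max} = 0.3$ Hz. At 360 Hz this gives $J = 7$: 10.4% residual power at
0.3 Hz and under 5% at the 0.2 Hz band center, while a depth of 8 would leak
37% of a 0.3 Hz tone back into the output. The 15% band-edge allowance is the
deliberate compromise between drift cancellation and P/T-wave preservation
(deeper subtraction distorts the clean ECG less).

**Denoising keep-set.** The QRS energy concentrates at detail scales
$2^3..2^5$ and the T/P waves at scale $2^3$, so `denoise()` keeps scales
{3, 4, 5} plus the coarse approximation $S_5$ (so low-frequency P/T content
survives) and discards scales 1–2, where wideband noise dominates. The
keep-set is a configurable argument because the two statements above do not
uniquely determine one rule; keeping every scale reproduces the input exactly
(the telescoping identity), which the tests use as the oracle.

## Segmentation and the 70-point scheme

The downsampler passes the 15 samples centered on R (positions R−7..R+7)
through unchanged and must select the remaining points from the other 255.
A literal "every 6th sample" stride yields 15 + ⌈255/6⌉ = 58 points, which
contradicts the 70-point network width; we honor the 70-point total — it
fixes the architecture — and take the 55 non-central samples at
`round(seq())` positions over the remaining indices. The stride reading stays
available via `segmentation_scheme(method = "stride")`. The index map is
fixed, published by `downsample_indices()`, and the retained positions are
exact fixed points of the downsample→upsample round trip (gaps are filled by
linear interpolation; cubic is available). On a clean synthetic beat the
round trip costs under 5% PRD.

Both beat windows found in practice are supported: the default
270-sample (105/165) scheme and the 251-sample cluster (90 before R, R, 160
after — `pre = 90, post = 161`). Windows are half-open `[R − pre, R + post)`
with 1-based R indices inside the R API; files written by the CLI use 0-based
indices on the wire.

Per-beat min–max normalization to [0, 1] precedes the network because the
sigmoid hidden layer needs bounded inputs; the (min, max) pair is stored per
beat in the container and inverts the map exactly. A side effect worth
knowing: normalization cancels any per-beat multiplicative gain, so the
network sees beat *shape*, not amplitude.

## R-peak detection

Detection runs on the analytic detail at scale $2^3$: local maxima above
$s_1$ and minima below $s_2$ (defaults: 0.3 of the record's extreme positive
and negative detail values — record-relative fractions so synthetic and real
records share defaults and detection is amplitude-invariant), each maximum
paired with the nearest following minimum within a 120 ms window (a QRS
duration bound), the zero-crossing between the pair interpolated, and the
delay correction subtracted. Peaks closer than a 200 ms refractory period (a
physiological minimum RR interval) are resolved in favour of the larger
modulus pair. Thresholds that reject everything produce an empty result, not
an error.

## The synthetic generator

`generate_record()` emulates what the pipeline assumes of its input: a
periodic P-QRS-T morphology (five Gaussian bumps per beat; Q and S negative;
R strictly dominant so argmax = R), sinusoidal baseline wander inside the
0.15–0.3 Hz band, and seeded white Gaussian noise. Defaults: 360 Hz, 60 bpm,
noise sd 0.02 mV, wander 0.1 mV at 0.2 Hz — magnitudes typical of a clean
resting recording. Per-beat amplitude jitter is available but off by default
so fixture arithmetic is exact. The generator returns exact ground truth
(R indices and the clean signal), which is what makes the detector's
recall/precision and the distortion metrics testable.

What it does **not** emulate: arrhythmic or ectopic beats, RR-interval
variability, QRS morphology changes, electrode-motion artefacts, powerline
interference, or multi-lead structure. Passing tests on this generator
demonstrate the pipeline's mechanics — exact reconstruction identities,
detector geometry, descent of the energy, container integrity — not clinical
performance on pathological recordings.

## Numerical choices

* Weight initialization: uniform $(-r, r)$, $r = \sqrt{6/(fan_{in}+fan_{out})}$,
  zero biases, seeded; the whole train/compress path is a pure function of
  (data, configuration, seed).
* Gradients: analytic backpropagation through the per-beat PRD and CC terms
  (both are mean-free, so centering contributes nothing); validated against
  central finite differences to relative error < 1e-5. Degenerate beats
  (perfect fit, constant reconstruction) get a zero gradient for the affected
  term rather than a division by zero.
* Divergence guard: training aborts with the epoch and learning rate if the
  loss exceeds 1e6 or becomes non-finite.
* DTW: classic dynamic program, steps {(1,0),(0,1),(1,1)}, local cost
  $|a_i - b_j|$, cost divided by the backtracked optimal path length so the
  0.3 match threshold is length-independent; the threshold comparison is
  inclusive. The DP equals brute-force path enumeration for all inputs with
  $M, N \le 6$.
* Container: versioned JSON with 17-significant-digit doubles (bit-exact
  round trip) and an md5 checksum over the payload text; truncation and
  silent edits are both rejected.

## Problem sizes used in the tests

The shipped tests run the full stack at reduced scale, chosen so the suite
exercises every path on one CPU in seconds: training fixtures of 5–12 beats
at 150–3000 epochs, the hidden-size experiment at 40 beats × 500 epochs over
candidates {12, 14, 16}, and detector evaluation over 20 seeded records of 8
beats. At these sizes training reaches PRD ≈ 3–5% and CC > 0.999 on clean
synthetic beats; the defaults (`epochs = 10000`, `alpha = 0.4`) reproduce the
full-scale training regimen.

## Known limitations

* The energy compares networks only through their training-set distortion;
  no regularization or early stopping is provided, consistent with the
  full-batch formulation.
* Gradient descent with a fixed learning rate can oscillate near a minimum at
  large $\alpha$; the monotone-descent guarantee in the tests is stated at
  $\alpha = 0.01$.
* The baseline-removal subtraction also attenuates a few percent of genuine
  low-frequency cardiac content (mostly T-wave energy); at $J = 7$ and 360 Hz
  this costs about 2–3% PRD on clean synthetic beats before compression even
  begins.
* Only single-lead records are handled, and the CSV reader expects one value
  column (optionally with an index column); there is no reader for binary
  waveform-database formats.
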