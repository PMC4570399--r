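---
title: "Methods: streaming spike sorting with NEO detection and Hebbian PCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: streaming spike sorting with NEO detection and Hebbian PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikegha)
```

## The problem

Extracellular electrodes record the superimposed action potentials of an
unknown number of nearby neurons on top of background noise. Spike sorting
assigns each recorded spike to the neuron that fired it. When many channels
must be sorted online — for example by an implanted device — the algorithmic
budget per sample is tiny, which motivates the pipeline modelled by this
package: cheap nonlinear-energy-operator (NEO) detection, peak alignment,
and feature extraction by a streaming principal-component rule that never
forms a covariance matrix, with one shared computation core multiplexed
round-robin across channels.

`spikegha` implements that pipeline in full as testable software: the
synthetic recording generator, the detector, the generalized Hebbian
algorithm (GHA) trainer with double-precision and emulated 17-bit
fixed-point backends, a cycle-level behavioural model of the shared
datapath with its closed-form channel-capacity bounds, and fuzzy c-means
(FCM) scoring against ground truth.

## Detection and alignment

For samples $s_k$ of one channel, the discrete nonlinear energy operator is
$\psi_k = s_k^2 - s_{k-1}s_{k+1}$; a spike is declared where $\psi_k$
exceeds a threshold $\gamma$. The operator responds jointly to amplitude and
frequency, which separates brief, sharp action potentials from slower
background fluctuations far better than an amplitude threshold at the same
cost (three multiplications per sample).

Design choices around the bare operator:

* **Threshold.** $\gamma = c \cdot \overline{\psi}$ with $c = 8$ by
  default. A multiple of the mean NEO energy is the standard automatic
  choice; under the generator's default noise model this setting detects
  $\ge 95\%$ of true peaks at 10 dB SNR while keeping false alarms to a
  manageable level. An absolute $\gamma$ may be supplied instead.
* **Peak refinement.** A hit must also be the maximum of the raw trace
  within $\pm$ `dead_time` samples. The threshold crossing alone can sit a
  sample or two off the true extremum in noise; anchoring alignment at the
  local maximum is what makes downstream waveforms comparable.
* **Alignment geometry.** The emitted window has `peak_offset = 16`
  pre-peak samples out of `m = 64` (about 0.7 ms of depolarization onset at
  24 kHz, standard practice). Indices are 1-based throughout, the R
  convention.
* **Dead time.** `dead_time = m/2 = 32` samples suppresses re-detection of
  one spike; it is deliberately independent of the capacity parameter `Q`
  below.

## Streaming principal components (GHA)

Given aligned spikes $x \in \mathbb{R}^m$, the generalized Hebbian
algorithm (Sanger's rule) trains $p$ weight vectors $w_j$ that converge to
the leading eigenvectors of $E[xx^\top]$. With $y_j = w_j^\top x$, the
update is

$$w_{ji} \leftarrow w_{ji} + \eta\, y_j \Big(x_i - \sum_{k \le j} w_{ki}
y_k\Big),$$

which the implementation factors through the running residual
$z_j = z_{j-1} - y_j w_j$, $z_0 = x$ — the form a hardware datapath uses,
algebraically identical to the direct rule (property-tested to $10^{-12}$
relative). Features for clustering are the $p$ inner products $y_j$.

Choices that the source material leaves open:

* **Learning rate and epochs.** Defaults $\eta = 0.03$, 40 epochs over the
  detected-spike stream. On realistic detected-spike sets (a few hundred
  spikes), the second component's eigenvalue is small; at
  $\eta = 0.005$ and 10 epochs its weight vector is still near its random
  initialization (norm $\approx 0.2$), while the defaults chosen here
  converge it to the batch eigenvector (|cosine| $\ge 0.97$, unit norm) on
  the generator's study conditions. An optional $1/(1+n/\tau)$ decay is
  available and is what the Gaussian convergence tests use.
* **Initialization.** I.i.d. uniform$(-0.01, 0.01)$, seeded;
  bit-reproducible given seed and stream order (training is stream-order
  dependent, as for any stochastic-approximation rule).
* **Normalization.** Spike waveforms are scaled by their global maximum
  absolute amplitude into $[-1, 1]$ before training — required by the
  fixed-point range, applied in float mode too so the backends see the same
  numbers.
* **Sign.** Eigenvector sign is arbitrary; all comparisons use the absolute
  cosine.

The segment-streamed variant (`gha_update_segmented`) reproduces the
hardware's scheme of fetching vectors $L$ elements at a time: it only
reorders floating-point additions (agreement with the plain update to
$10^{-10}$; bit-identical when $L = m$) and costs $P = 2pb + 8$ clock
cycles per spike with $b = m/L$ — the calibrated latency model below.

## 17-bit fixed-point backend

The `fixed17` backend emulates the arithmetic of an ASIC datapath whose
stores are 17-bit signed fixed point. The published description fixes the
width but not the format split, rounding mode, or accumulator width, so the
package chooses and documents:

* **Q1.16** for stored samples and weights (range $[-1, 1 - 2^{-16}]$,
  LSB $2^{-16}$): both live in $[-1, 1]$ after normalization and weight
  vectors converge to unit norm.
* **Round-to-nearest-even, saturating overflow** (both configurable;
  truncation and wraparound are available for sensitivity studies).
* **Guard-bit registers for intermediates.** Feature values can reach
  $|y| \le \lVert x\rVert\,\lVert w\rVert \approx 2.5$ and residuals
  $|z| \le |x| + |y||w| \approx 2$ even for perfectly normalized inputs, so
  the $y$ and $z$ registers and the sum-of-products accumulator carry 6
  extra integer bits (same LSB). Quantizing them to Q1.16 instead
  saturates the first principal component's features and visibly corrupts
  training — with the guard bits, the emulated pipeline tracks the float
  pipeline to $2^{-10}$ per component per update and produces identical
  classification results on the bundled studies.

Quantization is exact on the grid (values are doubles that are integer
multiples of $2^{-16}$), idempotent, and property-tested against an
integer-arithmetic rational oracle.

## Capacity model of the shared datapath

All channels share one detection core and one GHA core. Three rates govern
how many channels $M$ the architecture sustains: the sampling rate $r_s$
(period $T_s$), the clock rate $r_c$ (period $T_c$), and the per-spike GHA
latency $P$ cycles. Round-robin sampling requires $M T_c \le T_s$. With
one-spike-per-channel buffers served first-come-first-serve, the worst case
has all $M$ channels firing at the minimum inter-peak gap $Q$ samples; no
spike is overwritten before service iff $M P T_c \le Q T_s$. Hence

$$M_{\max} = \begin{cases}
\lfloor (Q/P)(T_s/T_c) \rfloor & Q < P\\
\lfloor T_s/T_c \rfloor & Q \ge P.
\end{cases}$$

`latency_cycles()` implements $P = 2pb + 8$, the unique fit of the family
$a\,pb + c$ to the published latency column at $m = 64$, $p = 2$ (segment
lengths 1–32 give 264, 136, 72, 40, 24, 16 cycles); its extrapolation in
$p$ is a modelling assumption, not a measurement. `capacity_table()`
reproduces every published $M_{\max}$ entry, and the event-driven simulator
`stream_schedule()` confirms the bound is tight: worst-case traffic at
$M_{\max}$ loses no spikes, at $M_{\max}+1$ it must lose at least one
(property-tested over random $(Q, L, r_c)$ grids). Where a published
discussion cites "$L=8$ and $r_s = 1$ MHz", the rate is evidently the
clock rate $r_c$ ($r_s$ is 24 kHz throughout); the package treats it as
such. Whether the 8-cycle overhead scales with $p$ is not determinable
from the published latencies.

One behavioural choice the hardware description leaves open: when a new
spike overwrites an unserviced one, the stale queue entry is removed and
the channel re-enqueued at the tail, preserving most-recent semantics.
Under one-spike buffers the discard count is the same either way; only the
event log order differs. When a service start and a new hit coincide on a
cycle, the service is taken first.

## Synthetic recordings and the SNR convention

No public dataset accompanies the modelled study; recordings come from a
generator that emulates the standard extracellular simulators:

* **Templates** are smooth triphasic shapes — a sharp positive
  depolarization lobe (Gaussian SD 1.1–2 samples, i.e. 50–80 µs at
  24 kHz), a slower negative repolarization, a small after-wave — tapered
  to zero at the window ends and normalized to unit peak. Pairs are redrawn
  until distinguishable **in the peak-aligned geometry** (|correlation|
  < 0.80 after aligning maxima, < 0.95 at native offsets). Peak alignment
  forces every unit's maximum to the same window position, so native-offset
  correlation alone badly overstates separability; and the global extremum
  must be the positive lobe, because a peak-aligning detector can never
  align a trough-dominant unit.
* **Firing** is Poisson per unit (default 6 Hz, a typical cortical rate)
  thinned to a 3 ms refractory period; overlapping spikes from different
  units superpose. Each channel carries an independent realization.
* **Noise** is a 50/50 variance mixture of (a) dense low-amplitude
  spike-shaped background activity (5000 events/s, amplitudes 5–30% of a
  unit spike — the "correlated noise" regime of distant multi-unit hum)
  and (b) Gaussian noise band-limited to the 300–6000 Hz spike band.
  White noise at the full Nyquist band would be physically wrong and
  floods an energy operator that deliberately emphasizes high frequencies.
* **SNR** is defined on the **power scale over the spike extent**:
  $\mathrm{SNR}_{dB} = 10\log_{10}(\overline{x^2}/\sigma^2)$, the template
  mean square over its window divided by the noise variance, the
  convention of the simulator literature this generator emulates. The
  realized noise is rescaled so the definition holds exactly. The
  alternative amplitude-ratio reading ($20\log_{10}(\text{peak}/\sigma)$)
  would put 6 dB at $\sigma = 0.5$ of the peak — a regime in which energy
  detection collapses and no published classification rate near 97% is
  attainable — so it cannot be the convention behind the modelled study.

What passing tests on these recordings do **not** show about real data:
electrode drift, bursting amplitude adaptation, true cell-type waveform
statistics and cross-channel correlation are all absent, and every unit has
exactly unit peak amplitude. The generator is a controlled environment for
the *pipeline*, not a biophysical model.

## Clustering and scoring

Feature vectors of detections matched to ground truth (within ±3 samples
of a true peak) are clustered by fuzzy c-means — fuzzifier 2.0, tolerance
$10^{-6}$, at most 300 iterations, 5 seeded restarts keeping the best
objective; the per-iteration objective is recorded and its monotonicity
asserted on every run. The classification success rate (CSR) is the
fraction of matched spikes whose cluster agrees with their unit under the
best injective cluster-to-unit assignment (exhaustive over $k \le 8$).
Unmatched detections are false alarms: they are reported separately and
excluded from the CSR, which scores classification, not detection. The FCM
is implemented in the package (the objective trace and seeded determinism
are part of its contract) and is cross-checked against an independent
implementation in the test suite.

## Problem sizes and reproducibility

The bundled studies use 10 s two-unit recordings at 24 kHz, SNR levels 6,
8 and 10 dB, ten generator seeds per level, `p = 2` components and
`k = 2` clusters — roughly a hundred true spikes and a comparable number
of background false alarms per run, which is enough for the per-level mean
CSR to be stable to well under one point. Every random draw flows from an
explicit integer seed (generation, weight initialization, FCM restarts),
so all results in the README and test suite are exactly reproducible.

Known limitations: the latency model's 8-cycle overhead is calibrated at
$p = 2$ only; CSR point values of the modelled study are not reproducible
because its simulator parameters are unpublished (the package reproduces
the bounds and orderings instead); and the capacity analysis assumes
identical $Q$ across channels, as the worst-case argument requires.
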