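---
title: "Detecting vital activity in FMCW radar chirps under analog-hardware constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting vital activity in FMCW radar chirps under analog-hardware constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalchirp)
```

vitalchirp detects human respiratory activity in data produced by
frequency-modulated continuous-wave (FMCW) radar, with a classifier designed
to satisfy the constraints of analog VLSI neural hardware: weights stored at
4 bits plus sign, and physical neurons with at most six inputs. This
vignette is the package's account of the underlying models, the choices
that were genuinely open, and what the synthetic experiments do and do not
show.

## Signal model

An FMCW radar mixes each emitted chirp with its echo; a reflector at
distance $d_i$ appears as a harmonic of intermediate frequency (IF)
$\Delta f_i \propto d_i$ in the digitised in-phase/quadrature pair. A scan
on one TX--RX channel is modelled as

$$p_j = \sum_i A_i \cos(2\pi \Delta f_i\, j + \phi_i) + N_j,\qquad
  q_j = \sum_i A_i \sin(2\pi \Delta f_i\, j + \phi_i) + N_j,\qquad
  j = 1 \ldots n,$$

with i.i.d. Gaussian acquisition noise $N_j$. Motion enters through the
phase: a displacement $\Delta d$ advances $\phi_i$ by
$\Delta\phi = 4\pi f \Delta d / c$ with carrier $f$ = 79 GHz, so phases wrap
every half wavelength ($c/2f \approx 1.9$ mm) while the IF stays essentially
fixed for millimetre motion. The simulator holds $\Delta f_i$ constant by
default (a `full_physics` flag also shifts IF with distance for robustness
experiments).

Chirps are acquired as trains of three scans at 1 kHz, with trains starting
every $T_s = 50$ ms; a train is averaged element-wise into a filtered scan,
dividing the noise variance by three. Within a train the simulator freezes
reflector displacement at the train start time. This is a deliberate
modelling decision, not an approximation of convenience: the signal model
treats the subtracted chirps as sharing amplitudes and IFs, and at 79 GHz
even the sub-40-µm motion accumulated over a 2 ms train shifts phase by
~0.1 rad, which would make the train average differ from a clean snapshot
and break the exact correspondence between the pipeline and the closed-form
descriptor below. The physically moving-within-train variant is available
under `full_physics`.

$T_s = 50$ ms is chosen so that all four studied subtraction delays
(100/150/250/400 ms) are integer multiples of it.

## The motion descriptor

Filtered scans $\bar p^t, \bar q^t$ separated by a delay $\Delta t$ are
subtracted element-wise (differential chirps), and each channel is
summarised by the mean energy

$$f_t = \frac1n \sum_j \left(\Delta p_j^2 + \Delta q_j^2\right).$$

Static reflectors cancel exactly in the subtraction. For a single
reflector of amplitude $A$ whose phase advances by $\Delta\phi$, the
differential components are complementary harmonics of magnitude
$2A\sin(\Delta\phi/2)$, so

$$f_t = 4A^2\sin^2(\Delta\phi/2)$$

*exactly* (because $\cos^2+\sin^2=1$ sample by sample). `analytic_descriptor()`
implements this closed form and serves as the independent oracle for the
full pipeline in the tests; agreement is at machine precision
(relative error below $10^{-9}$ by test, ~$10^{-15}$ in practice). The
descriptor inherits the phase-wrap periodicity: net displacements differing
by $c/2f$ are indistinguishable.

Descriptor sequences are cut into non-overlapping observation windows of
2, 6 or 12 s. The first $\Delta t / T_s$ steps of each recording have no
subtraction partner and are dropped (warm-up); windows never cross
recording boundaries. A zero-phase Butterworth band-pass tuned to the
breathing range (0.1--1 Hz, from cycle durations of 2--8 s and a 1 Hz
maximum rate) is provided via `bandpass()` but is **off by default**: the
step-by-step extraction procedure the pipeline follows does not apply it,
and the descriptor's nonlinearity moves much of the breathing signature
above the breathing band (see below), so filtering there is not obviously
helpful. It remains an explicit opt-in rather than a guessed-at mandatory
stage.

Whether descriptor values should be rescaled before classification is
resolved the same way: the classifier's optional input batch normalization
is the only normalization in the pipeline.

## Scenes and the synthetic data generator

Scenes mirror a two-class indoor taxonomy: humans (single, multiple,
optically hidden) against empty rooms, rotating fans, a reciprocating
robotic arm, and randomly moving curtains. Key generator choices, made once:

* **Breathing** is sinusoidal chest displacement with rate drawn from
  0.125--0.5 Hz (2--8 s cycles, capped at 1 Hz) and amplitude 2--6 mm —
  typical quiet-breathing chest-wall excursion. At a 1.9 mm half
  wavelength these amplitudes put scenes anywhere between a gentle
  single-lobe energy modulation and several phase wraps per breath; the
  breathing rate and amplitude jointly set this wrapping regime, which is
  the dominant source of within-class variability.
* **Distractor calibration**: fan and arm periods are drawn from the same
  2--8 s interval and their amplitudes from the same millimetre range as
  breathing, so neither rate nor amplitude alone can separate the classes;
  only the temporal pattern can.
* **Fan** displacement is a periodic sawtooth (quasi-linear approach of the
  sweeping head/blade, then reset). A sinusoidal fan with matched period
  and amplitude would be mathematically identical to the breathing model
  and the classes would be unseparable by construction, contradicting the
  premise that patterns are class-specific; the sawtooth keeps the fan
  periodic and parameter-matched while retaining its own signature.
  The **arm** is triangular (constant-speed reciprocation), the **curtain**
  a clipped Gaussian random walk on the $T_s$ grid.
* **Hidden humans** are attenuated by an amplitude factor 0.3; every scene
  contains static clutter; channel diversity is realized as fixed
  per-reflector, per-channel phase offsets drawn uniformly in $[0, 2\pi)$
  at scene creation (no antenna geometry is modelled — a documented
  simplification).
* **Noise** is additive Gaussian with $\sigma = 0.1$ per sample against
  reflector amplitudes of order one, giving an empty-room descriptor floor
  of $4\sigma^2/3 \approx 0.013$, well below the weakest (hidden-human)
  motion signals.
* All randomness derives from one integer seed through a keyed
  linear-congruential split (`derive_seed`), so scenes, recordings and
  training runs are exactly reproducible.

What the generator deliberately does **not** model: multipath propagation,
antenna-array geometry and beamforming, RF front-end impairments beyond
additive Gaussian noise, breath-to-breath variability, and non-respiratory
human micro-motion (heartbeat, fidgeting). Passing tests on this generator
therefore show that the pipeline and training machinery behave as designed
on data with the assumed statistical structure — not that the detector
would reach the same accuracy on real indoor recordings, whose descriptor
patterns are substantially messier.

## The classifier

Architectures follow the `C{c}-W{w}-L{l}[-X]` encoding: `c` input channels
(1, 3 or 12), `l` stacked GRU layers (3--9) of `w` units (6--16), a
two-neuron fully connected head reading the final time step, and `-X`
marking input batch normalization plus inter-layer dropout
(exclusion probability 0.3) during training. The GRU cell uses one fixed
convention everywhere: two bias vectors per gate (each gate neuron
processes its inputs, the recurrent state, and two biases), the reset gate
applied to the recurrent contribution inside the candidate, and
$h' = (1-z)\odot h + z\odot\tilde h$. Initial states are zero. Weights are
initialized uniformly in $\pm 1/\sqrt{\text{fan-in}}$ and biases at zero.

`count_params()` counts $3W(I + W + 2)$ per layer, $2(W+1)$ for the head,
and $2C$ for batch normalization; the tests verify the formula against
enumeration of the actual parameter containers. These counts intentionally
make no claim of matching any externally printed table; the convention is
documented and self-consistent.

Physical neurons admit at most six inputs, so every wide dot product is
decomposed by `fanin_plan()` into a tree of partial-sum units (at most two
levels whenever $\lceil n/6\rceil \le 6$); the decomposition is exact up to
floating-point summation order, verified to $10^{-12}$.

## Training and quantization

Training is Adam on categorical cross-entropy. Quantization-aware runs use
the two-component loss $L = L_{CCE} + \lambda L_Q$ with the periodic
penalty

$$L_Q = \sum_i \left|\sin\!\big[(2^B - 1 - (B\bmod 2))\,\pi\, w_i\big]\right|,$$

whose minima are exactly the $2^{B+1}-1$ codebook levels $m/(2^B-1-(B\bmod 2))$
in $[-1,1]$ (31 levels at $B=4$; the $(B\bmod 2)$ correction makes the
even-$B$ codebooks come out at a power-of-two count of magnitudes — 16 at
$B=4$ — matching hardware programmability; odd $B$ is permitted but
flagged experimental). $L_Q$ is applied to *normalized* weights: each
neuron's weight vector (gate row or head row, biases appended as weights on
constant inputs) is mapped to $[-1,1]$ by

$$\hat w_j = \frac{2w_j - w_{max} - w_{min}}{w_{max} - w_{min}},\qquad
  k = \frac{w_{max}-w_{min}}2,\qquad B_{off} = \frac{w_{max}+w_{min}}2,$$

recomputed every forward pass with a straight-through gradient for the row
extrema (the extremal weights sit at $\hat w = \pm1$, a penalty minimum,
and receive a zero subgradient there — a kink-tolerance of $10^{-9}$ on
$|\sin|$ avoids floating-point sign noise at the zero crossings). The
quantization loss is activated at epoch 6 of 20, after the network has
learned basic discrimination.

$\lambda$ requires care: because the penalty is a sum of $|\sin|$ terms,
its per-weight gradient magnitude is $\lambda\,\cdot\,$`multiplier`$\,\pi
\approx 47\lambda$ *independent of how far the weight is from the
codebook*. Any $\lambda$ for which this exceeds typical task-gradient
magnitudes turns the penalty into a hard projection: under Adam's
per-parameter normalization every weight marches to its nearest codebook
level within a few updates and cross-entropy learning effectively stops —
at $\lambda = 1$ this demonstrably produces the very accuracy collapse the
two-component loss is meant to avoid. The default $\lambda = 10^{-5}$
keeps the pull one to two orders of magnitude below the task gradients at
the benchmark scale, acting as a regularizer. Weights the pull has not
fully discretized lose nothing at deployment: thanks to the per-neuron
renormalization, the final rounding error is at most half a codebook step
times the neuron's own scale, which the benchmark shows to be benign.

The neuron scales $k$ and offsets $B_{off}$ must also satisfy the 4-bit
constraint, and they are hard quantized *during* the quantization phase:
from the activation epoch on, the forward pass runs on the deployable
affine form (normalized weights times codebook-coded scale, plus
codebook-coded offset), with a straight-through gradient to the raw
weights, so the task loss compensates the scale rounding while training.

As printed, the identity $x^\top w = k\,(x^\top \hat w) + B_{off}$ is
dimensionally inconsistent; the offset must act through the input sum, and
the package uses $x^\top w = k\,(x^\top\hat w) + B_{off}\sum_j x_j$, which
holds exactly and is realizable in hardware as one extra synapse on a
constant input. `affine_dot()` implements this dataflow and the tests hold
it to $10^{-12}$.

After the final epoch the network is hard quantized: normalized weights are
rounded to the nearest codebook level (ties away from zero, documented),
and the per-neuron scales and offsets are themselves stored as codebook
codes against per-layer references $k_{ref} = \max_i |k^i|$,
$B_{ref} = \max_i |B_{off}^i|$. Because each layer's extremal neuron maps
to code $\pm 15$ exactly, quantization is idempotent. Batch-normalization
parameters are not separately quantized: they are folded into the first
layer's input weights and biases before quantization, so the deployed
forward pass uses only quantized quantities. The naive baseline
(`naive_quantize()`) rounds every weight of a float-trained model directly
onto the shared $[-1,1]$ codebook with no per-neuron renormalization.

## The synthetic benchmark and its scale

The end-to-end benchmark (`benchmark_run()`) is fixed in code: a 40-minute
simulated campaign of 120 independent 20-second recordings balanced over
all seven presets, three acquisition channels, $\Delta t = 250$ ms, 6 s
windows, an 80/20 recording-level split stratified by preset, and the
C3-W8-L3-X architecture trained 20 epochs per seed (float, QAT, and naive
quantization of the float model). Problem sizes were chosen to keep a full
five-seed comparison within a few minutes on one CPU.

Two scale-down decisions deserve justification:

* **Many short recordings.** Each recording is an independent scene draw,
  and the wrapping regime (rate × amplitude) varies so much between draws
  that coverage of scene space is the binding constraint at this scale —
  a few long recordings leave entire regimes unseen at test time. The
  per-category duration profile of a realistic campaign
  (`indoor_duration_profile()`) is kept separately for windowing
  arithmetic.
* **Scaled-down schedule.** The full-scale protocol (20 epochs, Adam,
  batch 64) presumes thousands of windows; with ~300 windows it yields
  only ~100 optimizer updates, which demonstrably undertrains. The
  benchmark schedule keeps 20 epochs but uses batch 8, step size
  $5\times10^{-3}$ and global gradient-norm clipping at 5 (standard
  recurrent-network practice), restoring an update count comparable to the
  full-scale setting. `train_schedule()`'s defaults remain the full-scale
  ones.

### A known limitation: dynamic range and hidden humans

Descriptor energies span about four orders of magnitude across scenes
(empty-room floor ~0.013; hidden humans ~0.25; multiple visible humans
~10). The pipeline's only normalization is linear (input batch
normalization), so after standardization the hidden-human signal is an
O(0.05) perturbation around the empty-room level. The information is
present, and the test suite verifies it with two probes: a random-forest
classifier on log-energy and spectral-shape summaries of the very same
windows recovers held-out hidden humans, and the same GRU trained on the
hidden-vs-empty subproblem alone (where batch statistics rescale the
signals to O(1)) separates them as well. But within the fixed 20-epoch
budget the full-task GRU does not allocate the needed input amplification,
and hidden humans dominate its errors. Held-out float accuracy on the
benchmark therefore plateaus around 0.75 (roughly the ceiling implied by
always missing the hidden-human sixth of the test windows) rather than
the ≥0.9 a dynamic-range-compressed front end would allow. We report this
honestly rather than compressing the descriptor (which would change the
published feature definition) or easing the generator (hidden-human
attenuation and matched distractors are part of the study conditions).
The quantization comparison is unaffected by this plateau: across
training seeds, hard-quantized QAT typically tracks the float model
within a few points while naive direct rounding does not beat it.

### A second scale effect: window length

At full scale, longer observation windows help — they cover several
breathing cycles. At a fixed 40-minute recording budget the opposite
holds: cutting 2 s windows instead of 12 s multiplies the number of
training samples by six, and the same architecture then exceeds 0.9
held-out accuracy (hidden humans included — with ~2900 optimizer updates
the needed input amplification *is* learned), while 12 s windows with a
sixth of the samples and 240-step backpropagation stay around 0.7. The
effect persists even at matched sample counts, implicating the longer
credit-assignment path as well. The benchmark keeps 6 s windows — the
shortest duration the full-scale study retains for its final evaluation —
so its numbers understate what the architecture achieves at this scale
when the window hyperparameter is chosen to favour sample count; the
acceptance script reports the 2 s/12 s comparison alongside the 6 s
benchmark.

## Numerical choices

* Hard-quantization ties round away from zero; idempotence is exact.
* `hard_quantize` clamps values beyond the codebook ends.
* Degenerate (constant) neuron rows map to $\hat w = 0$, $k = 0$,
  offset $= w$.
* Batch-norm inference uses running statistics (momentum 0.1);
  $\epsilon = 10^{-5}$.
* Softmax/cross-entropy use max-shifted logits; training aborts with a
  diagnostic on non-finite loss.
* Argmax ties in prediction resolve to the first (no-humans) class,
  deterministically.
* Recording and checkpoint JSON containers store arrays as base64
  little-endian float64 because 15-significant-digit decimal JSON does not
  round-trip doubles bit-exactly.
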