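---
title: "Multi-domain entropy and the dynamic synapse classifier: methods"
author: "dyscmde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain entropy and the dynamic synapse classifier: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyscmde)
```

## The problem and the model

Seizure onset in EEG is a transition from complex, broadband,
desynchronized activity to low-dimensional rhythmic order — clinically,
high-amplitude spikes, sharp waves and ~3 Hz spike-and-wave complexes.
`dyscmde` detects this transition by measuring signal complexity in three
domains at once and classifying the grouped measurements with a network
whose architecture mirrors that grouping.

### Amplitude-sensitive permutation entropy

Ordinary permutation entropy counts ordinal patterns of delay-embedded
vectors and is blind to amplitude.  The amplitude-sensitive variant
weights each embedded vector by its coefficient of variation
$w_i = \mathrm{sd}(Y_i)/|\overline{Y_i}|$, so the high-amplitude
excursions that characterize epileptiform activity dominate the pattern
distribution.  The entropy of the weighted distribution is normalized by
$\log_2 m!$, giving a value in $[0,1]$: exactly 0 for any strictly
monotone series (a single pattern), near 1 for iid noise with
well-behaved weights.

Two properties follow from the definitions and are enforced by tests:
the value is invariant under positive rescaling $x \mapsto a x$ (patterns
and coefficients of variation are both scale-free), and the weighted
probabilities always sum to 1.

One property of the weighting deserves a note: for zero-mean noise the
denominator $|\overline{Y_i}|$ is frequently near zero, making the weight
distribution heavy-tailed; a handful of vectors can then carry much of
the mass and the entropy of, e.g., zero-mean Gaussian noise sits well
below 1.  This is inherent to coefficient-of-variation weighting, not a
numerical artifact; iid *uniform* noise (positive mean) scores above
0.99.

### The three extensions

- **RCMASPE** (refined composite multiscale): at scale $s$, the $s$
  phase-shifted coarse-grained subsequences are each reduced to a pattern
  distribution, the distributions are averaged bin-wise, and one entropy
  is taken from the average.  Averaging distributions rather than
  entropies is what stabilizes large scales on 4097-sample records.
- **HASPE-DWT** (hierarchical): an $L$-level db4 decomposition, each
  coefficient set inverted with all others zeroed to give a band signal
  of the original length, and ASPE computed per band, ordered
  $[A_L, D_L, \dots, D_1]$.
- **TSMASPE** (time-shift): the mean ASPE of the $k$ stride-$k$ decimated
  subsequences, as a function of $k$.

### The classifier

The grouped features $x_m$ (ASPE + RCMASPE, 11 values at the defaults),
$x_h$ (HASPE-DWT, 5), $x_t$ (TSMASPE, 10) enter three pathways, each with
a gate matched to the group's semantics:

| pathway | gate | form | rationale |
|---|---|---|---|
| hierarchical | band attention | $x_h' = x_h \odot \tanh(x_h \odot W_h^{att})$ | input-dependent amplification of discriminative bands |
| time-invariant | stability gain | $x_t' = e^{-\gamma \mathrm{Var}(x_t)} x_t$ | consistent lag profiles pass; erratic ones are damped |
| multiscale | static mask | $x_m' = x_m \odot W_m^{att}$ | input-independent saliency of scales |

Each modulated group passes a tanh compression layer (width 16), the
concatenation passes one tanh fusion layer (width 32) and a linear
softmax output.  Training minimizes the cross-entropy by full-batch BFGS
capped at 50 iterations, using the analytic gradient of the whole
composition (including the chain through softplus for $\gamma$ and
through the sample variance of $x_t$).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m`, `tau` | 3, 1 | embedding dimension and delay (samples); $m=3$ keeps $m!=6$ patterns estimable from short subsequences |
| `s_max` | 10 | maximum coarse-graining scale (samples per window) |
| `level`, `basis` | 4, db4 | wavelet depth and family; 4 suits 173.61 Hz records, 5 suits 256 Hz |
| `k_max` | 10 | maximum decimation stride |
| `hidden_pathway`, `hidden_fusion` | 16, 32 | widths of the compression and fusion layers |
| `max_iter` | 50 | BFGS iteration cap (the function-evaluation budget of 1e6 never binds first) |
| `n_folds` | 10 | cross-validation folds; 20 is the common alternative |

## Design choices at genuinely open points

- **Zero-mean embedded vectors.**  The coefficient of variation is
  undefined at mean 0.  The denominator is floored at
  $10^{-12}\cdot\mathrm{range}(x)$ (or $10^{-12}$ if the range is 0):
  weights stay finite and nonnegative, and because the floor scales with
  the signal, positive-rescaling invariance is exact.  A signal with zero
  total weight (constant) falls back to unweighted frequencies, scoring 0.
- **Standard deviation and variance denominators** use $n-1$ (the
  default of the numerical environments this family of methods is
  usually developed in); a `sd_denom` switch selects $n$.
- **Ordinal ties** break by original index (stable sort), the dominant
  convention in the permutation-entropy literature.
- **Wavelet boundary extension.**  The default is linear extrapolation
  from the edge slope ("smooth").  With mirror (symmetric) extension, a
  purely monotone trend generates genuine boundary kinks in the detail
  bands, and the package's structural guarantee that *any strictly
  monotone series scores 0 in every feature* would fail.  Under linear
  extrapolation, db4's four vanishing moments annihilate polynomial
  trends everywhere, so detail bands of trend-only signals are
  numerically zero.  Symmetric extension remains available
  (`extension = "symmetric"`); both modes reproduce the standard
  reference implementations of the transform to machine precision and
  both reconstruct perfectly.
- **Numerically constant bands.**  A reconstructed band with
  $\mathrm{sd} \le 10^{-10}\,\mathrm{rms}(x)$ holds only floating-point
  residue; its "patterns" would be rounding noise.  Such bands score 0.
- **Feature standardization.**  The gating expressions are
  scale-sensitive ($\tanh(x\odot W)$, $e^{-\gamma\mathrm{Var}}$), so
  features are z-scored per column with statistics fitted on the
  training fold only (scale floored at $10^{-12}$; constant columns map
  to 0).  Switchable off via `standardize = FALSE`.
- **Fusion depth.**  The cross-pathway integrator is one hidden tanh
  layer of width 32 followed by the linear output: exactly one fusion
  width is part of the method's configuration, and a single hidden layer
  realizes it without inventing unstated depth.
- **Initialization.**  Attention and mask vectors start at 1 and
  $\gamma$ at 1 (neutral, pass-through gates, so early optimization sees
  undistorted features); fusion and output weights are uniform
  $\pm 1/\sqrt{\text{fan-in}}$ from a fixed seed; biases 0.  The seed is
  the only source of randomness in training.
- **Multi-class metrics** are macro-averaged one-vs-rest, with per-class
  values also reported and the macro F1 defined as the harmonic mean of
  macro precision and macro recall, so the identity
  $F_1 = 2PR/(P+R)$ holds at every level of the report.  Zero-denominator
  metrics return 0 and set a flag rather than NaN.
- **Fold remainders**: when a class is not divisible by the fold count,
  earlier folds receive the extra samples (block sizes differ by at most
  one).

## Numerical safeguards

Softmax subtracts the row maximum; cross-entropy floors probabilities at
$10^{-15}$ (natural log); $0\log 0 = 0$; normalized entropies are clamped
into $[0,1]$ against $\pm 10^{-16}$ rounding residue; $\gamma > 0$ is
guaranteed by softplus reparameterization, keeping BFGS unconstrained.
In gradient verification, central differences at $h=10^{-6}$ resolve
derivatives only down to about $\varepsilon |L|/h \approx 10^{-10}$, so
relative comparisons floor the denominator at $10^{-4}$; coordinates of
real magnitude are compared genuinely relatively at $10^{-5}$.

## The synthetic generator

`generate_dataset()` emulates the two regimes a seizure detector must
separate: background as zero-mean $1/f^{\alpha}$ colored noise
($\alpha = 1$, the standard stylized EEG spectral fact), and ictal
activity as that background plus a 3 Hz spike-and-wave train (slow sine
plus a sharp once-per-cycle pulse, unit-RMS template) at an RMS amplitude
ratio of 3.  A three-class preset adds an interictal class: background
with sparse (1/s) isolated 20 ms spikes.  Defaults produce 4097 samples
at 173.61 Hz per signal and 100 signals per class.  Per-signal seeds
derive deterministically from the master seed and are recorded in a
manifest, so datasets regenerate bit-identically.

What the generator does *not* emulate: real electrode artifacts, muscle
and eye-movement contamination, inter-patient variability, non-stationary
background drift, or the morphology-rich variety of real epileptiform
discharges.  Passing the end-to-end tests therefore demonstrates that the
pipeline recovers class structure whose entropy signature matches its
design assumptions — not clinical performance on recorded EEG, which
requires the corresponding public recordings.

## Problem sizes used by the tests

The oracle-equivalence suites use 100 random series of length ≤ 50
(entropy), 50 signals of 256–4097 samples (wavelet reconstruction) and 20
random network configurations (gradient).  The end-to-end study is the
generator's default: 100 signals per class, 4097 samples each, 10-fold
sequential stratified cross-validation — the scale at which the
reference protocol operates on the classic single-channel benchmark.

## Known limitations

- The CHB-MIT-style path (EDF reading, 5-minute segmentation, per-case
  channel tables) is exercised on synthetic EDF fixtures only.
- ASPE of heavy-tailed weighted distributions converges slowly; values
  on very short series (< 10 embedded vectors) are dominated by a few
  weights.
- The fold protocol, following the reference protocol, does not enforce
  patient-wise separation; leave-subject-out validation is out of scope.
- BFGS stores a dense approximate Hessian: fine at the default ~2,200
  parameters, not intended for much wider networks.
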