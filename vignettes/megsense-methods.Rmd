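---
title: "Optimal MEG sensor selection for phrase decoding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal MEG sensor selection for phrase decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Whole-head MEG systems carry 200–300 cryogenic sensors; wearable
optically-pumped alternatives make it attractive to ask how *few* sensors
suffice to decode covert and overt speech from neuromagnetic signals.
`megsense` implements a complete pipeline for that question: condition
multichannel epochs, summarize each sensor by six oscillatory band powers,
decode five phrase classes with a cross-validated SVM, and rank sensors with
a greedy forward-selection wrapper whose objective is the decoder itself. A
stacked sparse autoencoder provides the dimension-reduction comparison arm.

Because no public recordings accompany this problem setting, the package
ships a synthetic neuromagnetic generator with planted, band-specific class
effects. Every stage of the pipeline is validated against that known ground
truth.

# Signal conditioning

Raw epochs (nominally 196 gradiometers, 4 kHz, −0.5 to 5 s around stimulus
onset) pass through a fixed chain:

1. **Low-pass** below 250 Hz with a 4th-order Butterworth filter.
2. **Notch** at 60 Hz and harmonics up to 240 Hz (2nd-order band-stop,
   Q = 30).
3. **Resample** to 1 kHz (direct decimation for integer factors — the
   low-pass already bounds the spectrum — polyphase otherwise).
4. **Channel rejection**: flat channels (sd < `flatEps`, default 1e-10) and
   channels whose log-variance z-score exceeds 5.
5. **Trial rejection**: any trial whose absolute peak exceeds a threshold on
   any channel. The default threshold is three times the median per-trial peak,
   which separates blink-scale transients (an order of magnitude above
   background) from clean trials on the generator's output.
6. **Balancing**: the first 60 trials per class in acquisition order.
7. **Window extraction**: imagination = [1, 2) s, production = [2, 3) s
   after onset; 1000 samples at 1 kHz.

All filtering is zero-phase (forward–backward application with
odd-reflection edge padding), so time-locked windows are not skewed by group
delay. Filtering precedes resampling. Manual trial inspection is replaced by
the amplitude-peak rule — reproducibility requires an automated criterion.
The production window is the first second after the articulation cue; it is
exposed as a `window` argument because the exact analyzed second is a
protocol choice, not a property of the method.

# Wavelet band-power features

Each windowed 1 kHz signal is decomposed with the Daubechies-4 wavelet to 7
levels. The first two details (125–500 Hz) are discarded as noise; the
remaining branches map onto the canonical bands

| band | branch | dyadic edges (Hz) | nominal label (Hz) |
|------|--------|-------------------|--------------------|
| high-gamma | d3 | 62.5–125 | 61–125 |
| gamma | d4 | 31.25–62.5 | 31–59 |
| beta | d5 | 15.6–31.25 | 16–30 |
| alpha | d6 | 7.8–15.6 | 8–16 |
| theta | d7 | 3.9–7.8 | 4–8 |
| delta | a7 | 0–3.9 | 0.03–4 |

Each branch is reconstructed alone back to the original length
(single-branch inverse transform), and its RMS over the 1-s window is one
feature: 6 features per sensor, 1176 for 196 sensors. The transform uses
symmetric boundary extension (the common default; it minimizes edge
artifacts on short windows), and the implementation satisfies perfect
reconstruction: the eight branch reconstructions sum to the input to within
1e-8 relative — one of the acceptance checks. RMS is computed on
reconstructed signals rather than raw coefficients, matching the
"reconstructed back to the sampling frequency" reading; the two differ only
through boundary handling.

# Decoding

A 2nd-order polynomial SVM with C = 1 (one-vs-one multiclass) is evaluated
by stratified 5-fold cross-validation: 12 trials per class per fold held
out, 48 per class for training. Feature columns are z-scored with
parameters fit on the training folds only — polynomial kernels are
scale-sensitive and RMS magnitudes differ by an order of magnitude across
bands. After scaling, the kernel is \((x \cdot x'/p)^2\) with \(p\) the
feature count, which makes results invariant to duplicating feature columns
(a property test). Chance level for five balanced classes is 20%, and the
permuted-label pipeline must sit there — the quantity the acceptance script
recomputes.

# Forward sensor selection

Step 1 cross-validates every sensor alone (6 features) and keeps the best.
Step *t* appends each remaining sensor to the fixed set \(O_1..O_{t-1}\)
and keeps the best addition, so step *t* costs exactly \(n - t + 1\) CV
evaluations (a tested counting contract). Design choices where the
procedure is underdetermined:

- **Frozen folds.** The fold assignment is drawn once per dataset and
  reused for every candidate at every step, so all comparisons are paired;
  re-randomizing folds per step would confound sensor effects with fold
  noise. (Per-step re-randomization can be had by passing a fresh
  `foldAssign`.)
- **Ties** break toward the lowest sensor index — determinism across runs
  and implementations.
- **Plateau** = first step whose successor strictly decreases accuracy
  (`findPlateau`), matching the observed convergence behavior at the 9→10
  transition in this method's home setting. For the across-subject reading,
  apply `findPlateau` to the mean curve from `selectionCurve`.
- Candidate evaluations within a step are independent; results are
  invariant to evaluation order.

Equivalence with an independently coded brute-force greedy loop is asserted
exactly for small problems (≤ 8 sensors, K ≤ 4, 10 random datasets).

# Stacked sparse autoencoder

The comparison arm embeds the 1176-dimensional features to 54 dimensions
(the feature size of 9 sensors) through three greedily pretrained sigmoid
autoencoders (600 → 300 → 54 hidden units), then fine-tunes the stacked
encoder with a softmax head before an SVM decodes the codes. Pretraining
minimizes

\[ \frac{1}{N}\sum_n \lVert x_n - \hat x_n \rVert^2
   \;+\; \frac{\lambda}{2}\lVert W \rVert^2
   \;+\; \beta \sum_j \mathrm{KL}(\rho \,\Vert\, \hat\rho_j), \]

with \(\hat\rho_j\) the mean activation of hidden unit *j*. Defaults:
\(\lambda = 0.002\) (grid 0.001–0.004), \(\beta = 4\), \(\rho\) =
0.20/0.15/0.10 per layer, ≤ 400 pretraining epochs. Two numerical notes:

- **MSE convention.** The reconstruction term is summed over output
  dimensions and averaged over samples. The \(\lambda, \beta\) scales above
  are calibrated to that convention; an element-averaged MSE
  under-weights reconstruction by a factor of the input width and training
  collapses to predicting column means.
- **Optimizer.** Scaled conjugate gradient is replaced by full-batch
  L-BFGS run in chunks, with the loss recorded at each chunk boundary;
  every chunk is a descent, so the recorded history is non-increasing and
  the convergence contract (final ≤ initial loss, finite throughout) holds.
  The loss, not the optimizer, defines the method.

Inputs are min-max scaled to [0, 1] per column (fit on training rows) so the
sigmoid decoder range covers its targets. Within cross-validation the
autoencoder is refit per fold on the training rows only — encoding is
label-free by interface, so no test information reaches the embedding. A
`singleSplit` mode mirrors the single train/test split variant.

# The synthetic generator

`simulateEpochs` emulates the acquisition protocol: 196 gradiometers
(positions on a 10 cm upper shell, left = negative lateral coordinate — a
fixed, documented sign convention), 5 classes × 60 trials, 4 kHz raw
sampling, −0.5 to 5 s epochs, "MEG####" channel names. Trials are Gaussian
background noise (white by default, 1/f optional — no noise model is
prescribed by the protocol) plus class-dependent oscillatory bursts during
the imagination and production windows.

Bursts are band-limited Gaussian noise synthesized in the frequency domain
(random phase on the in-band FFT bins, unit variance, Tukey-tapered). This
is the same statistical model as Butterworth-filtered noise — band *power*,
not phase, carries class information, matching the RMS features — but it
remains exact and stable down to the 0.03 Hz delta edge, where a 4th-order
IIR band-pass is numerically ill-conditioned.

The default planted map spreads 9 informative sensors evenly across the
array. Every informative sensor is active for *every* class, at one of two
amplitude levels (0.6× or 1.4× the nominal amplitude, a fixed balanced
binary code per class), and each trial's burst amplitude receives mean-one
lognormal jitter (sd 0.4). This design is deliberate: if each class owned a
private (sensor, band) signature, a handful of sensors would decode
perfectly, the CV objective would saturate, and sensor ranking beyond that
point would be decided by tie-breaking — a degenerate regime in which no
selection algorithm can demonstrate recovery. With overlapping amplitude
patterns and trial-to-trial power variability, accuracy instead grows
steadily as sensors accumulate and plateaus near the planted-sensor count,
with the full 49-sensor array *below* the 9-sensor optimum (nuisance
sensors dilute the polynomial kernel) — the qualitative selection-curve
shape the method exists to exploit. The nominal amplitude (2× background
sd) and jitter were chosen once as a plausible effect-size regime for
task-band MEG power and are not calibrated to any recorded dataset.

What the generator does *not* emulate: forward-model field spread
(sensor correlations), head movement, cardiac/ocular physiology beyond the
stylized blink transient of `injectArtifacts`, or inter-subject anatomical
variability (synthetic "subjects" are independent seeds sharing planted
structure). Passing tests therefore demonstrate algorithmic correctness
and recoverable-signal behavior, not performance on real recordings.

# Problem sizes used by the test and acceptance runs

Validation runs use scaled configurations chosen to exercise every code
path at desk scale: structural checks at the full 196-sensor width (few
trials), chance-level calibration and the acceptance script on 12–24
sensors × 300 trials with 20 label permutations, greedy-oracle equivalence
on ≤ 8 sensors, recovery on 49 sensors (9 planted, amplitude 2× noise sd,
5 seeds, 12 selection steps), and autoencoder parity on 20 sensors with a
96/72/54 stack in a strong-effect regime (amplitude 5× noise sd, jitter
0.2) where both arms operate near ceiling and the comparison isolates the
embeddings rather than residual trial noise. These sizes are the package's
validation design; all defaults remain at the full protocol scale.

# Known limitations

- Greedy forward selection is myopic; backward elimination and floating
  search are out of scope.
- The autoencoder's per-subject hyperparameter grids are exposed as ranges,
  not fitted values.
- Anatomical attribution of selected sensors (e.g. proximity to speech
  areas) requires a head model and is deliberately not asserted from
  sensor ids.
- FIF import and HDF5 containers are not provided; epochs interchange uses
  the plain-text container of `writeEpochsDir` (CSV + JSON), features TSV,
  results JSON.
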