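---
title: "Methods: automated sleep staging for mouse EEG/EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated sleep staging for mouse EEG/EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scoring problem

Mouse sleep research scores vigilance in three states — WAKE, non-REM and
REM — from paired EEG (cortical surface) and EMG (neck muscle) voltage
recordings, divided into fixed 20-second epochs that each receive one label.
The stages have canonical signatures: WAKE shows mixed-frequency EEG with
high muscle tone; non-REM shows high-amplitude, delta-dominant (1–4 Hz) EEG
with reduced tone; REM shows theta-dominant (6–9 Hz) EEG with near-total
atonia. Stage *sequences* are also structured: stages persist in bouts, REM
bouts last tens of seconds to minutes, and REM essentially never follows
WAKE directly in healthy animals. A good automated scorer must exploit both
the within-epoch signal content and this between-epoch dynamics.

`sleepscorer` implements a convolutional/recurrent scorer for this problem,
a certainty-gated REM rescoring pass, a hand-crafted-feature random-forest
baseline, the standard agreement metrics, and a synthetic polysomnography
generator that makes the whole pipeline testable without animal data.

## Signal preprocessing

EEG epochs enter the network raw: spectral transforms are deliberately
avoided so the convolutional extractor can learn its own filters. EMG is
passed through a one-second moving root-mean-square filter, since for
muscle tone the amplitude envelope, not the frequency content, carries the
information. Two filter conventions are provided:

* `mode = "paper"` (default): $y_t = \frac{1}{F_s-1}\sqrt{\sum_{i=1}^{F_s} x_{t-i}^2}$,
  with the normalization outside the square root. This follows the
  formulation of the method as published; it is not unit-preserving (a
  constant $c$ maps to $c\sqrt{F_s}/(F_s-1)$), and the two modes differ
  only by that constant factor, so the choice cannot affect what a
  downstream scale-free learner can represent.
* `mode = "standard"`: the textbook RMS $\sqrt{\frac{1}{F_s}\sum x_{t-i}^2}$,
  for users who want unit-preserving envelopes. It is plausible that the
  published normalization was a typographical slip of this form, which is
  why both are exposed.

The filter window is the $F_s$ samples *preceding* $t$. The first second has
no full history; we reflect-pad the first second rather than zero-pad, which
would otherwise create a spurious upward ramp in epoch 0.

Optionally (default in the scoring pipeline) both channels are z-scored per
record. Electrode impedance and amplifier gain vary across animals; the
normalization bounds that variation before the network sees the data. Note
the z-scored RMS-EMG is no longer non-negative; the un-normalized filter
output is available by turning the flag off.

The default sampling rate is 250 Hz — the rate at which a 20-s epoch holds
5,000 samples, matching the feature definitions of the random-forest
baseline below. Every component accepts other rates.

## Network architecture

The feature extractor runs three 1-D convolutional branches per epoch:

* a **narrow-filter EEG branch** (first-layer filters of half a second,
  stride rate/16) tuned to high-frequency content;
* a **wide-filter EEG branch** (filters of four seconds, stride rate/2)
  tuned to low-frequency content;
* a **wide-filter EMG branch** — one branch only, because after RMS
  filtering the EMG envelope is smooth and needs no high-frequency path.

Each branch is conv → max-pool → dropout → three same-padded convs →
max-pool, with ReLU activations; the three flattened outputs are
concatenated into the epoch's feature vector. The published description of
this architecture specifies the branch layout and layer inventory but not
every kernel size; the numeric geometry here is a documented
reconstruction following the deep human-sleep scorer that inspired it, and
every number is overridable through `sleep_model_config()`.

The scoring head reads a **context window of 25 epochs** (12 past, the
target, 12 future — the symmetric reading of a bidirectional model) through
a two-layer bidirectional LSTM (1,024 units per layer at full scale, half
per direction, modelling forward and backward stage transitions), in
parallel with a fully-connected shortcut (1,024 units) on the target
epoch's own features. The two paths are projected to a common width and
combined by element-wise addition — the FC path lets the model assert an
"isolated" epoch against the recurrent smoothing — then dropout and a
3-way softmax produce per-stage certainties. The label is the argmax, ties
broken in the fixed order WAKE < NREM < REM.

Two variants replace the head: `pretrain_head` substitutes a per-epoch
softmax (used during pretraining), and `rescoring` drops the recurrent
block entirely, keeping FC + softmax, so it can contradict the neighbours.

Other defaulted choices the description leaves open: dropout rate 0.5;
initialization uniform with fan-in scaling $U(\pm\sqrt{1/\text{fan-in}})$,
LSTM forget-gate biases at 1; the element-wise add combines the recurrent
output with the FC shortcut (rather than summing LSTM layers), which is the
reading consistent with the shortcut's stated role.

`scale` multiplies all widths; `scale = 1/8` (128 LSTM units, 128 FC units,
8/16 channels) is the desk-size instance used throughout the tests. Scaling
preserves the architecture, so structural claims transfer; accuracy claims
at full scale on real data of course do not follow from synthetic runs.

## Training

Training is two-step:

1. **Pretraining** optimizes the extractor under the temporary per-epoch
   softmax, on a stage-balanced training set: REM is ~5% of epochs, and
   undersampling to the minority count stops the extractor from ignoring
   it. Cross-entropy loss
   $L(Y,\hat Y) = -\frac{1}{N}\sum_i \mathbf{y}_i\cdot\log \hat{\mathbf{y}}_i$
   (predictions clipped at $10^{-12}$), Adam optimizer.
2. **Fine-tuning** restores the full scoring head, transfers the extractor
   weights, and trains everything end-to-end at a smaller learning rate to
   avoid overfitting the now-unbalanced data.

Fine-tuning batches are **non-overlapping 25-epoch sequences** that never
cross a record boundary, with the loss evaluated at every sequence
position. The alternative — sliding a window one epoch at a time and
training on the center label only — re-feeds each epoch through the
extractor 25 times per pass for the same gradient information; the
sequence-labeling form gives each labeled epoch exactly one contribution
per pass and is what makes CPU-scale training practical. The chunking
phase is re-drawn every pass: with a fixed phase an epoch would always
occupy the same within-sequence position and bout transitions would only
ever be trained with one truncated context. Inference still
slides the window and reads the center position, where bidirectional
context is fullest; the two are consistent because the head is applied
position-wise.

Two optimizer profiles ship with the package. `training_plan("paper")`
carries the published full-scale settings: Adam with learning rates
1e-4 (pretrain) and 1e-6 (fine-tune), batch sizes 100 and 10, 10 and 20
passes. Those rates are matched to runs of millions of optimizer steps. A
desk-scale run makes hundreds of steps, where 1e-6 cannot move a freshly
initialized head off its random start, so the default profile
`training_plan("desk")` keeps the structure, batch sizes and pass counts
but uses 1e-3/1e-4 — preserving the defining constraint that the
fine-tuning rate is the smaller one. Adam moments are the conventional
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$; a global
gradient-norm clip of 5 guards the batch-of-10 fine-tuning stage.

With a fixed seed the whole run is bit-reproducible: all shuffling,
balancing and initialization draw from R's seeded RNG, and dropout masks
are generated in the compiled engine from seeds drawn in R, with a
platform-independent generator.

## REM rescoring

The trained scorer under-calls REM: REM is rare, so the network builds
conservative criteria for it, and isolated REM epochs get smoothed over by
the recurrent context. Diagnostically, most missed REM hides among
*low-certainty non-REM calls*. The rescoring pass therefore collects
epochs labeled non-REM with non-REM certainty strictly below 0.95 (strict
because the rule is "lower than"; the boundary case stays), and re-examines
only those with the recurrence-free `rescoring` variant, trained on exactly
those candidate epochs with their expert labels. Because missed REM
concentrates in the candidate set, its class balance is far less skewed
than the full data's — the benchmark reports both fractions. The rescoring
model keeps all three output classes (a re-examined epoch may also resolve
to WAKE), its extractor starts from the trained full model's branches, and
candidates are judged independently, without sequence context — forced by
the missing recurrent block. One pass only; epochs labeled WAKE or REM are
never touched. A structural consequence worth noting: because only
non-REM-labeled epochs are eligible to change, the pass can never lower
REM recall.

An empirical finding of the desk-scale benchmark: on clean synthetic data
the trained scorer saturates — every non-REM call carries certainty above
0.95, isolated REM epochs included (their distinctive theta-plus-atonia
signal is recognized outright) — so the candidate set is empty and the
rescoring pass is an identity. The benchmark reports this (zero
candidates) rather than failing; the rescoring machinery itself is
validated at module level, where less-trained models produce spread
certainties and real candidates. This is a property of the synthetic
task's separability, not of the method: real recordings, with genuinely
ambiguous epochs, are where the candidate set is populated.

## Synthetic polysomnography

Real mouse recordings of this kind are not publicly archived, so the
generator defines the package's study conditions:

* **Bout dynamics**: a first-order Markov chain over epochs. The default
  matrix is tuned so its stationary distribution is exactly the reference
  stage prevalence 49.7% WAKE / 45.4% non-REM / 4.9% REM, with
  $P(\text{WAKE}\to\text{REM}) = 0$ and REM self-transition 0.75 (mean
  bout 80 s at 20-s epochs, matching the tens-of-seconds-to-minutes
  persistence of REM); WAKE self-transition 0.95 gives ~6.7-minute mean
  WAKE bouts.
* **Signals**: stationary-per-epoch band-limited Gaussian noise. WAKE EEG
  is broadband 1–30 Hz with an active-wake theta component and scale
  40 µV; non-REM is delta-dominant at 80 µV (the largest EEG amplitude);
  REM is theta-dominant at 45 µV. EMG is broadband noise at 60/20/5 µV for
  WAKE/NREM/REM (atonia at the bottom). Amplitudes are internally
  consistent but arbitrary, as no absolute calibration is available.
  Lognormal per-epoch jitter (σ = 0.25) and per-record channel gains
  (σ = 0.15) emulate within-animal variability and electrode differences.
* **Noise injection** (optional, for robustness experiments):
  Poisson-scheduled 0.5–2 Hz motion-artifact bursts — the band that mimics
  delta and misleads delta-based scoring — plus continuous mains hum
  (default 50 Hz) and EMG leakage into the EEG channel.

What the generator does **not** emulate: sleep spindles, phasic REM
twitches, transient micro-arousals, circadian structure, or non-stationary
drift. Passing tests on this data therefore demonstrate that the
implementation learns and scores the *class of structure it claims to use*
(spectral signatures + bout dynamics); they do not certify accuracy on
real recordings.

A built-in sanity bound keeps the benchmark honest in the other direction:
a two-threshold classifier (EMG envelope, delta/theta ratio) must recover
≥85% of labels on clean defaults, guaranteeing the task is learnable and
that a deep model's success is meaningful rather than accidental.

## Random-forest baseline

The comparison scorer uses six classic features per epoch —
$P_{EEG} = \sum_t |eeg_t|$ and $P_{EMG} = \sum_t |emg_t|$ over all epoch
samples, plus summed spectral power: EEG 1–30 Hz ($W$), 1–6 Hz ($D$),
7–11 Hz ($T$), and EMG 30–100 Hz ($E$), all inclusive integer-Hz ranges —
with a random forest of 20 trees, depth ≤ 10, 2 candidate features per
split (the `ranger` backend exposes exactly these knobs). A 20-s epoch
gives 0.05 Hz resolution, so "the power at $i$ Hz" is implemented as
periodogram power aggregated over the 1-Hz bin centered on $i$; no taper is
applied by default (the feature definitions are plain sums), with a Hann
option. Whether the band sums were meant as power or amplitude is
ambiguous in the source description; power is the default, amplitude a
flag. The 100-Hz EMG band edge requires a sampling rate of at least
200 Hz.

## Evaluation

All metrics derive from the 3×3 confusion matrix with **rows = expert,
columns = scorer**: per-stage recall over expert marginals, precision over
predicted marginals, accuracy as the diagonal fraction, chance agreement
$p_e = \sum_s \frac{r_s}{M}\frac{c_s}{M}$ and Cohen's
$\kappa = (\text{acc} - p_e)/(1 - p_e)$, with $\kappa > 0.8$ the
conventional "nearly perfect agreement" bar. A stage absent from a marginal
yields an undefined (`NA`, displayed "—") metric, never 0. Record-edge
epochs that receive no context window are excluded from both hypnograms
before comparison. Display rounding is one decimal for percentages and two
for kappa; full precision is kept internally.

## Numerical and degenerate-input choices

* Softmax is computed with max-subtraction; cross-entropy clips
  probabilities at $10^{-12}$.
* Gradients are validated against central finite differences for every
  parameter block of all three variants (the check jitters parameters away
  from exact ReLU kinks, where one-sided derivatives make finite
  differences uninformative).
* A record shorter than one epoch yields an empty epoch set, not an error;
  a record shorter than one context window yields zero predictions with a
  warning.
* EDF I/O quantizes to 16 bits over the declared physical range; the
  round-trip bound is one quantization step. CSV round-trips exactly
  (17-significant-digit decimals).
* Markov sampling with a transition probability of exactly 0 can never
  emit that transition (cumulative-sum inversion).
* Model files embed a format version and the full configuration; loading
  verifies both, and an explicit expected variant can be enforced.

## Reference benchmark and problem sizes

`run_synthetic_benchmark()` fixes the package's reference conditions: 24
clean records of 360 epochs (2 h each), 18 for training and 6 held out; a
`scale = 1/8` network trained with the desk profile (10 pretraining + 20
fine-tuning passes); the random-forest baseline trained on the identical
folds and compared on exactly the epochs the deep model scored; and a
rescoring evaluation on held-out records seeded with 10 isolated REM
epochs each. These sizes are the package's chosen desk-scale reference
conditions — large enough that held-out kappa ≥ 0.8 ("nearly perfect")
is a meaningful bar, small enough to run routinely. The acceptance script
(`scripts/acceptance.R`) reruns this benchmark from scratch at a
user-supplied seed.

Two properties of this benchmark are worth knowing before interpreting
its numbers. First, clean synthetic data is *easy*: both the deep scorer
and the six-feature random forest reach ceiling (≈99.8–100% held-out
accuracy), so the ordering between them at the third decimal is decided
by a handful of epochs and flips with the seed — the benchmark
demonstrates that the deep pipeline learns the task to ceiling, not that
it dominates the baseline on data this separable. The deep model's rare
residual errors are transition epochs (typically the first WAKE epoch
after a sleep bout), a calibration effect of the few-hundred-step
desk-scale fine-tune. Second, as discussed above, the saturated scorer
leaves the rescoring candidate set empty on this data, so the rescoring
leg reports an identity pass.

## Known limitations

* Synthetic-only validation; no claim transfers to real recordings without
  retraining and expert-scored data.
* 20-s epochs only in this version; very short events (transient arousals)
  are invisible at this resolution, though the architecture itself is
  epoch-length-agnostic.
* Single EEG channel; no EOG/video modalities.
* The full-scale (scale = 1) network is constructible and correct but not
  intended for CPU training at realistic dataset sizes.
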