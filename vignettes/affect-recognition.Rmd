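---
title: "Recognising momentary affect from wrist-worn physiology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising momentary affect from wrist-worn physiology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Ambulatory studies pair multi-day wrist-sensor recordings — heart rate (HR,
1 Hz), galvanic skin response (GSR, 40 Hz) and tri-axial acceleration
(ACCEL, 20 Hz) — with experience-sampling (ESM) prompts delivered at random
moments of daily life. Each prompt collects a 10-item short-form PANAS (four
positive-affect items: *inspired, active, determined, attentive*; six
negative-affect items: *upset, hostile, alert, ashamed, nervous, afraid*;
each rated 1–5) plus single valence and arousal ratings on 1–5 scales.
`affectr` implements the full path from those raw streams to per-prompt
affect classification: preprocessing, label derivation, a Transformer-encoder
classifier, the subject-separated training/evaluation protocol, and a
synthetic-data generator so that every stage is testable offline.

# Label derivation

For each prompt the positive sum adds the four positive items (range 4–20)
and the negative sum the six negative items (range 6–30). The binary PANAS
category is whichever sum is larger. The comparison is undefined at
equality; `affectr` **excludes** tied prompts (returning `NA`) and counts
them, rather than force-assigning a side, because any forced assignment
would bias the class balance invisibly. No neutral band is added. Valence
and arousal ratings map to five classes by identity, and a secondary
binarisation groups classes 1–3 versus 4–5 for comparison with binary
baselines.

# Preprocessing chain

Per modality the chain is fixed, logged in each segment's provenance, and
applied in this order:

1. **ACCEL magnitude** `sqrt(ax^2 + ay^2 + az^2)`, quantised to 1/2048 g.
   Quantisation is applied after the norm (the sensor precision statement
   does not fix the order; applying it after preserves more information).
2. **Decimation to 1 Hz** by keeping every 40th (GSR) / 20th (ACCEL)
   sample. The retention phase is 0-based — indices 0, n, 2n, … — and
   configurable, since "every n-th sample" does not pin down a start index.
3. **LMS adaptive noise cancellation.** A linear filter with weights
   updated per sample by `w <- w + mu * e * x`. No reference channel is
   prescribed for single-channel wearable streams, so the default is the
   standard single-channel reading: a *delayed-self* reference (adaptive
   line enhancer; delay 1 sample, 8 taps, `mu = 0.01` on standardised
   input). The filter converges on the temporally predictable physiological
   component and the returned series is that prediction. An
   external-reference mode (e.g. acceleration as a motion reference) is
   provided, in which the filter estimates the interference and the
   *residual* is returned; this mode is implemented but not validated
   against real motion artifacts.
4. **Moving median, kernel 3,** with nearest-value edge replication (for a
   width-3 kernel the end samples are unchanged, because
   `median(a, a, b) = a`). This removes isolated single-sample spikes that
   survive the LMS stage.
5. **Per-subject, per-modality z-scoring** over the full recording. Input
   scaling is not part of the published chain description; it is enabled by
   default (and switchable) because the three channels differ by orders of
   magnitude in units and the model trains poorly on raw scales. Note that
   whole-recording statistics make this one step non-causal; the filter
   cascade itself is causal up to the median's one-sample lookahead, which
   is what the causality test asserts.
6. **Window extraction.** The 30 minutes (1800 samples; configurable) of
   1 Hz data immediately preceding each prompt, oldest first, ending at the
   last sample strictly before the prompt timestamp. Windows are scored for
   completeness; below the threshold (default 1.0 — only fully covered
   windows) they are excluded and reported, never padded silently. If the
   threshold is lowered, remaining internal gaps are linearly interpolated
   and the completeness fraction records how much was filled.

Missing samples are carried as explicit gap runs (start, length), not
silently interpolated at read time, so decimation and windowing can refuse
deterministically.

# The classifier

Each modality's 1 Hz window passes through its own feature extractor: two
1-D convolutions (kernels 7 and 5, stride 2 each, ReLU, hidden width
`cnn_hidden`), giving `T' = T/4` steps by `d_e` channels. The three
embeddings are concatenated along the feature axis in fixed order (HR, GSR,
ACCEL) and linearly projected to the encoder width `d_model`. The published
architecture fixes the extractor hidden size (128) and the fused width
(512) but not the internals; with three modalities `512/3` is not an
integer, so `affectr` uses `d_e = 128` per branch and an explicit fusion
projection to 512 — both knobs are in `model_config()`.

Sinusoidal positional encoding over the fused width is added
(`P(i,2j) = sin(i/10000^{2j/d})`, `P(i,2j+1) = cos(i/10000^{2j/d})`), then a
stack of encoder layers applies multi-head self-attention
(`Attention(Q,K,V) = Softmax(QK^T/sqrt(d_k))V`, heads concatenated and
projected by `W_O`) and a position-wise feed-forward network. The residual
composition as published writes a single residual,
`H^{l+1} = FFN(MultiHead(H^l)) + H^l`, with no normalisation; standard
post-norm layer normalisation is enabled by default for training stability,
and `layernorm = FALSE` selects the strict single-residual form for
equation-level verification. Temporal mean pooling (default; a learned CLS
token is the alternative) feeds a linear + softmax head, trained with
categorical cross-entropy (log clamped at 1e-12).

The "inner dimension" hyperparameter explored in the published grid
({4, 8, 16}) is not defined there; `affectr` maps it to the attention head
count — the only standard Transformer knob with that range — and keeps it a
free config key so other readings (e.g. per-head width) remain runnable.

Forward and backward passes are written analytically in base R matrix
algebra; the test suite verifies every gradient path against central finite
differences (relative error below 1e-4 on a 1-layer, 2-head instance, in
practice ~1e-6).

# Training and evaluation protocol

Splits are **subject-wise**: a seeded permutation assigns 80% of subjects
to training, so no participant contributes to both sides; the invariant is
asserted on every split. The published protocol describes early stopping on
"validation performance" but defines no validation set; stopping on the
test set would leak, so `affectr` carves a subject-wise 10% out of the
training side for validation.

Optimisation is Adam (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`) with L2
regularisation 1e-5 added to the gradients, dropout 0.2, an epoch budget of
100 and patience 10 (strict improvement in validation accuracy; the best
checkpoint is returned). The learning rate decays linearly from 1e-3:
`lr(e) = lr0 * (1 - e/max_epochs)` with a 0-based epoch index, so the first
epoch runs at `lr0` and epoch 50 of 100 at exactly `5e-4`. The batch size
default is 32 — the grid's best setting for the 5-class tasks — while the
protocol text's 64 remains a one-argument override; the discrepancy between
the two published values is documented rather than resolved.

Metrics are accuracy, macro precision and macro F1 (percentages), with
row-normalised confusion matrices (each cell the proportion of that true
label). Macro terms for degenerate classes are handled explicitly: a class
absent from both truth and predictions is dropped; a class present in the
truth but never predicted has undefined precision — skipped in macro
precision with a warning (default) or scored zero (`na_class = "zero"`) —
while its F1 is 0 through its defined zero recall. Both conventions are
config-selectable because published multi-class tables rarely state which
was used.

The ablation runner trains one model per nonempty modality subset (the
subset's branches only — not a zero-masked three-branch model, matching how
single-modality rows are normally produced) on a shared split and seed; the
grid runner crosses batch sizes with inner dimensions the same way, so
differences across cells are attributable to the hyperparameters alone.

# The synthetic generator

`sim_config()` defaults emulate the target study's shape: 88 subjects, 5
consecutive days of continuous recording, 8 prompts/day at random times
(the real dataset averages ~8.6/day), HR/GSR/ACCEL at 1/40/20 Hz. Each
prompt draws a latent binary affect state (prior 0.5) that expresses itself
only in the pre-prompt effect window:

- **HR**: 65 bpm baseline + slow random-walk drift + `hr_shift` (default
  +8 bpm) in positive-state windows + Gaussian noise (sigma 2 bpm).
- **GSR**: 2 uS tonic level + slow drift + exponentially decaying phasic
  events (amplitude 0.5 uS, tau 3 s) with Poisson arrivals at 1/min
  (negative state) versus `gsr_event_rate_ratio` times that (default 3) in
  positive windows, quantised to 0.01 uS.
- **ACCEL**: a shared AR(1) activity latent drives all three axes (so the
  magnitude is the informative summary), with state-dependent variance
  (ratio 2) plus gravity on z; quantised to 1/2048 g.
- Single-sample spike artifacts on every channel (12/hour) exercise the
  LMS + median stage.
- ESM items follow state-conditional discrete distributions: in the
  positive state the positive items are high and negative items low (and
  conversely), which makes the derived PANAS class track the latent state
  almost surely; valence and arousal are drawn from state-conditional
  distributions peaked (0.70) at class 4 / class 2 respectively, so the
  best achievable 5-class accuracy under the binary latent is about 70%.

This model is deliberately piecewise-stationary Gaussian/Poisson: the point
is known ground truth for recovery tests, not physiological realism. It
does **not** emulate circadian structure, inter-subject trait differences
beyond baseline offsets, tonic/phasic GSR coupling, heart-rate variability
spectra, or realistic motion artifacts — so passing recovery tests shows
the pipeline extracts planted class-dependent structure under noise; it
does not certify performance on real recordings.

# Problem sizes used in tests and the acceptance script

End-to-end checks run at a desk scale chosen so a full
simulate → preprocess → train → evaluate cycle takes seconds on one CPU: 12
subjects, one shortened 2-hour recording day, 10 prompts/day, 300-s
pre-prompt windows (a `window_s` override), and a compact model
(`d_e = 8`, `cnn_hidden = 16`, `d_model = 32`, 1 layer, 4 heads,
`ffn_dim = 64`, dropout 0.2, batch 16). Under the strong-effect defaults
this configuration recovers the binary planted effect at ~95–100% test
accuracy (3-seed mean ≥ 90%), stays within the 99% binomial interval of 50%
on null data, and reaches ≥ 60% 3-seed mean on the 5-class tasks whose
Bayes ceiling is ~70%. Paper-scale headline numbers on the real dataset are
out of scope: they require the external accession and unreported seeds.

# Numerical choices and degenerate inputs

- LMS weights start at zero; `mu = 0` therefore leaves the prediction at
  zero exactly. Inputs are standardised inside the filter (constant series
  use unit scale to avoid division by zero, making the filter exact on
  constants). Divergence (weight norm > 1e6 or non-finite) raises an error
  naming `mu`.
- Softmax subtracts the row maximum before exponentiating; attention rows
  sum to 1 at machine tolerance for arbitrary finite inputs.
- Cross-entropy clamps probabilities at 1e-12.
- Layer-norm uses eps 1e-5; its backward pass is implemented analytically
  and covered by the finite-difference check.
- Weight init is uniform fan-in scaling, `U(-sqrt(1/fan_in), sqrt(1/fan_in))`,
  from a seeded stream; one training seed fans out to split, init, shuffle
  and dropout, so identical seeds give bit-identical histories.
- Ties in `which.max` prediction resolve to the lower class index (base R
  convention), deterministic.
- The segment archive is a versioned single-file container serialised with
  R's native format, giving bit-exact round-trips of matrices, labels and
  provenance.

# Known limitations

- HR is consumed as a given 1 Hz stream; deriving it from raw PPG is out of
  scope.
- The published chain names adaptive noise cancellation without a reference
  channel; the delayed-self default is a documented interpretation, and the
  external-reference mode is unvalidated.
- Tied PANAS sums are excluded rather than assigned; published totals
  suggest ties either did not occur or were assigned, so distribution
  comparisons should use the reported tie counts.
- Only the single 8:2 subject split protocol is implemented; no
  cross-validation variants.
- Comparison baselines (random forests, SVMs, CNN/RNN architectures) are
  not reimplemented; the evaluation interface accepts any fit object that
  yields class predictions, which is the extension hook.
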