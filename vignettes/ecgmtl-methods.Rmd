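---
title: "Methods: multi-task ECG denoising, quality assessment and noise localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task ECG denoising, quality assessment and noise localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ambulatory and wearable single-lead ECG is contaminated by three
characteristic noise processes: baseline wander (BW; slow 0.05–1 Hz drift
from respiration and movement), electrode-motion artifact (EM; transient
300–500 ms baseline shifts whose amplitude exceeds the ECG's own
peak-to-peak), and muscle artifact (MA; broadband EMG-like interference
overlapping the 1–40 Hz ECG band). `ecgmtl` implements a multi-task model
that, given a 5 s window (1000 samples at 200 Hz), simultaneously

1. reconstructs the underlying clean waveform (denoising),
2. outputs a per-sample probability that the local noise is unacceptable
   (the *noise-level graph*), and
3. classifies three-level signal quality: Good (code 1), Medium (2),
   Bad (3).

Quality is tied to the EM+MA mixing SNR of the window: Good ≥ 16 dB,
Medium 5–14 dB, Bad ≤ −3 dB. BW is excluded from the SNR budget because it
does not alter waveform morphology. The unassigned gaps (14–16 and
−3–5 dB) are never sampled during synthesis, so the categories are well
separated by construction.

## Synthetic data: what it emulates, and what it does not

Because the corpora behind the original training setup are external
downloads, every stage here is testable on synthetic signals:

* **Clean ECG** — a Gaussian-bump P-QRS-T template laid on an RR grid with
  Gaussian beat-to-beat jitter (default SD 0.02 s). Default morphology:
  R = 1.0 mV (σ 10 ms), Q = −0.15, S = −0.20 (σ 8 ms), P = 0.12 mV at
  −200 ms (σ 25 ms), T = 0.30 mV at +250 ms (σ 45 ms). These give a
  ~90 ms QRS and a lead-I-like silhouette, and — crucially — exact beat
  and fiducial ground truth. A template model was chosen over an ODE
  simulator because only statistical realism is needed and the template
  yields exact annotations.
* **BW** — a sum of eight random-phase sinusoids confined to 0.05–0.9 Hz
  with a mildly red spectrum; ≥ 95% of periodogram mass lies below 1 Hz.
* **EM** — sparse smooth-edged baseline-shift events, durations uniform in
  300–500 ms, amplitude 2× a reference ECG peak-to-peak (1.2 mV) with
  random sign, occupancy configurable (default 10% of samples).
* **MA** — band-limited Gaussian noise with ~75% of its power in a 5–40 Hz
  band and ~25% above it (up to ~95 Hz). A pure white 5–100 Hz spectrum
  was rejected because, at a 200 Hz working rate, it would place under
  half its power inside the 1–40 Hz ECG band, contradicting the defining
  property of muscle artifact for this pipeline (its in-band overlap).

What the generator does **not** emulate: arrhythmia, respiration-coupled
morphology change, electrode lead-off saturation, powerline interference,
multi-lead structure, and pathological beats. Tests passing on this
synthetic family therefore demonstrate algorithmic correctness and
end-to-end trainability, not clinical performance on real recordings.

Mixing draws the target SNR uniformly from the category range, blends EM
and MA (per-sample blend drawn uniformly from EM-only, MA-only, or an
equal-power blend), scales the blend to the target SNR exactly
(`scale_noise_to_snr` is exact to machine precision), and adds BW outside
the SNR budget (default 0.1 mV SD). A configurable fraction (default 0.3)
of Bad windows is pure noise with no clean content, mirroring the use of
uninterpretable-noise segments as Bad-class training material; such
windows carry all-ones noise-level labels and are excluded from denoising
metrics.

**Weak labels.** Each half-open R-R segment is labeled 1 (unacceptable)
when its local SNR falls below 5 dB (the Medium floor) or the
clean-vs-noisy Pearson correlation falls below 0.8; otherwise 0. Samples
outside the first/last R peak inherit the adjacent segment's label. The
thresholds are config-exposed; the head trained on these binary targets is
free to output intermediate probabilities.

## Preprocessing chain

Flat-line detection (SD < 0.01 mV or too few detected peaks; default
minimum one peak per 2 s); baseline removal by two cascaded median filters
(0.2 s then 0.6 s windows, forced odd); zero-phase 4th-order Butterworth
band-pass 1–40 Hz; Savitzky–Golay smoothing (31 ms window, order 3);
isoline (mean) subtraction; Fourier resampling to 200 Hz; Pan–Tompkins
R-peak detection (5–15 Hz band-pass, derivative, squaring, 150 ms
integration window, adaptive signal/noise thresholds with search-back and
a 200 ms refractory period) followed by an adaptive correction that snaps
each detection to the band-passed extremum within ±50 ms. Butterworth +
forward–backward filtering was chosen because zero phase protects fiducial
timing; the Savitzky–Golay defaults smooth without widening the QRS at
200 Hz.

Delineation uses a periodized Daubechies-6 filter bank (hand-built,
perfect-reconstruction; orthogonality makes synthesis the exact transpose
of analysis). QRS onset/offset come from the level-2/3 detail envelope
thresholded at 25% of the beat-local maximum (floor: 3 scale MADs) within
±80 ms of the R peak; the 25% fraction was calibrated once against the
generator's template QRS duration. P and T are detected on the low-pass
residue (details 1–3 removed) as interior bumps exceeding 0.04/0.05 mV
over an edge-estimated baseline, with onsets/offsets at 15% of the peak
height; waves that do not clear the floor are reported absent rather than
fabricated.

## SQI features and the clean-segment selector

Eleven classical signal-quality indices (kurtosis in the Pearson
convention so white noise ≈ 3; sample entropy with m = 2, r = 0.2 SD;
threshold-crossing and amplitude-proportion features at 0.75×/0.25× the
maximum absolute amplitude; two band-power ratios; four beat-derived
features using the R-peak list, a ±60 ms QRS template and a
[R−200 ms, R−100 ms] P-window). Features needing ≥ 2 beats return `NA`
sentinels. A one-class SVM (RBF, ν = 0.1) over standardized features
emulates the pseudo-label selector used to pick clean training segments.
The kernel width defaults to γ = 1/(2d) rather than the textbook 1/d: on
11-dimensional standardized SQI vectors the wider kernel keeps the
training-inlier fraction near the 1 − ν contract (≈ 0.9 observed) where
1/d under-covered its own training set (≈ 0.75).

## Model

Patch embedding: conv(1→32, k 15, s 1) + batch norm + ReLU; conv(32→64,
k 7, s 1) + batch norm + ReLU; conv(64→128, k 20 = patch size, s 10) +
layer norm + ReLU. The last convolution pads 5 samples on each side so a
1000-sample window yields exactly 100 tokens of width 128 — the token grid
the parameter accounting and the overlap-add reconstruction both rely on.
Encoder: 6 pre-norm Transformer blocks (d 128, 8 heads, scaled dot-product
attention with biased Q/K/V/O projections, FFN expansion 3, residual
connections). Decoder: linear 128→64 followed by 3 blocks of the same
structure at width 64 (self-attention over the projected tokens; no
cross-attention — the printed dimension table implies projection followed
by self-blocks). No positional encoding anywhere, making the token maps
permutation-equivariant (a tested invariant). Heads: per-patch linear
64→20 → overlap-add (averaging by coverage count) → 1-channel smoothing
conv k 5 (identity-initialized) for the denoised trace; the same
linear+overlap-add structure followed by a logistic squashing for the
noise-level graph; mean over the patch axis (each patch contributes
equally) → dropout 0.1 → linear 64→3 → softmax for quality.

Parameter accounting is closed-form and matches the instantiated model
exactly: 179,328 (embedding), 992,256 (encoder), 133,440 (decoder), 2,801
(heads), 1,307,825 total ≈ 1.31 M, i.e. 4.99 MiB at 4 bytes/parameter.
Pre-norm block placement was chosen for small-batch training stability;
attention projections carry biases, which is what reproduces the printed
per-stage counts.

The network, its backpropagation, and Adam are implemented directly on
base-R arrays and BLAS matrix products (activations laid out batch-fastest
as `(B, L, C)` arrays; convolutions as shift-and-add matrix products).
Every layer's analytic gradient is verified against central finite
differences in the test suite.

## Losses

* **Denoising** — pointwise squared error; for Good-labeled samples the
  error at wavelet-mask positions is amplified by α = 2; per-sample time
  averages are averaged over non-Bad samples only (Bad windows carry
  weight 0; an all-Bad batch contributes 0 rather than dividing by zero).
  The α factor enters before time-averaging. The mask comes from a 4-level
  db6 decomposition of the clean target: detail levels 2–4 (≈ 3–25 Hz at
  200 Hz) hard-thresholded at the universal threshold σ√(2 log n) with σ
  estimated from the MAD of the finest details, mapped back to their time
  support; it concentrates on QRS complexes (a tested property).
* **Classification** — batch-mean cross-entropy (mean, not sum, so task
  magnitudes are batch-size independent), probabilities clamped at 1e-12.
* **Noise level** — mean squared error against the weak labels.
* **Combination** — learned homoscedastic uncertainty:
  Σᵢ Lᵢ/(2σᵢ²) + log σᵢ with σᵢ = exp(log σᵢ) trained jointly
  (∂/∂log σᵢ = 1 − Lᵢ/σᵢ², so each σᵢ is pulled toward its task's loss
  scale). The fixed-weight sum remains available by freezing log σ.

## Training and evaluation

Defaults mirror the published recipe: Adam, learning rate 1e-3, weight
decay 0.05 (applied to weight matrices only), Xavier initialization,
50 epochs, batch 64, balanced category sampling, fresh noise realizations
every step (online augmentation). An "epoch" over online batches is a step
budget (`steps_per_epoch`), not a corpus sweep. After the last epoch the
batch-norm running statistics are recalibrated by plain averaging over a
few fresh batches: with few total steps the exponential running estimate
lags the rapidly moving weights, and evaluation-mode normalization would
otherwise mismatch them (this showed up as a large train/eval accuracy
gap at desk scale).

Evaluation reports per-class precision/recall/F1 with support-weighted
averages and the 3×3 confusion matrix, plus denoising PRD, RMSE, output
SNR and cosine similarity, binned by the EM+MA mixing SNR into
[−5, 3], (3, 16) and [16, 18] dB. Cosine similarity uses the positive
sign convention (the magnitude-normalized inner product). Exact
reconstructions would make the SNR infinite; they are flagged and
excluded from averages.

**Desk-scale problem sizes.** The test suite trains a reduced model
(2 encoder / 1 decoder blocks) for 5 epochs × 120 steps at batch 16 on
online batches drawn from a 30-record clean pool, evaluating on 200
synthetic samples; the shorter loss-decrease check uses 5 seeds × 5
epochs × 4 steps at batch 8. Fewer steps leave the shared trunk too close
to initialization for evaluation-grade behavior; a higher learning rate
was tried and rejected (it lowered training loss but degraded
evaluation). These sizes are the package's chosen desk-scale study
conditions; the generator's SNR policy and category definitions are never
altered per run.

## Compression

Structured pruning ranks whole structures — embedding-conv output
channels, attention heads (removing a head removes its d_k-wide Q/K/V
slices and the matching rows of the output projection; the model width is
untouched), FFN hidden units — by mean absolute weight and removes the
least important until the parameter count reaches the target (default
20% of the original, i.e. an 80% reduction), with floors of 4 conv
channels, 1 head and 4 FFN units per block. The pruned architecture is
described by the same configuration object (per-block head/FFN vectors),
and the closed-form count again matches the sliced tensors exactly. No
fine-tuning is applied after pruning by default. Quantization is
post-training, weight-only, per-tensor affine INT8; the elementwise
dequantization error is bounded by half the scale, and parameter count is
preserved. Storage accounting: 4 bytes/parameter at fp32; 1
byte/parameter + 8 bytes/tensor at int8.

## Known limitations

* The synthetic family is stationary and single-morphology; classifier
  and denoiser behavior on arrhythmic or pathological ECG is untested
  here by design.
* Pure-noise Bad windows have no clean reference; their denoised output
  is unconstrained by the loss (weight 0), exactly as the masked loss
  prescribes.
* The desk-scale training runs demonstrate optimization behavior and
  class separation under the stated conditions, not the headline
  performance of a fully trained model.
* The noise-level head is trained on binary rule-based labels; its
  intermediate values are interpolations of the model, not calibrated
  probabilities.
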