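---
title: "Cycle-based ECG reconstruction from PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-based ECG reconstruction from PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppg2ecg)
```

## The problem

The electrocardiogram (ECG) and the photoplethysmogram (PPG) monitor the
same cardiac activity through different modalities — electrical versus
optical. Every heartbeat produces one ECG complex (P wave, QRS, T wave) and,
after the pulse-arrival time (PAT), one PPG pulse (systolic wave, often
followed by a dicrotic wave). Because PPG sensors are cheap and wearable
while ECG electrodes are not, reconstructing the ECG waveform from PPG is an
attractive target — if the reconstruction preserves what makes the ECG
valuable: QRS morphology (disease markers) and precise R-peak timing (heart
rate variability, PAT, blood-pressure estimation).

`ppg2ecg` implements a linear, cycle-based reconstruction pipeline and the
evaluation designs needed to probe exactly that question: how much
morphology and how much timing survive, under personalized and general
models.

## The pipeline

### Smoothing

Both channels are smoothed with a Savitzky–Golay filter (`smooth_savgol`,
defaults order 3, window 5 samples). A centered least-squares polynomial
filter has zero group delay and reproduces any cubic exactly, so wave
positions — in particular the R peak — are untouched; this is why it is used
instead of band-pass filtering. At the signal ends we use the filter
matrix's asymmetric end rows (a polynomial fit over the first and last
windows) rather than mirror padding: mirror padding creates an artificial
extremum at the boundary and breaks the polynomial-reproduction property
exactly where cycle boundaries will later be cut. The same filter is applied
to PPG and ECG; nothing in the method treats the channels asymmetrically
before segmentation.

### Cycle segmentation and the two pairing modes

Reference peaks are detected as local maxima constrained by (i) a refractory
distance of `60 / max_hr_bpm` seconds (default `max_hr_bpm = 200`) and (ii)
a topographic prominence of at least `prominence_frac` (default 0.3) times
the robust signal range (5th–95th percentile). The detector is deliberately
simple and deterministic; it assumes cleaned signals in which the systolic
wave (PPG) and the R wave (ECG) are the dominant positive deflections. A
`polarity` flag handles leads with negative R waves.

A PPG cycle is the span between consecutive systolic peaks. Its paired ECG
segment is chosen in one of two modes:

* **direct** — the ECG at the *same timestamps*. The R peak keeps its true
  position inside the cycle, but that position moves from cycle to cycle
  (heart-rate variability changes the cycle length while PAT stays roughly
  constant), so the model sees a moving target.
* **semantic** — the ECG between the two R peaks of the *same beat*, taking
  as governing R peak the latest one at or before the systolic peak (the R
  wave precedes its pulse by the PAT). Morphology is now aligned — every
  cycle starts at R — but the timing information is nulled by construction.

Cycles that cannot be paired one-to-one with an R–R interval (missed or
doubled detections) are dropped, not interpolated: imputed cycles would
silently inflate training and test counts. A duration filter
(`filter_cycles`, default 0.33–2 s) guards the resampling stage against
artifact cycles.

### Fixed-length representation and DCT compression

Each cycle is linearly resampled to `L = 300` samples — a conservative
length above the typical cycle duration at 300 Hz sampling (about 200
samples at rest) — and min–max normalized to [0, 1]. Min–max normalization
is scale-free and invertible (`denormalize_minmax`), and the Pearson metric
used downstream is unaffected by the affine choice.

The cycle is then compressed with the orthonormal DCT-II (`dct_forward`),
keeping the leading `n` coefficients; reconstruction zero-pads and inverts
(`dct_inverse`). The orthonormal convention is a deliberate numerical
choice: it makes Parseval exact (energy = sum of squared coefficients), so
the energy-based truncation rule below is well defined. The transform is
computed through a single FFT with even–odd reordering, not an O(L²) sum.

The truncation order is chosen by `select_coeff_count`: the smallest `n`
whose *mean* captured-energy fraction across training cycles reaches the
threshold (default 99.98%). Aggregating by the mean over cycles is our
choice among reasonable readings of a per-signal rule; percentile rules add
a parameter without changing behavior materially. Selection must be run on
training cycles only and then held fixed — `run_scheme` does this per fold.
The preset `coeff_selection(preset = "capnobase-paper")` pins 11 PPG and 100
ECG coefficients, the counts published for clean 300 Hz CapnoBase
recordings at this threshold. On our noisy synthetic cycles the data-driven
rule selects many more coefficients (order 100 for both channels): residual
broadband noise spreads energy across the spectrum, and a 99.98% rule
dutifully chases it. This is a property of the threshold, not a defect of
the transform; with the preset the pipeline behaves like the published
configuration.

### The ridge transfer function

With training coefficient matrices `X` (PPG, N×Lx) and `Y` (ECG, N×Ly), the
transfer function is the closed-form ridge solution

    f* = (XᵀX + γ I)⁻¹ XᵀY,      Ŷ = X f*

implemented by a Cholesky factorization of the normal matrix (never an
explicit inverse), with an `rcond` guard that turns numerical rank
deficiency at γ = 0 into an instructive error. There is no intercept and no
column standardization: the model is applied literally to normalized-cycle
coefficients. γ defaults to 1.0; `gamma_search = TRUE` picks it from a
log-spaced grid (10⁻⁶…10³) by chronological inner validation on the
training split. A fixed, documented default keeps runs reproducible; the
penalty mainly matters when training cycles are few relative to the ECG
coefficient count.

### Evaluation

Two per-cycle metrics:

* `pearson(recon, gt)` — morphological similarity of the normalized cycles.
  Undefined (constant-input) cases are returned as `NA`, excluded from
  aggregates and counted, never imputed as zero.
* `r_peak_delay` — the absolute time difference between the reconstructed R
  peak and the ground-truth R time. The reconstructed R location is the
  argmax of the normalized cycle, *placed on the PPG cycle's time span*.
  This absolute-time reading is deliberate: at inference only PPG timing
  exists, and it is the only reading under which semantic alignment shows
  its real cost — a delay close to the PAT — rather than a trivial zero.

Three split designs (`build_plan`):

* `general-cv` — sequential k-fold over cycles stacked subject-by-subject
  without shuffling; train and test folds come overwhelmingly from
  different subjects.
* `personalized-window` — per subject, each window of 20 cycles contributes
  its first 80% to a pooled training set and the rest to a pooled test set,
  and *one* model is fit per subject on the pool. Pooling is a design
  choice: 4 test cycles per window cannot score a model stably, and 16
  training cycles cannot determine an 11×100 map; the windowing's purpose
  is to spread both sets across the recording so heart-rate excursions
  appear in each. The default stride equals the window (non-overlapping);
  it is configurable because "sliding" is ambiguous.
* `loso` — leave-one-subject-out, the strongest test of a general model.

`concat_correlation` implements the long-segment experiment: each
reconstructed cycle is resampled back to its PPG cycle's duration (the
duration known at inference), `k` consecutive reconstructions are
concatenated, and the result is correlated against the raw ECG span of
equal length anchored at the first cycle's ECG reference (its governing R
peak in semantic mode). At `k = 1` this reduces to a per-cycle correlation
in the semantic frame; as `k` grows, the slow wander of the PAT makes the
placement of later cycles increasingly wrong and the correlation decays —
quantifying how much timing semantic alignment really loses.

## The simulator

`simulate_record` generates paired channels with analytic ground truth:

* **RR intervals** — AR(1) around `60 / hr_mean_bpm` (lag-1 coefficient
  0.6), with the BPM variability mapped to an RR standard deviation via
  `60 · hr_sd / hr_mean²`; defaults 70 BPM and 3.3 BPM give an RR sd of
  about 40 ms. An optional burst (`hr_burst`) switches the mean rate
  abruptly (e.g. to 100 BPM) for a fixed period — the transient that the
  personalized split design must represent on both sides.
* **ECG** — five Gaussian waves per beat. QRS offsets and widths are fixed
  in seconds (the QRS does not stretch with heart rate) while P and T
  positions scale with the RR interval, so normalized cycle shapes vary
  with rate as they do physiologically. R is the per-beat global maximum by
  construction, giving the prominence detector a well-defined target.
* **PPG** — systolic plus dicrotic Gaussians delayed by the PAT. The PAT is
  modeled as an AR(1) process (lag-1 coefficient 0.95, stationary sd
  `pat_sd_s`, default 20 ms) around `pat_s` (default 0.25 s): pulse-arrival
  time tracks respiration and blood pressure and therefore drifts smoothly
  across beats rather than jittering independently. This slow drift is what
  makes concatenated semantic reconstructions progressively misaligned.
* **Noise** — additive white Gaussian per channel, calibrated to a target
  SNR (default 20 dB) against the clean channel variance.

`simulate_subject_population` perturbs wave amplitudes, T-wave width,
dicrotic amplitude, PAT and mean heart rate log-normally per subject
(`subject_variation`, default 0.3), creating genuinely person-specific
PPG→ECG maps — the mechanism behind the personalized-versus-general
performance gap. `simulate_linear_pairs` plants an exact linear map in
coefficient space, giving the transfer model a ground-truth oracle.

What the simulator does **not** emulate: optical sensor physics and motion
artifacts, baseline wander, arrhythmia and ectopic beats, respiratory
amplitude modulation, and real inter-subject morphology beyond smooth
template perturbations. Passing tests on synthetic data therefore
demonstrate the correctness and the qualitative behavior of the pipeline —
not clinical-grade performance on hospital recordings.

## Numerical choices and degenerate inputs

* Orthonormal DCT verified against a naive cosine sum at 1e-9; Parseval at
  1e-9; ridge normal-equation residuals at 1e-8 relative.
* Constant cycles normalize to all-zeros with `scale = 0` flagged;
  constant inputs to `pearson` yield counted `NA`s; zero-energy cycles are
  excluded from coefficient selection.
* Ties in `which.max` resolve to the earliest index (base R), making R
  localization deterministic.
* Fold skipping: folds with fewer than two training cycles are skipped with
  a warning rather than fit degenerately.
* Test and script problem sizes — 10-minute single-subject records,
  10-subject populations of 2-minute records — were chosen as the smallest
  sizes at which detector statistics and split designs are exercised
  meaningfully (hundreds of cycles per subject, 20-cycle windows, 5-fold
  and LOSO plans all non-trivial).

## Known limitations

* With very slow heart rates (RR well above 1 s) a tall T wave can escape
  the default refractory distance and be detected as a spurious R peak;
  raising `prominence_frac` or lowering `max_hr_bpm` handles such records.
* The transfer function is linear by design; it reconstructs an averaged,
  subject-typical morphology and cannot express beat-conditional
  nonlinearities. The leave-one-subject-out results quantify how far that
  assumption carries.
* The R-delay metric reads the reconstructed R as the cycle argmax; for
  pathological reconstructions whose maximum is not the QRS, the optional
  `search_frac` window should be used.
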