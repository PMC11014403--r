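# ppg2ecg

Cycle-based reconstruction of ECG waveforms from photoplethysmography, with
the evaluation machinery needed to ask the question that matters: *how much
QRS morphology and how much R-peak timing actually survive the
reconstruction?*

The package is aimed at physiological-signal researchers studying
cross-modal cardiac monitoring: people who have synchronized PPG/ECG
recordings (or want a controlled synthetic stand-in) and need a transparent,
linear baseline pipeline whose every stage is inspectable — not a black-box
network.

## The method

Both channels are Savitzky–Golay smoothed (order 3, window 5; zero phase
delay, so wave positions are preserved) and cut into cycles at PPG systolic
peaks. Each PPG cycle is paired with an ECG segment in one of two modes:

* **direct** — the ECG at the same timestamps (preserves R timing, but the
  R position moves inside the cycle as heart rate varies);
* **semantic** — the R-to-R interval of the same beat (aligns morphology,
  discards the pulse-arrival delay).

Cycles are linearly resampled to `L = 300` samples, min–max normalized, and
compressed with the orthonormal DCT-II, keeping the smallest number of
coefficients whose mean captured energy reaches 99.98% (selected on training
cycles only; the published CapnoBase counts, 11 for PPG and 100 for ECG, are
available as a preset). The transfer function between coefficient spaces is
the closed-form ridge solution

```
f* = (XᵀX + γI)⁻¹ XᵀY,        Ŷ = X f*
```

solved by Cholesky factorization, and reconstruction is zero-padded inverse
DCT. Reconstructions are scored per cycle by the Pearson correlation ρ
against the true normalized cycle and by the absolute R-peak delay
`|R_loc(recon) − R_loc(truth)|` in seconds, under three split designs:
sequential k-fold over subject-stacked cycles (general model), pooled
20-cycle sliding windows per subject (personalized model), and
leave-one-subject-out.

A paired-waveform simulator (Gaussian-bump P-QRS-T and systolic/dicrotic
morphology, AR(1) RR intervals with optional heart-rate bursts, slowly
drifting pulse-arrival time, SNR-calibrated noise) provides ground-truth
beat annotations so the entire pipeline is testable without external data.

## Worked example

```r
library(ppg2ecg)

cfg <- sim_config(duration_s = 120, seed = 42)   # 70 BPM, PAT 0.25 s, 20 dB
rec <- smooth_record(simulate_record(cfg)$record)
rec
#> <record_pair subject=sim1: 36000 samples @ 300 Hz, t0=0 s>

for (m in c("direct", "semantic")) {
  pairs <- segment_record(rec, m)
  print(run_scheme(build_plan(pairs, "personalized-window"), pairs))
}
#> <scheme_result personalized-window: 24 cycles, mean rho=0.515, mean R delay=0.024 s>
#> <scheme_result personalized-window: 24 cycles, mean rho=0.993, mean R delay=0.263 s>
```

The two lines are the method's central trade-off. Direct pairing keeps the
R peak where it belongs — the reconstruction localizes it to within ~24 ms —
but the morphology correlation is mediocre (ρ ≈ 0.52) because the QRS sits
at a different position in every cycle. Semantic alignment reconstructs
morphology almost perfectly (ρ ≈ 0.99), but the R peak lands ~0.26 s away:
the nulled pulse-arrival time. Which mode is "better" depends entirely on
whether the application needs shapes or timestamps.

Records can also be read from CSV (`read_record`, columns `t,ppg,ecg`),
trimmed declaratively (`trim_record`), and driven from a YAML experiment
configuration (`run_experiment(read_experiment_config("experiment.yaml"))`,
see `inst/extdata/quickstart.yaml`); a thin command-line wrapper lives at
`inst/cli/ppg2ecg`.

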