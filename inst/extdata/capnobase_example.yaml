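# Example configuration for an on-disk CSV record pair (e.g. a CapnoBase
# TBME record exported to the canonical t,ppg,ecg CSV format at 300 Hz).
# The trim window replaces manual removal of distorted sections with a
# declarative, reproducible cut: this example keeps the first 250 s of the
# recording. One entry per subject; add further records with their own
# per-subject trim windows as identified by inspection.
data:
  type: csv
  records:
    - path: subject_0009.csv
      fs: 300
      subject_id: "0009"
      trim: [0, 250]
mode: semantic
scheme: personalized-window
window: 20
train_frac: 0.8
coeffs: capnobase-paper
gamma: 1.0
seed: 1
out_dir: capnobase_out
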