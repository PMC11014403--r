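# Quickstart experiment: simulated resting subject, semantic alignment,
# personalized sliding-window evaluation. Run with
#   Rscript inst/cli/ppg2ecg run --config quickstart.yaml
# or run_experiment(read_experiment_config("quickstart.yaml")) from R.
data:
  type: simulate
  preset: rest
  duration_s: 120
mode: semantic
scheme: personalized-window
window: 20
train_frac: 0.8
coeffs: auto
energy_threshold: 0.9998
gamma: 1.0
seed: 1
out_dir: quickstart_out
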