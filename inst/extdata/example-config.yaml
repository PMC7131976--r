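# Example pipeline configuration: simulate a small cohort on the packaged
# maze and run every analysis stage.
out_dir: "mazepoint-run"
seed: 7
layout: "packaged"
alternative:
  rotation_sign: -1
simulate:
  n_per_group:
    G: 12
    G+E: 12
    E: 12
  adoption: "participant"
mixture:
  restarts: 10
  w_min: 0.15
  min_separation: 30
  min_trial_n: 10
  bootstrap_B: 200
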