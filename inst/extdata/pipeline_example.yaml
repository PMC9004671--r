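# Example pipeline config: full synthetic run.
out_dir: pipeline_out
seed: 7
stages: [simulate, indicators, toggle, rrcs, matrix77, motif]
inputs:
  synthetic: true
  motif_tsv: pif_example.tsv   # resolve relative to your working directory
params:
  state_tolerance_A: 1.0
  matrix_threshold_A: 2.0
  rrcs: {d_full: 3.23, d_zero: 4.63, near_seq_sep: 4}
  schedule:
    segments:
      - {state: A, frames: 20}
      - {state: I, frames: 20}
    interp_frames: 10
    noise_sd: 0.1
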