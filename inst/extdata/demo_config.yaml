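# End-to-end demo: simulate every input at reduced size, then run all four
# analysis arms.  Rerunning with the same seed reproduces the report
# byte-for-byte.
seed: 7
out_dir: ctcfdyn_demo
simulate:
  footprint:
    n_motifs: 20
    reads_per_motif: 50
  trace:
    condition: insulator_wt
    duration_s: 5
    n_traces: 1
  kymo:
    n_particles: 10
    n_frames: 150
    substrate_kb: 50
  rupture:
    n_events: 83
footprint:
  run: true
trace:
  run: true
  k: 4
  n_restarts: 2
kymo:
  run: true
rupture:
  run: true
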