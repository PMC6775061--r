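# Example pipeline configuration (reduced scale; see read_config() for
# defaults and the full key set). The seed is mandatory.
seed: 1
output: artifacts
stages: [simulate, msm, tpt, cholmap, report]
simulate:
  n_traj: 50
  n_steps: 4000
  dt: 0.025
msm:
  k: 100
  lag: 10
  n_macro: 6
  n_boot: 50
tpt:
  source: M4
  sink: M2
cholmap:
  box: [20, 20, 12]
  n_particles: 60
  n_frames: 2500
  sites:
    - {x: 10, y: 10, z: 6, depth: -1.0, radius: 2.5}
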