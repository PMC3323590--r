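# Minimal homogeneous biased-diffusion benchmark configuration.
# All other fields take the documented package defaults.
problem: homogeneous
cells_per_dim: 64
kernel: fpt
runs: 20
seed: 101
params:
  drift: [2.0, 2.0]
  diffusivity: [1.0, 1.0]
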