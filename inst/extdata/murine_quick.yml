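# Desk-scale murine run configuration (see read_run_config())
preset: murine
diameter_um: 60
fov_pixels: [2, 2]
fine_sampling: 12
n_repetitions: 3
thicknesses_mm: [1.8, 3.6, 5.4, 7.2, 9.0, 10.8]
base_seed: 1
noise: false
eak: 1000
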