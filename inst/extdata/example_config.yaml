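# Example pipeline configuration for the synovasim command-line wrapper.
parameters: default      # or "synthetic", or set parameter_file: <csv>
seed: 1
n_samples: 200           # ensemble members (per condition for hormone-compare)
fraction: 0.20           # relative coefficient perturbation half-width
t_end: 480               # hours (20 days)
grid: 24                 # output spacing, hours
days: [1, 5, 10, 15, 20] # days tested by hormone-compare
out_dir: synovasim-out
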