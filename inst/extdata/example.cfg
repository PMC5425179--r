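# knotcage experiment config (key = value); see inst/cli/knotcage.R
# structure: omit `pdb` to use the synthetic trefoil toy
n_beads = 35
handedness = left
cage_sizes = Inf,2.9
temperatures = 150,165,180
n_steps = 200000
n_replicas = 1
record_stride = 1000
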