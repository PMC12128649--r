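# Example clutchsim run configuration.
# Usage: clutchsim sweep --config example-config.yaml --out out/sweep
# Flags override file values; unknown keys are rejected.
preset: desk          # desk = 20k events x 3 seeds; paper-full = 100k x 1
k_s: 0.1              # substrate spring constant, pN/nm (required)
k_s_eps0: 0.1         # orthogonal spring constant, pN/nm
l: 1000               # orthogonal spring rest length, nm
eps0: 0               # residual strain
strain_mode: none     # none | axial | transverse
model_variant: modified
burn_in: first-failure
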