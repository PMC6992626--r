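# Example run configuration: simulate a shell-expressing population and run
# the full report pipeline on it. All keys are optional; package defaults
# fill the gaps. Unknown keys are rejected.
simulate:
  n_events: 2000
  width_law: constant     # constant | linear | none
  w0_um: 13               # shell radial width (um)
  m_au_mm3: 5.0e+7        # fluorescence per mm^3 of shell
  noise_cv: 0.1
  debris_fraction: 0.1
  seed: 1
gating:
  profile: reporter       # reporter | wildtype
model:
  form: hyperbolic        # FS^-1 model: linear | hyperbolic | shell
  gamma_from: intercept   # intercept | dfdv
  n_boot: 200
  seed: 1
stats:
  n_boot: 1000
  seed: 1
io:
  out_dir: pelletshell-out
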