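# Baseline doxorubicin pulse in the single-vessel tumour geometry.
# Omitted keys take the package defaults (the tabulated parameter set);
# listed here are the pulse and a reduced grid suitable for quick runs.
pulse_S: 1
pulse_T_h: 1.5
switch_kind: bistable
numerics:
  nr_i: 64
  nz: 12
  dt_s: 10
  t_end_h: 10
  output_every_s: 3600
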