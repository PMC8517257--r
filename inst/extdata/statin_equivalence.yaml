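# Simvastatin-equivalence potency ratios: multiply a statin's daily dose in mg
# by `ratio` to obtain the simvastatin dose of equal LDL-lowering potency.
# Editable: studies cite external dosing references, so ratios are data, not code.
ratios:
  simvastatin: 1.0
  atorvastatin: 2.0
  rosuvastatin: 4.0
  pravastatin: 0.5
  fluvastatin: 0.5
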