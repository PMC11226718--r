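# Custom material definitions: element mass fractions, density (g/cm^3)
# and an optional mean excitation energy override (eV).
pmma:
  elements: {H: 0.080538, C: 0.599848, O: 0.319614}
  rho: 1.19
  I: 74.0
graphite:
  elements: {C: 1.0}
  rho: 1.70
  I: 78.0
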