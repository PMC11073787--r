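# Minimal compartmental model: 100 A and 100 B released into the cytosol
# CP react irreversibly to form C.
begin model
begin parameters
  MCELL_DIFFUSION_CONSTANT_3D_A 1e-5   # cm^2/s, fast: well-mixed regime
  MCELL_DIFFUSION_CONSTANT_3D_B 1e-5
  MCELL_DIFFUSION_CONSTANT_3D_C 1e-5
  k_on 1e9                             # M^-1 s^-1
end parameters
begin molecule types
  A()
  B()
  C()
end molecule types
begin compartments
  CP 3 1
end compartments
begin seed species
  @CP:A() 100
  @CP:B() 100
end seed species
begin observables
  Molecules A A()
  Molecules B B()
  Molecules C C()
end observables
begin reaction rules
  A() + B() -> C() k_on
end reaction rules
end model
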