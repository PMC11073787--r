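# Dual Ca2+-sensor model of the SNARE release machinery.
# One elementary molecule type `snare` carries a synchronous sensor `s`
# (0-5 bound calcium ions), an asynchronous sensor `a` (0-2 ions) and a
# vesicle-docking flag `dv`. Calcium binds/unbinds the sensors; a fully
# loaded synchronous sensor fuses the docked vesicle (consuming the docked
# state), a fully loaded asynchronous sensor drives a slower release leak,
# and an unloaded synchronous sensor allows a new vesicle to dock.
# Release timing is tracked by the dummy volume species V_release.
# Rate constants are synthetic fixture values adapted from the dual-sensor
# literature; the state/reaction structure is what matters here.
begin model
begin parameters
  MCELL_DIFFUSION_CONSTANT_2D_snare      1e-8   # cm^2/s
  MCELL_DIFFUSION_CONSTANT_3D_Ca         2e-6
  MCELL_DIFFUSION_CONSTANT_3D_V_release  1e-6
  s_on    6.12e7        # M-1 s-1, synchronous per-site on-rate
  s_off   2.32e3        # s-1, synchronous base off-rate
  b       0.25          # synchronous unbinding cooperativity
  a_on    1.2e7         # M-1 s-1, asynchronous per-site on-rate
  a_off   13            # s-1
  g_sync  6000          # s-1, synchronous fusion
  g_async 50            # s-1, asynchronous leak
  k_dock  2             # s-1, vesicle re-docking
  N_snare 70
  N_ca    5000
end parameters
begin molecule types
  snare(s~0~1~2~3~4~5,a~0~1~2,dv~0~1)
  Ca()
  V_release()
end molecule types
begin compartments
  PM 2 0.8836
  CP 3 0.25 PM
end compartments
begin seed species
  @PM:snare(s~0,a~0,dv~1) N_snare
  @CP:Ca() N_ca
end seed species
begin observables
  Molecules Ca_free Ca()
  Molecules docked snare(dv~1)
  Molecules s5 snare(s~5)
  Molecules released V_release()
end observables
begin reaction rules
  sync_b1: snare(s~0) + Ca()@CP <-> snare(s~1) 5*s_on, 1*s_off
  sync_b2: snare(s~1) + Ca()@CP <-> snare(s~2) 4*s_on, 2*s_off*b
  sync_b3: snare(s~2) + Ca()@CP <-> snare(s~3) 3*s_on, 3*s_off*b^2
  sync_b4: snare(s~3) + Ca()@CP <-> snare(s~4) 2*s_on, 4*s_off*b^3
  sync_b5: snare(s~4) + Ca()@CP <-> snare(s~5) 1*s_on, 5*s_off*b^4
  async_b1: snare(a~0) + Ca()@CP <-> snare(a~1) 2*a_on, 1*a_off
  async_b2: snare(a~1) + Ca()@CP <-> snare(a~2) 1*a_on, 2*a_off
  sync_release: snare(s~5,dv~1) -> snare(s~5,dv~0) + V_release()@CP g_sync
  async_release: snare(a~2) -> snare(a~2) + V_release()@CP g_async
  dock: snare(s~0,dv~0) -> snare(s~0,dv~1) k_dock
end reaction rules
end model
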