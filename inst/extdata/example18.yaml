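# Coexistence benchmark: linear target-cell growth, Crowley-Martin
# incidence, identity removals.  At tau3 = 0 the coexistence equilibrium E4
# (both CTL and antibody responses active) is the stable regime
# (R3 > 1, R4 > 1).
growth:
  form: linear
  params: {lambda: 10, d: 0.01}
incidence:
  form: crowley_martin
  params: {beta: 0.25, a: 0.01, b: 0.01}
removals: {g1: identity, g2: identity, g3: identity, g4: identity}
rates:
  a: 0.5
  b: 0.15
  c: 0.1
  k: 0.4
  u: 3
  p: 1
  q: 1
  r: 1.5
  h: 0.1
  m1: 0.01
  m2: 0.01
delays: {tau1: 5, tau2: 8, tau3: 0}
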