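# CTL-dominated benchmark: logistic target-cell growth, exponential-shift
# incidence, identity removals.  At tau3 = 0 the CTL-only equilibrium E3 is
# the stable regime (R2 > 1, R4 < 1).
growth:
  form: logistic
  params: {lambda: 10, d: 0.01, r1: 0.6, K: 500}
incidence:
  form: exp_shift
  params: {beta: 0.3, b1: 0.01, c1: 0.01}
removals: {g1: identity, g2: identity, g3: identity, g4: identity}
rates:
  a: 0.5
  b: 0.15
  c: 0.1
  k: 0.4
  u: 3
  p: 1
  q: 1
  # antibody activation rate; sometimes denoted g in the virus-dynamics
  # literature.  r = 1.5 reproduces the antibody competition number
  # R4 = 0.2854 of this parameter set.
  r: 1.5
  h: 1
  m1: 0.01
  m2: 0.01
delays: {tau1: 2, tau2: 5, tau3: 0}
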