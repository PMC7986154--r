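# Water-radiolysis reaction scheme, mixed reaction types.
#
# Observed rate constants follow the standard compilation used by particle
# track-chemistry codes.  Reaction types: "partially" reactions carry a bare
# contact radius `radius` (nm) from which kdif = 4*pi*R*D and kact via
# 1/kobs = 1/kdif + 1/kact; "totally" reactions derive R (or Reff for
# charged pairs) directly from kobs = 4*pi*R*D.  The spin flag marks
# radical pairs that react only from the singlet spin configuration
# (encounters of the hydrated electron and atomic hydrogen and their
# combinations); the singlet weight defaults to 1/4.
#
# Diffusion coefficients (m^2/s) are the defaults used by particle
# track-chemistry codes (literature values); they are configuration
# values, not fitted quantities.
species:
  - {name: eaq,  charge: -1, D: 4.9e-9}
  - {name: OH,   charge:  0, D: 2.8e-9}
  - {name: H,    charge:  0, D: 7.0e-9}
  - {name: H3O+, charge:  1, D: 9.0e-9}
  - {name: OH-,  charge: -1, D: 5.0e-9}
  - {name: H2O2, charge:  0, D: 2.3e-9}
  - {name: H2,   charge:  0, D: 4.8e-9}
reactions:
  - {reactants: [H, eaq],    products: [OH-, H2],      kobs: 2.5e10,   type: totally,   spin_factor: true}
  - {reactants: [H, OH],     products: [],             kobs: 1.55e10,  type: partially, spin_factor: false, radius: 0.40}
  - {reactants: [H, H],      products: [H2],           kobs: 0.503e10, type: totally,   spin_factor: true}
  - {reactants: [H2O2, eaq], products: [OH-, OH],      kobs: 1.1e10,   type: partially, spin_factor: false, radius: 0.40}
  - {reactants: [H3O+, eaq], products: [H],            kobs: 2.11e10,  type: partially, spin_factor: false, radius: 0.25}
  - {reactants: [H3O+, OH-], products: [],             kobs: 11.3e10,  type: totally,   spin_factor: false}
  - {reactants: [OH, eaq],   products: [OH-],          kobs: 2.95e10,  type: partially, spin_factor: false, radius: 0.60}
  - {reactants: [OH, OH],    products: [H2O2],         kobs: 0.55e10,  type: partially, spin_factor: false, radius: 0.40}
  - {reactants: [eaq, eaq],  products: [OH-, OH-, H2], kobs: 0.636e10, type: totally,   spin_factor: true}
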