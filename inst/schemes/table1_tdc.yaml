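# All-totally-diffusion-controlled variant of the water-radiolysis scheme:
# the same reactions and observed rate constants, every reaction handled as
# totally diffusion-controlled (R = kobs / 4*pi*D) and no spin statistical
# factors.  This is the scheme the reference SBS stepper uses, and the
# "TDC" variant scheme for the IRT stepper.
species:
  - {name: eaq,  charge: -1, D: 4.9e-9}
  - {name: OH,   charge:  0, D: 2.8e-9}
  - {name: H,    charge:  0, D: 7.0e-9}
  - {name: H3O+, charge:  1, D: 9.0e-9}
  - {name: OH-,  charge: -1, D: 5.0e-9}
  - {name: H2O2, charge:  0, D: 2.3e-9}
  - {name: H2,   charge:  0, D: 4.8e-9}
reactions:
  - {reactants: [H, eaq],    products: [OH-, H2],      kobs: 2.5e10,   type: totally, spin_factor: false}
  - {reactants: [H, OH],     products: [],             kobs: 1.55e10,  type: totally, spin_factor: false}
  - {reactants: [H, H],      products: [H2],           kobs: 0.503e10, type: totally, spin_factor: false}
  - {reactants: [H2O2, eaq], products: [OH-, OH],      kobs: 1.1e10,   type: totally, spin_factor: false}
  - {reactants: [H3O+, eaq], products: [H],            kobs: 2.11e10,  type: totally, spin_factor: false}
  - {reactants: [H3O+, OH-], products: [],             kobs: 11.3e10,  type: totally, spin_factor: false}
  - {reactants: [OH, eaq],   products: [OH-],          kobs: 2.95e10,  type: totally, spin_factor: false}
  - {reactants: [OH, OH],    products: [H2O2],         kobs: 0.55e10,  type: totally, spin_factor: false}
  - {reactants: [eaq, eaq],  products: [OH-, OH-, H2], kobs: 0.636e10, type: totally, spin_factor: false}
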