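# Reactions between the diffusing radicals (hydrated electron, hydroxyl
# radical, hydrogen atom) and static DNA elements (2-deoxyribose and the
# four bases), all treated as totally diffusion-controlled.  The reaction
# radius for a radical-sink pair follows kobs = 4*pi*R*D with D the
# radical's own diffusion coefficient (the sink is static).  Rates in 1/M/s.
# There is no guanine + H entry, and phosphate groups and hydration shells
# have no radical reactions (they enter direct-damage scoring only).
dna_reactions:
  - {target: deoxyribose, species: OH,  kobs: 1.8e9}
  - {target: adenine,     species: OH,  kobs: 6.1e9}
  - {target: guanine,     species: OH,  kobs: 9.2e9}
  - {target: thymine,     species: OH,  kobs: 6.4e9}
  - {target: cytosine,    species: OH,  kobs: 6.1e9}
  - {target: deoxyribose, species: eaq, kobs: 0.01e9}
  - {target: adenine,     species: eaq, kobs: 9.0e9}
  - {target: guanine,     species: eaq, kobs: 14.0e9}
  - {target: thymine,     species: eaq, kobs: 18.0e9}
  - {target: cytosine,    species: eaq, kobs: 13.0e9}
  - {target: deoxyribose, species: H,   kobs: 0.029e9}
  - {target: adenine,     species: H,   kobs: 0.10e9}
  - {target: thymine,     species: H,   kobs: 0.57e9}
  - {target: cytosine,    species: H,   kobs: 0.092e9}
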