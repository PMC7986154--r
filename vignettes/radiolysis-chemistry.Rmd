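---
title: "Simulating diffusion-controlled radiolysis chemistry and DNA damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating diffusion-controlled radiolysis chemistry and DNA damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtchem)
```

Ionizing radiation deposits energy in cellular water in nanometre-scale
clusters. Within a picosecond these deposits have relaxed into a population
of radiolysis species — the hydrated electron eaq⁻, the hydroxyl radical
•OH, atomic hydrogen H•, the ions H₃O⁺ and OH⁻, and the molecular products
H₂ and H₂O₂ — whose subsequent diffusion and mutual reactions over the next
nanoseconds to microseconds determine both the radiochemical yields
(G-values) and, when the track crosses chromatin, the indirect DNA damage
inflicted by radical attack on sugar and base moieties. `irtchem`
implements two stochastic simulation methods for this chemical stage — a
synchronous, position-explicit **independent reaction time (IRT)** stepper
and a reference **step-by-step (SBS)** Brownian-dynamics stepper — together
with a static chromatin-fiber target model and the scoring machinery for
G-values, material-balance audits and primary DNA damage.

## Two-body reaction kinetics

Both steppers rest on the Smoluchowski theory of diffusion-controlled
reactions. For a pair with relative diffusion coefficient $D = D_1 + D_2$
and reaction radius $R$ defined by the observed rate constant through
$k_{obs} = 4\pi R D$, the probability that the pair, initially separated by
$r_0$, has reacted by time $t$ under an absorbing boundary (*totally*
diffusion-controlled reaction) is

$$p(t\,|\,r_0) = \frac{R}{r_0}\,
  \mathrm{erfc}\!\left(\frac{r_0 - R}{\sqrt{4 D t}}\right),$$

with long-time limit $R/r_0$. Under a radiation boundary condition
(*partially* diffusion-controlled reaction) the encounter is not always
fertile: the rate splits into a transport part $k_{dif} = 4\pi R D$ and an
activation part $k_{act}$ through $1/k_{obs} = 1/k_{dif} + 1/k_{act}$, and

$$p(t\,|\,r_0) = P_0\left[\mathrm{erfc}(y) -
  e^{x^2 + 2xy}\,\mathrm{erfc}(x + y)\right],\qquad
  P_0 = \frac{R_{eff}}{r_0},\;
  R_{eff} = \frac{R\,k_{act}}{k_{dif}+k_{act}},$$

with $x = (k_{dif}+k_{act})\sqrt{Dt}/(k_{dif}R)$ and
$y = (r_0-R)/\sqrt{4Dt}$. Numerically the growing exponential is never
formed: $e^{x^2+2xy}\,\mathrm{erfc}(x+y) = \mathrm{erfcx}(x+y)\,e^{-y^2}$,
and `erfcx` switches to an asymptotic series above $x = 15$, so the
expression is finite for all arguments.

**Charged pairs.** A Coulomb interaction at the Onsager radius scale
($r_c = e^2/4\pi\varepsilon_0\varepsilon_r k_B T = 0.71$ nm for unit
charges in water at 25 °C, `onsager_radius()`) is folded in through the
Debye effective-distance transform
$d_{eff}(d) = r_c/(e^{r_c/d}-1)$, with $r_c$ signed positive for like
(repulsive) and negative for unlike (attractive) charges. The package
applies the transform to both the separation and the contact radius and
then runs the neutral machinery on the transformed problem; this choice
reproduces the classical charged $y$-variable
$y = r_c\left[\coth(r_c/2r_0) - \coth(r_c/2R)\right]/2\sqrt{4Dt}$
*identically* (the identity
$\tfrac{r_c}{2}\coth\tfrac{r_c}{2r} = d_{eff}(r) + \tfrac{r_c}{2}$ makes
the two forms equal), and it is the unique choice consistent with the
two-stage sampler below under the strong Markov property. For totally
diffusion-controlled charged pairs the effective radius comes directly
from $R_{eff} = k_{obs}/4\pi D$. One corner case is handled explicitly: an
attractive pair whose observed rate lies *below* the Debye-enhanced
diffusion limit $4\pi D |r_c|/(1 - e^{-|r_c|/R}) > 4\pi D\,|r_c|$ admits no
absorbing radius under the transform; such reactions are propagated with
neutral kinematics and $R = k_{obs}/4\pi D$, the Coulomb factor being
absorbed into the radius.

## Sampling reaction times

Totally controlled pairs use exact inversion: with $U \sim U(0,1)$, the
pair never reacts when $U \ge R/r_0$, otherwise

$$t = \left(\frac{r_0 - R}
  {2\sqrt{D}\,\mathrm{erfc}^{-1}(U r_0/R)}\right)^{2}.$$

Partially controlled pairs use a two-stage scheme. Stage one samples the
first passage to the contact radius with the inversion sampler. Stage two
samples the encounter-to-reaction time: starting at contact the eventual
reaction probability is $k_{act}/(k_{dif}+k_{act})$ and the conditional
CDF is $1 - e^{x^2}\mathrm{erfc}(x)$. The stage-two draw

$$t_2 = \frac{1}{D}\left(\frac{-R\,k_{dif}\,\ln U_2}
  {(k_{dif}+k_{act})\,Y}\right)^{2},\qquad
  Y \sim \left|\mathcal{N}(0, \sqrt{2})\right|,$$

is an *exact* inversion, not an approximation: the ratio of a unit
exponential to a half-normal variate of scale $\sqrt 2$ has CDF
$1 - e^{z^2}\mathrm{erfc}(z)$ (the half-normal scale is fixed by this
identity; the moment generating function
$E[e^{-zY}] = e^{z^2}\mathrm{erfc}(z)$ closes the proof). By the strong
Markov property the sum of the two stages is distributed per the
radiation-boundary solution, which the test suite confirms by
Kolmogorov–Smirnov comparison at $10^6$ draws for every reaction class,
including the charged ones (`sampler_check()`).

## The synchronous IRT stepper

`run_irt()` implements an IRT variant that keeps every molecule's position
explicit, so the chemistry can interact with a geometric target:

1. sample a tentative reaction time for **every** admissible reactant pair
   (and every radical–sink pair when a fiber is attached) from its two-body
   first-passage distribution;
2. select the global minimum and take it as the step;
3. displace every surviving molecule by an isotropic Gaussian of per-axis
   variance $2 D \Delta t$ (the *position approach*);
4. execute the winning reaction — reactants die, products are placed
   (one product at the diffusion-weighted encounter point
   $(\sqrt{D_b}\,p_a + \sqrt{D_a}\,p_b)/(\sqrt{D_a}+\sqrt{D_b})$, two
   products at the parent positions, a third at the encounter point);
5. sweep for contact reactions: the global displacement can carry a pair
   inside its reaction radius, where it reacts with the
   unsuccessful-encounter probability
   $\wp = R_s/\left[R_s + (k_{dif}/k_{act})(R+R_s)\right]$ (encounter
   separation $R_s = 0.3$ nm; $\wp = 1$ for totally controlled reactions;
   a charged variant with $e^{-r_c/r}$ factors applies to charged pairs);
6. resample **all** pair times from the new positions and repeat until the
   end of the simulated interval.

The full resample in step 6 is the price of keeping positions synchronous;
it is quadratic in the number of molecules per step but makes the coupling
to a static target exact at the level of the independent-pair
approximation. Radical–sink times use the totally-controlled sampler with
the radical's own diffusion coefficient (the sink is static).

Three design details deserve note:

* **Spin statistical factor.** Encounters of H• and eaq⁻ and their
  combinations react only from the singlet spin configuration. Flagged
  pairs draw a per-pair admissibility Bernoulli (weight 1/4 by default,
  configurable) once, cached for the pair's lifetime; blocked pairs never
  react. The reaction radii still derive from the printed observed rates,
  so the spin factor deliberately *suppresses* those channels relative to
  a spin-free run — visible as a lower H₂ yield.
* **Candidate cutoff.** Pairs whose reaction probability within the
  remaining simulation time falls below `cutoff_prob` ($10^{-4}$ by
  default) are skipped. The threshold distance is solved per reaction per
  step by bisection, so the cutoff adapts as the clock runs down. Sink
  candidates additionally use exact geometric thinning over coarse spatial
  cells: each cell bounds the per-sink acceptance probability by
  $R_{max}/d_{min}$, the sweep advances with geometric skips and corrects
  by the exact acceptance ratio, which reproduces per-sink Bernoulli draws
  without touching every far sink.
* **Determinism.** All randomness flows through R's RNG in a fixed
  traversal order: one `set.seed()` reproduces a whole campaign.
  Tie-breaks (contact sweeps, simultaneous hits) are resolved in
  ascending-separation order.

## The SBS reference stepper

`run_sbs()` is the reference dynamic-time-step Brownian stepper. Every
reaction is treated as totally diffusion-controlled (pair radii from
$k_{obs} = 4\pi R D$, the all-TDC scheme). Each step:

1. choose $\Delta t = \max(\text{minimum step},\ \min_{\text{pairs}}
   \Delta t_{dyn})$, capped at the remaining time, where the
   *protection-domain* step $\Delta t_{dyn}$ inverts the Smoluchowski
   probability at the confidence level $c$ (0.95 by default):
   $p(\Delta t_{dyn}|r_0) = 1 - c$, with no bound when $R/r_0 \le 1-c$;
2. displace all molecules by Gaussian steps;
3. react every pair whose post-step separation is inside the reaction
   radius, and every near miss with the Brownian-bridge encounter
   probability (below); molecules react at most once per step, closest
   pairs first.

The minimum step either stays fixed (`schedule_fixed(0.1)`, the reference
configuration) or grows with virtual time
(`schedule_kreipl()`: 0.1 ps below 10 ps up to 100 ps beyond 10 ns), since
spurs become sparse as the chemistry ages.

**Brownian bridge.** A pair at $d_0$ before and $d_1$ after a step of
duration $\Delta t$ may have crossed the reaction radius in between. The
image solution for the radial coordinate gives the conditional encounter
probability

$$p = \frac{e^{-(d_0-R)(d_1-R)/D\Delta t} - e^{-d_0 d_1/D\Delta t}}
  {1 - e^{-d_0 d_1/D\Delta t}},$$

which reduces to the familiar minimum-time-step expression
$\exp[-(d_0-R)(d_1-R)/D\Delta t]$ whenever $D\Delta t \ll d_0 d_1$. The
second exponential matters over the long protection-domain steps: the
radial coordinate of three-dimensional Brownian motion is transient, and
the plain exponential — exact only for one-dimensional motion — saturates
to 1 as $\Delta t$ grows, overcounting encounters severely. With the full
form the stepper reproduces the two-particle Smoluchowski law to Monte
Carlo accuracy at $10^5$ histories, and because the joint draw (endpoint,
hit indicator) matches the absorbing-sphere Green's function, surviving
endpoints automatically carry the correct conditional distribution.

**Charged pairs in SBS** use the effective-distance transform in all
Eq-1-derived quantities (protection-domain step, contact test, bridge),
matching the IRT treatment. A known limitation follows: trajectories are
propagated force-free, so the steady-state transform cannot fully restore
the path-level Coulomb bias, and attractive pairs react somewhat less in
SBS than the Debye theory predicts. The package's method comparisons are
method-vs-method on identical inputs, where this approximation is part of
the reference method's definition.

## The chromatin-fiber target

`build_fiber()` constructs a deterministic 40 nm heterochromatin segment:
3640 nucleotide pairs from 18 nucleosomes of 160 bp plus 19 linkers of 40
bp — the unique near-canonical integer split of $18n + 19l = 3640$ —
inside a cubic voxel of 40 nm. The architecture is a continuous *coiled
coil*: the DNA axis winds with uniform 0.34 nm rise around a solenoidal
tube (radius 3.7 nm, one winding per 3.5 nm of tube length) whose centre
line spirals up the fiber axis (radius 12 nm, pitch 11 nm). Each 160 bp
block wraps ~2.3 windings around a 2.4 nm histone sphere placed on the
tube centre line; linker identity is assigned to the alternating 40 bp
blocks. This junction-free construction was chosen over a literal
chain-of-nucleosomes assembly because it keeps the rise exactly uniform,
fits the voxel, and packs with **zero** overlapping element spheres, which
jointed constructions could not achieve in the available volume. Real
fibers are irregular and sequence-specific; since the damage quantities
compared here are counts and method ratios on a *fixed* geometry, the
regularity is immaterial, but absolute per-base damage maps should not be
read off this model.

Each nucleotide contributes per strand a 2-deoxyribose sphere, a phosphate
sphere, a base sphere (A/C/G/T cycling along the chain, complementary
across strands) and a concentric hydration shell on the two backbone
spheres. Element radii (0.20/0.15/0.13 nm) and radial offsets
(0.58/0.85/0.25 nm) are placeholders sized so that no two core spheres
overlap anywhere in the default build — `validate_fiber()` checks
containment, rise bounds and overlaps. Deoxyribose and base spheres are
reactive sinks with rates per the radical–DNA table (e.g. guanine + •OH at
$9.2\times10^9$ M⁻¹s⁻¹; there is no guanine + H• channel, and eaq⁻
attacks the sugar only weakly); phosphates and shells are
direct-damage accounting volumes only. Histones are inert: no scavenging
reaction is attached, which maximizes radical availability for DNA attack.

**Damage bookkeeping.** A radical–sink reaction is a primary *indirect*
damage event: the radical dies, the sink is flagged damaged and never
reacts again, and the record carries the nucleotide index, strand, element
and agent. *Direct* damage sums energy deposits per incident primary
within each nucleotide backbone group (phosphate + deoxyribose + their
shells, per strand) and records an event when the sum strictly exceeds
17.5 eV. Deposits belong to the nearest containing sphere. Radicals
leaving the voxel are discarded (escape events). Damage events are
primary lesions; their clustering into strand breaks is out of scope.
Each history sees an undamaged fiber — primaries are independent.
Direct records enter damage-yield time series at the grid origin (they
exist as soon as the physical stage ends); indirect records at their
reaction times.

## Synthetic sources

The package generates its own 1 ps initial conditions rather than coupling
to a track-structure code; the generators emulate only the statistical
shape the chemistry consumes.

* `gen_electron_spurs()` emulates a low-LET electron history depositing
  1 keV: well-separated spur sites along a random walk (mean spacing
  100 nm), species placed as Gaussian clouds of 2 nm around their site.
  Species arrive in three stoichiometric groups — ionization
  (eaq⁻ + •OH + H₃O⁺), excitation (•OH + H•) and molecular
  (H₂ + 2 •OH) — with group yields per 100 eV of 4.4 / 0.6 / 0.15 at
  1 ps, literature-informed configuration values. Because every group is
  individually charge-neutral and redox-balanced, each history satisfies
  the water material-balance identity
  $G_{eaq^-} + 2G_{H_2} + G_{H^\bullet} = G_{^\bullet OH} + 2G_{H_2O_2}$
  *exactly* at $t = 0$, so any later violation would indict the steppers
  or the scoring, not the input.
* `gen_proton_track()` emulates a 500 keV proton crossing the fiber voxel
  at normal incidence: entry uniform on a 20 nm disc, a radical column of
  Gaussian radial scale 1 nm along the axis with 27 eV/nm deposited (the
  stopping power of such protons in water), the same balanced group
  mixture, and jointly generated energy-deposit events (2 per nm,
  exponential energies) sharing the radial profile, so direct and indirect
  damage correlate spatially. The surrogate makes no claim to
  track-structure fidelity — no cross sections, no secondary-electron
  transport, no LET straggling — so *absolute* damage yields are not
  comparable to measured or track-structure values; method-versus-method
  ratios on identical inputs are.

## Scoring

`g_value_series()` converts an event log into yields: for each species the
mean number of molecules alive per history, right-continuous in time,
scaled to molecules per 100 eV. Populations are instantaneous, not
cumulative production. `material_balance()` evaluates the worst relative
deviation of the balance identity over the grid; since every reaction in
the water scheme moves both sides equally, a balanced initial state keeps
the deviation at floating-point zero — the audit is a strict conservation
theorem, not a statistical bound. `compare_methods()` reports per-time
relative differences with the second series as reference, and
`damage_yield_series()` bins damage records per primary with a cumulative
prefix sum. The default grid is logarithmic, 50 points per decade, 1 ps to
1 μs.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| diffusion coefficients | 4.9 (eaq⁻), 2.8 (•OH), 7.0 (H•), 9.0 (H₃O⁺), 5.0 (OH⁻), 2.3 (H₂O₂), 4.8 (H₂) ×10⁻⁹ | m²/s | species mobility (scheme YAML) |
| contact radii, partial reactions | 0.25–0.60 | nm | transport/activation split (scheme YAML) |
| Onsager radius | 0.71 | nm | charged-pair transform |
| encounter separation $R_s$ | 0.3 | nm | contact-reaction probability |
| singlet weight | 0.25 | — | spin statistical factor |
| confidence | 0.95 | — | protection-domain step |
| minimum steps | 0.1, or 0.1→100 by slice | ps | SBS schedules |
| candidate cutoff | 10⁻⁴ | — | IRT pair skipping |
| voxel side | 40 | nm | fiber target |
| direct-damage threshold | 17.5 | eV | strict `>` per primary |
| spur / track yields | 4.4 / 0.6 / 0.15 per 100 eV | — | source composition |
| LET surrogate | 27 | eV/nm | proton-track density |

Internally everything runs in nm and ps (SI conversions happen once at the
configuration boundary), which keeps erfc arguments in a benign range.

## What the checks do and do not show

The suite validates, among others: every sampler against its analytic
distribution (KS < 0.01 at 10⁶ draws, including the charged and two-stage
cases); the material-balance conservation theorem on 50-history IRT runs
to 1 μs; the protection-domain confidence contract by 10⁵-trial Brownian
simulation per random geometry; the two-particle escape law $R/r_0$ for
both steppers at 10⁵ histories; cumulative DNA damage per primary at 10 ns
agreeing within 10% between IRT and the fixed-0.1 ps SBS reference over
500 track primaries; and an •OH G-value difference at 1 μs of roughly 15%
between IRT (mixed scheme, spin factors) and SBS-dynamic (all-TDC scheme)
over 200 spur histories. Problem sizes (50/200/500 histories, 10⁵–10⁶
draws) were chosen as the smallest that pin each quantity well inside its
tolerance; they are the package's own verification scales.

Passing these checks shows the *methods* are implemented correctly and
that their mutual differences behave as the algorithms predict. It does
not validate the synthetic sources against real track structure, nor the
placeholder element radii against crystallographic DNA volumes, nor the
damage counts against measured strand-break yields.

## Known limitations

* The independent-pair approximation itself: with many competing sinks the
  IRT reaction probability is known to be biased upward relative to the
  exact multi-sink solution; the dense-fiber regime inherits this.
* Charged pairs in SBS diffuse force-free under a steady-state distance
  transform; attractive pairs under-react relative to Debye theory.
* The spin factor gates reactions on top of radii derived from observed
  rates, suppressing H•/eaq⁻ channels by the singlet weight rather than
  renormalizing them.
* Escapes are tested at event times in IRT but at every step in SBS, a
  small structural asymmetry inherent to comparing an event-driven with a
  time-driven method.
* No temperature dependence, pH equilibria, scavengers, or histone
  chemistry; damage records are primary lesions, not strand breaks.

```{r example, eval = FALSE}
# a complete small campaign
set.seed(1)
snap <- gen_electron_spurs(spur_model(), n_histories = 20)
tab <- build_reaction_table("table1_thiswork")
h <- run_chemistry(snap, tab, method = "irt", end_time = 1e6)
gv <- g_value_series(h)
material_balance(gv)     # ~1e-16: conserved to floating point
autoplot(gv)             # G-values vs virtual time
```
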