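---
title: "Models and methods: particle-based reaction-diffusion with rule-based chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The simulation model

`mcreact` simulates biochemical systems at single-molecule resolution.
Volume molecules are Brownian point particles inside triangulated meshes;
surface molecules occupy cells ("tiles") of a barycentric grid on membrane
meshes, at most one molecule per tile, which gives membranes volume
exclusion. Time advances in fixed steps $\Delta t$ (default $10^{-6}$ s).
Each iteration executes, in a fixed order: release events, a combined
diffusion/reaction sweep, the hybrid-species update (if any), and
observable counting. All randomness is drawn from one seedable 64-bit
xoshiro256++ stream per world, so a (model, seed, configuration) triple
reproduces its trajectory byte for byte, across platforms and regardless
of the cache-cleanup interval.

## Rule-based chemistry, resolved network-free

Chemistry is written in BNGL. Species and patterns are undirected bipartite
graphs of elementary molecules and their components (binding sites with
optional states); reactions are graph-rewriting rules. The reaction network
is never enumerated up front: when two species first collide (or a species
first needs its unimolecular pathways), every rule is matched against the
pair, each pattern-automorphism-distinct embedding becomes one concrete
pathway at the rule's full rate constant, and the resulting reaction class
is cached under the canonical labels of the species. Species with no live
molecules are periodically evicted from the caches together with the
reaction classes that reference them; ids are never reused, so cleanup
cannot perturb a trajectory (this is asserted bit-for-bit in the tests).

Canonical labels are computed by iterative partition refinement over
(molecule type, component multiset, state, bond structure) followed by a
deterministic adjacency-guided growth that branches over root choices and
takes the lexicographically smallest serialization. The label procedure is
validated property-style against a brute-force isomorphism matcher on
random species graphs; label equality coincided with isomorphism in every
generated pair.

For two identical reactant patterns applied to a pair of identical species,
the swapped role assignment is the same physical event and is counted once;
for distinct patterns both role assignments are distinct pathways. No
symmetry-factor division is applied (direct network-free evaluation); the
same convention (`c n (n-1) / 2` propensity for an identical pair) is used
by the bundled SSA and ODE oracles so the three routes are directly
comparable.

## Collision probabilities

For a bimolecular rate constant $k$ (internally $\mu m^3 N^{-1} s^{-1}$),
a diffusing volume molecule tests every partner whose center lies within
the interaction radius $r_\mathrm{int}$ of its displacement segment
(cylindrical sweep, no end caps) and reacts with probability

$$p_{vv} = \frac{k\,\Delta t}{\pi r_\mathrm{int}^2\,(\bar l_A + \bar l_B)},
\qquad \bar l = \sqrt{16 D \Delta t / \pi},$$

at most one reaction per moving molecule per step. Three implementation
details matter for accuracy and were fixed by explicit calibration against
the mass-action ODE oracle:

* the sweep is cylinder-only, because the formula's derivation counts
  swept volume $\pi r^2 \bar l$; including spherical end caps inflates the
  collision rate by about 10%;
* after a wall reflection the folded sub-segment re-tests partners
  (reflection principle); de-duplicating tests across the fold suppresses
  near-wall reaction rates by tens of percent in small compartments;
* the neighbor-search grid query is widened by one cell because partners
  are binned at their iteration-start positions but may have moved.

With these choices the well-mixed A+B$\to$C benchmark (1 $\mu m^3$ box,
$D = 10^{-5}$ cm$^2$/s) reproduces the ODE solution to better than 1% at
half-consumption over 32 seeds.

Volume-surface collisions use $p_{vs} = k \Delta t / (c_{vs} A_\mathrm{tile}
\sqrt{D\Delta t/\pi})$ per wall-tile hit. The calibrated constant is
$c_{vs} = 1$, which is exactly the one-sided diffusive flux onto a tile
($n A \sqrt{D \Delta t / \pi}$ expected hits per step at density $n$).
Surface-surface contacts between edge-adjacent tiles use
$p_{ss} = k \Delta t / (c_{ss} A_\mathrm{tile})$ with calibrated
$c_{ss} = 5.5$, close to the a-priori estimate 6 (three edge neighbors,
both partners moving). Both constants were fixed once against the ODE
oracle at low occupancy and are recorded in `simulation_config()`.

Probabilities above 1 are legal but lossy; the run summary
(`probability_report()`) lists, per rule, the maximum probability seen and
the estimated fraction of missed reactions.

## Geometry

Meshes are triangle soups with counter-clockwise winding defining outward
normals; `validate_mesh()` reports open edges, inconsistent winding, and
degenerate triangles (area below $10^{-12}\ \mu m^2$). A triangle of area
$A$ is tiled with $n = \lceil\sqrt{A\sigma}\rceil$ strips ($n^2$
congruent-area cells), so the realized tile density is at least the
requested $\sigma$ (default $10^4$ tiles/$\mu m^2$). The default
interaction radius is $1/\sqrt{\pi\sigma}$, which makes the volume
collision cross-section equal to one tile's area. Edge/vertex grazing
counts one hit (lowest triangle index); after a reflection the molecule
advances $10^{-9}\ \mu m$ along the reflected direction, which (unlike an
offset along the face normal) cannot push a near-corner molecule through
the adjacent face. Surface diffusion draws an in-plane Gaussian step and
unfolds it across shared edges by rotating the remaining displacement about
the edge; region-boundary edges marked reflective fold the step back.
Because surface positions are tile centers, the 2D walk is faithful only
when the step length exceeds the tile pitch; the diffusion-law tests run in
that regime and the limitation holds for real models too (choose
$\sigma$ accordingly).

## Unimolecular kinetics and hybrid coupling

Each molecule carries an exponentially distributed next-event time with the
total unimolecular rate of its species, redrawn whenever the species
changes; pathways are chosen proportionally to rate. A species whose rate
set contains a hybrid-coupled (time-varying) pathway is resampled every
iteration, which is statistically exact by memorylessness.

A hybrid model tracks one species as a continuous copy number $R(t)$
rather than as particles. Per iteration, after the diffusion/reaction
sweep: $R$ is updated by an explicit Euler step driven by the current
particle counts (production per driving molecule, first-order decay,
pseudo-first-order consumption), integer gains from designated rule firings
are added, and the coupled rule's pseudo-first-order rate is set to
$k\,R(t)$ for the next iteration. The coupling coefficients are frozen
over the iteration, but the scalar Euler update is internally sub-stepped
(at least 10 sub-steps per unit of loss-rate x $\Delta t$): during
activator bursts the sequestration loss makes the update stiff, and a
single full step would overshoot to negative copy numbers, clamp at zero,
and systematically shorten oscillation periods. Negative $R$ still clamps
to zero with a warning if production terms misbehave.

# Fixtures and the synthetic-data conditions

The package ships programmatic fixtures (`fixture_model()`); each BNGL
file or generated text is first-class tested code. Where the underlying
published models do not print every rate constant, the fixtures carry
synthetic values reconstructed from the model family they implement, chosen
once and documented here.

**Calcium-sensor release machinery (`snare`).** One membrane molecule type
with a synchronous sensor (six states: 0-5 bound calcium ions), an
asynchronous sensor (three states), and a vesicle-docking flag: 36 states,
18 docked. Five reversible synchronous binding rules (on-rates with site
multiplicity 5..1, off-rates with cooperativity $b^i$), two reversible
asynchronous binding rules, synchronous fusion (consumes the docked state,
emits a release marker), an asynchronous leak (emits the marker without
undocking), and re-docking gated on an unloaded synchronous sensor — ten
rules that expand to exactly 126 concrete reactions from the seed species.
The binding rates follow the dual-sensor literature (synchronous on-rate
$6.12\times10^7\ M^{-1}s^{-1}$, base off-rate $2.32\times10^3\ s^{-1}$,
cooperativity 0.25); fusion, leak and docking rates are synthetic.

**Membrane localization (`membrane_localization`).** The published
geometry: a $0.47 \times 0.47 \times 5\ \mu m^3$ box, lipid M released at
17000 molecules/$\mu m^2$ on one small face (surface grid density 40000
tiles/$\mu m^2$, hence 42.5% initial occupancy, 3755 molecules), the
face's edges reflective to 2D diffusion; volume proteins A and B bind M
and the membrane-bound forms dimerize in 2D. Binding rates are synthetic
($5\times10^7\ M^{-1}s^{-1}$ on, chosen to keep the per-hit reaction
probability below 1 at the default grid; 2D dimerization
$0.2\ \mu m^2 N^{-1} s^{-1}$). The tests run a reduced box
($0.2 \times 0.2 \times 1\ \mu m^3$, 150 + 150 volume proteins, 20 ms)
purely for run time; densities and mechanisms are unchanged. The measured
dimer count exceeds the whole-membrane well-mixed ODE prediction several
fold — the confinement effect the model exists to show.

**Autophosphorylation switch (`autophosphorylation`).** Thirty kinases and
one saturable phosphatase (explicit enzyme-substrate complex) in a
0.0078 $\mu m^3$ box. The parameters (trans-autophosphorylation
$1.1\times10^7\ M^{-1}s^{-1}$, basal $2\ s^{-1}$, phosphatase
on/off/catalytic $10^9\ M^{-1}s^{-1}$ / $100\ s^{-1}$ / $500\ s^{-1}$)
were chosen by a documented design scan so that the deterministic system
is genuinely bistable (ODE steady states near 5 and 22 phosphorylated
kinases) while stochastic switching occurs on the ~100 ms scale, so
three 1.5-s trajectories exhibit both states and transitions in both
directions with high probability.

**Activator-repressor clock (`clock_particle` / `clock_hybrid`).** The
two-gene relaxation oscillator (activator A enhances transcription of both
genes; repressor R sequesters A into a complex C whose decay releases R),
with all rates carried from hours to seconds and then accelerated 268-fold,
in a 0.25 $\mu m$ box; deterministic period 0.096 s. For ensemble tests a
further *exact concentration-preserving* reduction is applied
(`volume_scale`): volume and the two transcription rates are divided by
the same factor, which preserves every per-capita rate and the
deterministic dynamics while reducing copy numbers (at `volume_scale =
128`, A peaks near 20-40 copies). The hybrid variant treats R as the
continuous species; its time step is twice the particle step (a longer
step would push the promoter-binding probability above 1 under this
package's collision formula). The fast-diffusion comparison
($D = 10^{-5}$ cm$^2$/s) detects the first low-pass peak of A (moving
average window = one fifth of the period, prominence 25% of range) across
64 seeds and finds hybrid and SSA means within one SSA standard deviation.

The slow-diffusion regime ($D = 10^{-7}$ cm$^2$/s) is *not* reproduced at
desk scale: the same geometric reduction that makes 64-seed ensembles
affordable shortens the diffusive mixing time quadratically, so the small
box remains effectively well mixed and the particle, hybrid and SSA
variants agree instead of ordering. Observing the slow-diffusion
acceleration requires the full 0.25 $\mu m$ box at a $2.5\times10^{-7}$ s
step, i.e. hours of CPU per ensemble; the suite therefore asserts the
desk-scale equivalence and leaves the ordering claim untested here.

# What the synthetic fixtures do and do not show

The generators emulate: well-mixed mass-action kinetics at realistic
copy numbers, surface recruitment with volume exclusion, combinatorial
state spaces handled network-free, bistable switching driven by intrinsic
noise, and hybrid continuous/particle coupling. They do not emulate:
crowding or excluded volume in 3D (volume molecules are points), realistic
cellular geometries (boxes only in the fixtures, though arbitrary
triangle meshes load from OBJ), diffusion-limited re-binding statistics at
contact (the collision model is a fixed-radius sweep, not a Green's
function method), or transcellular contacts between separate membranes.
Passing tests therefore validate the algorithmic machinery and its
calibration, not any specific biological prediction.

# Numerical choices

* Intersection tolerance $10^{-12}$ (relative) in the segment-triangle
  test; grazing hits deduplicated at $10^{-12}$ in the path fraction;
  post-reflection advance $10^{-9}\ \mu m$ along the reflected direction.
* Bounded network expansion defaults: 5000 species / 50000 reactions,
  error beyond.
* The ODE oracle integrates with `lsoda` at `rtol 1e-8 / atol 1e-10`;
  conservation holds to $10^{-7}$ on the fixtures.
* gdat output: 15 significant digits, scientific notation, `# time ...`
  header; re-reading reproduces the matrix at formatted precision.
* Problem sizes used by the test suite (the package's own desk-scale
  choices): 64 seeds x 6 ms for the well-mixed benchmark, 3 x 1.5 s for
  the switch, 64 seeds x 0.2 s for the clock, $10^5$ displacement draws
  for the diffusion laws, 20 ms for the membrane comparison.

# Known limitations

* The per-collision probability formula loses accuracy when $p$
  approaches 1; the run summary reports the estimated missed-reaction
  fraction rather than silently under-reacting.
* Collision rates in compartments whose linear size is comparable to
  $r_\mathrm{int}$ are biased low by sweep clipping at the walls (about
  10% when the box edge is only 7x the interaction radius).
* Surface positions are quantized to tile centers; 2D diffusion and
  surface reaction placement are meaningful only when the diffusion step
  is not far below the tile pitch.
* Newly created surface molecules face outward; explicit orientation must
  be modeled as a component state.
* Zero-order synthesis rules (`0 -> X`) are not supported; timed release
  schedules cover the use cases.
* Transcellular and transmembrane reactions across separate membranes are
  out of scope.
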