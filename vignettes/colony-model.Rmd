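---
title: "The colony model: metabolic budgeting, cross-feeding and self-organized patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The colony model: metabolic budgeting, cross-feeding and self-organized patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonysim)
```

## The model

Mature, glucose-starved yeast colonies are not metabolically uniform: they
partition into gluconeogenic cells ("dark", after their appearance under
transmitted light) and glycolytic, pentose-phosphate-active cells
("light"), arranged in reproducible spatial patterns. The two
subpopulations cross-feed. Dark cells build trehalose from aspartate — a
non-limiting dual-use resource that can supply either carbon or nitrogen —
and leak part of it; light cells live off that extracellular trehalose and
emerge wherever it accumulates past a threshold. `colonysim` implements
this as a lattice agent-based model coupled to a diffusing scalar field.

Each agent is a *cell block* (a proxy for a small group of cells)
occupying one site of a 2D grid, in state dark or light, carrying internal
carbon (C) and nitrogen (N) pools. One extracellular trehalose
concentration value lives on every lattice site. Per time step, every
block present at the start of the step is processed once:

1. **Switching.** A dark block whose local trehalose exceeds `T_DL` (1.5
   units) becomes light with probability `P_DL` (0.5); a light block whose
   local trehalose is below `T_LD` (1e-4) reverts to dark with probability
   `P_LD` (1e-4). A block that switches takes no further action that step;
   its pools carry over unchanged.
2. **Metabolism.** A dark block takes up `AspU * Cmax` units of aspartate
   (0.2 under defaults), routes the fraction `f` (0.125) to its N pool and
   converts the rest to carbon with yield `Y` (0.31), then secretes the
   fraction `Pf` (0.049) of its carbon pool as trehalose at its own site,
   capped at `secretion_cap` (0.12) units per step. A light block consumes
   the trehalose at its site up to `Cmax` (0.05) into its C pool and takes
   up the same `AspU * Cmax` of aspartate into its N pool. Aspartate is
   never depleted and is not tracked spatially.
3. **Division.** A block may divide once its reserves suffice — C >= 1 and
   N >= 1 for dark; C >= 1 and N >= `ExN` (4.0) for light, reflecting the
   higher nucleotide-synthesis (hence nitrogen) demand of glycolytic
   cells — with probability `g` (0.04) per step, into an empty site of its
   4-neighborhood, preferring the candidate with the most occupied
   neighbors (ties uniform). Mother and daughter each keep half the C and
   N pools. If the neighborhood is full, nothing happens; there is no cell
   death or removal.
4. **Diffusion.** The field takes one explicit FTCS step,
   `u' = u + D_eff (u_E + u_W + u_N + u_S - 4u)`, with `D_eff = 0.24` and
   unit grid spacing and time step.

The initial colony is an approximately circular disk of radius
`init_radius` (20 grid lengths, 1257 blocks — every integer site within
Euclidean distance <= 20 of the grid center), each block independently
dark with probability `init_dark_fraction`, over a zero trehalose field
and with empty pools. Division of labor then bootstraps itself: dark
blocks accumulate carbon, leak trehalose, the field builds up where the
colony is dense, interior blocks cross `T_DL` and flip to light, and the
light subpopulation — fed by a resource it does not produce — expands
where trehalose is replenished.

```{r quick-run, eval = FALSE}
traj <- simulate_colony(sim_config(seed = 42))
traj
radial_state_profile(traj$state, n_bins = 5)
```

## Parameters

All parameters are fields of `sim_config()`; defaults are the wild-type
parameterization.

| symbol | default | units | meaning |
|---|---|---|---|
| `f` | 0.125 | — | dark-block aspartate flux fraction sent to N (the rest becomes C); swept over [0, 1] |
| `AspU` | 4.0 | — | aspartate uptake relative to `Cmax`; > 1 because aspartate is saturating; swept over [1, 8] |
| `Y` | 0.31 | C/N | yield of aspartate-carbon conversion (< 1: the same flux also feeds biosynthesis) |
| `Pf` | 0.049 | /step | fraction of the internal C pool leaked as trehalose |
| `secretion_cap` | 0.12 | units/step | absolute secretion limit, guarding against long-undivided blocks dumping their pool |
| `ExN` | 4.0 | — | multiplier on the light-block minimum N reserve |
| `g` | 0.04 | /step | division probability once reserves suffice (same for both states) |
| `Cmax` | 0.05 | units/step | maximal trehalose consumed by a light block |
| `T_DL`, `P_DL` | 1.5, 0.5 | units, /step | dark-to-light switching threshold and probability |
| `T_LD`, `P_LD` | 1e-4, 1e-4 | units, /step | light-to-dark switching threshold and probability |
| `D_eff` | 0.24 | grid²/step | scaled trehalose diffusion constant |

Runtime settings: `grid_shape` (201 x 201), `n_steps` (750, roughly six
days of colony development), `seed`, `init_radius` (20),
`init_dark_fraction` (0.97), `boundary_condition` (`"no_flux"`),
`light_rule` (`"extra_N"`), `on_boundary_contact` (`"warn"`).

Design choices where the model description is open:

* **Initial dark share.** The initial dark fraction is stated as a 95–99%
  range; we draw each block independently dark with a single configurable
  probability, defaulting to the midpoint 0.97 — the simplest generative
  reading of a stated range. Light seeds are placed uniformly (no
  clustering rule is given).
* **Initial pools.** All pools start at zero, forcing an accumulation
  phase before the first divisions; no initial reserve values are part of
  the model statement.
* **Grid size.** 201 x 201 (odd, so the center is a lattice site) leaves
  80 grid lengths of headroom around the radius-20 seed, ample for 750
  steps of growth; the engine warns (or aborts, per
  `on_boundary_contact`) if the colony ever touches the outer ring.
* **Disk membership.** Euclidean distance <= radius on integer
  coordinates; the <= convention is what yields the canonical 1257-block
  seed.
* **Light eligibility.** The division requirement for light blocks is
  C >= 1 together with N >= `ExN`: carbon minima are shared by both states
  and `ExN` is defined as *extra nitrogen* for light cells. The
  alternative reading (C >= `ExN`, N >= 1) is available as
  `light_rule = "swapped"` for sensitivity checks rather than silently
  discarded.
* **Eligibility comparisons** use `>=` for both states; with continuous
  pools the boundary between `>` and `>=` has measure zero.
* **Secretion** is computed from the pool *after* the step's carbon
  addition and deducted from it, so block carbon plus field trehalose is
  conserved exactly by construction.
* **Switch survivors.** Pools are retained unchanged across a state
  switch; discarding them would introduce an unstated loss term.

## The engine: ordering, randomness, reproducibility

Blocks are processed in a fresh uniform random permutation each step (a
fixed raster order would bias growth direction). Daughters born during a
step are appended but not processed until the next step, preventing
within-step division chains. All randomness flows from one seeded R
stream with a fixed per-step draw order — permutation, one switch draw
per block, one division draw per block, then site tie-breaks in
processing order — so a configuration plus seed reproduces a trajectory
byte for byte, including snapshot files (checksummed in each run's
manifest).

A structural observation simplifies the sweep: since a site holds at most
one block and a block secretes into or consumes from *its own* site only,
while diffusion runs after all agents, no block's local field reading is
affected by any other block within the same step. Live field updates and
a frozen per-step field snapshot are therefore provably the same
dynamics, and the processing order matters only when two eligible
dividers compete for one empty site. This is also why the switching,
metabolism and eligibility phases can be computed as vectorized
arithmetic over all blocks without changing a single trajectory: the test
suite verifies the vectorized path against a straight-line single-block
reference implementation, bit for bit, on 10^4 randomized inputs.

## Numerics

The FTCS scheme with unit spacing is stable and positivity-preserving iff
`D_eff <= 1/4`; `validate_config()` and `ftcs_step()` refuse anything
larger before computing (the default 0.24 sits just inside). Under the
default `"no_flux"` boundary (edge replication — an agar plate neither
feeds nor drains trehalose at its rim, and the upstream description
leaves the boundary unstated, so this is an assumption worth knowing
about) the discrete mass `sum(field)` is conserved to floating-point
rounding; `"absorbing"` (zero ghost cells) is offered as the alternative
and loses mass through the rim. Field serialization uses 17 significant
digits, which round-trips IEEE doubles exactly.

Degenerate inputs behave sensibly: `init_radius = 0` seeds a single
central block; `n_steps = 0` yields a trajectory with only the initial
record; an empty state diffuses its field and nothing else; a saturated
neighborhood simply skips the division.

## What the simulations show — and what they cannot

With default parameters the colony develops the hallmark organization: a
predominantly dark bulk with light blocks enriched toward the expanding
rim, dark lineages dividing markedly slower than trehalose-fed light
ones, and only a negligible share of dark blocks ever hitting the
secretion cap (all three are asserted quantitatively in the test suite on
a 750-step wild-type run). The two regime predictions are likewise
reproduced as paired, seeded sweeps: raising `f` starves the carbon
branch — at `f = 0.5` dark divisions all but cease, and at `f = 1` no
trehalose is ever made and no light lineage ever divides — while colony
size increases monotonically in `AspU` (tested as strictly ordered means
over `{1, 4, 8}` with five shared seeds at 300 steps, a problem size
chosen to keep the full suite fast while leaving the ordering
unambiguous).

These are statements about the model, not about yeast. The generator
emulates the *mechanism* — budgeting, leakage, diffusion,
threshold switching — on a coarse lattice with synchronous unit time
steps. It does not emulate measured colony geometry, real trehalose
kinetics, cell death, nutrient gradients in agar depth, or any biological
noise structure beyond the model's own stochasticity; passing tests
demonstrate internal consistency and the stated parameter-regime logic,
not quantitative agreement with microscopy data. The wall-clock label
(750 steps ≈ six days) is narrative only; no physical time unit enters
the dynamics.

## Known limitations

* 4-neighborhood lattice growth only; no continuous space, hexagonal or
  8-neighbor variant.
* No aspartate field: uptake always succeeds, by construction.
* No death, starvation penalty or reserve decay, so block counts never
  decrease and long runs on small grids end boundary-limited.
* The division-interval metric conditions on lineages that divide at
  least twice; slowly dividing states are under-sampled early in a run.
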