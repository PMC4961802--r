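---
title: "Model and methods: ATP-dependent endothelial rearrangement on a lattice sprout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: ATP-dependent endothelial rearrangement on a lattice sprout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The biological question

A growing blood-vessel sprout is led by a migratory *tip* cell and elongated
by trailing *stalk* cells. These are positions, not fates: endothelial cells
continuously overtake one another so that the most competitive cell leads.
Competitiveness is set by VEGF receptor signalling — VEGF activates VEGFR2,
VEGFR2 drives Dll4 expression, Dll4 activates Notch on the neighbours, and
Notch downregulates their VEGFR2 — which produces an alternating
("salt-and-pepper", S&P) pattern of activated and inhibited cells. Glycolytic
ATP modulates the cytoskeletal machinery downstream of this circuit: cells
with reduced glycolysis (e.g. PFKFB3 knockdown) form fewer filopodia, are
more strongly adhesive and lose tip-cell competitions. In mosaic spheroid
assays, knockdown cells take the tip in only 22.4% of 1:1 knockdown:wild-type
sprouts (instead of 50%) and 66.8% of 9:1 sprouts (instead of 90%).

`angiosprout` is an agent-based simulator of this system. ATP availability
enters through three effectors, each scaled by a constant `k` (1 = wild
type):

* **E^FIL^** (`k_FIL`) — the probability of filopodia extension;
* **E^COR^** (`k_COR`) — the probability of forming junctional cortex
  protrusions, the machinery of relative cell movement;
* **E^ADH^** (`k_ADH`) — the binary classification of intercellular adhesive
  strength via VE-cadherin endocytosis.

The simulator reproduces the calibration experiments (mosaic tip
competition), the Notch-inhibition (DAPT), elevated-VEGF and VEGFR2-blockade
(SU5416) scenarios, and the quantification algorithms used to score them:
tip identification on the front grid row, overtake counting, migration,
adhesive-strength tracking and S&P pattern scoring.

# Geometry

The sprout is a 2-D lattice on the unrolled cylindrical vessel wall:
`x` (axial, 0-based) increases towards the sprout front, `y`
(circumferential, 10 sites) wraps. Ten cells start as rectangular
territories, two per cross-sectional band of 10 axial sites, 50 sites per
cell; the remaining lattice ahead of the front is free medium. The
circumference is fixed at 10 sites so the front row of the lattice *is* the
10-grid-site window of the tip-identification rule. A cell's *memAgents* are
its boundary sites (any 4-neighbour not its own, with wrap) plus its
filopodium sites.

The original model in this lineage represents cells as membrane agents
connected by Hookean springs in 3-D. Here the cortex appears instead as
energy terms of a Cellular-Potts Hamiltonian (perimeter tension, contact
energies) and filopodial pulling as an energy bonus — the measured
observables (front-row occupancy, axial centres of mass, junction adjacency,
filopodia counts) live on the lattice.

# Signalling dynamics

One timestep is 30 s. Per cell `c` with `M_tot` memAgents and receptor
capacity `R_c`:

1. **Activation.** Each memAgent at axial position `x` contributes
   `V'_m = (R_c / M_tot) · min(1, m·(V0 + g·x) / (K_sat · f))`; the sum is
   the cell's active VEGFR2, `Vp_c`. `m` is the VEGF multiplier (1, 1.44, 2,
   10), `f ≥ 1` the VEGFR2-kinase-inhibition fold (SU5416). Filopodia carry
   receptors and reach into higher VEGF, so protrusive cells amplify their
   own signalling — the positive feedback of the tip phenotype.
2. **Dll4 production.** The target `min(D_max, delta_D · Vp_c(t))` takes
   effect after the expression delay `tau` and is approached with
   first-order kinetics at rate `rho_D`.
3. **Notch activation.** `Np_c` is the junction-length-weighted mean of the
   neighbours' *suprathreshold* Dll4 (`D ≥ theta_D`); DAPT sets `Np_c = 0`.
4. **Receptor downregulation.** The target
   `clamp(V_max − sigma · Np_c(t), R_floor, V_max)` takes effect after `tau`
   at rate `rho_R`.
5. **Effective levels.** `Vhat`, `Nhat` are trailing 60-step moving
   averages; they drive adhesion classification and protrusion gating.

A cell is *signal-active* when `D ≥ theta_D` and `Vp ≥ theta_V` (inclusive).

Three features of this scheme deserve comment, because each was forced by a
qualitative phenotype rather than chosen freely:

* **First-order kinetics (`rho_D`, `rho_R`).** With instantaneous jumps
  after the delay, the ten delayed negative-feedback loops synchronize into
  a global relaxation oscillation at every VEGF level and no stable S&P
  pattern can form. Finite synthesis/turnover rates damp the oscillation
  while leaving the delay intact.
* **Suprathreshold Dll4 presentation.** If arbitrarily low Dll4 activated
  Notch in proportion, a weakly activated cell (too little VEGF input to
  reach threshold itself) could still silence all its neighbours, and the
  sprout locks into patterns with fewer than three active cells. Requiring
  presentation competence (`D ≥ theta_D`) means a cell can only suppress a
  niche it could itself fill.
* **Basal capacity `R_floor`.** Notch cannot remove basal VEGFR2. At normal
  VEGF this is invisible (inhibited cells sit far below threshold anyway),
  but at saturating VEGF every cell — including maximally inhibited ones —
  reaches threshold activity: the sprout homogenizes into an all-active
  state, lateral inhibition loses its grip, and the S&P alternation
  disappears. This is the high-VEGF disorganization phenotype, and it
  emerges from receptor arithmetic rather than from a switch.

## Calibration of the signalling defaults

The binding criterion is: a resting 10-cell sprout (movement disabled) at
normal VEGF must settle into a stable configuration with exactly 3
signal-active, pairwise non-adjacent cells within the 1,000-timestep
stabilization window — 3 active cells being the ideal S&P pattern for 10
cells in this geometry. The defaults (`sigma = 12`, `delta_D = 1.35`,
`theta_D = 40`, `theta_V = 30`, `R_floor = 32`, `tau = 8`,
`rho_D = rho_R = 0.12`, gradient `V0 = 0.5`, `g = 0.05`, `K_sat = 5`)
satisfy it for the large majority of seeds with median settling around 300
timesteps. The delay had to be shorter than first guessed (8 steps = 4 min,
not 15 min): longer delays push settling past the stabilization window.

Two caveats are part of the honest picture. First, roughly one seed in five
settles into an alternative packing (2 or 4 active cells) — the
ladder-shaped cell-contact graph admits these, and the stochastic filopodia
that break the front-pair symmetry occasionally push a fourth, rear cell
over threshold. The property tests therefore assert the exact-3 pattern for
the large majority of seeds rather than all. Second, the stochastic
filopodia are load-bearing for patterning: with them disabled the clamped
dynamics erase the initial heterogeneity and geometrically equivalent cells
deadlock in perfect synchrony.

# Cytoskeleton

Each cell owns `A_max = 100` actin units; every filopodium site binds one
unit, returned on retraction (conservation holds at every step). Filopodia
are 1-site-wide axial chains, at most one per circumferential column,
growing from front-edge membrane sites. A site extends with probability
`min(1, k_FIL · C · V'_m / (V_max / M_tot))` — the E^FIL^ effector — and
tips retract spontaneously (`p_ret`) or when local activation falls below
`v_ret` (inhibited cells lose their filopodia). Filopodia are not
volume-exclusive: chains may reach over neighbouring cell bodies towards
the gradient (slower by `fil_over` if so configured), which is how a cell
behind the front can still sense ahead and compete. Filopodium sites count
as memAgents (they sense VEGF and carry receptor share) but never as
cell-body occupancy for the tip rule.

# Rearrangement

Junctional dynamics are a modified Cellular Potts model: per timestep,
`n_attempts = 60` random boundary copy-proposals, accepted with Metropolis
probability `min(1, exp(−ΔH/T))`. The Hamiltonian has heterotypic contact
energies `J0 − (α_i + α_j)` (strong adhesion ⇒ larger bonus α ⇒ lower
interfacial energy ⇒ contacts harder to break), cell–medium contact `J_cm`,
a quadratic area constraint and cortex tension `γ·perimeter`.

*Adhesion (E^ADH^).* A cell is WEAK iff `k_ADH · Vhat ≥ eta` (high VEGFR2
activity ⇒ VE-cadherin endocytosis ⇒ weak junctions); `k_ADH < 1` (less ATP
⇒ less endocytosis) shifts cells toward strong adhesion. The classification
is strictly binary, per the adhesive-strength scoring convention.

*Cortical protrusions (E^COR^).* Expansion proposals are gated by
`min(1, k_COR · lambda_mig · (1 − min(1, Nhat/N_ref)))`: Notch suppresses
protrusions on an absolute scale `N_ref`, so a uniformly Notch-high sprout
(saturating VEGF) is uniformly non-motile rather than rescaled to full
drive. Protrusions are polarized up the VEGF gradient (multipliers
`cor_lat`, `cor_back` for lateral/rearward proposals); polarized junctional
protrusions are what let an active cell actually migrate tip-ward.

*Tension homeostasis.* Two gate bypasses keep the dense cylinder from
jamming: a cell squeezed more than `spread_slack` sites below its target
area re-spreads passively into neighbouring cells, and a neighbour bloated
above target yields its excess passively. Without these, interior motion is
impossible — a mover's rear must be back-filled by a gated neighbour, and
volume exchange deadlocks. Breaching into free medium is never exempt: that
always needs the protrusion machinery.

*Filopodial traction (`beta_fil`).* An expansion into a site covered by the
cell's own filopodium gets an energy bonus and absorbs the filopodium
site — the lattice version of the body following its protrusion. This is
the main mechanical route from `k_FIL` to tip competition: front advance
into free medium is expensive (`2(J_cm+γ)` per site) unless subsidized by
traction, so cells without filopodia barely lead.

*Connectivity.* Proposals that would split the invaded territory are
rejected before evaluation: a fast local (Moore-neighbourhood) certificate
with an exact BFS fallback, so legitimate passes (e.g. breaking a thin
one-row cap that remains globally connected) are not spuriously blocked.

Movement is disabled for the first 1,000 timesteps, letting the S&P pattern
form before rearrangement starts; a run lasts 15,000 timesteps (125 h), the
alternative endpoint being 2,880 (24 h). Metrics are computed from the
post-stabilization window.

# Quantification

* **Tip identification.** The cell with most cell-body memAgents among the
  10 sites of the front-most occupied row; exact ties go to the higher
  active VEGFR2, double ties to the lower cell id. Filopodia never count:
  the tip is decided by cell-body position, like the manual in vitro
  scoring.
* **Overtakes.** A persistent inversion of a cell pair's `COM_x` rank order
  (debounce 10 timesteps = 5 min; transient flips do not count). Centres of
  mass for positional metrics are cell-body centres: including protrusion
  sites would let filopodia flutter dominate the count at high VEGF.
* **Migration.** `Σ_t |COM_x(t+1) − COM_x(t)|` per cell.
* **Adhesive strength.** Per-genotype fraction of strongly adhesive
  cell-timesteps.
* **S&P scoring.** Per timestep, signal-active cells with at least
  `theta_A` deployed actin units are *sprout active*, without *stunted
  active*; a stable pattern requires sprout + stunted active = 3 with no
  two active cells adjacent. Contiguous stable runs give the average and
  maximal pattern times; the gaps before newly formed patterns give the
  stabilizing time (the counter does not run during a stable pattern and
  resets when a new pattern forms; a window with no pattern reports the
  full window length).
* **Statistics.** Tip-cell competition is tested with a two-sided Fisher
  exact test implemented by hypergeometric enumeration; replicate sets use
  at least 50 seeds (150 for competition quantification), each seed
  determining the initial genotype placement and all stochastic dynamics.

# Calibration of the effector constants

`calibrate_single_effector()` sweeps a mechanism's `k` over a grid, runs
seeded 1:1 and 9:1 mosaic replicate sets at every point (50 per point by
default), selects `k*` by summed squared deviation from the in vitro
fractions (22.4%, 66.8%), re-estimates the best point and its neighbours at
150 replicates, and checks both targets against the 95% binomial confidence
intervals. For the filopodia mechanism a single `k* ≈ 0.55` matches both
fractions. Cortex-only modification saturates near 32%/92% — suppressing
protrusions cannot prevent a knockdown cell that starts at the front from
keeping the tip — and adhesion-only modification barely moves competition
(the weakly adhesive class occupies only a few percent of cell-time at
normal VEGF); for these the calibration reports its failure path. That only
filopodia-containing mechanisms reproduce the competition data is itself
the central mechanistic conclusion this model family supports.

# What the simulations do and do not show

The generator emulates: lateral-inhibition patterning with an axial VEGF
gradient, actin-limited VEGF-sensing filopodia, differential-adhesion and
protrusion-driven rearrangement, mosaic genetics and pharmacological
(all-cell) perturbations. It does not emulate: proliferation, lumen
formation, 3-D mechanics, VEGF consumption or diffusion dynamics, molecular
VE-cadherin turnover, or any in vivo context — so passing tests support the
mechanistic logic (which effector can explain which phenotype), not
quantitative predictions about real vessels.

Known limitations, found and kept honest during development:

* At 2x VEGF the disorganization is driven by body-surface VEGF saturation
  at the front, so pharmacological filopodia inhibition cannot normalize it
  here (the saturation function `min(1, m(V0+gx)/K_sat)` has no spare
  degree of freedom: rescaling `(V0, g, K_sat)` jointly is the identity).
  The corresponding direction-only acceptance checks are expected to fail
  and are left failing rather than weakened.
* Sixfold VEGFR2 inhibition at 10x VEGF (receptor-proximal division,
  effective drive ≈ 1.67x) already restores near-normal dynamics on its
  own, so the combined anti-VEGF + anti-glycolysis treatment — while fully
  normalizing relative to untreated 10x and to glycolysis inhibition
  alone — cannot strictly improve on VEGFR2 blockade alone on every metric.
* Under DAPT at normal VEGF the adhesive-strength gap between knockdown and
  wild-type cells is directionally correct but small, because adhesion
  classification at normal VEGF is nearly saturated towards STRONG.

# Reproducibility and problem sizes

Every stochastic element of a run — genotype placement, initial receptor
heterogeneity, filopodia draws, Metropolis proposals — flows from one
64-bit generator seeded by the run seed, so a `(configuration, seed)` pair
is bit-reproducible. Default problem sizes: 10 cells on a 120x10 lattice,
15,000 timesteps per run (~0.2 s wall time), 50-replicate sets for
perturbation phenotypes, 150-replicate sets for competition fractions, and
a 9-point k-sweep at 50 replicates per point with a 150-replicate
refinement for calibration.
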