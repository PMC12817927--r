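---
title: "Methods: a constraint-based agent model of the colonic microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a constraint-based agent model of the colonic microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonsim)
```

## The model

`colonsim` simulates the colonic microenvironment as a 2D grid in
which every cell of the epithelium and every bacterium is an
individual agent. The simulation couples three layers:

1. **Metabolism.** Each agent carries a genome-scale-style metabolic
   model (stoichiometric matrix $S$, bounds, biomass objective). Per
   1-h iteration the agent's fluxes are the parsimonious FBA solution:
   stage one maximizes growth $\mu^\* = \max c'v$ s.t. $Sv = 0$,
   $lb \le v \le ub$; stage two minimizes $\sum_i |v_i|$ with
   $c'v = \mu^\*$ pinned (flux splitting $v = p - n$). pFBA removes
   the arbitrary flux of alternate optima and internal cycles, so the
   recorded exchange fluxes are parsimonious and reproducible.
2. **Environment.** Each compound is a per-cell amount field (mmol).
   Uptake bounds follow the amount-to-rate rule
   $lb = -\min(|lb_{default}|,\; a_{local} / (m \cdot \Delta t))$
   with $a_{local}$ the pool the exchange faces, $m$ the agent's dry
   weight, $\Delta t$ the step. After the solve, the environment is
   debited/credited by $v \cdot m \cdot \Delta t$ per compound.
   Because agents act sequentially in a randomized order and bounds
   are recomputed from the current pools, co-located agents can never
   jointly overdraw a pool.
3. **Population dynamics.** Bacteria grow exponentially
   ($m \leftarrow m e^{\mu \Delta t}$), divide at twice the minimum
   mass with an equal split onto a free 8-neighbor cell, die after
   two consecutive zero-growth steps, and random-walk within the
   permitted sectors. Host cells grow linearly
   ($m \leftarrow m + \mu m_0 \Delta t$), are capped at the crypt
   weight equivalent, and never move, divide, or die.

## The arena

Five sectors partition the default 179 x 24 grid of
0.00025 x 0.00025 cm cells: 59 rows of lumen, a 54-row mucus blanket
split 2:1 into outer (36) and inner (18) rows, and a 66-row tissue
region. Two half-crypts are rasterized as 31-cell vertical walls on
the lateral columns plus an 8-cell basal band on the tissue surface,
giving 70 host slots; all other tissue cells form the intermediate
space, where bacteria may sit next to host cells but luminal
compounds do not diffuse.

Three geometric choices were genuinely open and are our own:

* **The crypt raster.** Published anchors fix 31.1 epithelial cells
  per crypt column and 70 host slots in total, but not the raster
  between them; two 31-cell walls plus an 8-cell basal band is the
  simplest shape reproducing both.
* **The intermediate region.** We make the whole tissue block
  (minus the 70 host cells) intermediate rather than a one-cell
  adjacency fringe. Reason: the published starting counts (below)
  force the three bacterial sectors to cover only ~63% of the arena,
  which a thin fringe cannot accommodate; a wide submucosal spacer
  can. Bacteria rarely reach deep tissue anyway: they enter it only
  through degraded inner mucus.
* **Layer widths.** Absolute widths in rows are configuration values;
  the defaults (59/36/18/66) are documented as the set that
  reproduces the published seeding counts under the inoculum rule.

## Seeding

The printed inoculum-partition formula is dimensionally inconsistent
(its volume term multiplies four lengths). We adopt the reading
$volume_{arena} = (area_{arena})^{3/2}$ and

$$N_{sector} = \mathrm{round}\!\left(\frac{area_{sector}}{area_{total}}
  \cdot volume_{arena} \cdot 2\times 10^7\right),$$

which under the default geometry yields 29.00 / 17.70 / 8.85, i.e.
the published 29 / 18 / 9 for lumen / outer / inner mucus. The gut
volume (0.37 cm^3) is retained as configuration context but does not
enter this formula — dividing by it cannot reproduce the printed
counts for any row layout. A `seed_override` bypasses the formula.
Species composition within each sector uses largest-remainder
apportionment of the relative abundances (deterministic at the
expected value); positions are uniform over the sector's free cells.

## Transport

Diffusion is explicit conservative FTCS on the 4-neighbor stencil
with per-cell coefficients and automatic sub-stepping to satisfy
$D\,\delta t / h^2 \le 1/4$. Interface coefficients are arithmetic
means, zeroed when either side is impermeable, which yields zero-flux
borders at sector boundaries for free. Coefficients come from a
power law $D = a\,\mathrm{MW}^b$ fitted per medium
(`fit_power_law()`); unknown molecular weights fall back to
glucose's.

The shipped calibration table is **synthetic**: the historical
intestinal diffusivity measurements behind the original coefficients
are not redistributable, and physically realistic coefficients
(~1e-5 cm^2/s) would both demand ~1e6 sub-steps per hour on a 2.5 µm
grid and flatten every gradient within minutes of model time. The
defaults (glucose: 1.49e-9 cm^2/s in the lumen, half that in mucus,
with the exact 2/3 and 1/3 outer/inner multipliers) preserve the
qualitative ordering lumen > outer > inner >> impermeable at a few
hundred sub-steps per hour. Consequences of a green diffusion test:
mass conservation, stability, and agreement with the analytic heat
kernel at matched $D \cdot t$ — not quantitative transit times.

Mucus compounds never diffuse; the per-cell mucus concentration of
the inner layer is 4x the outer's (the printed sentence is
self-contradictory about the direction; we put the denser mucin at
the epithelium, and a flag flips it). Blood compounds and oxygen
exist only in the host area: host-sector cells are reset to the blood
level each step (Dirichlet source) and diffuse into the intermediate
space only, which keeps the arena anaerobic outside the tissue by
construction. Lumen advection (peristalsis) is available (`wrap` or
fresh-medium `inflow`) but off by default, matching the reference
experiments.

## Host cells

Host biomass is expressed in bacterium-equivalent units: minimum
weight $132.73229/4.42 \approx 30\times$ the 1 pg bacterial default
(the cross-section ratio of a 13 µm colonocyte to a bacterium), and
maximum weight $1000/70$ times the minimum (70 modeled cells stand in
for ~1000 crypt cells). Host models exchange apically (`e`, the
pool of adjacent intermediate/inner-mucus cells) and basolaterally
(`u`, the blood reservoir); dietary compounds are re-tagged into an
exclusive `d` compartment that host models cannot see, so
diet-derived and host-consumable pools never mix.

## Context-specific host models

`classify_reaction_expression()` maps gene expression to reactions
through GPR rules (AND = min, OR = max) and classifies reactions at
the quartiles: $\le Q_1$ low, $\ge Q_3$ high (inclusive at the
quartile). `imat()` then solves the integrative MILP — maximize the
count of high reactions carrying $|v| \ge v_{min}$ plus low reactions
at zero — honoring forced reactions and unconstrained nutrition
exchanges, and drops the low reactions that the optimum switches off.
Every exchange reaction, the ATP demand (`DM_atp_c`) and all forced
reactions are retained unconditionally. Values the source did not
state and we fixed: $v_{min} = 10^{-3}$ mmol/gDW/h (the common iMAT
magnitude), inclusive quartile ties, and branch-and-bound over the
package's own simplex (no external solver exists in the supported
stack; all solves are cross-checked against enumeration oracles in
the tests).

## The toy community

Genome-scale reconstructions are out of scope, so the generator
builds hand-sized, carbon-balanced stand-ins: a mucus degrader
(N-acetylneuraminate or dietary glucose to acetate), an SCFA producer
(glucose, mucin fucose, or cross-fed acetate to butyrate), generic
fermenters with seed-jittered yields, and a colonocyte (blood glucose
and oxygen, apical butyrate, ATP demand, alanine synthesis route).
N-acetylneuraminate is deliberately usable only by the degrader, so
selective mucus degradation and acetate cross-feeding emerge rather
than being scripted; fucose exists so that non-degraders seeded in
mucus are viable, mirroring the reference workflow's requirement that
every model grows on the lumen-plus-mucus medium. The toy medium's
scales are chosen once for 1 pg agents: 5e-11 mmol glucose per lumen
cell (uptake-saturating), 1.5e-11 mmol per outer-mucus cell of each
mucin sugar (a maximal degrader consumes ~20-30% of its cell per
hour, so the movement gate opens after a few hours of foraging), and
1e-9 mmol per host cell in blood (non-limiting). What the toys do
not emulate: realistic yields and maintenance costs, redox and
elemental balance beyond carbon, pH/oxygen sensitivity, hundreds of
exchangeable metabolites. A green toy test therefore establishes the
*mechanics* (spatial gating, cross-feeding topology, conservation,
schedule), never literal community composition or the published
compound lists.

## Numerical choices

* LP: two-phase bounded-variable primal simplex, Bland's rule
  (guaranteed termination), fresh basis factorization per pivot
  (problems have tens of variables; robustness beats speed), feasibility
  tolerance 1e-9. Infinite bounds are clamped at 1e6.
* pFBA pins the optimum by equality; with an exact simplex vertex this
  is safe and keeps $\sum|v|$ comparable across runs.
* Degenerate duals: the reported shadow prices are the optimal-basis
  duals; tests assert agreement with finite differences, and any
  optimal dual vector is accepted where the optimum is degenerate.
* Zero thresholds: exchange fluxes below 1e-12 are not recorded;
  net-flux sums below 1e-6 are classified zero (published rule);
  growth below 1e-9 counts as starvation.
* The agent update order is re-randomized every iteration from a
  dedicated RNG stream; placement, order, and movement use separate
  streams derived from the replicate seed so toggling one feature does
  not shift another's draws.

## Known limitations

* 2D, two half-crypts, single host cell type, no villi.
* Biomass of dead cells is not recycled (lysis chemistry unstated).
* The interaction-frequency denominator is (replicate x metabolic
  time point) units; a replicate-only variant is available by flag.
* Host "apical" pools include adjacent inner-mucus cells because the
  raster puts surface epithelium directly under the inner mucus.
* The blood reservoir is a Dirichlet boundary: blood and oxygen pools
  are open and excluded from conservation accounting.
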