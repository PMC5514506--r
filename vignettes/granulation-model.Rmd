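---
title: "The granusim model: individual-based anaerobic granulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The granusim model: individual-based anaerobic granulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granusim)
```

## The system

In an up-flow anaerobic sludge blanket (UASB) reactor, dispersed
microbes self-organise into dense spherical granules. granusim models
this *de novo* granulation with an individual-based (agent-based)
model of two trophic groups: **acidogens**, which ferment glucose to
acetate, and **methanogens**, which convert acetate to methane gas.
Each cell is a spherical particle with a mass, a position in a 2-D
domain, and a starvation clock. Cells grow by Monod kinetics on the
local solute concentrations, divide above a radius threshold, are
packed by shoving and adhesion mechanics, and irreversibly turn into
inert dead biomass after prolonged starvation. The emergent object is
a granule with the experimentally observed radial stratification: a
dead core, a methanogen shell, and an acidogen rim facing the glucose
supply.

Two scenarios are built in. The **reactor** (macroscale) scenario is
mechanics-only: dispersed cells under random agitation and mutual
adhesion collapse into a handful of agglomerates, the nuclei of future
granules. The **granule** (mesoscale) scenario starts from one such
mixed agglomerate — 100 acidogens and 100 methanogens in a small
central disc by default — and grows it into a mature granule while
glucose is supplied from all four domain edges.

## Solute fields

Three solutes live on a square node-centred grid: glucose $S_g$,
acetate $S_a$ and methane $S_m$. Because biomass growth is far slower
than diffusion, the fields are treated as in (pseudo-)steady state
with respect to the biomass distribution. Each biological step solves

$$0 = \nabla\!\cdot\!\big(B(x,y)\,D\,\nabla S\big) + r(S),$$

with the reaction terms

$$r_g = -\mu_a(S_g,S_a)\,\frac{B_a}{\alpha_{bg}},\qquad
  r_a = +\mu_a\,\frac{\alpha_{ag} B_a}{\alpha_{bg}}
        -\mu_m(S_a)\,\frac{B_m}{\alpha_{ba}},\qquad
  r_m = +\mu_m\,\frac{\alpha_{ma} B_m}{\alpha_{ba}},$$

where $B_a, B_m$ are the rasterized live biomass concentrations and
$B(x,y)$ is the relative diffusivity: 1 in free liquid, $\gamma=0.3$
wherever biomass (live or dead) occupies a grid cell, representing the
increased mass-transfer resistance of the biofilm matrix.

Growth follows Monod kinetics with non-competitive product inhibition
for the acidogens and plain Monod for the methanogens:

$$\mu_a(S_g,S_a) = \hat\mu_a\,\frac{S_g}{K_{sg}+S_g}\,
   \frac{K_i}{K_i+S_a},\qquad
  \mu_m(S_a) = \hat\mu_m\,\frac{S_a}{K_{sa}+S_a}.$$

Two equation-level choices deserve a note. First, methane production
is scaled by the methane yield $\alpha_{ma} = 0.26$ g CH~4~ per g
acetate, so that acetate consumed and methane produced are
stoichiometrically linked; the `literal_methane_stoich` switch removes
this factor for users who want methane produced at the full rate of
acetate turnover. Second, the methanogen biomass equation uses
$\mu_m(S_a) B_m$, the methanogen growth law, which is dimensionally
consistent with the rest of the model.

### Boundary conditions

The three solutes get three different far-field treatments, matching
their physical roles:

* **glucose** — held at the bulk value `SBulk` throughout the
  well-mixed reactor liquid, which in an agitated system extends up to
  a diffusive **boundary layer** around the biomass
  (`boundary_layer`, default 40 µm): concentration gradients exist
  only inside the biofilm and its boundary layer, as in the
  individual-based biofilm simulators this model family builds on.
  Numerically the bulk region is pinned by a stiff exchange term
  (penalty rate 10⁶ h⁻¹), which keeps the cached matrix pattern
  fixed; the domain edge additionally carries the bulk value as a
  Dirichlet ring. Setting `boundary_layer = Inf` recovers a pure
  edge-fed domain — in that mode the supply shrinks as the domain
  grows, and a granule in a wide domain starves long before reaching
  millimetre size;
* **acetate** — zero-flux: acetate is non-volatile and has nowhere to
  go, so it accumulates in the closed system. Under a closed boundary
  no steady state exists while there is net production, so the acetate
  field is advanced by one implicit-Euler transient step per
  biological step instead of a steady solve. This accumulation is what
  eventually throttles the acidogens (product inhibition) and feeds
  the methanogen bloom;
* **methane** — absorbing (zero Dirichlet): methane is volatile and
  diffuses out of the system; the cumulative production ledger, not
  the standing field, tracks the total yield.

The choice of a closed acetate boundary matters: with an absorbing
boundary most acetate produced in the acidogen rim escapes outward,
methanogens starve for the wrong reason, acidogens are never
product-inhibited, and the dead-core/methanogen-shell/acidogen-rim
stratification does not form.

### Discretization and numerics

The operator is a 5-point finite-difference stencil with harmonic-mean
face diffusivities across the liquid/biofilm jump, which keeps the
matrix symmetric positive definite. Monod uptake is linearized about
the previous iterate, $S/(K_s + S_{\mathrm{prev}})$, making the system
an M-matrix, so solved concentrations are nonnegative by construction
(values are additionally clipped at zero against round-off). Glucose
and acetate are iterated jointly (Picard) until the relative change
falls below `solver_tol` ($10^{-6}$ by default); methane follows in
one linear solve from the converged acetate sink, which enforces the
acetate-to-methane stoichiometry at field level. The sparse Cholesky
factorisation is symbolically cached per boundary mode, so each step
only refreshes numeric values.

The reference grid spacing is 2 µm (254 nodes across the 508 µm
domain). All granule-scale results in the test-suite and the
acceptance script use the coarse 8 µm mode (64 nodes), which resolves
the 20–40 µm solute penetration depths with a handful of cells while
keeping a 650 h simulation in the minutes range on one CPU; the
methods-level tests verify the solver against a dense direct solve on
16×16 grids to $10^{-6}$.

## Agents

Parameters follow the anaerobic-digestion literature: acidogens
(300 fg, $\hat\mu_a = 0.208\,h^{-1}$, $K_{sg} = 0.26$ g/L,
$K_i = 0.1$ g/L, yields 0.3 g biomass and 0.82 g acetate per g
glucose, death threshold 0.02 g/L glucose) and methanogens (1500 fg
plus a 10 fg EPS capsule, $\hat\mu_m = 0.1\,h^{-1}$,
$K_{sa} = 0.005$ g/L, yields 0.15 g biomass and 0.26 g methane per g
acetate, death threshold $10^{-5}$ g/L). Both divide at a 3 µm radius
and die after 48 h of continuous starvation; there is no biomass
decay. The EPS capsule is inert: it adds to the radius (and hence to
contact mechanics) but not to the kinetics.

Each step a cell gains $\Delta m = \mu m\,\Delta t$ (sub-stepped so no
sub-step changes a mass by more than 10%), consumes
$\Delta m/\alpha_b$ of its substrate and secretes
$\alpha_p \cdot \Delta m/\alpha_b$ of its product. The per-grid-cell
substrate draw is capped by the standing solute mass plus what the
solved fluxes deliver over the step; cap events are counted in the run
log. The starvation clock accumulates while the monitored substrate
sits below the species' death threshold and resets on recovery; at
48 h the cell converts irreversibly to the inert dead species, mass
preserved. Methanogens monitor their own substrate (acetate) by
default — their $10^{-5}$ g/L threshold is on the scale of $K_{sa}$ —
with `methanogen_starves_on = "glucose"` available as the literal
alternative. Division splits the biomass 0.5 ± 5% (uniform) between
daughters placed at a small antipodal offset along a random direction;
the asymmetry and random axis break lattice artifacts. Daughters each
carry a fresh EPS capsule, treated as secreted matrix not drawn from
substrate.

### Mass and geometry conventions

The paper-style parameter set gives cell masses and a division radius
but no density, so the package fixes `biomass_density` = 573 fg/µm³,
which makes a 300 fg acidogen a 0.50 µm sphere in 3-D terms. The 2-D
simulations use disc geometry with a fixed slice thickness
$\tau = 2$ µm: a cell of mass $m$ has radius
$r = \sqrt{m/(\rho\pi\tau)}$, and grid concentrations are
fg per (grid-cell area × $\tau$). Because both the boundary flux and
the biomass-to-area conversion scale linearly with $\tau$, the
emergent granule diameter and all specific (per-biomass) quantities
are insensitive to the choice of $\tau$.

## Mechanics

Overlap from growth and division is removed by **shoving**: every
pair closer than $(1+0.1)(r_i+r_j)$ receives equal-and-opposite
displacements along the centre line, half of $k = 0.5$ times the
overlap each, iterated until the largest single displacement falls
below `relax_tol` (0.1 µm in production, tighter in tests).
Coincident centres separate along a seeded random direction.
**Adhesion** attracts pairs within a reach of
$0.6\,(r_i+r_j)$ — with an absolute floor of 0.5 µm so that small
cells still capture neighbours — closing half of 0.5 of the gap per
pass, same- and cross-species strengths independently configurable.
One adhesion capture pass precedes the shove iteration in each
relaxation; iterating adhesion *against* shove would compress dense
clusters into persistent overlap. **Agitation** (reactor scenario)
gives every agglomerate — a connected component of the contact graph,
computed with the adhesion reach so tethered cells travel together — a
rigid Gaussian displacement ($\sigma = 5$ µm per step) plus a small
independent per-cell jitter (3% of $\sigma$), with displacement
clamping at the domain walls. The jitter is what makes adhesion
observable: without it, clusters never erode and adhesive and
non-adhesive runs are indistinguishable.

None of the mechanics constants are literature values; they were tuned
once on the reactor scenario until (i) 200 dispersed cells agglomerate
into a small number of clusters within a few hundred steps and
(ii) a preformed cluster holds together under agitation with adhesion
but disperses without it, and then frozen. Van der Waals substratum
attachment is deliberately absent — there is no substratum in a UASB
sludge blanket.

## Calibration of the bulk glucose supply

The literature parameter table used by the model does not include the
bulk glucose concentration of the reference granule run; only the scan
range 0.1–0.4 g/L is given. The default `SBulk` = 0.175 g/L was fixed
by a supply-side mass balance — the time-integrated diffusive glucose
flux through the boundary layer, times the biomass yields, must
provide the biomass of a mature sub-millimetre granule — followed by
one calibration pass against the two reported growth milestones
(≈0.5 mm at 650 h; ≈1 mm around 800 h in the wider domain). Under
perimeter-limited supply the granule radius grows essentially
linearly, so those two milestones are mutually inconsistent in the
strict sense (the second implies a doubling in 150 h); 0.175 g/L is
the joint best fit, reaching ~0.6 mm at 650 h and ~1 mm shortly after
1000 h. This mirrors how non-literature parameters are usually fixed
in this model family: against the reported morphology, then left
alone.

## What the simulations show (and what they do not)

The default granule run reproduces, at coarse grid, the qualitative
and scale features of mature anaerobic granules: sub-millimetre
diameter after ~27 days, a contiguous dead core, and the radial
ordering dead < methanogen < acidogen of mean distances from the
centroid. The reactor run shows agglomeration of a dispersed
inoculum. The parameter scan shows methane yield increasing with
glucose supply and decreasing when the inoculum is overloaded with
methanogens that the acetate supply cannot sustain.

The synthetic scenarios emulate a well-mixed UASB liquid around a
single 2-D granule slice. They do not emulate: up-flow hydrodynamics
and shear (agitation is an abstraction), granule breakage and
detachment, filamentous morphology, 3-D packing, complex feeds, or
the pixel noise of real fluorescence micrographs. Passing tests
therefore establish internal consistency with the model's equations
and qualitative agreement with reported granule morphology — not
quantitative prediction for a particular reactor.

A note on the specific methanogenic activity (SMA). The package
computes SMA as cumulative methane gas volume (at 0.716 g/L, 0 °C and
1 atm; configurable) divided by final total biomass, over the whole
run. Under the model's own stoichiometry this ratio has a hard
structure: each gram of methanogen growth implies
$\alpha_{ma}/\alpha_{ba} \approx 1.73$ g of methane, so whenever
methanogens capture a substantial share of the acetate the SMA lands
at hundreds of ml/g — the default run gives roughly 700 ml/g.
Reported literature values in the low ml/g range cannot be reproduced
by this cumulative definition for any parameterisation in which
methanogens grow appreciably; they presumably reflect a different
averaging window or normalisation. The definition used here is stated
precisely so the number can be interpreted.

## Problem sizes used by the test-suite and acceptance script

Unit and property tests run on miniature worlds (128–400 µm domains,
16–50 grid nodes, tens of cells, tens of hours). The study-scale
checks use the full 508 µm domain at the coarse 8 µm grid (64 nodes):
five seeds of 650 h for the maturation endpoints and the
stratification census. The wide-domain (1.16 mm) growth check uses
10 µm cells (116 nodes, which resolve the 40 µm boundary layer
exactly); the yield-trend scan runs its 27 replicates for 200 h on a
half-size domain (254 µm, 32 nodes) with a 30 µm seeding disc so the
largest inocula fit. These sizes keep the whole suite within a
desktop-minutes budget while leaving the physics unchanged; the 2 µm
reference grid is available through `grid_resolution` for production
use.

## Known limitations

* Agent substrate draws are Euler-compounded against fields solved
  once per step, so the agent ledger and the field sinks agree only to
  a few percent per step (asserted in the tests); the discrepancy does
  not accumulate into the granule geometry but is visible in strict
  mass-balance comparisons.
* The dead core is detected on radial bins with a 50% dead-mass
  majority rule; for very small or patchy cores the estimate is
  bin-width limited.
* Only square domains and node-centred square grids are supported.
* The reactor scenario does not model up-flow velocity fields; washout
  and shear selection are out of scope.
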