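---
title: "Modelling resource-driven neurite outgrowth and competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling resource-driven neurite outgrowth and competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritecomp)
```

## The model

`neuritecomp` simulates neurite outgrowth limited by a single growth
resource — free tubulin — on a compartmental representation of a neuron.
The neuron is a rooted tree of cylindrical compartments: one soma at the
root, shaft compartments along every neurite, and a constant-size
growth-cone compartment at every tip.

Tubulin dynamics follow a finite-volume balance on that tree. For
compartment $i$ with quantity $Q_i$ (mol), volume $V_i$ and concentration
$C_i = Q_i / V_i$:

$$\frac{dQ_i}{dt} \;=\; \sum_{j \in \mathrm{nbr}(i)}
  \frac{D\,A_{ij}}{d_{ij}}\,(C_j - C_i)
  \;+\; f\,v\,C_{\mathrm{parent}(i)}\,A_i
  \;-\; \sum_{c \in \mathrm{child}(i)} f\,v\,C_i\,A_c
  \;-\; b\,Q_i
  \;-\; \left[\,X\frac{dL}{dt}\,\right]_{\text{growth cone only}}$$

where $D$ is the tubulin diffusion constant, $A_{ij}$ the interface
cross-section, $d_{ij}$ the centre-to-centre distance, $f$ the fraction of
tubulin bound to the active transport system moving anterogradely at speed
$v$, $b$ a first-order decay, and $X$ the tubulin cost per metre of
neurite. The soma is a Dirichlet boundary: its concentration is clamped to
$C_{\mathrm{soma}}$ every step, and the injected mass is booked as
production (tubulin synthesis is overwhelmingly somatic, and somatic
concentration is under homeostatic control). Growth cones consume tubulin
when elongating and release it when retracting.

Neurite elongation is governed by the growth-cone concentration alone:

$$\frac{dL}{dt} = p\,C_{\mathrm{gc}} - q$$

with polymerization rate $p$ and concentration-independent
depolymerization rate $q$ (disassembly from existing microtubules does not
depend on the free pool). The defaults are calibrated so growth is zero at
$q/p \approx 5\,\mu M$ and $0.033$ mm/h at $10\,\mu M$:

```{r anchors}
p <- transport_params()
ms_to_mmh(elongation_rate(uM_to_molm3(10), p)) # mm/h at 10 uM
molm3_to_uM(p$q / p$p)                         # zero-growth concentration, uM
```

$X = 4\times10^{-14}$ mol/m comes from 1640 tubulin dimers per µm of
microtubule and roughly 15 microtubules per neurite cross-section.

## Parameters

| symbol | default | unit | meaning |
|---|---|---|---|
| `D` | 1e-11 | m²/s | tubulin diffusion constant |
| `f` | 6e-3 | – | fraction bound to active transport |
| `v` | 440e-9 | m/s | active transport speed (anterograde) |
| `b` | 5.67e-7 | 1/s | tubulin decay |
| `X` | 4e-14 | mol/m | tubulin consumed per metre of neurite |
| `p` | 1.83e-6 | m/(s·mM) | polymerization rate |
| `q` | 9.17e-9 | m/s | depolymerization rate |
| `C_soma` | 5.5e-3 | mol/m³ (5.5 µM) | clamped soma concentration |

Everything internal is SI; note 1 mM ≡ 1 mol/m³, so `p` multiplies
concentrations held in mol/m³ directly. Reporting helpers convert to µm,
µM, minutes/hours and mm/h.

## Moving mesh

Growth moves the growth cone but never resizes it (resizing the small tip
compartment would cause large artificial concentration fluctuations).
Instead the *second* compartment — the unique shaft directly proximal to
the growth cone — absorbs every length change. When it exceeds 2.5 µm it
splits into two halves, each inheriting half its tubulin; when it shrinks
below 0.5 µm it merges into its parent (lengths and quantities summed).
Both operations conserve tubulin and cable length exactly. If the parent
is the soma or a branch point, the sub-minimum compartment is left in
place and further retraction is clamped: a neurite can shrink to a growth
cone plus one minimal shaft but never disappears, and simulated trees
never lose branches. Because retraction is capped at `q` (≈ 0.55 µm per
minute), time steps up to ~30 s cannot step a shaft from within bounds to
a negative length.

## Numerics

The transport operator is linear in the quantities, so each step solves a
backward-Euler system $(I - \Delta t\,M)\,Q^{n+1} = Q^n$. On a tree this
system is solved exactly in $O(n)$ by eliminating leaves upward and
back-substituting from the root (no fill-in); the elimination is
implemented in C++. The scheme is unconditionally stable, conservative
(sealed-system mass drift is at rounding level over 10⁵ steps) and
positivity-preserving (the matrix is an M-matrix). Advection uses the
upwind donor-cell form — the flux into a compartment is $f v C$ of its
*parent* times the interface area — which keeps the operator
mass-conservative and positive. At a branch point each child receives
$f\,v\,C_{\mathrm{parent}} A_{\mathrm{child}}$: the flux *density* is
continuous across the bifurcation, as expected if transport runs on
microtubule rails that fill each daughter's cross-section. Interface areas
between unequal neighbours default to the distal compartment's
cross-section (the narrower child limits flux at tapering branch points);
the mean is available as an option.

Growth and remeshing are operator-split from transport: each step is
transport → growth (free kinetics or forced replay) → remesh. The
growth-cone concentration that drives $dL/dt$ is the post-transport value
at the start of the growth sub-step. Consumption is capped so the
growth-cone quantity never goes negative; every capping event is counted
and reported. A plain explicit-Euler transport mode (with a positivity
check that aborts on instability) is retained purely as an independent
cross-check of the implicit path; the two agree as $\Delta t \to 0$.

The default step is `dt = 1` s. The growth-cone compartment turns over its
tubulin in ~10 s under default consumption, so steps of 5–10 s resolve the
growth coupling well; long simulations in the package's experiment suites
use 5 s (perturbation experiments), 10 s (trace generation and parameter
recovery) and 30 s (the large replay grid search), sizes at which halving
the step changes final lengths by well under 0.5%.

Degenerate inputs are guarded, not silently absorbed: zero centre
distances are geometry errors, forced elongation beyond the available
tubulin is skipped for that step, and retraction past the minimal neurite
is clamped and logged.

## Geometry conventions

* The soma is a single well-mixed compartment, spherical by convention
  (10 µm diameter by default). Only its clamped concentration matters
  dynamically. Its half-length in the centre-to-centre distance to the
  first shaft compartment is its radius; analytic cable comparisons in the
  tests therefore use a near-point soma so the clamped boundary sits at
  x = 0.
* Path distances are measured along the tree between compartment distal
  ends with the soma as the origin point. On a Y-tree with trunk `d_a` and
  daughters `d_b` the soma→growth-cone distance is exactly `d_a + d_b`,
  and the two growth cones are `2 d_b` apart — the same convention as the
  figure axes ("neurite length from the soma to the growth cone").
* Simple morphologies default to 1 µm neurite diameter and a 1 µm-long
  growth-cone compartment at the neurite diameter; both are configurable.
  A small fixed growth cone minimizes concentration artifacts.

## The experiment suites

**Y-tree perturbation.** A soma, a trunk of length $d_A$, and two daughter
branches of length $d_B$. After 10 h of free outgrowth the polymerization
rate of one growth cone is raised by 50%. With transport by diffusion only
(`v = 0`, the configuration under which this experiment is defined) the
modified branch accelerates at the expense of its neighbour, which falls
below its pre-perturbation length: the faster-consuming cone deepens its
tubulin gradient and diverts the common supply. With the default
active-transport contribution ($f v \approx 2.6\times10^{-9}$ m/s) the
concentration-proportional advective feed is enough to keep the neighbour
slowly advancing at the default geometry — competition shows as a large
growth-rate asymmetry rather than net retraction. The perturbation run
uses $d_A = 50\,\mu m$, $d_B = 10\,\mu m$ (the source experiments do not
print their geometry; only the qualitative behaviour is comparable).

**Sweeps.** `competition_sweep()` varies one axis — diffusion constant,
active transport speed, or the $(d_A, d_B)$ geometry — and reports both
lengths at read-out plus the neighbour's change since the perturbation.
The geometry sweep applies the perturbation at $t = 0$ and reads out
10 000 s later; its grids are $d_A \in \{25, 50, 100, 150\}$ µm and
$d_B \in \{10, 20, 30, 40\}$ µm. $d_B$ starts at 10 µm because a 5 µm
branch can retract at most 3.5 µm before the minimum-length clamp
truncates the read-out and masks the trend. On these grids the neighbour's
retraction increases monotonically with $d_A$ and decreases monotonically
with $d_B$. In the transport sweep, the neighbour's retraction is
monotonically relieved by increasing $v$; the raw length difference
between the branches, however, first rises by about 2% (extra advective
supply compounds the faster branch's advantage) before the equalizing
effect dominates and the difference falls steeply — the attenuation of
competition by active transport holds across the sweep but is not
pointwise monotone in the length difference.

**Complex-tree competition.** On a deterministic branched fixture with
8 terminal branches (30–255 µm from the soma), each growth cone in turn
gets +100% polymerization; the statistic is the total retraction of all
other terminals relative to the control run, divided by the modified
cone's growth. This total relative retraction increases with the modified
cone's path distance to the soma (rank correlation 1 on the fixture): the
further a growth cone sits from the source, the more it must recruit from
its siblings. The fixture is synthetic — generated in code, with tapering
diameters chosen to resemble a pyramidal-cell dendritic tree — because no
reconstructed morphology ships with the package; any SWC file can be used
instead.

**Forced-growth replay and fitting.** Observed growth-cone traces (time
series of soma→tip path length) can drive selected growth cones: each
step interpolates the trace, removes $X \Delta L$ from the growth cone on
elongation (skipping the step entirely if that would drive the quantity
negative) and releases it on retraction. Remaining growth cones stay under
model control. `grid_search_fit()` evaluates an exhaustive parameter grid
($D$, $v$, $b$, $C_{\mathrm{soma}}$; log-spaced except the linear
concentration axis, with 0 kept as the first transport point) and ranks
grid points by the replay error — the square root of the summed squared
deviations of the free cone from its observed trace at the observed
sample times. Beyond the last trace sample the target length is held
constant (holding avoids spurious terminal retraction).

## The synthetic trace generator

`make_synthetic_traces()` emulates the outgrowth pattern of a developing
neuron in culture followed by time-lapse imaging: three unbranched
neurites with onsets at 0, 980 and 1650 minutes; the first two grow and
stall, the third starts slowly and shows a late growth spurt
(0.15 µm/min from 2300 to 2700 min). Samples are every 10 min over
2940 min with 0.2 µm Gaussian jitter after each onset, deterministic per
seed. These traces are synthetic stand-ins for hand-tracked microscopy
data: they reproduce the qualitative structure (staggered onsets, stalls,
a spurt) but not the frame-to-frame autocorrelation, tracking noise or
guidance-cue effects of real cultures. Tests passing on them show the
replay and fitting machinery works and the model can discriminate
parameter sets — not that the fitted parameters describe any real neuron.
The `"model-generated"` template instead records the model's own free
outgrowth at a chosen parameter set, which is what the parameter-recovery
tests use (the generating grid point must win the search with near-zero
error).

## Design choices made where the source was open

* **Discretization of the balance law.** The equation is implemented as
  finite-volume with upwind advection; upwinding is this package's choice
  (positivity and mass conservation), as is the implicit integrator.
* **Single pool.** The bound fraction `f` is not a separate species: the
  whole pool diffuses and decays, and a fraction `f` of it advects.
* **Initial concentrations** default to the clamped soma value everywhere
  (the tree starts equilibrated with its source), so early growth is not
  an artifact of filling an empty tree.
* **Elongation bookkeeping.** Elongation always edits the shaft proximal
  to the growth cone; after a merge the merged compartment becomes the
  elongating one. Retraction releases tubulin into the growth cone (the
  freed dimers appear where depolymerization happens).
* **Perturbations multiply `p` only**; `q` is untouched.
* **Read-out conventions.** "30 h after the perturbation" means simulation
  time 10 h + 30 h; the geometry sweep's 10 000 s read-out is measured
  from a perturbation at t = 0 without burn-in. Both are arguments, not
  constants.
* **Replay error** sums over all observed sample times of the free cone's
  trace (no subsampling).

## Problem sizes used by the packaged experiments

The perturbation experiments run a 40 h Y-tree protocol (~29 000 implicit
steps at dt = 5 s, a few hundred compartments). The complex-tree suite
runs one control plus one perturbed 10 h simulation per tested growth
cone on the 8-tip fixture. The recovery search generates 300 min of
model-generated traces and evaluates 3⁴ = 81 grid points at dt = 10 s;
the culture-like replay search evaluates the same grid over 2940 min
traces at dt = 30 s. All sizes are arguments of the corresponding
functions and scale linearly in duration and grid size.

## Known limitations

* Tubulin is the only state variable: no actin dynamics, microtubule
  polymer transport or sliding, vesicle or mitochondrial transport, and no
  regulation of the transport rates themselves.
* Tree topology changes only through elongation and retraction; growth
  cones never split, branch interstitially, or disappear.
* The growth law is deterministic; real growth cones show strong
  stochastic switching between advance, pause and retreat.
* SWC coordinates are used only for segment lengths; 3-D geometry,
  tortuosity and spines are ignored, and multi-point somata are collapsed
  to a single clamped compartment.
* With several neurites all near the elongation threshold, lengths become
  sensitive to small supply differences; conclusions there should be
  checked against the time-step refinement behaviour (the suites do).
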