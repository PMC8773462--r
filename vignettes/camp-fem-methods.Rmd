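---
title: "Modeling intracellular cAMP signals with tetrahedral finite elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling intracellular cAMP signals with tetrahedral finite elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campfem)
```

## The model

Cyclic AMP (cAMP) is a diffusible second messenger: it is synthesized by
adenylyl cyclase (AC), mostly at or near the plasma membrane, spreads through
the cytosol by diffusion, and is degraded by phosphodiesterase (PDE — the
enzyme, not the equation). `campfem` simulates the concentration field
$C(t, x, y, z)$ (in $\mu$M) over the cytosolic domain — the region between
the plasma membrane and the nuclear envelope; the nucleus is excluded because
no cAMP transport across the nuclear envelope is modeled — governed by

$$
\frac{\partial C}{\partial t} =
\begin{cases}
D\nabla^2 C, & t < t_s,\\
D\nabla^2 C + E_{AC}, & t_s \le t < t_d,\\
D\nabla^2 C + E_{AC} - M(C), & t \ge t_d,
\end{cases}
\qquad
M(C) = \frac{V_{\max}\, C}{K_M + C}.
$$

$D$ ($\mu$m$^2$/s) is the diffusion coefficient, $E_{AC}$ ($\mu$M/s) a
uniform volumetric synthesis rate, and $M(C)$ the saturating Michaelis–Menten
degradation with maximum rate $V_{\max}$ ($\mu$M/s) and Michaelis constant
$K_M$ ($\mu$M). Activities can switch on at different times: synthesis at
$t_s$, degradation at $t_d \ge t_s$ (both intervals closed on the left).
Membrane-bound AC activity is modeled instead (or in addition) through a
prescribed normal flux $D\,\partial C/\partial n = \beta$ on a tagged
boundary surface, with $\beta > 0$ an influx; prescribed concentrations
(Dirichlet sets) are also supported.

The default parameter set is the one used throughout the validation studies:
$E_{AC} = 0.1412$, $V_{\max} = 0.295$, $K_M = 2$, $C_o = 0.05$, $D$ between
$0.3$ and $300$, on a spherical cell model with $R_o = 9.34\ \mu$m and
$R_i = 5.26\ \mu$m.

## Discretization

The domain is meshed with four-node (P1) tetrahedra. Every element integral
is exact in closed form: the consistent mass matrix is
$K_1^e = \tfrac{V}{20}(J + I)$ ($J$ the all-ones matrix), the stiffness
matrix $K_2^e = V D\, B^\top B$ with $B$ the constant-gradient operator
$B = E^{-1} G$ ($E$ the edge matrix from vertex 1, $G$ the nodal difference
stencil), a constant face flux loads $\beta A/3$ onto the face's three
nodes, and a uniform volumetric rate loads $V\,\mathrm{rate}/4$ onto the
element's nodes. Mass is kept consistent (not lumped): the discrete total
content $\mathbf{1}^\top K_1 c$ is then exactly the integral of the P1
interpolant, and the scheme conserves it exactly in the absence of loads.

Assembly produces sparse symmetric $K_1$ and $K_2$; Dirichlet conditions are
applied by symmetric row/column elimination (values moved to the right-hand
side), which preserves symmetry and conditioning, and solutions are
re-embedded through a recovery map.

### Time integration and quasi-linearization

The semi-discrete system is advanced with the one-parameter implicit family

$$
\Big[\tfrac{1}{\Delta t}K_1 + \gamma (K_2 + K_3)\Big] c_{i+1}
= \Big[\tfrac{1}{\Delta t}K_1 - (1-\gamma)(K_2 + K_3)\Big] c_i
+ (1-\gamma) R_i + \gamma R_{i+1},
$$

with $\gamma = 2/3$ (Galerkin's implicit method) by default. This member is
unconditionally stable — runs at $\Delta t = 1, 5, 10$ s all remain bounded
and share the same steady state — and first-order accurate in $\Delta t$
(only $\gamma = 1/2$ would be second order). $\gamma$ is configurable in
$[1/2, 1]$; values below $1/2$ are refused as conditionally stable.

The Michaelis–Menten term makes the reaction matrix state-dependent. Within
each step it is quasi-linearized about an expansion point $C_1$:

$$
M(C) \approx a\,C + (E_{AC} - b), \qquad
a = \frac{V_{\max} K_M}{(K_M + C_1)^2}, \qquad
b = E_{AC} - \frac{V_{\max} C_1^2}{(K_M + C_1)^2},
$$

so $K_3 = a\,K_1$ element-wise and $b$ enters the load. The expansion is
exact at $C_1$. Each step iterates: $C_1$ starts at $c_i$, the system is
solved, and $C_1$ is replaced by the new solution until the relative
max-norm change drops below `inner_tol` (default $10^{-8}$, at most 50
iterations — both engineering defaults; typical steps take 2–4 iterations).
$a$ and $b$ are evaluated per element at the mean of the four nodal $C_1$
values, since the element integrals treat them as element constants; nodal
evaluation would differ only at the discretization order.

Two useful exactness properties follow from the construction and are tested:
a uniform state with uniform rates stays exactly uniform (so compartmental
runs are independent of geometry and of $D$), and any steady state of the
continuous kinetics, $M(C_{ss}) = E_{AC}$, is an exact fixed point of the
discrete step at any $\Delta t$ — which is why even $\Delta t = 10$ s runs
land on the right plateau.

Phase switches are snapped to the time grid: $t_s$ and $t_d$ must be
integer multiples of $\Delta t$ (validated up front). Across a phase
boundary each side of the $\gamma$-weighted right-hand side reflects the
phase at its own time point, so the step ending exactly at $t_s$ already
carries $\gamma$ of the new load. Transient negative concentrations on
coarse meshes are logged (below $-10^{-6}$ $\mu$M) but never clamped —
clamping would break both conservation and the oracle-agreement tests.
Linear systems are solved by sparse Cholesky factorization; the
factorization is reused across steps while the matrix is unchanged and
rebuilt on every quasi-linearization iterate.

## Mesh generation

No general tetrahedral mesher is bundled; instead two deterministic
generators cover the study geometries, and arbitrary meshes can be imported
(Gmsh MSH 2.2 ASCII, TetGen `.node`/`.ele`/`.face`).

Both generators share one construction: a subdivided-icosahedron
triangulation supplies surface directions; nodes are placed in layers along
rays (radial for the sphere shell; from the nuclear-cavity center for the
cell-like geometry, both surfaces being star-shaped from that point); and
each triangular prism between consecutive layers is split into three
tetrahedra. Quad diagonals are chosen by the minimum-global-node-index rule,
which is always realizable and makes neighboring prisms conform; every quad
is planar by construction (it lies in the plane spanned by two ray
directions), so the fan from the prism's minimum vertex tiles it exactly.
The subdivision level and layer count are chosen from the requested edge
length; the seed enters only as a rigid rotation of the direction set, so
meshes are bitwise reproducible per seed and mesh quality is
seed-independent.

The sphere shell at `target_edge_length = 2.4` gives 486 nodes / 1920
elements — the same scale as the published convergence-study mesh (381 /
1472); node counts are generator-dependent and only matched in order of
magnitude. The chord polyhedron slightly underestimates the analytic shell
volume (by ~3% at that resolution, within the 5% contract).

The cell-like geometry is a synthetic stand-in for image-derived cell
shapes: a flattened super-ellipsoid ($|x/12|^{2.5} + |y/8|^{2.5} +
|z/3.5|^{2.5} = 1$, i.e. roughly $24 \times 16 \times 7\ \mu$m) with an
off-center ellipsoidal nuclear cavity (semi-axes $3.5, 2.5, 1.8\ \mu$m at
$(2, 1, 0.3)$). The axes were chosen once to caricature a flattened
cultured endothelial cell; reconstructing real geometries from microscopy
is out of scope, and users with segmented surfaces should import them.

Element quality is reported with two measures normalized to $(0, 1]$ with 1
attained by the regular tetrahedron: aspect ratio $= 3 r_{in}/R_{circ}$ and
the minimum vertex solid angle divided by $\arccos(23/27)$ (the regular
tetrahedron's vertex solid angle). The published quality table cites a
reference whose exact formulas are unavailable; these normalizations match
the stated best/worst values of 1 and 0 but are not verified against that
reference. The layered sphere mesh averages ~0.76 aspect ratio.

## Reference solutions

With no boundary fluxes and uniform rates the field stays spatially uniform
and obeys the compartmental ODE $dC/dt = E_{AC} - M(C)$. Separation of
variables gives a strictly monotone time map $T(C)$ in closed form (with
explicit branches for $V_{\max} = 0$ and $E_{AC} = V_{\max}$), inverted by
a bracketed root solve to $10^{-12}$; an independent adaptive integrator
(`deSolve`, tolerances $10^{-10}/10^{-12}$) provides the cross-check, and
the two routes agree to about $10^{-10}$. The steady state
$C_{ss} = E_{AC} K_M / (V_{\max} - E_{AC})$ exists for $E_{AC} < V_{\max}$;
otherwise the solver reports no finite steady state.

The other oracles are the spherical-shell Laplace steady state
$C(r) = A + B/r$ fixed by the two boundary concentrations, and the
total-activity flux equivalence $\beta = E_{AC}(R_o^3 - R_i^3)/(3 R_o^2)$,
which converts a volumetric synthesis rate into the plasma-membrane influx
carrying the same total activity ($0.3611\ \mu$M$\cdot\mu$m/s for the
reference parameters). The ratio $V_{\max}/K_M$ (the first-order decay rate
in the $C \ll K_M$ limit) identifies kinetically equivalent parameter sets:
$(0.118, 2)$ and $(0.295, 5)$ share $0.059$ s$^{-1}$ and produce
near-identical low-concentration decay curves.

## How agreement is measured

Curve agreement is always reported as
$\max_t |C(t) - C_{ref}(t)| \,/\, \max_t |C_{ref}(t)|$ — the maximum
discrepancy normalized by the response amplitude. Pointwise relative error
is the wrong metric for these curves: on a decaying exponential tail the
absolute error of any fixed-step scheme tends to zero more slowly than the
solution itself, so the pointwise ratio grows without bound even as the
curves become visually indistinguishable — and even two exact solutions
with equal $V_{\max}/K_M$ drift by >1% pointwise at late times while never
separating by more than 0.4% of the initial concentration.

At $\Delta t = 1$ s over 600 s with the reference parameters, the
amplitude-normalized discrepancy against the compartmental ODE is 0.44%
(synthesis + degradation) and 0.81% (degradation only), identical across
the sphere and cell-like meshes and across $D = 0.3$ and $300$; at
$\Delta t = 10$ s the transient error grows (~3.6%) but the plateau is
still exact. The Dirichlet shell scenario reaches $A + B/r$ within 0.5% at
the probe nodes on the 486-node sphere mesh (each node compared against the
profile at its own radius, so only discretization error is measured).

## Scenarios, probes, and sizes

Preset scenarios (`scenario_presets()`) reproduce the validation studies:
compartmental degradation / synthesis / both, membrane-flux synthesis with
cytosolic degradation ($\beta = 0.3611$, $D = 3$), the Dirichlet shell
(4 and 1 $\mu$M boundaries, $D = 30$), and delayed activation ($\beta = 2$,
$D = 10$, $t_s = 10$ s, $t_d = 20$ s). Probes are specified by coordinates
and snapped to the nearest node (published node ids are mesh-specific and
not reproducible). End times default to 600 s for the steady-state studies
— the underlying figures' exact end times are not stated — and the
convergence studies use meshes of roughly 84, 486, and 2568 nodes with
$\Delta t \in \{10, 5, 1\}$ s; these sizes keep every preset deterministic
and fast on a single CPU while the mesh study still spans a 30-fold range
of element counts.

One geometry-dependent caveat: with $\beta = 2$ the effective volumetric
influx $\beta S/V$ exceeds $V_{\max}$ on both bundled geometries (the
sphere's surface-to-volume ratio gives ~0.78 $\mu$M/s), so delayed-start
curves approach a linear asymptote of slope $\beta S/V - V_{\max}$ rather
than a plateau; Michaelis–Menten degradation can remove at most $V_{\max}$
per unit volume. On the original image-derived geometry the same loading
saturates; whether it does is purely a property of $S/V$.

```{r example}
tc <- run_scenario(scenario_preset("compartmental_ac_pde", t_end_s = 120))
ref <- compartmental_timecourse(tc$times, 0.1412, 0.295, 2, 0.05)
max(abs(tc$probes[, 1] - ref)) / max(ref)
```

## What the synthetic data do and do not show

The generators emulate the geometric features the model is sensitive to — a
closed cytosolic shell with tagged plasma-membrane and perinuclear
surfaces, realistic cell dimensions, a flattened irregular outline with an
off-center nucleus — under exactly the published kinetic parameters.
They do not emulate image-derived surface roughness, organelle crowding,
spatially heterogeneous enzyme distributions beyond region tags, or
stochastic single-molecule effects. Passing the validation suite therefore
shows the numerics (element integrals, assembly, quasi-linearization, time
stepping, boundary handling) are correct against independent oracles; it
does not by itself validate the biological parameter choices for any
particular cell type.

## Known limitations

- P1 elements and first-order time accuracy at $\gamma = 2/3$; no adaptive
  refinement, no higher-order elements, no mass lumping option.
- Isotropic, spatially constant $D$; degradation parameters uniform per
  region tag.
- Direct sparse factorization per (re)build targets meshes up to a few tens
  of thousands of elements.
- The delayed-start loading is reproduced exactly, but its long-time
  saturation depends on the geometry's surface-to-volume ratio (see above).
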