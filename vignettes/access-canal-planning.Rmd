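---
title: "Planning curvature-bounded access canals through the temporal bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning curvature-bounded access canals through the temporal bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The planning problem

Robot-assisted temporal bone surgery with a flexible drilling unit replaces
the classical straight drill channel with a nonlinear access canal from the
skull surface to a clinical target — the round window of the cochlea for a
cochlear implantation, or the internal auditory canal (IAC) for vestibular
schwannoma removal.  A canal is a 3D trajectory constrained by

* the instrument's maximum curvature $\kappa_{max} \ge 0$ (in mm$^{-1}$;
  $\kappa_{max} = 0.05$ corresponds to a 20 mm minimum turning radius),
* a minimal safety distance $d_{min} > 0$ (mm) to every risk structure
  (internal carotid artery, jugular vein, facial nerve, chorda tympani,
  cochlea, ossicles, semicircular canals, internal and external auditory
  canal), and
* fixed endpoint states $q_I, q_G \in R^3 \times S^2$: position **and**
  approach direction at both the skull surface and the target.

`otoplan` implements the planning half of a two-step preoperative pipeline
(segmentation, then motion planning): risk-structure segmentations enter as
label volumes or triangle meshes, and the package computes and locally
optimizes collision-free trajectories, then scores them with
functional-evaluation metrics.

## Trajectories: cubic Bezier spiral splines

A trajectory is a waypoint sequence $W_0, \dots, W_{N_W}$.  Each interior
triple $(W_{j-1}, W_j, W_{j+1})$ implicitly defines a spline: a pair of
mirrored cubic Bezier *spirals* whose first three control points lie on the
corner legs.  This placement makes the curvature start at exactly zero (a
G2 join with the straight legs), grow monotonically, and peak at the shared
join point on the corner bisector.  The control points sit at distances
proportional to one configuration length $d$ along the legs, using the
classical analytic constants $c_1 = 7.2364$, $c_2 = 2(\sqrt6 - 1)/5$ and
$c_3 = (c_2+4)/(c_1+6)$; because scaling $d$ rescales the whole corner
similarly (curvature $\propto 1/d$), the implementation measures the peak
curvature of a trial construction once and rescales $d$ analytically so the
peak equals $\kappa_{max}$ exactly.  A corner is *infeasible* when the
required $d$ does not fit on its legs (two corners share each leg); the
builder either raises an error naming the offending leg or, in the
optimizer's clamped mode, fits the largest possible spiral and reports the
resulting curvature excess.

Curvature is evaluated with the standard space-curve formula
$\kappa = \lVert r' \times r'' \rVert / \lVert r' \rVert^3$; arc lengths use
24-point Gauss–Legendre quadrature per cubic, and discretization refines
parameter intervals adaptively until every chord is shorter than the
requested step.

## Obstacles and signed distances

Risk structures are watertight triangle meshes.  Queries return the exact
Euclidean distance to the nearest triangle (accelerated by an axis-aligned
bounding-box tree whose results are identical to an exhaustive scan), the
nearest surface point $x_0$, and a sign — positive outside, negative inside
— decided by the angle-weighted pseudonormal at the nearest surface feature.
The *normal* reported with a query is the gradient of the signed distance at
the query point (the outward unit vector through $x_0$), so the first-order
expansion used by the optimizer,
$sd(x) = sd(x_0) + n(x_0)^\top (x - x_0)$, is exact at the expansion point
with a second-order remainder.

Label volumes bridge from segmentation to meshes: the package keeps the
largest 26-connected component per structure, computes the volume of
interest (the padded union box of the non-excluded structures, made square
in X–Y and clipped to the grid; the chorda tympani box is always unioned in
because the structure is small enough to fall out of a naive box), and
extracts iso-level-0.5 surfaces by marching tetrahedra over the voxel-centre
lattice with a virtual background ghost layer, so meshes are closed even at
the volume boundary.  Binary masks produce staircase surfaces whose area is
biased upward; Taubin smoothing (default 50 iterations,
$\lambda = 0.8$, $\mu = -0.83$ — a shrink-free band-pass choice) removes the
staircase, recovering the area and volume of digitized analytic shapes to
within a few percent while preserving watertightness.

## Initial planning: bidirectional RRT

Two search trees grow from $q_I$ and $q_G$ (the goal tree with negated
heading, so its edges read backward), strictly alternating.  Each iteration
samples a uniform point in the inflated environment bounding box, finds the
in-ball neighbours (radius $r_b$) that still have spare child capacity
($< N_c$ children; when the ball is empty the nearest open node is used, so
small $r_b$ values remain productive), and extends each by one steering step
of length $\Delta t$, turning the heading by at most the deflection a corner
spiral can realise within 45% of a step per leg — the 45% budget leaves
slack so that consecutive corners sharing a leg stay jointly feasible.
After every extension, nodes of the opposite tree inside a cone ahead of the
new state (apex and axis from the state, height $c_h$, base radius $c_r$)
are tried in ascending distance.  A candidate connects either directly or
through two inserted bridge waypoints placed along the end headings, which
absorb the direction mismatch between the trees; the combined waypoint
sequence must pass a fast corner-feasibility screen, build into a spline
trajectory, and clear the obstacles.  Every returned trajectory is densely
re-checked (0.05 mm sampling) before the planner reports success, so
returned solutions are sound by construction.

Defaults follow the printed planner setup: $r_b = 1$ mm, $\Delta t = 4$ mm,
$c_r = 5$ mm, $c_h = 18$ mm, $N_c = 10$, and a time budget $T_{max}$ of
0.1 s.  The printed budget carries no unit; we read it as seconds and expose
it as such, and additionally provide an iteration cap (`max_iter`) because a
wall-clock budget is inherently nondeterministic — with the cap, a fixed
seed reproduces the planner run byte for byte, which is the mode used in all
tests and benchmarks (cap 2500–3000 iterations).  Cone candidacy filters on
position only; heading compatibility is left to the connection-spline
feasibility test, which rejects incompatible candidates anyway.

## Clearance optimization: penalty SCO

The optimizer improves an initial trajectory over its interior waypoints
while the first and last two waypoints stay fixed (pinning both endpoint
positions and directions; their equality constraints are eliminated rather
than penalised, so endpoints are bit-identical).  The cost is

$$f = \alpha_\Gamma f_\Gamma + \sum_i \alpha_O\, f_{i,O}, \qquad
  f_\Gamma = \sum_i \sum_{k \in \{x,y,z\}} |W_{i,k} - W_{i+1,k}|^2, \qquad
  f_{i,O} = \theta - sd_{S_iO}(W_i),$$

with the squared-length surrogate kept exactly as printed (squared segment
lengths, which also regularises waypoint spacing) and the clearance terms
linear and unclamped — clearances beyond the target $\theta$ keep producing
(negative) cost, so the equilibrium shape balances the outward pull against
the length stiffness and is independent of $\theta$'s absolute value.
Constraints are $g_{i,O} = d_{min} - sd(W_i) \le 0$ per spline and, for
splines whose measured peak curvature exceeds $\kappa_{max}$ at the current
iterate, the quadratic straightening penalty $g_{i,\kappa}$ built from the
printed waypoint-translation targets
$\bar W_{i-1}, \bar W_i, \bar W_{i+1}$ (algebraically,
$g_{i,\kappa} = \tfrac{9}{64}\lVert W_{i-1} - 2W_i + W_{i+1}\rVert^2$).

The solver is the classic sequential convex optimization triple loop with an
$\ell_1$ exact-penalty merit function $f + \mu(\sum_i |h_i| + \sum_j
\max(0, g_j))$: an outer penalty loop ($\mu \leftarrow k\mu$ while
violations exceed $\epsilon_c$), a convexification loop that relinearises
signed distances around nearest-point anchors frozen per convexification,
and a trust-region loop over a box of half-width $s$ ($s \leftarrow \tau^+ s$
on steps whose true-merit improvement reaches at least 25% of the model's
prediction, $s \leftarrow \tau^- s$ otherwise, capped at $10\,s_0$).  Each
convex subproblem — a positive-definite quadratic plus hinge penalties in a
box — is solved by a purpose-built ADMM iteration (box projection and hinge
proximal steps) run to a $10^{-11}$ residual.  Model and true merit agree
exactly at zero displacement, so accepted steps never increase the true
merit.

Printed parameters are used where legible: $N_P = 15$, $N_C = 50$,
$N_T = 10$, $\tau^+ = 1.1$, $\tau^- = 0.9$,
$\epsilon_x = \epsilon_f = 10^{-4}$, $\epsilon_c = 0.25$.  The remaining
cells of the printed table are typographically garbled; $k = 10$,
$\mu_0 = 0.5$, $s_0 = 0.15$ mm, $\theta = 1$ mm, $\alpha_\Gamma = 1$ and
$\alpha_O = 10$ are reconstructed defaults, all exposed in `sco_config()`
and to be treated as package defaults rather than published values.  The
violation measure compared against $\epsilon_c$ mixes millimetres (distance
hinges) and the relative curvature excess $(\kappa - \kappa_{max}) /
\kappa_{max}$; at convergence the realised curvature therefore stays within
$\kappa_{max}(1 + \epsilon_c)$.

## Functional evaluation

For paired environments — surfaces used for planning versus ground-truth
surfaces — the package reports the paper-style metrics: the success rate
$r_s$ (fraction of cases with a planned trajectory), the mean minimal
distance $r_d$ (mean over *successful* cases of the trajectory's minimal
obstacle distance on the planning surfaces), and the failure rate $r_f$
(fraction of successful cases whose clearance re-evaluated against the
ground-truth surfaces falls below $d_{min}$ — plans that looked safe on the
segmentation but are not).  The denominators are declared choices: $r_d$
and $r_f$ average over successes only, since a minimal distance presupposes
a planned path.  Per-case rows report both distances so either convention
can be recomputed.  Dice and classical (maximum) Hausdorff distance between
label masks are provided for conventional segmentation scoring; Hausdorff
distances are measured between surface voxels in physical millimetres.

Scenario constraint defaults are the printed triples: cochlear implantation
(**Access**) $\kappa_{max} = 0.05$, $d_{min} = 0.8$; vestibular schwannoma
through the superior semicircular canal (**SSC-Access**) $0.05 / 1.5$; and
retrolabyrinthine (**RL-Access**) $0.05 / 2.0$.

## Synthetic anatomy

No patient data ship with the package.  `generate_anatomy()` rasterizes a
temporal-bone-*like* arrangement: nine structures with the right topology
and scale — thick curved vessel tubes (ICA, JV with a bulb), large canal
tubes (EAC, IAC), three orthogonal semicircular arcs, a spiral cochlea
analogue with tapering radius, an ossicle blob cluster, a thin facial-nerve
tube with a thinner chorda-tympani branch forming a millimetre-scale
facial-recess corridor — inside a ~48 mm field enclosed by a spherical
"skull" shell used only for start placement (the shell is not an obstacle:
the canal is drilled through bone).  Default spacing is the anisotropic
$0.2 \times 0.2 \times 0.4$ mm of a typical temporal-bone CT label volume.
Per-seed variation applies a rigid whole-anatomy jitter (±0.8 mm),
independent per-structure jitter (±0.5 mm) and ±8% radius scaling; start
states sit on the shell aiming at the scenario goal (a point offset from
the cochlea analogue standing in for the round window, or a point posterior
and inferior to the IAC).  Rasterization priority (vessels > canals >
arcs/cochlea > ossicles > nerves) resolves overlaps deterministically.

`perturb_segmentation()` produces the paired "automatic segmentation"
variant: per-structure dilation or erosion (over-/under-segmentation),
random hole cutting (fragmentation) or boundary voxel noise, each with an
independent seeded stream per structure so single-structure failure modes
can be induced selectively.  Benchmarks plan on the perturbed surfaces and
evaluate against the ground truth, mirroring the automatic-versus-expert
comparison.

**What passing tests do and do not show.**  The generator mimics scale and
topology, not anatomical shape or imaging physics: corridors are smoother
and risk-structure poses more regular than in patients, and there is no
intensity model, so results quantify the *planner's* soundness,
determinism and optimization behaviour on realistic geometry — they say
nothing about segmentation accuracy on real CT, and the package must not be
used clinically.

## Problem sizes and numerical choices

Benchmarks and the acceptance script rasterize the same 48 mm field at
$0.4 \times 0.4 \times 0.8$ mm (`benchmark_params()`), a deliberate
benchmark design choice: the planner consumes meshes, whose fidelity at
this resolution is ample for the printed constraint scales, and the
many-case suites (50-case planner soundness, 20-case optimizer behaviour)
then run in minutes on one CPU.  The full-resolution default generator is
exercised by a dedicated ten-seed viability check.  Other numerical
defaults: trajectory feasibility re-checks sample at 0.05 mm; planner edge
collision checks at 0.1 mm; near-collinear corners (deflection
$< 10^{-6}$ rad) are emitted as straight pieces; component tie-breaks are
by scan order; and all geometry downstream of file IO lives in physical
millimetres — voxel indices never leak past the label-volume layer.

## Known limitations

* The spiral corner construction requires generous legs near
  $\kappa_{max} = 0.05$ (a 90° corner needs ~32 mm per leg), so the planner
  works with many small deflections rather than few sharp turns; very
  cluttered environments raise the iteration budget needed.
* $g_{i,\kappa}$ enters the merit as a penalised (soft) constraint; at the
  printed $\epsilon_c = 0.25$ a converged trajectory may carry up to 25%
  curvature excess.  Callers needing a hard bound should re-check with
  `is_feasible()` and tighten `eps_c`.
* The clearance cost is linear and unclamped as printed; its equilibrium is
  insensitive to $\theta$, so clearance gains come mostly from the corridor
  geometry.
* Wall-clock (`t_max`) planning is nondeterministic by nature; use the
  iteration cap for reproducibility.
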