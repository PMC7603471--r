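# otoplan

Curvature-constrained access-canal planning for robot-assisted temporal bone
surgery.

Flexible drilling units can reach targets such as the cochlea's round window
or the internal auditory canal (IAC) along *nonlinear* canals, but only if a
preoperative planner finds a trajectory that (i) stays drillable — curvature
never exceeds the instrument bound κ_max (mm⁻¹), (ii) stays safe — clearance
to every risk structure of the temporal bone (carotid artery, jugular vein,
facial nerve, chorda tympani, cochlea, ossicles, semicircular canals,
auditory canals) never falls below a margin d_min (mm), and (iii) meets
fixed endpoint states (position *and* heading) q_I, q_G ∈ R³×S² at the skull
surface and at the target.

`otoplan` implements the planning half of that pipeline in R:

* **Geometry** — trajectories are waypoint sequences whose interior corners
  are smoothed by pairs of mirrored cubic Bézier *spirals*: curvature starts
  at zero on each leg, grows monotonically, and peaks exactly at κ_max on
  the corner bisector (κ = ‖r′×r″‖/‖r′‖³).
* **Environment** — risk structures are watertight triangle meshes with
  exact signed-distance / nearest-point / outward-normal queries (BVH
  accelerated, identical to an exhaustive scan); label-volume utilities
  provide largest connected components, the square-in-X–Y volume of
  interest, and marching-tetrahedra surface extraction with Taubin
  smoothing. NIfTI / MetaImage volumes and STL / PLY meshes are supported.
* **Planner** — a bidirectional RRT over Bézier spiral splines, strictly
  alternating two trees and bridging them through a connection cone; every
  returned trajectory passes a dense feasibility re-check (soundness by
  construction), and an iteration-cap mode makes runs seed-reproducible.
* **Optimizer** — penalty-based sequential convex optimization of the
  interior waypoints: squared-length cost f_Γ, linear clearance terms
  θ − sd(W_i), linearized signed-distance safety constraints, quadratic
  straightening penalties where κ_max is exceeded, endpoints fixed; solved
  by convexification inside an adaptive trust region under an ℓ1 exact
  penalty.
* **Evaluation** — the functional metrics r_s (success rate), r_d (mean
  minimal obstacle distance over successful cases) and r_f (fraction of
  plans that violate d_min when re-evaluated against ground-truth surfaces),
  plus Dice / Hausdorff utilities; scenario presets `Access` (0.05 / 0.8),
  `SSC-Access` (0.05 / 1.5) and `RL-Access` (0.05 / 2.0).
* **Synthetic anatomy** — a seeded generator of temporal-bone-*like* label
  volumes (nine structures with realistic topology and scale, a paired
  "automatic segmentation" perturbation, per-scenario start/goal states) so
  the entire pipeline is testable without patient data. It mimics scale and
  topology only — never use it, or this package, clinically.

## Worked example

```r
library(otoplan)

# a synthetic patient: label volume + per-scenario endpoint states
an  <- generate_anatomy(benchmark_params(seed = 3))
env <- environment_from_labels(an$volume)       # nine risk-structure meshes
fid <- an$fiducials[["Access"]]                 # round-window approach
scn <- scenario_defaults("Access")              # kappa_max 0.05, d_min 0.8

pr <- plan_trajectory(env, fid$start, fid$goal, scn$kappa_max, scn$d_min,
                      rrt_config(max_iter = 3000L, seed = 11))
pr
#> <ot_plan_result> success after 2 iterations (trees 3/3): length 26.36 mm

opt <- optimize_trajectory(pr$trajectory, env, scn$kappa_max, scn$d_min,
                           sco_config())
is_feasible(opt$trajectory, env, scn$kappa_max, scn$d_min, ds = 0.05)[
  c("max_curvature", "min_distance", "pass")]
#> $max_curvature
#> [1] 0.05
#> $min_distance
#> [1] 1.827643
#> $pass
#> [1] TRUE
```

The planned canal runs 26.4 mm from the skull surface to the round-window
goal, bends at exactly the instrument's curvature limit (0.05 mm⁻¹, a 20 mm
turning radius) and keeps 1.83 mm of clearance to the nearest risk
structure — comfortably above the 0.8 mm margin of the cochlear-implant
scenario.

A full benchmark (synthesize → perturb → plan on the perturbed surfaces →
optimize → evaluate against ground truth) is one call:

```r
res <- run_pipeline(list(out_dir = "run1", n_cases = 6, seed = 5,
                         rrt = list(max_iter = 3000L)))
res$report
#> <ot_benchmark_report> 6 cases: r_s = 0.833, r_d = 1.809 mm, r_f = 0.000
```

A thin command-line interface with `synth`, `plan`, `optimize`, `evaluate`
and `run` subcommands is installed at `inst/cli/otoplan`.

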