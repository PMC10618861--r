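# osteoROM

Automated, exhaustive assessment of **osteological intervertebral range of
motion (ROM)** from triangle meshes of vertebrae — for comparative
biomechanists and virtual functional morphologists who want joint mobility
estimates that account for *interacting* rotations instead of one axis at a
time.

## What it computes

For a chain of vertebrae (caudal → cranial) articulated in an osteological
neutral pose (ONP):

* a **centre of rotation** per joint — the centre of a least-squares sphere
  fitted to the anterior vertebra's postzygapophyseal facet outline — with an
  anatomical joint frame (x = roll / long-axis, y = yaw / dorso-ventral,
  z = pitch / latero-lateral; positive = clockwise roll from anterior, yaw
  right, dorsal pitch);
* an **exhaustive sweep** of the (roll, yaw, pitch) Euler grid (default step
  2°) per joint, classifying each pose as *viable* iff the adjacent bones do
  not collide **and** the moving vertebra still intersects both left and
  right articulation gap volumes (disarticulation at 0% facet overlap);
* **cosine-corrected pose spaces** `(roll·cos yaw, yaw, pitch)` and their
  Delaunay **alpha-shape volumes** in cubed degrees (preset α = 50 with a
  critical-alpha fallback that guarantees all poses are enclosed as one
  solid);
* per-axis extrema, whole-chain **summed ROM**, **maximum neck-turn**
  composition (lexicographic yaw → roll → pitch priority, with
  joint-exclusion experiments), and spherical-frame-projection (SFP) point
  clouds.

A parametric generator of watertight synthetic vertebrae (with ground-truth
CORs and facet spheres) replaces specimen scans for testing and
demonstrations; real OBJ/PLY/STL meshes with JSON facet annotations are the
production input.

## Worked example

```r
library(osteoROM)

# a 4-vertebra (3-joint) synthetic chain in ONP
chain <- make_chain(chain_recipe(n_vertebrae = 4))
measure_spacing(chain)
#>   joint body_gap   zyg_gap centrum_length body_ratio  zyg_ratio
#> 1 V1-V2      1.2 0.5890983       12.71507 0.09437623 0.04633074
#> 2 V2-V3      1.2 0.5890983       12.00000 0.10000000 0.04909153
#> 3 V3-V4      1.2 0.5890983       11.99152 0.10007069 0.04912623

# exhaustive interacting sweep of one joint
grid <- pose_grid(roll = c(-40, 40), yaw = c(-40, 40), pitch = c(-40, 40),
                  step = 2)
rec <- sweep_joint(chain, "V2-V3", grid)
env <- rom_envelope(rec)
env
#> <rom_envelope V2-V3: 5714 viable poses, volume 67372 deg^3 (alpha 50.0)>
env$extrema
#>        axis min max
#> roll   roll -30  30
#> yaw     yaw -28  28
#> pitch pitch -22  40
```

The extrema are the maximal viable rotations of the *interacting* sweep (a
pose may reach its roll maximum only at a particular yaw); the volume is the
cosine-corrected alpha-shape volume, the scalar used to compare overall
mobility across joints. A full report bundle — per-joint CSVs, a summary
JSON, SFP PLY clouds and a reproducibility manifest — comes from:

```r
res <- run_pipeline(run_config(recipe = chain_recipe(4), out_dir = "rom_out"))
res$summary
```

Command line (after install):

```sh
Rscript inst/cli/rom demo --out rom_out --bounds 40 --step 2
Rscript inst/cli/rom fixtures --out fixtures/        # synthetic PLY + JSON
Rscript inst/cli/rom sweep --chain fixtures/chain.json --joint V1-V2
```

Real specimens: write a chain definition JSON listing mesh paths (ordered
caudal → cranial), facet-annotation sidecars (`{"left_pre": [face ids], ...}`,
1-based), optional manual 4×4 ONP transforms and spacing ratios, then
`load_chain("chain.json")`. `align_onp()` refines a rough manual placement;
it does not replace it.

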