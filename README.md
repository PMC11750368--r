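# antsim

An R package for studying **embodied insect navigation** with a kinematic
hexapod ant — no physics engine required. It is aimed at computational
neuroethologists and bio-roboticists who want to test insect navigation
controllers in a closed sensorimotor loop (sense → brain → gait → body →
world) without the overhead, nondeterminism and install burden of a
rigid-body simulator.

## What it simulates

**Body.** A desert-ant-like morphology: 40 joints (five per leg — ThCx,
ThCz, CTr, FTi, TiTa — three per antenna, two neck, two abdomen), eight
tactile end-effector tips, hind legs longer than front. Leg kinematics are
closed-form: forward kinematics composes the joint chain; inverse
kinematics solves the yaw joint plus a planar two-link chain by the law of
cosines.

**Gait.** Forward-kinematic gaits drive the joint-angle triple
(α = ThCz, β = CTr, γ = FTi) with continuous swing/stance profiles
parameterised by hip swing *Sl*, lift swing *Sh* and half-swing count
*Sn*; inverse-kinematic gaits prescribe Cartesian tip targets (step length
*L*, height *H*). Steering enters through a rotation configuration
θ ∈ [−1, 1] that asymmetrises the left/right stride (θ = 0 straight,
|θ| = 1 spin). Tripod, ripple and wave coordination emerge from one phase
schedule and reproduce the tripod > ripple > wave speed ordering.

**Locomotion without physics.** Feet in stance are treated as
ground-anchored; the least-squares planar rigid fit of their apparent
displacement, inverted, advances the body pose (stance-foot odometry).

**Worlds.** Analytic silhouette ray-casting for a 72×72 spherical panorama
and 74×19 planar eye cameras (FOV 2 rad × 0.5 rad); floor-painted odour
trails read by bilinear reflectance sensors at the antenna tips; a
filament-based odour plume (Gaussian puffs in coloured-noise wind) with
point queries for concentration and wind.

**Brains.** Five controllers, each coupled to the gait through (θ, Sl):

| Controller | Core rule |
|---|---|
| Path integration | CX circuit (TN2/TB1/CPU4/CPU1); θ = k<sub>PI</sub>(ΣCPU1<sub>L</sub> − ΣCPU1<sub>R</sub>); Sl = Sl₀ + Sl<sub>f</sub>(1 − min(\|θ\|, 1)) ∈ [5°, 25°] |
| Visual beacon | copy-and-shift: shift = ⌈\|6δ/W\|⌉ columns toward the landmark, steering circuit → θ |
| Visual compass | Zernike moment Z₇,₁ phase vs stored phase: θ = sign(ΔΦ), Sl = \|ΔΦ/5\| |
| Trail following | bilateral: \|O<sub>l</sub>−O<sub>r</sub>\| < 5 → straight (Sl = 8); else θ = (O<sub>l</sub>−O<sub>r</sub>)/400 (Sl = 4); no odour → random cast (Sl = 3) |
| Plume tracking | odour > 10⁻⁶ → orient upwind (θ = sign(m−h), Sl = min(5+\|m−h\| mod 5, 15)), surge 2 loops; else random search |

## Worked example

```r
library(antsim)

model <- build_ant_model()
model
#> <ant_model> 40 joints, 6 legs, 8 end effectors

# open-loop walking: straight tripod gait, 10 cycles
log <- run_locomotion(model, fk_gait_params(Sl = 15, Sh = 15, Sn = 5),
                      n_cycles = 10)
attr(log, "summary")$mean_speed
#> [1] 0.111345        # model units per tick; heading drift 0.00 deg/cycle

# closed-loop path integration: 60-cycle outbound walk, then CX homing
res <- run_scenario(scenario_config("path_integration", seed = 42))
res$metrics[c("route_length", "bearing_error_deg",
              "min_homing_distance", "homing_cycles", "success")]
#> route_length        111.6    # outbound path length (model units)
#> bearing_error_deg   0.90     # decoded home bearing vs true direction
#> min_homing_distance 2.08     # closest approach to the nest while homing
#> homing_cycles       39
#> success             TRUE

autoplot(res)   # outbound loop + homing leg, coloured by cycle
```

The decoded home bearing comes from the CPU4 memory sinusoid; 0.9° error
after a 112-unit outbound route means the embodied circuit integrated the
route essentially perfectly, and the agent re-approaches the nest to within
about half a body length.

Other scenarios run the same way: `visual_beacon` (modes `"binocular"`,
`"left"`, `"right"`), `visual_compass` (incremental or jump world
rotation), `trail_following` (`moving` vs `fixed` antennae, configurable
trail width) and `plume_tracking`. A thin command-line wrapper is installed
at `inst/cli/antsim.R`:

```sh
Rscript inst/cli/antsim.R run trail_following --seed 3 --out /tmp/run
Rscript inst/cli/antsim.R fixtures trail --seed 1 --out /tmp/fixtures
```

## Package layout

- `R/morphology.R`, `R/model.R`, `R/kinematics.R` — body model, FK/IK
- `R/gait.R`, `R/locomotion.R` — gait generation, stance odometry
- `R/scene.R`, `R/trail.R`, `R/antenna.R`, `R/plume.R` — worlds & sensors
- `R/brain_cx.R`, `R/brain_vision.R`, `R/brain_olfaction.R` — controllers
- `R/fixtures.R`, `R/scenarios.R` — world generators and scenario runners
- `vignettes/antsim-methods.Rmd` — models, parameters and design decisions
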