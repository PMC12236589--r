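# gridnav

A computational-neuroscience workbench for studying how grid cells in the
medial entorhinal cortex (MEC) and place cells in the hippocampus (HC)
could jointly support localization, cue-triggered recall of goal
locations, and planning of novel routes.

The package is aimed at researchers who want a small, fully inspectable
implementation of three linked ideas:

1. **A single recurrent network models the HC–MEC loop.** All populations
   (grid cells GC, spatially modulated sensory cells SMC, speed and
   head-direction cells, and unsupervised hidden units) share one state
   vector updated as

   z[t+1] = α ⊙ z[t] + (1 − α) ⊙ ( inject(u[t]) + W f(z[t]) ),

   with a single unconstrained recurrent matrix `W`, per-unit learnable
   leak `α`, and rectified rates `f(z)`. Inputs are injected raw into
   input-node coordinates (no learned input projection); GC and SMC
   coordinates are supervised against simulated ground truth. Trained with
   masked, noisy inputs, the network path-integrates self-motion,
   autoencodes sensory patterns, and develops place-cell-like hidden units
   whose number grows with the masking ratio.

2. **Recall is pattern completion.** Clamping a sensory pattern onto the
   SMC inputs of a zero-initialized trained network drives the whole state
   to the attractor encoding the cued location; decoding any population
   against its ratemap recovers the goal position.

3. **Planning lives on the grid torus.** A module's population state is a
   phase φ on a torus; the shortest wrapped phase difference Δφ ∈ (−π, π]
   decodes a displacement B·Δφ/2π through the lattice basis; averaging
   per-module decoded displacements over a geometric scale stack
   ℓᵢ = ℓ₀·sⁱ contracts toward the target; a row-stochastic transition
   matrix over discretized phases plans step sequences; and a learned
   planner subnetwork drives the frozen network with internally generated
   speed/direction activity.

## Worked example

Generate the reference grid hierarchy (six modules, smallest spacing
30 cm, scale factor √e, spacing/field-size ratio 3.26), measure its
geometry, and plan on the phase torus:

```r
library(gridnav)

a <- arena(150, 150, bin_size = 1)
h <- phase_hierarchy()
mods <- make_grid_modules(h, n_cells_per_module = 1, a, seed = 1)
g <- measure_grid_geometry(mods[[1]]$ratemap$rates[, , 1], a, h$sigmas[1])
round(c(spacing = g$spacing, field_size = g$field_size, ratio = g$ratio), 3)
#>    spacing field_size      ratio
#>     30.000      9.202      3.260
```

The measured spacing is the median nearest-neighbour distance between
detected firing-field centers (30 cm: the configured smallest module
period) and the field size is the diameter at two standard deviations of
a Gaussian fit per field, so their ratio recovers 3.26.

```r
## displacement decoding on the torus: 1-D module with 30 cm period
decode_module_displacement(pi / 2, pi, 30)
#> [1] 7.5

## sequential planning on an 8-bin phase ring: 0 -> 3 takes the geodesic
m <- build_transition_matrix(8, dims = 1)
plan_phase_path(m, start_bin = 1, target_bin = 4)$path
#> [1] 1 2 3 4

## multi-scale vector navigation: 4 scales, start 100 cm from the target
l <- 30 * exp(1)^(0:3)
target <- lapply(l, function(L) phase_of_position(100, L))
nav <- vector_navigate(0, target, as.list(l), tol = 1.5)
round(drop(nav$positions), 2)
#> [1]   0.00  57.11  72.11  92.50 100.00
```

Training a path integrator and recalling locations from sensory cues use
the same interface (`fit_gridnet()` returns a classed model with
`print`/`summary`/`coef`/`predict`/`simulate` methods; see the vignette
for the study conditions and `?fit_gridnet`, `?recall_query`,
`?fit_planner` for the protocol details):

```r
cfg <- gridnet_config(hierarchy = phase_hierarchy(n_modules = 2))
fit <- fit_gridnet(cfg, variant = "gc_only", seed = 101)
pr  <- predict(fit, duration = 10, n_traj = 5, seed = 1)   # held-out decoding
```

## Package layout

- `R/arena.R` — arenas, random-foraging trajectories, self-motion codes
- `R/tuning_maps.R` — grid-module and SMC ratemaps, sampling, masking,
  field-geometry measurement
- `R/phase_planner.R` — toroidal phase algebra, multi-scale displacement
  combination, Markov sequential planning, vector navigation
- `R/rnn.R`, `R/training.R` — the recurrent model, losses, BPTT training
- `R/planner.R` — the learned planner subnetwork
- `R/analysis.R` — ratemap aggregation, nearest-neighbour decoding,
  spatial information, place-cell identification, recall queries, grid
  scores, PCA projections
- `R/experiment.R`, `inst/cli/gridnav.R` — YAML-configured experiment
  runner and a thin command-line wrapper
- `vignettes/hcmec-grid-planning.Rmd` — the methods vignette
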