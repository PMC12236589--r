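## Shared fitted models for the test suite. Training is expensive, so each
## configuration is fitted once per session and reused across test files.
## All sizes and schedules are the desk-scale study conditions described in
## the methods vignette.

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, builder(), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

## GC-only path integrator: 2 modules x 64 cells (the reference scaled-down
## configuration). Continuous foraging (no pauses): this experiment probes
## pure path integration.
gc_only_fit <- function() {
  cached("gc_only", function() {
    cfg <- gridnet_config(
      hierarchy = phase_hierarchy(n_modules = 2),
      n_gc_per_module = 64, n_dir = 32, n_spd = 16,
      motion = motion_params(pause_prob = 0),
      r_mask = 0.3, noise_sigma = 0.1, state_noise = 0.02,
      batch_size = 32, n_steps = 6800, learning_rate = 3e-3,
      curriculum = data.frame(n = c(3000, 1000, 2000, 800),
                              duration = c(1, 2.5, 5, 5),
                              lr = c(3e-3, 1e-3, 5e-4, 2e-4)),
      loss_every = 50)
    fit_gridnet(cfg, "gc_only", seed = 101)
  })
}

## GC-only base for the learned planner: 4 modules x 32 cells (the
## multi-scale stack planning relies on), run/pause foraging.
planner_base_fit <- function() {
  cached("planner_base", function() {
    cfg <- gridnet_config(
      hierarchy = phase_hierarchy(n_modules = 4),
      n_gc_per_module = 32, n_dir = 32, n_spd = 16,
      r_mask = 0.3, noise_sigma = 0.1, state_noise = 0.02,
      batch_size = 32, n_steps = 6800, learning_rate = 3e-3,
      curriculum = data.frame(n = c(3000, 1000, 2000, 800),
                              duration = c(1, 2.5, 5, 5),
                              lr = c(3e-3, 1e-3, 5e-4, 2e-4)),
      loss_every = 50)
    fit_gridnet(cfg, "gc_only", seed = 101)
  })
}

## Full HC-MEC network for the recall experiment and the full-loop planner:
## 4 modules x 16 GC, 64 SMC, 96 hidden, masking ramp up to r_mask = 0.9,
## cold-start episodes included.
hcmec_recall_fit <- function() {
  cached("hcmec_recall", function() {
    cfg <- gridnet_config(
      hierarchy = phase_hierarchy(n_modules = 4),
      n_gc_per_module = 16, n_smc = 64, n_dir = 32, n_spd = 16,
      n_hidden = 96, smc_correlation_length = 15,
      r_mask = 0.9, noise_sigma = 0.1, state_noise = 0.02,
      cold_start_prob = 0.25,
      batch_size = 32, n_steps = 3100, learning_rate = 3e-3,
      curriculum = data.frame(n = c(1200, 700, 900, 300),
                              duration = c(1, 1, 5, 5),
                              lr = c(3e-3, 2e-3, 7e-4, 3e-4),
                              r_mask = c(0.3, 0.9, 0.9, 0.9),
                              batch = c(32, 32, 24, 24)),
      loss_every = 50)
    fit_gridnet(cfg, "hcmec", seed = 501)
  })
}

## Small HC-MEC networks for the masking-ratio trend comparison (three
## seeds, two masking ratios, identical otherwise).
hcmec_trend_fit <- function(r_mask, seed) {
  cached(sprintf("trend_%03d_%d", round(100 * r_mask), seed), function() {
    cfg <- gridnet_config(
      hierarchy = phase_hierarchy(n_modules = 4),
      n_gc_per_module = 12, n_smc = 32, n_dir = 16, n_spd = 8,
      n_hidden = 64, smc_correlation_length = 15,
      r_mask = r_mask, noise_sigma = 0.1, state_noise = 0.02,
      cold_start_prob = 0.25,
      batch_size = 24, n_steps = 1400, learning_rate = 3e-3,
      curriculum = data.frame(n = c(700, 400, 300),
                              duration = c(1, 1, 5),
                              lr = c(3e-3, 2e-3, 7e-4),
                              r_mask = c(min(0.3, r_mask), r_mask, r_mask),
                              batch = c(24, 24, 20)),
      loss_every = 100)
    fit_gridnet(cfg, "hcmec", seed = seed)
  })
}

planner_gc_fit <- function() {
  cached("planner_gc", function() {
    fit_planner(planner_base_fit(),
                planner_config(planner_dim = 64, plan_horizon = 120,
                               n_pairs = 128, pair_duration = 1,
                               n_steps = 500, batch_size = 12,
                               learning_rate = 2e-3, state_noise = 0.02),
                seed = 301)
  })
}

planner_hcmec_fit <- function() {
  cached("planner_hcmec", function() {
    fit_planner(hcmec_recall_fit(),
                planner_config(planner_dim = 64, plan_horizon = 120,
                               n_pairs = 128, pair_duration = 1,
                               n_steps = 350, batch_size = 12,
                               learning_rate = 2e-3, state_noise = 0.02),
                seed = 302)
  })
}

## Start/goal pairs drawn from the endpoints of random trajectories.
trajectory_pairs <- function(fit, duration, n, seed) {
  tb <- traj_batch(fit$config$arena, fit$config$motion, duration, n,
                   seed = seed)
  Tn <- nrow(tb$px)
  list(start = cbind(tb$px[1, ], tb$py[1, ]),
       goal = cbind(tb$px[Tn, ], tb$py[Tn, ]))
}
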