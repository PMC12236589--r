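test_that("training batches respect masking and initial-state contracts", {
  cfg <- gridnet_config(arena = arena(80, 80, 4),
                        hierarchy = phase_hierarchy(n_modules = 1),
                        n_gc_per_module = 8, n_smc = 6, n_dir = 4, n_spd = 2,
                        n_hidden = 5, r_mask = 1, noise_sigma = 0,
                        traj_duration = 1, batch_size = 6)
  env <- build_fit_env(cfg, "hcmec", 11)
  set.seed(12)
  b <- make_training_batch(env, 6)
  expect_equal(dim(b$U), c(12, 6, 19))
  expect_equal(dim(b$gc), c(8, 6, 20))
  ## targets are the noiseless, unmasked ground truth
  bins <- position_to_bin(cbind(b$px[3, 2], b$py[3, 2]), cfg$arena)
  expect_equal(b$gc[, 2, 3], env$gc_flat[bins, ])
  expect_equal(b$smc[, 2, 3], env$smc_flat[bins, ])
  ## masked entries are exactly zero (with noise_sigma = 0 the unmasked SMC
  ## inputs equal the sampled truth, so zeros below the truth are masks)
  expect_true(mean(b$U == 0) > 0.05)

  ## with r_mask = 0 and no noise, inputs match the encodings exactly
  env0 <- env; env0$config$r_mask <- 0
  set.seed(13)
  b0 <- make_training_batch(env0, 3)
  expect_equal(b0$z0[env$layout$gc, ], b0$gc[, , 1])
  expect_equal(b0$z0[env$layout$smc, ], b0$smc[, , 1])
  expect_true(all(b0$z0[env$layout$hidden, ] == 0))
  expect_equal(b0$U[1:6, , 5], b0$smc[, , 6]) # observation at arrival point
})

test_that("the input-node pathway has no learnable projection", {
  ## parameter inventory: gradients exist only for W_rec and alpha; the
  ## injected input enters unscaled, so perturbing the input by delta moves
  ## the input-node pre-state by exactly (1 - alpha) * delta
  lay <- population_layout(n_gc = 4, n_smc = 3, n_dir = 2, n_spd = 2,
                           n_hidden = 3)
  p <- rnn_params_init(lay, seed = 9)
  expect_named(p[c("W", "beta")], c("W", "beta"))
  z <- rnorm(lay$d)
  u <- runif(length(lay$input_idx))
  delta <- runif(length(u))
  a <- 1 / (1 + exp(-p$beta))
  z1 <- rnn_step(p, z, u)
  z2 <- rnn_step(p, z, u + delta)
  expect_equal((z2 - z1)[lay$input_idx],
               (1 - a[lay$input_idx]) * delta, tolerance = 1e-12)
  expect_equal((z2 - z1)[-lay$input_idx],
               rep(0, lay$d - length(u)), tolerance = 1e-12)
})

test_that("short fits decrease the loss and are reproducible", {
  cfg <- gridnet_config(arena = arena(80, 80, 4),
                        hierarchy = phase_hierarchy(n_modules = 1),
                        n_gc_per_module = 10, n_smc = 8, n_dir = 6, n_spd = 3,
                        n_hidden = 8, r_mask = 0.5,
                        traj_duration = 1, batch_size = 8, n_steps = 120,
                        curriculum = FALSE, loss_every = 10)
  f1 <- fit_gridnet(cfg, "hcmec", seed = 21)
  expect_s3_class(f1, "gridnet")
  lt <- f1$loss_trace
  ## moving-average decrease from start to finish
  expect_lt(mean(utils::tail(lt$loss, 3)), mean(utils::head(lt$loss, 3)))
  f2 <- fit_gridnet(cfg, "hcmec", seed = 21)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$params$W, f2$params$W)

  ## model methods run end to end
  expect_output(print(f1), "hcmec")
  cf <- coef(f1)
  expect_equal(dim(cf[["gc<-smc"]]), c(10, 8))
  expect_true(all(cf$alpha >= 0 & cf$alpha <= 1))
  pr <- predict(f1, duration = 2, n_traj = 2, seed = 31)
  expect_equal(dim(pr$error), c(40, 2))
  tr <- simulate(f1, nsim = 2, seed = 5, duration = 1)
  expect_length(tr, 2)
})

test_that("planner training keeps frozen blocks at exact zero", {
  cfg <- gridnet_config(arena = arena(80, 80, 4),
                        hierarchy = phase_hierarchy(n_modules = 1),
                        n_gc_per_module = 8, n_smc = 6, n_dir = 4, n_spd = 2,
                        n_hidden = 5, traj_duration = 1, batch_size = 4,
                        n_steps = 10, curriculum = FALSE)
  base <- fit_gridnet(cfg, "hcmec", seed = 41)
  W0 <- base$params$W
  pl <- fit_planner(base, planner_config(planner_dim = 8, plan_horizon = 10,
                                         n_pairs = 8, n_steps = 15,
                                         batch_size = 4), seed = 42)
  ## structural zeros stay bitwise zero; base weights stay frozen
  expect_identical(pl$planner$W_smc_p, matrix(0, 8, 6))
  expect_identical(pl$planner$W_hpc_p, matrix(0, 8, 5))
  expect_identical(pl$base$params$W, W0)
  ## planning runs and reports terminal distances
  pth <- predict(pl, start = c(20, 20), goal = c(30, 30), horizon = 12)
  expect_length(pth$terminal_distance, 1)
  expect_equal(dim(pth$gc_path), c(12, 2, 1))
  expect_false(is.na(pth$smc_gc_discrepancy[1]))
})
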