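test_that("population layout is contiguous, disjoint, and flagged correctly", {
  lay <- population_layout(n_gc = 10, n_smc = 6, n_dir = 4, n_spd = 3,
                           n_hidden = 5)
  all_idx <- c(lay$gc, lay$smc, lay$dir, lay$spd, lay$hidden)
  expect_equal(sort(all_idx), 1:28)
  expect_equal(lay$d, 28)
  expect_equal(lay$input_idx, c(lay$smc, lay$dir, lay$spd))
  expect_equal(lay$output_idx, c(lay$gc, lay$smc))
  expect_length(lay$planner, 0)
})

test_that("rnn_step implements the leaky update with raw input injection", {
  lay <- population_layout(n_gc = 4, n_smc = 3, n_dir = 2, n_spd = 2,
                           n_hidden = 3)
  p <- rnn_params_init(lay, seed = 1)
  z <- rnorm(lay$d)
  u <- runif(length(lay$input_idx))

  ## alpha = 1: state frozen regardless of weights and input
  p1 <- p; p1$beta <- rep(1e3, lay$d) # sigmoid -> 1
  expect_equal(rnn_step(p1, z, u), z, tolerance = 1e-12)

  ## W = 0, alpha = 0: state is exactly the injected input
  p0 <- p; p0$W <- p0$W * 0; p0$beta <- rep(-1e3, lay$d)
  z1 <- rnn_step(p0, z, u)
  expect_equal(z1[lay$input_idx], u)
  expect_equal(z1[-lay$input_idx], rep(0, lay$d - length(u)))

  ## W = 0, alpha = 0.5, constant input from z0 = 0: geometric series
  ph <- p; ph$W <- ph$W * 0; ph$beta <- rep(0, lay$d) # sigmoid(0) = 0.5
  states <- rnn_rollout(ph, rep(0, lay$d), list(u, u, u))
  for (k in 1:3)
    expect_equal(states[[k + 1]][lay$input_idx], (1 - 0.5^k) * u,
                 tolerance = 1e-12)

  ## numeric failure names the offending population
  pb <- p; pb$W <- pb$W * NA
  expect_error(rnn_step(pb, z, u), "population")
})

test_that("rollout is deterministic and handles empty input", {
  lay <- population_layout(n_gc = 5, n_smc = 0, n_dir = 3, n_spd = 2,
                           n_hidden = 4)
  p <- rnn_params_init(lay, seed = 2)
  z0 <- rnorm(lay$d)
  expect_identical(rnn_rollout(p, z0), list(z0))
  us <- lapply(1:5, function(i) runif(length(lay$input_idx)))
  s1 <- rnn_rollout(p, z0, us)
  s2 <- rnn_rollout(p, z0, us)
  expect_identical(s1, s2)
  expect_length(s1, 6)
})

test_that("linear dynamics match the closed-form recursion", {
  lay <- population_layout(n_gc = 3, n_smc = 2, n_dir = 2, n_spd = 1,
                           n_hidden = 2)
  p <- rnn_params_init(lay, seed = 3, init_scale = 0.2,
                       nonlinearity = "identity")
  a <- 1 / (1 + exp(-p$beta))
  z <- rnorm(lay$d, 0, 0.1)
  us <- lapply(1:100, function(i) rnorm(length(lay$input_idx), 0, 0.1))
  states <- rnn_rollout(p, z, us)
  zc <- z
  for (t in 1:100) {
    U <- numeric(lay$d); U[lay$input_idx] <- us[[t]]
    zc <- a * zc + (1 - a) * (U + p$W %*% zc)
    zc <- as.numeric(zc)
  }
  expect_equal(states[[101]], zc, tolerance = 1e-8)
})

test_that("BPTT gradients match finite differences", {
  cfg <- gridnet_config(hierarchy = phase_hierarchy(n_modules = 1),
                        n_gc_per_module = 5, n_smc = 4, n_dir = 3, n_spd = 2,
                        n_hidden = 5, r_mask = 0.5, traj_duration = 0.5,
                        batch_size = 2, n_steps = 1, state_noise = 0,
                        supervise = "rate")
  env <- build_fit_env(cfg, "hcmec", 17)
  p <- rnn_params_init(env$layout, seed = 18)
  set.seed(19)
  batch <- make_training_batch(env, 2)
  g <- bptt_step(p$W, p$beta, env, batch)
  lossfn <- function(W, beta) {
    r <- bptt_step(W, beta, env, batch)
    r$loss_gc + r$loss_smc
  }
  eps <- 1e-6
  set.seed(20)
  idx <- cbind(sample(env$layout$d, 8, TRUE), sample(env$layout$d, 8, TRUE))
  for (r in seq_len(nrow(idx))) {
    Wp <- p$W; Wp[idx[r, 1], idx[r, 2]] <- Wp[idx[r, 1], idx[r, 2]] + eps
    Wm <- p$W; Wm[idx[r, 1], idx[r, 2]] <- Wm[idx[r, 1], idx[r, 2]] - eps
    fd <- (lossfn(Wp, p$beta) - lossfn(Wm, p$beta)) / (2 * eps)
    expect_equal(g$dW[idx[r, 1], idx[r, 2]], fd, tolerance = 1e-4)
  }
  for (i in sample(env$layout$d, 5)) {
    bp <- p$beta; bp[i] <- bp[i] + eps
    bm <- p$beta; bm[i] <- bm[i] - eps
    fd <- (lossfn(p$W, bp) - lossfn(p$W, bm)) / (2 * eps)
    expect_equal(g$dbeta[i], fd, tolerance = 1e-4)
  }
})

test_that("losses match an elementwise oracle and the alpha bound holds", {
  lay <- population_layout(n_gc = 4, n_smc = 3, n_dir = 2, n_spd = 2,
                           n_hidden = 3)
  set.seed(5)
  Tn <- 6; B <- 2
  states <- array(rnorm(lay$d * B * Tn), c(lay$d, B, Tn))
  gc_truth <- array(runif(4 * B * Tn), c(4, B, Tn))
  smc_truth <- array(runif(3 * B * Tn), c(3, B, Tn))
  ## brute-force elementwise oracle
  acc <- 0; n <- 0
  for (t in 2:Tn) for (b in 1:B) for (i in 1:4) {
    acc <- acc + (states[lay$gc[i], b, t] - gc_truth[i, b, t])^2; n <- n + 1
  }
  expect_equal(path_integration_loss(states, gc_truth, lay), acc / n)
  expect_equal(smc_autoencode_loss(states, smc_truth, lay),
               mean((states[lay$smc, , 2:Tn] - smc_truth[, , 2:Tn])^2))
  ## identities
  perfect <- array(0, c(lay$d, B, Tn)); perfect[lay$gc, , ] <- gc_truth
  expect_equal(path_integration_loss(perfect, gc_truth, lay), 0)
  offset <- perfect; offset[lay$gc, , ] <- gc_truth + 0.3
  expect_equal(path_integration_loss(offset, gc_truth, lay), 0.09,
               tolerance = 1e-12)
  expect_error(path_integration_loss(states, gc_truth[, , 1:3], lay),
               "differ in length")

  ## a brief fit keeps alpha within [0, 1] and its trace reproducible
  cfg <- gridnet_config(hierarchy = phase_hierarchy(n_modules = 1),
                        n_gc_per_module = 6, n_dir = 4, n_spd = 2,
                        traj_duration = 0.5, batch_size = 2, n_steps = 8,
                        curriculum = FALSE, loss_every = 2)
  f1 <- fit_gridnet(cfg, "gc_only", seed = 30)
  f2 <- fit_gridnet(cfg, "gc_only", seed = 30)
  expect_identical(f1$loss_trace, f2$loss_trace)
  alpha <- 1 / (1 + exp(-f1$params$beta))
  expect_true(all(alpha >= 0 & alpha <= 1))
})
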