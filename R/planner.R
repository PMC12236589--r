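#' Planner subnetwork configuration
#'
#' The planner is an extra recurrent block attached to a pre-trained network.
#' It receives the goal grid pattern through a learned projection
#' (`W_in g*`) plus the current grid rates through a second learned
#' projection (`W_gp g_t`), runs its own leaky recurrent dynamics (`W_pp`),
#' and drives the frozen base network exclusively through its action
#' readout: activity injected into the speed and head-direction input nodes.
#' Projections from SMC and hidden (place-cell) units into the planner are
#' structurally fixed to zero, so planning uses grid information only.
#'
#' @param planner_dim Planner population size.
#' @param plan_horizon Rollout length (timesteps) of each planning episode.
#' @param n_pairs Number of fixed start/goal pairs sampled for training.
#' @param pair_duration Duration (s) of the random trajectories whose
#'   endpoints define training pairs.
#' @param n_steps,batch_size,learning_rate Optimization settings.
#' @param alpha_p Planner leak (fixed scalar).
#' @param state_noise Sd of state perturbations injected into the base
#'   network during planner-training rollouts only; trains the policy to
#'   correct drift and hold the goal state robustly.
#' @return Object of class `"planner_config"`.
#' @export
planner_config <- function(planner_dim = 64, plan_horizon = 160,
                           n_pairs = 128, pair_duration = 1,
                           n_steps = 400, batch_size = 16,
                           learning_rate = 2e-3, alpha_p = 0.5,
                           state_noise = 0.02) {
  stopifnot(planner_dim >= 1, plan_horizon >= 2, n_pairs >= 1,
            alpha_p >= 0, alpha_p < 1)
  structure(as.list(environment()), class = "planner_config")
}

## Forward + backward of one planner training batch. The base network
## parameters (W, beta) are frozen; only the planner projections learn.
planner_bptt <- function(pp, fit, z0, gstar, Tn, state_noise = 0) {
  lay <- fit$layout
  nl <- rnn_nonlinearity(fit$params$nonlinearity)
  a <- sigmoid(fit$params$beta)
  one_a <- 1 - a
  W <- fit$params$W
  act_rows <- match(c(lay$dir, lay$spd), lay$input_idx)
  n_gc <- length(lay$gc)
  B <- ncol(z0)
  dp <- nrow(pp$W_pp)
  ap <- pp$alpha_p
  cin <- pp$W_in %*% gstar # dp x B, constant over time

  Zs <- array(0, c(lay$d, B, Tn + 1))
  Ps <- array(0, c(dp, B, Tn + 1))
  Z <- z0; P <- matrix(0, dp, B)
  Zs[, , 1] <- Z
  for (t in seq_len(Tn)) {
    q <- nl$f(P)
    g <- nl$f(Z[lay$gc, , drop = FALSE])
    A <- nl$f(pp$W_out %*% q) # actions are non-negative rate patterns
    Fz <- nl$f(Z)
    M <- W %*% Fz
    M[lay$input_idx[act_rows], ] <- M[lay$input_idx[act_rows], ] + A
    Znew <- a * Z + one_a * M
    if (state_noise > 0)
      Znew <- Znew + stats::rnorm(length(Znew), 0, state_noise)
    Pnew <- ap * P + (1 - ap) * (pp$W_pp %*% q + pp$W_gp %*% g + cin)
    Z <- Znew; P <- Pnew
    Zs[, , t + 1] <- Z; Ps[, , t + 1] <- P
  }
  if (any(!is.finite(Z)) || any(!is.finite(P)))
    stop("planner training diverged: non-finite state", call. = FALSE)

  norm <- Tn * n_gc * B
  G_rates <- nl$f(Zs[lay$gc, , 2:(Tn + 1), drop = FALSE])
  err <- G_rates - array(gstar, c(n_gc, B, Tn))
  loss <- sum(err^2) / norm

  dW_out <- matrix(0, nrow(pp$W_out), dp)
  dW_pp <- matrix(0, dp, dp)
  dW_gp <- matrix(0, dp, n_gc)
  dW_in <- matrix(0, dp, n_gc)
  dZ <- matrix(0, lay$d, B)
  dP <- matrix(0, dp, B)
  act_idx <- lay$input_idx[act_rows]
  for (t in Tn:1) {
    Zt1 <- matrix(Zs[, , t + 1], lay$d, B)
    ## supervision on rates at state t+1
    S <- matrix(0, lay$d, B)
    S[lay$gc, ] <- 2 * matrix(err[, , t], n_gc, B) *
      nl$df(Zt1[lay$gc, , drop = FALSE]) / norm
    dZ <- dZ + S
    dn <- one_a * dZ           # through the base update gate
    dPn <- (1 - ap) * dP       # through the planner update gate
    Zt <- matrix(Zs[, , t], lay$d, B); Pt <- matrix(Ps[, , t], dp, B)
    qt <- nl$f(Pt)
    gt <- nl$f(Zt[lay$gc, , drop = FALSE])
    dA <- dn[act_idx, , drop = FALSE] * nl$df(pp$W_out %*% qt)
    dW_out <- dW_out + tcrossprod(dA, qt)
    dW_pp <- dW_pp + tcrossprod(dPn, qt)
    dW_gp <- dW_gp + tcrossprod(dPn, gt)
    dW_in <- dW_in + tcrossprod(dPn, gstar)
    ## propagate to states at time t
    dZprev <- a * dZ + nl$df(Zt) * crossprod(W, dn)
    gc_back <- crossprod(pp$W_gp, dPn) # via g_t into planner
    dZprev[lay$gc, ] <- dZprev[lay$gc, ] +
      nl$df(Zt[lay$gc, , drop = FALSE]) * gc_back
    dPprev <- ap * dP + nl$df(Pt) *
      (crossprod(pp$W_pp, dPn) + crossprod(pp$W_out, dA))
    dZ <- dZprev; dP <- dPprev
  }
  list(loss = loss, dW_out = dW_out, dW_pp = dW_pp, dW_gp = dW_gp,
       dW_in = dW_in, states = Zs)
}

#' Train a planner subnetwork on a pre-trained network
#'
#' Start/goal pairs are the endpoints of short random trajectories (the
#' trajectories themselves are never shown to the planner). Each episode
#' initializes the frozen base network at the start location's ground-truth
#' grid (and, for hcmec fits, sensory) response, rolls the joint system for
#' `plan_horizon` steps with the planner producing speed/head-direction
#' input activity, and minimizes the mean squared error between the current
#' and goal grid rates over all timesteps. The base network weights stay
#' frozen, and the structural zero blocks from SMC/hidden units into the
#' planner are never touched by the optimizer.
#'
#' @param object A fitted [fit_gridnet()] model (either variant).
#' @param config A [planner_config()].
#' @param seed Integer seed.
#' @param verbose Print loss every 50 steps.
#' @return Object of class `"gridnet_planner"`.
#' @export
fit_planner <- function(object, config = planner_config(), seed = 1,
                        verbose = FALSE) {
  stopifnot(inherits(object, "gridnet"), inherits(config, "planner_config"))
  set.seed(as.integer(seed))
  lay <- object$layout
  n_gc <- length(lay$gc)
  n_act <- length(lay$dir) + length(lay$spd)
  dp <- config$planner_dim
  ## fixed training pairs from short random trajectories
  tb <- traj_batch(object$config$arena, object$config$motion,
                   config$pair_duration, config$n_pairs)
  Tn0 <- nrow(tb$px)
  starts <- cbind(tb$px[1, ], tb$py[1, ])
  goals <- cbind(tb$px[Tn0, ], tb$py[Tn0, ])
  sb <- position_to_bin(starts, object$config$arena)
  gb <- position_to_bin(goals, object$config$arena)

  sc <- 1 / sqrt(dp)
  pp <- list(W_pp = matrix(stats::rnorm(dp * dp, 0, sc), dp, dp),
             W_gp = matrix(stats::rnorm(dp * n_gc, 0, sc), dp, n_gc),
             W_in = matrix(stats::rnorm(dp * n_gc, 0, sc), dp, n_gc),
             ## small action readout at init: the planner starts near
             ## "stand still" and learns gentle pushes from there
             W_out = matrix(stats::rnorm(n_act * dp, 0, 0.2 * sc), n_act, dp),
             ## structural zeros: sensory and place-cell projections into the
             ## planner are pinned to zero and never updated
             W_smc_p = matrix(0, dp, length(lay$smc)),
             W_hpc_p = matrix(0, dp, length(lay$hidden)),
             alpha_p = config$alpha_p)
  learn <- c("W_pp", "W_gp", "W_in", "W_out")
  opt <- adam_new(pp[learn], config$learning_rate)
  trace <- list()
  for (step in seq_len(config$n_steps)) {
    pick <- sample(config$n_pairs, min(config$batch_size, config$n_pairs))
    z0 <- matrix(0, lay$d, length(pick))
    z0[lay$gc, ] <- t(object$gc_flat[sb[pick], , drop = FALSE])
    if (length(lay$smc) > 0)
      z0[lay$smc, ] <- t(object$smc_flat[sb[pick], , drop = FALSE])
    gstar <- t(object$gc_flat[gb[pick], , drop = FALSE])
    g <- planner_bptt(pp, object, z0, gstar, config$plan_horizon,
                      state_noise = config$state_noise)
    upd <- adam_update(opt, pp[learn],
                       list(W_pp = g$dW_pp, W_gp = g$dW_gp,
                            W_in = g$dW_in, W_out = g$dW_out))
    opt <- upd$opt
    pp[learn] <- upd$params
    if (step %% 10 == 0 || step == 1) {
      trace[[length(trace) + 1]] <- data.frame(step = step, loss = g$loss)
      if (verbose && (step %% 50 == 0 || step == 1))
        message(sprintf("planner step %4d  loss %.5f", step, g$loss))
    }
  }
  structure(list(planner = pp, base = object, config = config, seed = seed,
                 pairs = list(starts = starts, goals = goals),
                 loss_trace = do.call(rbind, trace)),
            class = "gridnet_planner")
}

#' @export
print.gridnet_planner <- function(x, ...) {
  cat(sprintf("Planner subnetwork: %d units driving a '%s' base network\n",
              nrow(x$planner$W_pp), x$base$variant))
  cat(sprintf("  trained on %d fixed pairs (%g s apart), final loss %.5f\n",
              x$config$n_pairs, x$config$pair_duration,
              utils::tail(x$loss_trace$loss, 1)))
  invisible(x)
}

#' Plan between locations with a trained planner
#'
#' @param object A [fit_planner()] result.
#' @param start,goal Length-2 positions (cm), or matrices (one row per
#'   episode).
#' @param horizon Rollout length; defaults to the training horizon.
#' @param ... Unused.
#' @return List of class `"planner_paths"`: decoded GC positions per step
#'   (`gc_path`, T x 2 x n), decoded SMC positions when available
#'   (`smc_path`), terminal GC-decoded distance to goal per episode
#'   (`terminal_distance`), and mean per-step GC/SMC decoded discrepancy
#'   (`smc_gc_discrepancy`).
#' @export
predict.gridnet_planner <- function(object, start, goal, horizon = NULL, ...) {
  fit <- object$base
  lay <- fit$layout
  nl <- rnn_nonlinearity(fit$params$nonlinearity)
  start <- matrix(start, ncol = 2)
  goal <- matrix(goal, ncol = 2)
  n <- nrow(start)
  Tn <- horizon %||% object$config$plan_horizon
  sb <- position_to_bin(start, fit$config$arena)
  gb <- position_to_bin(goal, fit$config$arena)
  z0 <- matrix(0, lay$d, n)
  z0[lay$gc, ] <- t(fit$gc_flat[sb, , drop = FALSE])
  if (length(lay$smc) > 0)
    z0[lay$smc, ] <- t(fit$smc_flat[sb, , drop = FALSE])
  gstar <- t(fit$gc_flat[gb, , drop = FALSE])
  fw <- planner_bptt(object$planner, fit, z0, gstar, Tn)
  Zs <- fw$states
  r2 <- rowSums(fit$gc_flat^2)
  gc_path <- array(0, c(Tn, 2, n))
  smc_path <- NULL
  disc <- rep(NA_real_, n)
  if (length(lay$smc) > 0) {
    smc_path <- array(0, c(Tn, 2, n))
    r2s <- rowSums(fit$smc_flat^2)
  }
  term <- numeric(n)
  for (b in seq_len(n)) {
    Q <- nl$f(Zs[lay$gc, b, 2:(Tn + 1), drop = TRUE])
    d2 <- r2 - 2 * fit$gc_flat %*% Q
    dec <- bin_to_position(apply(d2, 2, which.min), fit$config$arena)
    gc_path[, , b] <- dec
    term[b] <- sqrt(sum((dec[Tn, ] - goal[b, ])^2))
    if (!is.null(smc_path)) {
      Qs <- nl$f(Zs[lay$smc, b, 2:(Tn + 1), drop = TRUE])
      d2s <- r2s - 2 * fit$smc_flat %*% Qs
      decs <- bin_to_position(apply(d2s, 2, which.min), fit$config$arena)
      smc_path[, , b] <- decs
      disc[b] <- mean(sqrt(rowSums((dec - decs)^2)))
    }
  }
  structure(list(gc_path = gc_path, smc_path = smc_path,
                 terminal_distance = term, smc_gc_discrepancy = disc,
                 start = start, goal = goal),
            class = "planner_paths")
}

#' @export
print.planner_paths <- function(x, ...) {
  cat(sprintf("%d planned episodes: terminal GC-decoded distance %.1f cm (mean)\n",
              length(x$terminal_distance), mean(x$terminal_distance)))
  if (!all(is.na(x$smc_gc_discrepancy)))
    cat(sprintf("  mean SMC-vs-GC decoded discrepancy: %.1f cm\n",
                mean(x$smc_gc_discrepancy, na.rm = TRUE)))
  invisible(x)
}
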