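#' @export
print.gridnet <- function(x, ...) {
  cat(sprintf("Fitted HC-MEC network (variant '%s')\n", x$variant))
  print(x$layout)
  cat(sprintf("  modules: %s cm; arena %.0f x %.0f cm\n",
              paste(round(x$config$hierarchy$periods, 1), collapse = ", "),
              x$config$arena$width, x$config$arena$height))
  lt <- x$loss_trace
  cat(sprintf("  %d training steps, final loss %.5f (r_mask = %.2f)\n",
              max(lt$step), utils::tail(lt$loss, 1), x$config$r_mask))
  invisible(x)
}

#' @export
summary.gridnet <- function(object, duration = 10, n_traj = 5,
                            seed = 2024, ...) {
  pr <- predict(object, duration = duration, n_traj = n_traj, seed = seed)
  out <- list(variant = object$variant,
              layout = object$layout,
              final_loss = utils::tail(object$loss_trace$loss, 1),
              decode_error = summary(as.numeric(pr$error)),
              duration = duration,
              alpha = summary(sigmoid(object$params$beta)))
  class(out) <- "summary.gridnet"
  out
}

#' @export
print.summary.gridnet <- function(x, ...) {
  cat(sprintf("HC-MEC network ('%s'): final training loss %.5f\n",
              x$variant, x$final_loss))
  cat(sprintf("GC-decoded position error on %g s held-out trajectories (cm):\n",
              x$duration))
  print(x$decode_error)
  cat("learned per-unit forgetting rates alpha:\n")
  print(x$alpha)
  invisible(x)
}

#' Extract fitted weights
#'
#' @param object A fitted [fit_gridnet()] model.
#' @param ... Unused.
#' @return List with the full recurrent matrix `W`, the per-unit forgetting
#'   vector `alpha`, and named inter-population blocks of `W`
#'   (e.g. `W[["gc<-smc"]]` maps SMC rates into GC updates).
#' @export
coef.gridnet <- function(object, ...) {
  lay <- object$layout
  pops <- list(gc = lay$gc, smc = lay$smc, dir = lay$dir, spd = lay$spd,
               hidden = lay$hidden)
  pops <- pops[vapply(pops, length, integer(1)) > 0]
  blocks <- list()
  for (to in names(pops)) for (from in names(pops))
    blocks[[paste0(to, "<-", from)]] <-
      object$params$W[pops[[to]], pops[[from]], drop = FALSE]
  c(list(W = object$params$W, alpha = sigmoid(object$params$beta)), blocks)
}

#' Decode held-out trajectories with a fitted network
#'
#' Rolls the network over freshly simulated (or supplied) trajectories with
#' noisy self-motion input and decodes the grid-cell rates against the
#' ground-truth grid dictionary by exact nearest-neighbour search.
#'
#' @param object A fitted [fit_gridnet()] model.
#' @param trajectory Optional `"trajectory"` (or list of them) to decode;
#'   default simulates `n_traj` fresh ones.
#' @param duration,n_traj,seed Simulation settings when `trajectory` is NULL.
#' @param ... Unused.
#' @return List of class `"gridnet_prediction"`: `decoded` (T x 2 x n array
#'   of decoded positions), `truth` (same shape), `error` (T x n cm), and
#'   the state array.
#' @export
predict.gridnet <- function(object, trajectory = NULL, duration = 10,
                            n_traj = 5, seed = NULL, ...) {
  lay <- object$layout
  nl <- rnn_nonlinearity(object$params$nonlinearity)
  if (is.null(trajectory)) {
    ro <- gridnet_rollout(object, duration = duration, n = n_traj,
                          seed = seed, noise = TRUE)
    px <- ro$batch$px; py <- ro$batch$py
    S <- ro$states
  } else {
    if (inherits(trajectory, "trajectory")) trajectory <- list(trajectory)
    n_traj <- length(trajectory)
    S <- NULL; px <- NULL; py <- NULL
    for (tr in trajectory) {
      ro1 <- rollout_given(object, tr)
      S <- if (is.null(S)) ro1$states else abind3(S, ro1$states)
      px <- cbind(px, tr$positions[, 1]); py <- cbind(py, tr$positions[, 2])
    }
  }
  Tn <- dim(S)[3]
  r2 <- rowSums(object$gc_flat^2)
  decoded <- array(0, c(Tn, 2, n_traj))
  err <- matrix(0, Tn, n_traj)
  for (b in seq_len(n_traj)) {
    Q <- nl$f(S[lay$gc, b, , drop = TRUE])
    d2 <- r2 - 2 * object$gc_flat %*% Q
    dec <- bin_to_position(apply(d2, 2, which.min), object$config$arena)
    decoded[, , b] <- dec
    err[, b] <- sqrt((dec[, 1] - px[, b])^2 + (dec[, 2] - py[, b])^2)
  }
  structure(list(decoded = decoded,
                 truth = array(c(px, py), c(Tn, n_traj, 2)),
                 error = err, states = S),
            class = "gridnet_prediction")
}

#' @export
print.gridnet_prediction <- function(x, ...) {
  cat(sprintf("Decoded %d trajectories x %d timesteps; error mean %.2f, median %.2f cm\n",
              dim(x$error)[2], dim(x$error)[1], mean(x$error),
              stats::median(x$error)))
  invisible(x)
}

## bind two d x B x T arrays along B
abind3 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2] + dim(b)[2], d[3]))
  out[, seq_len(d[2]), ] <- a
  out[, d[2] + seq_len(dim(b)[2]), ] <- b
  out
}

## Roll the fitted network over one externally supplied trajectory.
rollout_given <- function(object, traj, r_mask = 0, noise = TRUE) {
  env <- object$env
  cfg <- object$config
  lay <- object$layout
  Tn <- nrow(traj$positions)
  bins <- position_to_bin(traj$positions, cfg$arena)
  gc_t <- t(object$gc_flat[bins, , drop = FALSE])
  smc_t <- if (env$n_smc > 0) t(object$smc_flat[bins, , drop = FALSE])
  sm <- object$self_motion
  dir_enc <- t(exp((cos(outer(traj$headings, sm$preferred_dirs, "-")) - 1) /
                     sm$dir_tuning_width^2))
  spd_enc <- t(outer(traj$speeds, sm$speed_gains))
  n_in <- length(lay$input_idx)
  U <- array(0, c(n_in, 1, Tn - 1))
  for (t in seq_len(Tn - 1)) {
    u <- c(if (env$n_smc > 0) smc_t[, t + 1], dir_enc[, t], spd_enc[, t])
    U[, 1, t] <- u
  }
  if (noise && cfg$noise_sigma > 0)
    U <- U + stats::rnorm(length(U), 0, cfg$noise_sigma)
  z0 <- matrix(0, lay$d, 1)
  z0[lay$gc, 1] <- gc_t[, 1]
  if (env$n_smc > 0) z0[lay$smc, 1] <- smc_t[, 1]
  nl <- rnn_nonlinearity(object$params$nonlinearity)
  a <- sigmoid(object$params$beta)
  W <- object$params$W
  S <- array(0, c(lay$d, 1, Tn))
  Z <- z0; S[, 1, 1] <- z0
  for (t in seq_len(Tn - 1)) {
    M <- W %*% nl$f(Z)
    M[lay$input_idx, ] <- M[lay$input_idx, ] + U[, , t, drop = FALSE][, , 1]
    Z <- a * Z + (1 - a) * M
    S[, 1, t + 1] <- Z
  }
  list(states = S)
}

#' Simulate trajectories from the fitted model's motion model
#'
#' @param object A fitted [fit_gridnet()] model.
#' @param nsim Number of trajectories.
#' @param seed Integer seed.
#' @param duration Trajectory duration (s).
#' @param ... Unused.
#' @return A list of `"trajectory"` objects (a single object for `nsim = 1`).
#' @export
simulate.gridnet <- function(object, nsim = 1, seed = NULL, duration = 5,
                             ...) {
  simulate_trajectory(object$config$arena, object$config$motion,
                      duration = duration, n = nsim, seed = seed)
}

#' Decode-error residuals of a fitted network
#'
#' @param object A fitted [fit_gridnet()] model.
#' @param duration,n_traj,seed Passed to [predict.gridnet()].
#' @param ... Unused.
#' @return T x n matrix of per-timestep position decode errors (cm).
#' @export
residuals.gridnet <- function(object, duration = 10, n_traj = 5,
                              seed = NULL, ...) {
  predict(object, duration = duration, n_traj = n_traj, seed = seed)$error
}

#' Plot a fitted network
#'
#' @param x A fitted [fit_gridnet()] model.
#' @param type `"loss"` (training trace), `"ratemap"` (one cell's
#'   ground-truth grid map), or `"connectivity"` (the recurrent matrix with
#'   population boundaries).
#' @param cell Cell index for `type = "ratemap"`.
#' @param ... Unused.
#' @export
plot.gridnet <- function(x, type = c("loss", "ratemap", "connectivity"),
                         cell = 1, ...) {
  type <- match.arg(type)
  if (type == "loss") {
    lt <- x$loss_trace
    graphics::plot(lt$step, lt$loss, type = "l", log = "y",
                   xlab = "training step", ylab = "loss",
                   main = "training loss")
  } else if (type == "ratemap") {
    arena <- x$config$arena
    m <- matrix(x$gc_flat[, cell], arena$nx, arena$ny)
    graphics::image(seq_len(arena$nx) * arena$bin_size,
                    seq_len(arena$ny) * arena$bin_size, m,
                    xlab = "x (cm)", ylab = "y (cm)", useRaster = TRUE,
                    main = sprintf("grid cell %d ground-truth ratemap", cell))
  } else {
    graphics::image(x$params$W, useRaster = TRUE,
                    main = "recurrent connectivity", xlab = "", ylab = "")
  }
  invisible(x)
}
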