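#' Training configuration for the recurrent network
#'
#' Defaults are the desk-scale study conditions: a 1.5 m x 1.5 m arena at
#' 2 cm binning, two grid modules of 64 cells (smallest period 30 cm, scale
#' factor sqrt(e)), 5 s training trajectories at dt = 0.05 s, masked inputs
#' with a per-trajectory masking fraction drawn from Uniform(0, r_mask), and
#' additive Gaussian noise on the self-motion inputs.
#'
#' @param arena An [arena()].
#' @param hierarchy A [phase_hierarchy()]; use `n_modules = 2` (default here)
#'   for desk-scale fits.
#' @param n_gc_per_module,n_smc,n_dir,n_spd,n_hidden Population sizes. SMC
#'   and HIDDEN are only instantiated by the `"hcmec"` variant.
#' @param smc_correlation_length,smc_amplitude SMC map parameters (cm, rate).
#' @param motion A [motion_params()].
#' @param dir_tuning_width Head-direction tuning width (radians).
#' @param r_mask Maximum masking fraction in `[0, 1]`.
#' @param noise_sigma Sd of additive Gaussian noise on self-motion inputs
#'   (signal scale is order 1).
#' @param traj_duration Training-trajectory duration (seconds).
#' @param batch_size Trajectories per gradient step.
#' @param n_steps Gradient steps.
#' @param learning_rate Adam learning rate.
#' @param alpha_init,init_scale,nonlinearity Passed to [rnn_params_init()].
#' @param supervise `"rate"` (default) supervises the rectified activations
#'   f(z) of the output populations against the non-negative ground-truth
#'   rates, leaving the subthreshold range free for computation; `"state"`
#'   supervises z directly.
#' @param state_noise Sd of small Gaussian perturbations added to the state
#'   each timestep during training only; encourages contraction onto the
#'   represented manifold (0 disables).
#' @param cold_start_prob Probability that a training trajectory starts with
#'   its grid-cell initial state fully zeroed (a "cold start"), forcing the
#'   network to localize from the sensory stream alone. 0 (default)
#'   reproduces the plain masking protocol; small positive values are a
#'   desk-scale aid that exposes the network to the cue-recall condition.
#' @param mask_per_population `"auto"` (default) draws the effective masking
#'   fraction independently per masking target (SMC/DIR/SPD inputs, GC/SMC
#'   initial state) when SMC units are present - the regime in which pathway
#'   trade-offs drive cross-population association - and uses one shared
#'   draw otherwise; `TRUE`/`FALSE` force either behaviour.
#' @param curriculum Either `TRUE` (default: the first 60% of steps use 1 s
#'   trajectory segments at the full learning rate, the rest the full
#'   `traj_duration` at a quarter of it), `FALSE` (all steps at
#'   `traj_duration`), or a data.frame with columns `n`, `duration`, `lr`.
#' @param loss_every Record the loss trace at this cadence.
#' @return Object of class `"gridnet_config"`.
#' @export
gridnet_config <- function(arena = NULL,
                           hierarchy = phase_hierarchy(n_modules = 2),
                           n_gc_per_module = 64, n_smc = 128, n_dir = 32,
                           n_spd = 16, n_hidden = 256,
                           smc_correlation_length = 30, smc_amplitude = 1,
                           motion = motion_params(),
                           dir_tuning_width = 0.5,
                           r_mask = 0.5, noise_sigma = 0.1,
                           traj_duration = 5, batch_size = 32,
                           n_steps = 5000, learning_rate = 3e-3,
                           alpha_init = 0.9, init_scale = 0.5,
                           nonlinearity = "relu", supervise = "rate",
                           state_noise = 0.02, curriculum = TRUE,
                           mask_per_population = "auto",
                           cold_start_prob = 0,
                           loss_every = 10) {
  if (is.null(arena)) arena <- arena(150, 150, 2)
  stopifnot(inherits(arena, "arena"),
            r_mask >= 0, r_mask <= 1, noise_sigma >= 0, traj_duration > 0,
            batch_size >= 1, n_steps >= 1, learning_rate > 0,
            supervise %in% c("rate", "state"), state_noise >= 0)
  structure(as.list(environment()), class = "gridnet_config")
}

## Resolve the curriculum into phases of (n steps, segment duration, lr) and
## optionally a per-phase masking ratio ramp ending at config$r_mask.
curriculum_phases <- function(config) {
  cur <- config$curriculum
  if (is.data.frame(cur)) {
    if (is.null(cur$r_mask)) cur$r_mask <- config$r_mask
    if (is.null(cur$batch)) cur$batch <- config$batch_size
    return(cur)
  }
  if (identical(cur, FALSE) || config$traj_duration <= 1)
    return(data.frame(n = config$n_steps, duration = config$traj_duration,
                      lr = config$learning_rate, r_mask = config$r_mask,
                      batch = config$batch_size))
  n1 <- round(0.6 * config$n_steps)
  data.frame(n = c(n1, config$n_steps - n1),
             duration = c(1, config$traj_duration),
             lr = c(config$learning_rate, config$learning_rate / 4),
             r_mask = config$r_mask, batch = config$batch_size)
}

## Mean squared error between the supervised coordinates of a state sequence
## and ground truth, over timesteps t >= 2 (the initial state is provided,
## not predicted). states: d x B x T array or list of d x B matrices;
## truth: n x B x T array over the population coordinates.
population_mse <- function(states, truth, idx) {
  if (is.list(states)) states <- simplify2array(states)
  if (length(dim(states)) == 2) states <- array(states, c(dim(states), 1))
  Tn <- dim(states)[3]
  if (dim(truth)[3] != Tn)
    stop("state and truth sequences differ in length", call. = FALSE)
  if (Tn < 2) return(0)
  diff <- states[idx, , 2:Tn, drop = FALSE] - truth[, , 2:Tn, drop = FALSE]
  mean(diff^2)
}

#' Path-integration loss
#'
#' Mean squared error between the grid-cell output coordinates of a state
#' sequence and the ground-truth grid rates, over all timesteps after the
#' initial condition.
#'
#' @param states State sequence: list of d x B matrices or d x B x T array.
#' @param gc_truth Ground truth, n_gc x B x T array.
#' @param layout The [population_layout()].
#' @return Scalar loss.
#' @export
path_integration_loss <- function(states, gc_truth, layout) {
  population_mse(states, gc_truth, layout$gc)
}

#' Sensory autoencoding loss
#'
#' Mean squared error between the SMC output coordinates and the noiseless,
#' unmasked ground-truth sensory responses.
#'
#' @param states State sequence as in [path_integration_loss()].
#' @param smc_truth Ground truth, n_smc x B x T array.
#' @param layout The [population_layout()].
#' @return Scalar loss.
#' @export
smc_autoencode_loss <- function(states, smc_truth, layout) {
  population_mse(states, smc_truth, layout$smc)
}

## ---------------------------------------------------------------------------
## Batch construction: trajectories -> inputs, initial state, targets.
## Input at update t (driving state t -> t+1) carries the motion command at t
## and the sensory observation at the arrival point t+1.
make_training_batch <- function(env, B, duration = NULL, mask = TRUE) {
  cfg <- env$config
  duration <- duration %||% cfg$traj_duration
  tb <- traj_batch(cfg$arena, cfg$motion, duration, B)
  Tn <- nrow(tb$px)
  bins <- position_to_bin(cbind(as.numeric(tb$px), as.numeric(tb$py)),
                          cfg$arena) # (Tn*B)
  gc_t <- array(t(env$gc_flat[bins, , drop = FALSE]),
                c(env$n_gc, Tn, B)) # n x T x B
  gc_t <- aperm(gc_t, c(1, 3, 2))   # n x B x T
  smc_t <- NULL
  if (env$n_smc > 0) {
    smc_t <- aperm(array(t(env$smc_flat[bins, , drop = FALSE]),
                         c(env$n_smc, Tn, B)), c(1, 3, 2))
  }
  ## self-motion encodings per timestep
  w2 <- cfg$dir_tuning_width^2
  dir_enc <- exp((cos(outer(as.numeric(tb$hd), env$pref_dirs, "-")) - 1) / w2)
  spd_enc <- outer(as.numeric(tb$sp), env$spd_gains)
  dir_t <- aperm(array(t(dir_enc), c(env$n_dir, Tn, B)), c(1, 3, 2))
  spd_t <- aperm(array(t(spd_enc), c(env$n_spd, Tn, B)), c(1, 3, 2))

  n_in <- env$n_smc + env$n_dir + env$n_spd
  U <- array(0, c(n_in, B, Tn - 1))
  smc_rows <- seq_len(env$n_smc)
  dir_rows <- env$n_smc + seq_len(env$n_dir)
  spd_rows <- env$n_smc + env$n_dir + seq_len(env$n_spd)
  for (t in seq_len(Tn - 1)) {
    if (env$n_smc > 0) U[smc_rows, , t] <- smc_t[, , t + 1]
    U[dir_rows, , t] <- dir_t[, , t]
    U[spd_rows, , t] <- spd_t[, , t]
  }
  if (cfg$noise_sigma > 0)
    U <- U + stats::rnorm(length(U), 0, cfg$noise_sigma)
  ## initial state: ground-truth GC (and SMC) at t = 1, zero elsewhere
  z0 <- matrix(0, env$layout$d, B)
  z0[env$layout$gc, ] <- gc_t[, , 1]
  if (env$n_smc > 0) z0[env$layout$smc, ] <- smc_t[, , 1]
  ## masking: an effective fraction f ~ U(0, r_mask) is drawn per trajectory
  ## *and per masking target* (SMC, DIR and SPD inputs; GC and SMC initial
  ## states), then independent Bernoulli(f) entries are zeroed. Independent
  ## per-target draws create trajectories in which one pathway (e.g. all
  ## self-motion input) is nearly absent while the others survive, which is
  ## what forces the cross-population associations to form.
  if (mask && cfg$r_mask > 0) {
    per_pop <- cfg$mask_per_population %||% "auto"
    if (identical(per_pop, "auto")) per_pop <- env$n_smc > 0
    if (per_pop) {
      tgt_rows <- list(smc_rows, dir_rows, spd_rows)
    } else {
      tgt_rows <- list(seq_len(n_in))
    }
    tgt_rows <- tgt_rows[vapply(tgt_rows, length, integer(1)) > 0]
    init_idx <- list(env$layout$gc, env$layout$smc)
    init_idx <- init_idx[vapply(init_idx, length, integer(1)) > 0]
    if (!per_pop) init_idx <- list(unlist(init_idx))
    for (b in seq_len(B)) {
      f <- stats::runif(1, 0, cfg$r_mask)
      for (rows in tgt_rows) {
        if (per_pop) f <- stats::runif(1, 0, cfg$r_mask)
        U[rows, b, ][stats::runif(length(rows) * (Tn - 1)) < f] <- 0
      }
      for (idx in init_idx) {
        if (per_pop) f <- stats::runif(1, 0, cfg$r_mask)
        z0[idx, b][stats::runif(length(idx)) < f] <- 0
      }
    }
  }
  if (mask && (cfg$cold_start_prob %||% 0) > 0) {
    cold <- stats::runif(B) < cfg$cold_start_prob
    z0[env$layout$gc, cold] <- 0
  }
  list(U = U, z0 = z0, gc = gc_t, smc = smc_t, Tn = Tn,
       px = tb$px, py = tb$py)
}

## ---------------------------------------------------------------------------
## Forward + backward through time. Returns loss components and gradients of
## the mean losses w.r.t. W and beta (alpha = sigmoid(beta)). Dispatches to
## the compiled core for the rectified nonlinearity; the R reference below
## covers the alternatives and serves as the cross-check in the tests.
bptt_step <- function(W, beta, env, batch, train = TRUE) {
  cfg <- env$config
  if (identical(cfg$nonlinearity, "relu")) {
    smc <- batch$smc
    res <- .bptt_core(W, beta, batch$U, batch$z0, batch$gc, smc,
                      env$layout$gc, env$layout$smc %||% integer(0),
                      env$layout$input_idx,
                      if (train) cfg$state_noise else 0,
                      identical(cfg$supervise, "rate"), TRUE)
    return(list(loss_gc = res$loss_gc, loss_smc = res$loss_smc,
                dW = res$dW, dbeta = as.numeric(res$dbeta)))
  }
  bptt_step_r(W, beta, env, batch, train)
}

bptt_step_r <- function(W, beta, env, batch, train = TRUE) {
  lay <- env$layout
  cfg <- env$config
  nl <- rnn_nonlinearity(cfg$nonlinearity)
  rate_sup <- identical(cfg$supervise, "rate")
  a <- sigmoid(beta)
  one_a <- 1 - a
  U <- batch$U; Tn <- batch$Tn
  B <- ncol(batch$z0)
  d <- lay$d
  S <- array(0, c(d, B, Tn))
  Fc <- array(0, c(d, B, Tn - 1))
  S[, , 1] <- batch$z0
  Z <- batch$z0
  snoise <- if (train) cfg$state_noise else 0
  for (t in seq_len(Tn - 1)) {
    Fz <- nl$f(Z)
    Fc[, , t] <- Fz
    M <- W %*% Fz
    M[lay$input_idx, ] <- M[lay$input_idx, ] + U[, , t]
    Z <- a * Z + one_a * M
    ## small state perturbations during training encourage contraction back
    ## onto the represented manifold (treated as constants in the backward
    ## pass, like the masking noise)
    if (snoise > 0) Z <- Z + stats::rnorm(length(Z), 0, snoise)
    S[, , t + 1] <- Z
  }
  if (any(!is.finite(Z)))
    stop("training diverged: non-finite state", call. = FALSE)

  out_of <- function(x) if (rate_sup) nl$f(x) else x
  norm_gc <- (Tn - 1) * env$n_gc * B
  err_gc <- out_of(S[lay$gc, , 2:Tn, drop = FALSE]) -
    batch$gc[, , 2:Tn, drop = FALSE]
  loss_gc <- sum(err_gc^2) / norm_gc
  loss_smc <- 0
  if (env$n_smc > 0) {
    norm_smc <- (Tn - 1) * env$n_smc * B
    err_smc <- out_of(S[lay$smc, , 2:Tn, drop = FALSE]) -
      batch$smc[, , 2:Tn, drop = FALSE]
    loss_smc <- sum(err_smc^2) / norm_smc
  }

  dbeta_acc <- numeric(d)
  delta_next <- matrix(0, d, B) # dL/dS_{t+1}, filled from t = Tn down
  ## collect per-step gradient factors and run one large GEMM at the end:
  ## dW = sum_t ((1-a) * delta_{t+1}) F_t' = DN %*% t(FC)
  DN <- matrix(0, d, B * (Tn - 1))
  G <- matrix(0, d, B)
  for (t in (Tn - 1):1) {
    ## supervision gradient at state t+1 (through f if supervising rates)
    G[] <- 0
    G[lay$gc, ] <- 2 * err_gc[, , t] / norm_gc
    if (env$n_smc > 0) G[lay$smc, ] <- 2 * err_smc[, , t] / norm_smc
    if (rate_sup) {
      out_idx <- lay$output_idx
      G[out_idx, ] <- G[out_idx, ] * nl$df(S[out_idx, , t + 1])
    }
    delta_next <- delta_next + G
    dn <- one_a * delta_next
    DN[, (t - 1) * B + seq_len(B)] <- dn
    ## d/da: S_{t+1} = a S_t + (1-a) M_t  =>  dS_{t+1}/da = S_t - M_t
    St <- S[, , t]
    Mt <- (S[, , t + 1] - a * St) / one_a
    dbeta_acc <- dbeta_acc + rowSums(delta_next * (St - Mt))
    ## propagate to state t (nonlinearity derivative at the pre-state)
    delta_next <- a * delta_next + nl$df(St) * crossprod(W, dn)
  }
  dW <- tcrossprod(DN, matrix(Fc, d, B * (Tn - 1)))
  dbeta <- dbeta_acc * a * one_a
  list(loss_gc = loss_gc, loss_smc = loss_smc, dW = dW, dbeta = dbeta)
}

## Minimal Adam optimizer over a named list of arrays.
adam_new <- function(shapes, lr) {
  list(lr = lr, b1 = 0.9, b2 = 0.999, eps = 1e-8, t = 0,
       m = lapply(shapes, function(x) x * 0),
       v = lapply(shapes, function(x) x * 0))
}

adam_update <- function(opt, params, grads, clip = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > clip) grads <- lapply(grads, function(g) g * clip / gn)
  opt$t <- opt$t + 1
  corr1 <- 1 - opt$b1^opt$t
  corr2 <- 1 - opt$b2^opt$t
  for (nm in names(params)) {
    opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * grads[[nm]]
    opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - opt$lr * (opt$m[[nm]] / corr1) /
      (sqrt(opt$v[[nm]] / corr2) + opt$eps)
  }
  list(opt = opt, params = params)
}

## Shared fitting environment: ground-truth maps, layout, flat dictionaries.
build_fit_env <- function(config, variant, seed) {
  set.seed(as.integer(seed))
  hier <- config$hierarchy
  gm <- make_grid_modules(hier, config$n_gc_per_module, config$arena,
                          seed = seed)
  n_gc <- hier$n_modules * config$n_gc_per_module
  gc_flat <- do.call(cbind, lapply(gm, function(g) {
    d <- dim(g$ratemap$rates)
    matrix(g$ratemap$rates, d[1] * d[2], d[3])
  }))
  n_smc <- if (variant %in% c("hcmec")) config$n_smc else 0
  n_hidden <- if (variant %in% c("hcmec")) config$n_hidden else 0
  smc_map <- NULL; smc_flat <- NULL
  if (n_smc > 0) {
    smc_map <- make_smc_map(n_smc, config$arena, config$smc_correlation_length,
                            config$smc_amplitude, seed = seed + 1)
    d <- dim(smc_map$rates)
    smc_flat <- matrix(smc_map$rates, d[1] * d[2], d[3])
  }
  layout <- population_layout(n_gc = n_gc, n_smc = n_smc, n_dir = config$n_dir,
                              n_spd = config$n_spd, n_hidden = n_hidden)
  sm <- self_motion_spec(config$n_dir, config$dir_tuning_width, config$n_spd)
  list(config = config, variant = variant, layout = layout,
       modules = lapply(gm, `[[`, "module"),
       gc_maps = lapply(gm, `[[`, "ratemap"),
       gc_flat = gc_flat, smc_map = smc_map, smc_flat = smc_flat,
       self_motion = sm, pref_dirs = sm$preferred_dirs,
       spd_gains = sm$speed_gains,
       n_gc = n_gc, n_smc = n_smc, n_dir = config$n_dir,
       n_spd = config$n_spd, n_hidden = n_hidden)
}

#' Fit the recurrent network
#'
#' Trains the extended RNN by backpropagation through time with Adam, on
#' freshly simulated trajectories each gradient step. Variant `"gc_only"`
#' contains grid, speed, and head-direction cells and learns pure path
#' integration; `"hcmec"` adds SMC units (supervised to autoencode masked
#' sensory inputs) and unsupervised hidden units, the candidate place cells,
#' with masking applied to inputs and initial states.
#'
#' @param config A [gridnet_config()].
#' @param variant `"gc_only"` or `"hcmec"`.
#' @param seed Integer seed; fixes maps, weights, trajectories and masks.
#' @param verbose Print loss every 100 steps.
#' @return Object of class `"gridnet"`: the fitted parameters, ground-truth
#'   maps, layout, config and loss trace.
#' @examples
#' \donttest{
#' cfg <- gridnet_config(n_gc_per_module = 16, n_dir = 12, n_spd = 6,
#'                       n_steps = 50, batch_size = 4)
#' fit <- fit_gridnet(cfg, "gc_only", seed = 1)
#' print(fit)
#' }
#' @export
fit_gridnet <- function(config = gridnet_config(),
                        variant = c("gc_only", "hcmec"),
                        seed = 1, verbose = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "gridnet_config"))
  env <- build_fit_env(config, variant, seed)
  params <- rnn_params_init(env$layout, seed = seed + 2,
                            init_scale = config$init_scale,
                            alpha_init = config$alpha_init,
                            nonlinearity = config$nonlinearity)
  W <- params$W; beta <- params$beta
  opt <- adam_new(list(W = W, beta = beta), config$learning_rate)
  phases <- curriculum_phases(config)
  trace <- list()
  step <- 0
  for (ph in seq_len(nrow(phases))) {
    opt$lr <- phases$lr[ph]
    env$config$r_mask <- phases$r_mask[ph]
    for (i in seq_len(phases$n[ph])) {
      step <- step + 1
      batch <- make_training_batch(env, phases$batch[ph],
                                   duration = phases$duration[ph])
      g <- bptt_step(W, beta, env, batch)
      upd <- adam_update(opt, list(W = W, beta = beta),
                         list(W = g$dW, beta = g$dbeta))
      opt <- upd$opt; W <- upd$params$W; beta <- upd$params$beta
      if (step %% config$loss_every == 0 || step == 1) {
        trace[[length(trace) + 1]] <-
          data.frame(step = step, duration = phases$duration[ph],
                     loss = g$loss_gc + g$loss_smc,
                     loss_gc = g$loss_gc, loss_smc = g$loss_smc)
        if (verbose && (step %% 100 == 0 || step == 1))
          message(sprintf("step %5d  loss %.5f (gc %.5f, smc %.5f)",
                          step, g$loss_gc + g$loss_smc, g$loss_gc, g$loss_smc))
      }
    }
  }
  params$W <- W; params$beta <- beta
  structure(list(params = params, layout = env$layout, config = config,
                 variant = variant, seed = seed,
                 modules = env$modules, gc_maps = env$gc_maps,
                 gc_flat = env$gc_flat, smc_map = env$smc_map,
                 smc_flat = env$smc_flat, self_motion = env$self_motion,
                 loss_trace = do.call(rbind, trace), env = env),
            class = "gridnet")
}

## Roll the fitted network over given trajectories (no masking, optional
## noise), returning the state array and the trajectory bin indices.
gridnet_rollout <- function(object, duration, n = 1, seed = NULL,
                            noise = FALSE, r_mask = 0) {
  env <- object$env
  env$config$noise_sigma <- if (noise) object$config$noise_sigma else 0
  env$config$r_mask <- r_mask
  if (!is.null(seed)) set.seed(as.integer(seed))
  batch <- make_training_batch(env, n, duration = duration,
                               mask = r_mask > 0)
  lay <- object$layout
  if (identical(object$params$nonlinearity, "relu")) {
    S <- .rollout_core(object$params$W, object$params$beta, batch$U,
                       batch$z0, lay$input_idx)
    return(list(states = S, batch = batch))
  }
  nl <- rnn_nonlinearity(object$params$nonlinearity)
  a <- sigmoid(object$params$beta)
  W <- object$params$W
  Tn <- batch$Tn
  S <- array(0, c(lay$d, n, Tn))
  Z <- batch$z0
  S[, , 1] <- Z
  for (t in seq_len(Tn - 1)) {
    M <- W %*% nl$f(Z)
    M[lay$input_idx, ] <- M[lay$input_idx, ] + batch$U[, , t]
    Z <- a * Z + (1 - a) * M
    S[, , t + 1] <- Z
  }
  list(states = S, batch = batch)
}
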