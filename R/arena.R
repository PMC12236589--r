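#' Define a rectangular arena
#'
#' An arena is the rectangular environment `[0, width) x [0, height)` (cm,
#' origin at the lower-left corner) in which trajectories are simulated and
#' over which ratemaps are binned. Bins are half-open squares of side
#' `bin_size`.
#'
#' @param width,height Arena extent in cm.
#' @param bin_size Ratemap bin side in cm.
#' @return An object of class `"arena"`: a list with fields `width`, `height`,
#'   `bin_size`, and the derived bin counts `nx`, `ny`.
#' @examples
#' a <- arena(150, 150, bin_size = 2)
#' a$nx # 75
#' @export
arena <- function(width = 150, height = 150, bin_size = 2) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(bin_size),
            width > 0, height > 0, bin_size > 0)
  nx <- floor(width / bin_size)
  ny <- floor(height / bin_size)
  if (nx < 4 || ny < 4)
    stop("arena must span at least 4 bins in each axis", call. = FALSE)
  structure(list(width = width, height = height, bin_size = bin_size,
                 nx = nx, ny = ny),
            class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("Arena: %.1f x %.1f cm, %d x %d bins of %.1f cm\n",
              x$width, x$height, x$nx, x$ny, x$bin_size))
  invisible(x)
}

#' Random-foraging motion parameters
#'
#' Parameters of the stochastic motion model used by [simulate_trajectory()].
#' Heading follows a wrapped first-order autoregressive walk whose per-step
#' turn standard deviation is `(1 - heading_persistence) * pi` radians; speed
#' is drawn per step from a Rayleigh distribution with mean `mean_speed`,
#' interpolated towards the constant `mean_speed` as `speed_scale` goes to 0.
#' Walls reflect.
#'
#' @param dt Timestep in seconds.
#' @param mean_speed Mean running speed, cm/s.
#' @param speed_scale Dimensionless spread factor in `[0, 1]`: 1 gives the full
#'   Rayleigh speed distribution, 0 a constant speed.
#' @param heading_persistence In `[0, 1)`: 0 is uncorrelated headings, values
#'   near 1 give smooth, persistent runs.
#' @param pause_prob Per-step probability of entering a pause (speed 0,
#'   heading held), as in natural foraging, which alternates runs and stops;
#'   0 disables pausing.
#' @param unpause_prob Per-step probability of leaving a pause; the mean
#'   pause length is `dt / unpause_prob`.
#' @return An object of class `"motion_params"`.
#' @export
motion_params <- function(dt = 0.05, mean_speed = 15, speed_scale = 1,
                          heading_persistence = 0.9,
                          pause_prob = 0.03, unpause_prob = 0.1) {
  stopifnot(dt > 0, mean_speed >= 0, speed_scale >= 0, speed_scale <= 1,
            heading_persistence >= 0, heading_persistence < 1,
            pause_prob >= 0, pause_prob < 1,
            unpause_prob > 0, unpause_prob <= 1)
  structure(list(dt = dt, mean_speed = mean_speed, speed_scale = speed_scale,
                 heading_persistence = heading_persistence,
                 pause_prob = pause_prob, unpause_prob = unpause_prob,
                 boundary_mode = "reflect"),
            class = "motion_params")
}

wrap_angle <- function(theta) theta %% (2 * pi)

## Reflect proposed positions into [0, extent); returns list(pos, flipped).
## A single reflection suffices when step length < extent, which motion_params
## guarantees for any sane configuration; loop for safety.
reflect_axis <- function(p, extent) {
  flipped <- rep(FALSE, length(p))
  for (i in 1:100) {
    below <- p < 0
    above <- p >= extent
    if (!any(below) && !any(above)) break
    p[below] <- -p[below]
    ## reflect about the wall, keeping strictly inside the half-open interval
    p[above] <- 2 * extent - p[above] - 1e-9
    flipped <- xor(flipped, below | above)
  }
  list(p = p, flipped = flipped)
}

#' Simulate random-foraging trajectories
#'
#' Generates one or more random-walk trajectories in a rectangular arena with
#' reflective walls, at a fixed timestep. Used both to train the recurrent
#' network (short 5 s trials) and to probe it (longer held-out trials).
#'
#' @param arena An [arena()].
#' @param params A [motion_params()].
#' @param duration Trajectory duration in seconds; must be at least `2 * dt`.
#' @param n Number of independent trajectories.
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @param start Optional n x 2 matrix (or length-2 vector) of start positions;
#'   default uniform in the arena interior.
#' @return For `n = 1` an object of class `"trajectory"`: list with
#'   `positions` (T x 2 cm), `headings` (T, radians in `[0, 2pi)`), `speeds`
#'   (T, cm/s) and `dt`. For `n > 1` a list of such objects.
#'   `positions[t + 1, ] - positions[t, ]` has length `speeds[t] * dt` up to
#'   boundary reflection; `headings[t]`/`speeds[t]` are the motion command
#'   applied between samples `t` and `t + 1`.
#' @examples
#' tr <- simulate_trajectory(arena(), motion_params(), duration = 5, seed = 1)
#' nrow(tr$positions) # 100
#' @export
simulate_trajectory <- function(arena, params = motion_params(), duration = 5,
                                n = 1, seed = NULL, start = NULL) {
  b <- traj_batch(arena, params, duration, n, seed, start)
  out <- lapply(seq_len(n), function(i) {
    structure(list(positions = cbind(x = b$px[, i], y = b$py[, i]),
                   headings = b$hd[, i], speeds = b$sp[, i], dt = params$dt),
              class = "trajectory")
  })
  if (n == 1L) out[[1L]] else out
}

## Batched trajectory core: returns T x n matrices px, py, hd, sp.
traj_batch <- function(arena, params, duration, n, seed = NULL, start = NULL) {
  stopifnot(inherits(arena, "arena"), inherits(params, "motion_params"))
  if (duration < 2 * params$dt)
    stop("duration must be at least 2 * dt", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nt <- ceiling(duration / params$dt)
  if (is.null(start)) {
    start <- cbind(stats::runif(n, 0.05, 0.95) * arena$width,
                   stats::runif(n, 0.05, 0.95) * arena$height)
  } else {
    start <- matrix(start, ncol = 2)
    if (nrow(start) == 1L && n > 1L) start <- start[rep(1L, n), , drop = FALSE]
  }
  dt <- params$dt
  turn_sd <- (1 - params$heading_persistence) * pi
  ray_scale <- params$mean_speed / sqrt(pi / 2) # Rayleigh scale with mean mean_speed

  px <- matrix(0, nt, n); py <- matrix(0, nt, n)
  hd <- matrix(0, nt, n); sp <- matrix(0, nt, n)
  px[1, ] <- start[, 1]; py[1, ] <- start[, 2]
  theta <- stats::runif(n, 0, 2 * pi)
  hd[1, ] <- theta
  paused <- rep(FALSE, n)
  for (t in seq_len(nt)) {
    ## two-state run/pause process: foraging alternates runs and stops
    paused <- ifelse(paused,
                     stats::runif(n) > params$unpause_prob,
                     stats::runif(n) < params$pause_prob)
    raw <- ray_scale * sqrt(-2 * log(stats::runif(n))) # Rayleigh draw
    s <- pmax(0, params$mean_speed + params$speed_scale * (raw - params$mean_speed))
    s[paused] <- 0
    sp[t, ] <- s
    hd[t, ] <- theta
    if (t < nt) {
      qx <- px[t, ] + s * cos(theta) * dt
      qy <- py[t, ] + s * sin(theta) * dt
      rx <- reflect_axis(qx, arena$width)
      ry <- reflect_axis(qy, arena$height)
      px[t + 1, ] <- rx$p; py[t + 1, ] <- ry$p
      ## record the motion actually realized (reflections mirror the step),
      ## so self-motion inputs are always consistent with the displacement
      dx <- px[t + 1, ] - px[t, ]; dy <- py[t + 1, ] - py[t, ]
      d <- sqrt(dx^2 + dy^2)
      sp[t, ] <- d / dt
      hd[t, ] <- ifelse(d > 0, wrap_angle(atan2(dy, dx)), theta)
      ## mirror the heading off any wall that was hit
      theta <- ifelse(rx$flipped, pi - theta, theta)
      theta <- ifelse(ry$flipped, -theta, theta)
      theta <- wrap_angle(theta + stats::rnorm(n, 0, turn_sd))
    }
  }
  list(px = px, py = py, hd = hd, sp = sp)
}

#' @export
print.trajectory <- function(x, ...) {
  nt <- nrow(x$positions)
  cat(sprintf("Trajectory: %d samples at dt = %.3f s (%.1f s), mean speed %.1f cm/s\n",
              nt, x$dt, nt * x$dt, mean(x$speeds)))
  invisible(x)
}

#' Self-motion population code specification
#'
#' Head-direction cells have preferred allocentric directions uniformly spaced
#' on `[0, 2pi)` and circular tuning `exp((cos(theta - theta_pref) - 1) / w^2)`
#' (strictly positive, peak 1, population activity on a 1-D ring). Speed cells
#' respond linearly, `gain * speed`, with positive per-cell gains.
#'
#' @param n_dir_cells,n_speed_cells Population sizes.
#' @param dir_tuning_width Tuning width `w` in radians.
#' @param speed_gains Positive gains, recycled to `n_speed_cells`. The default
#'   spreads gains so that typical foraging speeds map to order-1 responses.
#' @return An object of class `"self_motion_spec"`.
#' @export
self_motion_spec <- function(n_dir_cells = 32, dir_tuning_width = 0.5,
                             n_speed_cells = 16,
                             speed_gains = seq(0.02, 0.08, length.out = n_speed_cells)) {
  stopifnot(n_dir_cells >= 1, n_speed_cells >= 1, dir_tuning_width > 0,
            all(speed_gains > 0))
  structure(list(n_dir_cells = as.integer(n_dir_cells),
                 dir_tuning_width = dir_tuning_width,
                 n_speed_cells = as.integer(n_speed_cells),
                 speed_gains = rep_len(speed_gains, n_speed_cells),
                 preferred_dirs = 2 * pi * (seq_len(n_dir_cells) - 1) / n_dir_cells),
            class = "self_motion_spec")
}

#' Encode a trajectory as self-motion cell responses
#'
#' @param traj A [simulate_trajectory()] result.
#' @param spec A [self_motion_spec()].
#' @return Non-negative matrix, timesteps x (n_dir_cells + n_speed_cells);
#'   direction cells first.
#' @export
encode_self_motion <- function(traj, spec = self_motion_spec()) {
  stopifnot(inherits(spec, "self_motion_spec"))
  w2 <- spec$dir_tuning_width^2
  dir_block <- exp((cos(outer(traj$headings, spec$preferred_dirs, "-")) - 1) / w2)
  spd_block <- outer(traj$speeds, spec$speed_gains)
  cbind(dir_block, spd_block)
}
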