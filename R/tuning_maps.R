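#' Multi-scale grid-module hierarchy
#'
#' Spatial periods follow a geometric stack `l_i = l0 * s^i`, `i = 1..m`, so
#' the smallest module has period `l0 * s`. Defaults follow the reference
#' configuration: six modules, smallest spacing 30 cm, scale factor
#' `sqrt(e)` in 2-D (`e` is the 1-D optimum).
#'
#' @param smallest_period Period of module 1 in cm (spacing between
#'   neighbouring firing-field centers).
#' @param scale_factor Ratio `s > 1` between successive periods.
#' @param n_modules Number of modules `m`.
#' @param spacing_field_ratio Grid spacing divided by field diameter; fields
#'   are Gaussian blobs whose radius is two standard deviations, so
#'   `sigma_i = l_i / (4 * spacing_field_ratio)`.
#' @return Object of class `"phase_hierarchy"` with `periods`, `sigmas`,
#'   `base_period` (`l0`), `scale_factor`, `n_modules`.
#' @examples
#' h <- phase_hierarchy()
#' h$periods[1] # 30
#' @export
phase_hierarchy <- function(smallest_period = 30, scale_factor = sqrt(exp(1)),
                            n_modules = 6, spacing_field_ratio = 3.26) {
  stopifnot(smallest_period > 0, scale_factor > 1, n_modules >= 1,
            spacing_field_ratio > 0)
  periods <- smallest_period * scale_factor^(seq_len(n_modules) - 1)
  structure(list(base_period = smallest_period / scale_factor,
                 scale_factor = scale_factor,
                 n_modules = as.integer(n_modules),
                 periods = periods,
                 spacing_field_ratio = spacing_field_ratio,
                 sigmas = periods / (4 * spacing_field_ratio)),
            class = "phase_hierarchy")
}

#' @export
print.phase_hierarchy <- function(x, ...) {
  cat(sprintf("Grid hierarchy: %d modules, periods %s cm (s = %.3f)\n",
              x$n_modules, paste(round(x$periods, 1), collapse = ", "),
              x$scale_factor))
  invisible(x)
}

#' Geometry of a single grid module
#'
#' The triangular lattice of field centers is spanned by the basis columns
#' `l * (1, 0)` and `l * (1/2, sqrt(3)/2)`, rotated by `orientation`. Each
#' cell is a copy of the lattice translated by its phase offset (a point in
#' the unit cell, expressed in lattice coordinates in `[0, 1)^2`).
#'
#' @param period Lattice constant `l` in cm.
#' @param orientation Rotation of the lattice, radians.
#' @param sigma Gaussian field standard deviation in cm; field radius is
#'   `2 * sigma`.
#' @param phase_offsets n x 2 matrix of per-cell phase offsets in `[0, 1)^2`.
#' @return Object of class `"grid_module"` with the 2 x 2 `basis` matrix.
#' @export
grid_module <- function(period, orientation = 0, sigma = period / (4 * 3.26),
                        phase_offsets = matrix(0, 1, 2)) {
  stopifnot(period > 0, sigma > 0)
  phase_offsets <- matrix(phase_offsets, ncol = 2)
  R <- matrix(c(cos(orientation), sin(orientation),
                -sin(orientation), cos(orientation)), 2, 2)
  basis <- R %*% (period * cbind(c(1, 0), c(0.5, sqrt(3) / 2)))
  structure(list(period = period, orientation = orientation, sigma = sigma,
                 phase_offsets = phase_offsets, basis = basis,
                 n_cells = nrow(phase_offsets)),
            class = "grid_module")
}

## Gaussian-blob grid rates at arbitrary positions (npos x 2), one column per
## cell. Sums blobs at the 3x3 nearest lattice translates, which is exact to
## double precision for sigma << period (here sigma ~ period / 13).
grid_rates <- function(positions, module) {
  positions <- matrix(positions, ncol = 2)
  inv_b <- solve(module$basis)
  lat <- positions %*% t(inv_b) # lattice coordinates, npos x 2
  npos <- nrow(positions)
  off <- as.matrix(expand.grid(-1:1, -1:1))
  out <- matrix(0, npos, module$n_cells)
  two_sig2 <- 2 * module$sigma^2
  for (j in seq_len(module$n_cells)) {
    cj <- lat - matrix(module$phase_offsets[j, ], npos, 2, byrow = TRUE)
    base <- round(cj)
    r <- numeric(npos)
    for (k in seq_len(nrow(off))) {
      frac <- cj - base - matrix(off[k, ], npos, 2, byrow = TRUE)
      cart <- frac %*% t(module$basis)
      r <- r + exp(-(cart[, 1]^2 + cart[, 2]^2) / two_sig2)
    }
    out[, j] <- r
  }
  out
}

bin_centers <- function(arena) {
  list(x = (seq_len(arena$nx) - 0.5) * arena$bin_size,
       y = (seq_len(arena$ny) - 0.5) * arena$bin_size)
}

## All bin-center positions as an (nx*ny) x 2 matrix, x index fastest.
bin_center_grid <- function(arena) {
  bc <- bin_centers(arena)
  cbind(rep(bc$x, times = arena$ny), rep(bc$y, each = arena$nx))
}

new_ratemap <- function(rates, arena, tag) {
  stopifnot(all(is.finite(rates)), all(rates >= 0))
  structure(list(rates = rates, arena = arena, population_tag = tag),
            class = "ratemap")
}

#' @export
print.ratemap <- function(x, ...) {
  cat(sprintf("Ratemap [%s]: %d x %d bins x %d cells, peak %.3f\n",
              x$population_tag, dim(x$rates)[1], dim(x$rates)[2],
              dim(x$rates)[3], max(x$rates)))
  invisible(x)
}

#' Generate ground-truth grid-module ratemaps
#'
#' Each cell's map is a sum of Gaussian blobs (sd `sigma_i`) centered on the
#' module's triangular lattice translated by the cell's phase offset, peak
#' normalized to 1. Phase offsets are drawn uniformly over the unit cell;
#' the first cell of each module sits at phase (0, 0) so that a field center
#' lies exactly on the lattice origin.
#'
#' @param hierarchy A [phase_hierarchy()].
#' @param n_cells_per_module Cells per module (>= 1).
#' @param arena An [arena()].
#' @param seed Integer seed for the phase offsets.
#' @param orientations Per-module lattice orientations (radians); default 0.
#' @return List with one element per module: `list(module = grid_module,
#'   ratemap = ratemap)`.
#' @export
make_grid_modules <- function(hierarchy, n_cells_per_module, arena,
                              seed = NULL,
                              orientations = rep(0, hierarchy$n_modules)) {
  stopifnot(inherits(hierarchy, "phase_hierarchy"), n_cells_per_module >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (arena$width < hierarchy$periods[1] || arena$height < hierarchy$periods[1])
    warning("arena smaller than the smallest grid period; fields may not repeat")
  pos <- bin_center_grid(arena)
  lapply(seq_len(hierarchy$n_modules), function(i) {
    offs <- matrix(stats::runif(2 * n_cells_per_module), ncol = 2)
    offs[1, ] <- 0
    mod <- grid_module(period = hierarchy$periods[i],
                       orientation = orientations[i],
                       sigma = hierarchy$sigmas[i],
                       phase_offsets = offs)
    r <- grid_rates(pos, mod)
    r <- sweep(r, 2, apply(r, 2, max), "/") # peak-normalize each cell
    rates <- array(r, dim = c(arena$nx, arena$ny, mod$n_cells))
    list(module = mod, ratemap = new_ratemap(rates, arena, "GC"))
  })
}

## Row-normalized 1-D Gaussian smoothing matrix for n bins of width h.
gauss_smooth_matrix <- function(n, sigma_bins) {
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma_bins^2))
  K / rowSums(K)
}

#' Generate a synthetic spatially-modulated-cell (SMC) ratemap
#'
#' A stand-in for sensory tuning: per-cell smoothed spatial white noise
#' (Gaussian blur with kernel sd `correlation_length / 1.665`, placing the
#' half-correlation point of the autocovariance at roughly the correlation
#' length), rectified at zero and scaled to a fixed peak amplitude. This map
#' is synthetic; it emulates spatially informative sensory embeddings, not
#' any measured sensory data.
#'
#' @param n_cells Number of SMC units.
#' @param arena An [arena()].
#' @param correlation_length Spatial autocorrelation scale in cm.
#' @param amplitude Peak rate after scaling.
#' @param seed Integer seed.
#' @return A `"ratemap"` with tag `"SMC"`.
#' @export
make_smc_map <- function(n_cells, arena, correlation_length = 30,
                         amplitude = 1, seed = NULL) {
  stopifnot(n_cells >= 1, correlation_length > 0, amplitude > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sig_bins <- correlation_length / 1.665 / arena$bin_size
  Kx <- gauss_smooth_matrix(arena$nx, sig_bins)
  Ky <- gauss_smooth_matrix(arena$ny, sig_bins)
  rates <- array(0, dim = c(arena$nx, arena$ny, n_cells))
  for (j in seq_len(n_cells)) {
    z <- matrix(stats::rnorm(arena$nx * arena$ny), arena$nx, arena$ny)
    sm <- Kx %*% z %*% t(Ky)
    sm <- pmax(sm, 0)
    pk <- max(sm)
    if (pk > 0) sm <- sm * (amplitude / pk)
    rates[, , j] <- sm
  }
  new_ratemap(rates, arena, "SMC")
}

#' Map positions to ratemap bin indices
#'
#' @param positions n x 2 matrix of positions (cm).
#' @param arena An [arena()].
#' @return Integer vector of flattened bin indices (x index fastest).
#' @export
position_to_bin <- function(positions, arena) {
  positions <- matrix(positions, ncol = 2)
  if (any(positions[, 1] < 0) || any(positions[, 2] < 0) ||
      any(positions[, 1] >= arena$width) || any(positions[, 2] >= arena$height))
    stop("position outside arena", call. = FALSE)
  ix <- pmin(floor(positions[, 1] / arena$bin_size), arena$nx - 1)
  iy <- pmin(floor(positions[, 2] / arena$bin_size), arena$ny - 1)
  as.integer(ix + iy * arena$nx + 1)
}

#' Center coordinates of flattened bin indices
#' @param bins Integer vector of flattened bin indices.
#' @param arena An [arena()].
#' @return n x 2 matrix of bin-center positions (cm).
#' @export
bin_to_position <- function(bins, arena) {
  ix <- (bins - 1) %% arena$nx
  iy <- (bins - 1) %/% arena$nx
  cbind(x = (ix + 0.5) * arena$bin_size, y = (iy + 0.5) * arena$bin_size)
}

#' Sample ground-truth responses along a trajectory
#'
#' Nearest-bin lookup: each timestep's response is the rate vector of the bin
#' containing the position.
#'
#' @param map A `"ratemap"`.
#' @param traj A `"trajectory"` (or an n x 2 position matrix).
#' @return Matrix, timesteps x n_cells.
#' @export
sample_responses <- function(map, traj) {
  stopifnot(inherits(map, "ratemap"))
  positions <- if (inherits(traj, "trajectory")) traj$positions else traj
  bins <- position_to_bin(positions, map$arena)
  d <- dim(map$rates)
  flat <- matrix(map$rates, d[1] * d[2], d[3])
  flat[bins, , drop = FALSE]
}

#' Apply the random masking protocol
#'
#' For each trajectory (matrix) an effective masking fraction
#' `f ~ Uniform(0, r_mask)` is drawn, then independent Bernoulli(`f`) entries
#' over time x cells are set to zero. New masks are drawn on every call, so
#' masks vary across trajectories, time and cells.
#'
#' @param batch Numeric matrix (timesteps x cells), or a list of them (one
#'   effective fraction per element).
#' @param r_mask Maximum masking fraction in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return List with `masked` (same shape, masked entries exactly 0) and
#'   `mask` (logical, TRUE where zeroed).
#' @export
apply_mask <- function(batch, r_mask, seed = NULL) {
  stopifnot(r_mask >= 0, r_mask <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mask_one <- function(m) {
    f <- stats::runif(1, 0, r_mask)
    mk <- matrix(stats::runif(length(m)) < f, nrow(m), ncol(m))
    m[mk] <- 0
    list(masked = m, mask = mk)
  }
  if (is.list(batch)) {
    out <- lapply(batch, mask_one)
    list(masked = lapply(out, `[[`, "masked"), mask = lapply(out, `[[`, "mask"))
  } else mask_one(batch)
}

#' Detect firing-field centers in a single-cell map
#'
#' Local maxima above half the map peak, with a minimum separation of
#' `2 * sigma` (taller fields suppress smaller neighbours). Centers are
#' refined to the rate-weighted centroid of the bins within `sigma`.
#'
#' @param cell_map nx x ny matrix of rates.
#' @param arena An [arena()].
#' @param sigma Field standard deviation used for the separation radius (cm).
#' @return n x 2 matrix of field-center coordinates (cm).
#' @export
detect_field_centers <- function(cell_map, arena, sigma) {
  nx <- nrow(cell_map); ny <- ncol(cell_map)
  thr <- 0.5 * max(cell_map)
  ## 3x3-neighbourhood local maxima above threshold
  pad <- matrix(-Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- cell_map
  is_max <- cell_map >= thr
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    is_max <- is_max & (cell_map >= pad[2:(nx + 1) + dx, 2:(ny + 1) + dy])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 2))
  heights <- cell_map[idx]
  ord <- order(heights, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  cx <- (idx[, 1] - 0.5) * arena$bin_size
  cy <- (idx[, 2] - 0.5) * arena$bin_size
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    ok <- TRUE
    if (any(keep)) {
      dmin <- min(sqrt((cx[keep] - cx[i])^2 + (cy[keep] - cy[i])^2))
      ok <- dmin >= 2 * sigma
    }
    keep[i] <- ok
  }
  idx <- idx[keep, , drop = FALSE]
  h <- arena$bin_size
  ## sub-bin refinement: 1-D parabolic interpolation of log-rate about the
  ## peak bin per axis (exact for Gaussian fields); skip bins on the border
  refine <- function(i, j) {
    cx <- (i - 0.5) * h; cy <- (j - 0.5) * h
    if (i > 1 && i < nx && all(cell_map[(i - 1):(i + 1), j] > 0)) {
      lx <- log(cell_map[(i - 1):(i + 1), j])
      den <- lx[1] - 2 * lx[2] + lx[3]
      if (den < 0) cx <- cx + h * (lx[1] - lx[3]) / (2 * den)
    }
    if (j > 1 && j < ny && all(cell_map[i, (j - 1):(j + 1)] > 0)) {
      ly <- log(cell_map[i, (j - 1):(j + 1)])
      den <- ly[1] - 2 * ly[2] + ly[3]
      if (den < 0) cy <- cy + h * (ly[1] - ly[3]) / (2 * den)
    }
    c(cx, cy)
  }
  t(apply(idx, 1, function(r) refine(r[1], r[2])))
}

#' Measure grid spacing and field size from a ratemap
#'
#' Spacing is the median nearest-neighbour distance between detected field
#' centers. Field size is the diameter at two standard deviations of a
#' Gaussian fitted to each field (log-rate regressed on squared distance over
#' bins above 20% of the field peak), averaged over fields.
#'
#' @param cell_map nx x ny matrix of rates for one cell.
#' @param arena An [arena()].
#' @param sigma Nominal field sd (cm), used only for detection radii.
#' @return List with `spacing`, `field_size` (both cm), `ratio`
#'   (= spacing / field_size), `centers`, and the per-field `sigma_fit`.
#' @export
measure_grid_geometry <- function(cell_map, arena, sigma) {
  centers <- detect_field_centers(cell_map, arena, sigma)
  ## fields truncated by the arena border are unreliable: keep interior ones
  margin <- 2 * sigma
  interior <- centers[, 1] >= margin & centers[, 1] <= arena$width - margin &
    centers[, 2] >= margin & centers[, 2] <= arena$height - margin
  centers <- centers[interior, , drop = FALSE]
  if (nrow(centers) < 2)
    stop("need at least two interior fields to measure spacing", call. = FALSE)
  D <- as.matrix(stats::dist(centers))
  diag(D) <- Inf
  spacing <- stats::median(apply(D, 1, min))
  bc <- bin_centers(arena)
  sig_fits <- numeric(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    wx <- which(abs(bc$x - centers[i, 1]) <= spacing / 2.5)
    wy <- which(abs(bc$y - centers[i, 2]) <= spacing / 2.5)
    sub <- cell_map[wx, wy, drop = FALSE]
    pk <- max(sub)
    r2 <- outer((bc$x[wx] - centers[i, 1])^2, (bc$y[wy] - centers[i, 2])^2, "+")
    sel <- sub > 0.2 * pk
    ## log rate = log A - r^2 / (2 sigma^2): slope of log-rate on r^2
    fit <- stats::lm.fit(cbind(1, r2[sel]), log(sub[sel]))
    sig_fits[i] <- sqrt(-1 / (2 * fit$coefficients[2]))
  }
  field_size <- mean(4 * sig_fits) # diameter at two standard deviations
  list(spacing = spacing, field_size = field_size,
       ratio = spacing / field_size, centers = centers, sigma_fit = sig_fits)
}
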