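#' Toroidal phase of a position in a grid module
#'
#' A grid module's population activity is summarized by a phase on the
#' n-torus: `phi = 2 * pi * frac(B^-1 p)`, where `B` is the module's lattice
#' basis. In 1-D, `B` is the scalar period.
#'
#' @param pos Position: length-n vector, or an m x n matrix of positions.
#' @param basis n x n lattice basis (columns are lattice vectors, cm), or a
#'   `"grid_module"` object, or a scalar period for 1-D.
#' @return Phase vector in `[0, 2pi)^n` (or m x n matrix).
#' @export
phase_of_position <- function(pos, basis) {
  B <- as_basis(basis)
  if (abs(det(B)) < .Machine$double.eps * 10)
    stop("singular lattice basis", call. = FALSE)
  p <- matrix(pos, ncol = ncol(B))
  phi <- (2 * pi * (p %*% t(solve(B)))) %% (2 * pi)
  if (is.matrix(pos)) phi else drop(phi)
}

as_basis <- function(basis) {
  if (inherits(basis, "grid_module")) return(basis$basis)
  if (length(basis) == 1L) return(matrix(basis, 1, 1))
  stopifnot(is.matrix(basis), nrow(basis) == ncol(basis))
  basis
}

#' Shortest-wrap phase difference
#'
#' Wraps `phi_t - phi_c` per component into `(-pi, pi]`, the unique wrapped
#' difference of minimum norm (the antipodal tie `+-pi` resolves to `+pi`,
#' i.e. the positive lattice direction).
#'
#' @param phi_c,phi_t Current and target phases (radians, same length).
#' @return Wrapped difference in `(-pi, pi]^n`.
#' @export
wrap_phase_difference <- function(phi_c, phi_t) {
  d <- (phi_t - phi_c) %% (2 * pi) # in [0, 2pi)
  ifelse(d > pi, d - 2 * pi, d)    # (-pi, pi]
}

#' Decode physical displacement from a single module's phases
#'
#' Selects the wrapped phase difference of minimal norm and converts it to a
#' Cartesian displacement through the lattice basis:
#' `d = B %*% (dphi / (2 pi))`. Each component of the decoded displacement is
#' at most half the period along its lattice axis.
#'
#' @param phi_c,phi_t Current and target phases.
#' @param basis Lattice basis (see [phase_of_position()]).
#' @return Displacement vector (cm), length n.
#' @export
decode_module_displacement <- function(phi_c, phi_t, basis) {
  B <- as_basis(basis)
  dphi <- wrap_phase_difference(phi_c, phi_t)
  drop(B %*% (dphi / (2 * pi)))
}

#' Combine decoded displacements across grid scales
#'
#' Decodes the wrapped phase difference within each module first, then
#' averages the per-module Cartesian displacements:
#' `d_hat = (1/m) * sum_i B_i dphi_i / (2 pi)`. Modules whose half-period
#' exceeds the true displacement ("decodable" scales) contribute the exact
#' displacement; undercovered scales contribute wrapped, possibly
#' wrong-signed terms, but under the contraction condition (see
#' [contraction_margin()]) the average still moves the agent strictly closer
#' to the target.
#'
#' @param phis_c,phis_t Lists of current/target phases, one per module,
#'   ordered by increasing period.
#' @param bases List of lattice bases (or `"grid_module"`s), same length.
#' @return Averaged displacement estimate (cm).
#' @export
combine_multiscale <- function(phis_c, phis_t, bases) {
  m <- length(bases)
  if (length(phis_c) != m || length(phis_t) != m)
    stop("one phase pair per module is required", call. = FALSE)
  d <- 0
  for (i in seq_len(m))
    d <- d + decode_module_displacement(phis_c[[i]], phis_t[[i]], bases[[i]])
  d / m
}

#' Contraction margin of the multi-scale average
#'
#' For geometric scale stacks `l_i = l0 * s^i` with `k` undercovered scales,
#' averaging per-module decoded displacements is guaranteed to reduce the
#' remaining 1-D distance whenever `m > k + (1 - s^-k) / (s - 1)`; this
#' function returns the margin term `(1 - s^-k) / (s - 1)`. For `s = e` the
#' margin is below 1 for every `k`, so `m > k` suffices in 1-D; in 2-D with
#' `s = sqrt(e)` the condition tightens to `m > k + 1`. (The inequality as
#' printed in the source text is typographically garbled; this is the
#' reconstruction consistent with both corollaries.)
#'
#' @param s Scale factor, `s > 1`.
#' @param k Number of undercovered scales, `k >= 0`.
#' @return The margin `(1 - s^-k) / (s - 1)`.
#' @examples
#' contraction_margin(exp(1), 1) # 1/e
#' @export
contraction_margin <- function(s, k) {
  if (s <= 1) stop("scale factor must exceed 1", call. = FALSE)
  stopifnot(k >= 0)
  (1 - s^(-k)) / (s - 1)
}

## --- Markov sequential planning on a discretized phase torus ---------------

torus_neighbours <- function(n_bins, dims) {
  if (dims == 1L) {
    lapply(seq_len(n_bins), function(i) {
      ## positive direction first: deterministic tie-break
      c((i %% n_bins) + 1L, ((i - 2L) %% n_bins) + 1L)
    })
  } else {
    ## product binning, x index fastest; 8-neighbour torus adjacency with a
    ## fixed preference order starting at +x and proceeding counter-clockwise
    steps <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L),
                  c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))
    lapply(seq_len(n_bins^2), function(i) {
      ix <- (i - 1L) %% n_bins; iy <- (i - 1L) %/% n_bins
      vapply(steps, function(s) {
        jx <- (ix + s[1]) %% n_bins; jy <- (iy + s[2]) %% n_bins
        as.integer(jx + jy * n_bins + 1)
      }, integer(1))
    })
  }
}

#' Build a phase transition matrix
#'
#' Either the ideal local topology (uniform over self plus torus neighbours)
#' or an empirical matrix from binned phase sequences with add-one smoothing
#' over torus-adjacent bins.
#'
#' @param n_bins Bins per torus dimension (>= 3).
#' @param dims 1 or 2.
#' @param phase_sequences Optional list of phase sequences (vectors of
#'   radians for `dims = 1`, T x 2 matrices for `dims = 2`); omitted means
#'   the ideal topology.
#' @return Object of class `"transition_model"`: `n_bins`, `dims`, the
#'   row-stochastic matrix `T` over the `n_bins^dims` product bins, and the
#'   neighbour lists.
#' @export
build_transition_matrix <- function(n_bins, dims = 1, phase_sequences = NULL) {
  stopifnot(n_bins >= 3, dims %in% c(1, 2))
  n_states <- n_bins^dims
  nb <- torus_neighbours(n_bins, dims)
  Tm <- matrix(0, n_states, n_states)
  if (is.null(phase_sequences)) {
    for (i in seq_len(n_states)) Tm[i, c(i, nb[[i]])] <- 1
  } else {
    if (length(phase_sequences) == 0)
      stop("empty trajectory set", call. = FALSE)
    bin_of <- function(phi) {
      ix <- pmin(floor(phi / (2 * pi) * n_bins), n_bins - 1)
      if (dims == 1L) ix + 1L
      else ix[, 1] + ix[, 2] * n_bins + 1L
    }
    for (seq_i in phase_sequences) {
      b <- bin_of(if (dims == 1L) as.numeric(seq_i) else matrix(seq_i, ncol = 2))
      from <- b[-length(b)]; to <- b[-1]
      for (t in seq_along(from)) Tm[from[t], to[t]] <- Tm[from[t], to[t]] + 1
    }
    ## add-one smoothing restricted to the torus-adjacent support
    for (i in seq_len(n_states)) Tm[i, c(i, nb[[i]])] <- Tm[i, c(i, nb[[i]])] + 1
  }
  Tm <- Tm / rowSums(Tm)
  structure(list(n_bins = as.integer(n_bins), dims = as.integer(dims),
                 T = Tm, neighbours = nb),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("Transition model: %d^%d phase bins, row-stochastic %d x %d\n",
              x$n_bins, x$dims, nrow(x$T), ncol(x$T)))
  invisible(x)
}

#' Sequential planning by transition-matrix diffusion
#'
#' Initializes a planning vector with equal mass on the start and target
#' bins, then repeatedly diffuses it through the transition matrix,
#' renormalizes, and re-clamps the target bin to the running maximum so the
#' goal stays a persistent source. After each update the path advances to
#' the torus-neighbour of the current bin carrying the highest planning
#' mass (ties resolve in the positive direction).
#'
#' @param model A [build_transition_matrix()] result.
#' @param start_bin,target_bin State indices in `1..n_bins^dims`.
#' @param max_iters Diffusion-iteration cap; default `8 * n_states + 4 *
#'   n_bins^2`, enough for the diffusion front to bridge any start/target
#'   pair before the field flattens.
#' @return List: `path` (bin indices, starting at `start_bin`; a new bin is
#'   appended only when the walk advances), `converged`, and the final
#'   planning vector `v_plan` (non-negative, sums to 1).
#' @export
plan_phase_path <- function(model, start_bin, target_bin, max_iters = NULL) {
  n <- nrow(model$T)
  stopifnot(start_bin >= 1, start_bin <= n, target_bin >= 1, target_bin <= n)
  path <- c(start_bin)
  if (start_bin == target_bin)
    return(list(path = path, converged = TRUE, v_plan = NULL))
  if (is.null(max_iters)) max_iters <- 8 * n + 4 * model$n_bins^2
  v <- numeric(n)
  v[start_bin] <- 0.5; v[target_bin] <- v[target_bin] + 0.5
  tT <- t(model$T)
  current <- start_bin
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    v <- as.numeric(tT %*% v)
    ## goal stays a persistent source: re-mark it with the running maximum
    ## so the renormalized field keeps a stationary gradient towards it
    v[target_bin] <- v[target_bin] + max(v)
    v <- v / sum(v)
    ## advance only when a neighbour strictly beats the current bin, i.e.
    ## when the diffusion front from the target has reached the walker;
    ## neighbour order resolves exact ties in the positive direction
    nb <- model$neighbours[[current]]
    ## tolerant argmax: numerically tied neighbours resolve by preference
    ## order (positive direction first), not by float round-off
    vnb <- v[nb]
    j <- which(vnb >= max(vnb) * (1 - 1e-9))[1]
    ## the clamped target carries the global maximum, so it can tie with but
    ## never strictly beat the current bin: step into it whenever adjacent
    if (target_bin %in% nb) j <- match(target_bin, nb)
    if (v[nb[j]] > v[current] || nb[j] == target_bin) {
      current <- nb[j]
      path <- c(path, current)
      if (current == target_bin) { converged <- TRUE; break }
    }
  }
  list(path = path, converged = converged, v_plan = v)
}

#' Greedy multi-scale vector navigation
#'
#' Repeatedly decodes the multi-scale displacement from the current phases
#' to fixed target phases, moves a fraction of it, and recomputes phases
#' from the new position. As the agent approaches the target more scales
#' become decodable and the estimate sharpens.
#'
#' @param start_pos Start position (length n).
#' @param target_phases List of target phases, one per module.
#' @param bases List of lattice bases / `"grid_module"`s, ordered by period.
#' @param step_fraction Fraction of the decoded displacement taken per step;
#'   default 1 in 1-D, 0.5 in 2-D.
#' @param tol Stop when the decoded remaining displacement is below this (cm).
#' @param max_steps Step cap.
#' @return List: `positions` (step x n matrix including the start),
#'   `converged`, `final_estimate` (norm of the last decoded displacement).
#' @export
vector_navigate <- function(start_pos, target_phases, bases,
                            step_fraction = NULL, tol = 0.1, max_steps = 100) {
  n <- length(start_pos)
  if (is.null(step_fraction)) step_fraction <- if (n == 1L) 1 else 0.5
  stopifnot(step_fraction > 0, step_fraction <= 1)
  pos <- matrix(start_pos, 1, n)
  p <- start_pos
  converged <- FALSE
  dnorm_last <- Inf
  for (step in seq_len(max_steps)) {
    phis <- lapply(bases, function(b) phase_of_position(p, b))
    dhat <- combine_multiscale(phis, target_phases, bases)
    dnorm_last <- sqrt(sum(dhat^2))
    if (dnorm_last < tol) { converged <- TRUE; break }
    p <- p + step_fraction * dhat
    pos <- rbind(pos, p)
  }
  rownames(pos) <- NULL
  list(positions = pos, converged = converged, final_estimate = dnorm_last)
}
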