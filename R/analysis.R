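#' Aggregate model activity into occupancy-weighted ratemaps
#'
#' Rolls the fitted network over test trajectories and averages each unit's
#' activation (rate, i.e. the rectified state) per spatial bin, weighted by
#' bin occupancy. Bins that are never visited are marked invalid (`NA`), not
#' zero.
#'
#' @param object A fitted [fit_gridnet()] model.
#' @param duration,n_traj Test-trajectory duration (s) and count.
#' @param seed Integer seed for the test trajectories.
#' @param populations Character vector among `"GC"`, `"SMC"`, `"HPC"`.
#' @return Named list of `"ratemap"` objects (with `NA` at unvisited bins)
#'   plus `occupancy` (per-bin visit probabilities) and `valid` (logical).
#' @export
aggregate_ratemaps <- function(object, duration = 10, n_traj = 20, seed = 1234,
                               populations = c("GC", "SMC", "HPC")) {
  stopifnot(inherits(object, "gridnet"))
  ro <- gridnet_rollout(object, duration = duration, n = n_traj, seed = seed,
                        noise = TRUE)
  arena <- object$config$arena
  bins <- position_to_bin(cbind(as.numeric(ro$batch$px),
                                as.numeric(ro$batch$py)), arena)
  if (length(bins) == 0) stop("zero total occupancy", call. = FALSE)
  nl <- rnn_nonlinearity(object$params$nonlinearity)
  lay <- object$layout
  counts <- tabulate(bins, nbins = arena$nx * arena$ny)
  valid <- counts > 0
  idx_of <- list(GC = lay$gc, SMC = lay$smc, HPC = lay$hidden)
  out <- list()
  for (pop in populations) {
    idx <- idx_of[[pop]]
    if (length(idx) == 0) next
    ## states: d x B x T -> (T*B) x n ordered like bins (T fastest, then B)
    A <- nl$f(ro$states[idx, , , drop = FALSE])
    A <- t(matrix(A, nrow = length(idx)))  # (B*T) x n, B fastest
    ## bins is ordered T fastest within trajectory; reorder A accordingly
    B <- dim(ro$states)[2]; Tn <- dim(ro$states)[3]
    ord <- as.numeric(t(matrix(seq_len(B * Tn), B, Tn)))
    A <- A[ord, , drop = FALSE]
    sums <- rowsum(A, bins, reorder = FALSE)
    ubins <- as.integer(rownames(sums))
    rates <- matrix(NA_real_, arena$nx * arena$ny, length(idx))
    rates[ubins, ] <- sums / counts[ubins]
    rm <- structure(list(rates = array(rates, c(arena$nx, arena$ny, length(idx))),
                         arena = arena, population_tag = pop),
                    class = "ratemap")
    out[[pop]] <- rm
  }
  out$occupancy <- counts / sum(counts)
  out$valid <- valid
  out
}

## Flatten a ratemap's rates to (bins x cells).
flat_rates <- function(map) {
  d <- dim(map$rates)
  matrix(map$rates, d[1] * d[2], d[3])
}

#' Decode position by nearest-neighbour ratemap lookup
#'
#' Exhaustive exact search: returns the center of the bin whose rate vector
#' minimizes the Euclidean distance to the query. Ties resolve to the lowest
#' flattened bin index (x index fastest). Invalid (unvisited) bins are
#' excluded.
#'
#' @param query Population rate vector (length n_cells) or a T x n_cells
#'   matrix of queries.
#' @param map A `"ratemap"`.
#' @return For a single query, a length-2 position (cm); for a matrix, a
#'   T x 2 matrix.
#' @export
decode_position <- function(query, map) {
  stopifnot(inherits(map, "ratemap"))
  Q <- if (is.matrix(query)) query else matrix(query, 1)
  R <- flat_rates(map)
  if (ncol(Q) != ncol(R))
    stop("query length does not match the number of cells", call. = FALSE)
  ok <- stats::complete.cases(R)
  if (!any(ok)) stop("ratemap has no valid bins", call. = FALSE)
  Rv <- R[ok, , drop = FALSE]
  ## argmin over ||r - q||^2 = |r|^2 - 2 r.q (+ |q|^2, constant per query)
  d2 <- rowSums(Rv^2) - 2 * tcrossprod(Rv, Q) # valid-bins x T
  best <- which(ok)[apply(d2, 2, which.min)]
  pos <- bin_to_position(best, map$arena)
  if (is.matrix(query)) pos else drop(pos)
}

#' Skaggs spatial information content
#'
#' `SIC = sum_i p_i (r_i / rbar) log2(r_i / rbar)` with `rbar = sum_i p_i
#' r_i`, in bits per activation unit; 0 for silent or spatially uniform
#' cells. Invalid bins (NA rate or zero occupancy) are ignored.
#'
#' @param cell_map Matrix (nx x ny) or vector of per-bin rates for one cell.
#' @param occupancy Per-bin occupancy probabilities (same length, sums to 1
#'   over valid bins).
#' @return Scalar information score (>= 0).
#' @export
spatial_information <- function(cell_map, occupancy) {
  r <- as.numeric(cell_map)
  p <- as.numeric(occupancy)
  ok <- !is.na(r) & p > 0
  r <- r[ok]; p <- p[ok] / sum(p[ok])
  if (any(r < 0)) stop("negative rates", call. = FALSE)
  rbar <- sum(p * r)
  if (rbar <= 0) return(0)
  x <- r / rbar
  sum(p[x > 0] * x[x > 0] * log2(x[x > 0]))
}

#' Place-cell identification criteria
#'
#' Thresholds for identifying place-cell-like hidden units: minimum mean
#' activation and minimum spatial information. The defaults mirror the
#' reference protocol (rate 0.01, information 20); because the information
#' score scale depends on the (unavailable) original definition, analyses in
#' this package calibrate `min_sic` to model units (1.5 bits) - the
#' *trend* of counts across masking ratios, not the absolute threshold, is
#' the meaningful quantity.
#'
#' @param min_rate Minimum occupancy-weighted mean activation.
#' @param min_sic Minimum [spatial_information()] score.
#' @param min_cells_for_decoding Decode from this population only when more
#'   than this many units pass.
#' @return Object of class `"cell_criteria"`.
#' @export
cell_criteria <- function(min_rate = 0.01, min_sic = 20,
                          min_cells_for_decoding = 10) {
  stopifnot(min_rate >= 0, min_sic >= 0)
  structure(list(min_rate = min_rate, min_sic = min_sic,
                 min_cells_for_decoding = min_cells_for_decoding),
            class = "cell_criteria")
}

#' Identify place-cell-like units
#'
#' @param map A `"ratemap"` of the hidden population (or any population).
#' @param occupancy Per-bin occupancy probabilities.
#' @param criteria A [cell_criteria()].
#' @return Integer vector of unit indices passing both thresholds.
#' @export
identify_place_cells <- function(map, occupancy,
                                 criteria = cell_criteria(min_sic = 1.5)) {
  stopifnot(inherits(map, "ratemap"), inherits(criteria, "cell_criteria"))
  R <- flat_rates(map)
  p <- as.numeric(occupancy)
  hits <- vapply(seq_len(ncol(R)), function(j) {
    r <- R[, j]
    ok <- !is.na(r) & p > 0
    mean_rate <- sum(r[ok] * p[ok]) / sum(p[ok])
    mean_rate > criteria$min_rate &&
      spatial_information(r, p) > criteria$min_sic
  }, logical(1))
  which(hits)
}

#' Query the network with a clamped sensory pattern
#'
#' Implements the recall protocol: the network state is initialized to zero,
#' the SMC input is clamped to the query pattern for `Tq` timesteps (all
#' other inputs zero), and the decoded position of each readable population
#' is tracked against the cued target location.
#'
#' @param object A fitted `"hcmec"` [fit_gridnet()] model.
#' @param target_pos Length-2 cue location (cm); the query pattern is the
#'   ground-truth SMC response there unless `pattern` is given.
#' @param Tq Query length in timesteps (100 = 5 s at dt 0.05).
#' @param pattern Optional explicit SMC pattern.
#' @param maps Optional [aggregate_ratemaps()] result to decode against;
#'   default decodes against the ground-truth GC/SMC dictionaries.
#' @param criteria [cell_criteria()] for HPC decoding eligibility (used only
#'   with aggregated maps).
#' @return Object of class `"recall_trace"`: per-step decoded positions and
#'   L2 distance-to-target curves per population, the state sequence, and
#'   the target.
#' @export
recall_query <- function(object, target_pos, Tq = 100, pattern = NULL,
                         maps = NULL, criteria = cell_criteria(min_sic = 1.5)) {
  stopifnot(inherits(object, "gridnet"))
  lay <- object$layout
  if (length(lay$smc) == 0)
    stop("recall queries require an hcmec fit with SMC units", call. = FALSE)
  if (is.null(pattern)) {
    bin <- position_to_bin(matrix(target_pos, 1), object$config$arena)
    pattern <- object$smc_flat[bin, ]
  }
  n_in <- length(lay$input_idx)
  u <- numeric(n_in)
  u[seq_along(lay$smc)] <- pattern # SMC rows come first in input order
  z <- numeric(lay$d)
  nl <- rnn_nonlinearity(object$params$nonlinearity)
  a <- sigmoid(object$params$beta)
  W <- object$params$W
  U <- inject_input(lay, matrix(u, n_in, 1), 1)
  S <- matrix(0, lay$d, Tq)
  Z <- matrix(0, lay$d, 1)
  for (t in seq_len(Tq)) {
    Z <- a * Z + (1 - a) * (U + W %*% nl$f(Z))
    S[, t] <- Z
  }
  dict <- list()
  if (!is.null(maps)) {
    dict$GC <- maps$GC
    dict$SMC <- maps$SMC
    if (!is.null(maps$HPC)) {
      hp <- identify_place_cells(maps$HPC, maps$occupancy, criteria)
      if (length(hp) > criteria$min_cells_for_decoding) {
        sub <- maps$HPC
        sub$rates <- sub$rates[, , hp, drop = FALSE]
        dict$HPC <- list(map = sub, idx = lay$hidden[hp])
      }
    }
  } else {
    dict$GC <- structure(list(rates = array(object$gc_flat,
                                            c(object$config$arena$nx,
                                              object$config$arena$ny,
                                              ncol(object$gc_flat))),
                              arena = object$config$arena,
                              population_tag = "GC"), class = "ratemap")
    dict$SMC <- object$smc_map
  }
  decoded <- list(); dist <- list()
  pops <- list(GC = lay$gc, SMC = lay$smc)
  if (!is.null(dict$HPC)) pops$HPC <- dict$HPC$idx
  for (pop in names(pops)) {
    mp <- if (pop == "HPC") dict$HPC$map else dict[[pop]]
    if (is.null(mp)) next
    Q <- t(nl$f(S[pops[[pop]], , drop = FALSE]))
    dp <- decode_position(Q, mp)
    decoded[[pop]] <- dp
    dist[[pop]] <- sqrt(rowSums((dp - matrix(target_pos, Tq, 2,
                                             byrow = TRUE))^2))
  }
  structure(list(states = S, decoded = decoded, distance = dist,
                 target = target_pos, Tq = Tq),
            class = "recall_trace")
}

#' @export
print.recall_trace <- function(x, ...) {
  cat(sprintf("Recall trace: %d steps, target (%.1f, %.1f)\n",
              x$Tq, x$target[1], x$target[2]))
  for (pop in names(x$distance))
    cat(sprintf("  %s final distance-to-target: %.2f cm\n",
                pop, utils::tail(x$distance[[pop]], 1)))
  invisible(x)
}

## --- Grid metrics ----------------------------------------------------------

## 2-D spatial autocorrelogram via FFT: Pearson correlation at each lag over
## the overlapping region.
autocorrelogram <- function(m) {
  m <- as.matrix(m)
  nx <- nrow(m); ny <- ncol(m)
  px <- 2 * nx - 1; py <- 2 * ny - 1
  pad <- function(a) { out <- matrix(0, px, py); out[1:nx, 1:ny] <- a; out }
  F1 <- stats::fft(pad(m))
  Fo <- stats::fft(pad(matrix(1, nx, ny)))
  F2 <- stats::fft(pad(m^2))
  cc <- function(A, B) Re(stats::fft(A * Conj(B), inverse = TRUE)) / (px * py)
  ## cross terms at every lag (circular -> recentred linear correlation)
  sxy <- cc(F1, F1); sx <- cc(F1, Fo); sy <- cc(Fo, F1)
  sxx <- cc(F2, Fo); syy <- cc(Fo, F2); n <- cc(Fo, Fo)
  shift <- function(a) {
    a <- rbind(a[(nx + 1):px, , drop = FALSE], a[1:nx, , drop = FALSE])
    cbind(a[, (ny + 1):py, drop = FALSE], a[, 1:ny, drop = FALSE])
  }
  sxy <- shift(sxy); sx <- shift(sx); sy <- shift(sy)
  sxx <- shift(sxx); syy <- shift(syy); n <- shift(n)
  n <- pmax(round(n), 1)
  num <- sxy - sx * sy / n
  den <- sqrt(pmax(sxx - sx^2 / n, 0) * pmax(syy - sy^2 / n, 0))
  ac <- num / den
  ac[!is.finite(ac)] <- 0
  ac[n < 20] <- NA # too little overlap to estimate a correlation
  ac
}

## Bilinear sampling of matrix `m` at fractional (row, col) coordinates.
bilinear <- function(m, ri, ci) {
  nx <- nrow(m); ny <- ncol(m)
  r0 <- pmax(pmin(floor(ri), nx - 1), 1); c0 <- pmax(pmin(floor(ci), ny - 1), 1)
  fr <- ri - r0; fc <- ci - c0
  v00 <- m[cbind(r0, c0)]; v10 <- m[cbind(r0 + 1, c0)]
  v01 <- m[cbind(r0, c0 + 1)]; v11 <- m[cbind(r0 + 1, c0 + 1)]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

#' Grid metrics: autocorrelogram and grid score
#'
#' The grid score is the standard 60-degree rotational statistic on the
#' spatial autocorrelogram: the maximum of the correlations at 60 and 120
#' degrees minus the maximum at 30, 90 and 150 degrees, computed on an
#' annulus that excludes the central peak and extends past the first ring
#' of side peaks.
#'
#' @param cell_map nx x ny matrix of rates for one cell.
#' @param inner,outer Annulus radii in bins; defaults pick the trough of the
#'   central peak and 90% of the maximum lag.
#' @return List with `autocorrelogram` (matrix, 1 at zero lag) and
#'   `grid_score` (NA with status `"degenerate"` for constant maps).
#' @export
grid_metrics <- function(cell_map, inner = NULL, outer = NULL) {
  if (stats::sd(as.numeric(cell_map), na.rm = TRUE) == 0)
    return(list(autocorrelogram = NULL, grid_score = NA_real_,
                status = "degenerate"))
  ac <- autocorrelogram(cell_map)
  nx <- nrow(cell_map); ny <- ncol(cell_map)
  cx <- nx; cy <- ny # zero-lag index in the (2nx-1) x (2ny-1) map
  rr <- sqrt(outer((1:(2 * nx - 1) - cx)^2, (1:(2 * ny - 1) - cy)^2, "+"))
  if (is.null(inner)) {
    ## first radius where the angular-mean correlation dips below 0.2
    prof <- vapply(1:(min(nx, ny) - 1), function(r)
      mean(ac[rr >= r - 0.5 & rr < r + 0.5], na.rm = TRUE), numeric(1))
    inner <- which(prof < 0.2)[1]
    if (is.na(inner)) inner <- round(min(nx, ny) / 4)
  }
  if (is.null(outer)) outer <- floor(0.9 * (min(nx, ny) - 1))
  sel <- which(rr >= inner & rr <= outer & !is.na(ac), arr.ind = TRUE)
  if (nrow(sel) < 10)
    return(list(autocorrelogram = ac, grid_score = NA_real_,
                status = "degenerate"))
  base <- ac[sel]
  rot_corr <- function(theta) {
    dx <- sel[, 1] - cx; dy <- sel[, 2] - cy
    rx <- cx + cos(theta) * dx - sin(theta) * dy
    ry <- cy + sin(theta) * dx + cos(theta) * dy
    acz <- ac; acz[is.na(acz)] <- 0
    stats::cor(base, bilinear(acz, rx, ry))
  }
  on_peak <- vapply(c(60, 120) * pi / 180, rot_corr, numeric(1))
  off_peak <- vapply(c(30, 90, 150) * pi / 180, rot_corr, numeric(1))
  list(autocorrelogram = ac, grid_score = max(on_peak) - max(off_peak),
       status = "ok")
}

#' Project a recall trace into ratemap principal components
#'
#' Fits a 3-component PCA on the flattened (bins x cells) ratemap of one
#' population and projects both the map and the recall states into that
#' basis, for visualizing convergence of the recall dynamics onto the
#' spatial manifold.
#'
#' @param map A `"ratemap"` (>= 3 cells).
#' @param trace A [recall_query()] result.
#' @param population Which population's states to project (`"GC"` or
#'   `"SMC"`); cell count must match the map.
#' @param layout The model's [population_layout()].
#' @return List: `map_coords` (bins x 3), `trace_coords` (Tq x 3),
#'   `target_coords` (projection of the target bin's response),
#'   `explained_variance` (fraction, <= 1).
#' @export
project_recall_pca <- function(map, trace, population, layout) {
  stopifnot(inherits(map, "ratemap"), inherits(trace, "recall_trace"))
  R <- flat_rates(map)
  if (ncol(R) < 3) stop("need at least 3 cells for a 3-D projection",
                        call. = FALSE)
  ok <- stats::complete.cases(R)
  pc <- stats::prcomp(R[ok, , drop = FALSE], center = TRUE, scale. = FALSE)
  idx <- switch(population, GC = layout$gc, SMC = layout$smc,
                stop("unknown population", call. = FALSE))
  states <- t(trace$states[idx, , drop = FALSE])
  proj <- function(X) scale(X, center = pc$center, scale = FALSE) %*%
    pc$rotation[, 1:3]
  tb <- position_to_bin(matrix(trace$target, 1), map$arena)
  list(map_coords = proj(R[ok, , drop = FALSE]),
       trace_coords = proj(states),
       target_coords = proj(R[tb, , drop = FALSE]),
       explained_variance = sum(pc$sdev[1:3]^2) / sum(pc$sdev^2))
}
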