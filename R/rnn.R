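#' Population layout of the recurrent network state
#'
#' The state vector concatenates contiguous, disjoint index ranges for the
#' cell populations: grid cells (GC), spatially modulated cells (SMC),
#' head-direction cells (DIR), speed cells (SPD), unsupervised hidden units
#' (HIDDEN, the place-cell candidates), and an optional planner block.
#' SMC/DIR/SPD are input nodes that integrate raw external input without a
#' learned projection; GC and SMC are output nodes supervised against
#' ground-truth responses; GC additionally receives its ground-truth state at
#' t = 0 only; HIDDEN is neither input nor output.
#'
#' @param n_gc,n_smc,n_dir,n_spd,n_hidden,n_planner Population sizes (0 to
#'   omit a population).
#' @return Object of class `"population_layout"` with index vectors `gc`,
#'   `smc`, `dir`, `spd`, `hidden`, `planner`, the combined `input_idx`
#'   (SMC, DIR, SPD order) and `output_idx` (GC, SMC), and total size `d`.
#' @export
population_layout <- function(n_gc, n_smc = 0, n_dir = 32, n_spd = 16,
                              n_hidden = 0, n_planner = 0) {
  sizes <- c(gc = n_gc, smc = n_smc, dir = n_dir, spd = n_spd,
             hidden = n_hidden, planner = n_planner)
  stopifnot(all(sizes >= 0), n_gc > 0)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  rng <- function(nm) if (sizes[nm] == 0) integer(0) else starts[nm]:ends[nm]
  out <- list(gc = rng("gc"), smc = rng("smc"), dir = rng("dir"),
              spd = rng("spd"), hidden = rng("hidden"),
              planner = rng("planner"), d = sum(sizes))
  out$input_idx <- c(out$smc, out$dir, out$spd)
  out$output_idx <- c(out$gc, out$smc)
  structure(out, class = "population_layout")
}

#' @export
print.population_layout <- function(x, ...) {
  cat(sprintf(
    "Population layout (%d units): GC %d, SMC %d, DIR %d, SPD %d, HIDDEN %d, PLANNER %d\n",
    x$d, length(x$gc), length(x$smc), length(x$dir), length(x$spd),
    length(x$hidden), length(x$planner)))
  invisible(x)
}

rnn_nonlinearity <- function(name) {
  switch(name,
         relu = list(f = function(z) (z > 0) * z, df = function(z) (z > 0) * 1),
         tanh = list(f = tanh, df = function(z) 1 - tanh(z)^2),
         identity = list(f = identity, df = function(z) array(1, dim(z) %||% length(z))),
         stop("unknown nonlinearity: ", name, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize recurrent network parameters
#'
#' The full recurrent matrix is randomly initialized with no block structure
#' imposed; the per-unit forgetting rate alpha is learnable, parameterized
#' through a sigmoid to stay in `[0, 1]`, and starts at `alpha_init`.
#'
#' @param layout A [population_layout()].
#' @param seed Integer seed.
#' @param init_scale Weight sd is `init_scale / sqrt(d)`.
#' @param alpha_init Initial forgetting rate in (0, 1).
#' @param nonlinearity `"relu"` (default, non-negative rates), `"tanh"`, or
#'   `"identity"`.
#' @return Object of class `"rnn_params"`: `W` (d x d), `beta`
#'   (pre-sigmoid alpha), `layout`, `nonlinearity`.
#' @export
rnn_params_init <- function(layout, seed = NULL, init_scale = 0.5,
                            alpha_init = 0.9, nonlinearity = "relu") {
  stopifnot(inherits(layout, "population_layout"),
            alpha_init > 0, alpha_init < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- layout$d
  W <- matrix(stats::rnorm(d * d, 0, init_scale / sqrt(d)), d, d)
  structure(list(W = W, beta = rep(log(alpha_init / (1 - alpha_init)), d),
                 layout = layout, nonlinearity = nonlinearity),
            class = "rnn_params")
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf("RNN parameters: %d units, %s nonlinearity, mean alpha %.3f\n",
              x$layout$d, x$nonlinearity, mean(sigmoid(x$beta))))
  print(x$layout)
  invisible(x)
}

## Place raw input rows (aligned to layout$input_idx) into full-state coords.
inject_input <- function(layout, u, n_col) {
  U <- matrix(0, layout$d, n_col)
  if (length(layout$input_idx) > 0 && !is.null(u))
    U[layout$input_idx, ] <- u
  U
}

#' One recurrent update
#'
#' `z' = alpha * z + (1 - alpha) * (inject(u) + W f(z))`, where `inject`
#' places the raw input values into the input-node coordinates (no learned
#' input projection) and zeros elsewhere.
#'
#' @param params An [rnn_params_init()] result.
#' @param state State vector (length d) or d x B matrix.
#' @param input Input aligned to `layout$input_idx` (vector or matrix), or
#'   NULL for no external input.
#' @return Updated state, same shape as `state`.
#' @export
rnn_step <- function(params, state, input = NULL) {
  lay <- params$layout
  vec <- !is.matrix(state)
  Z <- if (vec) matrix(state, lay$d, 1) else state
  if (!is.null(input) && !is.matrix(input))
    input <- matrix(input, length(lay$input_idx), ncol(Z))
  nl <- rnn_nonlinearity(params$nonlinearity)
  a <- sigmoid(params$beta)
  U <- inject_input(lay, input, ncol(Z))
  Znew <- a * Z + (1 - a) * (U + params$W %*% nl$f(Z))
  if (any(!is.finite(Znew))) {
    pops <- c("GC", "SMC", "DIR", "SPD", "HIDDEN", "PLANNER")
    idx <- list(lay$gc, lay$smc, lay$dir, lay$spd, lay$hidden, lay$planner)
    bad <- pops[vapply(idx, function(i)
      length(i) > 0 && any(!is.finite(Znew[i, ])), logical(1))]
    stop("non-finite state in population(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (vec) drop(Znew) else Znew
}

#' Roll the network out over an input sequence
#'
#' @param params An [rnn_params_init()] result.
#' @param init_state Initial state (length d vector or d x B matrix). Grid
#'   coordinates of the initial state carry the ground-truth grid response at
#'   t = 0 (possibly masked); later timesteps receive no grid input.
#' @param input_sequence List of inputs (each as in [rnn_step()]), possibly
#'   empty, or a 3-d array `n_inputs x B x T`.
#' @return List of states, starting with `init_state` (length T + 1).
#' @export
rnn_rollout <- function(params, init_state, input_sequence = list()) {
  if (is.array(input_sequence) && length(dim(input_sequence)) == 3) {
    input_sequence <- lapply(seq_len(dim(input_sequence)[3]),
                             function(t) input_sequence[, , t])
  }
  states <- vector("list", length(input_sequence) + 1)
  states[[1]] <- init_state
  z <- init_state
  for (t in seq_along(input_sequence)) {
    z <- rnn_step(params, z, input_sequence[[t]])
    states[[t + 1]] <- z
  }
  states
}

#' @useDynLib gridnav, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
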