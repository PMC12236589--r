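test_that("position-to-phase mapping is linear and lattice-periodic", {
  mod <- grid_module(period = 30, orientation = 0.3,
                     phase_offsets = matrix(0, 1, 2))
  expect_equal(phase_of_position(c(0, 0), mod), c(0, 0))
  ## pos = basis %*% (0.25, 0.5) -> phase (pi/2, pi)
  p <- as.numeric(mod$basis %*% c(0.25, 0.5))
  expect_equal(phase_of_position(p, mod), c(pi / 2, pi), tolerance = 1e-12)
  ## periodicity under integer lattice shifts
  set.seed(12)
  for (i in 1:50) {
    pos <- runif(2, -200, 200)
    ab <- sample(-3:3, 2, replace = TRUE)
    shifted <- pos + as.numeric(mod$basis %*% ab)
    d <- (phase_of_position(pos, mod) - phase_of_position(shifted, mod)) %%
      (2 * pi)
    expect_equal(pmin(d, 2 * pi - d), c(0, 0), tolerance = 1e-8)
  }
  expect_error(phase_of_position(c(1, 1), matrix(0, 2, 2)), "singular")
})

test_that("displacement decoding picks the minimal wrap (oracle equivalence)", {
  ## spec'd 1-D example: l = 30, phases pi/2 -> pi gives +7.5 cm
  expect_equal(decode_module_displacement(pi / 2, pi, 30), 7.5)
  expect_equal(decode_module_displacement(c(1, 2), c(1, 2), diag(2)), c(0, 0))

  ## brute-force oracle over candidate wrappings
  brute_wrap <- function(phi_c, phi_t) {
    n <- length(phi_c)
    cand <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), n))) * 2 * pi
    diffs <- matrix(phi_t - phi_c, nrow(cand), n, byrow = TRUE) + cand
    ok <- apply(diffs, 1, function(d) all(d > -pi & d <= pi + 1e-12))
    diffs <- diffs[ok, , drop = FALSE]
    unname(diffs[which.min(rowSums(diffs^2)), ])
  }
  ## 2-D spec example
  expect_equal(brute_wrap(c(0, 0), c(3 * pi / 2, pi / 2)),
               c(-pi / 2, pi / 2))
  expect_equal(wrap_phase_difference(c(0, 0), c(3 * pi / 2, pi / 2)),
               c(-pi / 2, pi / 2))

  set.seed(77)
  B <- grid_module(period = 50, orientation = 0.7)$basis
  for (i in 1:500) {
    pc <- runif(2, 0, 2 * pi); pt <- runif(2, 0, 2 * pi)
    expect_equal(wrap_phase_difference(pc, pt), brute_wrap(pc, pt),
                 tolerance = 1e-12)
    d <- decode_module_displacement(pc, pt, B)
    expect_equal(d, as.numeric(B %*% (brute_wrap(pc, pt) / (2 * pi))),
                 tolerance = 1e-12)
  }
  ## 1-D random cases
  for (i in 1:500) {
    pc <- runif(1, 0, 2 * pi); pt <- runif(1, 0, 2 * pi)
    expect_equal(wrap_phase_difference(pc, pt), brute_wrap(pc, pt),
                 tolerance = 1e-12)
  }
  ## per-axis displacement bound l/2
  for (i in 1:100) {
    pc <- runif(2, 0, 2 * pi); pt <- runif(2, 0, 2 * pi)
    expect_true(all(abs(wrap_phase_difference(pc, pt)) / (2 * pi) <= 0.5))
  }
})

test_that("multi-scale combination matches the wrapped-phase algebra", {
  ## m = 1 reduces to single-module decoding
  B <- grid_module(period = 40)$basis
  pc <- list(c(1, 2)); pt <- list(c(2.5, 0.4))
  expect_equal(combine_multiscale(pc, pt, list(B)),
               decode_module_displacement(pc[[1]], pt[[1]], B))

  ## spec'd 1-D example: m = 2, l = (30, 30e), true d = 20
  l <- c(30, 30 * exp(1))
  pcs <- lapply(l, function(L) phase_of_position(0, L))
  pts <- lapply(l, function(L) phase_of_position(20, L))
  dhat <- combine_multiscale(pcs, pts, as.list(l))
  expect_equal(dhat, 5, tolerance = 1e-9)
  expect_lt(20 - dhat, 20) # remaining distance shrinks

  ## all modules decodable (d < l1/2) -> exact recovery, 1-D and 2-D
  set.seed(31)
  mods <- lapply(c(30, 30 * sqrt(exp(1))), function(L) grid_module(L))
  for (i in 1:50) {
    d1 <- runif(1, -14, 14)
    got <- combine_multiscale(lapply(l, function(L) phase_of_position(10, L)),
                              lapply(l, function(L) phase_of_position(10 + d1, L)),
                              as.list(l))
    expect_equal(got, d1, tolerance = 1e-9)
    d2 <- runif(2, -8, 8) # inside l1/2 along both lattice axes
    start <- runif(2, 0, 150)
    got2 <- combine_multiscale(
      lapply(mods, function(m) phase_of_position(start, m)),
      lapply(mods, function(m) phase_of_position(start + d2, m)),
      mods)
    expect_equal(got2, d2, tolerance = 1e-8)
  }
  expect_error(combine_multiscale(pcs[1], pts, as.list(l)), "one phase pair")
})

test_that("contraction margin has the closed form and its corollaries", {
  expect_equal(contraction_margin(2, 0), 0)
  expect_equal(contraction_margin(exp(1), 1), exp(-1), tolerance = 1e-12)
  ## for s = e the margin stays below 1 for any k, so m > k suffices there
  for (k in 1:10) expect_lt(contraction_margin(exp(1), k), 1)
  expect_error(contraction_margin(0.9, 2), "exceed 1")
})

test_that("transition matrices are row-stochastic with torus support", {
  m <- build_transition_matrix(8, 1)
  expect_equal(rowSums(m$T), rep(1, 8), tolerance = 1e-9)
  for (i in 1:8) {
    nb <- sort(c(i, m$neighbours[[i]]))
    expect_equal(which(m$T[i, ] > 0), nb)
    expect_equal(unname(m$T[i, nb]), rep(1 / 3, 3))
  }
  m2 <- build_transition_matrix(5, 2)
  expect_equal(rowSums(m2$T), rep(1, 25), tolerance = 1e-9)
  expect_true(all(vapply(m2$neighbours, length, integer(1)) == 8))

  ## empirical matrix from a slow phase walk recovers the local support
  set.seed(3)
  phis <- lapply(1:20, function(i) {
    (cumsum(rnorm(400, 0, 2 * pi / 8 * 0.3))) %% (2 * pi)
  })
  me <- build_transition_matrix(8, 1, phase_sequences = phis)
  expect_equal(rowSums(me$T), rep(1, 8), tolerance = 1e-9)
  for (i in 1:8) {
    beyond <- setdiff(seq_len(8), c(i, me$neighbours[[i]]))
    ## smoothing mass only on the local support; no observed long jumps
    expect_true(all(me$T[i, beyond] == 0))
  }
  expect_error(build_transition_matrix(8, 1, phase_sequences = list()),
               "empty")
})

test_that("phase-path planning follows ring/torus geodesics", {
  ring_geo <- function(n, i, j) min(abs(i - j), n - abs(i - j))
  for (N in c(5, 8, 16)) {
    m <- build_transition_matrix(N, 1)
    for (i in seq_len(N)) for (j in seq_len(N)) {
      p <- plan_phase_path(m, i, j)
      expect_true(p$converged)
      expect_equal(length(p$path) - 1, ring_geo(N, i - 1, j - 1))
      expect_equal(p$path[1], i)
      if (!is.null(p$v_plan)) {
        expect_true(all(p$v_plan >= 0))
        expect_equal(sum(p$v_plan), 1, tolerance = 1e-9)
      }
    }
  }
  ## antipodal tie resolves to the positive direction
  m8 <- build_transition_matrix(8, 1)
  p <- plan_phase_path(m8, 1, 5)
  expect_equal(p$path, c(1, 2, 3, 4, 5))
  ## 2-D: 8-neighbour torus geodesic (Chebyshev distance with wrap)
  tor_geo <- function(n, a, b) {
    dd <- abs(a - b); dd <- pmin(dd, n - dd); max(dd)
  }
  N <- 6
  m2 <- build_transition_matrix(N, 2)
  set.seed(14)
  for (rep in 1:40) {
    ij <- sample(N^2, 2)
    a <- c((ij[1] - 1) %% N, (ij[1] - 1) %/% N)
    b <- c((ij[2] - 1) %% N, (ij[2] - 1) %/% N)
    p <- plan_phase_path(m2, ij[1], ij[2])
    expect_true(p$converged)
    expect_equal(length(p$path) - 1, tor_geo(N, a, b))
  }
  ## start equals target
  expect_equal(plan_phase_path(m8, 3, 3)$path, 3)

  ## larger torus, sampled pairs: geodesic except when an axis displacement
  ## is exactly N/2 (two geodesics interfere and commitment can cost one
  ## extra step; see the methods vignette)
  N <- 16
  m16 <- build_transition_matrix(N, 2)
  set.seed(4)
  for (rep in 1:30) {
    ij <- sample(N^2, 2)
    a <- c((ij[1] - 1) %% N, (ij[1] - 1) %/% N)
    b <- c((ij[2] - 1) %% N, (ij[2] - 1) %/% N)
    p <- plan_phase_path(m16, ij[1], ij[2])
    expect_true(p$converged)
    dd <- abs(a - b); dd <- pmin(dd, N - dd)
    antipodal_axis <- any(dd == N / 2)
    expect_lte(length(p$path) - 1, max(dd) + as.integer(antipodal_axis))
    if (!antipodal_axis) expect_equal(length(p$path) - 1, max(dd))
  }
})

test_that("vector navigation is greedy multi-scale descent", {
  ## 1-D, all scales decodable: one full step converges immediately
  l <- 30 * exp(1)^(0:2)
  tgt <- lapply(l, function(L) phase_of_position(110, L))
  nv <- vector_navigate(100, tgt, as.list(l), step_fraction = 1, tol = 0.1)
  expect_true(nv$converged)
  expect_equal(nrow(nv$positions), 2) # start + single step
  expect_equal(nv$positions[2, 1], 110, tolerance = 1e-6)

  ## start at target: zero steps
  nv0 <- vector_navigate(100, lapply(l, function(L) phase_of_position(100, L)),
                         as.list(l))
  expect_true(nv0$converged)
  expect_equal(nrow(nv0$positions), 1)

  ## 1-D monotone contraction whenever one scale of slack is available
  set.seed(99)
  for (rep in 1:200) {
    k <- sample(0:3, 1); m <- sample((k + 2):6, 1) # m > k + 1
    li <- 30 * exp(1)^(0:(m - 1))
    lo <- if (k == 0) 0.5 else li[k] / 2
    d <- runif(1, lo, li[k + 1] / 2)
    tgt <- lapply(li, function(L) phase_of_position(d, L))
    nv <- vector_navigate(0, tgt, as.list(li), step_fraction = 1,
                          tol = 30 / 20, max_steps = 50)
    rem <- abs(d - nv$positions[, 1])
    expect_true(all(diff(rem) < 1e-9))
    expect_true(nv$converged)
  }
})
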