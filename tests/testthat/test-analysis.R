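## A tiny synthetic "fitted" object whose dynamics just replay ground-truth
## rates is enough to exercise the analysis pipeline without training.
make_tiny_fit <- function(seed = 42) {
  cfg <- gridnet_config(arena = arena(60, 60, 4),
                        hierarchy = phase_hierarchy(n_modules = 1),
                        n_gc_per_module = 8, n_smc = 6, n_dir = 4, n_spd = 2,
                        n_hidden = 5, traj_duration = 1, batch_size = 2,
                        n_steps = 2, curriculum = FALSE)
  fit_gridnet(cfg, "hcmec", seed = seed)
}

test_that("aggregated ratemaps recover sampled ground truth on visited bins", {
  a <- arena(60, 60, 4)
  map <- make_smc_map(3, a, correlation_length = 15, seed = 7)
  trs <- simulate_trajectory(a, motion_params(), duration = 20, n = 10,
                             seed = 8)
  ## manual occupancy-weighted aggregation of exact samples must return the
  ## ratemap itself on visited bins
  bins <- unlist(lapply(trs, function(tr) position_to_bin(tr$positions, a)))
  R <- do.call(rbind, lapply(trs, function(tr) sample_responses(map, tr)))
  agg <- rowsum(R, bins) / as.numeric(table(bins))
  truth <- matrix(map$rates, a$nx * a$ny, 3)[sort(unique(bins)), ]
  expect_equal(unname(agg), unname(truth), tolerance = 1e-12)
})

test_that("aggregate_ratemaps flags unvisited bins and is occupancy-weighted", {
  fit <- make_tiny_fit()
  maps <- aggregate_ratemaps(fit, duration = 5, n_traj = 3, seed = 99,
                             populations = c("GC", "SMC", "HPC"))
  expect_equal(sum(maps$occupancy), 1, tolerance = 1e-12)
  gc <- maps$GC$rates
  flat <- matrix(gc, prod(dim(gc)[1:2]), dim(gc)[3])
  visited <- maps$valid
  expect_true(all(is.na(flat[!visited, ])))
  expect_true(all(!is.na(flat[visited, ])))
  expect_true(all(flat[visited, ] >= 0))
})

test_that("decode_position is an exact nearest-neighbour with tie-breaks", {
  a <- arena(40, 40, 4) # 10 x 10 bins
  set.seed(21)
  rates <- array(runif(10 * 10 * 6), c(10, 10, 6))
  map <- structure(list(rates = rates, arena = a, population_tag = "GC"),
                   class = "ratemap")
  flat <- matrix(rates, 100, 6)
  ## exact hit at every bin
  for (b in c(1, 37, 100)) {
    expect_equal(position_to_bin(matrix(decode_position(flat[b, ], map), 1), a),
                 b)
  }
  ## sub-gap noise cannot change the decoded bin
  D <- as.matrix(dist(flat)); diag(D) <- Inf
  gap <- min(D)
  q <- flat[37, ] + rep(gap / (2 * sqrt(6)) * 0.9, 6) *
    sign(rnorm(6)) / sqrt(6)
  expect_equal(position_to_bin(matrix(decode_position(q, map), 1), a), 37)
  ## brute-force oracle on random queries (including matrix form)
  Q <- matrix(runif(50 * 6), 50, 6)
  got <- decode_position(Q, map)
  for (i in 1:50) {
    d2 <- rowSums((flat - matrix(Q[i, ], 100, 6, byrow = TRUE))^2)
    expect_equal(position_to_bin(matrix(got[i, ], 1), a), which.min(d2))
  }
  ## tie-break: two identical bins resolve to the lower flattened index
  flat2 <- flat; flat2[80, ] <- flat2[15, ]
  map2 <- map; map2$rates <- array(flat2, c(10, 10, 6))
  expect_equal(position_to_bin(matrix(decode_position(flat2[15, ], map2), 1),
                               a), 15)
})

test_that("spatial information has the Skaggs closed forms", {
  B <- 64
  occ <- rep(1 / B, B)
  expect_equal(spatial_information(rep(3, B), occ), 0)
  expect_equal(spatial_information(rep(0, B), occ), 0)
  one_bin <- c(5, rep(0, B - 1))
  expect_equal(spatial_information(one_bin, occ), log2(B))
  ## scale invariance
  set.seed(9)
  r <- runif(B)
  expect_equal(spatial_information(r, occ),
               spatial_information(10 * r, occ), tolerance = 1e-12)
  ## sharpening a field (same peak mass in fewer bins) raises information
  broad <- c(rep(1, 8), rep(0, B - 8))
  sharp <- c(rep(2, 4), rep(0, B - 4))
  expect_gt(spatial_information(sharp, occ), spatial_information(broad, occ))
  expect_gte(spatial_information(r, occ), 0)
  expect_error(spatial_information(-r, occ), "negative")
})

test_that("place-cell identification applies both thresholds", {
  a <- arena(40, 40, 4)
  occ <- rep(1 / 100, 100)
  ## unit 1: single strong field; unit 2: uniform; unit 3: silent
  r1 <- numeric(100); r1[45] <- 1
  r2 <- rep(0.5, 100)
  r3 <- numeric(100)
  rates <- array(c(r1, r2, r3), c(10, 10, 3))
  map <- structure(list(rates = rates, arena = a, population_tag = "HPC"),
                   class = "ratemap")
  got <- identify_place_cells(map, occ, cell_criteria(min_rate = 0.001,
                                                      min_sic = 1.5))
  expect_equal(got, 1L)
  expect_length(identify_place_cells(map, occ,
                                     cell_criteria(min_rate = 10,
                                                   min_sic = 1.5)), 0)
  silent <- map; silent$rates <- array(0, dim(rates))
  expect_length(identify_place_cells(silent, occ, cell_criteria(0.001, 0.5)),
                0)
})

test_that("grid metrics separate grids from single fields", {
  a <- arena(120, 120, 2)
  h <- phase_hierarchy(n_modules = 1)
  gm <- make_grid_modules(h, 1, a, seed = 31)
  cellmap <- gm[[1]]$ratemap$rates[, , 1]
  gmtr <- grid_metrics(cellmap)
  expect_equal(gmtr$status, "ok")
  expect_gt(gmtr$grid_score, 0)
  ## zero-lag autocorrelation is 1
  ac <- gmtr$autocorrelogram
  expect_equal(ac[a$nx, a$ny], 1, tolerance = 1e-6)

  ## a single Gaussian place field scores at or below zero
  bc <- outer((1:60 - 30)^2, (1:60 - 30)^2, "+")
  place <- exp(-bc / (2 * 36))
  gp <- grid_metrics(place)
  expect_lte(gp$grid_score, 0)

  ## degenerate map
  expect_equal(grid_metrics(matrix(1, 30, 30))$status, "degenerate")
})

test_that("recall traces and their PCA projection are well-formed", {
  fit <- make_tiny_fit()
  tr <- recall_query(fit, target_pos = c(30, 30), Tq = 40)
  expect_s3_class(tr, "recall_trace")
  expect_length(tr$distance$GC, 40)
  expect_length(tr$distance$SMC, 40)
  expect_true(all(unlist(tr$distance) >= 0))

  maps <- aggregate_ratemaps(fit, duration = 5, n_traj = 4, seed = 17)
  pj <- project_recall_pca(maps$GC, tr, "GC", fit$layout)
  expect_equal(ncol(pj$trace_coords), 3)
  expect_equal(nrow(pj$trace_coords), 40)
  expect_lte(pj$explained_variance, 1)
  expect_gt(pj$explained_variance, 0)
  ## the target bin's map response projects onto the map manifold point
  tbin <- position_to_bin(matrix(c(30, 30), 1), maps$GC$arena)
  flat <- matrix(maps$GC$rates, prod(dim(maps$GC$rates)[1:2]))
  valid_rows <- which(stats::complete.cases(flat))
  expect_equal(pj$target_coords,
               pj$map_coords[match(tbin, valid_rows), , drop = FALSE])
})
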