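## Schema for the nested experiment configuration. Each entry lists the
## allowed keys; unknown keys are rejected before any computation runs.
config_schema <- list(
  seed = "integer",
  pipeline = "character", # subset of simulate, train, recall, plan, analyze
  out_dir = "character",
  arena = c("width", "height", "bin_size"),
  hierarchy = c("smallest_period", "scale_factor", "n_modules",
                "spacing_field_ratio"),
  motion = c("dt", "mean_speed", "speed_scale", "heading_persistence"),
  populations = c("n_gc_per_module", "n_smc", "n_dir", "n_spd", "n_hidden"),
  masking = c("r_mask", "noise_sigma"),
  training = c("variant", "traj_duration", "batch_size", "n_steps",
               "learning_rate", "alpha_init", "init_scale", "nonlinearity",
               "supervise", "state_noise", "cold_start_prob"),
  planner = c("planner_dim", "n_steps", "learning_rate", "plan_horizon",
              "n_pairs", "batch_size"),
  recall = c("Tq", "n_queries", "min_sic", "min_rate"),
  simulate = c("duration", "n_traj"),
  analyze = c("duration", "n_traj")
)

validate_experiment_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in intersect(names(cfg), names(config_schema))) {
    sch <- config_schema[[nm]]
    if (length(sch) > 1 || !sch %in% c("integer", "character")) {
      bad <- setdiff(names(cfg[[nm]]), sch)
      if (length(bad) > 0)
        stop(sprintf("unknown config key(s) under '%s': %s", nm,
                     paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  rm <- cfg$masking$r_mask
  if (!is.null(rm) && (rm < 0 || rm > 1))
    stop("masking$r_mask must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

experiment_to_gridnet_config <- function(cfg) {
  a <- do.call(arena, as.list(cfg$arena %||% list()))
  h <- do.call(phase_hierarchy,
               c(as.list(cfg$hierarchy %||% list(n_modules = 2))))
  mo <- do.call(motion_params, as.list(cfg$motion %||% list()))
  args <- c(list(arena = a, hierarchy = h, motion = mo),
            as.list(cfg$populations %||% list()),
            as.list(cfg$masking %||% list()),
            as.list(cfg$training[setdiff(names(cfg$training %||% list()),
                                         "variant")] %||% list()))
  do.call(gridnet_config, args)
}

#' Run a configured experiment end to end
#'
#' Reads a YAML configuration (or an equivalent nested list), validates it
#' against the schema (unknown keys are rejected), runs the requested
#' pipeline stages (`simulate`, `train`, `recall`, `analyze`), and writes
#' artifacts - trajectory and loss CSVs, ratemap PNGs, and a JSON summary of
#' every computed metric together with the config and seeds needed to
#' reproduce the run.
#'
#' @param config Path to a YAML file, or a nested list.
#' @param out_dir Output directory (created if missing); overrides the
#'   config's `out_dir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the summary list (also written to `summary.json`).
#' @export
run_experiment <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_experiment_config(cfg)
  out_dir <- out_dir %||% cfg$out_dir %||% "gridnav_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1)
  pipeline <- cfg$pipeline %||% c("simulate", "train", "analyze")
  say <- function(...) if (!quiet) message(...)
  summary <- list(seed = seed, pipeline = pipeline, config = cfg)
  gcfg <- experiment_to_gridnet_config(cfg)

  if ("simulate" %in% pipeline) {
    sim <- cfg$simulate %||% list()
    dur <- sim$duration %||% 5
    n <- sim$n_traj %||% 10
    say(sprintf("simulating %d trajectories of %.1f s", n, dur))
    trs <- simulate_trajectory(gcfg$arena, gcfg$motion, dur, n = n,
                               seed = seed)
    if (n == 1) trs <- list(trs)
    df <- do.call(rbind, lapply(seq_along(trs), function(i) {
      tr <- trs[[i]]
      data.frame(traj = i, t = (seq_len(nrow(tr$positions)) - 1) * tr$dt,
                 x = tr$positions[, 1], y = tr$positions[, 2],
                 heading = tr$headings, speed = tr$speeds)
    }))
    utils::write.csv(df, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    summary$simulate <- list(n_traj = n, duration = dur,
                             timesteps_per_trajectory =
                               nrow(trs[[1]]$positions),
                             mean_speed = mean(df$speed))
  }

  fit <- NULL
  if ("train" %in% pipeline) {
    variant <- cfg$training$variant %||% "gc_only"
    say(sprintf("training variant '%s' (%d steps)", variant, gcfg$n_steps))
    fit <- fit_gridnet(gcfg, variant, seed = seed, verbose = !quiet)
    utils::write.csv(fit$loss_trace, file.path(out_dir, "loss_trace.csv"),
                     row.names = FALSE)
    saveRDS(fit, file.path(out_dir, "fit.rds"))
    pr <- predict(fit, duration = 10, n_traj = 5, seed = seed + 100)
    summary$train <- list(variant = variant,
                          final_loss = utils::tail(fit$loss_trace$loss, 1),
                          decode_error_cm = list(
                            mean = mean(pr$error),
                            median = stats::median(pr$error)))
  }

  if ("analyze" %in% pipeline && !is.null(fit)) {
    an <- cfg$analyze %||% list()
    say("aggregating ratemaps")
    maps <- aggregate_ratemaps(fit, duration = an$duration %||% 10,
                               n_traj = an$n_traj %||% 10, seed = seed + 7)
    summary$analyze <- list()
    if (!is.null(maps$HPC)) {
      crit <- cell_criteria(min_rate = cfg$recall$min_rate %||% 0.01,
                            min_sic = cfg$recall$min_sic %||% 1.5)
      hp <- identify_place_cells(maps$HPC, maps$occupancy, crit)
      utils::write.csv(data.frame(hpc_unit = hp),
                       file.path(out_dir, "hpc_units.csv"),
                       row.names = FALSE)
      summary$analyze$n_hpc <- length(hp)
    }
    grDevices::png(file.path(out_dir, "gc_ratemap.png"), 600, 600)
    plot(fit, type = "ratemap", cell = 1)
    grDevices::dev.off()
  }

  if ("recall" %in% pipeline && !is.null(fit) && fit$variant == "hcmec") {
    rc <- cfg$recall %||% list()
    nq <- rc$n_queries %||% 5
    say(sprintf("running %d recall queries", nq))
    set.seed(seed + 11)
    targets <- cbind(stats::runif(nq, 10, gcfg$arena$width - 10),
                     stats::runif(nq, 10, gcfg$arena$height - 10))
    curves <- lapply(seq_len(nq), function(i)
      recall_query(fit, targets[i, ], Tq = rc$Tq %||% 100))
    df <- do.call(rbind, lapply(seq_len(nq), function(i) {
      tr <- curves[[i]]
      data.frame(query = i, step = seq_len(tr$Tq),
                 d_GC = tr$distance$GC, d_SMC = tr$distance$SMC)
    }))
    utils::write.csv(df, file.path(out_dir, "recall_curves.csv"),
                     row.names = FALSE)
    summary$recall <- list(n_queries = nq,
                           final_d_GC = mean(vapply(curves, function(tr)
                             utils::tail(tr$distance$GC, 1), numeric(1))))
  }

  summary$timesteps_check <- if (!is.null(summary$simulate))
    summary$simulate$timesteps_per_trajectory else NULL
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
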