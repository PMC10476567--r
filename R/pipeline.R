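# File-based orchestration: simulate -> extract -> call -> analyze ->
# report, with a validated configuration object and a run manifest so that
# reruns are auditable and byte-reproducible.

pipeline_keys <- c("mode", "k", "smoothing_window", "mcc_threshold",
                   "mi_positive", "bandwidth", "persistence", "t_eval",
                   "seed", "sim", "fate", "control_n_cells", "plots")

#' Pipeline configuration
#'
#' Validates and completes the configuration driving [run_simulate()] and
#' [run_analyze()].  Unknown keys are rejected so that typos cannot
#' silently fall back to defaults.
#'
#' @param ... configuration entries, or a single named list.  Keys:
#'   `mode` ("tracking" or "endpoint"; sets the death-threshold multiplier
#'   k to 5 or 10 unless `k` is given), `k`, `smoothing_window`,
#'   `mcc_threshold`, `mi_positive` ("otsu"/"raw"), `bandwidth`,
#'   `persistence`, `t_eval`, `seed`, `sim` (list of [sim_config()]
#'   overrides), `fate` (list of [fate_model()] overrides),
#'   `control_n_cells`, `plots` (logical).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && is.list(args[[1]]))
    args <- args[[1]]
  unknown <- setdiff(names(args), pipeline_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- list(mode = "tracking", k = NULL, smoothing_window = 5L,
              mcc_threshold = 0.60, mi_positive = "otsu",
              bandwidth = "scott", persistence = 1L, t_eval = 40,
              seed = 1L, sim = list(), fate = list(),
              control_n_cells = 40L, plots = FALSE)
  cfg[names(args)] <- args
  stopifnot(cfg$mode %in% c("tracking", "endpoint"),
            cfg$mi_positive %in% c("otsu", "raw"))
  if (is.null(cfg$k)) cfg$k <- if (cfg$mode == "tracking") 5 else 10
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  c2 <- cfg
  class(c2) <- NULL
  yaml::write_yaml(c2, f)
  unname(tools::md5sum(f))
}

write_manifest <- function(dir, cfg, files) {
  manifest <- list(config_hash = config_hash(cfg),
                   package_version = as.character(
                     utils::packageVersion("mcctrack")),
                   seed = cfg$seed,
                   file_md5 = as.list(tools::md5sum(unname(files))),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

build_sim_objects <- function(cfg) {
  sim_args <- cfg$sim
  sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)
  fm <- do.call(fate_model, cfg$fate)
  list(sim = scfg, fate = fm)
}

#' Simulate stress and control experiments to disk
#'
#' Writes a stressed cohort (under `out_dir/stress`) following the
#' configured fate model, and a matched no-stress control cohort (under
#' `out_dir/control`, no deaths) used for threshold derivation and survival
#' normalization, plus a run manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, the list of written paths.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  obj <- build_sim_objects(config)
  message(sprintf("simulate: %d stress cells [%s], seed %d",
                  obj$sim$n_cells, obj$fate$condition_label, config$seed))
  stress <- simulate_experiment(obj$sim, obj$fate)
  p1 <- write_experiment(stress, file.path(out_dir, "stress"))
  ctrl_cfg <- obj$sim
  ctrl_cfg$n_cells <- as.integer(config$control_n_cells)
  ctrl_cfg$seed <- obj$sim$seed + 1L
  message(sprintf("simulate: %d control cells", ctrl_cfg$n_cells))
  ctrl <- simulate_experiment(ctrl_cfg, control_fate_model())
  p2 <- write_experiment(ctrl, file.path(out_dir, "control"))
  write_manifest(out_dir, config, c(p1, p2))
  invisible(list(stress = p1, control = p2))
}

#' Analyze an experiment directory
#'
#' Recomputes every figure-analog from the raw stacks in one pass: per-cell
#' dye traces and death calls (threshold from the control experiment),
#' survival table with control normalization, per-cell MCC time courses,
#' smoothed series and initial MCC, high/low split, initial-MCC versus
#' time-to-death correlation, and pooled KDE.  Results are written as
#' CSV/JSON (and optionally PNG plots) under `out_dir/results`.
#'
#' @param out_dir directory previously written by [run_simulate()] (or laid
#'   out the same way: `stress/` and `control/` subdirectories).
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results.
#' @export
run_analyze <- function(out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stress_dir <- file.path(out_dir, "stress")
  control_dir <- file.path(out_dir, "control")
  if (!dir.exists(stress_dir))
    stop("missing stress experiment directory: ", stress_dir)
  res_dir <- file.path(out_dir, "results")
  if (!dir.exists(res_dir)) dir.create(res_dir, recursive = TRUE)
  stress <- read_experiment(stress_dir)
  if (!any(stress$roi != 0L)) stop("empty ROI stack in ", stress_dir)
  fi <- stress$config$frame_interval
  message(sprintf("analyze: %d cells in ROI stack",
                  length(setdiff(unique(as.integer(stress$roi)), 0L))))
  ## death calling ----------------------------------------------------------
  ctrl <- read_experiment(control_dir)
  ctrl_traces <- extract_traces(ctrl$stacks$dye, ctrl$roi, fi)
  thr <- derive_threshold(ctrl_traces, k = config$k)
  traces <- extract_traces(stress$stacks$dye, stress$roi, fi)
  calls <- call_deaths(traces, thr, config$persistence, fi)
  message(sprintf("analyze: %d dead / %d cells (threshold %.4g, k = %g)",
                  sum(calls$status == "dead"), nrow(calls),
                  thr$threshold, thr$k))
  ## survival ----------------------------------------------------------------
  times <- sort(unique(traces$time_h))
  ctrl_calls <- call_deaths(ctrl_traces, thr, config$persistence, fi)
  surv_raw <- survival_curve(calls, times, condition = "stress")
  surv_ctrl <- survival_curve(ctrl_calls, times, condition = "control")
  surv <- normalize_to_control(surv_raw, surv_ctrl)
  ## colocalization ----------------------------------------------------------
  mcc <- mcc_timecourse(stress$stacks$reporter, stress$stacks$mito,
                        stress$roi, fi, config$mi_positive)
  pool <- align_and_pool(mcc, calls, config$smoothing_window)
  ini <- vapply(split(mcc, mcc$cell_id), function(d)
    initial_mcc(d$mcc[order(d$frame)], config$smoothing_window),
    numeric(1))
  ini <- ini[match(calls$cell_id, as.integer(names(ini)))]
  split <- split_by_threshold(ini, calls, config$mcc_threshold)
  dead <- calls$status == "dead"
  corr <- if (sum(dead) >= 3)
    correlate_initial_mcc_vs_death_time(ini[dead], calls$death_time_h[dead])
  else NULL
  kde <- if (length(pool$dead$pooled) >= 2)
    mcc_kde(pool$dead$pooled, config$bandwidth) else NULL
  message(sprintf("analyze: split at %.2f -> %d high / %d low",
                  config$mcc_threshold, sum(split$class == "high"),
                  sum(split$class == "low")))
  ## outputs -----------------------------------------------------------------
  utils::write.csv(calls, file.path(res_dir, "fate_calls.csv"),
                   row.names = FALSE)
  utils::write.csv(surv, file.path(res_dir, "survival.csv"),
                   row.names = FALSE)
  utils::write.csv(mcc, file.path(res_dir, "mcc_timecourse.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(threshold = unclass(thr),
                            split = split$summary,
                            config_hash = config_hash(config)),
                       file.path(res_dir, "split_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(corr))
    jsonlite::write_json(list(mean_r = corr$mean_r, sem_r = corr$sem_r,
                              slope = corr$slope,
                              intercept = corr$intercept, n = corr$n,
                              config_hash = config_hash(config)),
                         file.path(res_dir, "correlation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (isTRUE(config$plots)) {
    grDevices::png(file.path(res_dir, "survival.png"), 700, 500)
    plot_survival_curves(list(stress = surv_raw, control = surv_ctrl))
    grDevices::dev.off()
    grDevices::png(file.path(res_dir, "aligned_mcc.png"), 900, 500)
    plot_aligned_mcc(pool, threshold = config$mcc_threshold)
    grDevices::dev.off()
    if (!is.null(corr)) {
      grDevices::png(file.path(res_dir, "mcc_scatter.png"), 700, 500)
      plot_mcc_scatter(ini[dead], calls$death_time_h[dead], corr)
      grDevices::dev.off()
    }
  }
  invisible(list(threshold = thr, calls = calls, survival = surv,
                 mcc = mcc, pool = pool, initial_mcc = ini,
                 split = split, correlation = corr, kde = kde))
}

#' Power analysis entry point with a JSON report
#'
#' @param props,n_per_group,alpha,test,n_reps,seed,comparison see
#'   [simulate_power()].
#' @param target_power if not NULL, also run [min_n_for_power()] at this
#'   target.
#' @param out_file optional path for a JSON report.
#' @return list with `power` (a `power_result`) and optionally `min_n`.
#' @export
run_power <- function(props, n_per_group, alpha = 0.05,
                      test = "steel_dwass", n_reps = 2000L, seed = 1L,
                      comparison = "designated_all", target_power = NULL,
                      out_file = NULL) {
  pw <- simulate_power(props, n_per_group, alpha, test, n_reps, seed,
                       comparison)
  out <- list(power = pw)
  if (!is.null(target_power))
    out$min_n <- min_n_for_power(props, target_power, alpha, test,
                                 n_reps, seed, comparison)
  if (!is.null(out_file)) {
    rep <- list(power = pw$power, mc_se = pw$mc_se, n_reps = pw$n_reps,
                props = props, n_per_group = n_per_group, alpha = alpha,
                test = test, comparison = comparison, seed = seed)
    if (!is.null(out$min_n)) {
      rep$min_n <- out$min_n$n
      rep$power_at_min_n <- out$min_n$power_at_n
      rep$target_power <- target_power
    }
    jsonlite::write_json(rep, out_file, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  out
}
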