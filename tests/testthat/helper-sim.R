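# Shared fixtures, built in code and cached for the whole test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# full default WT-like run: simulation, control, traces, calls, MCC, initial
default_wt_run <- function() {
  cached("wt", {
    cfg <- sim_config()                      # 100 cells, 80 frames, seed 1
    sim <- simulate_experiment(cfg, fate_model())
    ctrl <- simulate_experiment(
      sim_config(n_cells = 40L, seed = 2L), control_fate_model())
    thr <- derive_threshold(
      extract_traces(ctrl$stacks$dye, ctrl$roi, cfg$frame_interval), k = 5)
    traces <- extract_traces(sim$stacks$dye, sim$roi, cfg$frame_interval)
    calls <- call_deaths(traces, thr, 1L, cfg$frame_interval)
    mcc <- mcc_timecourse(sim$stacks$reporter, sim$stacks$mito, sim$roi,
                          cfg$frame_interval)
    ini <- vapply(split(mcc, mcc$cell_id), function(d)
      initial_mcc(d$mcc[order(d$frame)]), numeric(1))
    ini <- ini[order(as.integer(names(ini)))]
    list(cfg = cfg, sim = sim, thr = thr, traces = traces, calls = calls,
         mcc = mcc, ini = ini)
  })
}

# mutant-like run (delay_slope = 0): larger cohort for a tight null on r
default_mutant_run <- function() {
  cached("mutant", {
    cfg <- sim_config(n_cells = 200L, field_shape = c(500L, 500L),
                      seed = 3L)
    sim <- simulate_experiment(cfg, mutant_fate_model())
    ctrl <- simulate_experiment(
      sim_config(n_cells = 40L, seed = 4L), control_fate_model())
    thr <- derive_threshold(
      extract_traces(ctrl$stacks$dye, ctrl$roi, cfg$frame_interval), k = 5)
    calls <- call_deaths(
      extract_traces(sim$stacks$dye, sim$roi, cfg$frame_interval),
      thr, 1L, cfg$frame_interval)
    mcc <- mcc_timecourse(sim$stacks$reporter, sim$stacks$mito, sim$roi,
                          cfg$frame_interval)
    ini <- vapply(split(mcc, mcc$cell_id), function(d)
      initial_mcc(d$mcc[order(d$frame)]), numeric(1))
    ini <- ini[order(as.integer(names(ini)))]
    list(cfg = cfg, sim = sim, calls = calls, mcc = mcc, ini = ini)
  })
}

# independent brute-force oracles ------------------------------------------

# Manders M1 by an explicit pixel loop
brute_manders <- function(tert, mito, tert_mask, mito_mask) {
  num <- 0; den <- 0
  for (i in seq_along(tert)) {
    if (tert_mask[i]) {
      den <- den + tert[i]
      if (mito_mask[i]) num <- num + tert[i]
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Otsu by exhaustive search over the same 256-bin histogram
brute_otsu_bin <- function(x, n_bins = 256L) {
  r <- range(x)
  idx <- pmin(n_bins, 1L + floor((x - r[1]) / diff(r) * n_bins))
  best <- -Inf; best_k <- NA_integer_
  for (k in seq_len(n_bins - 1L)) {
    g1 <- x[idx <= k]; g2 <- x[idx > k]
    if (!length(g1) || !length(g2)) next
    w1 <- length(g1) / length(x)
    sb <- w1 * (1 - w1) * (mean(g1) - mean(g2))^2
    if (sb > best + 1e-12) { best <- sb; best_k <- k }
  }
  best_k
}
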