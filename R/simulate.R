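# End-to-end synthetic experiment: latent per-cell parameters -> geometry ->
# rendered per-cell tiles -> assembled multi-channel stacks + labelled ROI
# masks + ground-truth table.  Everything derives from one seed.

#' Simulate a multi-channel time-lapse experiment
#'
#' Generates reporter, mitochondria and death-dye image stacks for a cohort
#' of synthetic cells, together with per-frame labelled ROI masks (loose
#' elliptical regions around each cell, emulating manually drawn ROIs that
#' include some background) and the latent ground truth: per-cell
#' mitochondrial fraction of the reporter, expression, death time and
#' centroid path.
#'
#' Cells are placed on a jittered grid and drift slowly (integer-pixel
#' translations of their rendered tile).  Upon death a cell's footprint
#' contracts by `config$death_shrink` and the dye signal rises steeply in
#' its nucleus.  Identical `(config, model, seed)` give identical output.
#'
#' @param config a [sim_config()].
#' @param model a [fate_model()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return an object of class `sim_experiment`: list with `stacks` (named
#'   list of `H x W x n_frames` arrays of integer counts: `reporter`,
#'   `mito`, `dye`), `roi` (integer label array of the same shape), `truth`
#'   (data frame: cell_id, f_mito, expression, death_time_h, death_frame,
#'   f_class), `paths` (data frame of per-frame centroids), `config`,
#'   `model`, `seed`.
#' @export
simulate_experiment <- function(config, model, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(model, "fate_model"))
  H <- config$field_shape[1]; W <- config$field_shape[2]
  Fn <- config$n_frames
  t_frames <- frame_times(config)
  empty_truth <- data.frame(cell_id = integer(), f_mito = numeric(),
                            expression = numeric(), death_time_h = numeric(),
                            death_frame = integer(), f_class = character(),
                            stringsAsFactors = FALSE)
  if (config$n_cells == 0L) {
    z <- array(0L, dim = c(H, W, Fn))
    return(structure(list(stacks = list(reporter = z, mito = z, dye = z),
                          roi = z, truth = empty_truth,
                          paths = data.frame(), config = config,
                          model = model, seed = seed),
                     class = "sim_experiment"))
  }
  with_seed(seed, {
    n <- config$n_cells
    ## latent per-cell parameters -------------------------------------------
    mix <- config$f_mito_mix
    is_high_mode <- stats::runif(n) < mix$w_high
    f_mito <- ifelse(is_high_mode,
                     stats::rbeta(n, mix$high[1], mix$high[2]),
                     stats::rbeta(n, mix$low[1], mix$low[2]))
    s2 <- log(1 + config$expression_cv^2)
    expression <- stats::rlnorm(n, log(config$expression_mean) - s2 / 2,
                                sqrt(s2))
    t_max <- (Fn - 1) * config$frame_interval
    death_time <- sample_fates(f_mito, model, t_max = t_max)
    death_frame <- ifelse(is.na(death_time), NA_integer_,
                          1L + as.integer(ceiling(death_time /
                                                  config$frame_interval - 1e-9)))
    ## placement -------------------------------------------------------------
    geom_seed0 <- sample.int(.Machine$integer.max %/% 2L, 1L)
    tile <- make_cell_geometry(config, 1L, seed = geom_seed0)$tile
    half <- (tile - 1L) %/% 2L
    margin <- half + 6L
    spacing <- as.integer(ceiling(2.3 * config$cell_radius + 5))
    gx <- seq(margin + 1L, W - margin, by = spacing)
    gy <- seq(margin + 1L, H - margin, by = spacing)
    slots <- expand.grid(x = gx, y = gy)
    if (n > nrow(slots))
      stop(sprintf("cannot place %d cells: only %d grid slots fit the field",
                   n, nrow(slots)))
    pick <- sample.int(nrow(slots), n)
    cx0 <- slots$x[pick] + round(stats::runif(n, -2, 2))
    cy0 <- slots$y[pick] + round(stats::runif(n, -2, 2))
    ## drift paths (integer offsets per frame) -------------------------------
    ox <- oy <- matrix(0L, n, Fn)
    if (config$drift_sd > 0) {
      for (i in seq_len(n)) {
        ox[i, ] <- as.integer(round(cumsum(stats::rnorm(Fn, 0, config$drift_sd))))
        oy[i, ] <- as.integer(round(cumsum(stats::rnorm(Fn, 0, config$drift_sd))))
      }
    }
    cx <- pmin(pmax(cx0 + ox, margin + 1L), W - margin)
    cy <- pmin(pmax(cy0 + oy, margin + 1L), H - margin)
    ## per-cell rendered tiles ------------------------------------------------
    geom_seeds <- geom_seed0 + seq_len(n)
    rep_alive <- mito_alive <- dye_dead <- rep_dead <- mito_dead <-
      vector("list", n)
    for (i in seq_len(n)) {
      ga <- make_cell_geometry(config, i, seed = geom_seeds[i])
      rep_alive[[i]] <- render_reporter_channel(ga, f_mito[i], expression[i],
                                                config)
      mito_alive[[i]] <- render_mito_channel(ga, config)
      if (!is.na(death_frame[i])) {
        gd <- make_cell_geometry(config, i, seed = geom_seeds[i],
                                 scale = config$death_shrink)
        rep_dead[[i]] <- render_reporter_channel(gd, f_mito[i], expression[i],
                                                 config)
        mito_dead[[i]] <- render_mito_channel(gd, config)
        dye_dead[[i]] <- render_dye_template(gd, config)
      }
    }
    ## assemble stacks --------------------------------------------------------
    rel <- seq_len(tile) - 1L - half
    reporter <- array(0, dim = c(H, W, Fn))
    mito <- array(0, dim = c(H, W, Fn))
    dye <- array(0, dim = c(H, W, Fn))
    roi <- array(0L, dim = c(H, W, Fn))
    r_roi <- config$cell_radius * 1.3 + config$roi_margin
    for (f in seq_len(Fn)) {
      dist_best <- matrix(Inf, H, W)
      lab <- matrix(0L, H, W)
      for (i in seq_len(n)) {
        dead <- !is.na(death_frame[i]) && f >= death_frame[i]
        rows <- cy[i, f] + rel
        cols <- cx[i, f] + rel
        reporter[rows, cols, f] <- reporter[rows, cols, f] +
          (if (dead) rep_dead[[i]] else rep_alive[[i]])
        mito[rows, cols, f] <- mito[rows, cols, f] +
          (if (dead) mito_dead[[i]] else mito_alive[[i]])
        if (dead) {
          amp <- dye_amplitude(t_frames[f], death_time[i], config) /
            config$dye_plateau
          dye[rows, cols, f] <- dye[rows, cols, f] +
            config$dye_plateau * amp * dye_dead[[i]]
        }
        ## labelled ROI: loose disk, ties resolved to the nearest centroid
        rr <- as.integer(ceiling(r_roi))
        rrows <- (cy[i, f] - rr):(cy[i, f] + rr)
        rcols <- (cx[i, f] - rr):(cx[i, f] + rr)
        d2 <- outer((rrows - cy[i, f])^2, (rcols - cx[i, f])^2, "+")
        inside <- d2 <= r_roi^2
        closer <- inside & d2 < dist_best[rrows, rcols]
        dsub <- dist_best[rrows, rcols]; lsub <- lab[rrows, rcols]
        dsub[closer] <- d2[closer]; lsub[closer] <- i
        dist_best[rrows, rcols] <- dsub; lab[rrows, rcols] <- lsub
      }
      roi[, , f] <- lab
    }
    ## camera: offset, photon + read noise, integer counts --------------------
    add_noise <- function(a) {
      a <- a + config$offset
      if (config$poisson_scale > 0) {
        lam <- pmax(a, 0) * config$poisson_scale
        a <- stats::rpois(length(lam), lam) / config$poisson_scale
        dim(a) <- c(H, W, Fn)
      }
      if (config$gaussian_sd > 0)
        a <- a + stats::rnorm(length(a), 0, config$gaussian_sd)
      array(as.integer(pmin(pmax(round(a), 0), 65535L)), dim = c(H, W, Fn))
    }
    stacks <- list(reporter = add_noise(reporter),
                   mito = add_noise(mito),
                   dye = add_noise(dye))
    truth <- data.frame(
      cell_id = seq_len(n),
      f_mito = f_mito,
      expression = expression,
      death_time_h = death_time,
      death_frame = death_frame,
      f_class = ifelse(f_mito >= model$f_high_threshold, "high", "low"),
      stringsAsFactors = FALSE)
    paths <- data.frame(cell_id = rep(seq_len(n), each = Fn),
                        frame = rep(seq_len(Fn), n),
                        x = as.vector(t(cx)), y = as.vector(t(cy)))
    structure(list(stacks = stacks, roi = roi, truth = truth, paths = paths,
                   config = config, model = model, seed = seed),
              class = "sim_experiment")
  })
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("Synthetic experiment [%s]: %d cells, %d frames, %d x %d px\n",
              x$model$condition_label, nrow(x$truth), x$config$n_frames,
              x$config$field_shape[1], x$config$field_shape[2]))
  if (nrow(x$truth))
    cat(sprintf("  dead: %d / %d  (window %.3g h)\n",
                sum(!is.na(x$truth$death_time_h)), nrow(x$truth),
                (x$config$n_frames - 1) * x$config$frame_interval))
  invisible(x)
}

#' Stoichiometric equivalents of sodium percarbonate
#'
#' Sodium percarbonate (2Na2CO3.3H2O2) dissolves into sodium carbonate and
#' hydrogen peroxide in a 2:3 molar ratio, so a given SPC concentration is
#' equivalent to the same concentration of carbonate (per formula unit of
#' the 2:3 adduct as conventionally quoted, i.e. 1x) and 1.5x H2O2.  Used to
#' express an oxidative-stress dose in H2O2 terms.
#'
#' @param spc_concentration SPC concentration (any unit; typically uM).
#' @return list with `sodium_carbonate` and `h2o2` at 3 significant figures.
#' @examples
#' spc_equivalents(267)  # 267 uM carbonate, 400 uM H2O2
#' @export
spc_equivalents <- function(spc_concentration) {
  if (!is.numeric(spc_concentration) || any(spc_concentration < 0))
    stop("spc_concentration must be non-negative")
  list(sodium_carbonate = signif(spc_concentration, 3),
       h2o2 = signif(1.5 * spc_concentration, 3))
}
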