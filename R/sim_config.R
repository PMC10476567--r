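#' Configuration for the synthetic time-lapse generator
#'
#' Collects and validates every knob of the synthetic microscopy generator:
#' field and cohort size, acquisition timing, optics (Gaussian PSF width),
#' the two-term noise model (Poisson photon noise plus additive Gaussian read
#' noise on top of a constant camera offset), per-cell expression level, cell
#' geometry, and the intensity model of the death-dye channel.
#'
#' Defaults describe a cohort of 100 adherent cells followed for about 40 h
#' at one frame per 30 min -- the observation window over which survival
#' curves in this kind of experiment plateau.  All times are hours, all
#' lengths pixels, all intensities camera counts.
#'
#' @param n_cells number of cells to place (>= 0).
#' @param field_shape integer (height, width) of the field in pixels.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval hours between frames.
#' @param psf_sigma Gaussian PSF standard deviation in pixels (0 disables
#'   blurring).
#' @param gaussian_sd additive read-noise SD in counts (0 disables).
#' @param poisson_scale photons per count for Poisson noise (0 disables).
#' @param offset camera offset added to every pixel, counts.
#' @param expression_mean,expression_cv mean and coefficient of variation of
#'   the per-cell total reporter intensity (lognormal across cells).
#' @param cell_radius approximate cell semi-axis, pixels; actual semi-axes
#'   are drawn per cell around this value.
#' @param roi_margin margin in pixels added around the cell footprint when
#'   building the labelled ROI masks (emulates a loose, manually drawn ROI
#'   that contains some background).
#' @param mito_area_frac target fraction of the non-nuclear cytoplasm covered
#'   by the mitochondrial network.
#' @param mito_gain per-pixel brightness of the mitochondria channel, counts.
#' @param texture_cv lognormal coefficient of variation of within-compartment
#'   intensity texture.
#' @param drift_sd per-frame SD of the whole-cell random drift, pixels.
#' @param death_shrink linear shrink factor applied to the cell footprint
#'   after death (apoptotic body contraction).
#' @param dye_plateau plateau amplitude of the death-dye signal, counts.
#' @param dye_tau time constant (hours) of the sigmoidal dye rise; small
#'   values give an essentially step-like rise.
#' @param f_mito_mix parameters of the across-cell mixture for the latent
#'   mitochondrial fraction: list with `w_high` (weight of the
#'   high-accumulation mode) and Beta shape pairs `low` and `high`.
#' @param seed integer seed making the whole simulation reproducible.
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [fate_model()], [simulate_experiment()]
#' @export
sim_config <- function(n_cells = 100L,
                       field_shape = c(360L, 360L),
                       n_frames = 80L,
                       frame_interval = 0.5,
                       psf_sigma = 1.2,
                       gaussian_sd = 3,
                       poisson_scale = 1,
                       offset = 100,
                       expression_mean = 6e4,
                       expression_cv = 0.25,
                       cell_radius = 11,
                       roi_margin = 5,
                       mito_area_frac = 0.3,
                       mito_gain = 120,
                       texture_cv = 0.6,
                       drift_sd = 0.35,
                       death_shrink = 0.6,
                       dye_plateau = 600,
                       dye_tau = 0.08,
                       f_mito_mix = list(w_high = 0.45,
                                         low = c(8, 12),
                                         high = c(18, 8)),
                       seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells),
              field_shape = as.integer(field_shape),
              n_frames = as.integer(n_frames),
              frame_interval = frame_interval,
              psf_sigma = psf_sigma,
              gaussian_sd = gaussian_sd,
              poisson_scale = poisson_scale,
              offset = offset,
              expression_mean = expression_mean,
              expression_cv = expression_cv,
              cell_radius = cell_radius,
              roi_margin = roi_margin,
              mito_area_frac = mito_area_frac,
              mito_gain = mito_gain,
              texture_cv = texture_cv,
              drift_sd = drift_sd,
              death_shrink = death_shrink,
              dye_plateau = dye_plateau,
              dye_tau = dye_tau,
              f_mito_mix = f_mito_mix,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cells >= 0,
            length(cfg$field_shape) == 2, all(cfg$field_shape >= 8),
            cfg$n_frames >= 2,
            cfg$frame_interval > 0,
            cfg$psf_sigma >= 0,
            cfg$gaussian_sd >= 0,
            cfg$poisson_scale >= 0,
            cfg$expression_mean > 0, cfg$expression_cv >= 0,
            cfg$cell_radius >= 3,
            cfg$mito_area_frac > 0, cfg$mito_area_frac < 1,
            cfg$texture_cv >= 0,
            cfg$drift_sd >= 0,
            cfg$death_shrink > 0, cfg$death_shrink <= 1,
            cfg$dye_plateau > 0, cfg$dye_tau > 0)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic time-lapse configuration\n")
  cat(sprintf("  cells: %d on a %d x %d px field\n",
              x$n_cells, x$field_shape[1], x$field_shape[2]))
  cat(sprintf("  frames: %d every %.2g h (%.3g h total)\n",
              x$n_frames, x$frame_interval,
              (x$n_frames - 1) * x$frame_interval))
  cat(sprintf("  optics: psf sigma %.2g px; noise: read sd %.3g, poisson scale %.3g, offset %.3g\n",
              x$psf_sigma, x$gaussian_sd, x$poisson_scale, x$offset))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Per-cell fate model linking mitochondrial accumulation to death
#'
#' Encodes the cell-fate structure recovered by the tracking analysis: cells
#' whose latent mitochondrial fraction of the reporter is at or above
#' `f_high_threshold` die with probability `p_death_high` (1 by default --
#' high accumulation predetermines death), cells below it die with
#' probability `p_death_low`.  Among dying cells the time until death grows
#' linearly with the mitochondrial fraction (`delay_base + delay_slope * f`,
#' Gaussian jitter `delay_sd`), so that high-accumulation cells die late: a
#' positive correlation between initial colocalization and time-to-death.
#'
#' The `mutant_fate_model()` preset describes the mutant-like condition:
#' higher survival in the low-accumulation class and `delay_slope = 0`
#' exactly, i.e. no correlation between accumulation and timing.
#'
#' @param f_high_threshold latent-fraction cut for the high class, in [0,1].
#' @param p_death_high,p_death_low death probabilities for the two classes.
#' @param delay_base hours; expected time-to-death at fraction 0.
#' @param delay_slope hours per unit fraction.
#' @param delay_sd hours; SD of the timing jitter.
#' @param condition_label free-text condition name.
#' @return an object of class `fate_model`.
#' @export
fate_model <- function(f_high_threshold = 0.6,
                       p_death_high = 1,
                       p_death_low = 0.9,
                       delay_base = 5,
                       delay_slope = 25,
                       delay_sd = 4,
                       condition_label = "WT-like") {
  stopifnot(f_high_threshold >= 0, f_high_threshold <= 1,
            p_death_high >= 0, p_death_high <= 1,
            p_death_low >= 0, p_death_low <= 1,
            delay_sd >= 0)
  structure(list(f_high_threshold = f_high_threshold,
                 p_death_high = p_death_high,
                 p_death_low = p_death_low,
                 delay_base = delay_base,
                 delay_slope = delay_slope,
                 delay_sd = delay_sd,
                 condition_label = condition_label),
            class = "fate_model")
}

#' @rdname fate_model
#' @export
mutant_fate_model <- function(p_death_low = 0.75,
                              condition_label = "mutant-like") {
  fate_model(p_death_high = 1, p_death_low = p_death_low,
             delay_base = 21, delay_slope = 0, delay_sd = 5,
             condition_label = condition_label)
}

#' @rdname fate_model
#' @export
control_fate_model <- function(condition_label = "no-stress control") {
  fate_model(p_death_high = 0, p_death_low = 0,
             condition_label = condition_label)
}

#' @export
print.fate_model <- function(x, ...) {
  cat(sprintf("Fate model [%s]\n", x$condition_label))
  cat(sprintf("  death prob: %.3g (f >= %.2f) / %.3g (below)\n",
              x$p_death_high, x$f_high_threshold, x$p_death_low))
  cat(sprintf("  time-to-death: %.3g + %.3g * f  (sd %.3g h)\n",
              x$delay_base, x$delay_slope, x$delay_sd))
  invisible(x)
}
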