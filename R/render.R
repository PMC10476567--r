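# Rendering: noise-free per-cell intensity tiles, separable Gaussian blur,
# and the camera noise model.  Blur is applied once per (cell, channel) tile;
# whole-cell drift uses integer translations, so a blurred tile can be reused
# across frames.

# Separable Gaussian blur by two banded matrix products.  The kernel is
# normalized over its full support, so mass is conserved as long as signal
# stays >= ~3 sigma away from the tile edge (tiles are padded accordingly).
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  n <- nrow(m)
  stopifnot(ncol(m) == n)
  half <- as.integer(ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    d <- j - i
    out <- numeric(length(d))
    inside <- abs(d) <= half
    out[inside] <- k[d[inside] + half + 1L]
    out
  })
  K %*% m %*% t(K)
}

# lognormal texture with mean 1 and the configured CV
texture_field <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Render the reporter channel for one cell
#'
#' Distributes a cell's total reporter intensity over its compartments so
#' that, before blurring and noise, exactly `f_mito` of the intensity mass
#' lies on the mitochondrial mask and the remainder on the rest of the
#' cytoplasm (nucleus included).  Each compartment carries multiplicative
#' lognormal texture.  The tile is then blurred with the configured PSF.
#'
#' @param geometry a [make_cell_geometry()] result.
#' @param f_mito fraction of reporter mass on mitochondria, in [0,1].
#' @param expression total reporter intensity mass (counts).
#' @param config a [sim_config()].
#' @param blur apply the Gaussian PSF (set FALSE to inspect the raw mass
#'   allocation).
#' @return numeric tile matrix of noise-free intensities (no offset).
#' @export
render_reporter_channel <- function(geometry, f_mito, expression, config,
                                    blur = TRUE) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (!is.finite(f_mito) || f_mito < 0 || f_mito > 1)
    stop("f_mito must lie in [0, 1]")
  tile <- geometry$tile
  img <- matrix(0, tile, tile)
  mito_px <- which(geometry$mito)
  rest_px <- which(geometry$cytoplasm & !geometry$mito)
  if (length(mito_px) && f_mito > 0) {
    w <- texture_field(length(mito_px), config$texture_cv)
    img[mito_px] <- w / sum(w) * (f_mito * expression)
  }
  if (length(rest_px) && f_mito < 1) {
    w <- texture_field(length(rest_px), config$texture_cv)
    img[rest_px] <- w / sum(w) * ((1 - f_mito) * expression)
  }
  if (blur) img <- gauss_blur(img, config$psf_sigma)
  img
}

# mitochondria channel: constant gain times texture on the network
render_mito_channel <- function(geometry, config, blur = TRUE) {
  tile <- geometry$tile
  img <- matrix(0, tile, tile)
  px <- which(geometry$mito)
  if (length(px))
    img[px] <- config$mito_gain * texture_field(length(px), config$texture_cv)
  if (blur) img <- gauss_blur(img, config$psf_sigma)
  img
}

# death-dye nuclear template (unit amplitude); scaled per frame by dye_amplitude
render_dye_template <- function(geometry, config, blur = TRUE) {
  tile <- geometry$tile
  img <- matrix(0, tile, tile)
  px <- which(geometry$nucleus)
  if (length(px))
    img[px] <- texture_field(length(px), config$texture_cv / 2) # tighter: dye fills nucleus
  if (blur) img <- gauss_blur(img, config$psf_sigma)
  img
}

# sigmoidal dye amplitude at times t (hours) for a cell dying at death_time;
# survivors (death_time = NA) stay at zero
dye_amplitude <- function(t, death_time, config) {
  if (is.na(death_time)) return(numeric(length(t)))
  config$dye_plateau / (1 + exp(-(t - death_time) / config$dye_tau))
}

#' Simulate a death-dye intensity trace for one cell
#'
#' Produces the per-frame maximum dye intensity over a cell ROI: Gaussian
#' baseline noise around the camera offset before the death time, then a
#' steep sigmoidal rise to a plateau far above baseline.  Survivors
#' (`death_time = NA`) stay at baseline throughout.
#'
#' @param death_time hours, or NA for a survivor; must be >= 0.
#' @param config a [sim_config()].
#' @param n_noise_px effective number of ROI pixels over which the per-frame
#'   maximum of the baseline noise is taken.
#' @return numeric vector of length `config$n_frames`.
#' @export
render_death_dye <- function(death_time, config, n_noise_px = 400L) {
  if (!is.na(death_time) && death_time < 0)
    stop("death_time must be >= 0 or NA")
  t <- frame_times(config)
  base_sd <- max(config$gaussian_sd,
                 if (config$poisson_scale > 0)
                   sqrt(config$offset / config$poisson_scale) else 0)
  noise_max <- vapply(seq_along(t), function(i)
    max(stats::rnorm(n_noise_px, 0, base_sd)), numeric(1))
  config$offset + noise_max + dye_amplitude(t, death_time, config)
}

# acquisition times of the frames, hours; frame 1 is t = 0
frame_times <- function(config) {
  (seq_len(config$n_frames) - 1) * config$frame_interval
}
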