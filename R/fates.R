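#' Sample per-cell fates from a fate model
#'
#' Cells with latent mitochondrial fraction at or above the model's
#' `f_high_threshold` die with probability `p_death_high`, the rest with
#' `p_death_low`.  Dying cells get a death time of
#' `delay_base + delay_slope * f_mito` plus Gaussian jitter, truncated to
#' the observation window `[0, t_max]`.
#'
#' @param f_mito numeric vector of latent fractions in [0,1].
#' @param model a [fate_model()].
#' @param t_max end of the observation window, hours.
#' @param seed optional integer seed.
#' @return numeric vector of death times (hours); NA marks survivors.
#' @export
sample_fates <- function(f_mito, model, t_max = Inf, seed = NULL) {
  stopifnot(inherits(model, "fate_model"),
            all(f_mito >= 0 & f_mito <= 1))
  with_seed(seed, {
    high <- f_mito >= model$f_high_threshold
    p <- ifelse(high, model$p_death_high, model$p_death_low)
    dies <- stats::runif(length(f_mito)) < p
    dt <- rep(NA_real_, length(f_mito))
    n_d <- sum(dies)
    if (n_d) {
      dt[dies] <- model$delay_base + model$delay_slope * f_mito[dies] +
        stats::rnorm(n_d, 0, model$delay_sd)
      dt[dies] <- pmin(pmax(dt[dies], 0), t_max)
    }
    dt
  })
}
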