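#' Otsu threshold of a set of intensities
#'
#' Classic histogram thresholding: the intensities are binned into a fixed
#' 256-bin histogram spanning their observed range (regardless of bit
#' depth), and the threshold maximizing the between-class variance is
#' returned.  Ties are broken toward the lower threshold.  Pixels strictly
#' above the returned value form the foreground class.
#'
#' @param intensities numeric vector (one cell ROI, one channel, one frame).
#' @param n_bins histogram resolution.
#' @return the threshold, on the intensity scale of the input.
#' @examples
#' otsu_threshold(c(0, 0, 0, 10, 10, 10))   # strictly between 0 and 10
#' @export
otsu_threshold <- function(intensities, n_bins = 256L) {
  x <- intensities[is.finite(intensities)]
  if (length(x) < 2L)
    stop("otsu_threshold needs at least 2 finite intensities")
  r <- range(x)
  if (r[1] == r[2])
    stop("degenerate input: all intensities identical")
  width <- diff(r)
  idx <- pmin(n_bins, 1L + as.integer(floor((x - r[1]) / width * n_bins)))
  h <- tabulate(idx, n_bins)
  p <- h / length(x)
  w <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb <- (mu_t * w - mu)^2 / (w * (1 - w))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)            # first maximum = lowest threshold on ties
  r[1] + k / n_bins * width     # upper edge of bin k
}
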