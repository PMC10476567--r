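# Population-level views of the per-cell MCC series: death-aligned pooling,
# kernel density of pooled MCC values, high/low splitting on the initial
# MCC, initial-MCC vs time-to-death correlation, per-cell slope fits.

# per-cell smoothed (block-mean) series with block-centre times
smooth_tracks <- function(mcc_df, window = 5L) {
  fi <- attr(mcc_df, "frame_interval")
  if (is.null(fi)) fi <- diff(sort(unique(mcc_df$time_h)))[1]
  out <- lapply(split(mcc_df, mcc_df$cell_id), function(d) {
    d <- d[order(d$frame), ]
    s <- block_mean(d$mcc, window)
    blk <- (seq_len(nrow(d)) - 1L) %/% as.integer(window)
    t_blk <- as.numeric(tapply(d$time_h, blk, mean))
    data.frame(cell_id = d$cell_id[1], block = seq_along(s),
               time_h = t_blk, mcc_smoothed = s)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "window") <- window
  res
}

#' Death-aligned pooling of smoothed MCC series
#'
#' Splits cells into surviving and dead groups.  Dead cells keep only the
#' smoothed blocks up to their death and are re-timed so that their last
#' retained point sits at t = 0 (the moment of death); survivors keep the
#' acquisition clock (t = 0 at observation start).  All defined smoothed
#' values are also pooled per group for histogram / KDE display.
#'
#' @param mcc_df a [mcc_timecourse()] data frame.
#' @param calls a [call_deaths()] data frame covering every cell in
#'   `mcc_df`.
#' @param window smoothing window (frames).
#' @return list of class `aligned_mcc_pool` with elements `surviving` and
#'   `dead`, each a list of `series` (data frame cell_id, t_aligned,
#'   mcc_smoothed) and `pooled` (numeric vector).
#' @export
align_and_pool <- function(mcc_df, calls, window = 5L) {
  sm <- smooth_tracks(mcc_df, window)
  miss <- setdiff(unique(sm$cell_id), calls$cell_id)
  if (length(miss))
    stop(sprintf("no fate call for cell(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  fate <- calls[match(sm$cell_id, calls$cell_id), ]
  is_dead <- fate$status == "dead"
  surv <- sm[!is_dead, , drop = FALSE]
  surv$t_aligned <- surv$time_h
  dead <- sm[is_dead, , drop = FALSE]
  dead$death_time_h <- fate$death_time_h[is_dead]
  dead <- dead[dead$time_h <= dead$death_time_h + 1e-9, , drop = FALSE]
  if (nrow(dead)) {
    last_t <- tapply(dead$time_h, dead$cell_id, max)
    dead$t_aligned <- dead$time_h - as.numeric(last_t[as.character(dead$cell_id)])
  } else dead$t_aligned <- numeric(0)
  keep <- c("cell_id", "t_aligned", "mcc_smoothed")
  structure(list(
    surviving = list(series = surv[, keep],
                     pooled = surv$mcc_smoothed[!is.na(surv$mcc_smoothed)]),
    dead = list(series = dead[, keep],
                pooled = dead$mcc_smoothed[!is.na(dead$mcc_smoothed)])),
    class = "aligned_mcc_pool")
}

#' Gaussian kernel density of MCC values
#'
#' Scott's bandwidth rule (`sd(x) * n^(-1/5)`) by default; the density is
#' evaluated on a grid extended 3 bandwidths beyond the data so that it
#' integrates to 1.
#'
#' @param values numeric vector (>= 2 values).
#' @param bw bandwidth: "scott" or a positive number.
#' @param n_grid grid resolution.
#' @return data frame with `x` and `density`; bandwidth in attribute "bw".
#' @export
mcc_kde <- function(values, bw = "scott", n_grid = 512L) {
  x <- values[is.finite(values)]
  if (length(x) < 2L) stop("need at least 2 values for a density estimate")
  h <- if (identical(bw, "scott")) stats::sd(x) * length(x)^(-1 / 5)
  else as.numeric(bw)
  if (!is.finite(h) || h <= 0)
    stop("degenerate bandwidth (constant values?)")
  d <- stats::density(x, bw = h, n = n_grid, cut = 3)
  out <- data.frame(x = d$x, density = d$y)
  attr(out, "bw") <- h
  out
}

#' Split cells into high / low initial-MCC classes and tabulate survival
#'
#' Class is `high` iff the initial smoothed MCC is strictly above the
#' threshold (0.60 by default).  Reports per-class cell counts and survival
#' percentages; when replicate labels are given, also the replicate-wise
#' mean +/- SEM of the survival percentage.
#'
#' @param initial_mcc numeric vector, one value per cell.
#' @param calls a [call_deaths()] data frame aligned with `initial_mcc`
#'   (same cells, same order), or a character vector of statuses.
#' @param threshold class boundary.
#' @param replicate optional replicate labels, one per cell.
#' @return object of class `mcc_split`: per-class data frame `summary`
#'   (class, n, n_surviving, pct_surviving, mean_pct, sem_pct) and the
#'   per-cell `class` vector.
#' @export
split_by_threshold <- function(initial_mcc, calls, threshold = 0.60,
                               replicate = NULL) {
  status <- if (is.data.frame(calls)) calls$status else as.character(calls)
  stopifnot(length(status) == length(initial_mcc))
  cls <- ifelse(initial_mcc > threshold, "high", "low")
  surv <- status == "surviving"
  if (is.null(replicate)) replicate <- rep(1L, length(cls))
  per_class <- lapply(c("high", "low"), function(cl) {
    i <- cls == cl
    n <- sum(i)
    ns <- sum(surv & i)
    rep_pct <- if (n) tapply(surv[i], replicate[i], function(v)
      100 * mean(v)) else numeric(0)
    data.frame(class = cl, n = n, n_surviving = ns,
               pct_surviving = if (n) 100 * ns / n else NA_real_,
               mean_pct = if (length(rep_pct)) mean(rep_pct) else NA_real_,
               sem_pct = if (length(rep_pct) > 1)
                 stats::sd(rep_pct) / sqrt(length(rep_pct)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, per_class),
                 class = cls, threshold = threshold),
            class = "mcc_split")
}

#' @export
print.mcc_split <- function(x, ...) {
  cat(sprintf("Initial-MCC split at %.2f\n", x$threshold))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Correlation and regression of initial MCC against time until death
#'
#' Pearson r is computed per replicate and summarized as mean +/- SEM across
#' replicates; an ordinary least-squares line is fitted to the pooled dead
#' cells, with a 95% confidence band (+/- 1.96 standard errors of the mean
#' prediction).
#'
#' @param initial_mcc,time_to_death numeric vectors over dead cells.
#' @param replicate replicate labels (>= 2 replicates for an SEM).
#' @param conf_mult multiplier for the confidence band.
#' @return object of class `mcc_correlation`: per-replicate r, mean_r,
#'   sem_r, pooled slope/intercept, and a `band` data frame (x, fit, lower,
#'   upper).
#' @export
correlate_initial_mcc_vs_death_time <- function(initial_mcc, time_to_death,
                                                replicate = NULL,
                                                conf_mult = 1.96) {
  stopifnot(length(initial_mcc) == length(time_to_death))
  ok <- is.finite(initial_mcc) & is.finite(time_to_death)
  x <- initial_mcc[ok]; y <- time_to_death[ok]
  if (is.null(replicate)) replicate <- rep(1L, length(initial_mcc))
  rep_ok <- replicate[ok]
  r_by_rep <- vapply(split(seq_along(x), rep_ok), function(i) {
    if (length(i) < 3 || stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0)
      return(NA_real_)
    stats::cor(x[i], y[i])
  }, numeric(1))
  if (anyNA(r_by_rep))
    warning("replicate(s) with < 3 cells or zero variance excluded from r")
  r_def <- r_by_rep[!is.na(r_by_rep)]
  fit <- stats::lm(y ~ x)
  grid <- seq(min(x), max(x), length.out = 100)
  pr <- stats::predict(fit, newdata = data.frame(x = grid), se.fit = TRUE)
  structure(list(
    r_by_replicate = r_by_rep,
    mean_r = if (length(r_def)) mean(r_def) else NA_real_,
    sem_r = if (length(r_def) > 1) stats::sd(r_def) / sqrt(length(r_def))
    else NA_real_,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = length(x),
    band = data.frame(x = grid, fit = pr$fit,
                      lower = pr$fit - conf_mult * pr$se.fit,
                      upper = pr$fit + conf_mult * pr$se.fit)),
    class = "mcc_correlation")
}

#' @export
print.mcc_correlation <- function(x, ...) {
  cat(sprintf("Initial MCC vs time-to-death (n = %d dead cells)\n", x$n))
  cat(sprintf("  Pearson r: %.3f +/- %.3f (mean +/- SEM over %d replicate(s))\n",
              x$mean_r, ifelse(is.na(x$sem_r), 0, x$sem_r),
              sum(!is.na(x$r_by_replicate))))
  cat(sprintf("  OLS: time = %.2f + %.2f * MCC\n", x$intercept, x$slope))
  invisible(x)
}

#' Least-squares slope of a smoothed MCC series over time
#'
#' Used to ask whether a cell's localization changes after stress: a slope
#' whose confidence interval covers 0 is "unchanged localization".
#'
#' @param time_h,mcc numeric vectors (>= 2 defined points).
#' @param conf_mult CI multiplier (1.96 for 95%).
#' @return list of class `slope_fit`: slope (per hour), intercept,
#'   slope_se, ci (length 2), covers_zero.
#' @export
fit_mcc_slope <- function(time_h, mcc, conf_mult = 1.96) {
  ok <- is.finite(time_h) & is.finite(mcc)
  if (sum(ok) < 2L) stop("need at least 2 defined points")
  fit <- stats::lm(mcc[ok] ~ time_h[ok])
  # summary() warns on an exactly collinear fit (e.g. a constant series);
  # that case is legitimate here and handled below
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- co[2, 1]
  se <- if (nrow(co) >= 2 && ncol(co) >= 2) co[2, 2] else NA_real_
  if (!is.finite(se)) se <- 0   # exactly collinear (e.g. 2 points): slope exact
  ci <- slope + c(-1, 1) * conf_mult * se
  structure(list(slope = slope, intercept = co[1, 1], slope_se = se,
                 ci = ci, covers_zero = ci[1] <= 0 && ci[2] >= 0),
            class = "slope_fit")
}
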