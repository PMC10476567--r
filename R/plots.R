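# Publication-style base-graphics views of the pipeline outputs.

#' Plot survival curves
#'
#' @param tables named list of [survival_curve()] tables.
#' @param normalized plot the control-normalized percentage if present.
#' @export
plot_survival_curves <- function(tables, normalized = FALSE) {
  if (inherits(tables, "survival_table")) tables <- list(tables)
  ycol <- if (normalized) "normalized_pct" else "fraction"
  ymax <- if (normalized) 110 else 1.02
  cols <- grDevices::hcl.colors(max(3, length(tables)), "Dark 3")
  graphics::plot(NULL, xlim = range(tables[[1]]$time_h), ylim = c(0, ymax),
                 xlab = "time (h)",
                 ylab = if (normalized) "dye-negative cells (% of control)"
                 else "fraction dye-negative")
  for (i in seq_along(tables))
    graphics::lines(tables[[i]]$time_h, tables[[i]][[ycol]],
                    col = cols[i], lwd = 2, type = "s")
  if (!is.null(names(tables)))
    graphics::legend("bottomleft", legend = names(tables),
                     col = cols[seq_along(tables)], lwd = 2, bty = "n")
  invisible(NULL)
}

#' Plot death-aligned smoothed MCC traces with a pooled density margin
#'
#' Dead cells on a death-aligned axis (0 = moment of death), survivors on
#' the acquisition clock; the pooled MCC density of each group is drawn in
#' the right margin.
#'
#' @param pool an [align_and_pool()] result.
#' @param threshold optional horizontal class boundary to draw.
#' @export
plot_aligned_mcc <- function(pool, threshold = NULL) {
  stopifnot(inherits(pool, "aligned_mcc_pool"))
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (grp in c("dead", "surviving")) {
    s <- pool[[grp]]$series
    graphics::plot(NULL,
                   xlim = if (nrow(s)) range(s$t_aligned) else c(-1, 1),
                   ylim = c(0, 1),
                   xlab = if (grp == "dead") "time before death (h)"
                   else "time (h)",
                   ylab = "MCC (5-frame mean)", main = grp)
    for (d in split(s, s$cell_id))
      graphics::lines(d$t_aligned, d$mcc_smoothed,
                      col = grDevices::adjustcolor("grey30", 0.4))
    if (length(pool[[grp]]$pooled) >= 2) {
      k <- mcc_kde(pool[[grp]]$pooled)
      xr <- graphics::par("usr")[1:2]
      graphics::lines(xr[2] - 0.15 * diff(xr) * k$density /
                        max(k$density), k$x, col = "steelblue")
    }
    if (!is.null(threshold))
      graphics::abline(h = threshold, col = "red", lty = 2)
  }
  invisible(NULL)
}

#' Scatter of initial MCC versus time until death with regression band
#'
#' @param initial_mcc,time_to_death dead-cell vectors.
#' @param corr a [correlate_initial_mcc_vs_death_time()] result (computed
#'   from the data if NULL).
#' @export
plot_mcc_scatter <- function(initial_mcc, time_to_death, corr = NULL) {
  if (is.null(corr))
    corr <- correlate_initial_mcc_vs_death_time(initial_mcc, time_to_death)
  graphics::plot(initial_mcc, time_to_death, pch = 19,
                 col = grDevices::adjustcolor("grey20", 0.6),
                 xlab = "initial MCC", ylab = "time until death (h)")
  graphics::polygon(c(corr$band$x, rev(corr$band$x)),
                    c(corr$band$lower, rev(corr$band$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(corr$band$x, corr$band$fit, col = "steelblue", lwd = 2)
  graphics::mtext(sprintf("r = %.2f", corr$mean_r), side = 3, adj = 1)
  invisible(NULL)
}
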