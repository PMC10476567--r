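# Dye-based death calling: control-derived intensity thresholds, per-cell
# threshold-crossing calls, survival tables and their control normalization.

#' Derive a death-calling threshold from negative-control traces
#'
#' Pools the per-frame maximum dye intensities of negative-control cells
#' across cells and frames and sets the threshold to `mean + k * SD`.
#' The conventional multipliers are k = 10 for endpoint imaging and k = 5
#' for tracking mode.
#'
#' @param control_traces either a numeric vector of pooled control
#'   intensities, a list of per-cell numeric traces, or a data frame with a
#'   `dye_max` column (as from [extract_traces()]).
#' @param k SD multiplier (> 0).
#' @return object of class `death_threshold`: baseline_mean, baseline_sd,
#'   k, threshold.
#' @export
derive_threshold <- function(control_traces, k = 5) {
  stopifnot(k > 0)
  x <- if (is.data.frame(control_traces)) {
    if (!"dye_max" %in% names(control_traces))
      stop("control trace data frame needs a 'dye_max' column")
    if (!is.null(control_traces$cell_id) &&
        length(unique(control_traces$cell_id)) < 2L)
      stop("need at least 2 control cells")
    control_traces$dye_max
  } else if (is.list(control_traces)) {
    if (length(control_traces) < 2L) stop("need at least 2 control cells")
    unlist(control_traces, use.names = FALSE)
  } else as.numeric(control_traces)
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("no usable control intensities")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) warning("control traces have zero variance; threshold = mean")
  structure(list(baseline_mean = m, baseline_sd = s, k = k,
                 threshold = m + k * s),
            class = "death_threshold")
}

#' @export
print.death_threshold <- function(x, ...) {
  cat(sprintf("Death threshold: %.4g  (baseline %.4g +/- %.4g, k = %g)\n",
              x$threshold, x$baseline_mean, x$baseline_sd, x$k))
  invisible(x)
}

#' Call death from a single dye trace
#'
#' A cell is called dead at the first frame where the dye intensity exceeds
#' the threshold for `persistence` consecutive frames; a trace that never
#' crosses is a survivor.
#'
#' @param trace numeric per-frame dye intensities (frame 1 = t 0).
#' @param threshold a [derive_threshold()] object or a plain number.
#' @param persistence consecutive frames required above threshold.
#' @param frame_interval hours between frames.
#' @return list of class `fate_call`: status ("dead"/"surviving"),
#'   death_frame, death_time_h (NA for survivors).
#' @export
call_death <- function(trace, threshold, persistence = 1L,
                       frame_interval = 0.5) {
  stopifnot(length(trace) >= 1, persistence >= 1)
  thr <- if (inherits(threshold, "death_threshold"))
    threshold$threshold else as.numeric(threshold)
  above <- trace > thr
  death_frame <- NA_integer_
  if (any(above)) {
    run <- rle(above)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    hit <- which(run$values & run$lengths >= persistence)
    if (length(hit)) death_frame <- starts[hit[1]]
  }
  structure(list(status = if (is.na(death_frame)) "surviving" else "dead",
                 death_frame = death_frame,
                 death_time_h = if (is.na(death_frame)) NA_real_
                 else (death_frame - 1L) * frame_interval),
            class = "fate_call")
}

#' Call death for every cell in a trace table
#'
#' @param traces data frame with cell_id, frame, dye_max (and optionally
#'   time_h), as produced by [extract_traces()].
#' @param threshold a [derive_threshold()] object or number.
#' @param persistence,frame_interval see [call_death()].
#' @return data frame of class `fate_calls`: cell_id, status, death_frame,
#'   death_time_h.
#' @export
call_deaths <- function(traces, threshold, persistence = 1L,
                        frame_interval = 0.5) {
  stopifnot(all(c("cell_id", "frame", "dye_max") %in% names(traces)))
  traces <- traces[order(traces$cell_id, traces$frame), ]
  calls <- lapply(split(traces$dye_max, traces$cell_id), call_death,
                  threshold = threshold, persistence = persistence,
                  frame_interval = frame_interval)
  out <- data.frame(cell_id = as.integer(names(calls)),
                    status = vapply(calls, `[[`, "", "status"),
                    death_frame = vapply(calls, function(c)
                      as.integer(c$death_frame), integer(1)),
                    death_time_h = vapply(calls, `[[`, numeric(1),
                                          "death_time_h"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fate_calls", "data.frame")
  out
}

#' Survival table from fate calls
#'
#' Fraction of cells not yet dye-positive at each requested time.  Cells
#' never crossing the threshold count as surviving through the end of the
#' window (right censoring at window end).  If a `censor_time_h` column is
#' present, cells leaving the field are removed from the at-risk set from
#' their exit time on (Kaplan-Meier product-limit estimate); without
#' censoring this reduces to the simple empirical fraction.
#'
#' @param calls a [call_deaths()] data frame (optionally with
#'   `censor_time_h`).
#' @param times numeric time grid, hours.
#' @param condition optional condition label stored in the result.
#' @param replicate optional replicate id stored in the result.
#' @return data frame of class `survival_table`: condition, replicate,
#'   time_h, fraction, n_at_risk, n_cells.
#' @export
survival_curve <- function(calls, times, condition = "cohort",
                           replicate = 1L) {
  if (nrow(calls) == 0L) stop("empty cohort")
  dt <- calls$death_time_h
  cens <- if ("censor_time_h" %in% names(calls)) calls$censor_time_h
  else rep(NA_real_, nrow(calls))
  has_cens <- any(is.finite(cens))
  frac <- if (!has_cens) {
    vapply(times, function(t) mean(!(is.finite(dt) & dt <= t)), numeric(1))
  } else {
    obs_t <- ifelse(is.finite(dt), dt, cens)
    obs_t[!is.finite(obs_t)] <- Inf
    event <- is.finite(dt)
    ut <- sort(unique(obs_t[event]))
    km <- 1
    km_step <- vapply(ut, function(u) {
      at_risk <- sum(obs_t >= u)
      d <- sum(event & obs_t == u)
      km <<- km * (1 - d / at_risk)
      km
    }, numeric(1))
    vapply(times, function(t) {
      i <- findInterval(t, ut)
      if (i == 0) 1 else km_step[i]
    }, numeric(1))
  }
  at_risk <- vapply(times, function(t)
    sum((!is.finite(dt) | dt > t) & (!is.finite(cens) | cens > t)),
    numeric(1))
  out <- data.frame(condition = condition, replicate = replicate,
                    time_h = times, fraction = frac,
                    n_at_risk = at_risk, n_cells = nrow(calls),
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_table", "data.frame")
  out
}

# interpolate a survival table's fraction onto times
interp_fraction <- function(tab, times) {
  stats::approx(tab$time_h, tab$fraction, xout = times, rule = 2)$y
}

#' Normalize a survival table to a no-stress control
#'
#' `normalized(t) = 100 * raw_stress(t) / raw_control(t)`, the convention
#' used to report dye-negative percentages relative to unstressed control
#' experiments.  Grids are aligned by linear interpolation; points where
#' the control fraction is 0 are undefined (NA, with a warning).
#'
#' @param stress,control [survival_curve()] tables.
#' @return the stress table with an extra `normalized_pct` column.
#' @export
normalize_to_control <- function(stress, control) {
  ctrl <- interp_fraction(control, stress$time_h)
  bad <- ctrl == 0
  if (any(bad))
    warning(sprintf("control fraction is 0 at %d time(s); normalized value undefined",
                    sum(bad)))
  out <- stress
  out$normalized_pct <- ifelse(bad, NA_real_,
                               100 * stress$fraction / ctrl)
  out
}

#' Relative viability between paired (inhibitor / no-inhibitor) experiments
#'
#' Ratio of the control-normalized survival percentage with an inhibitor to
#' the one without, evaluated at `t_eval`:
#' `ratio_pct = 100 * with(t) / without(t)`; the reported "increase" is
#' `ratio_pct - 100`.
#'
#' @param with_inhibitor,without_inhibitor survival tables carrying a
#'   `normalized_pct` column (see [normalize_to_control()]).
#' @param t_eval evaluation time, hours.
#' @return list with `ratio_pct` and `increase_pct`.
#' @export
relative_viability <- function(with_inhibitor, without_inhibitor,
                               t_eval = 40) {
  stopifnot("normalized_pct" %in% names(with_inhibitor),
            "normalized_pct" %in% names(without_inhibitor))
  w <- stats::approx(with_inhibitor$time_h, with_inhibitor$normalized_pct,
                     xout = t_eval, rule = 2)$y
  wo <- stats::approx(without_inhibitor$time_h,
                      without_inhibitor$normalized_pct,
                      xout = t_eval, rule = 2)$y
  if (!is.finite(wo) || wo == 0)
    return(list(ratio_pct = NA_real_, increase_pct = NA_real_))
  r <- 100 * w / wo
  list(ratio_pct = r, increase_pct = r - 100)
}
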