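# Thresholded Manders colocalization.  The M1 coefficient used throughout
# is the fraction of above-threshold reporter intensity that falls on
# pixels where the mitochondria channel is positive:
#   MCC = sum_i T_i,colocal / sum_i T_i,   T_i,colocal = T_i if M_i > 0 else 0
# with the sums running over reporter pixels above the reporter's own Otsu
# threshold, and "M_i > 0" meaning above the mitochondria channel's Otsu
# threshold (default) or literally > 0 (mi_positive = "raw").

#' Manders M1 coefficient on one ROI
#'
#' @param tert reporter intensities, one value per ROI pixel.
#' @param mito mitochondria intensities on the same pixels, same order.
#' @param tert_mask,mito_mask logical masks ("above threshold") on the same
#'   pixels; if NULL they are derived with [otsu_threshold()].
#' @param mi_positive how "mitochondria positive" is defined when
#'   `mito_mask` is NULL: above the mitochondria Otsu threshold (`"otsu"`,
#'   default) or literally greater than zero (`"raw"`).
#' @return the coefficient in [0, 1], or NA if no reporter intensity is
#'   above threshold.
#' @examples
#' manders_m1(c(10, 20, 30), c(1, 0, 1),
#'            tert_mask = c(TRUE, TRUE, TRUE),
#'            mito_mask = c(TRUE, FALSE, TRUE))  # 40/60
#' @export
manders_m1 <- function(tert, mito, tert_mask = NULL, mito_mask = NULL,
                       mi_positive = c("otsu", "raw")) {
  mi_positive <- match.arg(mi_positive)
  if (length(tert) != length(mito))
    stop("reporter and mitochondria pixel sets differ in size")
  if (is.null(tert_mask))
    tert_mask <- tert > otsu_threshold(tert)
  if (is.null(mito_mask))
    mito_mask <- if (mi_positive == "otsu")
      mito > otsu_threshold(mito) else mito > 0
  if (length(tert_mask) != length(tert) || length(mito_mask) != length(tert))
    stop("masks must match the pixel set")
  denom <- sum(tert[tert_mask])
  if (denom <= 0) return(NA_real_)
  sum(tert[tert_mask & mito_mask]) / denom
}

# single-frame MCC with thresholds; returns NA mcc on degenerate input
mcc_frame <- function(tert, mito, mi_positive = "otsu") {
  thr_t <- tryCatch(otsu_threshold(tert), error = function(e) NA_real_)
  thr_m <- if (mi_positive == "otsu")
    tryCatch(otsu_threshold(mito), error = function(e) NA_real_)
  else 0
  if (is.na(thr_t) || is.na(thr_m))
    return(list(mcc = NA_real_, thr_t = thr_t, thr_m = thr_m,
                n_tert = NA_integer_, n_coloc = NA_integer_))
  tm <- tert > thr_t
  mm <- mito > thr_m
  denom <- sum(tert[tm])
  list(mcc = if (denom > 0) sum(tert[tm & mm]) / denom else NA_real_,
       thr_t = thr_t, thr_m = thr_m,
       n_tert = sum(tm), n_coloc = sum(tm & mm))
}

#' Per-cell, per-frame MCC time courses
#'
#' Runs Otsu thresholding and the Manders M1 computation on every (cell,
#' frame) pair defined by a labelled ROI stack.  Frames where a cell's ROI
#' is missing, or where thresholding is degenerate, are recorded with
#' `mcc = NA` rather than dropped.
#'
#' @param reporter,mito `H x W x n_frames` intensity arrays.
#' @param roi labelled ROI stack of the same shape (or one matrix recycled
#'   over frames); label 0 is background.
#' @param frame_interval hours between frames.
#' @param mi_positive see [manders_m1()].
#' @return data frame of class `mcc_timecourse`: cell_id, frame, time_h,
#'   mcc, thr_reporter, thr_mito, n_roi, n_reporter_mask, n_coloc.
#' @export
mcc_timecourse <- function(reporter, mito, roi, frame_interval = 0.5,
                           mi_positive = c("otsu", "raw")) {
  mi_positive <- match.arg(mi_positive)
  stopifnot(identical(dim(reporter), dim(mito)))
  dims <- dim(reporter)
  Fn <- dims[3]
  static_roi <- is.matrix(roi)
  if (!static_roi && !identical(dim(roi), dims))
    stop("ROI stack shape does not match the channel stacks")
  all_ids <- sort(setdiff(unique(as.integer(roi)), 0L))
  rows <- vector("list", Fn)
  n_gap <- 0L
  for (f in seq_len(Fn)) {
    lab <- if (static_roi) roi else roi[, , f]
    tv <- reporter[, , f]
    mv <- mito[, , f]
    keep <- lab != 0L
    labs <- lab[keep]
    split_idx <- split(seq_along(labs), labs)
    tvk <- tv[keep]; mvk <- mv[keep]
    res <- lapply(all_ids, function(id) {
      px <- split_idx[[as.character(id)]]
      if (is.null(px)) {
        n_gap <<- n_gap + 1L
        return(data.frame(cell_id = id, frame = f,
                          time_h = (f - 1) * frame_interval,
                          mcc = NA_real_, thr_reporter = NA_real_,
                          thr_mito = NA_real_, n_roi = 0L,
                          n_reporter_mask = NA_integer_,
                          n_coloc = NA_integer_))
      }
      r <- mcc_frame(tvk[px], mvk[px], mi_positive)
      data.frame(cell_id = id, frame = f,
                 time_h = (f - 1) * frame_interval,
                 mcc = r$mcc, thr_reporter = r$thr_t, thr_mito = r$thr_m,
                 n_roi = length(px), n_reporter_mask = r$n_tert,
                 n_coloc = r$n_coloc)
    })
    rows[[f]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  if (n_gap > 0L)
    warning(sprintf("%d (cell, frame) ROIs missing; recorded as NA", n_gap))
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("mcc_timecourse", "data.frame")
  out
}

#' Non-overlapping block means of a series
#'
#' Means over consecutive blocks of `window` frames; a trailing partial
#' block is averaged over its actual length.  NA values are excluded from
#' their block's mean, and a block whose values are all NA is NA.
#'
#' @param series numeric vector (e.g. a per-frame MCC series).
#' @param window block length in frames.
#' @return numeric vector of length `ceiling(length(series) / window)`.
#' @examples
#' block_mean(1:7, 5)  # c(3, 6.5)
#' @export
block_mean <- function(series, window = 5L) {
  stopifnot(window >= 1)
  n <- length(series)
  if (n == 0L) return(numeric(0))
  blk <- (seq_len(n) - 1L) %/% as.integer(window)
  out <- tapply(series, blk, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  as.numeric(out)
}

#' Initial MCC of a smoothed series
#'
#' The first defined value of the block-mean (window 5 by default) series;
#' this is the "colocalization at the beginning of the observation" summary
#' used to classify cells as high or low.
#'
#' @param series per-frame MCC values (raw); it is smoothed internally.
#' @param window smoothing window passed to [block_mean()].
#' @param smoothed set TRUE if `series` is already a block-mean series.
#' @return a single numeric value.
#' @export
initial_mcc <- function(series, window = 5L, smoothed = FALSE) {
  s <- if (smoothed) series else block_mean(series, window)
  s <- s[!is.na(s)]
  if (!length(s)) stop("no defined MCC values in the series")
  s[1]
}
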