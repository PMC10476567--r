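# File-based interchange: multi-page 16-bit TIFF per channel, labelled ROI
# TIFF, ground truth and traces as CSV, configuration as YAML.

# 3-D integer array -> list of [0,1] matrices for tiff::writeTIFF
stack_to_pages <- function(a) {
  lapply(seq_len(dim(a)[3]), function(f) a[, , f] / 65535)
}

pages_to_stack <- function(pages) {
  a <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages))
    a[, , f] <- as.integer(round(pages[[f]] * 65535))
  a
}

#' Write a simulated experiment to disk
#'
#' Writes one multi-page 16-bit TIFF per channel (`reporter.tif`,
#' `mito.tif`, `dye.tif`), the labelled ROI stack (`roi.tif`), the ground
#' truth and centroid paths as CSV, the per-cell dye traces as CSV, and the
#' generator configuration as YAML.  Outputs are byte-identical across runs
#' with the same seed.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(reporter = file.path(dir, "reporter.tif"),
             mito = file.path(dir, "mito.tif"),
             dye = file.path(dir, "dye.tif"),
             roi = file.path(dir, "roi.tif"),
             truth = file.path(dir, "truth.csv"),
             paths = file.path(dir, "centroids.csv"),
             traces = file.path(dir, "dye_traces.csv"),
             config = file.path(dir, "config.yaml"))
  tiff::writeTIFF(stack_to_pages(sim$stacks$reporter), paths["reporter"],
                  bits.per.sample = 16L)
  tiff::writeTIFF(stack_to_pages(sim$stacks$mito), paths["mito"],
                  bits.per.sample = 16L)
  tiff::writeTIFF(stack_to_pages(sim$stacks$dye), paths["dye"],
                  bits.per.sample = 16L)
  tiff::writeTIFF(stack_to_pages(sim$roi), paths["roi"],
                  bits.per.sample = 16L)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  utils::write.csv(sim$paths, paths["paths"], row.names = FALSE)
  utils::write.csv(extract_traces(sim$stacks$dye, sim$roi,
                                  sim$config$frame_interval),
                   paths["traces"], row.names = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  yaml::write_yaml(c(cfg, list(condition_label = sim$model$condition_label)),
                   paths["config"])
  invisible(paths)
}

#' Read an experiment directory written by [write_experiment()]
#'
#' @param dir directory containing the TIFF/CSV/YAML files.
#' @return list with `stacks`, `roi`, `truth` (NULL if absent), `config`
#'   (plain list).
#' @export
read_experiment <- function(dir) {
  read_stack <- function(p) pages_to_stack(tiff::readTIFF(p, all = TRUE))
  truth_path <- file.path(dir, "truth.csv")
  list(stacks = list(reporter = read_stack(file.path(dir, "reporter.tif")),
                     mito = read_stack(file.path(dir, "mito.tif")),
                     dye = read_stack(file.path(dir, "dye.tif"))),
       roi = read_stack(file.path(dir, "roi.tif")),
       truth = if (file.exists(truth_path))
         utils::read.csv(truth_path) else NULL,
       config = yaml::read_yaml(file.path(dir, "config.yaml")))
}

#' Extract per-cell death-dye traces from a dye stack
#'
#' The per-frame summary is the maximum dye intensity over the cell's ROI,
#' the quantity that is thresholded to call death.
#'
#' @param dye_stack `H x W x n_frames` array.
#' @param roi labelled ROI stack of the same shape (or a single matrix,
#'   recycled over frames).
#' @param frame_interval hours between frames.
#' @return data frame: cell_id, frame, time_h, dye_max.
#' @export
extract_traces <- function(dye_stack, roi, frame_interval = 0.5) {
  dims <- dim(dye_stack)
  Fn <- dims[3]
  static_roi <- is.matrix(roi)
  ids <- sort(setdiff(unique(as.integer(if (static_roi) roi else roi)), 0L))
  out <- vector("list", Fn)
  for (f in seq_len(Fn)) {
    lab <- if (static_roi) roi else roi[, , f]
    v <- dye_stack[, , f]
    keep <- lab != 0L
    mx <- tapply(v[keep], lab[keep], max)
    out[[f]] <- data.frame(cell_id = as.integer(names(mx)),
                           frame = f,
                           time_h = (f - 1) * frame_interval,
                           dye_max = as.numeric(mx))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$cell_id, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}
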