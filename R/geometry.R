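# Cell geometry: nested masks on a per-cell square tile.  The cytoplasm is
# an ellipse, the nucleus an interior disk, and the mitochondrial network a
# set of smoothed random filaments grown inside the cytoplasm but outside
# the nucleus.  All downstream rendering works on these tiles; whole-cell
# drift only translates the tile within the field.

#' Generate the compartment masks of one synthetic cell
#'
#' Builds, on a square tile, three nested boolean masks: an elliptical
#' cytoplasm, an interior nuclear disk, and a filamentous mitochondrial
#' network drawn as smoothed random walks restricted to the non-nuclear
#' cytoplasm.  Filaments are added until the network covers the configured
#' fraction of the available area, so the mitochondrial area is controlled
#' by `config$mito_area_frac`.  Fully deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param cell_id integer id (only recorded in the result).
#' @param seed integer seed for this cell's geometry.
#' @param scale linear scale factor applied to the footprint (used to render
#'   the contracted post-death morphology).
#' @return an object of class `cell_geometry`: logical matrices `cytoplasm`,
#'   `nucleus`, `mito` of size `tile x tile`, plus `tile`, `cell_id` and the
#'   semi-axes used.
#' @export
make_cell_geometry <- function(config, cell_id = 1L, seed = 1L, scale = 1) {
  stopifnot(inherits(config, "sim_config"), scale > 0, scale <= 1)
  r <- config$cell_radius
  tile <- 2L * (as.integer(ceiling(r * 1.6 + 3 * config$psf_sigma + 2))) + 1L
  if (any(config$field_shape < tile))
    stop("field too small for the requested cell radius")
  with_seed(seed, {
    a <- r * stats::runif(1, 0.85, 1.15) * scale
    b <- r * stats::runif(1, 0.7, 1.0) * scale
    theta <- stats::runif(1, 0, pi)
    c0 <- (tile + 1) / 2
    xy <- expand.grid(row = seq_len(tile), col = seq_len(tile))
    dx <- xy$col - c0
    dy <- xy$row - c0
    u <- cos(theta) * dx + sin(theta) * dy
    v <- -sin(theta) * dx + cos(theta) * dy
    cyto <- matrix((u / a)^2 + (v / b)^2 <= 1, tile, tile)
    # nucleus: interior disk, slightly off-centre
    rn <- 0.45 * min(a, b)
    ncx <- c0 + stats::runif(1, -0.15, 0.15) * a
    ncy <- c0 + stats::runif(1, -0.15, 0.15) * b
    nuc <- matrix((xy$col - ncx)^2 + (xy$row - ncy)^2 <= rn^2, tile, tile)
    nuc <- nuc & cyto
    # mitochondrial network: smoothed random walks stamped with a 3x3 brush,
    # grown until the target area fraction of (cytoplasm \ nucleus) is hit
    avail <- cyto & !nuc
    target <- config$mito_area_frac * sum(avail)
    mito <- matrix(FALSE, tile, tile)
    guard <- 0L
    while (sum(mito) < target && guard < 400L) {
      guard <- guard + 1L
      ok <- which(avail & !mito)
      if (!length(ok)) break
      start <- ok[ceiling(stats::runif(1) * length(ok))]
      px <- ((start - 1L) %/% tile) + 1L   # col
      py <- ((start - 1L) %% tile) + 1L    # row
      ang <- stats::runif(1, 0, 2 * pi)
      steps <- 6L + as.integer(stats::runif(1) * 14)
      x <- px; y <- py
      for (s in seq_len(steps)) {
        ang <- ang + stats::rnorm(1, 0, 0.45)
        x <- x + cos(ang)
        y <- y + sin(ang)
        xi <- as.integer(round(x)); yi <- as.integer(round(y))
        if (xi < 2L || xi > tile - 1L || yi < 2L || yi > tile - 1L) break
        rows <- (yi - 1L):(yi + 1L)
        cols <- (xi - 1L):(xi + 1L)
        stamp <- avail[rows, cols]
        mito[rows, cols][stamp] <- TRUE
        if (sum(mito) >= target) break   # cap overshoot at one brush stamp
      }
    }
    geom <- structure(list(cytoplasm = cyto, nucleus = nuc, mito = mito,
                           tile = tile, cell_id = as.integer(cell_id),
                           semi_axes = c(a = a, b = b)),
                      class = "cell_geometry")
    validate_cell_geometry(geom)
    geom
  })
}

validate_cell_geometry <- function(geom) {
  stopifnot(!any(geom$nucleus & !geom$cytoplasm),
            !any(geom$mito & !geom$cytoplasm),
            !any(geom$mito & geom$nucleus))
  invisible(geom)
}
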