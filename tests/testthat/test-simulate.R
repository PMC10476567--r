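small_cfg <- function(...) {
  args <- list(n_cells = 6L, field_shape = c(170L, 170L), n_frames = 10L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("cell geometry is deterministic and respects mask nesting", {
  cfg <- small_cfg()
  g1 <- make_cell_geometry(cfg, 1L, seed = 9L)
  g2 <- make_cell_geometry(cfg, 1L, seed = 9L)
  expect_identical(g1, g2)
  expect_false(identical(g1$mito, make_cell_geometry(cfg, 1L, seed = 10L)$mito))
  expect_false(any(g1$nucleus & !g1$cytoplasm))
  expect_false(any(g1$mito & !g1$cytoplasm))
  expect_false(any(g1$mito & g1$nucleus))
})

test_that("mitochondrial coverage stays inside the configured density band", {
  cfg <- small_cfg(mito_area_frac = 0.3)
  fracs <- vapply(1:100, function(s) {
    g <- make_cell_geometry(cfg, 1L, seed = s)
    sum(g$mito) / sum(g$cytoplasm & !g$nucleus)
  }, numeric(1))
  # growth stops at the target; a single brush stamp can overshoot slightly
  expect_true(all(fracs >= 0.3))
  expect_true(all(fracs <= 0.38))
})

test_that("a too-small field for the cell radius is a sizing error", {
  expect_error(make_cell_geometry(sim_config(field_shape = c(20L, 20L)),
                                  1L, 1L),
               "field too small")
})

test_that("reporter rendering places exactly f_mito of the mass on mitochondria", {
  cfg <- small_cfg(psf_sigma = 0, texture_cv = 0.5)
  g <- make_cell_geometry(cfg, 1L, seed = 21L)
  for (f in c(0, 0.6, 1)) {
    set.seed(1)
    img <- render_reporter_channel(g, f, 5e4, cfg, blur = FALSE)
    expect_equal(sum(img[g$mito]) / sum(img), f, tolerance = 1e-10)
    expect_equal(sum(img), 5e4, tolerance = 1e-9)
  }
  expect_error(render_reporter_channel(g, 1.2, 5e4, cfg), "f_mito")
})

test_that("Gaussian blurring conserves the reporter mass", {
  cfg <- small_cfg(psf_sigma = 1.5, texture_cv = 0.5)
  g <- make_cell_geometry(cfg, 1L, seed = 22L)
  set.seed(2)
  img <- render_reporter_channel(g, 0.5, 3e4, cfg, blur = TRUE)
  expect_equal(sum(img), 3e4, tolerance = 0.001)
})

test_that("fate sampling follows the two-class probabilities and delay law", {
  set.seed(31)
  f <- runif(2000)
  m <- fate_model(f_high_threshold = 0.5, p_death_high = 0.8,
                  p_death_low = 0.2, delay_base = 5, delay_slope = 10,
                  delay_sd = 0)
  dt <- sample_fates(f, m, seed = 131)
  high <- f >= 0.5
  p_hat_high <- mean(!is.na(dt[high]))
  p_hat_low <- mean(!is.na(dt[!high]))
  expect_lt(abs(p_hat_high - 0.8), 3 * sqrt(0.8 * 0.2 / sum(high)))
  expect_lt(abs(p_hat_low - 0.2), 3 * sqrt(0.2 * 0.8 / sum(!high)))
  # with no jitter the delay law is exact
  dead <- !is.na(dt)
  expect_equal(dt[dead], 5 + 10 * f[dead], tolerance = 1e-12)
})

test_that("degenerate death probability 1 kills every high-fraction cell", {
  f <- seq(0, 1, by = 0.05)
  m <- fate_model(f_high_threshold = 0.6, p_death_high = 1, p_death_low = 0)
  dt <- sample_fates(f, m, seed = 1)
  expect_true(all(!is.na(dt[f >= 0.6])))
  expect_true(all(is.na(dt[f < 0.6])))
})

test_that("slope zero decorrelates fraction and death time", {
  set.seed(32)
  f <- runif(500)
  m <- fate_model(p_death_high = 1, p_death_low = 1, delay_slope = 0,
                  delay_base = 15, delay_sd = 4)
  dt <- sample_fates(f, m, seed = 32)
  expect_lt(abs(cor(f, dt)), 0.15)
  # WT-like slope recovers a clearly positive correlation
  m2 <- fate_model(p_death_high = 1, p_death_low = 0.9)
  dt2 <- sample_fates(f, m2, seed = 33)
  dead <- !is.na(dt2)
  ct <- cor.test(f[dead], dt2[dead])
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 1e-6)
})

test_that("death-dye traces separate survivors from dying cells", {
  cfg <- small_cfg(n_frames = 40L)
  set.seed(41)
  surv_max <- replicate(60, max(render_death_dye(NA, cfg)))
  base <- render_death_dye(NA, cfg)
  # survivor traces stay near baseline: far below the dye plateau
  expect_true(all(surv_max < cfg$offset + cfg$dye_plateau / 4))
  # dying: baseline before, plateau after
  tr <- render_death_dye(10, cfg)
  t <- (seq_along(tr) - 1) * cfg$frame_interval
  expect_true(all(tr[t < 9] < cfg$offset + cfg$dye_plateau / 4))
  expect_true(all(tr[t > 11] > cfg$offset + 0.8 * cfg$dye_plateau))
  # plateau/baseline contrast matches the configuration
  expect_equal(mean(tr[t > 12]) - cfg$offset, cfg$dye_plateau,
               tolerance = 0.1 * cfg$dye_plateau)
  # death at t = 0 rises from the first frame
  tr0 <- render_death_dye(0, cfg)
  expect_gt(tr0[1], cfg$offset + 0.3 * cfg$dye_plateau)
  expect_error(render_death_dye(-1, cfg), ">= 0")
})

test_that("simulation is deterministic and rejects impossible packing", {
  cfg <- small_cfg()
  s1 <- simulate_experiment(cfg, fate_model())
  s2 <- simulate_experiment(cfg, fate_model())
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$stacks, s2$stacks)
  expect_identical(s1$roi, s2$roi)
  expect_error(simulate_experiment(sim_config(n_cells = 500L,
                                              field_shape = c(170L, 170L),
                                              n_frames = 4L),
                                   fate_model()),
               "cannot place")
})

test_that("an empty cohort yields empty stacks and truth", {
  s <- simulate_experiment(small_cfg(n_cells = 0L), fate_model())
  expect_equal(nrow(s$truth), 0L)
  expect_true(all(s$roi == 0L))
  expect_equal(dim(s$stacks$reporter), c(170L, 170L, 10L))
})

test_that("experiment files round-trip exactly and reproducibly", {
  cfg <- small_cfg(n_frames = 6L)
  sim <- simulate_experiment(cfg, fate_model())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_experiment(sim, d1)
  write_experiment(sim, d2)
  f1 <- sort(list.files(d1))
  expect_true(all(c("reporter.tif", "mito.tif", "dye.tif", "roi.tif",
                    "truth.csv", "config.yaml") %in% f1))
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
  back <- read_experiment(d1)
  expect_identical(back$stacks$reporter, sim$stacks$reporter)
  expect_identical(back$roi, sim$roi)
  expect_equal(back$config$frame_interval, cfg$frame_interval)
})

test_that("SPC dose conversion follows the 2:3 adduct stoichiometry", {
  eq <- spc_equivalents(267)
  expect_equal(eq$sodium_carbonate, 267)
  expect_equal(eq$h2o2, 400)
  expect_equal(spc_equivalents(0), list(sodium_carbonate = 0, h2o2 = 0))
  expect_equal(spc_equivalents(100)$h2o2, 150)
  expect_error(spc_equivalents(-1), "non-negative")
})

test_that("mutant-like preset encodes no delay correlation exactly", {
  expect_identical(mutant_fate_model()$delay_slope, 0)
  expect_identical(control_fate_model()$p_death_high, 0)
})
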