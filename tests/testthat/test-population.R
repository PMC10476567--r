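toy_mcc <- function(series_list, frame_interval = 0.5) {
  out <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    data.frame(cell_id = i, frame = seq_along(s),
               time_h = (seq_along(s) - 1) * frame_interval, mcc = s)
  }))
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("mcc_timecourse", "data.frame")
  out
}

toy_calls <- function(status, death_time_h) {
  d <- data.frame(cell_id = seq_along(status), status = status,
                  death_frame = NA_integer_, death_time_h = death_time_h,
                  stringsAsFactors = FALSE)
  class(d) <- c("fate_calls", "data.frame")
  d
}

test_that("death alignment puts the last retained point at t = 0", {
  mcc <- toy_mcc(list(rep(0.5, 20), rep(0.3, 20)))
  calls <- toy_calls(c("dead", "surviving"), c(4.5, NA))  # death at frame 10
  pool <- align_and_pool(mcc, calls, window = 5)
  dead_series <- pool$dead$series
  expect_equal(max(dead_series$t_aligned), 0)
  expect_true(all(dead_series$t_aligned <= 0))
  surv_series <- pool$surviving$series
  expect_equal(min(surv_series$t_aligned), mean(0:4) * 0.5)
  # pooled counts equal the defined smoothed points
  expect_equal(length(pool$dead$pooled), nrow(dead_series))
  expect_true(all(pool$dead$pooled == 0.5))
  # all-survivor cohort leaves the dead pool empty
  pool2 <- align_and_pool(mcc, toy_calls(c("surviving", "surviving"),
                                         c(NA, NA)))
  expect_equal(length(pool2$dead$pooled), 0L)
  expect_error(align_and_pool(mcc, toy_calls("dead", 4.5)[0, ]), "no fate")
})

test_that("KDE integrates to one, is nonnegative, and resolves two modes", {
  set.seed(61)
  x <- rnorm(2000, 0.5, 0.1)
  k <- mcc_kde(x)
  expect_true(all(k$density >= 0))
  dx <- diff(k$x)[1]
  expect_equal(sum(k$density) * dx, 1, tolerance = 0.01)
  # pointwise accuracy relative to the density peak, plus mean accuracy
  expect_lt(max(abs(k$density - dnorm(k$x, 0.5, 0.1))),
            0.15 * dnorm(0.5, 0.5, 0.1))
  expect_lt(mean(abs(k$density - dnorm(k$x, 0.5, 0.1))), 0.05)
  # two well-separated clusters -> two local maxima
  y <- c(rnorm(1000, 0.25, 0.05), rnorm(1000, 0.75, 0.05))
  k2 <- mcc_kde(y)
  d <- k2$density
  n_modes <- sum(d[2:(length(d) - 1)] > d[1:(length(d) - 2)] &
                   d[2:(length(d) - 1)] > d[3:length(d)])
  expect_equal(n_modes, 2L)
  expect_error(mcc_kde(0.4), "at least 2")
})

test_that("threshold splitting classifies strictly above the boundary", {
  ini <- c(0.2, 0.6, 0.61, 0.9)
  calls <- toy_calls(c("surviving", "surviving", "dead", "dead"),
                     c(NA, NA, 3, 5))
  sp <- split_by_threshold(ini, calls, 0.60)
  expect_equal(unname(sp$class), c("low", "low", "high", "high"))
  sm <- sp$summary
  expect_equal(sum(sm$n), 4L)
  expect_equal(sm$pct_surviving[sm$class == "high"], 0)
  expect_equal(sm$pct_surviving[sm$class == "low"], 100)
  # boundary settings
  expect_true(all(split_by_threshold(ini, calls, 0)$class == "high"))
  expect_true(all(split_by_threshold(ini, calls, 1)$class == "low"))
  # replicate-wise mean +/- SEM
  sp2 <- split_by_threshold(c(0.2, 0.3, 0.2, 0.3),
                            toy_calls(c("dead", "surviving", "dead", "dead"),
                                      c(1, NA, 1, 1)),
                            0.6, replicate = c(1, 1, 2, 2))
  low <- sp2$summary[sp2$summary$class == "low", ]
  expect_equal(low$mean_pct, mean(c(50, 0)))
  expect_equal(low$sem_pct, sd(c(50, 0)) / sqrt(2))
})

test_that("correlation summary handles exact, null and replicate structure", {
  # exactly linear increasing data -> r = 1
  r1 <- correlate_initial_mcc_vs_death_time(c(0.1, 0.2, 0.3, 0.4),
                                            c(1, 2, 3, 4))
  expect_equal(r1$mean_r, 1)
  expect_equal(r1$slope, 10)
  # zero-variance replicate is excluded with a warning
  expect_warning(
    r2 <- correlate_initial_mcc_vs_death_time(
      c(0.1, 0.2, 0.3, 0.5, 0.5, 0.5), c(1, 2, 3, 1, 2, 3),
      replicate = rep(1:2, each = 3)),
    "excluded")
  expect_equal(unname(r2$r_by_replicate["1"]), 1)
  expect_true(is.na(r2$r_by_replicate["2"]))
})

test_that("Pearson r is affine-invariant; the slope rescales inversely", {
  set.seed(62)
  x <- runif(40); y <- 2 * x + rnorm(40, 0, 0.3)
  a <- correlate_initial_mcc_vs_death_time(x, y)
  b <- correlate_initial_mcc_vs_death_time(10 * x + 3, y)
  c_ <- correlate_initial_mcc_vs_death_time(x, 5 * y - 1)
  expect_equal(a$mean_r, b$mean_r, tolerance = 1e-12)
  expect_equal(a$mean_r, c_$mean_r, tolerance = 1e-12)
  expect_equal(b$slope, a$slope / 10, tolerance = 1e-12)
  expect_equal(c_$slope, a$slope * 5, tolerance = 1e-12)
})

test_that("null-slope simulation keeps the mean r near zero", {
  set.seed(63)
  reps <- rep(1:3, length.out = 200)
  f <- runif(200)
  dt <- sample_fates(f, fate_model(p_death_high = 1, p_death_low = 1,
                                   delay_slope = 0, delay_base = 15,
                                   delay_sd = 4), seed = 63)
  r <- correlate_initial_mcc_vs_death_time(f, dt, replicate = reps)
  expect_lt(abs(r$mean_r), 0.15)
})

test_that("slope fits recover trends and flag static cells", {
  expect_equal(fit_mcc_slope(c(0, 10), c(0.2, 0.4))$slope, 0.02)
  s0 <- fit_mcc_slope(0:9, rep(0.5, 10))
  expect_equal(s0$slope, 0)
  expect_true(s0$covers_zero)
  expect_error(fit_mcc_slope(1, 0.5), "at least 2")
  # static simulated series: most slope CIs cover zero
  set.seed(64)
  covered <- replicate(100, {
    s <- rep(0.4, 16) + rnorm(16, 0, 0.03)   # static MCC with frame noise
    fit_mcc_slope((0:15) * 2.5, s)$covers_zero
  })
  expect_gte(mean(covered), 0.9)
})

test_that("recovered OLS slope tracks the ground-truth delay slope", {
  run <- default_wt_run()
  calls <- run$calls
  truth <- run$sim$truth
  dead <- calls$status == "dead"
  # oracle regression: called death time on the *latent* fraction
  oracle <- unname(coef(lm(calls$death_time_h[dead] ~ truth$f_mito[dead]))[2])
  # measured regression: on the measured initial MCC
  meas <- correlate_initial_mcc_vs_death_time(run$ini[dead],
                                              calls$death_time_h[dead])
  # MCC-per-f gain from the measured-vs-latent calibration
  gain <- unname(coef(lm(run$ini ~ truth$f_mito))[2])
  expect_equal(meas$slope, oracle / gain, tolerance = 0.2)
})
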