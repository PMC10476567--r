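test_that("Mann-Whitney U and exact p match hand enumeration and wilcox.test", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / 6, tolerance = 1e-12)   # C(4,2) arrangements
  # identical multisets: U = n1*n2/2 by symmetry
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$U, 4.5)
  # tie-free exact p agrees with wilcox.test's exact distribution
  set.seed(91)
  for (i in 1:25) {
    x <- rnorm(sample(2:6, 1))
    y <- rnorm(sample(2:6, 1))
    expect_equal(mann_whitney_u(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # one-sided alternatives
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4), "less")$p, 1 / 6,
               tolerance = 1e-12)
})

test_that("normal approximation stays close to the exact p at n = 6 + 6", {
  set.seed(92)
  devs <- replicate(100, {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    abs(mann_whitney_u(x, y, exact = TRUE)$p -
          mann_whitney_u(x, y, exact = FALSE)$p)
  })
  expect_lt(max(devs), 0.02)
  expect_lt(mean(devs), 0.01)
})

test_that("Steel-Dwass reduces to Mann-Whitney with two groups", {
  set.seed(93)
  x <- rnorm(12); y <- rnorm(12, 0.8)
  p_mw <- mann_whitney_u(x, y, exact = FALSE, correct = FALSE)$p
  p_asym <- steel_dwass(list(x, y), method = "asymptotic")$pairs$p
  expect_equal(p_asym, p_mw, tolerance = 1e-12)
  p_mc <- steel_dwass(list(x, y), n_mc = 4000, seed = 7)$pairs$p
  expect_lt(abs(p_mc - p_mw), 0.03)
})

test_that("Steel-Dwass flags an overwhelming shift and rejects empty groups", {
  set.seed(94)
  g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 10))
  res <- steel_dwass(g, n_mc = 2000, seed = 8)
  p <- res$pairs
  expect_true(all(p$p[p$group1 == "c" | p$group2 == "c"] < 0.01))
  expect_gt(p$p[p$group1 == "a" & p$group2 == "b"], 0.05)
  expect_error(steel_dwass(list(1:3, numeric(0), 1:3)), "empty")
  # p-values symmetric in pair order: statistic unchanged if groups swapped
  res2 <- steel_dwass(list(a = g$b, b = g$a, c = g$c),
                      method = "asymptotic")
  expect_equal(sort(res2$pairs$p), sort(steel_dwass(g,
               method = "asymptotic")$pairs$p), tolerance = 1e-12)
})

test_that("family-wise size of Steel-Dwass is close to alpha under the null", {
  set.seed(95)
  rej <- replicate(1000, {
    g <- lapply(1:3, function(i) rnorm(15))
    any(steel_dwass(g, method = "asymptotic")$pairs$p < 0.05)
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
  # Monte-Carlo branch (smaller replicate count: each rep permutes)
  set.seed(96)
  rej_mc <- replicate(300, {
    g <- lapply(1:3, function(i) rnorm(12))
    any(steel_dwass(g, n_mc = 400)$pairs$p < 0.05)
  })
  expect_lt(abs(mean(rej_mc) - 0.05), 0.035)
})

test_that("pairwise logrank matches survdiff and a hand-computed pair", {
  # events {1,2} vs {3,4}: O-E/V by hand
  # event times 1,2,3,4; group1 at risk 2,1,0,0 of 4,3,2,1 totals
  # E1 = 2/4 + 1/3 + 0 + 0 = 5/6; O1 = 2
  # V  = sum d*(n1/n)(1-n1/n)(n-d)/(n-1) = (1/2)(1/2)(3/3) + (1/3)(2/3)(2/2)
  #    = 0.25 + 2/9
  V <- 0.25 + 2 / 9
  chi_hand <- (2 - 5 / 6)^2 / V
  res <- pairwise_logrank(c(1, 2, 3, 4), rep(1, 4), c(1, 1, 2, 2))
  expect_equal(res$pairs$statistic, chi_hand, tolerance = 1e-12)
  skip_if_not_installed("survival")
  sd_ <- survival::survdiff(survival::Surv(c(1, 2, 3, 4), rep(1, 4)) ~
                              c(1, 1, 2, 2))
  expect_equal(res$pairs$statistic, unname(sd_$chisq), tolerance = 1e-10)
  # identical groups: statistic 0, p 1
  t2 <- rep(c(1, 3, 5, 7), 2)
  g2 <- rep(1:2, each = 4)
  res2 <- pairwise_logrank(t2, rep(1, 8), g2)
  expect_equal(res2$pairs$statistic, 0)
  expect_equal(res2$pairs$p, 1)
  # strong hazard ratio is detected
  set.seed(97)
  t3 <- c(rexp(100, 1), rexp(100, 4))
  res3 <- pairwise_logrank(t3, rep(1, 200), rep(1:2, each = 100))
  expect_lt(res3$pairs$p, 1e-3)
  # a pair with zero events is flagged as NA
  res4 <- pairwise_logrank(c(1, 2, 3, 4), rep(0, 4), c(1, 1, 2, 2))
  expect_true(is.na(res4$pairs$p))
})

test_that("Tukey-on-proportions is calibrated, symmetric and sharp", {
  # extreme contrast
  expect_lt(tukey_proportions(c(0, 50), c(50, 50))$pairs$p[1], 1e-3)
  # success/failure swap leaves p unchanged (arcsine symmetry)
  s <- c(12, 30, 25); n <- c(60, 70, 55)
  p1 <- tukey_proportions(s, n)$pairs$p
  p2 <- tukey_proportions(n - s, n)$pairs$p
  expect_equal(p1, p2, tolerance = 1e-12)
  # two-group case close to a two-proportion z-test on a deterministic grid
  grid <- expand.grid(n = c(60, 100, 160), pa = c(.25, .4, .6, .75),
                      pb = c(.25, .4, .6, .75))
  devs <- apply(grid, 1, function(g) {
    s1 <- round(g[2] * g[1]); s2 <- round(g[3] * g[1])
    if (s1 == s2) return(0)
    tp <- tukey_proportions(c(s1, s2), rep(g[1], 2))$pairs$p
    p1 <- s1 / g[1]; p2 <- s2 / g[1]
    z <- abs(p1 - p2) / sqrt(p1 * (1 - p1) / g[1] + p2 * (1 - p2) / g[1])
    abs(tp - 2 * pnorm(-z))
  })
  expect_lt(max(devs), 0.02)
  # family-wise size under the null
  set.seed(98)
  rej <- replicate(2000, {
    s <- rbinom(3, 60, 0.3)
    any(tukey_proportions(s, rep(60, 3))$pairs$p < 0.05)
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("Mann-Whitney size is close to alpha under the null", {
  set.seed(99)
  rej <- replicate(2000, mann_whitney_u(rnorm(20), rnorm(20),
                                        exact = FALSE)$p < 0.05)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("power simulation has size alpha at equal proportions", {
  null_pw <- simulate_power(rep(0.3, 3), 70, n_reps = 3000, seed = 10,
                            comparison = "designated_any")
  # with the any-rule, power at the null is the family-wise error of the
  # designated set, at most alpha; designated_all is strictly smaller
  expect_lt(null_pw$power, 0.05 + 2 * null_pw$mc_se + 0.01)
  expect_gt(null_pw$power, 0.005)
})

test_that("power is monotone in effect size and sample size", {
  pw <- function(props, n) simulate_power(props, n, n_reps = 1500,
                                          seed = 11)$power
  expect_gt(pw(c(0.05, 0.95, 0.95), 100), 0.99)
  n_grid <- c(30, 70, 140)
  p_n <- vapply(n_grid, function(n) pw(c(0.093, 0.241, 0.256), n),
                numeric(1))
  expect_true(all(diff(p_n) > 0))
  eff <- vapply(c(0.241, 0.35, 0.5), function(p2)
    pw(c(0.093, p2, 0.256), 70), numeric(1))
  expect_true(all(diff(eff) >= 0))
})

test_that("power agrees between the fast binary path and the general tests", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(20:60, 2)
    s <- c(rbinom(1, n[1], 0.3), rbinom(1, n[2], 0.6))
    k <- 3
    # steel_dwass closed form on binary data vs the general implementation
    p_fast <- mcctrack:::pair_p_binary(s[1], n[1], s[2], n[2], k,
                                       "steel_dwass")
    x <- c(rep(1, s[1]), rep(0, n[1] - s[1]))
    y <- c(rep(1, s[2]), rep(0, n[2] - s[2]))
    stat <- mcctrack:::sd_pair_stat(x, y)
    expect_equal(p_fast, ptukey(stat, k, Inf, lower.tail = FALSE),
                 tolerance = 1e-12)
    # tukey path vs tukey_proportions with k = 2 statistic convention
    p_fast_t <- mcctrack:::pair_p_binary(s[1], n[1], s[2], n[2], 2, "tukey")
    expect_equal(p_fast_t, tukey_proportions(s, n)$pairs$p, tolerance = 1e-12)
  }
})

test_that("minimum n search is monotone in the target and finds easy cases", {
  r1 <- min_n_for_power(c(0.05, 0.95), target_power = 0.8, n_reps = 400,
                        seed = 12, comparison = "designated_any")
  expect_lte(r1$n, 10)
  r2 <- min_n_for_power(c(0.2, 0.5), target_power = 0.8, n_reps = 800,
                        seed = 12)
  r3 <- min_n_for_power(c(0.2, 0.5), target_power = 0.9, n_reps = 800,
                        seed = 12)
  expect_gte(r3$n, r2$n)
  expect_error(min_n_for_power(c(0.3, 0.3), 0.8), "unattainable")
  expect_warning(simulate_power(c(0.2, 0.5), 30, n_reps = 50, seed = 1),
                 "unstable")
})
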