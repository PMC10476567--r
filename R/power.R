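# Simulation-based power and sample-size analysis for multi-group
# proportion comparisons, as used for post-hoc power assessment of
# per-condition survival percentages.

# vectorized per-pair p-values over Monte-Carlo replicates; s1, s2 are
# vectors of successes for the two groups across replicates
pair_p_binary <- function(s1, n1, s2, n2, k, test) {
  if (test == "tukey") {
    q <- abs(asin(sqrt(s1 / n1)) - asin(sqrt(s2 / n2))) /
      sqrt((1 / (4 * n1) + 1 / (4 * n2)) / 2)
  } else { # steel_dwass: closed-form pairwise rank statistic on binary data
    N <- n1 + n2
    ones <- s1 + s2
    zeros <- N - ones
    # midranks: zeros share (zeros+1)/2, ones share zeros + (ones+1)/2
    W <- (n1 - s1) * (zeros + 1) / 2 + s1 * (zeros + (ones + 1) / 2)
    EW <- n1 * (N + 1) / 2
    VW <- n1 * n2 / 12 *
      ((N + 1) - (zeros^3 - zeros + ones^3 - ones) / (N * (N - 1)))
    q <- ifelse(VW <= 0, 0, sqrt(2) * abs(W - EW) / sqrt(VW))
  }
  stats::ptukey(q, k, Inf, lower.tail = FALSE)
}

#' Monte-Carlo power of a multi-group pairwise proportion comparison
#'
#' Repeatedly draws binomial groups at the given success probabilities,
#' applies the chosen pairwise test at level `alpha`, and estimates power
#' as the fraction of replicates in which the designated comparisons reach
#' significance.  The designated set is the reference group against every
#' other group; `comparison` controls whether *all* of those pairs must be
#' rejected (default -- "are the differences significant"), *any* of them,
#' or all pairs of all groups.
#'
#' @param props success probabilities per group.
#' @param n_per_group per-group sample size (scalar or vector).
#' @param alpha significance level.
#' @param test "steel_dwass" (pairwise rank statistic on the
#'   studentized-range scale; on binary data this is the Steel-Dwass
#'   statistic with midrank ties) or "tukey" (arcsine-transform Tukey).
#' @param n_reps Monte-Carlo replicates (>= 100 recommended).
#' @param seed optional seed.
#' @param comparison success rule: "designated_all", "designated_any" or
#'   "all_pairs".
#' @param reference index of the reference group.
#' @return object of class `power_result`: power, mc_se, n_reps, and the
#'   settings.
#' @export
simulate_power <- function(props, n_per_group, alpha = 0.05,
                           test = c("steel_dwass", "tukey"),
                           n_reps = 2000L, seed = NULL,
                           comparison = c("designated_all",
                                          "designated_any", "all_pairs"),
                           reference = 1L) {
  test <- match.arg(test)
  comparison <- match.arg(comparison)
  k <- length(props)
  stopifnot(k >= 2, all(props >= 0 & props <= 1), all(n_per_group >= 2))
  if (n_reps < 100L) warning("n_reps < 100: power estimate will be unstable")
  n <- if (length(n_per_group) == 1L) rep(n_per_group, k) else n_per_group
  stopifnot(length(n) == k)
  succ <- with_seed(seed, {
    matrix(stats::rbinom(k * n_reps, rep(n, each = n_reps),
                         rep(props, each = n_reps)),
           nrow = n_reps, ncol = k)
  })
  pair_set <- if (comparison == "all_pairs") utils::combn(k, 2)
  else rbind(rep(reference, k - 1), setdiff(seq_len(k), reference))
  rej <- matrix(FALSE, n_reps, ncol(pair_set))
  for (j in seq_len(ncol(pair_set))) {
    i1 <- pair_set[1, j]; i2 <- pair_set[2, j]
    p <- pair_p_binary(succ[, i1], n[i1], succ[, i2], n[i2], k, test)
    rej[, j] <- p < alpha
  }
  hit <- if (comparison == "designated_any") rowSums(rej) > 0
  else rowSums(rej) == ncol(pair_set)
  power <- mean(hit)
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / n_reps),
                 n_reps = n_reps, props = props, n_per_group = n,
                 alpha = alpha, test = test, comparison = comparison,
                 reference = reference, seed = seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo power: %.3f +/- %.3f (MC SE, %d reps)\n",
              x$power, x$mc_se, x$n_reps))
  cat(sprintf("  %s, %s, alpha = %g, n = %s, props = %s\n",
              x$test, x$comparison, x$alpha,
              paste(x$n_per_group, collapse = "/"),
              paste(signif(x$props, 3), collapse = "/")))
  invisible(x)
}

#' Smallest per-group sample size reaching a target power
#'
#' Bisection over the per-group n with [simulate_power()] as the oracle.
#' Each candidate n is evaluated with the same seed (common random numbers),
#' which keeps the estimated power monotone in n up to Monte-Carlo noise.
#'
#' @param props success probabilities per group.
#' @param target_power target (in (alpha, 1)).
#' @param alpha significance level.
#' @param test,comparison,reference passed to [simulate_power()].
#' @param n_reps Monte-Carlo replicates per evaluation.
#' @param seed seed used for every evaluation.
#' @param n_max upper bound of the search.
#' @return list of class `min_n_result`: n (smallest per-group size with
#'   estimated power >= target), power_at_n, and the evaluation trace.
#' @export
min_n_for_power <- function(props, target_power = 0.8, alpha = 0.05,
                            test = c("steel_dwass", "tukey"),
                            n_reps = 1000L, seed = 1L,
                            comparison = "designated_all",
                            reference = 1L, n_max = 100000L) {
  test <- match.arg(test)
  stopifnot(target_power > alpha, target_power < 1)
  if (length(unique(props)) == 1L)
    stop("all proportions equal: target power unattainable")
  pw <- function(n) simulate_power(props, n, alpha, test, n_reps, seed,
                                   comparison, reference)$power
  trace <- data.frame(n = integer(), power = numeric())
  note <- function(n, p) trace[nrow(trace) + 1L, ] <<- list(n, p)
  lo <- 2L; hi <- 16L
  p_hi <- pw(hi); note(hi, p_hi)
  while (p_hi < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max) stop("target power not reached below n_max")
    p_hi <- pw(hi); note(hi, p_hi)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    p_mid <- pw(mid); note(mid, p_mid)
    if (p_mid >= target_power) hi <- mid else lo <- mid
  }
  structure(list(n = hi, power_at_n = pw(hi), target_power = target_power,
                 trace = trace, test = test, props = props,
                 alpha = alpha, n_reps = n_reps, seed = seed),
            class = "min_n_result")
}

#' @export
print.min_n_result <- function(x, ...) {
  cat(sprintf("Smallest per-group n with power >= %.2f: %d (power %.3f)\n",
              x$target_power, x$n, x$power_at_n))
  invisible(x)
}
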