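# Nonparametric inference procedures implemented from first principles:
# Mann-Whitney U (exact enumeration for small samples, tie-corrected normal
# approximation otherwise), the Steel-Dwass all-pairs rank comparison with
# a Monte-Carlo or studentized-range null, the pairwise logrank test, and
# Tukey's multiple comparison on (arcsine-transformed) proportions.

pairwise_result <- function(labels, pairs, statistic, p, procedure,
                            alpha = 0.05, extra = NULL) {
  out <- data.frame(group1 = labels[pairs[1, ]],
                    group2 = labels[pairs[2, ]],
                    statistic = statistic, p = p,
                    stringsAsFactors = FALSE)
  structure(c(list(pairs = out, procedure = procedure, alpha = alpha),
              extra),
            class = "pairwise_test")
}

#' @export
print.pairwise_test <- function(x, ...) {
  cat(sprintf("%s (alpha = %g)\n", x$procedure, x$alpha))
  df <- x$pairs
  df$p <- signif(df$p, 3)
  df$statistic <- signif(df$statistic, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U is computed from midranks (so ties are handled); the p-value is exact
#' by enumeration of all group assignments when `n1 + n2 <= 12` (or when
#' `exact = TRUE`), otherwise a tie-corrected normal approximation with
#' continuity correction is used.  The exact two-sided p is the permutation
#' probability of a U at least as far from its null mean as observed.
#'
#' @param x,y numeric samples.
#' @param alternative "two.sided", "less" or "greater" (x vs y).
#' @param exact force or forbid enumeration; NULL = automatic.
#' @param correct continuity correction in the normal approximation.
#' @return list of class `mw_test`: U, p, method, n1, n2.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less",
                                                 "greater"),
                           exact = NULL, correct = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (is.null(exact)) exact <- N <= 12
  if (exact) {
    combs <- utils::combn(N, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
                two.sided = mean(abs(Us - mu) >= abs(U - mu) - 1e-9),
                less = mean(Us <= U + 1e-9),
                greater = mean(Us >= U - 1e-9))
    method <- "exact enumeration"
  } else {
    tie <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) return(structure(list(U = U, p = 1,
                                           method = "degenerate",
                                           n1 = n1, n2 = n2),
                                      class = "mw_test"))
    cc <- if (correct) 0.5 else 0
    z2 <- (U - mu - sign(U - mu) * cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z2)),
                less = stats::pnorm((U - mu + cc) / sqrt(sigma2)),
                greater = stats::pnorm((U - mu - cc) / sqrt(sigma2),
                                       lower.tail = FALSE))
    p <- min(p, 1)
    method <- "normal approximation"
  }
  structure(list(U = U, p = p, method = method, n1 = n1, n2 = n2),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.4g (%s; n = %d, %d)\n",
              x$U, x$p, x$method, x$n1, x$n2))
  invisible(x)
}

# standardized pairwise rank statistic on the studentized-range scale:
# sqrt(2) * |W - E W| / sd(W), with midranks and tie correction computed
# within the pair
sd_pair_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (N + 1) / 2
  tie <- table(r)
  VW <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (VW <= 0) return(0)
  sqrt(2) * abs(W - EW) / sqrt(VW)
}

#' Steel-Dwass all-pairs rank comparison
#'
#' For every pair of groups the two-sample rank statistic (midranks, tie
#' corrected) is standardized and referred to the studentized-range null
#' for k groups.  The null distribution is obtained either by Monte-Carlo
#' permutation of the pooled observations (the per-pair p-value is the
#' fraction of permutations whose *maximum* pairwise statistic reaches the
#' observed one, which controls the family-wise error), or from the
#' asymptotic studentized-range distribution.
#'
#' @param groups list of >= 2 numeric vectors (2 groups degenerate to a
#'   Mann-Whitney comparison on the studentized-range scale).
#' @param n_mc Monte-Carlo permutations.
#' @param seed optional seed for the permutations.
#' @param method "monte_carlo" or "asymptotic".
#' @param alpha significance level recorded in the result.
#' @return a `pairwise_test` object.
#' @export
steel_dwass <- function(groups, n_mc = 5000L, seed = NULL,
                        method = c("monte_carlo", "asymptotic"),
                        alpha = 0.05) {
  method <- match.arg(method)
  k <- length(groups)
  stopifnot(k >= 2)
  if (any(vapply(groups, length, 0L) == 0L)) stop("empty group")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  obs <- apply(pairs, 2, function(ij)
    sd_pair_stat(groups[[ij[1]]], groups[[ij[2]]]))
  if (method == "asymptotic") {
    p <- stats::ptukey(obs, k, Inf, lower.tail = FALSE)
  } else {
    pooled <- unlist(groups, use.names = FALSE)
    sizes <- vapply(groups, length, 0L)
    idx_end <- cumsum(sizes)
    idx_start <- idx_end - sizes + 1L
    p <- with_seed(seed, {
      max_null <- vapply(seq_len(n_mc), function(rep) {
        perm <- sample(pooled)
        gs <- lapply(seq_len(k), function(i)
          perm[idx_start[i]:idx_end[i]])
        max(apply(pairs, 2, function(ij)
          sd_pair_stat(gs[[ij[1]]], gs[[ij[2]]])))
      }, numeric(1))
      vapply(obs, function(o) (1 + sum(max_null >= o - 1e-12)) / (n_mc + 1),
             numeric(1))
    })
  }
  pairwise_result(names(groups), pairs, obs, p,
                  sprintf("Steel-Dwass (%s)",
                          if (method == "monte_carlo")
                            sprintf("Monte Carlo, %d reps", n_mc)
                          else "studentized-range asymptotic"),
                  alpha)
}

#' Pairwise logrank test
#'
#' Standard two-group logrank chi-square (observed minus expected events
#' over the hypergeometric variance, summed over event times) for every
#' pair of groups, with multiplicity adjustment of the p-values.
#'
#' @param time event/censoring times.
#' @param event 1 = event (death), 0 = censored.
#' @param group group labels.
#' @param p_adjust adjustment method (see [stats::p.adjust()]).
#' @param alpha significance level recorded in the result.
#' @return a `pairwise_test` object; pairs with zero events get NA p.
#' @export
pairwise_logrank <- function(time, event, group, p_adjust = "holm",
                             alpha = 0.05) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- as.factor(group)
  labs <- levels(group)
  k <- length(labs)
  stopifnot(k >= 2)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    sel <- group %in% labs[ij]
    t <- time[sel]; e <- event[sel]
    g1 <- group[sel] == labs[ij[1]]
    if (sum(e) == 0) return(c(NA_real_, NA_real_))
    ut <- sort(unique(t[e == 1]))
    O1 <- E1 <- V <- 0
    for (u in ut) {
      at <- t >= u
      n <- sum(at); n1 <- sum(at & g1)
      d <- sum(e == 1 & t == u); d1 <- sum(e == 1 & t == u & g1)
      O1 <- O1 + d1
      E1 <- E1 + d * n1 / n
      if (n > 1)
        V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    if (V <= 0) return(c(NA_real_, NA_real_))
    chi <- (O1 - E1)^2 / V
    c(chi, stats::pchisq(chi, 1, lower.tail = FALSE))
  })
  stat <- res[1, ]
  p <- res[2, ]
  ok <- !is.na(p)
  p[ok] <- stats::p.adjust(p[ok], method = p_adjust)
  pairwise_result(labs, pairs, stat, p,
                  sprintf("pairwise logrank (%s-adjusted)", p_adjust),
                  alpha)
}

#' Tukey's multiple comparison on proportions
#'
#' Proportions are variance-stabilized with the angular (arcsine square
#' root) transform, whose sampling variance is 1/(4n); each pair is then
#' compared on the studentized-range scale for k groups:
#' `q = |phi_i - phi_j| / sqrt((1/(4 n_i) + 1/(4 n_j)) / 2)`.
#'
#' @param successes,totals integer vectors per group.
#' @param alpha significance level recorded in the result.
#' @param labels optional group labels.
#' @return a `pairwise_test` object.
#' @export
tukey_proportions <- function(successes, totals, alpha = 0.05,
                              labels = NULL) {
  stopifnot(length(successes) == length(totals), all(totals >= 1),
            all(successes >= 0), all(successes <= totals))
  k <- length(successes)
  stopifnot(k >= 2)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  phi <- asin(sqrt(successes / totals))
  se2 <- 1 / (4 * totals)
  pairs <- utils::combn(k, 2)
  q <- apply(pairs, 2, function(ij)
    abs(phi[ij[1]] - phi[ij[2]]) / sqrt((se2[ij[1]] + se2[ij[2]]) / 2))
  p <- stats::ptukey(q, k, Inf, lower.tail = FALSE)
  pairwise_result(labels, pairs, q, p,
                  "Tukey on arcsine-transformed proportions", alpha)
}
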