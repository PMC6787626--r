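new_test_result <- function(test_name, statistic, p_value, n_per_group, method) {
  structure(
    list(statistic = statistic, p.value = p_value,
         method = paste0(test_name, " (", method, ")"),
         test_name = test_name, n_per_group = n_per_group,
         approx = method, data.name = "grouped values"),
    class = c("wst_test", "htest")
  )
}

#' Mann-Whitney U test
#'
#' Two-sample rank test with midrank tie handling. The statistic is
#' \eqn{U = \#\{x_i > y_j\} + \tfrac12 \#\{x_i = y_j\}} over all pairs.
#' The two-sided p-value uses the exact null distribution when
#' `n1 * n2 <= 400` and there are no ties (or as forced via `exact`), and a
#' tie-corrected normal approximation (no continuity correction, for parity
#' with the two-group Kruskal-Wallis test) otherwise.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact `NULL` (auto rule above), or `TRUE`/`FALSE` to force.
#' @return A `wst_test` (also `htest`) with `statistic` (U), `p.value`,
#'   `n_per_group`, and `approx` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  do_exact <- if (is.null(exact)) (n1 * n2 <= 400 && !has_ties) else isTRUE(exact)
  if (do_exact && has_ties) {
    stop("exact p-value is not available with ties", call. = FALSE)
  }
  if (do_exact) {
    if (u > n1 * n2 / 2) {
      p <- 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(u, n1, n2)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  new_test_result("Mann-Whitney U", c(U = u), p, c(n1, n2), method)
}

#' Kruskal-Wallis rank-sum test
#'
#' k-sample rank test with the standard tie correction; p-value from the
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param groups List of non-empty numeric vectors (k >= 2, total n >= 3).
#' @return A `wst_test` with `statistic` (H) and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  n <- lengths(groups)
  if (any(n == 0)) stop("all groups must be non-empty", call. = FALSE)
  N <- sum(n)
  if (N < 3) stop("need total n >= 3", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  ties <- table(pooled)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_corr == 0) {
    stop("degenerate input: all values tied across all groups", call. = FALSE)
  }
  r <- rank(pooled)
  g <- rep(seq_len(k), n)
  rsum <- tapply(r, g, sum)
  h <- (12 / (N * (N + 1)) * sum(rsum^2 / n) - 3 * (N + 1)) / tie_corr
  p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  new_test_result("Kruskal-Wallis", c(H = h), p, unname(n), "chi_square")
}

# J statistic: sum over ordered group pairs i < j of #{x_i < y_j} + 1/2 ties.
jt_statistic <- function(groups) {
  k <- length(groups)
  j <- 0
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      j <- j + sum(outer(groups[[a]], groups[[b]], "<")) +
        0.5 * sum(outer(groups[[a]], groups[[b]], "=="))
    }
  }
  j
}

# Exact null tail probabilities of J for untied data: under the permutation
# null J is distributed as the sum of independent Mann-Whitney statistics
# U(n_1 + ... + n_{i-1}, n_i), so its distribution is their convolution.
jt_exact_tails_noties <- function(n, j_obs) {
  conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
      ib <- i:(i + length(b) - 1L)
      out[ib] <- out[ib] + a[i] * b
    }
    out
  }
  dist <- 1
  for (i in 2:length(n)) {
    m <- sum(n[seq_len(i - 1L)])
    dist <- conv(dist, stats::dwilcox(0:(m * n[i]), m, n[i]))
  }
  j_idx <- round(j_obs) + 1L  # support 0..sum_{i<j} n_i n_j
  list(p_ge = sum(dist[j_idx:length(dist)]), p_le = sum(dist[1:j_idx]))
}

# Exact null distribution of J by full enumeration of the multinomial
# assignments of the pooled values to the groups (feasible for total n <= 12;
# used when ties make the convolution form inapplicable).
jt_exact_tails <- function(pooled, n, j_obs) {
  k <- length(n)
  stats_env <- new.env()
  stats_env$ge <- 0; stats_env$le <- 0; stats_env$total <- 0
  recurse <- function(remaining_idx, gi, chosen) {
    if (gi == k) {
      groups <- c(chosen, list(pooled[remaining_idx]))
      j <- jt_statistic(groups)
      stats_env$total <- stats_env$total + 1
      if (j >= j_obs - 1e-9) stats_env$ge <- stats_env$ge + 1
      if (j <= j_obs + 1e-9) stats_env$le <- stats_env$le + 1
      return(invisible())
    }
    combos <- utils::combn(remaining_idx, n[gi], simplify = FALSE)
    for (sel in combos) {
      recurse(setdiff(remaining_idx, sel), gi + 1L,
              c(chosen, list(pooled[sel])))
    }
    invisible()
  }
  recurse(seq_along(pooled), 1L, list())
  # distinct index-assignments overcount by permutations within tied values,
  # but the overcount factor is identical in numerator and denominator
  list(p_ge = stats_env$ge / stats_env$total,
       p_le = stats_env$le / stats_env$total)
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone location trend across groups given in a stated
#' (ordinal) order, e.g. increasing severity classes. The statistic is
#' \eqn{J = \sum_{i<j} (\#\{x \in g_i < y \in g_j\} + \tfrac12 ties)}.
#' For total n <= 12 the p-value is exact against the permutation null
#' (computed as a convolution of Mann-Whitney null distributions for untied
#' data, by full enumeration when ties are present); otherwise a
#' tie-corrected normal approximation (Hollander-Wolfe variance, with a 0.5
#' continuity correction) is used. The two-sided p-value is twice the
#' smaller tail probability, capped at 1. The approximation tracks the
#' exact tail to within about 0.02 once every group has at least 3 members;
#' groups of 2 are too coarse for any normal approximation.
#'
#' @param ordered_groups List of non-empty numeric vectors in hypothesised
#'   order (k >= 2).
#' @param alternative `"two_sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @return A `wst_test` with `statistic` (J) and `p.value`.
#' @export
jonckheere_terpstra <- function(ordered_groups,
                                alternative = c("two_sided", "increasing", "decreasing")) {
  alternative <- match.arg(alternative)
  groups <- lapply(ordered_groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2) stop("need at least two ordered groups", call. = FALSE)
  n <- lengths(groups)
  if (any(n == 0)) stop("all groups must be non-empty", call. = FALSE)
  N <- sum(n)
  j <- jt_statistic(groups)
  pooled <- unlist(groups, use.names = FALSE)

  if (N <= 12) {
    has_ties <- any(duplicated(pooled))
    tails <- if (has_ties) jt_exact_tails(pooled, n, j) else
      jt_exact_tails_noties(n, j)
    p <- switch(alternative,
                increasing = tails$p_ge,
                decreasing = tails$p_le,
                two_sided = min(1, 2 * min(tails$p_ge, tails$p_le)))
    method <- "exact"
  } else {
    mu <- (N^2 - sum(n^2)) / 4
    t_sizes <- as.numeric(table(pooled))
    v1 <- (N * (N - 1) * (2 * N + 5) -
             sum(n * (n - 1) * (2 * n + 5)) -
             sum(t_sizes * (t_sizes - 1) * (2 * t_sizes + 5))) / 72
    v2 <- sum(n * (n - 1) * (n - 2)) * sum(t_sizes * (t_sizes - 1) * (t_sizes - 2)) /
      (36 * N * (N - 1) * (N - 2))
    v3 <- sum(n * (n - 1)) * sum(t_sizes * (t_sizes - 1)) / (8 * N * (N - 1))
    sigma2 <- v1 + v2 + v3
    if (sigma2 <= 0) stop("degenerate input: zero-variance permutation null", call. = FALSE)
    s <- sqrt(sigma2)
    p_ge <- stats::pnorm((j - 0.5 - mu) / s, lower.tail = FALSE)
    p_le <- stats::pnorm((j + 0.5 - mu) / s)
    p <- switch(alternative,
                increasing = p_ge,
                decreasing = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    method <- "normal_approx"
  }
  new_test_result("Jonckheere-Terpstra", c(J = j), p, unname(n), method)
}

#' Nonparametric test battery over a marker panel
#'
#' For each marker, runs the Kruskal-Wallis test across the (ordinal)
#' severity classes and the Jonckheere-Terpstra trend test on the same
#' groups in class order, and flags the marker `robust` when both tests are
#' significant at `alpha` -- the dual criterion used to nominate markers
#' whose variation across severity classes is statistically dependable.
#' No multiple-testing correction is applied (a faithful-reproduction
#' choice, not a statistical endorsement).
#'
#' @param table Cohort data frame (scored; see [score_standing_tests()]).
#' @param markers Marker column names.
#' @param group_column Ordinal class column (default `"class3"`).
#' @param alpha Significance level (default 0.05).
#' @return Data frame: `marker`, `kw_statistic`, `kw_p`, `jt_statistic`,
#'   `jt_p`, `jt_method`, `robust`.
#' @export
marker_test_battery <- function(table, markers = default_feature_panel(),
                                group_column = "class3", alpha = 0.05) {
  cls <- table[[group_column]]
  lev <- sort(unique(cls))
  out <- lapply(markers, function(m) {
    groups <- lapply(lev, function(l) table[[m]][cls == l])
    kw <- kruskal_wallis(groups)
    jt <- jonckheere_terpstra(groups)
    data.frame(marker = m,
               kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
               jt_statistic = unname(jt$statistic), jt_p = jt$p.value,
               jt_method = jt$approx,
               robust = kw$p.value <= alpha && jt$p.value <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-group (diagnosis) comparison battery
#'
#' Mann-Whitney U per marker between ME/CFS and healthy-control rows, with
#' the one-sample K-S normality screen alongside, mirroring the published
#' two-cohort comparison table.
#'
#' @inheritParams marker_test_battery
#' @param diagnosis_column Column holding `"ME/CFS"` / `"HC"`.
#' @return Data frame: `marker`, `u_statistic`, `p`, `method`, `ks_p`,
#'   `non_normal`.
#' @export
diagnosis_test_battery <- function(table, markers = default_feature_panel(),
                                   diagnosis_column = "diagnosis", alpha = 0.05) {
  d <- table[[diagnosis_column]]
  out <- lapply(markers, function(m) {
    mw <- mann_whitney_u(table[[m]][d == "ME/CFS"], table[[m]][d == "HC"])
    ks <- ks_normality_screen(table[[m]][!is.na(table[[m]])], alpha = alpha)
    data.frame(marker = m, u_statistic = unname(mw$statistic), p = mw$p.value,
               method = mw$approx, ks_p = ks$p_value, non_normal = ks$non_normal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
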