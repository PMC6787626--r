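test_that("mann_whitney_u statistic and exact p match the enumeration oracle", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)       # all y exceed all x
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r2$statistic), 9 / 2)  # identical multisets: U = n^2/2
  expect_equal(r2$p.value, 1)

  fixtures <- list(
    list(x = c(1, 4, 6), y = c(2, 3, 5)),
    list(x = c(10, 20, 30, 40), y = c(5, 15, 25)),
    list(x = c(1, 2, 3, 9), y = c(4, 5, 6, 7, 8))
  )
  for (f in fixtures) {
    ours <- mann_whitney_u(f$x, f$y)
    oracle <- mw_enum_oracle(f$x, f$y)
    expect_equal(unname(ours$statistic), oracle$u)
    expect_equal(ours$p.value, oracle$p, tolerance = 1e-12)
    expect_identical(ours$approx, "exact")
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
  expect_error(mann_whitney_u(c(1, 1), c(1, 2), exact = TRUE), "ties")
})

test_that("two-group Kruskal-Wallis agrees with the Mann-Whitney normal approximation", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    p_kw <- kruskal_wallis(list(x, y))$p.value
    p_mw <- mann_whitney_u(x, y, exact = FALSE)$p.value
    expect_equal(p_kw, p_mw, tolerance = 0.01)
  }
})

test_that("kruskal_wallis handles ties, degenerate input and tiny fixtures", {
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- kruskal_wallis(g)
  expect_equal(unname(r$statistic), 12 / (6 * 7) * (9 / 2 + 49 / 2 + 121 / 2) - 21)
  # chi-square approximation vs exact permutation oracle at the distribution's
  # extreme point: both in the same (non-significant) regime for n = 6
  p_exact <- kw_perm_oracle(g)
  expect_equal(p_exact, 1 / 15, tolerance = 1e-12)
  expect_lt(abs(r$p.value - p_exact), 0.05)
})

test_that("jonckheere_terpstra reduces to the Mann-Whitney pair count for 2 groups", {
  set.seed(17)
  x <- rnorm(6); y <- rnorm(5)
  j <- jonckheere_terpstra(list(x, y), "increasing")
  expect_equal(unname(j$statistic), sum(outer(x, y, "<")))
})

test_that("jonckheere_terpstra exact p matches full enumeration on the ladder fixture", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- jonckheere_terpstra(g, "increasing")
  expect_equal(unname(r$statistic), 12)  # J at its maximum sum n_i n_j
  expect_equal(r$p.value, 1 / 90, tolerance = 1e-12)
  expect_identical(r$approx, "exact")
  r2 <- jonckheere_terpstra(g, "two_sided")
  expect_equal(r2$p.value, 2 / 90, tolerance = 1e-12)
  # the tie-handling enumeration path agrees with the convolution path
  ours <- wstsev:::jt_exact_tails(unlist(g), lengths(g), 12)
  expect_equal(ours$p_ge, 1 / 90, tolerance = 1e-12)
  expect_error(jonckheere_terpstra(list(1:3)), "two ordered groups")
})

test_that("jonckheere_terpstra exact and approximate tails agree on small fixtures", {
  set.seed(51)
  for (i in 1:15) {
    n <- sample(3:4, 3, replace = TRUE)
    if (sum(n) > 12) n <- c(3, 3, 3)
    vals <- sample(1:500, sum(n))
    g <- split(vals, rep(1:3, n))
    p_exact <- jonckheere_terpstra(g)$p.value
    # force the approximation by replicating the fixture beyond n = 12? no:
    # recompute the approximation directly from the frozen statistic instead
    j <- wstsev:::jt_statistic(g); N <- sum(n)
    mu <- (N^2 - sum(n^2)) / 4
    v <- (N * (N - 1) * (2 * N + 5) - sum(n * (n - 1) * (2 * n + 5))) / 72
    pge <- pnorm((j - 0.5 - mu) / sqrt(v), lower.tail = FALSE)
    ple <- pnorm((j + 0.5 - mu) / sqrt(v))
    p_approx <- min(1, 2 * min(pge, ple))
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("rank tests are invariant under strictly monotone transformations", {
  set.seed(61)
  g <- list(rexp(8), rexp(9) + 0.3, rexp(7) + 0.6)
  trans <- function(x) exp(x)  # strictly increasing
  gt <- lapply(g, trans)
  expect_equal(kruskal_wallis(g)$statistic, kruskal_wallis(gt)$statistic)
  expect_equal(kruskal_wallis(g)$p.value, kruskal_wallis(gt)$p.value)
  expect_equal(jonckheere_terpstra(g)$statistic, jonckheere_terpstra(gt)$statistic)
  expect_equal(jonckheere_terpstra(g)$p.value, jonckheere_terpstra(gt)$p.value)
  x <- rnorm(12); y <- rnorm(10)
  expect_equal(mann_whitney_u(x, y)$p.value,
               mann_whitney_u(trans(x), trans(y))$p.value)
})

test_that("marker_test_battery applies the dual KW + J-T robustness criterion", {
  co <- make_separable_cohort(n_per_class = 25, seed = 8)
  bat <- marker_test_battery(co, c("urinary_creatinine", "alp"), "class3")
  expect_true(bat$robust[bat$marker == "urinary_creatinine"])  # the shifted marker
  expect_false(bat$robust[bat$marker == "alp"])                # pure noise
  expect_true(all(bat$kw_p >= 0 & bat$kw_p <= 1))
  expect_true(all(bat$jt_p >= 0 & bat$jt_p <= 1))
})
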