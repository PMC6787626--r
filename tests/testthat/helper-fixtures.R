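# Shared fixtures and independent oracles, built in code at test time.

# A strongly separable synthetic cohort: one marker's class-conditional
# distributions are shifted by ~3 IQR widths between the merged severity
# classes, the other panel markers are identically distributed noise.
# 4-class sizes are chosen so the merged classes have n_per_class each.
separable_specs <- function(shift_marker = "urinary_creatinine") {
  markers <- default_feature_panel()
  rows <- lapply(markers, function(m) {
    if (m == shift_marker) {
      # IQR width 2 around each median; adjacent merged-class medians 6 apart
      med <- c(10, 10, 16, 22)      # class4 = 0,1 -> merged 0; 2 -> 1; 3 -> 2
    } else {
      med <- rep(10, 4)
    }
    data.frame(marker = m, class4 = 0:3, median = med,
               q25 = med - 1, q75 = med + 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

make_separable_cohort <- function(n_per_class = 40L, seed = 1L) {
  n0 <- n_per_class %/% 2L
  cfg <- cohort_config(
    class_sizes = c(`0` = n0, `1` = n_per_class - n0,
                    `2` = n_per_class, `3` = n_per_class),
    marker_specs = separable_specs(),
    urine_missing_rate = 0, seed = seed
  )
  score_standing_tests(generate_cohort(cfg))
}

# Brute-force Mann-Whitney oracle: exact two-sided p by enumerating all
# C(n1+n2, n1) label assignments of the pooled (untied) values.
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(xi, yi) {
    sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  }
  u_obs <- u_of(x, y)
  us <- utils::combn(seq_along(pooled), n1, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  mu <- n1 * (length(pooled) - n1) / 2
  # two-sided: double the smaller tail (matching the exact wilcox convention)
  p <- if (u_obs > mu) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  list(u = u_obs, p = min(1, p))
}

# Exact permutation distribution of the Kruskal-Wallis H for tiny fixtures.
kw_perm_oracle <- function(groups) {
  n <- lengths(groups)
  pooled <- unlist(groups)
  h_of <- function(gs) unname(kruskal_wallis(gs)$statistic)
  h_obs <- h_of(groups)
  count <- 0; total <- 0
  rec <- function(remaining, gi, acc) {
    if (gi == length(n)) {
      gs <- c(acc, list(pooled[remaining]))
      total <<- total + 1
      if (h_of(gs) >= h_obs - 1e-9) count <<- count + 1
      return(invisible())
    }
    for (sel in utils::combn(remaining, n[gi], simplify = FALSE)) {
      rec(setdiff(remaining, sel), gi + 1L, c(acc, list(pooled[sel])))
    }
  }
  rec(seq_along(pooled), 1L, list())
  count / total
}
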