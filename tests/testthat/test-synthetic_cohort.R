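test_that("fit_lognormal_from_quantiles inverts the closed form", {
  z75 <- qnorm(0.75)
  par <- fit_lognormal_from_quantiles(100, 100 * exp(-z75 * 0.3), 100 * exp(z75 * 0.3))
  expect_equal(par$meanlog, log(100))
  expect_equal(par$sdlog, 0.3)
  # degenerate point mass
  expect_equal(fit_lognormal_from_quantiles(1, 1, 1),
               data.frame(meanlog = 0, sdlog = 0))
  # published activin B row (ME/CFS cohort): 85.95 (70.48-125.76)
  par <- fit_lognormal_from_quantiles(85.95, 70.48, 125.76)
  expect_equal(par$sdlog, log(125.76 / 70.48) / (2 * z75))
  expect_error(fit_lognormal_from_quantiles(-1, 1, 2), "positive")
  expect_error(fit_lognormal_from_quantiles(3, 2, 2.5), "q25 <= median <= q75")
})

test_that("fitted distribution reproduces median and IQR ratio in simulation", {
  set.seed(11)
  par <- fit_lognormal_from_quantiles(85.95, 70.48, 125.76)
  draws <- rlnorm(2e5, par$meanlog, par$sdlog)
  q <- quantile(draws, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(q[2], 85.95, tolerance = 0.01)
  expect_equal(q[3] / q[1], 125.76 / 70.48, tolerance = 0.02)
})

test_that("generate_cohort reproduces the study's class structure", {
  co <- generate_cohort(cohort_config(seed = 42))
  expect_identical(nrow(co), 97L)
  cls <- classify_severity(co$diagnosis, co$standing_time, co$difficulty)
  expect_identical(as.vector(table(cls)), c(17L, 19L, 38L, 23L))
  expect_identical(sum(merge_classes(cls) == 0), 36L)
  # every generated (time, difficulty) pair recovers its intended class
  intended <- rep(0:3, default_class_sizes())
  expect_identical(cls, as.integer(intended))
})

test_that("generation is deterministic and zero-size classes are allowed", {
  cfg <- cohort_config(seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg0 <- cohort_config(class_sizes = c(`0` = 0L, `1` = 5L, `2` = 5L, `3` = 5L),
                        seed = 1)
  co <- generate_cohort(cfg0)
  expect_identical(nrow(co), 15L)
  expect_false(any(co$diagnosis == "HC"))
})

test_that("generator recovers its own spec medians at n = 2000/class", {
  spec <- data.frame(marker = "activin_b", class4 = 0:3,
                     median = c(103.36, 80.73, 89.74, 95),
                     q25 = c(78.57, 71.27, 70.48, 80),
                     q75 = c(148.78, 107.81, 133.19, 110))
  cfg <- cohort_config(class_sizes = stats::setNames(rep(2000L, 4), 0:3),
                       marker_specs = spec, urine_missing_rate = 0,
                       missing_markers = character(0), seed = 9)
  co <- generate_cohort(cfg)
  cls <- rep(0:3, each = 2000)
  for (cl in 0:3) {
    emp <- median(co$activin_b[cls == cl])
    expect_lt(abs(emp - spec$median[cl + 1]) / spec$median[cl + 1], 0.05)
  }
})

test_that("missing marker spec for a generated class errors", {
  spec <- separable_specs()
  spec <- spec[!(spec$marker == "alp" & spec$class4 == 2), ]
  cfg <- cohort_config(class_sizes = c(`0` = 2L, `1` = 2L, `2` = 2L, `3` = 2L),
                       marker_specs = spec, urine_missing_rate = 0)
  expect_error(generate_cohort(cfg), "spec missing")
})

test_that("inject_missingness hits its rate and respects scope", {
  co <- make_separable_cohort(n_per_class = 10, seed = 2)
  expect_identical(inject_missingness(co, "alp", rate = 0), co)
  expect_error(inject_missingness(co, "nonexistent", rate = 0.1), "unknown marker")
  expect_error(inject_missingness(co, "alp", rate = 1), "rate")

  big <- data.frame(a = rnorm(1e4), b = rnorm(1e4))
  out <- inject_missingness(big, "a", rate = 0.175, seed = 4)
  frac <- mean(is.na(out$a))
  # 99% binomial interval around 0.175 at n = 1e4 is within [0.15, 0.20]
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.20)
  expect_false(anyNA(out$b))

  both <- inject_missingness(big, c("a", "b"), rate = 0.5, seed = 5)
  expect_equal(mean(is.na(both$a)), 0.5, tolerance = 0.05)
  expect_equal(mean(is.na(both$b)), 0.5, tolerance = 0.05)
  # independence: association between the two missingness masks is null
  tab <- table(is.na(both$a), is.na(both$b))
  chi <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(chi$p.value, 0.001)
})

test_that("cohort round-trips through CSV with missing fields", {
  co <- generate_cohort(cohort_config(seed = 3))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  msgs <- capture_messages(back <- read_cohort(path))
  expect_match(msgs, "97 rows", all = FALSE)
  expect_match(msgs, "urinary_creatinine", all = FALSE)
  expect_equal(back, co, tolerance = 1e-12)

  bad <- co[, setdiff(names(co), "standing_time")]
  write_cohort(bad, path)
  expect_error(suppressMessages(read_cohort(path)), "standing_time")

  co2 <- co
  co2$alp <- as.character(co2$alp)
  co2$alp[3] <- "oops"
  write_cohort(co2, path)
  expect_error(suppressMessages(read_cohort(path)), "non-numeric.*alp|alp.*row 3")
})
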