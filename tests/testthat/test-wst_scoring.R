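test_that("weighted_standing_time reproduces the published class boundaries", {
  expect_equal(round(weighted_standing_time(20, 1), 2), 18.57)
  expect_equal(round(weighted_standing_time(20, 4), 2), 14.29)
  expect_equal(round(weighted_standing_time(20, 3), 2), 15.71)
  expect_equal(round(weighted_standing_time(18, 12), 2), 2.57)
  expect_equal(weighted_standing_time(20, 7), 10)
  expect_equal(weighted_standing_time(c(4, 12, 16), 14), c(0, 0, 0))
})

test_that("weighted_standing_time rejects invalid inputs", {
  expect_error(weighted_standing_time(20, 11), "difficulty")
  expect_error(weighted_standing_time(20, 13), "difficulty")
  expect_error(weighted_standing_time(20, 15), "difficulty")
  expect_error(weighted_standing_time(7, 3), "grid")
  expect_error(weighted_standing_time(22, 3), "grid")
})

test_that("WST is monotone in time and difficulty", {
  times <- seq(0, 20, by = 2)
  codes <- c(0:10, 12, 14)
  for (t in times) {
    w <- weighted_standing_time(rep(t, length(codes)), codes)
    expect_true(all(diff(w) <= 1e-12), info = paste("time", t))
  }
  for (d in codes) {
    w <- weighted_standing_time(times, rep(d, length(times)))
    expect_true(all(diff(w) >= -1e-12), info = paste("difficulty", d))
  }
})

test_that("theoretical class ranges match the printed table for classes 0, 1, 3", {
  r <- wst_class_ranges()
  expect_equal(r[r$class4 == 0, c("wst_min", "wst_max")],
               data.frame(wst_min = 14.29, wst_max = 18.57, row.names = 1L))
  expect_equal(r[r$class4 == 1, ]$wst_min, 15.71)
  expect_equal(r[r$class4 == 1, ]$wst_max, 18.57)
  expect_equal(r[r$class4 == 3, ]$wst_min, 0)
  expect_equal(r[r$class4 == 3, ]$wst_max, 2.57)
  # class 2: theoretical lower bound (5.71) deliberately differs from the
  # printed observed minimum (6.43); upper bound agrees
  expect_equal(r[r$class4 == 2, ]$wst_min, 5.71)
  expect_equal(r[r$class4 == 2, ]$wst_max, 14.29)
})

test_that("assign_difficulty_code applies the time rules", {
  expect_identical(assign_difficulty_code(8, 5), 14L)
  expect_identical(assign_difficulty_code(14, 5), 12L)
  expect_identical(assign_difficulty_code(20, 4), 4L)
  expect_identical(assign_difficulty_code(c(0, 10, 20), c(NA, NA, 0)),
                   c(14L, 12L, 0L))
  expect_error(assign_difficulty_code(20, NA), "required")
  expect_error(assign_difficulty_code(20, 11), "0-10")
})

test_that("detect_pots uses the >= 30 bpm threshold", {
  expect_true(detect_pots(70, 100))
  expect_false(detect_pots(70, 99))
  expect_false(detect_pots(70, 70))
  expect_identical(detect_pots(c(60, 60), c(95, 80)), c(TRUE, FALSE))
  expect_error(detect_pots(0, 90), "positive")
  expect_error(detect_pots(70, -1), "positive")
})

test_that("classify_severity implements the class definitions", {
  expect_identical(classify_severity("HC", 20, 2), 0L)
  expect_identical(classify_severity("ME/CFS", 20, 4), 2L)
  expect_identical(classify_severity("ME/CFS", 12, 12), 3L)
  expect_identical(classify_severity("ME/CFS", 20, 3), 1L)
  # difficulty 0 is a legal scale value: mild for a full-time ME/CFS case
  expect_identical(classify_severity("ME/CFS", 20, 0), 1L)
  # diagnosis is primary at the ambiguous difficulty 4
  expect_identical(classify_severity("HC", 20, 4), 0L)
  # HC with a partial-stand code: anomaly warning, class 0 retained
  expect_warning(cls <- classify_severity("HC", 8, 14), "anomaly")
  expect_identical(cls, 0L)
  # inconsistent code/time pairings are rejected
  expect_error(classify_severity("ME/CFS", 20, 12), "inconsistent")
  expect_error(classify_severity("ME/CFS", 12, 14), "inconsistent")
  expect_error(classify_severity("ME/CFS", 12, 5), "inconsistent")
})

test_that("merge_classes pools healthy with mild", {
  expect_identical(merge_classes(0:3), c(0L, 0L, 1L, 2L))
  expect_error(merge_classes(4), "class4")
})

test_that("score_standing_tests adds the derived columns", {
  co <- make_separable_cohort(n_per_class = 10, seed = 3)
  expect_true(all(c("wst", "class4", "class3", "pots") %in% names(co)))
  expect_true(all(co$wst >= 0 & co$wst <= 20))
  expect_identical(co$class3, merge_classes(co$class4))
  tab <- data.frame(diagnosis = "HC", standing_time = 20)
  expect_error(score_standing_tests(tab), "lacks column")
})
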