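#' Weighted standing time (WST)
#'
#' The WST statistic down-weights the time a participant remained upright
#' during a 20-minute orthostatic-intolerance standing test by their
#' subjective standing-difficulty score:
#' \deqn{WST = t \times (1 - d / 14)}
#' where \eqn{t} is standing time in minutes on the 2-minute grid
#' \{0, 2, ..., 20\} and \eqn{d} is the difficulty code: the ordinal 0-10
#' scale for participants who stood the full 20 minutes, code 12 for those
#' who stood at least 10 but under 20 minutes, and code 14 for those unable
#' to stand 10 minutes. WST is a proxy for ME/CFS symptom severity and is
#' the basis of the severity classes assigned by [classify_severity()].
#'
#' @param standing_time Numeric vector, minutes on the grid \{0, 2, ..., 20\}.
#' @param difficulty Integer vector of difficulty codes: 0-10, 12 or 14.
#'   Codes 11, 13 and values above 14 are invalid.
#' @return Numeric vector of unrounded WST values in weighted minutes
#'   (0-20). For presentation the field rounds to 2 decimals; classification
#'   never uses the rounded value.
#' @examples
#' weighted_standing_time(20, 1)            # 18.571...
#' round(weighted_standing_time(18, 12), 2) # 2.57
#' @export
weighted_standing_time <- function(standing_time, difficulty) {
  check_standing_time(standing_time)
  check_difficulty(difficulty)
  standing_time * (1 - difficulty / 14)
}

check_standing_time <- function(standing_time) {
  if (!is.numeric(standing_time) || anyNA(standing_time)) {
    stop("standing_time must be numeric with no missing values", call. = FALSE)
  }
  on_grid <- standing_time >= 0 & standing_time <= 20 &
    abs(standing_time / 2 - round(standing_time / 2)) < 1e-8
  if (!all(on_grid)) {
    stop("standing_time must lie on the 2-minute grid {0, 2, ..., 20}; bad value(s): ",
         paste(unique(standing_time[!on_grid]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

check_difficulty <- function(difficulty) {
  if (!is.numeric(difficulty) || anyNA(difficulty)) {
    stop("difficulty must be numeric with no missing values", call. = FALSE)
  }
  ok <- difficulty %in% c(0:10, 12, 14)
  if (!all(ok)) {
    stop("difficulty must be in {0..10, 12, 14}; bad value(s): ",
         paste(unique(difficulty[!ok]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign the standing-difficulty code from the test outcome
#'
#' Participants unable to stand at least 10 minutes are coded 14; those who
#' stood 10 or more but under 20 minutes are coded 12; only participants who
#' completed the full 20 minutes carry their self-reported 0-10 difficulty.
#'
#' @param standing_time Numeric vector on the 2-minute grid.
#' @param reported_difficulty Self-reported 0-10 score; required (non-`NA`)
#'   whenever `standing_time == 20`, ignored otherwise.
#' @return Integer vector of difficulty codes in \{0..10, 12, 14\}.
#' @export
assign_difficulty_code <- function(standing_time, reported_difficulty = NA) {
  check_standing_time(standing_time)
  n <- max(length(standing_time), length(reported_difficulty))
  standing_time <- rep_len(standing_time, n)
  reported_difficulty <- rep_len(reported_difficulty, n)
  code <- integer(n)
  code[standing_time < 10] <- 14L
  code[standing_time >= 10 & standing_time < 20] <- 12L
  full <- standing_time == 20
  if (any(full)) {
    rd <- reported_difficulty[full]
    if (anyNA(rd)) {
      stop("reported_difficulty is required for participants standing the full 20 min",
           call. = FALSE)
    }
    if (!all(rd %in% 0:10)) {
      stop("reported_difficulty must be an integer in 0-10", call. = FALSE)
    }
    code[full] <- as.integer(rd)
  }
  code
}

#' Detect postural orthostatic tachycardia syndrome (POTS)
#'
#' POTS is operationalised as a heart-rate increase of at least 30 bpm on
#' standing from a lying position.
#'
#' @param hr_supine,hr_standing_max Positive heart rates in bpm: at repose
#'   and the maximum recorded while standing.
#' @return Logical vector: `TRUE` iff `hr_standing_max - hr_supine >= 30`.
#' @export
detect_pots <- function(hr_supine, hr_standing_max) {
  if (!is.numeric(hr_supine) || !is.numeric(hr_standing_max) ||
      anyNA(hr_supine) || anyNA(hr_standing_max) ||
      any(hr_supine <= 0) || any(hr_standing_max <= 0)) {
    stop("heart rates must be positive and non-missing", call. = FALSE)
  }
  (hr_standing_max - hr_supine) >= 30
}

#' Assign the 4-class WST severity label
#'
#' Severity classes from the standing test, given an ME/CFS or healthy
#' control (HC) diagnosis:
#' \itemize{
#'   \item class 0 -- healthy control (no disease);
#'   \item class 1 -- mild: ME/CFS, stood 20 min at difficulty 0-3;
#'   \item class 2 -- moderate: ME/CFS, stood 20 min at difficulty 4-10;
#'   \item class 3 -- severe: ME/CFS, under 20 min standing (code 12 or 14).
#' }
#' Diagnosis is primary: a difficulty of 4 is class 0 for a control and
#' class 2 for an ME/CFS case (mild is explicitly 0-3). A control carrying
#' code 12/14 is a protocol anomaly: a warning is emitted and class 0 kept.
#'
#' @param diagnosis Character vector, `"ME/CFS"` or `"HC"`.
#' @param standing_time Minutes on the 2-minute grid.
#' @param difficulty Difficulty code from [assign_difficulty_code()].
#' @return Integer vector of classes 0-3.
#' @export
classify_severity <- function(diagnosis, standing_time, difficulty) {
  if (!all(diagnosis %in% c("ME/CFS", "HC"))) {
    stop('diagnosis must be "ME/CFS" or "HC"', call. = FALSE)
  }
  check_standing_time(standing_time)
  check_difficulty(difficulty)
  n <- max(length(diagnosis), length(standing_time), length(difficulty))
  diagnosis <- rep_len(diagnosis, n)
  standing_time <- rep_len(standing_time, n)
  difficulty <- rep_len(difficulty, n)

  partial <- difficulty %in% c(12, 14)
  bad14 <- difficulty == 14 & standing_time >= 10
  bad12 <- difficulty == 12 & (standing_time < 10 | standing_time >= 20)
  bad10 <- difficulty <= 10 & standing_time < 20
  if (any(bad14 | bad12 | bad10)) {
    stop("difficulty code inconsistent with standing time (14: <10 min; ",
         "12: 10-18 min; 0-10: full 20 min)", call. = FALSE)
  }

  cls <- integer(n)
  hc <- diagnosis == "HC"
  if (any(hc & partial)) {
    warning("healthy control(s) with difficulty code 12/14: protocol anomaly, class 0 retained",
            call. = FALSE)
  }
  me <- !hc
  cls[me & partial] <- 3L
  cls[me & !partial & difficulty <= 3] <- 1L
  cls[me & !partial & difficulty >= 4] <- 2L
  cls
}

#' Merge the 4-class severity labels into the 3-class scheme
#'
#' Healthy controls (0) and mild cases (1) are pooled into a single merged
#' class 0 to give workable class sizes for machine learning; moderate (2)
#' becomes 1 and severe (3) becomes 2.
#'
#' @param class4 Integer vector of 4-class labels in \{0, 1, 2, 3\}.
#' @return Integer vector of merged 3-class labels in \{0, 1, 2\}.
#' @export
merge_classes <- function(class4) {
  if (!all(class4 %in% 0:3)) stop("class4 must be in {0, 1, 2, 3}", call. = FALSE)
  c(0L, 0L, 1L, 2L)[class4 + 1L]
}

#' Theoretical WST range of each severity class
#'
#' Enumerates every (standing time, difficulty) pair consistent with a
#' class's definition and returns the minimum and maximum WST, rounded to
#' 2 decimals. Classes 0, 1 and 3 reproduce the published boundaries
#' (14.29-18.57, 15.71-18.57, 0.00-2.57); the class-2 theoretical lower
#' bound is 5.71 (20 min at difficulty 10), whereas published tables print
#' the observed cohort minimum 6.43.
#'
#' @return Data frame with columns `class4`, `wst_min`, `wst_max`.
#' @export
wst_class_ranges <- function() {
  grids <- list(
    `0` = expand.grid(time = 20, difficulty = 1:4),
    `1` = expand.grid(time = 20, difficulty = 1:3),
    `2` = expand.grid(time = 20, difficulty = 4:10),
    `3` = {
      t3 <- seq(0, 18, by = 2)
      data.frame(time = t3, difficulty = ifelse(t3 < 10, 14L, 12L))
    }
  )
  out <- lapply(names(grids), function(cl) {
    g <- grids[[cl]]
    w <- weighted_standing_time(g$time, g$difficulty)
    data.frame(class4 = as.integer(cl),
               wst_min = round(min(w), 2), wst_max = round(max(w), 2))
  })
  do.call(rbind, out)
}

#' Score the standing tests of a cohort table
#'
#' Adds `wst` (rounded to 2 decimals), `class4`, `class3` and `pots`
#' columns computed from `standing_time`, `difficulty`, `hr_supine`,
#' `hr_standing_max` and `diagnosis`. Classification uses the raw
#' time/difficulty values, never the rounded WST.
#'
#' @param table Cohort data frame (see [read_cohort()] for the schema).
#' @return The table with the four derived columns appended/overwritten.
#' @export
score_standing_tests <- function(table) {
  need <- c("diagnosis", "standing_time", "difficulty", "hr_supine", "hr_standing_max")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  table$wst <- round(weighted_standing_time(table$standing_time, table$difficulty), 2)
  table$class4 <- classify_severity(table$diagnosis, table$standing_time, table$difficulty)
  table$class3 <- merge_classes(table$class4)
  table$pots <- detect_pots(table$hr_supine, table$hr_standing_max)
  table
}
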